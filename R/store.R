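# ---- binary record codec ----------------------------------------------------
#
# Segment record layout (little-endian):
#   [record_length u32][offset u64][timestamp u64]
#   [key_length i32 (-1 = no key)][key bytes]
#   [value_length i32 (-1 = tombstone)][value bytes]
# Self-delimiting and crash-truncatable: a partial record at the tail of a
# segment is ignored when the store is reopened.

enc_u32 <- function(x) {
  out <- raw(4L)
  for (i in 1:4) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

enc_u64 <- function(x) {
  out <- raw(8L)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

enc_i32 <- function(x) enc_u32(if (x < 0) x + 4294967296 else x)

dec_uint <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))

dec_i32 <- function(bytes) {
  u <- dec_uint(bytes)
  if (u >= 2147483648) u - 4294967296 else u
}

encode_record <- function(offset, timestamp, key, value) {
  klen <- if (is.null(key)) -1L else length(key)
  vlen <- if (is.null(value)) -1L else length(value)
  body <- c(enc_u64(offset), enc_u64(timestamp), enc_i32(klen), key,
            enc_i32(vlen), value)
  c(enc_u32(length(body)), body)
}

# Parse a whole segment file. Returns list(msgs, offs); silently drops a
# truncated trailing record (crash recovery).
scan_segment <- function(path, topic_name, partition) {
  msgs <- list()
  offs <- numeric(0)
  if (!file.exists(path) || file.size(path) == 0) {
    return(list(msgs = msgs, offs = offs))
  }
  data <- readBin(path, "raw", n = file.size(path))
  len <- length(data)
  pos <- 1
  while (pos + 3 <= len) {
    reclen <- dec_uint(data[pos:(pos + 3)])
    if (pos + 3 + reclen > len) break
    body <- data[(pos + 4):(pos + 3 + reclen)]
    off <- dec_uint(body[1:8])
    ts <- dec_uint(body[9:16])
    cur <- 17
    klen <- dec_i32(body[cur:(cur + 3)])
    cur <- cur + 4
    key <- NULL
    if (klen >= 0) {
      key <- if (klen > 0) body[cur:(cur + klen - 1)] else raw(0)
      cur <- cur + klen
    }
    vlen <- dec_i32(body[cur:(cur + 3)])
    cur <- cur + 4
    value <- NULL
    if (vlen >= 0) {
      value <- if (vlen > 0) body[cur:(cur + vlen - 1)] else raw(0)
    }
    msgs[[length(msgs) + 1L]] <- new_message(topic_name, partition, off, ts,
                                             key, value)
    offs <- c(offs, off)
    pos <- pos + 4 + reclen
  }
  list(msgs = msgs, offs = offs)
}

new_message <- function(topic, partition, offset, timestamp, key, value) {
  structure(
    list(topic = topic, partition = partition, offset = offset,
         timestamp = timestamp, key = key, value = value),
    class = "log_message"
  )
}

#' @export
print.log_message <- function(x, ...) {
  k <- if (is.null(x$key)) "<none>" else msg_text(x$key)
  v <- if (is.null(x$value)) "<tombstone>" else {
    txt <- msg_text(x$value)
    if (nchar(txt) > 40) paste0(substr(txt, 1, 40), "...") else txt
  }
  cat(sprintf("<message %s[%d]@%s key=%s value=%s>\n",
              x$topic, x$partition, format(x$offset, scientific = FALSE),
              k, v))
  invisible(x)
}

# Printable form of raw key/value bytes; non-ASCII/NUL bytes are escaped.
msg_text <- function(bytes) {
  if (is.null(bytes)) return(NA_character_)
  if (any(bytes == as.raw(0L))) {
    return(paste0("0x", paste(as.character(bytes), collapse = "")))
  }
  rawToChar(bytes)
}

#' A message is a tombstone when it carries a key but no value
#' @param msg a `log_message`.
#' @return logical scalar.
#' @export
is_tombstone <- function(msg) !is.null(msg$key) && is.null(msg$value)

# ---- store and topic handles ------------------------------------------------

#' Open or create a file-backed log store
#'
#' A store is a directory holding one sub-directory per topic (segment file
#' per partition plus a JSON metadata file) and a `_groups/` directory for
#' consumer-group state. Replication is modelled as placement metadata over
#' `n_brokers` simulated brokers; no bytes are copied.
#'
#' @param root directory path; created if absent. Reopening an existing
#'   store rescans its segment files, so appends from a previous process
#'   are recovered.
#' @param n_brokers number of simulated brokers available for replica
#'   placement (ignored when reopening an existing store, which keeps its
#'   original broker count).
#' @param clock a zero-argument function returning the current time in
#'   integer milliseconds since epoch, used to timestamp appended
#'   messages. Injectable for deterministic tests; defaults to the system
#'   clock.
#' @return a `log_store` handle.
#' @examples
#' st <- log_store(tempfile("store"))
#' tp <- create_topic(st, topic_spec("demo", n_partitions = 2))
#' topic_append(tp, 0, key = "k1", value = "hello")
#' end_offsets(tp)
#' @export
log_store <- function(root, n_brokers = 3L, clock = NULL) {
  meta_path <- file.path(root, "store.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    n_brokers <- as.integer(meta$n_brokers)
  } else {
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(root, "_groups"), showWarnings = FALSE)
    jsonlite::write_json(list(n_brokers = as.integer(n_brokers)), meta_path,
                         auto_unbox = TRUE)
  }
  if (is.null(clock)) {
    clock <- function() floor(as.numeric(Sys.time()) * 1000)
  }
  store <- new.env(parent = emptyenv())
  store$root <- normalizePath(root)
  store$n_brokers <- as.integer(n_brokers)
  store$clock <- clock
  store$topics <- new.env(parent = emptyenv())
  store$groups <- new.env(parent = emptyenv())
  class(store) <- "log_store"
  # abandoned stores still record their offset watermarks on collection
  reg.finalizer(store, function(e) {
    suppressWarnings(try(close_store(e), silent = TRUE))
  }, onexit = TRUE)
  store
}

#' @export
print.log_store <- function(x, ...) {
  cat(sprintf("<log_store %s: %d topics, %d simulated brokers>\n",
              x$root, length(list_topics(x)), x$n_brokers))
  invisible(x)
}

#' Describe a topic: name, partition count, replication, compaction flag
#'
#' @param name topic name. Must not start with `_` (reserved) and may use
#'   letters, digits, `.`, `-` and `_`.
#' @param n_partitions number of partitions, `N >= 1`. The partition is the
#'   unit of parallel consumption: `N` group members can drain the topic
#'   in concert.
#' @param replication_factor number of simulated brokers each partition is
#'   placed on, `R >= 1`; any `R - 1` broker failures leave at least one
#'   replica of every partition.
#' @param compacted whether the topic is eligible for key-based log
#'   compaction (see [compact_partition()]).
#' @return a `topic_spec` object.
#' @export
topic_spec <- function(name, n_partitions, replication_factor = 1L,
                       compacted = FALSE) {
  if (!is.character(name) || length(name) != 1L ||
      !grepl("^[A-Za-z0-9][A-Za-z0-9._-]*$", name)) {
    stop("invalid topic name: ", deparse(name))
  }
  n_partitions <- as.integer(n_partitions)
  replication_factor <- as.integer(replication_factor)
  if (is.na(n_partitions) || n_partitions < 1L) {
    stop("n_partitions must be a positive integer")
  }
  if (is.na(replication_factor) || replication_factor < 1L) {
    stop("replication_factor must be a positive integer")
  }
  structure(
    list(name = name, n_partitions = n_partitions,
         replication_factor = replication_factor,
         compacted = isTRUE(compacted)),
    class = "topic_spec"
  )
}

topic_dir <- function(store, name) file.path(store$root, name)

topic_meta_path <- function(store, name) {
  file.path(topic_dir(store, name), "meta.json")
}

#' Create a topic with empty partitions and round-robin replica placement
#'
#' Partition `i` is placed on simulated brokers
#' `(i, i+1, ..., i+R-1) mod B` where `B` is the store's broker count, so
#' placements are spread evenly and any `R - 1` broker failures leave at
#' least one replica of every partition.
#'
#' @param store a [log_store()].
#' @param spec a [topic_spec()].
#' @return a topic handle.
#' @export
create_topic <- function(store, spec) {
  stopifnot(inherits(store, "log_store"), inherits(spec, "topic_spec"))
  if (topic_exists(store, spec$name)) {
    stop("topic exists: ", spec$name)
  }
  if (spec$replication_factor > store$n_brokers) {
    stop(sprintf("replication factor %d exceeds broker count %d",
                 spec$replication_factor, store$n_brokers))
  }
  dir <- topic_dir(store, spec$name)
  dir.create(dir, recursive = TRUE)
  placements <- lapply(seq_len(spec$n_partitions) - 1L, function(i) {
    (i + seq_len(spec$replication_factor) - 1L) %% store$n_brokers
  })
  write_topic_meta(store, spec, placements,
                   next_offsets = rep(0, spec$n_partitions))
  open_topic(store, spec$name)
}

write_topic_meta <- function(store, spec, placements, next_offsets) {
  jsonlite::write_json(
    list(spec = unclass(spec), placements = placements,
         next_offsets = next_offsets),
    topic_meta_path(store, spec$name),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname create_topic
#' @param name topic name.
#' @export
topic_exists <- function(store, name) {
  file.exists(topic_meta_path(store, name))
}

#' @rdname create_topic
#' @export
list_topics <- function(store) {
  dirs <- list.dirs(store$root, recursive = FALSE, full.names = FALSE)
  dirs[!startsWith(dirs, "_") &
         vapply(dirs, function(d) topic_exists(store, d), logical(1))]
}

#' Open a handle on an existing topic
#'
#' Rescans the partition segment files, recovering offsets written by a
#' previous process. Handles are cached per store.
#'
#' @inheritParams create_topic
#' @param name topic name.
#' @return a topic handle.
#' @export
open_topic <- function(store, name) {
  if (!is.null(store$topics[[name]])) {
    return(store$topics[[name]])
  }
  if (!topic_exists(store, name)) {
    stop("unknown topic: ", name)
  }
  meta <- jsonlite::read_json(topic_meta_path(store, name))
  spec <- topic_spec(meta$spec$name, meta$spec$n_partitions,
                     meta$spec$replication_factor, meta$spec$compacted)
  placements <- lapply(meta$placements, function(p) as.integer(unlist(p)))
  meta_next <- as.numeric(unlist(meta$next_offsets))
  topic <- new.env(parent = emptyenv())
  topic$store <- store
  topic$name <- name
  topic$spec <- spec
  topic$placements <- placements
  topic$dir <- topic_dir(store, name)
  topic$parts <- lapply(seq_len(spec$n_partitions) - 1L, function(i) {
    path <- file.path(topic$dir, sprintf("%d.log", i))
    seg <- scan_segment(path, name, i)
    part <- new.env(parent = emptyenv())
    part$index <- i
    part$path <- path
    part$msgs <- seg$msgs
    part$offs <- seg$offs
    part$n <- length(seg$msgs)
    scanned_next <- if (part$n > 0) seg$offs[part$n] + 1 else 0
    # compaction may have removed the youngest record; the metadata
    # watermark keeps offsets from being reused
    part$next_offset <- max(scanned_next, meta_next[i + 1L])
    part
  })
  class(topic) <- "log_topic"
  store$topics[[name]] <- topic
  topic
}

#' @export
print.log_topic <- function(x, ...) {
  cat(sprintf("<topic %s: N=%d R=%d%s, %s messages retained>\n",
              x$name, x$spec$n_partitions, x$spec$replication_factor,
              if (x$spec$compacted) " compacted" else "",
              format(topic_size(x), scientific = FALSE)))
  invisible(x)
}

get_partition <- function(topic, partition) {
  partition <- as.integer(partition)
  if (is.na(partition) || partition < 0L ||
      partition >= topic$spec$n_partitions) {
    stop(sprintf("partition %s out of range [0, %d) for topic %s",
                 partition, topic$spec$n_partitions, topic$name))
  }
  topic$parts[[partition + 1L]]
}

#' Append a message to a partition
#'
#' Messages are only ever appended, never overwritten; the returned offset
#' strictly increases within the partition. A keyed message with
#' `value = NULL` is a tombstone, marking its key for deletion at the next
#' compaction pass.
#'
#' @param topic a topic handle.
#' @param partition 0-based partition index in `[0, N)`.
#' @param key,value raw vectors, single character strings, or `NULL`
#'   (absent).
#' @param timestamp integer milliseconds since epoch; defaults to the
#'   store clock.
#' @return the assigned offset (invisibly a number).
#' @export
topic_append <- function(topic, partition, key = NULL, value = NULL,
                         timestamp = NULL) {
  part <- get_partition(topic, partition)
  key <- as_bytes(key)
  value <- as_bytes(value)
  if (is.null(timestamp)) timestamp <- topic$store$clock()
  off <- part$next_offset
  rec <- encode_record(off, timestamp, key, value)
  con <- file(part$path, open = "ab")
  writeBin(rec, con)
  close(con)
  if (part$n >= length(part$msgs)) {
    # amortized growth: the cache list is extended by doubling
    grow <- max(64L, length(part$msgs))
    part$msgs <- c(part$msgs, vector("list", grow))
    part$offs <- c(part$offs, numeric(grow))
  }
  part$n <- part$n + 1L
  part$msgs[[part$n]] <- new_message(topic$name, part$index, off, timestamp,
                                     key, value)
  part$offs[part$n] <- off
  part$next_offset <- off + 1
  off
}

#' Read retained messages from a partition
#'
#' Reading never deletes: the same call returns the same messages until a
#' compaction pass removes some of them. Offsets of retained messages are
#' preserved by compaction, so the sequence may contain gaps.
#'
#' @inheritParams topic_append
#' @param from_offset return messages with offset `>= from_offset`.
#' @param max_count cap on the number of messages returned.
#' @return a list of `log_message` objects in offset order.
#' @export
topic_read <- function(topic, partition, from_offset = 0, max_count = Inf) {
  if (from_offset < 0) stop("from_offset must be >= 0")
  part <- get_partition(topic, partition)
  if (part$n == 0L) return(list())
  idx <- which(part$offs[seq_len(part$n)] >= from_offset)
  if (length(idx) > max_count) idx <- idx[seq_len(max_count)]
  part$msgs[idx]
}

#' Per-partition next-offset map
#'
#' The end offset of a partition is the offset the next append will
#' receive; it is unaffected by compaction (which removes messages without
#' renumbering survivors). The sum over partitions is the "size" watched
#' by [detect_equilibrium()].
#'
#' @param topic a topic handle.
#' @return a named numeric vector, one entry per partition index.
#' @export
end_offsets <- function(topic) {
  stopifnot(inherits(topic, "log_topic"))
  offs <- vapply(topic$parts, function(p) p$next_offset, numeric(1))
  names(offs) <- as.character(seq_along(offs) - 1L)
  offs
}

#' @rdname end_offsets
#' @return `topic_size` returns the total number of retained messages.
#' @export
topic_size <- function(topic) {
  sum(vapply(topic$parts, function(p) p$n, integer(1)))
}

# ---- compaction -------------------------------------------------------------

#' Compact one partition: keep the youngest message per key
#'
#' Recopies the partition from oldest to youngest message, removing every
#' message that has a younger version with the same key. If the youngest
#' message for a key is a tombstone (null value), all messages for that
#' key -- the tombstone included -- are removed. Keyless messages have no
#' key identity and are never removed. Surviving messages keep their
#' original offsets and order. The rewrite goes to a temporary file which
#' is atomically renamed, so concurrent readers of the segment never see a
#' half-compacted partition.
#'
#' @inheritParams topic_append
#' @return a `compaction_report` with message counts before/after and the
#'   number of keys deleted by tombstone.
#' @export
compact_partition <- function(topic, partition) {
  if (!topic$spec$compacted) {
    stop("topic ", topic$name, " is not configured for compaction")
  }
  part <- get_partition(topic, partition)
  msgs <- part$msgs[seq_len(part$n)]
  before <- length(msgs)

  youngest <- new.env(parent = emptyenv()) # key id -> index of youngest msg
  for (i in seq_along(msgs)) {
    k <- msgs[[i]]$key
    if (!is.null(k)) youngest[[bytes_id(k)]] <- i
  }
  superseded <- 0L
  tombstoned_keys <- 0L
  keep <- logical(before)
  for (i in seq_along(msgs)) {
    m <- msgs[[i]]
    if (is.null(m$key)) {
      keep[i] <- TRUE
      next
    }
    yi <- youngest[[bytes_id(m$key)]]
    if (i < yi) {
      superseded <- superseded + 1L
    } else if (is_tombstone(msgs[[yi]])) {
      tombstoned_keys <- tombstoned_keys + 1L # the tombstone itself
    } else {
      keep[i] <- TRUE
    }
  }

  survivors <- msgs[keep]
  tmp <- paste0(part$path, ".tmp")
  con <- file(tmp, open = "wb")
  for (m in survivors) {
    writeBin(encode_record(m$offset, m$timestamp, m$key, m$value), con)
  }
  close(con)
  if (!file.rename(tmp, part$path)) stop("atomic rename failed: ", tmp)
  part$msgs <- survivors
  part$offs <- vapply(survivors, function(m) m$offset, numeric(1))
  part$n <- length(survivors)
  sync_topic_meta(topic)

  structure(
    list(topic = topic$name, partition = part$index,
         messages_before = before,
         messages_removed_superseded = superseded,
         keys_deleted_by_tombstone = tombstoned_keys,
         messages_after = length(survivors)),
    class = "compaction_report"
  )
}

#' @rdname compact_partition
#' @return `compact_topic` returns a list of reports, one per partition.
#' @export
compact_topic <- function(topic) {
  lapply(seq_len(topic$spec$n_partitions) - 1L,
         function(i) compact_partition(topic, i))
}

#' @export
print.compaction_report <- function(x, ...) {
  cat(sprintf(
    "<compaction %s[%d]: %d -> %d (%d superseded, %d keys tombstoned)>\n",
    x$topic, x$partition, x$messages_before, x$messages_after,
    x$messages_removed_superseded, x$keys_deleted_by_tombstone))
  invisible(x)
}

sync_topic_meta <- function(topic) {
  if (!dir.exists(topic$dir)) return(invisible(NULL)) # store removed
  write_topic_meta(topic$store, topic$spec, topic$placements,
                   vapply(topic$parts, function(p) p$next_offset, numeric(1)))
}

#' Close a store, recording its offset watermarks
#'
#' Every append is written and closed durably as it happens; closing a
#' store additionally records the per-partition offset watermarks in the
#' topic metadata, after which the directory can be reopened by another
#' process with nothing to recover.
#'
#' @param store a [log_store()].
#' @export
close_store <- function(store) {
  for (name in ls(store$topics)) {
    sync_topic_meta(store$topics[[name]])
  }
  invisible(store)
}

# ---- simulated replication --------------------------------------------------

#' Replica placements and failure-survival arithmetic
#'
#' Replication is modelled as placement metadata: each partition is
#' assigned `R` distinct simulated broker ids. `surviving_replicas` counts,
#' per partition, the replicas left after a set of brokers fails; a
#' data-loss event is any partition with count 0.
#'
#' @param topic a topic handle, or a bare list of integer broker-id vectors
#'   (one per partition).
#' @param failed_brokers integer vector of failed broker ids.
#' @return integer vector of surviving replica counts, named by partition.
#' @examples
#' st <- log_store(tempfile("store"), n_brokers = 7)
#' tp <- create_topic(st, topic_spec("t", n_partitions = 7,
#'                                   replication_factor = 3))
#' surviving_replicas(tp, c(0, 1))
#' max_safe_failures(tp)  # R - 1 = 2
#' @export
surviving_replicas <- function(topic, failed_brokers) {
  placements <- if (inherits(topic, "log_topic")) topic$placements else topic
  failed_brokers <- as.integer(failed_brokers)
  counts <- vapply(placements,
                   function(b) sum(!(as.integer(b) %in% failed_brokers)),
                   integer(1))
  names(counts) <- as.character(seq_along(counts) - 1L)
  counts
}

#' @rdname surviving_replicas
#' @param n_brokers broker universe size; defaults to the store's.
#' @return `max_safe_failures` returns the largest `k` such that every
#'   possible simultaneous failure of `k` brokers leaves at least one
#'   surviving replica of every partition, by exhaustive enumeration of
#'   all k-subsets. For round-robin placement this equals `R - 1`.
#' @export
max_safe_failures <- function(topic, n_brokers = NULL) {
  placements <- if (inherits(topic, "log_topic")) topic$placements else topic
  if (is.null(n_brokers)) {
    if (!inherits(topic, "log_topic")) {
      stop("n_brokers required when passing bare placements")
    }
    n_brokers <- topic$store$n_brokers
  }
  brokers <- seq_len(n_brokers) - 1L
  for (k in seq_len(n_brokers)) {
    sets <- utils::combn(brokers, k, simplify = FALSE)
    loss <- vapply(sets, function(f) {
      any(surviving_replicas(placements, f) == 0L)
    }, logical(1))
    if (any(loss)) return(k - 1L)
  }
  n_brokers
}
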