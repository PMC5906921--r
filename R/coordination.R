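# ---- producer partitioning --------------------------------------------------

#' Producer partitioning strategy
#'
#' Producers select a destination partition from the message key. The
#' default strategy hashes the key with FNV-1a 64-bit and reduces modulo
#' the partition count, so the same key lands on the same partition in
#' every run and process. Keyless messages are dealt round-robin over a
#' producer-local counter. An optional `key_extractor` maps the key to the
#' bytes actually hashed -- e.g. hashing only the accession part of a
#' sequence-chunk key so all chunks of one sequence are co-partitioned.
#'
#' @param strategy `"default-hash"`, `"round-robin"` (ignore keys), or
#'   `"custom"` (requires `key_extractor`).
#' @param key_extractor optional function raw-key -> raw partitioning
#'   bytes, applied before hashing.
#' @return a `partitioner_config` (stateful: holds the round-robin
#'   counter).
#' @export
partitioner_config <- function(strategy = c("default-hash", "round-robin",
                                            "custom"),
                               key_extractor = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "custom" && !is.function(key_extractor)) {
    stop("custom strategy requires a key_extractor function")
  }
  cfg <- new.env(parent = emptyenv())
  cfg$strategy <- strategy
  cfg$key_extractor <- key_extractor
  cfg$rr_counter <- 0
  class(cfg) <- "partitioner_config"
  cfg
}

#' Select a destination partition for a message key
#'
#' @param key raw vector, single character string, or `NULL` (keyless).
#' @param n_partitions topic partition count, `>= 1`.
#' @param config a [partitioner_config()].
#' @return 0-based partition index.
#' @export
partition_for_key <- function(key, n_partitions,
                              config = partitioner_config()) {
  n_partitions <- as.integer(n_partitions)
  if (n_partitions < 1L) stop("n_partitions must be >= 1")
  key <- as_bytes(key)
  if (config$strategy == "round-robin" || is.null(key)) {
    p <- as.integer(config$rr_counter %% n_partitions)
    config$rr_counter <- config$rr_counter + 1
    return(p)
  }
  if (!is.null(config$key_extractor)) {
    key <- as_bytes(config$key_extractor(key))
  }
  fnv1a64_mod(key, n_partitions)
}

#' Append a keyed message through the partitioner
#'
#' Convenience producer: picks the partition with [partition_for_key()]
#' and appends.
#'
#' @inheritParams topic_append
#' @inheritParams partition_for_key
#' @return the `(partition, offset)` pair, invisibly.
#' @export
produce <- function(topic, key = NULL, value = NULL,
                    config = partitioner_config(), timestamp = NULL) {
  p <- partition_for_key(key, topic$spec$n_partitions, config)
  off <- topic_append(topic, p, key = key, value = value,
                      timestamp = timestamp)
  invisible(list(partition = p, offset = off))
}

# ---- partition assignment ---------------------------------------------------

#' Divide a topic's partitions among consumer-group members
#'
#' Any given partition is read by exactly one member of a group at a time.
#' Two strategies are provided, both balanced to within one partition:
#'
#' * `"range"` (default): members sorted lexicographically each receive a
#'   contiguous block of numerically sorted partitions; the first
#'   `N mod M` members get one extra.
#' * `"round-robin"`: partitions are dealt to the sorted members in turn.
#'
#' Assignment is a pure function of `(n_partitions, sorted member ids,
#' strategy)`; members beyond the partition count receive empty sets and
#' sit idle.
#'
#' @param n_partitions topic partition count.
#' @param member_ids character vector of member identifiers (non-empty).
#' @param strategy `"range"` or `"round-robin"`.
#' @param topic topic name recorded in the assignment (informational).
#' @param group group name recorded in the assignment (informational).
#' @return an `assignment`: list with `member_partitions`, a named list of
#'   0-based partition index vectors.
#' @examples
#' assign_partitions(4, c("c1", "c2", "c3", "c4"))  # one partition each
#' assign_partitions(4, c("c1", "c2"))              # two partitions each
#' @export
assign_partitions <- function(n_partitions, member_ids,
                              strategy = c("range", "round-robin"),
                              topic = NA_character_, group = NA_character_) {
  strategy <- match.arg(strategy)
  member_ids <- as.character(member_ids)
  if (length(member_ids) == 0L) stop("member list is empty")
  if (anyDuplicated(member_ids)) stop("duplicate member ids")
  members <- sort(member_ids)
  n <- as.integer(n_partitions)
  m <- length(members)
  parts <- seq_len(n) - 1L
  assigned <- stats::setNames(vector("list", m), members)
  if (strategy == "range") {
    base <- n %/% m
    extra <- n %% m
    cursor <- 0L
    for (i in seq_len(m)) {
      take <- base + as.integer(i <= extra)
      assigned[[i]] <- if (take > 0) parts[cursor + seq_len(take)] else
        integer(0)
      cursor <- cursor + take
    }
  } else {
    for (i in seq_len(m)) {
      assigned[[i]] <- if (i > n) integer(0) else parts[seq(i, n, by = m)]
    }
  }
  structure(
    list(group = group, topic = topic, strategy = strategy,
         member_partitions = assigned),
    class = "assignment"
  )
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment %s/%s (%s)>\n", x$group, x$topic, x$strategy))
  for (m in names(x$member_partitions)) {
    cat(sprintf("  %s: [%s]\n", m,
                paste(x$member_partitions[[m]], collapse = ", ")))
  }
  invisible(x)
}

# ---- consumer groups --------------------------------------------------------

group_path <- function(store, group_id) {
  file.path(store$root, "_groups", paste0(group_id, ".json"))
}

#' Open or create a consumer group
#'
#' A group is a set of cooperating readers among which each subscribed
#' topic's partitions are divided. Membership and committed offsets are
#' persisted as JSON under `<store_root>/_groups/`, so committed positions
#' survive a store reopen.
#'
#' @param store a [log_store()].
#' @param group_id group identifier.
#' @param strategy default assignment strategy for the group.
#' @return a `consumer_group` handle.
#' @export
consumer_group <- function(store, group_id, strategy = "range") {
  cached <- store$groups[[group_id]]
  if (!is.null(cached)) return(cached)
  grp <- new.env(parent = emptyenv())
  grp$store <- store
  grp$id <- group_id
  grp$strategy <- strategy
  grp$members <- character(0)
  grp$committed <- new.env(parent = emptyenv()) # "topic/p" -> next offset
  grp$positions <- new.env(parent = emptyenv()) # in-memory read positions
  path <- group_path(store, group_id)
  if (file.exists(path)) {
    st <- jsonlite::read_json(path)
    grp$members <- as.character(unlist(st$members))
    grp$strategy <- st$strategy
    for (k in names(st$committed)) grp$committed[[k]] <- as.numeric(st$committed[[k]])
  }
  class(grp) <- "consumer_group"
  store$groups[[group_id]] <- grp
  grp
}

persist_group <- function(grp) {
  committed <- as.list(grp$committed)
  jsonlite::write_json(
    list(members = grp$members, strategy = grp$strategy,
         committed = committed),
    group_path(grp$store, grp$id),
    auto_unbox = TRUE, digits = NA
  )
}

#' @export
print.consumer_group <- function(x, ...) {
  cat(sprintf("<consumer_group %s: members [%s]>\n", x$id,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Change group membership (stop-the-world rebalance)
#'
#' Joining or leaving recomputes the assignment over the updated
#' membership and resets all in-memory read positions to the committed
#' offsets, so a partition's new owner resumes where the previous owner
#' committed.
#'
#' @param group a [consumer_group()].
#' @param member member id.
#' @return the group, invisibly.
#' @export
group_join <- function(group, member) {
  rebalance(group, joined = member)
  invisible(group)
}

#' @rdname group_join
#' @export
group_leave <- function(group, member) {
  rebalance(group, left = member)
  invisible(group)
}

#' @rdname group_join
#' @param joined,left character vectors of members entering/leaving
#'   (disjoint).
#' @param topic optional topic handle; when given, the new [assignment]
#'   for that topic is returned.
#' @return `rebalance` returns the new assignment (or the group invisibly
#'   when `topic` is `NULL`).
#' @export
rebalance <- function(group, joined = character(0), left = character(0),
                      topic = NULL) {
  joined <- as.character(joined)
  left <- as.character(left)
  if (length(intersect(joined, left)) > 0) {
    stop("a member cannot both join and leave")
  }
  members <- setdiff(union(group$members, joined), left)
  if (length(members) == 0L) {
    stop("rebalance would leave group ", group$id, " empty")
  }
  group$members <- sort(members)
  # stop-the-world: every owner restarts from the committed offset
  rm(list = ls(group$positions), envir = group$positions)
  persist_group(group)
  if (!is.null(topic)) {
    return(group_assignment(group, topic))
  }
  invisible(group)
}

#' @rdname group_join
#' @export
group_assignment <- function(group, topic) {
  assign_partitions(topic$spec$n_partitions, group$members,
                    strategy = group$strategy, topic = topic$name,
                    group = group$id)
}

offset_key <- function(topic_name, partition) {
  paste0(topic_name, "/", partition)
}

member_partitions <- function(group, member, topic) {
  if (!(member %in% group$members)) {
    stop("member ", member, " is not in group ", group$id)
  }
  group_assignment(group, topic)$member_partitions[[member]]
}

#' Poll messages from a member's assigned partitions
#'
#' Returns messages only from the partitions assigned to `member`, each
#' partition's messages in offset order, cycling among the assigned
#' partitions so none starves. Polling advances the member's in-memory
#' position; only [commit_offset()] makes progress durable, so an
#' uncommitted position is rewound by the next rebalance (at-least-once
#' delivery).
#'
#' @param group a [consumer_group()].
#' @param member member id (must hold at least one assigned partition).
#' @param topic a topic handle.
#' @param max_count cap on messages returned by this poll.
#' @return list of `log_message`.
#' @export
group_poll <- function(group, member, topic, max_count = 100) {
  parts <- member_partitions(group, member, topic)
  if (length(parts) == 0L) {
    stop("member ", member, " holds no partitions of ", topic$name)
  }
  out <- list()
  active <- parts
  while (length(out) < max_count && length(active) > 0) {
    still <- integer(0)
    for (p in active) {
      if (length(out) >= max_count) break
      k <- offset_key(topic$name, p)
      pos <- group$positions[[k]]
      if (is.null(pos)) {
        pos <- group$committed[[k]]
        if (is.null(pos)) pos <- 0
      }
      batch <- topic_read(topic, p, from_offset = pos, max_count = 1)
      if (length(batch) == 1L) {
        out[[length(out) + 1L]] <- batch[[1L]]
        group$positions[[k]] <- batch[[1L]]$offset + 1
        still <- c(still, p)
      }
    }
    active <- still
  }
  out
}

#' Commit a consumed offset
#'
#' Records `offset` as the next offset to read for `(topic, partition)` on
#' behalf of the group. Commits are monotone: an attempt to move a
#' committed offset backwards is ignored with a warning. Committed offsets
#' are persisted and survive rebalances and store reopens.
#'
#' @inheritParams group_poll
#' @param partition 0-based partition index (must be assigned to
#'   `member`).
#' @param offset next offset to read (i.e. last processed offset + 1).
#' @return the committed offset for the partition, invisibly.
#' @export
commit_offset <- function(group, member, topic, partition, offset) {
  parts <- member_partitions(group, member, topic)
  if (!(partition %in% parts)) {
    stop("partition ", partition, " is not assigned to member ", member)
  }
  k <- offset_key(topic$name, partition)
  cur <- group$committed[[k]]
  if (!is.null(cur) && offset < cur) {
    warning(sprintf(
      "ignoring commit of offset %s below committed %s on %s",
      format(offset), format(cur), k))
    return(invisible(cur))
  }
  group$committed[[k]] <- offset
  persist_group(group)
  invisible(offset)
}

#' @rdname commit_offset
#' @return `committed_offset` returns the committed next-offset-to-read,
#'   or 0 when nothing has been committed.
#' @export
committed_offset <- function(group, topic, partition) {
  v <- group$committed[[offset_key(topic$name, partition)]]
  if (is.null(v)) 0 else v
}
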