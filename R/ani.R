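# ---- fragments --------------------------------------------------------------

#' Cut a genome into fixed-length fragments
#'
#' Both query and subject genomes are broken into non-overlapping windows
#' of exactly `fragment_length` nucleotides (1020 by default, the OrthoANI
#' convention); the trailing remainder shorter than a full window is
#' discarded, so a genome shorter than one window yields no fragments.
#'
#' @param record a [sequence_record()].
#' @param fragment_length window length in nucleotides (`>= 1`).
#' @return a list of fragments, each a list with `genome_id`,
#'   `fragment_index` (0-based) and `residues`.
#' @export
fragment_genome <- function(record, fragment_length = 1020) {
  if (fragment_length < 1) stop("fragment_length must be >= 1")
  len <- nchar(record$residues)
  n <- len %/% fragment_length
  lapply(seq_len(n) - 1L, function(i) {
    list(genome_id = record$accession, fragment_index = i,
         residues = substr(record$residues, i * fragment_length + 1,
                           (i + 1) * fragment_length))
  })
}

# ---- matching ---------------------------------------------------------------

#' Ungapped positionwise identity between two equal-length fragments
#'
#' The default matcher: the fraction of positions where the two fragments
#' carry the same unambiguous base, case-insensitive; `N` never matches
#' anything (including another `N`). A gapped aligner can be substituted
#' through the `matcher` argument of [best_match()] and [compute_ani()].
#'
#' @param a,b equal-length nucleotide strings.
#' @return identity fraction in `[0, 1]`.
#' @export
positionwise_identity <- function(a, b) {
  ra <- charToRaw(toupper(a))
  rb <- charToRaw(toupper(b))
  if (length(ra) != length(rb)) {
    stop("fragments differ in length: ", length(ra), " vs ", length(rb))
  }
  if (length(ra) == 0) return(0)
  n_mark <- as.raw(78L) # 'N'
  sum(ra == rb & ra != n_mark) / length(ra)
}

#' Best-matching subject fragment for one query fragment
#'
#' Scans all subject fragments with `matcher` and returns the one with
#' maximal identity; ties are broken by the lowest
#' `(genome_id, fragment_index)`.
#'
#' @param query_fragment a fragment from [fragment_genome()].
#' @param subject_fragments non-empty list of candidate fragments.
#' @param matcher function `(query residues, subject residues) ->`
#'   identity in `[0, 1]`; defaults to [positionwise_identity()].
#' @return a `match_record`: query/subject `(genome_id, fragment_index)`
#'   pairs plus the identity.
#' @export
best_match <- function(query_fragment, subject_fragments,
                       matcher = positionwise_identity) {
  if (length(subject_fragments) == 0L) {
    stop("no subject fragments to match against")
  }
  ord <- order(vapply(subject_fragments, `[[`, character(1), "genome_id"),
               vapply(subject_fragments, `[[`, integer(1),
                      "fragment_index"))
  subject_fragments <- subject_fragments[ord]
  ids <- vapply(subject_fragments, function(s) {
    matcher(query_fragment$residues, s$residues)
  }, numeric(1))
  best <- which.max(ids) # first maximum = lowest (genome_id, index)
  s <- subject_fragments[[best]]
  structure(
    list(query_genome = query_fragment$genome_id,
         query_index = query_fragment$fragment_index,
         subject_genome = s$genome_id,
         subject_index = s$fragment_index,
         identity = ids[best]),
    class = "match_record"
  )
}

match_df <- function(matches) {
  if (length(matches) == 0L) {
    return(data.frame(query_genome = character(0),
                      query_index = integer(0),
                      subject_genome = character(0),
                      subject_index = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(matches, function(m) {
    data.frame(query_genome = m$query_genome, query_index = m$query_index,
               subject_genome = m$subject_genome,
               subject_index = m$subject_index, identity = m$identity,
               stringsAsFactors = FALSE)
  }))
}

frag_id <- function(genome, index) paste0(genome, "#", index)

#' Intersect two directional best-match sets into reciprocal pairs
#'
#' `forward` holds the best matches query-to-subject, `reverse` the best
#' matches subject-to-query. The reverse set is materialized as an
#' indexed lookup table keyed by its query side (the subject fragments),
#' and a forward match `q -> s` is emitted iff the table maps `s` back to
#' `q`. The two directional identities of a reciprocal pair need not be
#' equal under a general matcher; the emitted pair carries their mean,
#' which keeps the final ANI symmetric in query and subject.
#'
#' @param forward,reverse data frames (or lists of `match_record`) with
#'   columns `query_genome`, `query_index`, `subject_genome`,
#'   `subject_index`, `identity`.
#' @return a data frame of reciprocal pairs with the averaged identity.
#' @export
reciprocal_pairs <- function(forward, reverse) {
  if (!is.data.frame(forward)) forward <- match_df(forward)
  if (!is.data.frame(reverse)) reverse <- match_df(reverse)
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reverse))) {
    lookup[[frag_id(reverse$query_genome[i], reverse$query_index[i])]] <-
      list(target = frag_id(reverse$subject_genome[i],
                            reverse$subject_index[i]),
           identity = reverse$identity[i])
  }
  keep <- logical(nrow(forward))
  ident <- numeric(nrow(forward))
  for (i in seq_len(nrow(forward))) {
    back <- lookup[[frag_id(forward$subject_genome[i],
                            forward$subject_index[i])]]
    if (!is.null(back) &&
        back$target == frag_id(forward$query_genome[i],
                               forward$query_index[i])) {
      keep[i] <- TRUE
      ident[i] <- (forward$identity[i] + back$identity) / 2
    }
  }
  out <- forward[keep, , drop = FALSE]
  out$identity <- ident[keep]
  rownames(out) <- NULL
  out
}

# ---- running average --------------------------------------------------------

#' Streaming average nucleotide identity
#'
#' `ani_state` holds the running sum and count of reciprocal-pair
#' identities; `update_ani` folds one pair in. The running mean after all
#' pairs equals the batch mean whatever the arrival order. With no pairs
#' the ANI is undefined (`NA`), never 0.
#'
#' @return an `ani_state` with `reciprocal_count`, `identity_sum`,
#'   `running_mean`.
#' @export
ani_state <- function() {
  structure(
    list(reciprocal_count = 0L, identity_sum = 0, running_mean = NA_real_),
    class = "ani_state"
  )
}

#' @rdname ani_state
#' @param state an `ani_state`.
#' @param identity one reciprocal pair's identity (or a `match_record` /
#'   one-row data frame carrying an `identity` field).
#' @export
update_ani <- function(state, identity) {
  if (is.list(identity)) identity <- identity$identity
  state$reciprocal_count <- state$reciprocal_count + 1L
  state$identity_sum <- state$identity_sum + identity
  state$running_mean <- state$identity_sum / state$reciprocal_count
  state
}

#' @export
print.ani_state <- function(x, ...) {
  cat(sprintf("<ANI %s over %d reciprocal pairs>\n",
              ifelse(is.na(x$running_mean), "undefined",
                     format(x$running_mean, digits = 6)),
              x$reciprocal_count))
  invisible(x)
}

# ---- the topic-based ANI pipeline -------------------------------------------

#' Average nucleotide identity between two genomes, over message topics
#'
#' The reciprocal best-match ANI pipeline run through the log store: both
#' genomes are fragmented into topics; one consumer group reads the
#' subject topic to completion (building the in-memory fragment database)
#' and then streams the query topic, emitting each query fragment's best
#' match to a forward match topic; a second group does the opposite
#' direction. The reverse matches are read back into an indexed lookup
#' table, the forward matches are streamed against it to find reciprocal
#' pairs, and each pair's (direction-averaged) identity feeds the running
#' average. All sweeps terminate via back-markers. The final running mean
#' is the ANI of the two genomes.
#'
#' @param query,subject [sequence_record()] genomes.
#' @param fragment_length fragment window length (default 1020).
#' @param matcher fragment identity function; defaults to
#'   [positionwise_identity()]. The seam where an external aligner (e.g.
#'   BLAST-based matching) can be plugged in.
#' @param store a [log_store()] to run in; a throwaway temporary store is
#'   created (and removed) when `NULL`.
#' @param n_partitions partition count for the fragment and match topics.
#' @return a list: `ani` (`NA` when no reciprocal pairs exist),
#'   `n_pairs`, the final `state`, and the reciprocal `pairs` data frame.
#' @examples
#' g <- sequence_record("g1", paste(rep("ACGT", 600), collapse = ""))
#' compute_ani(g, g)$ani  # identical genomes: exactly 1
#' @export
compute_ani <- function(query, subject, fragment_length = 1020,
                        matcher = positionwise_identity, store = NULL,
                        n_partitions = 1L) {
  if (is.null(store)) {
    root <- tempfile("ani-store-")
    on.exit(unlink(root, recursive = TRUE), add = TRUE)
    store <- log_store(root)
  }
  tag <- sprintf("ani%d", next_run_id())
  t_query <- create_topic(store, topic_spec(paste0(tag, "-q"), n_partitions))
  t_subject <- create_topic(store, topic_spec(paste0(tag, "-s"), n_partitions))
  t_fwd <- create_topic(store, topic_spec(paste0(tag, "-fwd"), n_partitions))
  t_rev <- create_topic(store, topic_spec(paste0(tag, "-rev"), n_partitions))

  publish_fragments <- function(topic, record) {
    cfg <- partitioner_config()
    for (f in fragment_genome(record, fragment_length)) {
      produce(topic, key = frag_id(f$genome_id, f$fragment_index),
              value = f$residues, config = cfg)
    }
    emit_back_markers(topic, "frags")
  }
  publish_fragments(t_query, query)
  publish_fragments(t_subject, subject)

  # drain a fragment topic to completion (sweep via back-markers)
  drain_fragments <- function(topic, group_id) {
    grp <- consumer_group(store, group_id)
    member <- paste0(group_id, "-m1")
    group_join(grp, member)
    frags <- list()
    markers <- list()
    repeat {
      msgs <- group_poll(grp, member, topic, max_count = 200)
      for (m in msgs) {
        if (is_back_marker(m)) {
          markers[[length(markers) + 1L]] <- m
        } else {
          fields <- strsplit(rawToChar(m$key), "#", fixed = TRUE)[[1]]
          frags[[length(frags) + 1L]] <-
            list(genome_id = fields[1],
                 fragment_index = as.integer(fields[2]),
                 residues = rawToChar(m$value))
        }
      }
      if (sweep_complete(markers, topic, "frags")) break
      if (length(msgs) == 0L) stop("fragment sweep stalled")
    }
    frags
  }

  # one direction: read `db_topic` to completion, stream `stream_topic`,
  # emit best matches to `out_topic`
  run_direction <- function(db_topic, stream_topic, out_topic, group_id) {
    db <- drain_fragments(db_topic, paste0(group_id, "-db"))
    streamed <- drain_fragments(stream_topic, paste0(group_id, "-stream"))
    cfg <- partitioner_config()
    for (f in streamed) {
      m <- best_match(f, db, matcher)
      topic_append(out_topic,
                   partition_for_key(frag_id(m$query_genome,
                                             m$query_index),
                                     out_topic$spec$n_partitions, cfg),
                   key = frag_id(m$query_genome, m$query_index),
                   value = jsonlite::toJSON(unclass(m), auto_unbox = TRUE,
                                            digits = NA))
    }
    emit_back_markers(out_topic, "matches")
  }
  run_direction(t_subject, t_query, t_fwd, paste0(tag, "-fwdgrp"))
  run_direction(t_query, t_subject, t_rev, paste0(tag, "-revgrp"))

  read_matches <- function(topic) {
    rows <- list()
    for (p in seq_len(topic$spec$n_partitions) - 1L) {
      for (m in topic_read(topic, p)) {
        if (is_back_marker(m)) next
        rows[[length(rows) + 1L]] <-
          as.data.frame(jsonlite::fromJSON(rawToChar(m$value)),
                        stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) return(match_df(list()))
    do.call(rbind, rows)
  }
  pairs <- reciprocal_pairs(read_matches(t_fwd), read_matches(t_rev))

  state <- ani_state()
  for (i in seq_len(nrow(pairs))) {
    state <- update_ani(state, pairs$identity[i])
  }
  list(ani = state$running_mean, n_pairs = state$reciprocal_count,
       state = state, pairs = pairs)
}
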