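# ---- FASTA records ----------------------------------------------------------

#' A named nucleotide sequence
#'
#' @param accession first whitespace-delimited token of the FASTA header.
#' @param residues nucleotide string (`A/C/G/T/N` and IUPAC ambiguity
#'   codes, case-insensitive).
#' @param description remainder of the header after the accession.
#' @return a `sequence_record`.
#' @export
sequence_record <- function(accession, residues, description = "") {
  if (!nzchar(accession)) stop("accession must be non-empty")
  structure(
    list(accession = accession, description = description,
         residues = residues),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence %s: %s nt%s>\n", x$accession,
              format(nchar(x$residues), big.mark = ","),
              if (nzchar(x$description)) paste0(" (", x$description, ")")
              else ""))
  invisible(x)
}

#' Read FASTA text into sequence records
#'
#' Line wrapping is removed, CRLF line endings are tolerated, empty lines
#' are skipped and the leading `>` is stripped from headers. Residue text
#' appearing before the first header is a format error reported with its
#' line number.
#'
#' @param path a file path or readable connection.
#' @return a list of [sequence_record()] in file order.
#' @export
read_fasta <- function(path) {
  lines <- if (inherits(path, "connection")) readLines(path, warn = FALSE)
           else readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  records <- list()
  acc <- NULL
  desc <- ""
  parts <- character(0)
  finish <- function() {
    if (!is.null(acc)) {
      records[[length(records) + 1L]] <<-
        sequence_record(acc, paste0(parts, collapse = ""), desc)
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      finish()
      header <- sub("^>", "", line)
      acc <- sub("\\s.*$", "", header)
      if (!nzchar(acc)) {
        stop(sprintf("empty FASTA header at line %d", i))
      }
      desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
      parts <- character(0)
    } else {
      if (is.null(acc)) {
        stop(sprintf("FASTA format error: sequence data before first '>' at line %d", i))
      }
      parts <- c(parts, line)
    }
  }
  finish()
  records
}

#' Write sequence records as FASTA
#'
#' @param records a list of [sequence_record()] (a single record is
#'   accepted).
#' @param path a file path or writable connection.
#' @param line_width residues per line.
#' @return the number of records written, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 70) {
  if (inherits(records, "sequence_record")) records <- list(records)
  con <- if (inherits(path, "connection")) path else {
    con <- file(path, open = "w")
    on.exit(close(con))
    con
  }
  for (rec in records) {
    header <- if (nzchar(rec$description)) {
      paste(rec$accession, rec$description)
    } else {
      rec$accession
    }
    writeLines(paste0(">", header), con)
    n <- nchar(rec$residues)
    if (n > 0) {
      starts <- seq(1, n, by = line_width)
      writeLines(substring(rec$residues, starts,
                           pmin(starts + line_width - 1, n)), con)
    }
  }
  invisible(length(records))
}

# ---- chunking ---------------------------------------------------------------

#' A bounded-length slice of a sequence
#'
#' Sequences longer than the chunk size are stored as several messages;
#' the chunk carries its 0-based index and the total chunk count so the
#' original sequence can be reassembled.
#'
#' @param accession source sequence accession.
#' @param chunk_index 0-based index.
#' @param chunk_count total chunks for this accession.
#' @param residues at most `chunk_size` nucleotides.
#' @return a `sequence_chunk`.
#' @export
sequence_chunk <- function(accession, chunk_index, chunk_count, residues) {
  stopifnot(chunk_index >= 0, chunk_index < chunk_count)
  structure(
    list(accession = accession, chunk_index = as.integer(chunk_index),
         chunk_count = as.integer(chunk_count), residues = residues),
    class = "sequence_chunk"
  )
}

#' Split a sequence into bounded-size chunks
#'
#' A record of length `len` yields `ceiling(len / chunk_size)` chunks from
#' consecutive half-open windows; all chunks but the last have length
#' exactly `chunk_size`. A record of at most `chunk_size` nucleotides
#' (the default threshold is 100,000) yields a single chunk; an empty
#' record yields one empty chunk.
#'
#' @param record a [sequence_record()].
#' @param chunk_size maximum residues per chunk (`>= 1`).
#' @return list of [sequence_chunk()] in index order.
#' @export
chunk_sequence <- function(record, chunk_size = 100000) {
  if (chunk_size < 1) stop("chunk_size must be >= 1")
  len <- nchar(record$residues)
  n_chunks <- max(1L, as.integer(ceiling(len / chunk_size)))
  lapply(seq_len(n_chunks) - 1L, function(i) {
    sequence_chunk(record$accession, i, n_chunks,
                   substr(record$residues, i * chunk_size + 1,
                          min((i + 1) * chunk_size, len)))
  })
}

#' Reassemble a sequence from its chunks
#'
#' @param chunks list of [sequence_chunk()] for one accession, in any
#'   order; all indices `0 .. chunk_count-1` must be present exactly once.
#' @return the reconstructed [sequence_record()] (description is not
#'   carried by chunks and comes back empty).
#' @export
reassemble <- function(chunks) {
  stopifnot(length(chunks) > 0)
  accs <- unique(vapply(chunks, `[[`, character(1), "accession"))
  if (length(accs) != 1L) {
    stop("chunks from multiple accessions: ", paste(accs, collapse = ", "))
  }
  counts <- unique(vapply(chunks, `[[`, integer(1), "chunk_count"))
  if (length(counts) != 1L) {
    stop("conflicting chunk_count values for ", accs)
  }
  idx <- vapply(chunks, `[[`, integer(1), "chunk_index")
  expected <- seq_len(counts) - 1L
  missing <- setdiff(expected, idx)
  if (length(missing) > 0 || anyDuplicated(idx)) {
    stop(sprintf("incomplete sequence %s: missing chunk indices {%s}",
                 accs, paste(sort(missing), collapse = ", ")))
  }
  ord <- order(idx)
  sequence_record(accs, paste0(vapply(chunks[ord], `[[`, character(1),
                                      "residues"), collapse = ""))
}

# ---- chunk message encoding -------------------------------------------------

# '/' separates the key fields, so accessions must not contain it.
CHUNK_KEY_SEP <- "/"

#' Encode a chunk as a `(key, value)` message
#'
#' The key is `"<accession>/<chunk_index>/<chunk_count>"`; the value is
#' the residue text. The partitioning bytes -- extracted by
#' [chunk_key_extractor()] and fed to [partition_for_key()] -- are the
#' accession alone, so every chunk of one sequence lands on the same
#' partition and arrives in append order.
#'
#' @param chunk a [sequence_chunk()].
#' @return list with raw `key` and `value`.
#' @export
encode_chunk_message <- function(chunk) {
  if (grepl(CHUNK_KEY_SEP, chunk$accession, fixed = TRUE)) {
    stop("accession may not contain the reserved separator '",
         CHUNK_KEY_SEP, "': ", chunk$accession)
  }
  key <- paste(chunk$accession, chunk$chunk_index, chunk$chunk_count,
               sep = CHUNK_KEY_SEP)
  list(key = charToRaw(key), value = charToRaw(chunk$residues))
}

#' @rdname encode_chunk_message
#' @param key,value raw vectors from a chunk message.
#' @return `decode_chunk_message` returns the [sequence_chunk()].
#' @export
decode_chunk_message <- function(key, value) {
  fields <- strsplit(rawToChar(as_bytes(key)), CHUNK_KEY_SEP,
                     fixed = TRUE)[[1]]
  if (length(fields) != 3L) {
    stop("not a chunk key: ", rawToChar(as_bytes(key)))
  }
  sequence_chunk(fields[1], as.integer(fields[2]), as.integer(fields[3]),
                 if (length(value) > 0) rawToChar(value) else "")
}

#' @rdname encode_chunk_message
#' @return `chunk_key_extractor` returns the accession bytes of a chunk
#'   key (everything before the first separator), for use as a
#'   [partitioner_config()] `key_extractor`.
#' @export
chunk_key_extractor <- function(key) {
  sep <- charToRaw(CHUNK_KEY_SEP)
  cut <- which(key == sep)
  if (length(cut) == 0) key else key[seq_len(cut[1] - 1L)]
}

# ---- base counting ----------------------------------------------------------

#' Count nucleotide bases
#'
#' Case-insensitive counts of A, C, G, T; everything else (N and IUPAC
#' ambiguity codes) is `other`. Counts are additive --
#' `gc_counts(paste0(x, y)) == gc_counts(x) + gc_counts(y)` -- which is
#' what makes per-chunk GC aggregation exact.
#'
#' @param x a nucleotide string (or raw vector of ASCII bytes).
#' @return a `base_counts` object with fields `a`, `c`, `g`, `t`, `other`.
#' @examples
#' gc_fraction(gc_counts("ATGC"))  # 0.5
#' @export
gc_counts <- function(x) {
  b <- if (is.raw(x)) x else charToRaw(x)
  count2 <- function(up, lo) sum(b == as.raw(up) | b == as.raw(lo))
  a <- count2(65L, 97L)
  cc <- count2(67L, 99L)
  g <- count2(71L, 103L)
  t <- count2(84L, 116L)
  base_counts(a, cc, g, t, length(b) - a - cc - g - t)
}

#' @rdname gc_counts
#' @param a,c,g,t,other non-negative counts.
#' @export
base_counts <- function(a = 0, c = 0, g = 0, t = 0, other = 0) {
  # stored as doubles (exact below 2^53) so chunk sums and whole-sequence
  # counts compare identically whatever path produced them
  structure(list(a = as.numeric(a), c = as.numeric(c), g = as.numeric(g),
                 t = as.numeric(t), other = as.numeric(other)),
            class = "base_counts")
}

#' @export
`+.base_counts` <- function(e1, e2) {
  base_counts(e1$a + e2$a, e1$c + e2$c, e1$g + e2$g, e1$t + e2$t,
              e1$other + e2$other)
}

#' @export
print.base_counts <- function(x, ...) {
  cat(sprintf("<base_counts A=%s C=%s G=%s T=%s other=%s GC=%s>\n",
              format(x$a), format(x$c), format(x$g), format(x$t),
              format(x$other),
              format(gc_fraction(x), digits = 4)))
  invisible(x)
}

#' GC fraction from base counts
#'
#' `(G + C) / (A + C + G + T)`: the denominator excludes ambiguous bases.
#' When no unambiguous base was counted the fraction is undefined and
#' returned as `NA` (never 0).
#'
#' @param counts a [base_counts()] object, or a nucleotide string (counted
#'   first).
#' @return fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_fraction <- function(counts) {
  if (!inherits(counts, "base_counts")) counts <- gc_counts(counts)
  denom <- counts$a + counts$c + counts$g + counts$t
  if (denom == 0) return(NA_real_)
  (counts$g + counts$c) / denom
}

# ---- back-markers -----------------------------------------------------------

# Reserved key namespace for sweep markers: data keys may not start with
# byte 0x00, so marker keys can never collide with an accession.
marker_prefix <- function() c(as.raw(0L), charToRaw("MARK/"))

marker_key <- function(sweep_id, partition) {
  if (grepl("/", sweep_id, fixed = TRUE)) {
    stop("sweep_id may not contain '/'")
  }
  c(marker_prefix(), charToRaw(paste0(sweep_id, "/", partition)))
}

#' Back-markers: sentinel messages closing out a sweep
#'
#' Because each partition is read in order by one group member, a sentinel
#' appended at the end of each partition lets consumers perform an
#' exhaustive sweep of a topic and know when they have touched everything.
#' `emit_back_markers` appends exactly one marker per partition;
#' `sweep_complete` is true once a marker for `sweep_id` has been observed
#' from every partition.
#'
#' @param topic a topic handle.
#' @param sweep_id sweep identifier (no `/`); emitting the same sweep
#'   twice on a partition is an error.
#' @return named vector of marker offsets, one per partition.
#' @export
emit_back_markers <- function(topic, sweep_id) {
  n <- topic$spec$n_partitions
  keys <- lapply(seq_len(n) - 1L, function(p) marker_key(sweep_id, p))
  for (p in seq_len(n) - 1L) {
    existing <- topic_read(topic, p)
    for (m in existing) {
      if (!is.null(m$key) && identical(m$key, keys[[p + 1L]])) {
        stop(sprintf("duplicate sweep '%s' marker on %s[%d]",
                     sweep_id, topic$name, p))
      }
    }
  }
  offs <- vapply(seq_len(n) - 1L, function(p) {
    topic_append(topic, p, key = keys[[p + 1L]], value = raw(0))
  }, numeric(1))
  names(offs) <- as.character(seq_len(n) - 1L)
  offs
}

#' @rdname emit_back_markers
#' @param msg a `log_message` (or raw key).
#' @return `is_back_marker` tests whether a message is a sweep marker.
#' @export
is_back_marker <- function(msg) {
  key <- if (inherits(msg, "log_message")) msg$key else msg
  pre <- marker_prefix()
  !is.null(key) && length(key) >= length(pre) &&
    identical(key[seq_along(pre)], pre)
}

#' @rdname emit_back_markers
#' @param markers list of observed marker messages (non-markers are
#'   ignored).
#' @return `sweep_complete` returns `TRUE` iff a marker with this
#'   `sweep_id` has been seen from every partition of `topic`.
#' @export
sweep_complete <- function(markers, topic, sweep_id) {
  seen <- integer(0)
  pre <- marker_prefix()
  for (m in markers) {
    if (!is_back_marker(m)) next
    key <- if (inherits(m, "log_message")) m$key else m
    fields <- strsplit(rawToChar(key[-seq_along(pre)]), "/",
                       fixed = TRUE)[[1]]
    if (length(fields) == 2L && fields[1] == sweep_id) {
      seen <- c(seen, as.integer(fields[2]))
    }
  }
  setequal(seen, seq_len(topic$spec$n_partitions) - 1L)
}
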