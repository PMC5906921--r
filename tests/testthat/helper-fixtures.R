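# shared fixtures: everything is generated in code at test time

temp_store <- function(n_brokers = 3L, clock = NULL) {
  log_store(tempfile("store-"), n_brokers = n_brokers, clock = clock)
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste0(sample(bases, n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate` (always to a
# different base)
mutate_dna <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  }
  paste0(b, collapse = "")
}

# independent naive base counter (oracle for gc_counts)
naive_counts <- function(x) {
  ch <- toupper(strsplit(x, "", fixed = TRUE)[[1]])
  c(a = sum(ch == "A"), c = sum(ch == "C"), g = sum(ch == "G"),
    t = sum(ch == "T"),
    other = sum(!ch %in% c("A", "C", "G", "T")))
}

# brute-force compaction oracle: replay the append sequence into a
# dictionary (last write per key; tombstoned keys dropped; keyless
# appends always retained). Returns the retained (key, value, offset)
# triples in offset order.
replay_compaction <- function(keys, values) {
  last <- new.env(parent = emptyenv()) # key -> index of last write
  for (i in seq_along(keys)) {
    if (!is.na(keys[i])) last[[keys[i]]] <- i
  }
  retained <- logical(length(keys))
  for (i in seq_along(keys)) {
    if (is.na(keys[i])) {
      retained[i] <- TRUE
    } else if (last[[keys[i]]] == i && !is.na(values[i])) {
      retained[i] <- TRUE
    }
  }
  data.frame(offset = which(retained) - 1, key = keys[retained],
             value = values[retained], stringsAsFactors = FALSE)
}

# drive a random keyed append sequence (NA value = tombstone, NA key =
# keyless) into a fresh single-partition compacted topic
append_sequence <- function(topic, keys, values) {
  for (i in seq_along(keys)) {
    topic_append(topic, 0,
                 key = if (is.na(keys[i])) NULL else keys[i],
                 value = if (is.na(values[i])) NULL else values[i])
  }
}

retained_triples <- function(topic, partition = 0) {
  msgs <- topic_read(topic, partition)
  data.frame(
    offset = vapply(msgs, `[[`, numeric(1), "offset"),
    key = vapply(msgs, function(m) {
      if (is.null(m$key)) NA_character_ else rawToChar(m$key)
    }, character(1)),
    value = vapply(msgs, function(m) {
      if (is.null(m$value)) NA_character_ else rawToChar(m$value)
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

random_records <- function(n, max_len = 200) {
  lapply(seq_len(n), function(i) {
    sequence_record(sprintf("rec%03d", i),
                    random_dna(sample.int(max_len, 1)),
                    description = sample(c("", "some description"), 1))
  })
}
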