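test_that("FASTA parsing unwraps lines and tolerates CRLF and blank lines", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "ACGT", "ACGT",
               "", ">s2\r", "NNAA\r"), f, sep = "\n")
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$accession, "s1")
  expect_equal(recs[[1]]$description, "some description")
  expect_equal(recs[[1]]$residues, "ACGTACGT")
  expect_equal(recs[[2]]$accession, "s2")
  expect_equal(recs[[2]]$residues, "NNAA")
})

test_that("sequence data before the first header is an error with line number", {
  f <- tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">s1", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")
  f2 <- tempfile(fileext = ".fa")
  writeLines(c("", "", "GATTACA"), f2)
  expect_error(read_fasta(f2), "line 3")
})

test_that("FASTA writing wraps residue lines and round-trips", {
  f <- tempfile(fileext = ".fa")
  n <- write_fasta(sequence_record("long", random_dna(150)), f,
                   line_width = 70)
  expect_equal(n, 1)
  lines <- readLines(f)
  expect_length(lines, 4) # header + ceiling(150 / 70) residue lines
  expect_equal(nchar(lines[2:4]), c(70, 70, 10))

  set.seed(42)
  recs <- random_records(100)
  f2 <- tempfile(fileext = ".fa")
  write_fasta(recs, f2, line_width = 60)
  back <- read_fasta(f2)
  expect_equal(back, recs)
})

test_that("the parser agrees with Biostrings on a round-tripped file", {
  skip_if_not_installed("Biostrings")
  set.seed(7)
  recs <- random_records(20)
  f <- tempfile(fileext = ".fa")
  write_fasta(recs, f)
  ref <- Biostrings::readDNAStringSet(f)
  mine <- read_fasta(f)
  expect_equal(vapply(mine, `[[`, character(1), "accession"),
               unname(vapply(strsplit(names(ref), " "), `[`, character(1),
                             1)))
  expect_equal(vapply(mine, `[[`, character(1), "residues"),
               unname(as.character(ref)))
})

test_that("chunking respects the size threshold exactly", {
  at <- chunk_sequence(sequence_record("a", strrep("A", 100000)))
  expect_length(at, 1)
  over <- chunk_sequence(sequence_record("b", strrep("A", 100001)))
  expect_length(over, 2)
  expect_equal(nchar(vapply(over, `[[`, character(1), "residues")),
               c(100000, 1))
  expect_equal(vapply(over, `[[`, integer(1), "chunk_count"), c(2L, 2L))
  # empty records produce a single empty chunk
  empty <- chunk_sequence(sequence_record("c", ""))
  expect_length(empty, 1)
  expect_equal(empty[[1]]$residues, "")
  expect_error(chunk_sequence(sequence_record("d", "ACGT"), 0), ">= 1")
})

test_that("chunk then reassemble is the identity for arbitrary lengths", {
  set.seed(99)
  lens <- c(0, 1, sample.int(350000, 6))
  for (len in lens) {
    rec <- sequence_record("x", random_dna(len))
    expect_equal(reassemble(chunk_sequence(rec))$residues, rec$residues)
  }
  # and for pathological chunk sizes
  rec <- sequence_record("y", random_dna(123))
  for (cs in c(1, 2, 7, 123, 1000)) {
    chunks <- chunk_sequence(rec, cs)
    expect_length(chunks, ceiling(123 / cs))
    shuffled <- sample(chunks)
    expect_equal(reassemble(shuffled)$residues, rec$residues)
  }
})

test_that("reassembly reports missing chunk indices", {
  rec <- sequence_record("z", random_dna(30))
  chunks <- chunk_sequence(rec, 10)
  expect_error(reassemble(chunks[c(1, 3)]), "missing chunk indices \\{1\\}")
  expect_error(reassemble(chunks[c(1, 1, 2, 3)]), "incomplete")
})

test_that("chunk messages encode, decode and co-partition by accession", {
  chunk <- sequence_chunk("s1", 0, 1, "ACGT")
  msg <- encode_chunk_message(chunk)
  expect_equal(rawToChar(msg$key), "s1/0/1")
  expect_equal(rawToChar(msg$value), "ACGT")
  expect_equal(decode_chunk_message(msg$key, msg$value), chunk)
  expect_error(encode_chunk_message(sequence_chunk("a/b", 0, 1, "A")),
               "reserved separator")

  set.seed(5)
  for (i in 1:20) {
    c1 <- sequence_chunk(sprintf("acc%d", i), sample(0:3, 1), 4,
                         random_dna(sample.int(50, 1)))
    m <- encode_chunk_message(c1)
    expect_equal(decode_chunk_message(m$key, m$value), c1)
  }

  # all chunks of one accession land on one partition for every N
  rec <- sequence_record("NC_1", random_dna(5000))
  msgs <- lapply(chunk_sequence(rec, 1000), encode_chunk_message)
  cfg <- partitioner_config("custom", key_extractor = chunk_key_extractor)
  for (n in c(1, 2, 3, 5, 8)) {
    parts <- vapply(msgs, function(m) partition_for_key(m$key, n, cfg),
                    integer(1))
    expect_length(unique(parts), 1)
  }
})

test_that("base counts match a naive counter and are additive", {
  expect_equal(gc_fraction(gc_counts("ATGC")), 0.5)
  expect_equal(gc_fraction(gc_counts("GGCC")), 1.0)
  expect_equal(gc_fraction(gc_counts("AATT")), 0.0)
  expect_equal(gc_fraction(gc_counts("acgt")), 0.5) # case-insensitive
  # no unambiguous bases: undefined, not zero
  expect_true(is.na(gc_fraction(gc_counts("NNNN"))))
  expect_equal(gc_counts("NNRY")$other, 4)

  set.seed(21)
  x <- random_dna(10000, bases = c("A", "C", "G", "T", "N", "R", "a", "g"))
  ct <- gc_counts(x)
  ref <- naive_counts(x)
  expect_equal(c(ct$a, ct$c, ct$g, ct$t, ct$other), unname(ref))
  expect_equal(ct$a + ct$c + ct$g + ct$t + ct$other, nchar(x))

  # additivity over arbitrary splits enables per-chunk aggregation
  for (i in 1:10) {
    cut <- sample.int(nchar(x) - 1, 1)
    left <- substr(x, 1, cut)
    right <- substr(x, cut + 1, nchar(x))
    expect_equal(gc_counts(left) + gc_counts(right), ct)
  }
})

test_that("back-markers mark every partition and complete a sweep", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 4))
  for (i in 1:5) topic_append(tp, i %% 4, "k", "v")
  offs <- emit_back_markers(tp, "sweep1")
  expect_length(offs, 4)
  expect_error(emit_back_markers(tp, "sweep1"), "duplicate sweep")
  emit_back_markers(tp, "sweep2") # a new sweep is fine

  markers <- list()
  for (p in 0:2) {
    markers <- c(markers, Filter(is_back_marker, topic_read(tp, p)))
  }
  expect_false(sweep_complete(markers, tp, "sweep1"))
  markers <- c(markers, Filter(is_back_marker, topic_read(tp, 3)))
  expect_true(sweep_complete(markers, tp, "sweep1"))
  # markers for a different sweep never complete this one
  expect_false(sweep_complete(markers, tp, "sweep9"))
})
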