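test_that("appends assign strictly increasing offsets and reads are idempotent", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 4))
  expect_equal(topic_append(tp, 0, "k", "a"), 0)
  expect_equal(topic_append(tp, 0, "k", "b"), 1)
  expect_equal(topic_append(tp, 0, NULL, "keyless"), 2)

  first <- topic_read(tp, 0, 0)
  second <- topic_read(tp, 0, 0)
  expect_identical(first, second)
  expect_equal(vapply(first, `[[`, numeric(1), "offset"), c(0, 1, 2))

  # reading past the end is empty, not an error
  expect_length(topic_read(tp, 0, from_offset = 10), 0)
  # unwritten partitions are empty
  expect_length(topic_read(tp, 3), 0)
  # out-of-range partition is a range error
  expect_error(topic_append(tp, 7, "k", "v"), "out of range")
  expect_error(topic_read(tp, -1), "out of range")
})

test_that("topic creation validates names, partition counts and duplicates", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("refseq", 4))
  expect_equal(tp$spec$n_partitions, 4L)
  expect_equal(unname(end_offsets(tp)), rep(0, 4))
  expect_named(end_offsets(tp), c("0", "1", "2", "3"))
  expect_error(create_topic(st, topic_spec("refseq", 2)), "exists")
  expect_error(topic_spec("bad", 0), "positive")
  expect_error(topic_spec("_reserved", 1), "invalid topic name")
  # replication cannot exceed the simulated broker count
  expect_error(create_topic(st, topic_spec("wide", 1,
                                           replication_factor = 9)),
               "exceeds broker count")
})

test_that("tombstones are stored as keyed messages with absent values", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 1, compacted = TRUE))
  topic_append(tp, 0, "k1", "v1")
  off <- topic_append(tp, 0, "k1", NULL)
  expect_equal(off, 1) # offsets assigned normally
  msgs <- topic_read(tp, 0)
  expect_false(is_tombstone(msgs[[1]]))
  expect_true(is_tombstone(msgs[[2]]))
})

test_that("compaction keeps the youngest message per key and applies tombstones", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 2, compacted = TRUE))
  append_sequence(tp, c("k1", "k2", "k1"), c("v1", "v1", "v2"))
  rep0 <- compact_partition(tp, 0)
  got <- retained_triples(tp, 0)
  expect_equal(got$key, c("k2", "k1"))
  expect_equal(got$value, c("v1", "v2"))
  expect_equal(got$offset, c(1, 2)) # original offsets preserved
  expect_equal(rep0$messages_before, 3)
  expect_equal(rep0$messages_removed_superseded, 1)
  expect_equal(rep0$messages_after, 2)

  # a key whose youngest message is a tombstone disappears entirely
  topic_append(tp, 1, "k1", "v1")
  topic_append(tp, 1, "k1", NULL)
  rep1 <- compact_partition(tp, 1)
  expect_length(topic_read(tp, 1), 0)
  expect_equal(rep1$keys_deleted_by_tombstone, 1)
  expect_equal(rep1$messages_removed_superseded, 1)
  expect_equal(rep1$messages_after, 0)

  # end offsets are not rewound by compaction
  expect_equal(end_offsets(tp)[["1"]], 2)

  # compaction requires the compacted flag
  plain <- create_topic(st, topic_spec("plain", 1))
  topic_append(plain, 0, "k", "v")
  expect_error(compact_partition(plain, 0), "not configured")
})

test_that("keyless messages are exempt from compaction", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 1, compacted = TRUE))
  topic_append(tp, 0, NULL, "one")
  topic_append(tp, 0, "k", "a")
  topic_append(tp, 0, NULL, "two")
  topic_append(tp, 0, "k", "b")
  compact_partition(tp, 0)
  got <- retained_triples(tp)
  expect_equal(got$value, c("one", "two", "b"))
  expect_equal(got$offset, c(0, 2, 3))
})

test_that("compaction equals the brute-force last-write-per-key replay", {
  set.seed(101)
  st <- temp_store()
  tp <- create_topic(st, topic_spec("t", 1, compacted = TRUE))
  n <- 1000
  keys <- sprintf("key%02d", sample.int(10, n, replace = TRUE))
  keys[stats::runif(n) < 0.05] <- NA # occasional keyless message
  values <- sprintf("v%04d", seq_len(n))
  values[!is.na(keys) & stats::runif(n) < 0.1] <- NA # tombstones
  append_sequence(tp, keys, values)
  compact_partition(tp, 0)
  expect_equal(retained_triples(tp), replay_compaction(keys, values))

  # idempotence: a second pass changes nothing
  before <- retained_triples(tp)
  rep2 <- compact_partition(tp, 0)
  expect_equal(retained_triples(tp), before)
  expect_equal(rep2$messages_removed_superseded, 0)
  expect_equal(rep2$keys_deleted_by_tombstone, 0)
})

test_that("a store reopens with identical contents and offset watermarks", {
  root <- tempfile("persist-")
  st <- log_store(root)
  tp <- create_topic(st, topic_spec("t", 2, compacted = TRUE))
  topic_append(tp, 0, "k1", "v1")
  topic_append(tp, 0, "k2", "v2")
  topic_append(tp, 1, "gone", "x")
  topic_append(tp, 1, "gone", NULL)
  compact_partition(tp, 1) # empties partition 1 entirely
  before <- retained_triples(tp, 0)
  close_store(st)

  st2 <- log_store(root)
  tp2 <- open_topic(st2, "t")
  expect_equal(retained_triples(tp2, 0), before)
  # the watermark survives even though compaction removed every record
  expect_equal(end_offsets(tp2)[["1"]], 2)
  expect_equal(topic_append(tp2, 1, "new", "v"), 2)
})

test_that("a torn final record is dropped on reopen, earlier records survive", {
  root <- tempfile("torn-")
  st <- log_store(root)
  tp <- create_topic(st, topic_spec("t", 1))
  topic_append(tp, 0, "k1", "v1")
  topic_append(tp, 0, "k2", "v2")
  close_store(st)
  # simulate a crash mid-append: half a record at the segment tail
  seg <- file.path(root, "t", "0.log")
  con <- file(seg, open = "ab")
  writeBin(as.raw(c(200, 0, 0, 0, 1, 2, 3)), con) # length prefix + stub
  close(con)

  st2 <- log_store(root)
  tp2 <- open_topic(st2, "t")
  got <- retained_triples(tp2)
  expect_equal(got$key, c("k1", "k2"))
  expect_equal(topic_append(tp2, 0, "k3", "v3"), 2)
})

test_that("replica placement survives R-1 failures but not R", {
  st <- temp_store(n_brokers = 7)
  tp <- create_topic(st, topic_spec("t", 7, replication_factor = 3))

  # partition i sits on brokers {i, i+1, i+2 mod 7}
  expect_equal(tp$placements[[1]], c(0L, 1L, 2L))
  expect_equal(tp$placements[[7]], c(6L, 0L, 1L))

  expect_equal(unname(surviving_replicas(tp, integer(0))), rep(3L, 7))

  # every 2-broker failure leaves at least one replica everywhere
  for (f in utils::combn(0:6, 2, simplify = FALSE)) {
    expect_true(all(surviving_replicas(tp, f) >= 1))
  }
  # but failing three consecutive brokers wipes a partition
  expect_equal(unname(surviving_replicas(tp, c(0, 1, 2))[1]), 0L)
  expect_equal(max_safe_failures(tp), 2L)
})

test_that("the safe-failure bound equals R - 1 across broker counts", {
  for (B in 4:8) {
    for (R in 1:3) {
      st <- temp_store(n_brokers = B)
      tp <- create_topic(st, topic_spec("t", B, replication_factor = R))
      expect_equal(max_safe_failures(tp), R - 1L,
                   info = sprintf("B=%d R=%d", B, R))
    }
  }
})
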