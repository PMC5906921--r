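# a tiny handler for exercising the runner: echoes the payload upper-cased
echo_handler <- function(msg) {
  list(list(key = msg$key, value = toupper(rawToChar(msg$value))))
}

setup_instruction_topic <- function(store, n_partitions, payloads) {
  t_in <- create_topic(store, topic_spec("instructions", n_partitions))
  t_out <- create_topic(store, topic_spec("outputs", n_partitions))
  cfg <- partitioner_config()
  for (i in seq_along(payloads)) {
    produce(t_in, key = as.character(i - 1L), value = payloads[i],
            config = cfg)
  }
  emit_back_markers(t_in, "job")
  list(t_in = t_in, t_out = t_out)
}

test_that("a single agent handles every instruction exactly once", {
  st <- temp_store()
  tt <- setup_instruction_topic(st, 4, paste0("job", 1:4))
  cfg <- agent_config("workers", "instructions", "outputs")
  report <- run_agent(st, cfg, echo_handler, sweep_id = "job")
  expect_equal(report$jobs, 4)
  expect_equal(report$messages_out, 4)
  expect_equal(report$errors, 0)
})

test_that("cooperating agents split the work with no duplicates", {
  st <- temp_store()
  tt <- setup_instruction_topic(st, 4, paste0("job", 0:7))
  cfg <- agent_config("workers", "instructions", "outputs",
                      parallelization = 4)
  reports <- run_agent_group(st, cfg, echo_handler, sweep_id = "job")
  expect_equal(sum(vapply(reports, `[[`, numeric(1), "jobs")), 8)
  outs <- unlist(lapply(0:3, function(p) {
    vapply(Filter(Negate(is_back_marker), topic_read(tt$t_out, p)),
           function(m) rawToChar(m$value), character(1))
  }))
  expect_equal(sort(outs), sort(toupper(paste0("job", 0:7))))
})

test_that("surplus agents beyond the partition count idle harmlessly", {
  st <- temp_store()
  tt <- setup_instruction_topic(st, 2, paste0("job", 1:6))
  cfg <- agent_config("workers", "instructions", "outputs",
                      parallelization = 5)
  reports <- run_agent_group(st, cfg, echo_handler, sweep_id = "job")
  jobs <- vapply(reports, `[[`, numeric(1), "jobs")
  expect_equal(sum(jobs), 6)
  expect_gte(sum(jobs == 0), 3) # at least the three surplus members
})

test_that("handler failures are diverted to the error topic", {
  st <- temp_store()
  tt <- setup_instruction_topic(st, 1, paste0("job", 1:8))
  failing <- function(msg) {
    if (rawToChar(msg$value) == "job3") stop("boom on job3")
    echo_handler(msg)
  }
  cfg <- agent_config("workers", "instructions", "outputs")
  report <- run_agent(st, cfg, failing, sweep_id = "job")
  expect_equal(report$errors, 1)
  expect_equal(report$messages_out, 7)
  errs <- topic_read(open_topic(st, "instructions.errors"), 0)
  expect_length(errs, 1)
  expect_match(rawToChar(errs[[1]]$value), "boom on job3")
})

test_that("the loader emits one message per chunk of each record", {
  st <- temp_store()
  fasta <- tempfile(fileext = ".fa")
  write_fasta(list(sequence_record("r1", random_dna(50)),
                   sequence_record("r2", random_dna(100000)),
                   sequence_record("r3", random_dna(150000))), fasta)
  tt <- setup_instruction_topic(st, 1, fasta)
  cfg <- agent_config("loaders", "instructions", "outputs",
                      output_partitioner = partitioner_config(
                        "custom", key_extractor = chunk_key_extractor))
  report <- run_agent(st, cfg, loader_handler(), sweep_id = "job")
  expect_equal(report$messages_out, 1 + 1 + 2) # ceil-sum over records

  # an empty source succeeds with zero messages
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  st2 <- temp_store()
  setup_instruction_topic(st2, 1, empty)
  r2 <- run_agent(st2, cfg, loader_handler(), sweep_id = "job")
  expect_equal(r2$messages_out, 0)
  expect_equal(r2$errors, 0)

  # an unresolvable source becomes a failed instruction, not a crash
  st3 <- temp_store()
  setup_instruction_topic(st3, 1, "/no/such/file.fa")
  r3 <- run_agent(st3, cfg, loader_handler(), sweep_id = "job")
  expect_equal(r3$errors, 1)
  errs <- topic_read(open_topic(st3, "instructions.errors"), 0)
  expect_match(rawToChar(errs[[1]]$value), "cannot resolve source")
})

test_that("per-chunk GC results aggregate to whole-sequence counts", {
  set.seed(33)
  st <- temp_store()
  rec <- sequence_record("big", random_dna(250000))
  t_in <- create_topic(st, topic_spec("chunks", 2))
  t_out <- create_topic(st, topic_spec("gc", 2))
  cfg <- partitioner_config("custom", key_extractor = chunk_key_extractor)
  for (chunk in chunk_sequence(rec)) {
    m <- encode_chunk_message(chunk)
    produce(t_in, key = m$key, value = m$value, config = cfg)
  }
  emit_back_markers(t_in, "gc")
  acfg <- agent_config("gcers", "chunks", "gc", output_partitioner = cfg)
  report <- run_agent(st, acfg, gc_handler(), sweep_id = "gc")
  expect_equal(report$messages_out, 3) # ceil(250000 / 100000)

  agg <- aggregate_gc(st, "gc")
  expect_equal(nrow(agg), 1)
  truth <- gc_counts(rec$residues)
  expect_equal(agg$g, truth$g)
  expect_equal(agg$c, truth$c)
  expect_equal(agg$length, 250000)
  expect_equal(agg$gc_fraction, gc_fraction(truth))

  # an all-N chunk yields defined counts but an undefined fraction
  h <- gc_handler()
  nn <- encode_chunk_message(sequence_chunk("nn", 0, 1, strrep("N", 40)))
  out <- h(list(key = nn$key, value = nn$value))
  parsed <- jsonlite::fromJSON(rawToChar(out[[1]]$value))
  expect_equal(parsed$other, 40)
  expect_null(parsed$fraction)
})

test_that("chunks arriving out of order still aggregate once complete", {
  st <- temp_store()
  t_out <- create_topic(st, topic_spec("gc", 1))
  rec <- sequence_record("acc", random_dna(30))
  chunks <- chunk_sequence(rec, 10)
  h <- gc_handler()
  for (i in c(3, 1, 2)) {
    m <- encode_chunk_message(chunks[[i]])
    out <- h(list(key = m$key, value = m$value))[[1]]
    topic_append(t_out, 0, out$key, out$value)
  }
  agg <- aggregate_gc(st, "gc", group = "agg-ooo")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$length, 30)
  expect_equal(agg$gc_fraction, gc_fraction(rec$residues))

  # redelivery of a chunk does not change the aggregate
  m <- encode_chunk_message(chunks[[2]])
  out <- h(list(key = m$key, value = m$value))[[1]]
  topic_append(t_out, 0, out$key, out$value)
  agg2 <- aggregate_gc(st, "gc", group = "agg-redelivered")
  expect_equal(agg2$g, agg$g)

  # an incomplete accession is withheld and reported
  t2 <- create_topic(st, topic_spec("gc2", 1))
  m1 <- encode_chunk_message(chunks[[1]])
  o1 <- h(list(key = m1$key, value = m1$value))[[1]]
  topic_append(t2, 0, o1$key, o1$value)
  agg3 <- aggregate_gc(st, "gc2", group = "agg-partial")
  expect_equal(nrow(agg3), 0)
  expect_equal(attr(agg3, "incomplete"), "acc")
})

test_that("equilibrium fires after consecutive unchanged windows", {
  st <- temp_store()
  tp <- create_topic(st, topic_spec("out", 1))
  for (i in 1:5) topic_append(tp, 0, NULL, "x")

  # static size: samples [5, 5, 5] complete at the third window
  ev <- detect_equilibrium(tp, equilibrium_config(clock = logical_clock()))
  expect_true(ev$complete)
  expect_equal(ev$size, 5)
  expect_equal(ev$windows, 3)
  expect_equal(ev$elapsed, 30) # three 10-second logical windows

  # a late write defers completion by one sample: sizes [3, 5, 5, 5]
  st2 <- temp_store()
  tp2 <- create_topic(st2, topic_spec("out", 1))
  for (i in 1:3) topic_append(tp2, 0, NULL, "x")
  window <- 0L
  ev2 <- detect_equilibrium(
    tp2, equilibrium_config(clock = logical_clock()),
    on_window = function() {
      window <<- window + 1L
      if (window == 2L) {
        topic_append(tp2, 0, NULL, "y")
        topic_append(tp2, 0, NULL, "z")
      }
    })
  expect_true(ev2$complete)
  expect_equal(ev2$size, 5)
  expect_equal(ev2$windows, 4)

  # a stream that keeps growing times out distinguishably
  st3 <- temp_store()
  tp3 <- create_topic(st3, topic_spec("out", 1))
  ev3 <- detect_equilibrium(
    tp3, equilibrium_config(clock = logical_clock(), max_windows = 10),
    on_window = function() topic_append(tp3, 0, NULL, "more"))
  expect_false(ev3$complete)
  expect_equal(ev3$event, "timeout")
  expect_equal(ev3$windows, 10)
})
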