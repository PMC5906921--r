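# ---- agent configuration ----------------------------------------------------

#' Configure an autonomous agent
#'
#' An agent is a small autonomous consumer-producer: it joins a consumer
#' group on an instruction (input) topic, handles each message exactly
#' once across the group, and appends its outputs to an output topic
#' through the producer partitioner. Deployed per the coupling used here,
#' the instruction topic's partition count equals the parallelization
#' level, so each of the T/A agents owns one partition.
#'
#' @param group consumer-group id the agents join.
#' @param instruction_topic name of the input topic.
#' @param output_topic name of the output topic (`NULL` for sink agents).
#' @param parallelization intended number of cooperating agents (T/A).
#' @param poll_batch messages fetched per poll.
#' @param output_partitioner a [partitioner_config()] for produced
#'   messages; defaults to the key-hash strategy.
#' @return an `agent_config`.
#' @export
agent_config <- function(group, instruction_topic, output_topic = NULL,
                         parallelization = 1L, poll_batch = 50L,
                         output_partitioner = NULL) {
  stopifnot(parallelization >= 1, poll_batch >= 1)
  structure(
    list(group = group, instruction_topic = instruction_topic,
         output_topic = output_topic,
         parallelization = as.integer(parallelization),
         poll_batch = as.integer(poll_batch),
         output_partitioner = output_partitioner),
    class = "agent_config"
  )
}

ensure_topic <- function(store, name, n_partitions = 1L, ...) {
  if (topic_exists(store, name)) open_topic(store, name)
  else create_topic(store, topic_spec(name, n_partitions, ...))
}

errors_topic_name <- function(config) {
  paste0(config$instruction_topic, ".errors")
}

# ---- the agent itself -------------------------------------------------------

# An agent is an env with a step() driven from outside, so several agents
# can be interleaved cooperatively and pumped from the equilibrium loop.
make_agent <- function(store, config, handler, member) {
  ag <- new.env(parent = emptyenv())
  ag$store <- store
  ag$config <- config
  ag$handler <- handler
  ag$member <- member
  ag$group <- consumer_group(store, config$group)
  ag$topic_in <- open_topic(store, config$instruction_topic)
  ag$topic_out <- if (!is.null(config$output_topic)) {
    open_topic(store, config$output_topic)
  }
  ag$partitioner <- config$output_partitioner %||% partitioner_config()
  ag$marker_parts <- integer(0)
  ag$sweep_id <- NULL
  ag$done <- FALSE
  ag$jobs <- 0L
  ag$messages_out <- 0L
  ag$errors <- 0L
  group_join(ag$group, member)
  class(ag) <- "log_agent"
  ag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One scheduling quantum: poll a batch, handle it, commit. Returns the
# number of messages consumed (0 when idle).
agent_step <- function(ag) {
  if (ag$done) return(0L)
  parts <- group_assignment(ag$group, ag$topic_in)$member_partitions[[ag$member]]
  if (length(parts) == 0L) {
    # more agents than partitions: surplus members sit idle
    ag$done <- TRUE
    return(0L)
  }
  msgs <- group_poll(ag$group, ag$member, ag$topic_in,
                     max_count = ag$config$poll_batch)
  if (length(msgs) == 0L) {
    if (!is.null(ag$sweep_id) &&
        all(parts %in% ag$marker_parts)) {
      ag$done <- TRUE
    }
    return(0L)
  }
  for (m in msgs) {
    if (is_back_marker(m)) {
      ag$marker_parts <- union(ag$marker_parts, m$partition)
      next
    }
    outs <- tryCatch(ag$handler(m), error = function(e) e)
    if (inherits(outs, "error")) {
      err_topic <- ensure_topic(ag$store, errors_topic_name(ag$config))
      topic_append(err_topic, 0L, key = m$key,
                   value = conditionMessage(outs))
      ag$errors <- ag$errors + 1L
      ag$jobs <- ag$jobs + 1L
      next
    }
    ag$jobs <- ag$jobs + 1L
    for (out in outs) {
      produce(ag$topic_out, key = out$key, value = out$value,
              config = ag$partitioner)
      ag$messages_out <- ag$messages_out + 1L
    }
  }
  # commit per partition: next offset to read = max consumed offset + 1
  for (p in unique(vapply(msgs, `[[`, numeric(1), "partition"))) {
    offs <- vapply(msgs[vapply(msgs, function(m) m$partition == p,
                               logical(1))],
                   `[[`, numeric(1), "offset")
    commit_offset(ag$group, ag$member, ag$topic_in, p, max(offs) + 1)
  }
  if (!is.null(ag$sweep_id) && all(parts %in% ag$marker_parts)) {
    ag$done <- TRUE
  }
  length(msgs)
}

agent_report <- function(ag) {
  list(member = ag$member, jobs = ag$jobs,
       messages_out = ag$messages_out, errors = ag$errors)
}

#' Run one agent to completion
#'
#' The agent polls its assigned partitions of the instruction topic,
#' applies `handler` to every non-marker message, appends the handler's
#' output messages to the output topic, and commits after each batch.
#' A handler error does not stop processing: the failing instruction is
#' recorded on `"<instruction_topic>.errors"` and the agent moves on.
#' With a `sweep_id` the agent stops once it has seen that sweep's
#' back-marker on every partition it owns; without one it stops when a
#' poll comes back empty.
#'
#' @param store a [log_store()].
#' @param config an [agent_config()].
#' @param handler function taking a `log_message` and returning a list of
#'   output messages, each a list with `key` and `value`.
#' @param member member id within the group.
#' @param sweep_id sweep whose back-markers terminate the agent (see
#'   [emit_back_markers()]), or `NULL`.
#' @return a report list: `member`, `jobs`, `messages_out`, `errors`.
#' @export
run_agent <- function(store, config, handler, member = "agent-1",
                      sweep_id = NULL) {
  ag <- make_agent(store, config, handler, member)
  ag$sweep_id <- sweep_id
  idle <- 0L
  repeat {
    n <- agent_step(ag)
    if (ag$done) break
    idle <- if (n == 0L) idle + 1L else 0L
    if (idle > 0L && is.null(sweep_id)) break
    if (idle > 2L) {
      stop("agent ", member, " stalled before observing all back-markers")
    }
  }
  agent_report(ag)
}

#' @rdname run_agent
#' @param n_agents number of cooperating agent instances; defaults to
#'   `config$parallelization`. All members join before any consumes, so
#'   the assignment is stable, and the agents are stepped round-robin.
#' @return `run_agent_group` returns the list of per-member reports.
#' @export
run_agent_group <- function(store, config, handler,
                            n_agents = config$parallelization,
                            sweep_id = NULL) {
  agents <- lapply(seq_len(n_agents), function(i) {
    make_agent(store, config, handler, sprintf("%s-m%02d", config$group, i))
  })
  for (ag in agents) ag$sweep_id <- sweep_id
  pump_agents(agents, until_done = !is.null(sweep_id))
  lapply(agents, agent_report)
}

# Round-robin scheduler over a set of agents. With until_done, loops until
# every agent has seen its back-markers; otherwise until a full round
# consumes nothing.
pump_agents <- function(agents, until_done = TRUE, max_rounds = 1e6) {
  for (round in seq_len(max_rounds)) {
    consumed <- 0L
    for (ag in agents) consumed <- consumed + agent_step(ag)
    alldone <- all(vapply(agents, function(a) a$done, logical(1)))
    if (alldone) return(invisible(TRUE))
    if (consumed == 0L && !until_done) return(invisible(TRUE))
    if (consumed == 0L && until_done && round > 2L) {
      # markers pending but nothing arriving: nothing left to do
      stop("agents stalled before observing all back-markers")
    }
  }
  stop("agent scheduler exceeded max_rounds")
}

# ---- the loader and GC handlers --------------------------------------------

#' Resolve an instruction payload to a local FASTA file
#'
#' The default fetcher seam: the loader instruction payload names a
#' source, and the fetcher turns it into a readable FASTA path. This
#' default handles local files only; a network fetcher (FTP download plus
#' archive unpacking and format conversion) can be plugged in through the
#' same interface.
#'
#' @return a function `payload -> path` erroring on unresolvable sources.
#' @export
local_file_fetcher <- function() {
  function(payload) {
    if (!file.exists(payload)) {
      stop("cannot resolve source: ", payload)
    }
    payload
  }
}

#' Loader agent handler: FASTA source to sequence-chunk messages
#'
#' Processes one loader instruction (payload = source locator), resolves
#' it through `fetcher`, reads every FASTA record in the source and emits
#' it as encoded chunk messages -- one message per chunk, partitioned by
#' accession so a sequence's chunks stay together and in order.
#'
#' @param fetcher a function payload -> FASTA path; defaults to
#'   [local_file_fetcher()].
#' @param chunk_size maximum residues per chunk message.
#' @return a handler function for [run_agent()].
#' @export
loader_handler <- function(fetcher = local_file_fetcher(),
                           chunk_size = 100000) {
  function(msg) {
    payload <- rawToChar(msg$value)
    path <- fetcher(payload)
    records <- read_fasta(path)
    outs <- list()
    for (rec in records) {
      for (chunk in chunk_sequence(rec, chunk_size)) {
        outs[[length(outs) + 1L]] <- encode_chunk_message(chunk)
      }
    }
    outs
  }
}

#' GC-content agent handler: chunk message to GC result message
#'
#' Counts bases in one sequence chunk. The output key equals the chunk
#' key, so redelivered chunks overwrite rather than duplicate once the
#' result topic is compacted (idempotent outputs); the counts are additive
#' so per-chunk results aggregate exactly to whole-sequence values.
#'
#' @return a handler function for [run_agent()]. Output values are JSON
#'   records with the accession, chunk index/count, base counts and the
#'   per-chunk GC fraction (`null` when the chunk has no unambiguous
#'   bases).
#' @export
gc_handler <- function() {
  function(msg) {
    chunk <- decode_chunk_message(msg$key, msg$value)
    counts <- gc_counts(chunk$residues)
    list(list(key = msg$key, value = encode_gc_result(chunk, counts)))
  }
}

encode_gc_result <- function(chunk, counts) {
  charToRaw(as.character(jsonlite::toJSON(
    list(accession = chunk$accession, chunk_index = chunk$chunk_index,
         chunk_count = chunk$chunk_count,
         a = counts$a, c = counts$c, g = counts$g, t = counts$t,
         other = counts$other, fraction = gc_fraction(counts)),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")))
}

decode_gc_result <- function(value) {
  jsonlite::fromJSON(rawToChar(value))
}

#' Aggregate per-chunk GC results into per-accession values
#'
#' Drains a result topic through a consumer group and, for every
#' accession whose `chunk_count` chunks have all been observed, sums the
#' per-chunk base counts and computes the whole-sequence GC fraction.
#' Redelivered chunks (same chunk index) are ignored; conflicting
#' `chunk_count` values for one accession are an error.
#'
#' @param store a [log_store()].
#' @param results_topic name of the topic carrying [gc_handler()] output.
#' @param group consumer-group id used for the drain.
#' @return a data frame with one row per complete accession: base counts,
#'   total length, chunk count and `gc_fraction`, sorted by accession.
#'   Accessions still missing chunks are reported in the `"incomplete"`
#'   attribute.
#' @export
aggregate_gc <- function(store, results_topic, group = "gc-aggregate") {
  topic <- open_topic(store, results_topic)
  grp <- consumer_group(store, group)
  member <- paste0(group, "-m1")
  group_join(grp, member)
  acc_env <- new.env(parent = emptyenv())
  repeat {
    msgs <- group_poll(grp, member, topic, max_count = 500)
    if (length(msgs) == 0L) break
    for (m in msgs) {
      if (is_back_marker(m) || is.null(m$value)) next
      r <- decode_gc_result(m$value)
      slot <- acc_env[[r$accession]]
      if (is.null(slot)) {
        slot <- list(chunk_count = r$chunk_count,
                     seen = integer(0), counts = base_counts())
      } else if (slot$chunk_count != r$chunk_count) {
        stop("conflicting chunk_count for accession ", r$accession)
      }
      if (r$chunk_index %in% slot$seen) next # redelivery: idempotent
      slot$seen <- c(slot$seen, r$chunk_index)
      slot$counts <- slot$counts +
        base_counts(r$a, r$c, r$g, r$t, r$other)
      acc_env[[r$accession]] <- slot
    }
    for (p in unique(vapply(msgs, `[[`, numeric(1), "partition"))) {
      offs <- vapply(msgs[vapply(msgs, function(m) m$partition == p,
                                 logical(1))],
                     `[[`, numeric(1), "offset")
      commit_offset(grp, member, topic, p, max(offs) + 1)
    }
  }
  accs <- sort(ls(acc_env))
  complete <- vapply(accs, function(a) {
    s <- acc_env[[a]]
    length(s$seen) == s$chunk_count
  }, logical(1))
  rows <- lapply(accs[complete], function(a) {
    s <- acc_env[[a]]
    ct <- s$counts
    data.frame(accession = a, a = ct$a, c = ct$c, g = ct$g, t = ct$t,
               other = ct$other,
               length = ct$a + ct$c + ct$g + ct$t + ct$other,
               chunks = s$chunk_count,
               gc_fraction = gc_fraction(ct),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(accession = character(0), a = numeric(0), c = numeric(0),
               g = numeric(0), t = numeric(0), other = numeric(0),
               length = numeric(0), chunks = integer(0),
               gc_fraction = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "incomplete") <- accs[!complete]
  out
}

# ---- equilibrium completion -------------------------------------------------

#' Clocks for equilibrium sampling
#'
#' `logical_clock` is a deterministic clock whose `sleep` simply advances
#' a counter -- sampling windows become logical steps, which is how the
#' pipeline harness and the tests drive equilibrium detection.
#' `system_clock` sleeps for real.
#'
#' @return a clock: list with `now()` (seconds) and `sleep(dt)`.
#' @export
logical_clock <- function() {
  env <- new.env(parent = emptyenv())
  env$t <- 0
  list(
    now = function() env$t,
    sleep = function(dt) env$t <- env$t + dt
  )
}

#' @rdname logical_clock
#' @export
system_clock <- function() {
  list(now = function() as.numeric(Sys.time()), sleep = Sys.sleep)
}

#' Equilibrium detection settings
#'
#' A streamed computation is considered complete when the size of its
#' output topic stops changing: by default, when the size is unchanged
#' over two consecutive 10-second observation windows.
#'
#' @param window_seconds observation window length (default 10).
#' @param consecutive_windows unchanged windows required (default 2).
#' @param clock a clock from [logical_clock()] or [system_clock()].
#' @param max_windows give up (timeout event) after this many samples.
#' @return an `equilibrium_config`.
#' @export
equilibrium_config <- function(window_seconds = 10,
                               consecutive_windows = 2L,
                               clock = system_clock(),
                               max_windows = Inf) {
  stopifnot(window_seconds > 0, consecutive_windows >= 1)
  structure(
    list(window_seconds = window_seconds,
         consecutive_windows = as.integer(consecutive_windows),
         clock = clock, max_windows = max_windows),
    class = "equilibrium_config"
  )
}

#' Wait for a topic to reach output equilibrium
#'
#' Samples the topic size (sum of end offsets) once per window and fires
#' when `consecutive_windows` successive inter-sample periods show no
#' change. With a [logical_clock()] the behaviour is deterministic; the
#' optional `on_window` callback runs before each sample and is how the
#' benchmark harness pumps its cooperative agents.
#'
#' @param topic a topic handle.
#' @param config an [equilibrium_config()].
#' @param on_window optional zero-argument callback invoked each window.
#' @return a list: `complete` (logical), `event` (`"complete"` or
#'   `"timeout"`), `size` (last sampled size), `windows` (samples taken),
#'   `elapsed` (clock seconds).
#' @export
detect_equilibrium <- function(topic, config = equilibrium_config(),
                               on_window = NULL) {
  t0 <- config$clock$now()
  last <- NULL
  stable <- 0L
  windows <- 0L
  repeat {
    config$clock$sleep(config$window_seconds)
    if (!is.null(on_window)) on_window()
    size <- sum(end_offsets(topic))
    windows <- windows + 1L
    if (!is.null(last) && size == last) {
      stable <- stable + 1L
    } else {
      stable <- 0L
    }
    last <- size
    if (stable >= config$consecutive_windows) {
      return(list(complete = TRUE, event = "complete", size = size,
                  windows = windows,
                  elapsed = config$clock$now() - t0))
    }
    if (windows >= config$max_windows) {
      return(list(complete = FALSE, event = "timeout", size = size,
                  windows = windows,
                  elapsed = config$clock$now() - t0))
    }
  }
}
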