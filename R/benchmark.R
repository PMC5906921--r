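# ---- synthetic corpus -------------------------------------------------------

#' Length distributions for the synthetic corpus generator
#'
#' * `length_fixed(L)`: every record has length `L`.
#' * `length_uniform(lo, hi)`: lengths drawn uniformly.
#' * `length_mix(...)`: mostly short records with a small fraction of
#'   records longer than the 100,000-nt chunking threshold, so a corpus
#'   always exercises both the single-chunk and the multi-chunk path.
#'
#' @param length,lo,hi record lengths in nucleotides.
#' @param short,long `c(lo, hi)` ranges for the two mixture components.
#' @param long_fraction probability of drawing from the long component.
#' @return a `length_distribution`.
#' @export
length_fixed <- function(length) {
  structure(list(kind = "fixed", length = length),
            class = "length_distribution")
}

#' @rdname length_fixed
#' @export
length_uniform <- function(lo, hi) {
  stopifnot(lo >= 0, hi >= lo)
  structure(list(kind = "uniform", lo = lo, hi = hi),
            class = "length_distribution")
}

#' @rdname length_fixed
#' @export
length_mix <- function(short = c(1000, 39000), long = c(100001, 180000),
                       long_fraction = 0.02) {
  stopifnot(long[1] > 100000, long_fraction >= 0, long_fraction <= 1)
  structure(list(kind = "mix", short = short, long = long,
                 long_fraction = long_fraction),
            class = "length_distribution")
}

draw_lengths <- function(dist, n) {
  switch(dist$kind,
    fixed = rep(dist$length, n),
    uniform = sample(seq(dist$lo, dist$hi), n, replace = TRUE),
    mix = {
      is_long <- stats::runif(n) < dist$long_fraction
      out <- sample(seq(dist$short[1], dist$short[2]), n, replace = TRUE)
      if (any(is_long)) {
        out[is_long] <- sample(seq(dist$long[1], dist$long[2]),
                               sum(is_long), replace = TRUE)
      }
      out
    },
    stop("unknown length distribution kind: ", dist$kind))
}

#' Specify a synthetic FASTA corpus
#'
#' The generator stands in for the reference-database files a production
#' deployment would stream from an archive: a set of multi-record FASTA
#' files with seeded, fully reproducible content. Defaults are the
#' desk-scale study conditions used throughout: 4 files of 250 records
#' with mean length about 20,000 nt (roughly 20 MB), a 2% admixture of
#' records above the 100,000-nt chunking threshold, and a GC target of
#' 0.5.
#'
#' @param n_files number of FASTA files.
#' @param records_per_file records per file.
#' @param length_distribution a [length_fixed()], [length_uniform()] or
#'   [length_mix()].
#' @param gc_target expected GC fraction of generated residues, in
#'   `[0, 1]`.
#' @param seed RNG seed; the corpus is byte-identical for a given spec.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_files = 4L, records_per_file = 250L,
                           length_distribution = length_mix(),
                           gc_target = 0.5, seed = 42L) {
  stopifnot(n_files >= 0, records_per_file >= 0,
            gc_target >= 0, gc_target <= 1,
            inherits(length_distribution, "length_distribution"))
  structure(
    list(n_files = as.integer(n_files),
         records_per_file = as.integer(records_per_file),
         length_distribution = length_distribution,
         gc_target = gc_target, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic FASTA corpus with a ground-truth manifest
#'
#' Residues are drawn i.i.d. with `P(G) = P(C) = gc_target / 2`. The
#' manifest records the exact per-record base counts observed at
#' generation time, giving an independent ground truth for every
#' downstream GC computation. Generation is deterministic: the same spec
#' produces byte-identical files (the caller's RNG state is left
#' untouched).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return a list: `files` (paths), `manifest` (data frame with per-record
#'   lengths, base counts and GC fraction; also written as
#'   `manifest.tsv`), and the `spec`.
#' @export
generate_corpus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - spec$gc_target) / 2, spec$gc_target / 2,
             spec$gc_target / 2, (1 - spec$gc_target) / 2)
  files <- character(0)
  manifest <- list()
  for (f in seq_len(spec$n_files)) {
    path <- file.path(dir, sprintf("synthetic-%03d.fasta", f))
    lens <- draw_lengths(spec$length_distribution, spec$records_per_file)
    records <- vector("list", spec$records_per_file)
    for (r in seq_len(spec$records_per_file)) {
      idx <- sample.int(4L, lens[r], replace = TRUE, prob = probs)
      counts <- tabulate(idx, nbins = 4L)
      acc <- sprintf("SYN%03d-%04d", f, r)
      records[[r]] <- sequence_record(acc, paste0(bases[idx],
                                                  collapse = ""),
                                      "synthetic")
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = basename(path), accession = acc, length = lens[r],
        a = counts[1], c = counts[2], g = counts[3], t = counts[4],
        other = 0,
        gc_fraction = if (lens[r] > 0) {
          (counts[2] + counts[3]) / lens[r]
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
    write_fasta(records, path)
    files <- c(files, path)
  }
  manifest <- if (length(manifest) > 0) do.call(rbind, manifest) else
    data.frame(file = character(0), accession = character(0),
               length = numeric(0), a = numeric(0), c = numeric(0),
               g = numeric(0), t = numeric(0), other = numeric(0),
               gc_fraction = numeric(0), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  list(files = files, manifest = manifest, spec = spec)
}

# ---- baseline: multithreaded flat-file processing ---------------------------

benchmark_row <- function(mode, parallelization, load_units,
                          elapsed_seconds, sequences_processed,
                          valid = TRUE) {
  data.frame(mode = mode, parallelization = parallelization,
             load_units = load_units, elapsed_seconds = elapsed_seconds,
             sequences_processed = sequences_processed, valid = valid,
             stringsAsFactors = FALSE)
}

baseline_worker <- function(path) {
  records <- read_fasta(path)
  rows <- lapply(records, function(rec) {
    ct <- gc_counts(rec$residues)
    data.frame(accession = rec$accession, a = ct$a, c = ct$c, g = ct$g,
               t = ct$t, other = ct$other,
               length = nchar(rec$residues),
               gc_fraction = gc_fraction(ct), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Single-process multithreaded baseline
#'
#' The comparison system: one process parses the flat FASTA files and
#' computes whole-record GC in memory, parallelized over files with
#' forked workers (no log store involved). The parallelization factor is
#' capped by the file count -- each file must be read start to finish by
#' one worker -- which is exactly the structural limit the message-log
#' repository removes.
#'
#' @param files FASTA file paths.
#' @param n_threads forked workers (files are split among them).
#' @return a list: `row` (mode, parallelization, load, elapsed seconds,
#'   sequences processed) and `results` (per-accession base counts and GC,
#'   sorted by accession).
#' @export
run_baseline <- function(files, n_threads = 1L) {
  t0 <- proc.time()[["elapsed"]]
  parts <- if (n_threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, baseline_worker, mc.cores = n_threads)
  } else {
    lapply(files, baseline_worker)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  results <- if (length(parts) > 0) do.call(rbind, parts) else
    data.frame(accession = character(0), a = numeric(0), c = numeric(0),
               g = numeric(0), t = numeric(0), other = numeric(0),
               length = numeric(0), gc_fraction = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(results) && nrow(results) > 0) {
    results <- results[order(results$accession), , drop = FALSE]
    rownames(results) <- NULL
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  list(row = benchmark_row("baseline", n_threads, length(files), elapsed,
                           if (is.null(results)) 0L else nrow(results)),
       results = results)
}

# ---- pipeline: loader agents -> GC agents over the log store ----------------

#' Full loader-to-GC agent pipeline over a log store
#'
#' Reproduces the streamed architecture end to end: loader instructions
#' (one per file, incremental numeric keys, default partitioning) go to an
#' instruction topic whose partition count equals the number of agents;
#' loader agents chunk the FASTA records into a sequence topic
#' (co-partitioned by accession); GC agents stream the sequence topic into
#' a result topic. The loader sweep terminates via back-markers; overall
#' completion is detected by output equilibrium on the result topic --
#' the agents are pumped once per observation window and the run is
#' complete when the result topic's size is unchanged over
#' `consecutive_windows` windows.
#'
#' @param files FASTA file paths (the load; scaled in tandem with
#'   `n_agents` by [run_benchmark()]).
#' @param n_agents parallelization level (T/A): agent instances per stage
#'   and instruction-topic partitions.
#' @param store a [log_store()]; a temporary one is created when `NULL`.
#' @param chunk_size maximum residues per chunk message.
#' @param eq an [equilibrium_config()]; defaults to the standard
#'   two-consecutive-10-unit-window rule on a [logical_clock()], which
#'   makes completion detection deterministic.
#' @return a list: `row` (a benchmark row; `valid = FALSE` on equilibrium
#'   timeout), `results` (per-accession aggregate, as [aggregate_gc()]),
#'   `equilibrium` (the completion event) and the per-agent `reports`.
#' @export
run_pipeline <- function(files, n_agents = 1L, store = NULL,
                         chunk_size = 100000,
                         eq = equilibrium_config(clock = logical_clock(),
                                                 max_windows = 10000)) {
  if (is.null(store)) {
    root <- tempfile("bench-store-")
    on.exit(unlink(root, recursive = TRUE), add = TRUE)
    store <- log_store(root)
  }
  tag <- sprintf("run%d", next_run_id())
  t_instr <- create_topic(store, topic_spec(paste0(tag, "-instructions"),
                                            n_agents))
  t_seq <- create_topic(store, topic_spec(paste0(tag, "-sequences"),
                                          n_agents))
  t_gc <- create_topic(store, topic_spec(paste0(tag, "-gc"), n_agents))

  t0 <- proc.time()[["elapsed"]]
  producer <- partitioner_config()
  for (i in seq_along(files)) {
    produce(t_instr, key = as.character(i - 1L), value = files[i],
            config = producer)
  }
  emit_back_markers(t_instr, "load")

  loader_cfg <- agent_config(
    group = paste0(tag, "-loaders"),
    instruction_topic = t_instr$name, output_topic = t_seq$name,
    parallelization = n_agents, poll_batch = 1L,
    output_partitioner = partitioner_config(
      "custom", key_extractor = chunk_key_extractor))
  gc_cfg <- agent_config(
    group = paste0(tag, "-gc-agents"),
    instruction_topic = t_seq$name, output_topic = t_gc$name,
    parallelization = n_agents, poll_batch = 200L,
    output_partitioner = partitioner_config(
      "custom", key_extractor = chunk_key_extractor))

  loaders <- lapply(seq_len(n_agents), function(i) {
    ag <- make_agent(store, loader_cfg, loader_handler(chunk_size = chunk_size),
                     sprintf("%s-loader%02d", tag, i))
    ag$sweep_id <- "load"
    ag
  })
  gcs <- lapply(seq_len(n_agents), function(i) {
    make_agent(store, gc_cfg, gc_handler(),
               sprintf("%s-gc%02d", tag, i))
  })

  # each observation window gives every agent one scheduling quantum;
  # loaders run first so chunks appended in a window are visible to the
  # GC agents within the same window
  ev <- detect_equilibrium(t_gc, eq, on_window = function() {
    for (ag in loaders) agent_step(ag)
    for (ag in gcs) agent_step(ag)
  })

  results <- aggregate_gc(store, t_gc$name, group = paste0(tag, "-agg"))
  elapsed <- proc.time()[["elapsed"]] - t0
  list(row = benchmark_row("pipeline", n_agents, length(files), elapsed,
                           nrow(results), valid = ev$complete),
       results = results, equilibrium = ev,
       reports = lapply(c(loaders, gcs), agent_report))
}

# ---- the scaled experiment --------------------------------------------------

#' Run the scalability experiment: load and parallelization in tandem
#'
#' For each level `k` in `levels`, processes the first `k` corpus files
#' with `k` baseline threads and, separately, with `k` pipeline agents --
#' the load grows with the parallelization, so a perfectly scalable
#' system shows a flat elapsed-time response. Correctness, not timing, is
#' the contract: both modes must produce identical per-accession GC
#' results for the same files.
#'
#' @param levels parallelization levels (the corpus must have at least
#'   `max(levels)` files).
#' @param spec a [synthetic_spec()]; `n_files` defaults to `max(levels)`.
#' @param dir working directory for the corpus (temporary when `NULL`).
#' @return a `scalability_report`: the benchmark rows, per-mode
#'   least-squares slopes of elapsed time against parallelization, the
#'   per-level result sets and the corpus manifest.
#' @export
run_benchmark <- function(levels = c(1L, 2L, 4L), spec = NULL, dir = NULL) {
  levels <- sort(unique(as.integer(levels)))
  if (is.null(spec)) spec <- synthetic_spec(n_files = max(levels))
  if (spec$n_files < max(levels)) {
    stop("corpus has fewer files than the highest parallelization level")
  }
  if (is.null(dir)) {
    dir <- tempfile("bench-corpus-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  }
  corpus <- generate_corpus(spec, dir)
  rows <- list()
  results <- list()
  for (k in levels) {
    files_k <- corpus$files[seq_len(k)]
    base <- run_baseline(files_k, n_threads = k)
    pipe <- run_pipeline(files_k, n_agents = k)
    rows[[length(rows) + 1L]] <- base$row
    rows[[length(rows) + 1L]] <- pipe$row
    results[[as.character(k)]] <- list(baseline = base$results,
                                       pipeline = pipe$results)
  }
  rows <- do.call(rbind, rows)
  rep <- scalability_report(rows)
  rep$results <- results
  rep$manifest <- corpus$manifest
  rep
}

#' Summarize benchmark rows into a scalability report
#'
#' Scalability is read off the slope of elapsed time against
#' parallelization when load is scaled in tandem: a flat line (slope near
#' zero) is perfect scalability, and the steeper the slope the less
#' scalable the system. The slope is fit by least squares per mode and
#' only when at least three parallelization levels are present;
#' otherwise the report carries the rows alone. Verdicts are
#' informational -- absolute timings are hardware-bound.
#'
#' @param rows a data frame of benchmark rows (as produced by
#'   [run_baseline()] / [run_pipeline()]).
#' @return a `scalability_report` with `rows` and a `slopes` data frame
#'   (mode, slope, verdict).
#' @export
scalability_report <- function(rows) {
  stopifnot(is.data.frame(rows))
  slopes <- lapply(split(rows, rows$mode), function(d) {
    if (length(unique(d$parallelization)) < 3L) {
      return(data.frame(mode = d$mode[1], slope = NA_real_,
                        verdict = "insufficient levels (need >= 3)",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(elapsed_seconds ~ parallelization, data = d)
    slope <- unname(stats::coef(fit)[["parallelization"]])
    span <- diff(range(d$parallelization))
    drift <- abs(slope) * span
    verdict <- if (drift <= 0.25 * mean(d$elapsed_seconds) + 1e-9) {
      "flat"
    } else if (slope > 0) "rising" else "falling"
    data.frame(mode = d$mode[1], slope = slope, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  structure(
    list(rows = rows, slopes = do.call(rbind, c(slopes,
                                                make.row.names = FALSE))),
    class = "scalability_report"
  )
}

#' @export
print.scalability_report <- function(x, ...) {
  cat("Scalability (load scaled in tandem with parallelization)\n\n")
  wide <- stats::reshape(
    x$rows[, c("parallelization", "mode", "elapsed_seconds")],
    idvar = "parallelization", timevar = "mode", direction = "wide")
  names(wide) <- sub("^elapsed_seconds\\.", "", names(wide))
  hdr <- sprintf("%6s %12s %12s", "T/A",
                 if ("baseline" %in% names(wide)) "baseline(s)" else "",
                 if ("pipeline" %in% names(wide)) "pipeline(s)" else "")
  cat(hdr, "\n")
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("%6d %12.2f %12.2f\n", wide$parallelization[i],
                if ("baseline" %in% names(wide)) wide$baseline[i] else NA,
                if ("pipeline" %in% names(wide)) wide$pipeline[i] else NA))
  }
  cat("\nLeast-squares slope of elapsed vs parallelization:\n")
  for (i in seq_len(nrow(x$slopes))) {
    s <- x$slopes[i, ]
    cat(sprintf("  %-9s %s  (%s)\n", s$mode,
                ifelse(is.na(s$slope), "--",
                       format(s$slope, digits = 4)), s$verdict))
  }
  invisible(x)
}
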