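---
title: "A message-log repository for genomic sequences: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A message-log repository for genomic sequences: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genelog)
```

## Why a log, not files

Flat sequence files couple the parallelization factor to the file
count: one reader per file, start to finish. This package implements
the alternative architecture — an append-only, partitioned message log
as the sequence repository — as a single-process, file-backed library,
so that the architecture's *semantics* (delivery, compaction,
completion, scaling shape) can be exercised and property-tested on one
machine. Nothing here talks to a real broker cluster; where a cluster
would replicate bytes across machines, this implementation models
replication as placement metadata, which is exactly the part of
replication that carries the safety arithmetic.

## The storage model

A **topic** has `N ≥ 1` partitions; each partition is an append-only
sequence of immutable `(key, value)` messages addressed by offset.
Segment files use a self-delimiting binary record format
(`[record_length u32][offset u64][timestamp u64][key_length i32][key]
[value_length i32][value]`, little-endian, length −1 encoding an absent
field), which makes a partition crash-truncatable: a torn final record
is simply dropped on reopen. Offsets and timestamps are handled as R
doubles, exact for integers below 2^53 — far beyond any message count
or epoch-millisecond value this store will meet. Timestamps come from
an injectable store clock so tests can be deterministic.

**Compaction** recopies a partition oldest-to-youngest, keeping only
the youngest message per key; a key whose youngest message is a
tombstone (absent value) is removed altogether, tombstone included.
Three choices here were genuinely open:

* *Offsets are preserved, never renumbered.* Renumbering would break
  every committed consumer position; retained-offset stability is also
  what makes "compaction idempotence" a testable property.
* *Tombstones are removed in the same pass that applies them.* A
  retention grace period matters when concurrent consumers may be
  mid-partition in a distributed deployment; in-process, the simplest
  semantics satisfying the deletion rule wins. A grace period would be
  a straightforward extension.
* *Keyless messages are exempt* — with no key identity there is nothing
  to supersede.

Compaction rewrites to a temporary file and atomically renames it, so a
reader never observes a half-compacted segment. Because compaction can
delete a partition's youngest records, the next-offset watermark is
persisted in topic metadata; on reopen the store takes the maximum of
the scanned and recorded watermarks.

**Replication** is placement metadata: partition `i` of a topic with
replication factor `R` is placed on simulated brokers
`(i, i+1, …, i+R−1) mod B`. The safety claim — every failure of up to
`R − 1` brokers leaves at least one replica of every partition, and
some `R`-broker failure does not — is checked by exhaustive enumeration
of failure subsets (feasible for the broker counts in play; the test
suite sweeps `B ≤ 8`).

## Producers and consumer groups

Producers pick the destination partition by hashing the key.
The hash is **FNV-1a 64-bit** (offset basis `0xcbf29ce484222325`,
prime `0x100000001b3`), implemented over 16-bit limbs so every
operation is exact in doubles, and verified against the published test
vectors. The upstream ecosystem uses murmur2 here; any deterministic,
well-spread, platform-stable hash satisfies the contract ("a
partitioning strategy based on the key"), and FNV-1a is trivially
portable. A per-producer `key_extractor` reproduces the customization
hook: sequence-chunk producers hash only the accession portion of the
key. Keyless messages round-robin over a producer-local counter.

Consumer-group assignment is a pure function of `(N, sorted member
ids, strategy)`. Both **range** (contiguous blocks, first `N mod M`
members get one extra) and **round-robin** (deal in turn) are provided
because both reproduce the canonical worked examples (4 partitions / 4
consumers → one each; 4 / 2 → two each); range is the default, matching
broker-ecosystem convention. Rebalancing is stop-the-world: membership
changes reset all in-memory read positions to the committed offsets, so
a partition's new owner resumes exactly where the last commit left off.
Commits are explicit and monotone (a backwards commit is ignored with a
warning); together with idempotent output keys this gives the standard
at-least-once-with-idempotence approximation of exactly-once, which is
the weakest guarantee under which the pipeline invariants below are
still exact.

## Sequences as messages

A FASTA record becomes `ceiling(len / 100000)` chunk messages; 100,000
nt is the chunking threshold for "a full sequence or a part thereof",
and a record at exactly the threshold stays whole. The chunk key is
`accession/index/count`, but the *partitioning* bytes are the accession
alone. This resolves a real design conflict: if chunks were partitioned
by their full key they could scatter across partitions (losing
ordering), and if a compacted topic treated the full chunk key as
identity, re-publishing a shorter version of a sequence would leave
stale high-index chunks behind. Sequence topics are therefore created
non-compacted by default, and re-publication belongs in a new sweep
rather than in compaction.

Back-markers live in a reserved key namespace — keys starting with the
NUL byte, which no accession can contain since accessions come from
FASTA header text. One marker per partition closes a sweep; a consumer
group has "touched everything" exactly when it has seen the sweep's
marker on every partition.

**GC content.** Base counting is case-insensitive over A/C/G/T with
everything else (N and IUPAC ambiguity codes) in `other`, and the GC
fraction is `(G+C)/(A+C+G+T)`. The motivating description of GC as a
ratio of C+G "to" A+T reads literally as `(G+C)/(A+T)`; the
conventional fraction is implemented instead, and the full counts are
exposed so either ratio is a one-liner. A sequence with no unambiguous
bases has an *undefined* fraction (`NA`), never 0. Counts are additive
by construction, which is the exactness guarantee behind per-chunk
aggregation: the aggregate of any chunking equals the whole-sequence
count, bit for bit.

## Agents and completion

An agent joins a consumer group on an instruction topic, handles each
message, appends outputs through the producer partitioner, and commits
per batch. Handler failures are appended to
`"<instruction_topic>.errors"` and processing continues — errors must
not silently vanish, and must not poison the sweep either. Agents are
cooperative: a scheduler steps each agent in turn, which keeps
multi-agent runs deterministic and lets the equilibrium loop pump them.

Two completion rules are implemented because both are legitimate:

* **Back-markers** terminate the loader sweep (the instruction stream
  has a known end: one instruction per source file).
* **Equilibrium** terminates the GC stream: the output topic's size
  (sum of end offsets) is sampled once per window, and the computation
  is complete when `consecutive_windows` successive periods show no
  change — by default **two consecutive 10-second windows**. With a
  logical clock the windows become scheduling quanta and the rule is
  exactly testable: the detector fires iff the sampled size sequence
  ends with the required run of equal values, and a stream that keeps
  growing hits a distinguishable timeout event.

The harness uses markers for the loader and equilibrium for GC. The
asymmetry is deliberate: the loader's end is structurally knowable,
while the GC stream's input is itself a stream, which is precisely the
situation the equilibrium rule exists for. In the pipeline scheduler,
loaders are stepped before GC agents within each window, so any window
in which work remains strictly grows the output topic — premature
equilibrium is impossible by construction.

## The ANI pipeline

Average nucleotide identity between two genomes is computed entirely
over topics: fragment both genomes (fixed 1020-nt windows, remainder
discarded) into two topics; one consumer group reads the subject topic
to completion, builds the in-memory fragment database, then streams the
query topic emitting each fragment's best match to a forward-match
topic; a second group runs the opposite direction; the reverse matches
become an indexed lookup table; forward matches streaming against the
table yield reciprocal best pairs; the running mean of pair identities
is the ANI. Design decisions, all configurable or pluggable:

* **Fragment length 1020 nt** follows the OrthoANI convention for
  comparability; the architecture itself does not care.
* **The default matcher is ungapped positionwise identity** (matches /
  fragment length, case-insensitive, N matches nothing). A BLAST-like
  aligner belongs behind the `matcher` seam; the pipeline logic —
  topics, reciprocity, running average — is what is under test here,
  and the positionwise matcher keeps it deterministic at desk scale.
* **Ties** in best-match identity break to the lowest
  `(genome_id, fragment_index)`, making both directions deterministic.
* **A reciprocal pair's identity is the mean of its two directional
  identities.** The two directions need not agree under a general
  matcher, and averaging is the choice that makes
  `ANI(A, B) = ANI(B, A)` hold exactly.
* **Zero reciprocal pairs gives an undefined ANI** (`NA`), not 0.

With the default matcher, a subject mutated from the query at per-base
rate `r` has expected pair identity `1 − r`; the test suite checks
recovery of a seeded 2% divergence to within ±0.005 at ~98 fragment
pairs, which is comfortably wider than the binomial standard error at
that coverage, and that self-comparison returns exactly 1.

## The benchmark harness and the synthetic corpus

The experiment shape: process `k` files with parallelization `k` —
threads over flat files for the baseline, loader+GC agents over the log
store for the pipeline — for `k` in at least three levels, and fit the
least-squares slope of elapsed seconds against `k`. Load scaled in
tandem with parallelization means a perfectly scalable system draws a
flat line; scalability is inversely related to the slope. Absolute
timings are hardware-bound and never asserted; the asserted surface is
correctness: baseline and pipeline must produce identical per-accession
GC results, equal to the generator's manifest, at every level.

The generator emulates reference-database files at desk scale:
multi-record FASTA with seeded content, per-record lengths from a
mixture placing a small fraction above the 100,000-nt chunking
threshold, i.i.d. residues at a target GC of 0.5, and a manifest of
exact per-record base counts. Defaults are 4 files × 250 records at
mean ≈ 20,000 nt (about 20 MB) with levels {1, 2, 4} — sized so a full
sweep takes minutes, not hours, on one CPU; the heavier property tests
use smaller corpora (e.g. 4 files × 15 records for the agent-count
invariance check) since the invariants are size-independent. What the
synthetic corpus does **not** emulate: real accession structure,
repeat content, compositional heterogeneity, ambiguity codes, or
GB-scale file sizes. Passing tests therefore demonstrate the
*architectural* properties (conservation, invariance to agent count,
determinism) — not biological realism of the sequences, and not the
absolute throughput of a production cluster.

## Numerical and degenerate-input choices

* Offsets/sizes as doubles (exact < 2^53); 64-bit hashing in 16-bit
  limbs (exact products < 2^53); no integer overflow anywhere.
* Empty sequence → one empty chunk (the record still exists as a
  message); genome shorter than one fragment → zero fragments and an
  `NA` ANI; empty topic → equilibrium completes at size 0.
* Reading past a partition's end is an empty result, not an error;
  unknown partitions are range errors.
* Duplicate sweep markers on a partition are rejected; marker keys are
  namespace-separated from data keys by a leading NUL byte.
* `aggregate_gc` withholds accessions with missing chunks (reported in
  an attribute) and errors on conflicting chunk counts; redelivered
  chunks are ignored by chunk index, making aggregation idempotent.

## Package shape

The package is deliberately *not* shaped as a model-fitting API (no
single `fit()` returning a model object): the artifact is a storage and
streaming tool, so it exposes handles (store, topic, group) and verbs,
with S3 print methods on the reporting objects (`compaction_report`,
`assignment`, `ani_state`, `scalability_report`) and a thin
`exec/genelog` script for shell use.

## Known limitations

* Single-process, cooperative concurrency: no real broker network,
  leader election, heartbeats or transactional writes; replication is
  placement arithmetic only.
* At-least-once delivery with idempotent keys, not true exactly-once.
* The FASTA reader targets nucleotide repositories (no FASTQ
  qualities, no alignment formats).
* The default ANI matcher is ungapped; indel-divergent genomes need an
  aligner plugged into the `matcher` seam.
* The network fetcher for loader instructions (download + archive
  unpacking) is a seam with a local-file default; only the local path
  is exercised by tests.
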