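---
title: "Counting k-mers with signatures, superkmers and balanced partitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting k-mers with signatures, superkmers and balanced partitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skmercount)
```

## The problem

A k-mer statistic records how many times each length-k substring over
{A, C, G, T} occurs in a collection of DNA sequences. It underpins
alignment-free sequence comparison, de Bruijn graph assembly, and error and
repeat detection. The naive computation — slide a window of width k and
increment a hash-table entry per window — is exact but redundant: a sequence
of n bases unfolds into (n − k + 1) · k symbols of extracted text, nearly a
k-fold blow-up, which is the dominant cost as soon as the extracted k-mers
must be regrouped across workers or spilled to disk.

`skmercount` implements the standard two-stage remedy at local scale.
Stage 1 compresses runs of consecutive k-mers into **superkmers** and routes
them to partitions by a per-k-mer key; stage 2 counts each partition
independently and the disjoint tables are merged. Correctness rests on one
invariant: all occurrences of a k-mer carry the same key, hence meet in the
same partition.

## Minimizers, signatures, superkmers

The key of a k-mer is its **signature**: among the k − m + 1 substrings of
length m, each taken in canonical form (the lexicographic minimum of the
m-mer and its reverse complement), the signature is the smallest one passing
an *allowed* filter — it must not start with `AAA` or `ACA` and must not
contain `AA` anywhere except at its very beginning. The filter exists purely
for load reasons: without it, low-lexicographic m-mers (poly-A above all)
would be the minimizer of a huge share of k-mers, concentrating work on a
few keys. Windows with no allowed m-mer at all (a poly-A stretch) fall back
to the smallest canonical m-mer, flagged as disallowed; counting correctness
only needs the choice to be deterministic.

Consecutive k-mers usually share their signature, so a maximal run of them
is stored once as a superkmer of length L carrying L − k + 1 k-mers. The
decomposition conserves windows exactly: over a fragment of length n the
carried window counts always sum to n − k + 1, and adjacent superkmers
overlap by k − 1 bases. `split_superkmers()` computes per-position canonical
m-mer ranks once and takes sliding-window minima with a monotone deque, so
the scan is linear in the fragment length rather than O(n·k·m); the test
suite checks it against an independent naive per-window implementation.

The signature length m trades compression against balance: small m means
longer superkmers (less intermediate data) but more skewed key frequencies;
m → k removes compression entirely. The default m = 10 is the empirically
good operating point for metagenomic read sets and genome fragments.

## Packed representation

Sequences, k-mers and superkmers are held at two bits per base (A=0, C=1,
G=2, T=3) in 64-bit words of 31 bases each — the top bit stays clear so the
value is safe in signed containers — with the last word left-padded with
zero bits and the symbol count stored alongside. The code assignment and the
big-endian placement of the first base in the highest occupied bits are
deliberate: they make word-wise integer comparison of equal-length sequences
agree with string comparison, so canonical forms and sorted output need no
decoding. Versus 8-bit text this is a 75% space saving, which is what makes
the shuffle between the two stages cheap.

## Routing and the big-jobs problem

Two job granularities are supported. At **signature** granularity (the
default) every signature is its own job; at **bin** granularity signatures
are first scattered into B bins (default 8192) by hashing their packed
integer value, and bins are the jobs. The hash is a fixed xorshift-multiply
finalizer (`mix64`), chosen with published constants so routing is
bit-reproducible everywhere.

The data-oblivious **hash partitioner** maps a job to `mix64(key) mod p`.
It ignores job sizes, and real sequence data makes sizes very uneven: a
repeated motif funnels a large share of all k-mers through one signature,
so one partition finishes long after the rest. Placement is therefore also
available as an explicit multiprocessor-scheduling instance: jobs with
processing time equal to their k-mer count, p identical machines, minimize
the makespan. The NP-hardness of the exact problem is irrelevant at this
accuracy level — the **LPT heuristic** (sort jobs by size descending,
assign each to the least-loaded machine) guarantees a makespan within
(4/3 − 1/(3p)) of optimal, and the package ships a pruned exhaustive solver
(`brute_force_opt()`, up to 14 jobs on 4 machines) against which that bound
is property-tested on a thousand random instances.

Job sizes are not known in advance, so a preliminary pass estimates them:
each record is kept with probability equal to the sampling fraction under a
seeded generator, kept records are decomposed, and per-job k-mer counts are
divided by the fraction. The estimate is unbiased; at fraction 1 it is an
exact census. Jobs that never appeared in the sample are routed by the hash
partitioner — the sample cannot enumerate every signature, and the missing
jobs are overwhelmingly small.

**Choosing the sampling fraction.** The 1% default is meant for inputs
where 1% is still millions of reads. On desk-scale fixtures (hundreds to
thousands of reads) a 1% sample contains a handful of records and the
schedule degenerates to noise; the package's own skew experiments therefore
sample 10% of a 1,000-read fixture, which keeps the expected sample
(~100 reads) informative while exercising the unseen-job fallback. The
fraction should scale so that the expected retained record count stays in
the hundreds or more.

## The pipeline contract

`run_pipeline()` reads FASTA/FASTQ (via Biostrings), uppercases, splits at
ambiguity characters, chunks records by total bases (a stand-in for input
splits), decomposes chunks into superkmers, routes them by schedule,
counts each partition into a hash table, merges and writes sorted TSV.
Three properties are the contract, and all are tested:

* **Oracle equality.** The merged table is byte-identical to the naive
  sliding-window counter's sorted TSV, for every combination of k (single-
  and multi-word), m, worker count, granularity, partitioner and strand
  mode.
* **Placement neutrality.** Partitioning changes where k-mers are counted,
  never the counts: output is bit-identical for any p and either
  partitioner. Merging enforces this structurally — overlapping key sets
  across partition tables raise a partition-violation error rather than
  summing silently.
* **Determinism.** Identical config, seed and input give byte-identical
  output; all randomness (sampling, fixtures) flows through explicit seeds.

Counts default to **canonical** mode (a k-mer and its reverse complement
are one species), the convention of essentially all counting tools;
forward-strand mode is a flag. Counts are stored as doubles holding exact
64-bit-scale integers, since genome-scale totals exceed 32 bits.

## Synthetic fixtures, and what they do not show

`generate_uniform()` emits reads with i.i.d. bases at a stated GC content
and optional N injection; `generate_skewed()` plants tandem copies of a
short motif over a stated fraction of each read, which concentrates
superkmer mass on the motif's signature — the regime where size-aware
placement matters. Both are pure functions of their arguments.

These fixtures validate *algebraic* properties: exactness, conservation,
determinism, and the direction of the balancing effect. They do not emulate
sequencing error profiles, quality distributions, coverage structure, or
the heavy-tailed repeat content of real genomes, so passing tests bound no
claim about wall-clock performance on real data — on the skewed fixture a
single signature carries over half of all k-mers, so *any* placement has
nearly the same makespan floor and the measured LPT advantage is
deliberately directional rather than large.

## Numerical and design choices

* Problem sizes in the shipped tests: oracle equivalence over 200 fixtures
  of 25×150 bp (≈0.75 Mb total) spanning k ∈ {11, 28, 31, 32, 55},
  m ∈ {4, 7, 10}, p ∈ {1, 2, 8}; 1,000 random scheduling instances with
  n ≤ 12, t ≤ 4; estimator accuracy at 10⁵ bases over 100 seeds.
* Ties everywhere break deterministically: equal-size jobs by ascending
  key, equal machine loads by lowest index, equal minimizer values by
  leftmost position (equal values are the same signature, so this is
  unobservable in output).
* Fragments shorter than k yield no superkmers and no error; an empty
  input yields an empty (zero-byte) count file.
* FASTQ qualities are read and discarded; lowercase (soft-masked) bases
  are uppercased; both choices match how counting tools treat input.
* `estimate_job_sizes()` retains records by independent Bernoulli draws
  rather than a fixed-size subsample: it is streamable and unbiased, at
  the cost of a binomially varying sample size.

## Limitations

Counting is exact and in-memory: no minimum-count filtering, no
approximate sketches, no disk spilling, and partitions are processed
sequentially in one process — p is a partitioning parameter (and the
number of LPT machines), not a thread count. Only A/C/G/T contribute
k-mers; every other character is a fragment boundary.
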