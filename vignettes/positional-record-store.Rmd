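---
title: "A bulk-insert-optimised store for position-specific genomic records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bulk-insert-optimised store for position-specific genomic records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data model and its assumptions

`rangestore` stores *position-specific DNA-related records*: fixed-size
key-value pairs whose key is a tuple such as (accession, chromosome,
position) or (chromosome, start, end, …). Three empirical properties of this
data class drive every design choice:

1. **Fixed record size.** All records of one kind occupy the same number of
   bytes, so files need no per-record framing and offsets are pure
   arithmetic.
2. **Natural key order.** Keys sort lexicographically as tuples, and
   consumers overwhelmingly ask for *regions* — all SNPs of accession 7 on
   chromosome 2 between two positions — rather than single records.
3. **Bulk arrival.** Data arrives in huge write bursts (a resequencing panel,
   a BLAST run), interleaved with read phases; per-record transactional
   machinery is wasted cost.

The engine therefore buffers incoming records in *memory buckets* that
partition the key space by range, and synchronises each bucket to a sorted
on-disk *bucket file* by mergesort. Files are divided into fixed-count
*chunks* (default 4096 records) and carry a *sparse index* of one entry —
first key plus ordinal — per chunk, so a lookup does a binary search over the
in-memory index followed by a single chunk read, and a range select reads
only the chunks its closed interval `[K_S, K_E]` overlaps, sequentially,
crossing chunk and bucket boundaries without seeking backwards.

Two built-in schemas mirror the motivating workloads: `snp_schema()` packs
(accession 1 B, chromosome 2 B, position 4 B, ref/alt 1 B each) into 9 bytes
per record; `herv_schema()` packs a retroviral BLAST hit — chromosome
interval, fragment interval, fragment id, strand and the E-value — into 20
bytes with a 16-byte key. `record_schema()` builds custom layouts from the
same field kinds.

## Numerical and encoding choices

**Order-preserving codec.** Keys must compare correctly as raw bytes so that
sorting, merging and binary search never decode. Unsigned integers are stored
big-endian; signed integers are biased by $2^{8w-1}$ before the big-endian
write, which maps the signed range monotonically onto the unsigned one. With
that, `memcmp` order of encoded keys equals lexicographic order of decoded
key tuples — the property the whole engine rests on, and the subject of a
dedicated property test.

**Fixed-ascii padding.** Text fields are padded on the right with `0x00` up
to their declared width, and trailing `0x00` bytes are stripped on decode.
This keeps shorter strings sorting before their extensions. The flip side is
that strings containing embedded NUL bytes cannot be represented (R character
vectors cannot hold them either), and a stored value cannot be distinguished
from itself plus trailing NULs; for nucleotide codes and names this is
irrelevant.

**Float32 E-values.** E-values are stored as 4-byte IEEE-754 floats: ~7
significant digits, ample for threshold filtering. Two consequences are
documented rather than hidden: (a) doubles are *snapped* to float32 by the
generators and importers (`float32_round()`), so comparisons between the
store and any reference computation agree bit-for-bit; (b) float32
*underflows* below ≈1.4e-45, so an E-value of 1e-50 stores as 0.0. Because a
filter cutoff of 1e-50 keeps exactly the records whose stored value is
strictly smaller, filtering stays exact under this representation — both the
engine and the brute-force reference see the same snapped values.

**Bucket boundaries are half-open.** The range partition `M(K) → B_i` splits
the space of the leading `min(key_size, 6)` key bytes into even intervals
(six bytes keep the arithmetic exact in R doubles). A key equal to a boundary
belongs to the *upper* bucket, i.e. bucket *i* covers
`[boundary_{i-1}, boundary_i)`. Query ranges, by contrast, are *closed* on
both ends: `store_range(st, k, k)` is exactly a single lookup.

**Visibility.** Queries see synchronised (on-disk) data only; call
`store_flush()` for read-your-writes. This mirrors the durability contract of
the design: buffered records are lost on a crash, synchronised ones never
are, because every bucket file is replaced via write-to-temporary plus atomic
rename — an interrupted merge leaves the previous file byte-identical.

## Synchronisation and update rules

A synchronisation runs in four phases: the bucket's buffer is swapped for an
empty one (inserts continue during the merge); the run is stably sorted by
key; duplicates are collapsed by the *update rule*; and the run is merged
chunk-wise with the existing file. The rules are `replace` (newest wins, the
default), `keep_first` (stored value wins) and `reduce` (an associative
reducer combines old and new values — see `value_reducer()` for a
decoded-space wrapper, e.g. "keep the smaller E-value").

The merge is streaming: at most one disk chunk and one run slice are resident
at a time, so peak memory is O(chunk size), independent of bucket size. The
`stats` argument of `merge_runs()` instruments this bound and the test suite
asserts it. A bucket becomes *eligible* for synchronisation at 100 000
buffered records (`bucket_fill_level`) or 60 s of age (`bucket_max_age_s`);
crossing the 256 MiB global buffer cap forces the largest buffers out first,
ties broken by lowest bucket id. Synchronisations run inline and
deterministically; `max_parallel_syncs` is recorded configuration surface for
concurrent deployments.

## What the generators emulate

Downloads are deliberately not required: `gen_snps()` and `gen_herv()`
reproduce the *shapes* of the motivating data sets rather than their content.

* `gen_snps()` defaults — 251 accessions, 5 chromosomes, positions up to
  3×10⁷ — emulate per-accession SNP tables of a ~250-line plant resequencing
  panel. Reference and mutated bases are uniform with `ref ≠ alt`.
* `gen_herv()` defaults — 24 chromosomes, positions up to 2.5×10⁸, 7000
  fragment ids, hit lengths up to 10⁴, E-values log-uniform over
  10⁻⁶⁰…10⁻²⁰ — emulate BLAST hits of a retroviral fragment library against
  a human-sized genome.
* `dup_rate` re-emits the key of a uniformly chosen earlier row with fresh
  values (duplicate chains are resolved so every duplicate points at a real
  earlier key), which exercises the update rules exactly where they matter.

Real uniform draws are *harsher* than real data for a range-partitioned
store: genuine SNP density is clustered, which only improves bucket locality.
The importers (`parse_snp_tsv()`, `parse_blast_tab()`, `read_vcf_snps()`)
handle the real formats and intern names to dense ids via a persisted
dictionary (`names.tsv`).

## Problem sizes and verification

The package's own study conditions are desk-scale analogues of the original
hundreds-of-millions workloads, chosen to finish in minutes on one CPU while
keeping the generative shape: 10⁶-record bulk inserts, 10⁴ random single
lookups (half present, half absent), 10³ random range selects of 10³–10⁴ key
units, and E-value filters over the cutoff grid 10⁻²⁰…10⁻⁵⁰. Every
benchmark in `run_bench()` is simultaneously a correctness check: counts and
contents are asserted against `oracle_store()`, an independent in-memory
implementation of the same query semantics built on ordinary data-frame
operations (no shared code path with the engine). Timings are reported,
never asserted — absolute throughput is hardware-bound.

```r
library(rangestore)
cfg <- bench_config("snp", n_records = 1e5, n_lookups = 1e3, n_ranges = 100)
res <- run_bench(cfg)
autoplot(res, "insert")
```

## Limitations

* Single-process, single-writer; synchronisations run inline. The
  concurrency knobs are recorded but not exploited.
* Buffered (unflushed) records are invisible to queries and not
  crash-durable; this is the documented contract, not an accident.
* Fixed-width fields only: no variable-length values, no embedded NUL bytes
  in text fields, integers exact up to 2⁵³ (R doubles) for widths above 6
  bytes.
* Float32 E-values underflow below ≈1.4e-45 (see above).
* The store is append/merge-only: there is no delete operation; a `reduce`
  rule can implement logical tombstones if needed.
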