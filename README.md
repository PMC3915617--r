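# rangestore

An embedded, bulk-insert-optimised storage engine for **position-specific
genomic records** — SNP calls, BLAST hit intervals, and any other fixed-size
key-value record whose key is a (sequence, position, …) tuple.

## Why

Resequencing panels and homology searches produce records in enormous write
bursts, and consumers read them back almost exclusively by *genomic region*.
General-purpose databases pay for per-record framing, transactions and
variable-width layouts that this data class never uses. `rangestore` exploits
the three properties the data actually has:

* **fixed record size** — offsets are arithmetic, files need no framing;
* **naturally ordered keys** — an order-preserving big-endian codec makes
  byte comparison of encoded keys equal tuple comparison of decoded keys, so
  sorting, merging and binary search never decode;
* **bulk arrival** — incoming records are buffered in range-partitioned
  memory buckets and synchronised to sorted, sparse-indexed, chunked bucket
  files by a streaming mergesort whose memory use is bounded by the chunk
  size.

Single lookups binary-search a per-chunk sparse index and read one chunk;
range selects `[K_S, K_E]` (closed on both ends) stream sequentially across
chunk *and* bucket boundaries, with optional value predicates (e.g. BLAST
E-value cutoffs) applied after retrieval. Key collisions are resolved by
pluggable update rules: `replace`, `keep_first`, or a user-supplied `reduce`.

Built-in schemas cover the two motivating workloads: 9-byte SNP records
keyed by (accession, chromosome, position) and 20-byte retroviral (HERV)
BLAST-hit records with float32 E-values. `record_schema()` builds custom
layouts. Importers read SNP TSV tables, BLAST tabular output and plain VCF;
seeded generators (`gen_snps()`, `gen_herv()`) emulate both workload shapes
so nothing needs downloading. See the vignette
(`vignettes/positional-record-store.Rmd`) for the method details and the
numerical conventions.

## A worked example

```r
library(rangestore)

st <- store_create(file.path(tempdir(), "snp_demo"), "snp", n_buckets = 8)
snps <- gen_snps(250000, seed = 2024, dup_rate = 0.1)
snps
#> # A tibble: 250,000 × 5
#>   accession chromosome position ref   alt
#>       <dbl>      <dbl>    <dbl> <chr> <chr>
#> 1        65          2 26763494 T     C
#> 2        36          5 14222244 A     G
#> 3        44          1  6438095 C     A
#> 4       187          5 25709587 T     C
#> # ℹ 249,996 more rows

store_insert(st, snps)   # buffers + auto-syncs at the fill level
store_flush(st)          # read-your-writes from here on
st
#> <rs_store /tmp/.../snp_demo>  schema 'snp', 8 bucket(s), 224,782 record(s) on disk, 0 buffered

glance(st)               # duplicate keys were collapsed by the update rule
#> # A tibble: 1 × 10
#>   schema record_size key_size n_buckets chunk_size disk_records buffered_records
#>   <chr>        <int>    <int>     <int>      <int>        <dbl>            <int>
#> 1 snp              9        7         8       4096       224782                0
#> # ℹ 3 more variables: inserted <dbl>, duplicates_collapsed <dbl>, syncs <dbl>

store_lookup(st, snps[c(1, 42, 99), c("accession", "chromosome", "position")])
#> # A tibble: 3 × 6
#>   accession chromosome position ref   alt   found
#>       <dbl>      <dbl>    <dbl> <chr> <chr> <lgl>
#> 1        65          2 26763494 T     C     TRUE
#> 2       248          2  8901825 T     C     TRUE
#> 3       173          4 16237224 C     G     TRUE

store_range(st, list(accession = 17, chromosome = 2, position = 1),
                list(accession = 17, chromosome = 2, position = 5e6))
#> # A tibble: 35 × 5
#>   accession chromosome position ref   alt
#>       <dbl>      <dbl>    <dbl> <chr> <chr>
#> 1        17          2   102149 C     A
#> 2        17          2   144733 C     T
#> 3        17          2   464447 A     C
#> 4        17          2   468054 T     C
#> 5        17          2   710651 T     A
#> # ℹ 30 more rows
```

Everything returns tibbles; `tidy(st)` gives per-bucket detail, `glance(st)`
the one-row summary, and `store_verify(st)` re-audits every bucket file.
A thin command-line wrapper is installed at `inst/cli/rangestore`
(`create`, `import`, `put`, `get`, `range`, `scan`, `stats`, `verify`,
`bench`).

## Benchmarks that double as correctness checks

`run_bench()` replays the three classic workloads — bulk insert, random
single lookups, random range selects with E-value filters — against both the
store and `oracle_store()`, an independent in-memory reference
implementation. Counts and contents are asserted to match exactly; timings
are reported (CSV + `autoplot()`), never asserted.

```r
res <- run_bench(bench_config("snp", n_records = 1e5, n_lookups = 1e3,
                              n_ranges = 100))
autoplot(res, "insert")
```

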