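# Desk-scale benchmark harness mirroring the shapes of the three classic
# experiments -- bulk insert, random single lookups, random range selects with
# an E-value post-filter -- against both the store and the in-memory oracle.
# Every benchmark is simultaneously a correctness test: result counts and
# contents are asserted against the oracle; timings are reported, never
# asserted (absolute throughput is hardware-bound).

#' Benchmark configuration
#'
#' @param schema `"snp"` or `"herv"`.
#' @param n_records Records inserted (default 1e6 -- the desk-scale analogue
#'   of the original hundreds-of-millions workloads, same generative shape).
#' @param n_lookups Random single lookups (default 1e4).
#' @param n_ranges Random range selects (default 1e3).
#' @param range_len_min,range_len_max Range lengths in key (position) units
#'   (defaults 1e3 and 1e4).
#' @param evalue_cutoffs For the HERV schema: E-value thresholds sampled per
#'   range (default `10^-seq(20, 50, by = 5)`).
#' @param dup_rate Duplicate-key rate of the generated stream (default 0.1).
#' @param seed Workload seed; a fixed seed gives a bit-identical workload and
#'   report modulo the timing columns.
#' @param n_buckets,chunk_size,bucket_fill_level Store configuration.
#' @param batch_size Insert batch size (one timing row per batch).
#' @param dir Store directory (default: a fresh temporary directory).
#' @param report_dir If non-`NULL`, CSV reports are written here.
#' @return An `rs_bench_config` list.
#' @export
bench_config <- function(schema = c("snp", "herv"),
                         n_records = 1e6, n_lookups = 1e4, n_ranges = 1e3,
                         range_len_min = 1e3, range_len_max = 1e4,
                         evalue_cutoffs = 10^-seq(20, 50, by = 5),
                         dup_rate = 0.1, seed = 1L,
                         n_buckets = 16L, chunk_size = 4096L,
                         bucket_fill_level = 100000L,
                         batch_size = 100000L,
                         dir = NULL, report_dir = NULL) {
  schema <- match.arg(schema)
  stopifnot(n_records >= 1, range_len_min <= range_len_max)
  structure(list(schema = schema, n_records = n_records,
                 n_lookups = n_lookups, n_ranges = n_ranges,
                 range_len_min = range_len_min, range_len_max = range_len_max,
                 evalue_cutoffs = evalue_cutoffs, dup_rate = dup_rate,
                 seed = as.integer(seed), n_buckets = n_buckets,
                 chunk_size = chunk_size, bucket_fill_level = bucket_fill_level,
                 batch_size = batch_size,
                 dir = dir %||% tempfile("benchstore"),
                 report_dir = report_dir),
            class = "rs_bench_config")
}

bench_rows <- function(cfg) {
  if (cfg$schema == "snp")
    gen_snps(cfg$n_records, cfg$seed, dup_rate = cfg$dup_rate)
  else
    gen_herv(cfg$n_records, cfg$seed, dup_rate = cfg$dup_rate)
}

bench_store <- function(cfg) {
  store_create(cfg$dir, cfg$schema, n_buckets = cfg$n_buckets,
               chunk_size = cfg$chunk_size,
               bucket_fill_level = cfg$bucket_fill_level)
}

bench_oracle <- function(cfg, rows) {
  o <- oracle_store(builtin_schema(cfg$schema))
  oracle_insert(o, rows)
  o
}

oracle_mismatch <- function(what) {
  abort(sprintf("oracle mismatch in %s benchmark: store results differ from brute force (correctness bug)",
                what),
        class = "rangestore_integrity_error")
}

same_records <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                   check.attributes = FALSE, tolerance = 0))
}

#' Insert benchmark
#'
#' Inserts the generated stream batch by batch, timing each batch, then
#' flushes and verifies the full scan (count and content) against the oracle.
#'
#' @param cfg A [bench_config()].
#' @param store,rows Optionally a pre-created empty store and pre-generated
#'   rows (used by [run_bench()] to share one store across the three
#'   benchmarks).
#' @return A tibble with one row per batch: `records_inserted` (cumulative),
#'   `seconds`, `throughput` (records/s).
#' @export
run_insert_bench <- function(cfg, store = NULL, rows = NULL) {
  rows <- rows %||% bench_rows(cfg)
  if (is.null(store)) {
    store <- bench_store(cfg)
    on.exit(store_close(store, flush = FALSE)) # files persist in cfg$dir
  }
  n <- nrow(rows)
  starts <- seq(1L, n, by = cfg$batch_size)
  report <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    sel <- starts[i]:min(starts[i] + cfg$batch_size - 1L, n)
    t0 <- proc.time()[["elapsed"]]
    store_insert(store, rows[sel, , drop = FALSE])
    dt <- proc.time()[["elapsed"]] - t0
    report[[i]] <- tibble(records_inserted = sel[length(sel)],
                          seconds = dt,
                          throughput = length(sel) / max(dt, 1e-9))
  }
  store_flush(store)
  oracle <- bench_oracle(cfg, rows)
  got <- store_scan(store)
  want <- oracle_scan(oracle)
  if (nrow(got) != nrow(want) || !same_records(got, want))
    oracle_mismatch("insert")
  out <- dplyr::bind_rows(report)
  write_report(cfg, out, "insert")
  out
}

#' Random-lookup benchmark
#'
#' Half the query keys are keys of stored records, half are random keys from
#' the same space (mostly absent). Every answer is cross-checked against the
#' oracle.
#'
#' @inheritParams run_insert_bench
#' @return A tibble with one row per query batch: `n_queries`, `hits`,
#'   `seconds`.
#' @export
run_lookup_bench <- function(cfg, store = NULL, rows = NULL) {
  rows <- rows %||% bench_rows(cfg)
  if (is.null(store)) {
    store <- bench_store(cfg)
    on.exit(store_close(store, flush = FALSE))
    store_insert(store, rows)
    store_flush(store)
  }
  s <- store$schema
  kf <- key_fields(s)
  nq <- cfg$n_lookups
  queries <- withr::with_seed(cfg$seed + 1L, {
    present <- rows[sample.int(nrow(rows), ceiling(nq / 2), replace = TRUE),
                    kf, drop = FALSE]
    absent <- (if (cfg$schema == "snp")
      gen_snps(floor(nq / 2), cfg$seed + 2L)
    else gen_herv(floor(nq / 2), cfg$seed + 2L))[, kf, drop = FALSE]
    dplyr::slice_sample(dplyr::bind_rows(present, absent), prop = 1)
  })
  oracle <- bench_oracle(cfg, rows)
  batches <- split(seq_len(nrow(queries)),
                   ceiling(seq_len(nrow(queries)) / 1000))
  report <- lapply(batches, function(sel) {
    q <- queries[sel, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    got <- store_lookup(store, q)
    dt <- proc.time()[["elapsed"]] - t0
    want <- oracle_lookup(oracle, q)
    if (!same_records(got, want)) oracle_mismatch("lookup")
    tibble(n_queries = nrow(q), hits = sum(got$found), seconds = dt)
  })
  out <- dplyr::bind_rows(report)
  write_report(cfg, out, "lookup")
  out
}

#' Random range-select benchmark
#'
#' Ranges are anchored at stored records: for the SNP schema a range fixes
#' accession and chromosome and spans `range_len_min..range_len_max` positions;
#' for the HERV schema it spans chromosome start positions, with an E-value
#' cutoff drawn from `evalue_cutoffs` applied as a per-record post-filter.
#' Record counts and contents of every range are asserted against the oracle.
#'
#' @inheritParams run_insert_bench
#' @return A tibble with one row per range: `range_id`, `length`, `cutoff`
#'   (`NA` for SNP), `n_records`, `seconds`.
#' @export
run_range_bench <- function(cfg, store = NULL, rows = NULL) {
  rows <- rows %||% bench_rows(cfg)
  if (is.null(store)) {
    store <- bench_store(cfg)
    on.exit(store_close(store, flush = FALSE))
    store_insert(store, rows)
    store_flush(store)
  }
  oracle <- bench_oracle(cfg, rows)
  reqs <- withr::with_seed(cfg$seed + 3L, bench_ranges(cfg, rows))
  report <- vector("list", length(reqs))
  for (i in seq_along(reqs)) {
    r <- reqs[[i]]
    pred <- if (!is.na(r$cutoff)) {
      cut <- r$cutoff
      function(tbl) tbl$evalue < cut
    } else NULL
    t0 <- proc.time()[["elapsed"]]
    got <- store_range(store, r$k_start, r$k_end, predicate = pred)
    dt <- proc.time()[["elapsed"]] - t0
    want <- oracle_range(oracle, r$k_start, r$k_end, predicate = pred)
    if (nrow(got) != nrow(want) || !same_records(got, want))
      oracle_mismatch("range")
    report[[i]] <- tibble(range_id = i, length = r$len, cutoff = r$cutoff,
                          n_records = nrow(got), seconds = dt)
  }
  out <- dplyr::bind_rows(report)
  write_report(cfg, out, "range")
  out
}

# one list(k_start, k_end, len, cutoff) per requested range
bench_ranges <- function(cfg, rows) {
  anchors <- rows[sample.int(nrow(rows), cfg$n_ranges, replace = TRUE), ,
                  drop = FALSE]
  lens <- floor(stats::runif(cfg$n_ranges, cfg$range_len_min,
                             cfg$range_len_max + 1))
  lapply(seq_len(cfg$n_ranges), function(i) {
    a <- anchors[i, ]
    if (cfg$schema == "snp") {
      start <- max(1, a$position - floor(lens[i] / 2))
      list(k_start = list(accession = a$accession, chromosome = a$chromosome,
                          position = start),
           k_end = list(accession = a$accession, chromosome = a$chromosome,
                        position = start + lens[i] - 1),
           len = lens[i], cutoff = NA_real_)
    } else {
      start <- max(1, a$chrom_start - floor(lens[i] / 2))
      list(k_start = list(chromosome = a$chromosome, chrom_start = start,
                          chrom_end = 0, herv_start = 0, herv_end = 0,
                          herv_id = 0, strand = 0),
           k_end = list(chromosome = a$chromosome,
                        chrom_start = start + lens[i] - 1,
                        chrom_end = 4294967295, herv_start = 65535,
                        herv_end = 65535, herv_id = 65535, strand = 255),
           len = lens[i],
           cutoff = sample(cfg$evalue_cutoffs, 1L))
    }
  })
}

write_report <- function(cfg, report, name) {
  if (is.null(cfg$report_dir)) return(invisible(NULL))
  dir.create(cfg$report_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report, file.path(cfg$report_dir,
                                     paste0("bench_", name, ".csv")))
  invisible(NULL)
}

#' Run the full benchmark suite
#'
#' Builds one store, then runs the insert, lookup and range benchmarks on it.
#'
#' @param cfg A [bench_config()].
#' @return An `rs_bench` list with elements `config`, `insert`, `lookup`,
#'   `range`; see [autoplot.rs_bench()].
#' @export
run_bench <- function(cfg) {
  rows <- bench_rows(cfg)
  store <- bench_store(cfg)
  on.exit(store_close(store, flush = FALSE))
  ins <- run_insert_bench(cfg, store = store, rows = rows)
  lk <- run_lookup_bench(cfg, store = store, rows = rows)
  rg <- run_range_bench(cfg, store = store, rows = rows)
  structure(list(config = cfg, insert = ins, lookup = lk, range = rg),
            class = "rs_bench")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot benchmark results
#'
#' @param object An `rs_bench` result.
#' @param which `"insert"` (throughput vs records inserted), `"lookup"`
#'   (per-batch latency) or `"range"` (records returned vs elapsed time).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rs_bench <- function(object, which = c("insert", "lookup", "range"),
                              ...) {
  which <- match.arg(which)
  switch(which,
    insert = ggplot2::ggplot(object$insert,
               ggplot2::aes(x = .data$records_inserted, y = .data$throughput)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "records inserted", y = "inserts / s",
                    title = "Insert throughput"),
    lookup = ggplot2::ggplot(object$lookup,
               ggplot2::aes(x = .data$seconds / .data$n_queries * 1e3)) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "ms / lookup (batch mean)", y = "batches",
                    title = "Random lookup latency"),
    range = ggplot2::ggplot(object$range,
               ggplot2::aes(x = .data$n_records, y = .data$seconds)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::labs(x = "records returned", y = "seconds",
                    title = "Range select cost"))
}

#' @importFrom rlang .data
NULL
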