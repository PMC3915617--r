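new_snp_store <- function(rows, ...) {
  st <- store_create(tempfile(), "snp", ...)
  store_insert(st, rows)
  store_flush(st)
  st
}

test_that("lookups on an empty store find nothing", {
  st <- store_create(tempfile(), "snp", n_buckets = 4)
  on.exit(store_close(st, flush = FALSE))
  q <- gen_snps(10, seed = 1)[, 1:3]
  res <- store_lookup(st, q)
  expect_identical(nrow(res), 10L)
  expect_false(any(res$found))
  expect_true(all(is.na(res$ref)))
  expect_identical(nrow(store_scan(st)), 0L)
  expect_identical(nrow(store_range(st, list(accession = 0, chromosome = 0,
                                             position = 0),
                                    list(accession = 255, chromosome = 9,
                                         position = 1e6))), 0L)
})

test_that("present and absent lookups match the oracle", {
  rows <- gen_snps(3000, seed = 21, dup_rate = 0.1)
  st <- new_snp_store(rows, n_buckets = 8, chunk_size = 64)
  on.exit(store_close(st, flush = FALSE))
  o <- oracle_store(st$schema)
  oracle_insert(o, rows)
  q <- withr::with_seed(22, dplyr::slice_sample(dplyr::bind_rows(
    rows[sample.int(nrow(rows), 500), 1:3],
    gen_snps(500, seed = 23)[, 1:3]), prop = 1))
  expect_tbl_equal(store_lookup(st, q), oracle_lookup(o, q))
})

test_that("unflushed inserts are invisible until the next flush", {
  st <- store_create(tempfile(), "snp", n_buckets = 2)
  on.exit(store_close(st, flush = FALSE))
  rows <- gen_snps(50, seed = 30)
  store_insert(st, rows)
  expect_false(any(store_lookup(st, rows[, 1:3])$found))
  store_flush(st)
  expect_true(all(store_lookup(st, rows[, 1:3])$found))
})

test_that("a full-space range equals a scan and both match the oracle", {
  rows <- gen_snps(2000, seed = 24, dup_rate = 0.1)
  st <- new_snp_store(rows, n_buckets = 8, chunk_size = 32)
  on.exit(store_close(st, flush = FALSE))
  o <- oracle_store(st$schema)
  oracle_insert(o, rows)
  full <- store_range(st, list(accession = 0, chromosome = 0, position = 0),
                      list(accession = 255, chromosome = 65535,
                           position = 4294967295))
  expect_tbl_equal(full, store_scan(st))
  expect_tbl_equal(full, oracle_scan(o))
})

test_that("a degenerate range K_S = K_E behaves as a single select", {
  rows <- gen_snps(500, seed = 25)
  st <- new_snp_store(rows, n_buckets = 4, chunk_size = 16)
  on.exit(store_close(st, flush = FALSE))
  for (i in c(1, 250, 500)) {
    k <- as.list(rows[i, 1:3])
    got <- store_range(st, k, k)
    lk <- store_lookup(st, rows[i, 1:3])
    expect_identical(nrow(got), 1L)
    expect_tbl_equal(got, lk[lk$found, names(got)])
  }
  absent <- list(accession = 254, chromosome = 9, position = 123)
  expect_identical(nrow(store_range(st, absent, absent)), 0L)
})

test_that("ranges crossing chunk and bucket boundaries match the oracle", {
  # consecutive positions with a tiny chunk size force multi-chunk ranges;
  # accessions straddling 128 cross the bucket boundary of a 2-way split
  rows <- tibble::tibble(accession = rep(c(120, 135), each = 200),
                         chromosome = 1,
                         position = rep(1:200, 2),
                         ref = "A", alt = "G")
  st <- new_snp_store(rows, n_buckets = 2, chunk_size = 16)
  on.exit(store_close(st, flush = FALSE))
  o <- oracle_store(st$schema)
  oracle_insert(o, rows)
  cases <- list(
    list(list(accession = 120, chromosome = 1, position = 10),
         list(accession = 120, chromosome = 1, position = 90)),   # chunks
    list(list(accession = 120, chromosome = 1, position = 150),
         list(accession = 135, chromosome = 1, position = 50)),   # buckets
    list(list(accession = 0, chromosome = 0, position = 0),
         list(accession = 255, chromosome = 2, position = 1)))    # everything
  for (cs in cases) {
    got <- store_range(st, cs[[1]], cs[[2]])
    want <- oracle_range(o, cs[[1]], cs[[2]])
    expect_gt(nrow(got), 0)
    expect_tbl_equal(got, want)
  }
})

test_that("adjacent ranges concatenate to the enclosing range", {
  rows <- gen_snps(2000, seed = 26)
  st <- new_snp_store(rows, n_buckets = 4, chunk_size = 32)
  on.exit(store_close(st, flush = FALSE))
  lo <- list(accession = 10, chromosome = 1, position = 1)
  mid <- list(accession = 10, chromosome = 3, position = 500)
  mid2 <- list(accession = 10, chromosome = 3, position = 501)
  hi <- list(accession = 200, chromosome = 5, position = 3e7)
  whole <- store_range(st, lo, hi)
  parts <- dplyr::bind_rows(store_range(st, lo, mid), store_range(st, mid2, hi))
  expect_tbl_equal(whole, parts)
})

test_that("value predicates filter ranges after retrieval", {
  rows <- gen_herv(2000, seed = 27)
  st <- store_create(tempfile(), "herv", n_buckets = 4, chunk_size = 32)
  on.exit(store_close(st, flush = FALSE))
  store_insert(st, rows)
  store_flush(st)
  o <- oracle_store(st$schema)
  oracle_insert(o, rows)
  lo <- list(chromosome = 1, chrom_start = 0, chrom_end = 0, herv_start = 0,
             herv_end = 0, herv_id = 0, strand = 0)
  hi <- list(chromosome = 24, chrom_start = 4294967295,
             chrom_end = 4294967295, herv_start = 65535, herv_end = 65535,
             herv_id = 65535, strand = 255)
  pred <- function(tbl) tbl$evalue < 1e-40
  got <- store_range(st, lo, hi, predicate = pred)
  expect_tbl_equal(got, oracle_range(o, lo, hi, predicate = pred))
  expect_true(all(got$evalue < 1e-40))
  expect_lt(nrow(got), nrow(rows))
})

test_that("an inverted range is an argument error", {
  rows <- gen_snps(10, seed = 28)
  st <- new_snp_store(rows)
  on.exit(store_close(st, flush = FALSE))
  expect_error(
    store_range(st, list(accession = 5, chromosome = 1, position = 100),
                list(accession = 5, chromosome = 1, position = 99)),
    class = "rangestore_argument_error")
})
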