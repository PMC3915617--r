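test_that("a two-way split of a 1-byte key space cuts at 0x80", {
  m <- default_bucket_map(tiny_schema(), 2)
  expect_identical(m$n_buckets, 2L)
  expect_identical(m$boundaries, as.raw(0x80))
  expect_identical(route(m, as.raw(0x7f)), 1L)
  expect_identical(route(m, as.raw(0x80)), 2L) # boundary key -> upper bucket
  expect_identical(route(m, as.raw(0xff)), 2L)
})

test_that("the default map covers the key space for many bucket counts", {
  s <- snp_schema()
  for (n in c(1:8, 16, 33, 64)) {
    m <- default_bucket_map(s, n)
    expect_identical(m$n_buckets, as.integer(n))
    nb <- length(m$boundaries) / s$key_size
    expect_identical(nb, n - 1)
    if (nb > 1) {
      ks <- s$key_size
      for (i in seq_len(nb - 1)) {
        a <- m$boundaries[((i - 1) * ks + 1):(i * ks)]
        b <- m$boundaries[(i * ks + 1):((i + 1) * ks)]
        expect_identical(compare_keys(a, b), -1L)
      }
    }
    # extreme keys map to the first and last bucket
    expect_identical(route(m, as.raw(rep(0, s$key_size))), 1L)
    expect_identical(route(m, as.raw(rep(255, s$key_size))), as.integer(n))
  }
})

test_that("an over-split key space reduces the bucket count with a warning", {
  expect_warning(m <- default_bucket_map(tiny_schema(), 300),
                 "effective bucket count")
  expect_identical(m$n_buckets, 256L)
})

test_that("routing matches a linear boundary scan and is monotone", {
  s <- snp_schema()
  m <- default_bucket_map(s, 16)
  ks <- s$key_size
  nb <- length(m$boundaries) / ks
  bnd <- lapply(seq_len(nb), function(i)
    m$boundaries[((i - 1) * ks + 1):(i * ks)])
  linear <- function(key) 1L + sum(vapply(bnd, function(b)
    compare_keys(b, key) <= 0, TRUE))

  rows <- gen_snps(500, seed = 8)
  keys <- encode_keys(s, rows)
  got <- route(m, keys)
  want <- vapply(seq_len(500), function(i)
    linear(keys[((i - 1) * ks + 1):(i * ks)]), 1L)
  expect_identical(got, want)

  # monotone: sorting keys sorts bucket ids
  ord <- rangestore:::cxx_key_order(keys, ks, ks)
  expect_false(is.unsorted(got[ord]))

  # boundary keys themselves belong to the upper bucket (half-open ranges)
  for (i in seq_len(nb))
    expect_identical(route(m, bnd[[i]]), i + 1L)
})

test_that("the bucket map survives its hex serialisation", {
  s <- herv_schema()
  m <- default_bucket_map(s, 16)
  r <- rangestore:::map_from_hex(s, rangestore:::map_to_hex(m))
  expect_identical(r$boundaries, m$boundaries)
  expect_identical(r$n_buckets, m$n_buckets)
})

test_that("swap_out returns the buffer as a sorted, deduplicated run", {
  st <- store_create(tempfile(), "snp", n_buckets = 1)
  on.exit(store_close(st, flush = FALSE))
  rows <- gen_snps(2000, seed = 5, dup_rate = 0.2)
  store_insert(st, rows)
  run <- swap_out(st, 1L)
  s <- st$schema
  expect_identical(rangestore:::cxx_check_sorted(run, s$record_size, s$key_size), 0L)
  # replace rule: last occurrence of each key wins
  o <- oracle_store(s)
  oracle_insert(o, rows)
  expect_tbl_equal(decode_records(s, run), oracle_scan(o))
  # the buffer is now empty and counters add up
  expect_identical(rangestore:::buffered_counts(st), 0L)
  expect_identical(st$counters$collapsed,
                   nrow(rows) - length(run) / s$record_size)
})

test_that("inserts are buffered per bucket and nothing is lost on flush", {
  st <- store_create(tempfile(), "snp", n_buckets = 8, chunk_size = 64)
  on.exit(store_close(st, flush = FALSE))
  rows <- gen_snps(5000, seed = 10, dup_rate = 0.1)
  store_insert(st, rows)
  expect_identical(sum(rangestore:::buffered_counts(st)), 5000L)
  expect_identical(glance(st)$disk_records, 0)
  store_flush(st)
  g <- glance(st)
  expect_identical(g$buffered_records, 0L)
  expect_identical(g$inserted, 5000)
  expect_identical(g$disk_records + g$duplicates_collapsed, 5000)
  expect_true(all(store_verify(st)$pass))
})

test_that("reaching the fill level triggers an automatic synchronisation", {
  st <- store_create(tempfile(), "snp", n_buckets = 1, chunk_size = 64,
                     bucket_fill_level = 100)
  on.exit(store_close(st, flush = FALSE))
  store_insert(st, gen_snps(250, seed = 3))
  expect_gte(glance(st)$syncs, 1)
  expect_identical(glance(st)$buffered_records, 0L)
})

test_that("exceeding the global buffer cap forces a synchronisation", {
  st <- store_create(tempfile(), "snp", n_buckets = 4, chunk_size = 64,
                     global_buffer_bytes = 1000)
  on.exit(store_close(st, flush = FALSE))
  store_insert(st, gen_snps(500, seed = 3))
  expect_gte(glance(st)$syncs, 1)
  expect_lte(rangestore:::buffered_bytes(st), 1000)
})

test_that("buffering continues while a synchronisation is in flight", {
  st <- store_create(tempfile(), "snp", n_buckets = 2, chunk_size = 32)
  x1 <- gen_snps(800, seed = 1)
  x2 <- gen_snps(300, seed = 2)
  store_insert(st, x1)
  st$test_mid_hook <- function() store_insert(st, x2) # fires mid-merge
  store_flush(st)
  # the mid-merge inserts were buffered, not lost, and flush cleanly
  expect_gte(sum(rangestore:::buffered_counts(st)), 1L)
  store_flush(st)
  o <- oracle_store(st$schema)
  oracle_insert(o, x1)
  oracle_insert(o, x2)
  expect_tbl_equal(store_scan(st), oracle_scan(o))
  store_close(st)
})

test_that("a store can be closed and reopened with its data intact", {
  dir <- tempfile()
  st <- store_create(dir, "snp", n_buckets = 4, chunk_size = 32)
  rows <- gen_snps(1000, seed = 12)
  store_insert(st, rows)
  store_close(st) # flushes
  expect_error(store_insert(st, rows), class = "rangestore_state_error")

  st2 <- store_open(dir)
  on.exit(store_close(st2, flush = FALSE))
  expect_identical(st2$schema$hash, snp_schema()$hash)
  o <- oracle_store(st2$schema)
  oracle_insert(o, rows)
  expect_tbl_equal(store_scan(st2), oracle_scan(o))
  expect_error(store_create(dir, "snp"), class = "rangestore_state_error")
})

test_that("tidy() reports per-bucket state consistent with glance()", {
  st <- store_create(tempfile(), "snp", n_buckets = 4, chunk_size = 32)
  on.exit(store_close(st, flush = FALSE))
  store_insert(st, gen_snps(400, seed = 4))
  store_flush(st)
  td <- tidy(st)
  expect_identical(nrow(td), 4L)
  expect_identical(sum(td$disk_records), glance(st)$disk_records)
  expect_true(all(td$chunks == ceiling(td$disk_records / st$chunk_size)))
})
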