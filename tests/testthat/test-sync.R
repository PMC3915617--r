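test_that("the fullest eligible bucket is synchronised first, ties by id", {
  st <- store_create(tempfile(), "snp", n_buckets = 4, bucket_fill_level = 10)
  on.exit(store_close(st, flush = FALSE))
  set_n <- function(...) {
    ns <- c(...)
    for (i in seq_along(ns)) st$buffers[[i]]$n <- as.integer(ns[i])
  }
  set_n(5, 900, 40, 0)
  expect_identical(select_bucket_for_sync(st), 2L)
  set_n(5, 900, 900, 0)
  expect_identical(select_bucket_for_sync(st), 2L) # tie -> lowest id
  set_n(5, 5, 5, 5)
  expect_identical(select_bucket_for_sync(st), NA_integer_)
  # age alone also qualifies a buffer
  st$buffers[[4]]$n <- 3L
  st$buffers[[4]]$created_at <- Sys.time() - 2 * st$max_age_s
  expect_identical(select_bucket_for_sync(st), 4L)
})

test_that("resolving duplicates follows the update rule", {
  s <- snp_schema()
  rows <- tibble::tibble(accession = c(1, 1, 1, 2), chromosome = 1,
                         position = c(5, 5, 5, 6),
                         ref = c("A", "C", "G", "T"), alt = "T")
  recs <- encode_records(s, rows)
  dec <- function(rule) decode_records(
    s, rangestore:::resolve_duplicates(s, recs, rule))
  expect_identical(dec(update_rule("replace"))$ref, c("G", "T"))
  expect_identical(dec(update_rule("keep_first"))$ref, c("A", "T"))
  pick_max <- value_reducer(s, function(old, new)
    tibble::tibble(ref = pmax(old$ref, new$ref), alt = pmax(old$alt, new$alt)))
  expect_identical(dec(update_rule("reduce", reducer = pick_max))$ref,
                   c("G", "T"))
})

test_that("merging an empty run is bit-idempotent", {
  s <- snp_schema()
  path <- tempfile()
  run <- sorted_run(s, gen_snps(300, seed = 1))
  merge_runs(path, s, run, chunk_size = 32)
  before <- file_bytes(path)
  merge_runs(path, s, raw(0), chunk_size = 32)
  expect_identical(file_bytes(path), before)
})

test_that("merging into a missing file equals writing the run directly", {
  s <- snp_schema()
  run <- sorted_run(s, gen_snps(200, seed = 2))
  p1 <- tempfile(); p2 <- tempfile()
  merge_runs(p1, s, run, chunk_size = 16)
  write_bucket(p2, s, run, chunk_size = 16)
  expect_identical(file_bytes(p1), file_bytes(p2))
})

test_that("repeated merges agree with the oracle across random batches", {
  s <- snp_schema()
  for (seed in 0:9) {
    path <- tempfile()
    o <- oracle_store(s)
    for (batch in 1:4) {
      rows <- gen_snps(400, seed = seed * 10 + batch, dup_rate = 0.3,
                       n_accessions = 5, max_pos = 500) # force collisions
      merge_runs(path, s, sorted_run(s, rows), chunk_size = 32)
      oracle_insert(o, rows)
    }
    expect_tbl_equal(decode_all(path, s), oracle_scan(o))
    expect_true(all(verify_bucket(path, s)$pass))
    unlink(path)
  }
})

test_that("keep_first and reduce rules apply across disk and memory", {
  s <- herv_schema()
  rows1 <- gen_herv(500, seed = 1, n_chromosomes = 2, max_pos = 3000,
                    herv_len_max = 50)
  rows2 <- gen_herv(500, seed = 2, n_chromosomes = 2, max_pos = 3000,
                    herv_len_max = 50)

  for (rule_name in c("keep_first", "reduce")) {
    f <- function(old, new) tibble::tibble(evalue = pmin(old$evalue, new$evalue))
    rule <- if (rule_name == "reduce")
      update_rule("reduce", reducer = value_reducer(s, f))
    else update_rule(rule_name)
    path <- tempfile()
    merge_runs(path, s, sorted_run(s, rows1, rule), chunk_size = 16, rule = rule)
    merge_runs(path, s, sorted_run(s, rows2, rule), chunk_size = 16, rule = rule)
    o <- oracle_store(s, rule = rule_name,
                      reducer = if (rule_name == "reduce") f)
    oracle_insert(o, rows1)
    oracle_insert(o, rows2)
    expect_tbl_equal(decode_all(path, s), oracle_scan(o))
    unlink(path)
  }
})

test_that("a misbehaving reducer aborts and leaves the disk bucket untouched", {
  s <- herv_schema()
  rows <- gen_herv(100, seed = 3)
  bad <- update_rule("reduce", reducer = function(old, new) old[1, , drop = FALSE])
  path <- tempfile()
  merge_runs(path, s, sorted_run(s, rows, bad), chunk_size = 16, rule = bad)
  before <- file_bytes(path)
  expect_error(
    merge_runs(path, s, sorted_run(s, rows, update_rule("replace")),
               chunk_size = 16, rule = bad),
    class = "rangestore_integrity_error")
  expect_identical(file_bytes(path), before)
  expect_length(list.files(dirname(path), pattern = "merge$"), 0L)
})

test_that("an interrupted synchronisation leaves the old bucket intact", {
  st <- store_create(tempfile(), "snp", n_buckets = 1, chunk_size = 32)
  store_insert(st, gen_snps(300, seed = 1))
  store_flush(st)
  p <- rangestore:::bucket_file_path(st, 1L)
  before <- file_bytes(p)
  store_insert(st, gen_snps(300, seed = 2))
  st$test_mid_hook <- function() stop("simulated crash mid-merge")
  expect_error(store_flush(st), "simulated crash")
  expect_identical(file_bytes(p), before)
  expect_length(list.files(st$path, pattern = "merge$"), 0L)
  expect_true(all(store_verify(st)$pass))
  store_close(st, flush = FALSE)
})

test_that("merge memory stays bounded by the chunk size", {
  s <- snp_schema()
  path <- tempfile()
  merge_runs(path, s, sorted_run(s, gen_snps(5000, seed = 1)), chunk_size = 64)
  stats <- new.env()
  merge_runs(path, s, sorted_run(s, gen_snps(5000, seed = 2)),
             chunk_size = 64, stats = stats)
  expect_gt(stats$iterations, 10)
  expect_lte(stats$max_disk_blocks, 2)
  expect_lte(stats$max_run_blocks, 2)
})

test_that("the merge rejects an unsorted run", {
  s <- snp_schema()
  recs <- encode_records(s, gen_snps(10, seed = 1)[c(3, 1, 2, 4:10), ])
  expect_error(merge_runs(tempfile(), s, recs),
               class = "rangestore_integrity_error")
})
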