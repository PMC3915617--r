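test_that("built-in schemas have the documented layout", {
  s <- snp_schema()
  expect_identical(s$fields$width, c(1L, 2L, 4L, 1L, 1L))
  expect_identical(s$key_size, 7L)
  expect_identical(s$record_size, 9L)

  h <- herv_schema()
  expect_identical(h$fields$width, c(1L, 4L, 4L, 2L, 2L, 2L, 1L, 4L))
  expect_identical(h$key_size, 16L)
  expect_identical(h$record_size, 20L)
})

test_that("field and schema validation rejects malformed definitions", {
  expect_error(field_spec("x", "key", 4, "float32"),
               class = "rangestore_schema_error")
  expect_error(field_spec("x", "value", 8, "float32"),
               class = "rangestore_schema_error")
  expect_error(field_spec("x", "value", 4, "float64"),
               class = "rangestore_schema_error")
  expect_error(field_spec("x", "value", 0, "unsigned-int"),
               class = "rangestore_schema_error")
  expect_error(record_schema("t", field_spec("v", "value", 1, "unsigned-int")),
               class = "rangestore_schema_error")
  expect_error(record_schema("t",
                             field_spec("a", "key", 1, "unsigned-int"),
                             field_spec("a", "value", 1, "unsigned-int")),
               class = "rangestore_schema_error")
  expect_error(record_schema("t",
                             field_spec("v", "value", 1, "unsigned-int"),
                             field_spec("k", "key", 1, "unsigned-int")),
               class = "rangestore_schema_error")
})

test_that("schema hash distinguishes layouts and survives JSON round-trip", {
  a <- snp_schema()
  b <- record_schema("snp2", a$fields[, c("name", "role", "width", "kind")])
  expect_false(a$hash == b$hash)
  r <- schema_from_json(schema_to_json(a))
  expect_identical(r$hash, a$hash)
  expect_identical(r$fields, a$fields)
})

test_that("codec round-trips every field kind exactly", {
  s <- mixed_schema()
  rows <- mixed_rows(10000L, seed = 11)
  raw <- encode_records(s, rows)
  expect_length(raw, nrow(rows) * s$record_size)
  back <- decode_records(s, raw)
  expect_tbl_equal(back, rows)
})

test_that("codec round-trips the built-in schemas exactly", {
  snp <- gen_snps(5000, seed = 2)
  expect_tbl_equal(decode_records(snp_schema(),
                                  encode_records(snp_schema(), snp)), snp)
  herv <- gen_herv(5000, seed = 2)
  expect_tbl_equal(decode_records(herv_schema(),
                                  encode_records(herv_schema(), herv)), herv)
})

test_that("encoded-key byte order equals decoded tuple order", {
  s <- mixed_schema()
  rows <- mixed_rows(3000L, seed = 5)
  keys <- encode_keys(s, rows)
  ks <- s$key_size
  byte_ord <- rangestore:::cxx_key_order(keys, ks, ks)
  tuple_ord <- do.call(order, c(unname(key_tuple(s, rows)),
                                list(method = "radix")))
  # both orders are stable, so they must agree exactly
  expect_identical(byte_ord, as.integer(tuple_ord))
})

test_that("pairwise key comparison matches tuple comparison at the extremes", {
  s <- snp_schema()
  k <- function(a, c, p) encode_keys(s, list(accession = a, chromosome = c,
                                             position = p))
  expect_identical(compare_keys(k(0, 0, 0), k(0, 0, 0)), 0L)
  expect_identical(compare_keys(k(0, 0, 4294967295), k(0, 1, 0)), -1L)
  expect_identical(compare_keys(k(1, 0, 0), k(0, 65535, 4294967295)), 1L)
  expect_identical(compare_keys(k(255, 65535, 4294967295), k(255, 65535, 4294967294)), 1L)
})

test_that("signed integers order correctly across zero", {
  s <- record_schema("sgn", field_spec("x", "key", 2, "signed-int"),
                     field_spec("v", "value", 1, "unsigned-int"))
  vals <- c(-32768, -1, 0, 1, 32767)
  keys <- lapply(vals, function(v) encode_keys(s, list(x = v)))
  for (i in 1:4)
    expect_identical(compare_keys(keys[[i]], keys[[i + 1]]), -1L)
  rt <- decode_records(s, encode_records(s, list(x = vals, v = 0)))
  expect_identical(rt$x, as.numeric(vals))
})

test_that("fixed-ascii fields pad with zero bytes and round-trip", {
  s <- record_schema("str", field_spec("name", "key", 4, "fixed-ascii"),
                     field_spec("v", "value", 1, "unsigned-int"))
  r <- encode_records(s, list(name = "AB", v = 1))
  expect_identical(r[1:4], as.raw(c(0x41, 0x42, 0, 0)))
  expect_identical(decode_records(s, r)$name, "AB")
  # a short string sorts before its extensions
  expect_identical(compare_keys(encode_keys(s, list(name = "AB")),
                                encode_keys(s, list(name = "ABA"))), -1L)
})

test_that("encode rejects out-of-range, missing and oversized inputs", {
  s <- snp_schema()
  ok <- list(accession = 1, chromosome = 1, position = 1, ref = "A", alt = "G")
  bad <- function(field, value) {
    v <- ok; v[[field]] <- value
    expect_error(encode_records(s, v), field)
  }
  bad("accession", 256)
  bad("accession", -1)
  bad("position", 1.5)
  bad("position", NA)
  bad("ref", "AC") # wider than 1 byte
  expect_error(encode_records(s, ok[-1]), class = "rangestore_schema_error")
  expect_error(decode_records(s, as.raw(1:10))) # not a multiple of record size
})
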