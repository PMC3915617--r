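# Shared helpers for the test suite. All fixtures are generated in code.

expect_tbl_equal <- function(a, b) {
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    x
  }
  expect_identical(strip(a), strip(b))
}

# A minimal schema with a 1-byte key, handy for bucket-map edge cases.
tiny_schema <- function() {
  record_schema(
    "tiny",
    field_spec("k", "key", 1, "unsigned-int"),
    field_spec("v", "value", 1, "unsigned-int"))
}

# A schema exercising every field kind.
mixed_schema <- function() {
  record_schema(
    "mixed",
    field_spec("u1", "key", 1, "unsigned-int"),
    field_spec("s2", "key", 2, "signed-int"),
    field_spec("a3", "key", 3, "fixed-ascii"),
    field_spec("u4", "key", 4, "unsigned-int"),
    field_spec("f32", "value", 4, "float32"),
    field_spec("f64", "value", 8, "float64"),
    field_spec("av", "value", 2, "fixed-ascii"))
}

# Random rows for mixed_schema(), including field-range boundary values.
mixed_rows <- function(n, seed) {
  withr::with_seed(seed, {
    pickv <- function(lo, hi) {
      v <- floor(stats::runif(n, lo, hi + 1))
      # sprinkle in the extremes
      v[sample.int(n, min(n, 4L))] <- c(lo, hi, lo, hi)[seq_len(min(n, 4L))]
      v
    }
    rand_ascii <- function(w) {
      lens <- sample.int(w, n, replace = TRUE)
      vapply(lens, function(l)
        paste(sample(LETTERS, l, replace = TRUE), collapse = ""), "")
    }
    tibble::tibble(
      u1 = pickv(0, 255),
      s2 = pickv(-32768, 32767),
      a3 = rand_ascii(3L),
      u4 = pickv(0, 4294967295),
      f32 = rangestore:::float32_round(stats::rnorm(n)),
      f64 = stats::rnorm(n),
      av = rand_ascii(2L))
  })
}

# Encode rows and collapse them into a strictly sorted, key-unique run
# (what the memtable hands to the merge).
sorted_run <- function(schema, rows, rule = update_rule("replace")) {
  recs <- encode_records(schema, rows)
  ord <- rangestore:::cxx_key_order(recs, schema$record_size, schema$key_size)
  sorted <- rangestore:::cxx_gather(recs, schema$record_size, ord)
  rangestore:::resolve_duplicates(schema, sorted, rule)
}

decode_all <- function(path, schema) {
  b <- open_bucket(path, schema)
  on.exit(close_bucket(b))
  decode_records(schema, read_all(b))
}

file_bytes <- function(path) readBin(path, "raw", n = file.size(path))

# Key tuple of each row as an ordering data frame (for R-side comparisons).
key_tuple <- function(schema, rows) {
  as.data.frame(rows)[, rangestore:::key_fields(schema), drop = FALSE]
}
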