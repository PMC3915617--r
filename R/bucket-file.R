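# On-disk bucket format
#
#   magic "RSTOREBK" (8 B)
#   header, big-endian unsigned: format_version (4 B), schema_hash (4 B),
#     record_size (4 B), chunk_size (4 B), record_count (8 B),
#     index_entry_count (8 B)
#   sparse index: index_entry_count entries of (first_key: key_size B,
#     chunk ordinal: 4 B big-endian, 0-based)
#   payload: record_count sorted, key-unique records in chunks of
#     chunk_size records (the last chunk may be short)
#
# The layout is fixed-width and big-endian throughout, so files are
# bit-identical across platforms.

BUCKET_MAGIC <- charToRaw("RSTOREBK")
BUCKET_FORMAT_VERSION <- 1
HEADER_WIDTHS <- c(4L, 4L, 4L, 4L, 8L, 8L)
HEADER_KINDS <- rep(0L, 6)
HEADER_NAMES <- c("format_version", "schema_hash", "record_size",
                  "chunk_size", "record_count", "index_entry_count")
HEADER_LEN <- 8L + sum(HEADER_WIDTHS)

encode_header <- function(h) {
  c(BUCKET_MAGIC,
    cxx_encode(as.list(h[HEADER_NAMES]), HEADER_WIDTHS, HEADER_KINDS, HEADER_NAMES))
}

decode_header <- function(raw) {
  out <- cxx_decode(raw, HEADER_WIDTHS, HEADER_KINDS)
  names(out) <- HEADER_NAMES
  out
}

bucket_io_abort <- function(msg, class) {
  abort(msg, class = c(class, "rangestore_bucket_error"))
}

# ---- streaming writer ------------------------------------------------------
#
# Payload records are streamed to a side temp file while first keys per chunk
# are collected; `finish()` then assembles header + index + payload into the
# final file via a second temp file and an atomic rename. A sync that dies
# mid-way therefore never leaves a half-valid bucket behind.

bf_writer_open <- function(path, schema, chunk_size) {
  stopifnot(chunk_size >= 1)
  payload_tmp <- paste0(path, ".payload.tmp")
  env <- new.env(parent = emptyenv())
  env$path <- path
  env$schema <- schema
  env$chunk_size <- as.integer(chunk_size)
  env$payload_tmp <- payload_tmp
  env$con <- file(payload_tmp, open = "wb")
  env$pending <- raw(0)
  env$first_keys <- list()
  env$count <- 0
  env$last_key <- NULL
  env
}

bf_writer_add <- function(w, block) {
  if (length(block) == 0L) return(invisible(w))
  s <- w$schema
  st <- cxx_check_sorted(block, s$record_size, s$key_size)
  if (st != 0L)
    bucket_io_abort(if (st == 2L) "integrity error: unsorted input records"
                    else "integrity error: duplicate keys in input records",
                    "rangestore_integrity_error")
  first <- block[seq_len(s$key_size)]
  if (!is.null(w$last_key) && cxx_compare_keys(w$last_key, first) >= 0)
    bucket_io_abort("integrity error: blocks not in ascending key order",
                    "rangestore_integrity_error")
  n <- block_count(s, block)
  w$last_key <- block_keys(s, block_slice(s, block, n, n))
  w$pending <- c(w$pending, block)
  csz <- w$chunk_size
  while (block_count(s, w$pending) >= csz) {
    chunk <- block_slice(s, w$pending, 1L, csz)
    w$first_keys[[length(w$first_keys) + 1L]] <- chunk[seq_len(s$key_size)]
    writeBin(chunk, w$con)
    w$count <- w$count + csz
    w$pending <- block_slice(s, w$pending, csz + 1L, block_count(s, w$pending))
  }
  invisible(w)
}

bf_writer_finish <- function(w) {
  s <- w$schema
  if (length(w$pending) > 0L) {
    w$first_keys[[length(w$first_keys) + 1L]] <- w$pending[seq_len(s$key_size)]
    writeBin(w$pending, w$con)
    w$count <- w$count + block_count(s, w$pending)
    w$pending <- raw(0)
  }
  close(w$con)

  n_entries <- length(w$first_keys)
  header <- encode_header(list(
    format_version = BUCKET_FORMAT_VERSION,
    schema_hash = s$hash,
    record_size = s$record_size,
    chunk_size = w$chunk_size,
    record_count = w$count,
    index_entry_count = n_entries))
  index <- raw(0)
  if (n_entries > 0L) {
    ord <- cxx_encode(list(ordinal = as.numeric(seq_len(n_entries) - 1L)),
                      4L, 0L, "ordinal")
    ord_m <- matrix(ord, nrow = 4L)
    key_m <- matrix(unlist(w$first_keys), nrow = s$key_size)
    index <- as.raw(rbind(key_m, ord_m))
  }

  final_tmp <- paste0(w$path, ".tmp")
  out <- file(final_tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeBin(header, out)
    if (length(index)) writeBin(index, out)
    pin <- file(w$payload_tmp, open = "rb")
    block_bytes <- w$chunk_size * s$record_size
    repeat {
      buf <- readBin(pin, "raw", n = block_bytes)
      if (length(buf) == 0L) break
      writeBin(buf, out)
    }
    close(pin)
    ok <- TRUE
  }, finally = {
    close(out)
    unlink(w$payload_tmp)
    if (!ok) unlink(final_tmp)
  })
  if (!file.rename(final_tmp, w$path))
    bucket_io_abort(sprintf("I/O error: cannot move bucket into place at %s", w$path),
                    "rangestore_io_error")
  invisible(list(path = w$path, record_count = w$count,
                 index_entry_count = n_entries))
}

bf_writer_discard <- function(w) {
  try(close(w$con), silent = TRUE)
  unlink(w$payload_tmp)
  invisible(NULL)
}

# ---- public operations -----------------------------------------------------

#' Write a sorted run of encoded records as a bucket file
#'
#' The input must already be strictly ascending by key with duplicates
#' resolved; the file is written to a temporary path and atomically renamed
#' into place, so an existing file at `path` is never left half-replaced.
#'
#' @param path Destination file path.
#' @param schema The record schema.
#' @param records Encoded records (raw vector), strictly key-sorted and
#'   key-unique.
#' @param chunk_size Records per chunk (the sparse index holds one entry per
#'   chunk).
#' @return Invisibly, a list with `path`, `record_count` and
#'   `index_entry_count`.
#' @export
#' @examples
#' s <- snp_schema()
#' recs <- encode_records(s, tibble::tibble(accession = 0, chromosome = 1,
#'   position = 1:5, ref = "A", alt = "G"))
#' f <- tempfile()
#' write_bucket(f, s, recs, chunk_size = 2)
write_bucket <- function(path, schema, records, chunk_size = 4096L) {
  w <- bf_writer_open(path, schema, chunk_size)
  res <- tryCatch({
    bf_writer_add(w, records)
    bf_writer_finish(w)
  }, error = function(e) {
    bf_writer_discard(w)
    stop(e)
  })
  invisible(res)
}

#' Open a bucket file
#'
#' Reads the header and the full sparse index into memory and validates them
#' against the schema and the file length; payload chunks are read lazily via
#' [read_chunk()]. The handle counts bytes read from the payload, which is how
#' the lazy-read property is audited.
#'
#' @param path Bucket file path.
#' @param schema The record schema the file is expected to hold.
#' @return An `rs_bucket` handle.
#' @export
open_bucket <- function(path, schema) {
  if (!file.exists(path))
    bucket_io_abort(sprintf("no bucket file at %s", path), "rangestore_io_error")
  fsize <- file.size(path)
  con <- file(path, open = "rb")
  head_raw <- readBin(con, "raw", n = HEADER_LEN)
  if (length(head_raw) < HEADER_LEN ||
      !identical(head_raw[1:8], BUCKET_MAGIC)) {
    close(con)
    bucket_io_abort(sprintf("incompatible file: %s is not a bucket file", path),
                    "rangestore_incompatible_error")
  }
  h <- decode_header(head_raw[-(1:8)])
  if (h$format_version != BUCKET_FORMAT_VERSION) {
    close(con)
    bucket_io_abort(sprintf("incompatible file: format version %d (expected %d)",
                            h$format_version, BUCKET_FORMAT_VERSION),
                    "rangestore_incompatible_error")
  }
  if (h$schema_hash != schema$hash || h$record_size != schema$record_size) {
    close(con)
    bucket_io_abort("incompatible file: schema does not match",
                    "rangestore_incompatible_error")
  }
  ks <- schema$key_size
  expected_entries <- ceiling(h$record_count / h$chunk_size)
  expected_size <- HEADER_LEN + h$index_entry_count * (ks + 4) +
    h$record_count * h$record_size
  if (h$index_entry_count != expected_entries || fsize != expected_size) {
    close(con)
    bucket_io_abort(sprintf("corrupt bucket file: %s (size %d, expected %d)",
                            path, fsize, expected_size),
                    "rangestore_corruption_error")
  }
  index_keys <- raw(0)
  if (h$index_entry_count > 0) {
    idx_raw <- readBin(con, "raw", n = h$index_entry_count * (ks + 4))
    m <- matrix(idx_raw, nrow = ks + 4L)
    index_keys <- as.raw(m[seq_len(ks), , drop = FALSE])
    ords <- cxx_decode(as.raw(m[ks + 1:4, , drop = FALSE]), 4L, 0L)[[1]]
    if (!identical(ords, as.numeric(seq_len(h$index_entry_count) - 1)))
      bucket_io_abort("corrupt bucket file: index ordinals out of sequence",
                      "rangestore_corruption_error")
    if (h$index_entry_count > 1 &&
        cxx_check_sorted(index_keys, ks, ks) != 0L)
      bucket_io_abort("corrupt bucket file: index keys not strictly ascending",
                      "rangestore_corruption_error")
  }
  env <- new.env(parent = emptyenv())
  env$path <- path
  env$schema <- schema
  env$con <- con
  env$record_count <- h$record_count
  env$chunk_size <- as.integer(h$chunk_size)
  env$n_chunks <- as.integer(h$index_entry_count)
  env$index_keys <- index_keys
  env$data_offset <- HEADER_LEN + h$index_entry_count * (ks + 4)
  env$payload_bytes_read <- 0
  class(env) <- "rs_bucket"
  env
}

#' @export
print.rs_bucket <- function(x, ...) {
  cat(sprintf("<rs_bucket %s>  %d record(s) in %d chunk(s) of %d\n",
              basename(x$path), x$record_count, x$n_chunks, x$chunk_size))
  invisible(x)
}

#' Close a bucket handle
#' @param bucket An `rs_bucket` handle.
#' @export
close_bucket <- function(bucket) {
  if (!is.null(bucket$con)) {
    try(close(bucket$con), silent = TRUE)
    bucket$con <- NULL
  }
  invisible(NULL)
}

#' Locate the chunk that could contain a key
#'
#' Binary search over the sparse index: returns the unique chunk whose
#' `[first_key_c, first_key_c+1)` range covers `key`; keys below the first
#' index entry map to chunk 1, keys past the last record to the last chunk.
#'
#' @param bucket An open `rs_bucket`.
#' @param key Encoded key (raw, `key_size` bytes).
#' @return 1-based chunk ordinal, or `NA_integer_` for an empty bucket.
#' @export
locate_chunk <- function(bucket, key) {
  if (bucket$record_count == 0) return(NA_integer_)
  ks <- bucket$schema$key_size
  n_le <- cxx_upper_bound(bucket$index_keys, ks, ks, key) - 1L
  max(n_le, 1L)
}

#' Read one chunk of a bucket
#'
#' @param bucket An open `rs_bucket`.
#' @param ordinal 1-based chunk ordinal.
#' @return Raw vector of the chunk's encoded records (`chunk_size` records,
#'   fewer for the last chunk).
#' @export
read_chunk <- function(bucket, ordinal) {
  if (is.na(ordinal) || ordinal < 1L || ordinal > bucket$n_chunks)
    bucket_io_abort(sprintf("bounds error: chunk %s of %d", ordinal, bucket$n_chunks),
                    "rangestore_bounds_error")
  rs <- bucket$schema$record_size
  n <- if (ordinal == bucket$n_chunks)
    bucket$record_count - (bucket$n_chunks - 1) * bucket$chunk_size
  else bucket$chunk_size
  seek(bucket$con, where = bucket$data_offset +
         (ordinal - 1) * bucket$chunk_size * rs, origin = "start")
  out <- readBin(bucket$con, "raw", n = n * rs)
  if (length(out) != n * rs)
    bucket_io_abort("corrupt bucket file: short chunk read",
                    "rangestore_corruption_error")
  bucket$payload_bytes_read <- bucket$payload_bytes_read + length(out)
  out
}

#' Read every record of a bucket file
#' @param bucket An open `rs_bucket`.
#' @return Raw vector of all encoded records, in key order.
#' @export
read_all <- function(bucket) {
  if (bucket$n_chunks == 0L) return(raw(0))
  do.call(c, lapply(seq_len(bucket$n_chunks), function(i) read_chunk(bucket, i)))
}

#' Audit a bucket file
#'
#' Re-validates the whole file: header consistency (done at open), strict key
#' order across all chunks, and that every sparse-index entry equals the key
#' of its chunk's first record.
#'
#' @param path Bucket file path.
#' @param schema The record schema.
#' @return A tibble of checks with columns `check` and `pass`.
#' @export
verify_bucket <- function(path, schema) {
  b <- open_bucket(path, schema)
  on.exit(close_bucket(b))
  ks <- schema$key_size
  sorted_ok <- TRUE
  index_ok <- TRUE
  last_key <- NULL
  for (i in seq_len(b$n_chunks)) {
    chunk <- read_chunk(b, i)
    if (cxx_check_sorted(chunk, schema$record_size, ks) != 0L) sorted_ok <- FALSE
    first <- chunk[seq_len(ks)]
    idx_key <- b$index_keys[((i - 1) * ks + 1):(i * ks)]
    if (!identical(first, idx_key)) index_ok <- FALSE
    if (!is.null(last_key) && cxx_compare_keys(last_key, first) >= 0)
      sorted_ok <- FALSE
    n <- block_count(schema, chunk)
    last_key <- block_keys(schema, block_slice(schema, chunk, n, n))
  }
  tibble(check = c("header_consistent", "strictly_sorted", "index_first_keys"),
         pass = c(TRUE, sorted_ok, index_ok))
}
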