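#' Encode records to their fixed-width binary form
#'
#' Turns a batch of decoded records into a single raw vector of
#' `n * record_size` bytes. Integer fields are written big-endian (signed
#' ones biased by 2^(8w-1)), floats as big-endian IEEE-754, and fixed-ascii
#' fields are padded on the right with 0x00 up to their declared width.
#' The first `key_size` bytes of every record are its encoded key; by
#' construction, `memcmp` order of encoded keys equals lexicographic order of
#' the decoded key tuples.
#'
#' @param schema An [record_schema()].
#' @param values A data frame (or named list of equal-length vectors) with one
#'   column per schema field. Extra columns are ignored; missing ones error.
#' @return A raw vector of length `nrow(values) * schema$record_size`.
#' @seealso [decode_records()], [compare_keys()]
#' @export
#' @examples
#' s <- snp_schema()
#' r <- encode_records(s, tibble::tibble(accession = 0, chromosome = 1,
#'                                       position = 42, ref = "A", alt = "G"))
#' length(r)  # 9
encode_records <- function(schema, values) {
  vals <- field_columns(schema, values, schema$fields$name)
  cxx_encode(vals, schema$widths, schema$kinds, schema$fields$name)
}

#' Decode fixed-width binary records
#'
#' Exact inverse of [encode_records()] (up to the documented fixed-ascii
#' padding convention: trailing 0x00 bytes are stripped on decode).
#'
#' @param schema An [record_schema()].
#' @param raw A raw vector whose length is a multiple of
#'   `schema$record_size`.
#' @return A tibble with one column per schema field.
#' @export
decode_records <- function(schema, raw) {
  out <- cxx_decode(raw, schema$widths, schema$kinds)
  names(out) <- schema$fields$name
  as_tibble(out)
}

# Extract the named columns in schema order, coercing to the types the codec
# expects. `values` may be a data frame or a named list.
field_columns <- function(schema, values, wanted) {
  missing <- setdiff(wanted, names(values))
  if (length(missing))
    abort(sprintf("schema error: missing field(s): %s",
                  paste(missing, collapse = ", ")),
          class = "rangestore_schema_error")
  kinds <- schema$fields$kind[match(wanted, schema$fields$name)]
  out <- vector("list", length(wanted))
  for (i in seq_along(wanted)) {
    v <- values[[wanted[i]]]
    out[[i]] <- if (kinds[i] == "fixed-ascii") as.character(v) else as.numeric(v)
  }
  n <- max(lengths(out))
  out <- lapply(out, function(v) if (length(v) == 1L && n > 1L) rep(v, n) else v)
  names(out) <- wanted
  out
}

#' Encode only the key part of records
#'
#' @inheritParams encode_records
#' @return A raw vector of length `nrow(values) * schema$key_size`.
#' @export
encode_keys <- function(schema, values) {
  kn <- key_fields(schema)
  vals <- field_columns(schema, values, kn)
  cxx_encode(vals, key_widths(schema), key_kinds(schema), kn)
}

#' Compare two encoded keys bytewise
#'
#' Bytewise lexicographic comparison; because the key codec is
#' order-preserving this equals comparison of the decoded key tuples.
#'
#' @param a,b Raw vectors of equal length (encoded keys).
#' @return -1, 0 or 1.
#' @export
#' @examples
#' s <- snp_schema()
#' k1 <- encode_keys(s, list(accession = 0, chromosome = 1, position = 100))
#' k2 <- encode_keys(s, list(accession = 0, chromosome = 1, position = 2000))
#' compare_keys(k1, k2)  # -1
compare_keys <- function(a, b) {
  cxx_compare_keys(a, b)
}

# Key bytes of every record in a block.
block_keys <- function(schema, recs) {
  cxx_keys(recs, schema$record_size, schema$key_size)
}

# Records i..j (1-based, inclusive) of a block, as raw bytes.
block_slice <- function(schema, recs, i, j) {
  if (j < i) return(raw(0))
  rs <- schema$record_size
  recs[((i - 1) * rs + 1):(j * rs)]
}

block_count <- function(schema, recs) length(recs) %/% schema$record_size
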