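#' @useDynLib rangestore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom rlang abort warn
NULL

FIELD_KINDS <- c("unsigned-int" = 0L, "signed-int" = 1L,
                 "float32" = 2L, "float64" = 3L, "fixed-ascii" = 4L)
ORDERABLE_KINDS <- c("unsigned-int", "signed-int", "fixed-ascii")

#' Declare one fixed-width record field
#'
#' A field is a named, fixed-width slot of a record, either part of the key
#' (and therefore orderable) or part of the value. Integer fields are stored
#' big-endian -- signed ones with a bias of 2^(8w-1) -- so that bytewise
#' comparison of encoded keys equals numeric comparison of the decoded values.
#'
#' @param name Field name (short string).
#' @param role `"key"` or `"value"`.
#' @param width Width in bytes (>= 1). Forced to 4 for `float32` and 8 for
#'   `float64`. Integer fields wider than 6 bytes are exact only up to 2^53
#'   because values travel through R doubles.
#' @param kind One of `"unsigned-int"`, `"signed-int"`, `"float32"`,
#'   `"float64"`, `"fixed-ascii"`. Key fields must be orderable, i.e. one of
#'   the integer kinds or `fixed-ascii`.
#' @return A one-row tibble describing the field.
#' @export
#' @examples
#' field_spec("position", "key", 4, "unsigned-int")
field_spec <- function(name, role = c("key", "value"), width, kind) {
  role <- match.arg(role)
  kind <- match.arg(kind, names(FIELD_KINDS))
  if (kind == "float32" && width != 4)
    abort(sprintf("field '%s': float32 requires width 4, got %d", name, width),
          class = "rangestore_schema_error")
  if (kind == "float64" && width != 8)
    abort(sprintf("field '%s': float64 requires width 8, got %d", name, width),
          class = "rangestore_schema_error")
  if (width < 1)
    abort(sprintf("field '%s': width must be >= 1", name),
          class = "rangestore_schema_error")
  if (role == "key" && !kind %in% ORDERABLE_KINDS)
    abort(sprintf("field '%s': key parts must be orderable (integer or fixed-ascii), not %s",
                  name, kind),
          class = "rangestore_schema_error")
  tibble(name = as.character(name), role = role,
         width = as.integer(width), kind = kind)
}

#' Define a fixed-width record schema
#'
#' A record schema lists all key parts first (key part 1, 2, ...), then all
#' value parts. Every record of a schema occupies exactly `record_size` bytes
#' on disk; the first `key_size` bytes are the encoded key, laid out so that
#' bytewise lexicographic comparison of two encoded keys equals lexicographic
#' comparison of the decoded key tuples.
#'
#' @param name Schema name.
#' @param ... [field_spec()] rows (or a single tibble of them), key fields
#'   first.
#' @return An object of class `rs_schema`.
#' @export
#' @examples
#' record_schema("toy",
#'   field_spec("chrom", "key", 1, "unsigned-int"),
#'   field_spec("pos",   "key", 4, "unsigned-int"),
#'   field_spec("score", "value", 4, "float32"))
record_schema <- function(name, ...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1]]) && nrow(parts[[1]]) > 1L)
    fields <- as_tibble(parts[[1]])
  else
    fields <- dplyr::bind_rows(parts)
  if (nrow(fields) == 0L || !any(fields$role == "key"))
    abort("a schema needs at least one key part", class = "rangestore_schema_error")
  if (anyDuplicated(fields$name))
    abort("duplicate field names in schema", class = "rangestore_schema_error")
  kpos <- which(fields$role == "key")
  if (!identical(kpos, seq_along(kpos)))
    abort("all key parts must come first, in key-part order",
          class = "rangestore_schema_error")
  fields$position <- c(seq_along(kpos),
                       seq_len(nrow(fields) - length(kpos)))
  fields <- fields[, c("name", "role", "position", "width", "kind")]
  key_size <- sum(fields$width[fields$role == "key"])
  record_size <- sum(fields$width)
  structure(
    list(name = name, fields = fields,
         key_size = as.integer(key_size),
         record_size = as.integer(record_size),
         widths = as.integer(fields$width),
         kinds = unname(FIELD_KINDS[fields$kind]),
         hash = schema_hash_fields(name, fields)),
    class = "rs_schema")
}

#' @export
print.rs_schema <- function(x, ...) {
  cat(sprintf("<rs_schema '%s'>  record %d B (key %d B, value %d B)\n",
              x$name, x$record_size, x$key_size, x$record_size - x$key_size))
  print(x$fields)
  invisible(x)
}

n_fields <- function(schema) nrow(schema$fields)
key_fields <- function(schema) schema$fields$name[schema$fields$role == "key"]
value_fields <- function(schema) schema$fields$name[schema$fields$role == "value"]
value_size <- function(schema) schema$record_size - schema$key_size
key_widths <- function(schema) schema$widths[schema$fields$role == "key"]
key_kinds <- function(schema) schema$kinds[schema$fields$role == "key"]

# FNV-1a 32-bit over the canonical schema description, done with doubles
# (kept below 2^53 by splitting the 32-bit state for the multiply).
fnv1a32 <- function(bytes) {
  h <- 2166136261
  prime <- 16777619
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- ((lo16 * prime) %% 4294967296 + ((hi16 * prime) %% 65536) * 65536) %% 4294967296
  }
  h
}

schema_hash_fields <- function(name, fields) {
  canon <- paste(c(name, paste(fields$name, fields$role, fields$width,
                               fields$kind, sep = "|")),
                 collapse = ";")
  fnv1a32(utf8ToInt(canon))
}

#' Built-in schema for SNP records
#'
#' Nine bytes per record: a 7-byte key of accession id (1 B unsigned),
#' chromosome (2 B unsigned) and 1-based position (4 B unsigned), plus a
#' 2-byte value of reference and mutated nucleotide (1 ASCII byte each,
#' uppercase A/C/G/T/N).
#'
#' @return An `rs_schema`.
#' @export
#' @examples
#' snp_schema()$record_size  # 9
snp_schema <- function() {
  record_schema(
    "snp",
    field_spec("accession",  "key",   1, "unsigned-int"),
    field_spec("chromosome", "key",   2, "unsigned-int"),
    field_spec("position",   "key",   4, "unsigned-int"),
    field_spec("ref",        "value", 1, "fixed-ascii"),
    field_spec("alt",        "value", 1, "fixed-ascii"))
}

#' Built-in schema for HERV BLAST-hit records
#'
#' Twenty bytes per record: a 16-byte key of chromosome (1 B), start/end on
#' the chromosome (4 B each), start/end on the HERV fragment (2 B each), HERV
#' id (2 B) and strand (1 B, 0 = plus / 1 = minus), plus the BLAST E-value as
#' a big-endian IEEE-754 float32 (about 7 significant digits, ample for
#' threshold filtering at 1e-20..1e-50).
#'
#' @return An `rs_schema`.
#' @export
#' @examples
#' herv_schema()$key_size  # 16
herv_schema <- function() {
  record_schema(
    "herv",
    field_spec("chromosome",  "key",   1, "unsigned-int"),
    field_spec("chrom_start", "key",   4, "unsigned-int"),
    field_spec("chrom_end",   "key",   4, "unsigned-int"),
    field_spec("herv_start",  "key",   2, "unsigned-int"),
    field_spec("herv_end",    "key",   2, "unsigned-int"),
    field_spec("herv_id",     "key",   2, "unsigned-int"),
    field_spec("strand",      "key",   1, "unsigned-int"),
    field_spec("evalue",      "value", 4, "float32"))
}

builtin_schema <- function(name) {
  switch(name,
         snp = snp_schema(),
         herv = herv_schema(),
         abort(sprintf("unknown built-in schema '%s'", name),
               class = "rangestore_schema_error"))
}

#' Serialise / restore a schema as JSON text
#'
#' The JSON form is what the store writes into its `store.meta` file and what
#' benchmark configs may embed.
#'
#' @param schema An `rs_schema`.
#' @param json JSON text produced by `schema_to_json()`.
#' @return `schema_to_json()` a JSON string; `schema_from_json()` an
#'   `rs_schema`.
#' @export
schema_to_json <- function(schema) {
  jsonlite::toJSON(list(name = schema$name,
                        fields = schema$fields[, c("name", "role", "width", "kind")]),
                   auto_unbox = TRUE)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  f <- as_tibble(x$fields)
  record_schema(x$name, f)
}
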