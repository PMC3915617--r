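#' Range-partitioned bucket map
#'
#' The mapping M(K) -> bucket assigns every key to one of `n_buckets`
#' contiguous key ranges. Range partitioning (rather than hashing) is what
#' lets a range select cross bucket boundaries with purely sequential reads:
#' the mapping is monotone, so k1 <= k2 implies bucket(k1) <= bucket(k2).
#'
#' The default map splits the space of the leading `min(key_size, 6)` key
#' bytes into `n_buckets` even intervals (6 bytes keeps the arithmetic exact
#' in doubles); for the SNP schema this approximates a per-accession /
#' per-chromosome partitioning. Boundaries use the half-open convention: a key
#' equal to boundary i belongs to bucket i + 1, i.e. bucket i covers
#' `[boundary_{i-1}, boundary_i)`.
#'
#' @param schema An [record_schema()].
#' @param n_buckets Number of buckets (>= 1). If the leading key bytes cannot
#'   distinguish that many even splits the effective count is reduced with a
#'   warning.
#' @return An object of class `rs_bucket_map`.
#' @export
#' @examples
#' m <- default_bucket_map(snp_schema(), 4)
#' m$n_buckets
default_bucket_map <- function(schema, n_buckets) {
  stopifnot(n_buckets >= 1)
  ks <- schema$key_size
  if (n_buckets == 1L)
    return(new_bucket_map(schema, raw(0)))
  p <- min(ks, 6L)
  total <- 256^p
  cuts <- unique(floor(total * seq_len(n_buckets - 1) / n_buckets))
  cuts <- cuts[cuts > 0 & cuts < total]
  if (length(cuts) < n_buckets - 1L)
    warn(sprintf("key space supports only %d distinct boundaries; effective bucket count reduced to %d",
                 length(cuts), length(cuts) + 1L))
  bnd <- vapply(cuts, function(v) {
    b <- integer(p)
    for (j in p:1) { b[j] <- v %% 256; v <- v %/% 256 }
    as.raw(c(b, integer(ks - p)))
  }, raw(ks))
  new_bucket_map(schema, as.raw(bnd))
}

new_bucket_map <- function(schema, boundaries) {
  structure(list(key_size = schema$key_size,
                 boundaries = boundaries,
                 n_buckets = length(boundaries) %/% schema$key_size + 1L),
            class = "rs_bucket_map")
}

#' @export
print.rs_bucket_map <- function(x, ...) {
  cat(sprintf("<rs_bucket_map>  %d bucket(s), key size %d B\n",
              x$n_buckets, x$key_size))
  invisible(x)
}

#' Route an encoded key to its bucket
#'
#' Binary search over the map's boundary keys; bucket ids are 1-based.
#'
#' @param map An [default_bucket_map()] result.
#' @param key An encoded key (raw vector of `key_size` bytes), or several
#'   concatenated keys.
#' @return Integer bucket id(s).
#' @export
route <- function(map, key) {
  cxx_route(key, map$key_size, map$key_size, map$boundaries)
}

# Bucket per record of an encoded block.
route_block <- function(map, schema, recs) {
  cxx_route(recs, schema$record_size, schema$key_size, map$boundaries)
}

map_to_hex <- function(map) {
  if (length(map$boundaries) == 0L) return(character(0))
  m <- matrix(map$boundaries, nrow = map$key_size)
  apply(m, 2, function(col) paste(sprintf("%02x", as.integer(col)), collapse = ""))
}

map_from_hex <- function(schema, hex) {
  if (length(hex) == 0L) return(new_bucket_map(schema, raw(0)))
  bnd <- unlist(lapply(hex, function(h) {
    as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
  }))
  new_bucket_map(schema, bnd)
}
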