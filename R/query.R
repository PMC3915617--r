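# Query path (disk buckets only): route the key to its bucket, binary-search
# the sparse index for the chunk, binary-search inside the chunk, then -- for
# ranges -- read sequentially across chunk and bucket boundaries until the end
# key is passed. Queries see flushed data only; call store_flush() first for
# read-your-writes.

#' Look up records by exact key
#'
#' A single lookup is the degenerate range select with equal start and end
#' keys; this function runs the first three steps of that path (bucket, chunk,
#' in-chunk binary search) for a whole batch of keys at once, grouping them by
#' bucket and chunk so each chunk is read once.
#'
#' @param store An open `rs_store`.
#' @param keys A data frame with the schema's key columns, one row per query
#'   (extra columns ignored).
#' @return A tibble with the key columns as queried, the value columns
#'   (`NA` where absent) and a logical `found` column, in query order.
#' @export
#' @examples
#' st <- store_create(tempfile(), "snp", n_buckets = 2)
#' store_insert(st, tibble::tibble(accession = 0, chromosome = 1,
#'                                 position = 42, ref = "A", alt = "G"))
#' store_flush(st)
#' store_lookup(st, tibble::tibble(accession = 0, chromosome = 1, position = 42))
store_lookup <- function(store, keys) {
  check_open(store)
  s <- store$schema
  nq <- nrow(keys)
  kf <- key_fields(s)
  vf <- value_fields(s)
  out_vals <- lapply(vf, function(f) {
    kind <- s$fields$kind[s$fields$name == f]
    rep(if (kind == "fixed-ascii") NA_character_ else NA_real_, nq)
  })
  names(out_vals) <- vf
  found <- logical(nq)
  if (nq > 0) {
    qkeys <- encode_keys(s, keys)
    ks <- s$key_size
    ids <- cxx_route(qkeys, ks, ks, store$map$boundaries)
    for (grp in split(seq_len(nq), ids)) {
      id <- ids[grp[1]]
      h <- get_handle(store, id)
      if (is.null(h) || h$record_count == 0) next
      bk <- cxx_gather(qkeys, ks, as.integer(grp)) # this bucket's query keys
      # chunk per key: number of index entries <= key, clamped to >= 1
      chunks <- pmax(cxx_route(bk, ks, ks, h$index_keys) - 1L, 1L)
      for (cgrp in split(seq_along(grp), chunks)) {
        ord <- chunks[cgrp[1]]
        chunk <- read_chunk(h, ord)
        ck <- cxx_gather(bk, ks, as.integer(cgrp))
        pos <- cxx_match_keys(chunk, s$record_size, ks, ck)
        hit <- !is.na(pos)
        if (!any(hit)) next
        recs <- cxx_gather(chunk, s$record_size, as.integer(pos[hit]))
        dec <- decode_records(s, recs)
        rows <- grp[cgrp][hit]
        found[rows] <- TRUE
        for (f in vf) out_vals[[f]][rows] <- dec[[f]]
      }
    }
  }
  res <- as_tibble(keys[, kf, drop = FALSE])
  for (f in kf) # type-stable keys: doubles for numeric kinds, as decode yields
    res[[f]] <- if (is.character(res[[f]])) res[[f]] else as.numeric(res[[f]])
  for (f in vf) res[[f]] <- out_vals[[f]]
  res$found <- found
  res
}

#' Select all records with keys in a closed range
#'
#' Returns every stored record with `k_start <= key <= k_end` (both ends
#' inclusive) in ascending key order, reading sequentially across chunk and
#' bucket boundaries. Keys absent from the store inside the range are simply
#' skipped. The scan holds one chunk at a time; memory grows only with the
#' result.
#'
#' @param store An open `rs_store`.
#' @param k_start,k_end Named lists (or one-row data frames) of key field
#'   values; `k_start` must not exceed `k_end` in key order.
#' @param predicate Optional filter: `function(tbl)` on a tibble of decoded
#'   records returning a logical vector. Evaluated per chunk as records are
#'   read (a post-filter on value fields, e.g. an E-value threshold).
#' @return A tibble of decoded records.
#' @export
#' @examples
#' st <- store_create(tempfile(), "snp", n_buckets = 2)
#' store_insert(st, tibble::tibble(accession = 0, chromosome = 1,
#'                                 position = c(5, 9, 14), ref = "A", alt = "G"))
#' store_flush(st)
#' store_range(st,
#'   k_start = list(accession = 0, chromosome = 1, position = 1),
#'   k_end   = list(accession = 0, chromosome = 1, position = 10))
store_range <- function(store, k_start, k_end, predicate = NULL) {
  check_open(store)
  s <- store$schema
  klo <- encode_keys(s, one_key(k_start))
  khi <- encode_keys(s, one_key(k_end))
  if (cxx_compare_keys(klo, khi) > 0)
    abort("argument error: k_start exceeds k_end", class = "rangestore_argument_error")
  ks <- s$key_size
  rs <- s$record_size
  b0 <- route(store$map, klo)
  b1 <- route(store$map, khi)
  pieces <- list()
  done <- FALSE
  for (id in b0:b1) {
    if (done) break
    h <- get_handle(store, id)
    if (is.null(h) || h$record_count == 0) next
    c0 <- if (id == b0) locate_chunk(h, klo) else 1L
    for (ord in c0:h$n_chunks) {
      chunk <- read_chunk(h, ord)
      n <- block_count(s, chunk)
      i0 <- if (id == b0 && ord == c0) cxx_lower_bound(chunk, rs, ks, klo) else 1L
      i1 <- cxx_upper_bound(chunk, rs, ks, khi) - 1L
      if (i1 >= i0) {
        dec <- decode_records(s, block_slice(s, chunk, i0, i1))
        if (!is.null(predicate)) dec <- dec[predicate(dec), , drop = FALSE]
        if (nrow(dec)) pieces[[length(pieces) + 1L]] <- dec
      }
      if (i1 < n) { done <- TRUE; break } # a key past k_end exists here
    }
  }
  if (!length(pieces)) return(empty_records(s))
  dplyr::bind_rows(pieces)
}

#' Scan every record of a store in key order
#'
#' Equivalent to a range select over the whole key space.
#'
#' @param store An open `rs_store`.
#' @return A tibble of all decoded records, ascending by key.
#' @export
store_scan <- function(store) {
  check_open(store)
  s <- store$schema
  pieces <- list()
  for (id in seq_len(store$map$n_buckets)) {
    h <- get_handle(store, id)
    if (is.null(h) || h$record_count == 0) next
    for (ord in seq_len(h$n_chunks))
      pieces[[length(pieces) + 1L]] <- decode_records(s, read_chunk(h, ord))
  }
  if (!length(pieces)) return(empty_records(s))
  dplyr::bind_rows(pieces)
}

one_key <- function(k) {
  if (is.data.frame(k)) {
    if (nrow(k) != 1L)
      abort("argument error: expected exactly one key", class = "rangestore_argument_error")
    return(k)
  }
  as_tibble(as.list(k))
}

empty_records <- function(schema) {
  out <- lapply(schema$fields$kind, function(k)
    if (k == "fixed-ascii") character(0) else numeric(0))
  names(out) <- schema$fields$name
  as_tibble(out)
}
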