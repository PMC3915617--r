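# In-memory brute-force reference. It answers the same queries as the store
# from a plain tibble of all inserted rows, resolving duplicate keys by
# insertion order under the same update-rule semantics -- but through an
# entirely different code path (dplyr on decoded values, no byte codec, no
# merge), which is what makes it a meaningful cross-check for the benchmark
# harness and the test-suite.

#' Create an in-memory reference oracle
#'
#' @param schema The record schema.
#' @param rule `"replace"`, `"keep_first"`, or `"reduce"`.
#' @param reducer For `"reduce"`: `function(old, new)` on two tibbles of value
#'   fields (one row per colliding key) returning one of the same shape --
#'   the decoded-space counterpart of the store's byte-level reducer.
#' @return An `rs_oracle` handle.
#' @export
#' @examples
#' o <- oracle_store(snp_schema())
#' oracle_insert(o, tibble::tibble(accession = 0, chromosome = 1,
#'                                 position = 7, ref = "A", alt = "T"))
#' oracle_scan(o)
oracle_store <- function(schema, rule = "replace", reducer = NULL) {
  if (rule == "reduce" && !is.function(reducer))
    abort("the 'reduce' rule needs a decoded-space reducer",
          class = "rangestore_schema_error")
  env <- new.env(parent = emptyenv())
  env$schema <- schema
  env$rule <- rule
  env$reducer <- reducer
  env$rows <- list()
  env$resolved <- NULL # memoised resolved view
  class(env) <- "rs_oracle"
  env
}

#' @rdname oracle_store
#' @param oracle An `rs_oracle`.
#' @param values A data frame of records (schema columns).
#' @export
oracle_insert <- function(oracle, values) {
  s <- oracle$schema
  values <- as_tibble(values)
  # rebuild the tibble from scratch: drops foreign attributes and normalises
  # column types to what the codec round-trip yields (double for numeric
  # kinds, character for ascii) so comparisons are type-stable
  cols <- lapply(seq_len(nrow(s$fields)), function(i)
    if (s$fields$kind[i] == "fixed-ascii")
      as.character(values[[s$fields$name[i]]])
    else as.numeric(values[[s$fields$name[i]]]))
  names(cols) <- s$fields$name
  oracle$rows[[length(oracle$rows) + 1L]] <- as_tibble(cols)
  oracle$resolved <- NULL
  invisible(oracle)
}

# Resolve duplicates in insertion order and sort by key tuple.
oracle_view <- function(oracle) {
  if (!is.null(oracle$resolved)) return(oracle$resolved)
  s <- oracle$schema
  kf <- key_fields(s)
  vf <- value_fields(s)
  all <- dplyr::bind_rows(oracle$rows)
  if (nrow(all) == 0L) {
    oracle$resolved <- empty_records(s)
    return(oracle$resolved)
  }
  kdf <- all[, kf, drop = FALSE]
  res <- switch(
    oracle$rule,
    replace = all[!duplicated(kdf, fromLast = TRUE), , drop = FALSE],
    keep_first = all[!duplicated(kdf), , drop = FALSE],
    reduce = {
      grp <- vctrs_group_id(kdf)
      first <- which(!duplicated(grp))
      out <- all[first, , drop = FALSE]
      pos_in_out <- match(grp, grp[first])
      sizes <- tabulate(pos_in_out)
      occ <- stats::ave(seq_len(nrow(all)), grp, FUN = seq_along)
      maxs <- if (length(sizes)) max(sizes) else 1L
      if (maxs > 1L) for (pass in 2:maxs) {
        sel <- which(occ == pass)
        if (!length(sel)) break
        tgt <- pos_in_out[sel]
        out[tgt, vf] <- oracle$reducer(out[tgt, vf, drop = FALSE],
                                       all[sel, vf, drop = FALSE])
      }
      out
    })
  res <- res[do.call(order, c(unname(res[, kf, drop = FALSE]),
                              list(method = "radix"))), , drop = FALSE]
  oracle$resolved <- as_tibble(res)
  oracle$resolved
}

vctrs_group_id <- function(df) {
  # dense group ids by key tuple, first-appearance order
  key <- do.call(paste, c(unname(df), list(sep = "\r")))
  match(key, unique(key))
}

#' @rdname oracle_store
#' @param keys A data frame of key columns, one row per query.
#' @export
oracle_lookup <- function(oracle, keys) {
  s <- oracle$schema
  kf <- key_fields(s)
  vf <- value_fields(s)
  view <- oracle_view(oracle)
  keys <- as_tibble(keys)
  for (f in kf)
    keys[[f]] <- if (is.character(keys[[f]])) keys[[f]] else as.numeric(keys[[f]])
  res <- dplyr::left_join(keys[, kf, drop = FALSE],
                          dplyr::mutate(view, .present = TRUE),
                          by = kf)
  res$found <- !is.na(res$.present)
  res$.present <- NULL
  res[, c(kf, vf, "found")]
}

# -1/0/1 per row of df against a single key tuple `bound`
tuple_cmp <- function(df, bound, fields) {
  cmp <- integer(nrow(df))
  for (f in fields) {
    und <- cmp == 0L
    if (!any(und)) break
    x <- df[[f]][und]
    b <- bound[[f]]
    cmp[und][x < b] <- -1L
    cmp[und][x > b] <- 1L
  }
  cmp
}

#' @rdname oracle_store
#' @param k_start,k_end Named lists (or one-row data frames) of key values;
#'   closed range.
#' @param predicate Optional `function(tbl)` returning a logical filter.
#' @export
oracle_range <- function(oracle, k_start, k_end, predicate = NULL) {
  s <- oracle$schema
  kf <- key_fields(s)
  view <- oracle_view(oracle)
  lo <- one_key(k_start); hi <- one_key(k_end)
  keep <- tuple_cmp(view, lo, kf) >= 0L & tuple_cmp(view, hi, kf) <= 0L
  out <- view[keep, , drop = FALSE]
  if (!is.null(predicate)) out <- out[predicate(out), , drop = FALSE]
  out
}

#' @rdname oracle_store
#' @export
oracle_scan <- function(oracle) oracle_view(oracle)
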