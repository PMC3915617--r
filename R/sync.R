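#' Update rules for key collisions
#'
#' When a key arriving from memory collides with a key already stored on disk
#' (or appears twice inside one buffer), the store resolves it with a
#' state-dependent update rule:
#'
#' * `replace` -- the newest value wins (the default),
#' * `keep_first` -- the stored value wins,
#' * `reduce` -- an associative `reducer(old, new)` combines the two values.
#'
#' The reducer operates on raw value bytes: it receives two raw matrices of
#' dimension `value_size x n` (old and new values of the n colliding keys, in
#' key order) and must return a raw matrix of identical dimension. Returning
#' anything else aborts the synchronisation with the disk bucket untouched.
#' See [value_reducer()] for a decoded-space convenience wrapper.
#'
#' @param name `"replace"`, `"keep_first"` or `"reduce"`.
#' @param reducer Required for `"reduce"`: `function(old, new)` on raw value
#'   matrices as described above.
#' @return An `rs_update_rule`.
#' @export
#' @examples
#' update_rule("replace")
update_rule <- function(name = c("replace", "keep_first", "reduce"),
                        reducer = NULL) {
  name <- match.arg(name)
  if (name == "reduce" && !is.function(reducer))
    abort("the 'reduce' rule needs a reducer function", class = "rangestore_schema_error")
  structure(list(name = name,
                 code = match(name, c("replace", "keep_first", "reduce")),
                 reducer = reducer),
            class = "rs_update_rule")
}

#' Build a byte-level reducer from a decoded-space function
#'
#' Wraps `f(old, new)` -- which receives two tibbles of decoded value fields
#' and must return one of the same shape -- into the raw-bytes reducer that
#' [update_rule()] expects. Handy for rules like "keep the smaller E-value".
#'
#' @param schema The record schema.
#' @param f `function(old, new)` on tibbles of value fields.
#' @return A reducer suitable for `update_rule("reduce", reducer = ...)`.
#' @export
#' @examples
#' s <- herv_schema()
#' min_e <- value_reducer(s, function(old, new)
#'   dplyr::tibble(evalue = pmin(old$evalue, new$evalue)))
value_reducer <- function(schema, f) {
  vf <- value_fields(schema)
  vw <- schema$widths[schema$fields$role == "value"]
  vk <- schema$kinds[schema$fields$role == "value"]
  vs <- value_size(schema)
  force(f)
  function(old, new) {
    dec <- function(m) {
      out <- cxx_decode(as.raw(m), vw, vk)
      names(out) <- vf
      as_tibble(out)
    }
    res <- f(dec(old), dec(new))
    matrix(cxx_encode(field_columns_values(schema, res, vf), vw, vk, vf), nrow = vs)
  }
}

# like field_columns() but against value fields only
field_columns_values <- function(schema, values, wanted) {
  field_columns(schema, values, wanted)
}

# ---- duplicate resolution inside one sorted block ---------------------------

# `recs` sorted by key (possibly duplicate keys, in insertion order thanks to
# the stable sort). Collapses each duplicate-key group per the rule and
# returns a strictly sorted, key-unique block.
resolve_duplicates <- function(schema, recs, rule) {
  rs <- schema$record_size
  ks <- schema$key_size
  n <- block_count(schema, recs)
  if (n <= 1L) return(recs)
  gid <- cxx_dup_groups(recs, rs, ks)
  if (gid[n] == n) return(recs) # already unique
  if (rule$name == "replace") {
    keep <- which(!duplicated(gid, fromLast = TRUE))
    return(cxx_gather(recs, rs, as.integer(keep)))
  }
  first <- which(!duplicated(gid))
  if (rule$name == "keep_first")
    return(cxx_gather(recs, rs, as.integer(first)))
  # reduce: fold values left-to-right within each group
  out <- cxx_gather(recs, rs, as.integer(first))
  sizes <- tabulate(gid)
  vs <- value_size(schema)
  for (pass in 2:max(sizes)) {
    g <- which(sizes >= pass)            # group ids with a `pass`-th member
    if (!length(g)) break
    src_rows <- first[g] + (pass - 1L)   # rows in `recs`
    old <- value_bytes(schema, out, g)
    new <- value_bytes(schema, recs, src_rows)
    red <- apply_reducer(rule, old, new, vs)
    out <- patch_values(schema, out, g, red)
  }
  out
}

value_bytes <- function(schema, recs, rows) {
  rs <- schema$record_size
  ks <- schema$key_size
  pos <- outer((ks + 1):rs, (rows - 1L) * rs, `+`)
  matrix(recs[pos], nrow = rs - ks)
}

patch_values <- function(schema, recs, rows, values) {
  rs <- schema$record_size
  ks <- schema$key_size
  pos <- outer((ks + 1):rs, (rows - 1L) * rs, `+`)
  recs[pos] <- as.raw(values)
  recs
}

apply_reducer <- function(rule, old, new, vs) {
  red <- rule$reducer(old, new)
  if (!is.raw(red) || !identical(dim(red), dim(old)))
    abort(sprintf("integrity error: reducer must return a raw %d x %d matrix",
                  vs, ncol(old)),
          class = c("rangestore_integrity_error", "rangestore_bucket_error"))
  red
}

# ---- streaming merge of a sorted run with a disk bucket ---------------------

#' Merge a sorted in-memory run into a disk bucket
#'
#' The mergesort at the heart of synchronisation. Both inputs are strictly
#' key-sorted and key-unique; the output bucket holds the key union, with
#' collisions resolved by the update rule. The merge is chunk-wise: at any
#' moment at most one disk chunk and one run slice (plus at most one pending
#' output chunk) are resident, so peak memory is O(chunk_size * record_size)
#' regardless of bucket size. The new file replaces the old one atomically;
#' any failure (including a misbehaving reducer) leaves the old bucket
#' untouched.
#'
#' @param path Bucket file path (may not exist yet).
#' @param schema The record schema.
#' @param run Encoded records (raw), strictly key-sorted and key-unique.
#' @param chunk_size Records per chunk for the output file.
#' @param rule An [update_rule()].
#' @param stats Optional environment; if given, `max_disk_blocks`,
#'   `max_run_blocks` and `iterations` are recorded (merge instrumentation).
#' @param mid_hook Optional zero-argument function called once mid-merge
#'   (test hook emulating inserts arriving while a sync is in flight).
#' @return Invisibly, a list with `path`, `record_count`,
#'   `index_entry_count`.
#' @export
merge_runs <- function(path, schema, run, chunk_size = 4096L,
                       rule = update_rule("replace"),
                       stats = NULL, mid_hook = NULL) {
  rs <- schema$record_size
  ks <- schema$key_size
  if (length(run) && cxx_check_sorted(run, rs, ks) != 0L)
    abort("integrity error: run must be strictly sorted and key-unique",
          class = c("rangestore_integrity_error", "rangestore_bucket_error"))

  disk <- if (file.exists(path)) open_bucket(path, schema) else NULL
  on.exit(if (!is.null(disk)) close_bucket(disk), add = TRUE)
  out_tmp_path <- paste0(path, ".merge")
  w <- bf_writer_open(out_tmp_path, schema, chunk_size)

  run_n <- block_count(schema, run)
  ri <- 1L          # next unread run record
  di <- 1L          # next unread disk chunk
  n_disk_chunks <- if (is.null(disk)) 0L else disk$n_chunks
  a_rem <- raw(0)   # disk-side pending records
  b_rem <- raw(0)   # run-side pending records
  hook_fired <- is.null(mid_hook)
  iter <- 0L

  res <- tryCatch({
    repeat {
      if (length(a_rem) == 0L && di <= n_disk_chunks) {
        a_rem <- read_chunk(disk, di)
        di <- di + 1L
      }
      if (length(b_rem) == 0L && ri <= run_n) {
        hi <- min(ri + chunk_size - 1L, run_n)
        b_rem <- block_slice(schema, run, ri, hi)
        ri <- hi + 1L
      }
      na <- block_count(schema, a_rem)
      nb <- block_count(schema, b_rem)
      if (!is.null(stats)) {
        iter <- iter + 1L
        stats$max_disk_blocks <- max(stats$max_disk_blocks %||% 0L,
                                     ceiling(na / chunk_size))
        stats$max_run_blocks <- max(stats$max_run_blocks %||% 0L,
                                    ceiling(nb / chunk_size))
        stats$iterations <- iter
      }
      if (na == 0L && nb == 0L) break
      if (na == 0L || nb == 0L) {
        take_a <- na; take_b <- nb
      } else {
        a_last <- block_keys(schema, block_slice(schema, a_rem, na, na))
        b_last <- block_keys(schema, block_slice(schema, b_rem, nb, nb))
        # cut both sides at the smaller of the two last keys so that the
        # remainders can still collide with records yet to be read
        cut <- if (cxx_compare_keys(a_last, b_last) <= 0) a_last else b_last
        take_a <- cxx_upper_bound(a_rem, rs, ks, cut) - 1L
        take_b <- cxx_upper_bound(b_rem, rs, ks, cut) - 1L
      }
      m <- cxx_merge(block_slice(schema, a_rem, 1L, take_a),
                     block_slice(schema, b_rem, 1L, take_b),
                     rs, ks, rule$code)
      merged <- m$records
      if (rule$name == "reduce" && length(m$out_pos)) {
        old <- value_bytes(schema, a_rem, m$a_pos)
        new <- value_bytes(schema, b_rem, m$b_pos)
        red <- apply_reducer(rule, old, new, value_size(schema))
        merged <- patch_values(schema, merged, m$out_pos, red)
      }
      bf_writer_add(w, merged)
      a_rem <- block_slice(schema, a_rem, take_a + 1L, na)
      b_rem <- block_slice(schema, b_rem, take_b + 1L, nb)
      if (!hook_fired) { hook_fired <- TRUE; mid_hook() }
    }
    if (!is.null(disk)) close_bucket(disk)
    bf_writer_finish(w)
  }, error = function(e) {
    bf_writer_discard(w)
    unlink(out_tmp_path)
    stop(e)
  })
  if (!file.rename(out_tmp_path, path))
    bucket_io_abort(sprintf("I/O error: cannot replace bucket at %s", path),
                    "rangestore_io_error")
  invisible(list(path = path, record_count = res$record_count,
                 index_entry_count = res$index_entry_count))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
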