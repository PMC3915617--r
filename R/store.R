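# A store is a directory:
#   store.meta      JSON: format version, schema, bucket boundaries (hex),
#                   chunk_size, sync thresholds, update rule name
#   bucket_%04d.db  one bucket file per non-empty key range
#   names.tsv       optional name -> id dictionary written by importers
#
# The handle is an environment: buffers (the in-memory buckets), cached read
# handles, counters, and the configuration. Writes are buffered per bucket and
# synchronised to disk by mergesort when a bucket reaches its fill level or
# age, when buffered memory exceeds the global cap, or on store_flush().
# Queries see flushed (on-disk) data only; call store_flush() for
# read-your-writes.

STORE_META_VERSION <- 1L

#' Create a new record store
#'
#' @param path Directory to create the store in (must not already hold one).
#' @param schema The [record_schema()] of the records, or `"snp"` / `"herv"`
#'   for the built-ins.
#' @param n_buckets Number of key-range buckets (default 16).
#' @param chunk_size Records per chunk in bucket files (default 4096; the
#'   optimum is hardware- and record-size-dependent, so it is a per-store
#'   knob recorded in the metadata).
#' @param bucket_fill_level Buffered records in one bucket that trigger a
#'   synchronisation (default 100000).
#' @param bucket_max_age_s Age in seconds after which a non-empty buffer
#'   qualifies for synchronisation (default 60).
#' @param global_buffer_bytes Cap on total buffered bytes across buckets;
#'   exceeding it forces syncs of the largest buffers (default 256 MiB).
#' @param update_rule An [update_rule()] resolving key collisions
#'   (default `replace`).
#' @param max_parallel_syncs Recorded configuration surface for deployments
#'   that run synchronisations concurrently; this implementation runs syncs
#'   inline and deterministically.
#' @return An open `rs_store` handle.
#' @export
#' @examples
#' st <- store_create(tempfile(), "snp", n_buckets = 4)
#' store_close(st)
store_create <- function(path, schema,
                         n_buckets = 16L,
                         chunk_size = 4096L,
                         bucket_fill_level = 100000L,
                         bucket_max_age_s = 60,
                         global_buffer_bytes = 256 * 1024^2,
                         update_rule = rangestore::update_rule("replace"),
                         max_parallel_syncs = 2L) {
  if (is.character(schema)) schema <- builtin_schema(schema)
  meta_path <- file.path(path, "store.meta")
  if (file.exists(meta_path))
    abort(sprintf("a store already exists at %s", path),
          class = "rangestore_state_error")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  map <- default_bucket_map(schema, n_buckets)
  meta <- list(meta_version = STORE_META_VERSION,
               schema = jsonlite::fromJSON(schema_to_json(schema),
                                           simplifyVector = FALSE),
               boundaries_hex = map_to_hex(map),
               chunk_size = as.integer(chunk_size),
               bucket_fill_level = as.integer(bucket_fill_level),
               bucket_max_age_s = bucket_max_age_s,
               global_buffer_bytes = global_buffer_bytes,
               update_rule = update_rule$name,
               max_parallel_syncs = as.integer(max_parallel_syncs))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), meta_path)
  new_store(path, schema, map, meta, update_rule)
}

#' Open an existing store
#'
#' @param path Store directory.
#' @param reducer Reducer function, required when the store was created with
#'   the `reduce` update rule (functions are not serialisable).
#' @return An open `rs_store` handle.
#' @export
store_open <- function(path, reducer = NULL) {
  meta_path <- file.path(path, "store.meta")
  if (!file.exists(meta_path))
    abort(sprintf("no store at %s", path), class = "rangestore_state_error")
  meta <- jsonlite::fromJSON(readLines(meta_path), simplifyVector = TRUE)
  f <- as_tibble(meta$schema$fields)
  schema <- record_schema(meta$schema$name, f)
  map <- map_from_hex(schema, meta$boundaries_hex)
  rule <- update_rule(meta$update_rule, reducer = reducer)
  new_store(path, schema, map, meta, rule)
}

new_store <- function(path, schema, map, meta, rule) {
  env <- new.env(parent = emptyenv())
  env$path <- path
  env$schema <- schema
  env$map <- map
  env$chunk_size <- as.integer(meta$chunk_size)
  env$fill_level <- as.integer(meta$bucket_fill_level)
  env$max_age_s <- meta$bucket_max_age_s
  env$buffer_cap <- meta$global_buffer_bytes
  env$rule <- rule
  env$buffers <- lapply(seq_len(map$n_buckets), function(i)
    list(blocks = list(), n = 0L, bytes = 0, created_at = NULL))
  env$handles <- vector("list", map$n_buckets)
  env$counters <- list(inserted = 0, collapsed = 0, syncs = 0)
  env$closed <- FALSE
  env$verbose <- FALSE
  env$merge_stats <- NULL   # optional instrumentation environment
  env$test_mid_hook <- NULL # one-shot hook fired inside the next merge
  class(env) <- "rs_store"
  env
}

#' @export
print.rs_store <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<rs_store %s>  schema '%s', %d bucket(s), %s record(s) on disk, %s buffered\n",
              x$path, x$schema$name, x$map$n_buckets,
              format(g$disk_records, big.mark = ","),
              format(g$buffered_records, big.mark = ",")))
  invisible(x)
}

check_open <- function(store) {
  if (store$closed)
    abort("store is closed", class = "rangestore_state_error")
  invisible(store)
}

bucket_file_path <- function(store, id) {
  file.path(store$path, sprintf("bucket_%04d.db", id))
}

get_handle <- function(store, id) {
  h <- store$handles[[id]]
  if (!is.null(h) && !is.null(h$con)) return(h)
  p <- bucket_file_path(store, id)
  if (!file.exists(p)) return(NULL)
  h <- open_bucket(p, store$schema)
  store$handles[[id]] <- h
  h
}

drop_handle <- function(store, id) {
  h <- store$handles[[id]]
  if (!is.null(h)) close_bucket(h)
  store$handles[id] <- list(NULL)
}

#' Insert records into a store
#'
#' Records are encoded, routed to their memory buckets by the range-partition
#' map, and buffered. A bucket reaching the configured fill level or age, or
#' total buffered memory exceeding the global cap, triggers an inline
#' synchronisation (mergesort of the sorted, deduplicated buffer with the disk
#' bucket). Inserted records become visible to queries after the next
#' synchronisation of their bucket; [store_flush()] forces one.
#'
#' @param store An open `rs_store`.
#' @param values A data frame with one column per schema field (extra columns
#'   ignored). Duplicate keys are allowed; they are resolved by the store's
#'   update rule.
#' @return The store, invisibly (pipe-friendly).
#' @export
store_insert <- function(store, values) {
  check_open(store)
  n <- nrow(values) %||% length(values[[1]])
  if (is.null(n) || n == 0L) return(invisible(store))
  recs <- encode_records(store$schema, values)
  ids <- route_block(store$map, store$schema, recs)
  rs <- store$schema$record_size
  now <- Sys.time()
  for (chunk in split(seq_along(ids), ids)) {
    id <- ids[chunk[1]]
    block <- cxx_gather(recs, rs, as.integer(chunk))
    buf <- store$buffers[[id]]
    buf$blocks[[length(buf$blocks) + 1L]] <- block
    buf$n <- buf$n + length(chunk)
    buf$bytes <- buf$bytes + length(block)
    if (is.null(buf$created_at)) buf$created_at <- now
    store$buffers[[id]] <- buf
  }
  store$counters$inserted <- store$counters$inserted + n
  maybe_sync(store)
  invisible(store)
}

buffered_bytes <- function(store) sum(vapply(store$buffers, `[[`, 0, "bytes"))
buffered_counts <- function(store) vapply(store$buffers, `[[`, 0L, "n")

#' Pick the next bucket to synchronise
#'
#' Among buffers meeting the fill-level or age condition, returns the one with
#' the most buffered records (ties broken by lowest bucket id), or
#' `NA_integer_` when none qualifies.
#'
#' @param store An open `rs_store`.
#' @return A bucket id or `NA_integer_`.
#' @export
select_bucket_for_sync <- function(store) {
  pick_sync_bucket(store, force = FALSE)
}

pick_sync_bucket <- function(store, force) {
  counts <- buffered_counts(store)
  if (force) {
    elig <- counts > 0L
  } else {
    ages <- vapply(store$buffers, function(b) {
      if (is.null(b$created_at)) -Inf
      else as.numeric(difftime(Sys.time(), b$created_at, units = "secs"))
    }, 0)
    elig <- counts >= store$fill_level | (counts > 0L & ages >= store$max_age_s)
  }
  if (!any(elig)) return(NA_integer_)
  cand <- which(elig)
  cand[which.max(counts[cand])] # which.max takes the first (lowest id) on ties
}

maybe_sync <- function(store) {
  repeat {
    force <- buffered_bytes(store) > store$buffer_cap
    id <- pick_sync_bucket(store, force = force)
    if (is.na(id)) break
    sync_bucket(store, id)
  }
  invisible(store)
}

#' Take a bucket's buffer as a sorted, deduplicated run
#'
#' Phase 1 and 2 of the synchronisation: the buffer is replaced by a fresh
#' empty one (so buffering continues while the merge runs), then its records
#' are stably sorted by key and intra-buffer duplicate keys are collapsed by
#' the store's update rule.
#'
#' @param store An open `rs_store`.
#' @param bucket_id Bucket id (1-based).
#' @return Encoded records (raw), strictly key-sorted and key-unique.
#' @export
swap_out <- function(store, bucket_id) {
  check_open(store)
  buf <- store$buffers[[bucket_id]]
  store$buffers[[bucket_id]] <- list(blocks = list(), n = 0L, bytes = 0,
                                     created_at = NULL)
  if (buf$n == 0L) return(raw(0))
  recs <- do.call(c, buf$blocks)
  rs <- store$schema$record_size
  ord <- cxx_key_order(recs, rs, store$schema$key_size)
  sorted <- cxx_gather(recs, rs, ord)
  run <- resolve_duplicates(store$schema, sorted, store$rule)
  store$counters$collapsed <- store$counters$collapsed +
    (buf$n - block_count(store$schema, run))
  run
}

sync_bucket <- function(store, bucket_id) {
  run <- swap_out(store, bucket_id)
  if (length(run) == 0L) return(invisible(store))
  drop_handle(store, bucket_id)
  hook <- store$test_mid_hook
  store$test_mid_hook <- NULL
  t0 <- Sys.time()
  before <- {
    p <- bucket_file_path(store, bucket_id)
    if (file.exists(p)) file.size(p) else 0
  }
  res <- merge_runs(bucket_file_path(store, bucket_id), store$schema, run,
                    chunk_size = store$chunk_size, rule = store$rule,
                    stats = store$merge_stats, mid_hook = hook)
  store$counters$syncs <- store$counters$syncs + 1
  if (isTRUE(store$verbose))
    message(sprintf("sync bucket=%d run=%d disk_bytes_before=%.0f out=%d secs=%.3f",
                    bucket_id, block_count(store$schema, run), before,
                    res$record_count,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(store)
}

#' Synchronise every buffered bucket to disk
#'
#' Deterministic flush: after it returns, all prior inserts are persistent and
#' visible to queries. Idempotent.
#'
#' @param store An open `rs_store`.
#' @return The store, invisibly.
#' @export
store_flush <- function(store) {
  check_open(store)
  for (id in which(buffered_counts(store) > 0L))
    sync_bucket(store, id)
  invisible(store)
}

#' Close a store handle
#'
#' @param store An `rs_store`.
#' @param flush Synchronise buffered records first (default `TRUE`; with
#'   `FALSE`, un-flushed buffers are discarded, mirroring the design's
#'   crash-durability contract).
#' @return `NULL`, invisibly.
#' @export
store_close <- function(store, flush = TRUE) {
  if (store$closed) return(invisible(NULL))
  if (flush) store_flush(store)
  for (id in seq_along(store$handles)) drop_handle(store, id)
  store$closed <- TRUE
  invisible(NULL)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-bucket summary of a store
#'
#' @param x An `rs_store`.
#' @param ... Unused.
#' @return A tibble with one row per bucket: buffered and on-disk record
#'   counts, chunk count, index entries and file size.
#' @export
tidy.rs_store <- function(x, ...) {
  check_open(x)
  rows <- lapply(seq_len(x$map$n_buckets), function(id) {
    p <- bucket_file_path(x, id)
    if (file.exists(p)) {
      h <- get_handle(x, id)
      tibble(bucket_id = id, buffered = x$buffers[[id]]$n,
             disk_records = h$record_count, chunks = h$n_chunks,
             index_entries = h$n_chunks, file_bytes = file.size(p))
    } else {
      tibble(bucket_id = id, buffered = x$buffers[[id]]$n,
             disk_records = 0, chunks = 0L, index_entries = 0L, file_bytes = 0)
    }
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a store
#'
#' @param x An `rs_store`.
#' @param ... Unused.
#' @return A one-row tibble: schema name, sizes, bucket and record counts and
#'   insert/sync counters.
#' @export
glance.rs_store <- function(x, ...) {
  td <- tidy(x)
  tibble(schema = x$schema$name,
         record_size = x$schema$record_size,
         key_size = x$schema$key_size,
         n_buckets = x$map$n_buckets,
         chunk_size = x$chunk_size,
         disk_records = sum(td$disk_records),
         buffered_records = sum(td$buffered),
         inserted = x$counters$inserted,
         duplicates_collapsed = x$counters$collapsed,
         syncs = x$counters$syncs)
}

#' Audit a whole store
#'
#' Runs the bucket-file audit ([verify_bucket()]) on every bucket and checks
#' that bucket key ranges do not overlap (the last key of bucket i is below
#' the first key of bucket i+1).
#'
#' @param store An open `rs_store`.
#' @return A tibble of checks with columns `bucket_id`, `check`, `pass`.
#' @export
store_verify <- function(store) {
  check_open(store)
  out <- list()
  prev_last <- NULL
  for (id in seq_len(store$map$n_buckets)) {
    p <- bucket_file_path(store, id)
    if (!file.exists(p)) next
    v <- verify_bucket(p, store$schema)
    v$bucket_id <- id
    h <- get_handle(store, id)
    cross <- TRUE
    if (h$record_count > 0) {
      first <- h$index_keys[seq_len(store$schema$key_size)]
      if (!is.null(prev_last) && cxx_compare_keys(prev_last, first) >= 0)
        cross <- FALSE
      lastc <- read_chunk(h, h$n_chunks)
      n <- block_count(store$schema, lastc)
      prev_last <- block_keys(store$schema,
                              block_slice(store$schema, lastc, n, n))
    }
    out[[length(out) + 1L]] <- dplyr::bind_rows(
      v, tibble(check = "bucket_ranges_disjoint", pass = cross, bucket_id = id))
  }
  if (!length(out))
    return(tibble(bucket_id = integer(), check = character(), pass = logical()))
  dplyr::bind_rows(out)[, c("bucket_id", "check", "pass")]
}
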