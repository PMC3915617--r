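# Seeded synthetic record generators. These emulate the shapes of the two
# motivating data sets -- per-accession SNP tables of a ~250-accession plant
# resequencing panel, and BLAST hits of ~7000 retroviral fragments against a
# 24-chromosome genome -- with configurable record counts, key distributions,
# duplicate-key rates and E-value ranges, so every other module is testable
# without downloads.

#' Generate synthetic SNP records
#'
#' Keys (accession, chromosome, position) are drawn uniformly over the
#' configured space; the reference base is uniform over A/C/G/T and the
#' mutated base uniform over the remaining three. With probability `dup_rate`
#' a row re-emits the key of a uniformly chosen earlier row with fresh values,
#' exercising the update rule.
#'
#' @param n Number of rows.
#' @param seed Integer seed; the stream is deterministic given the seed.
#' @param n_accessions Number of accessions (ids 0 .. n_accessions-1;
#'   default 251).
#' @param n_chromosomes Chromosomes 1..n_chromosomes (default 5).
#' @param max_pos Largest 1-based position (default 3e7).
#' @param dup_rate Probability that a row (after the first) duplicates an
#'   earlier key (default 0).
#' @return A tibble with columns `accession`, `chromosome`, `position`,
#'   `ref`, `alt`.
#' @export
#' @examples
#' gen_snps(5, seed = 1)
gen_snps <- function(n, seed, n_accessions = 251L, n_chromosomes = 5L,
                     max_pos = 3e7, dup_rate = 0) {
  stopifnot(n >= 0)
  if (n == 0L) return(empty_records(snp_schema())[, 1:5])
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    acc <- sample.int(n_accessions, n, replace = TRUE) - 1
    chrom <- sample.int(n_chromosomes, n, replace = TRUE)
    pos <- ceiling(stats::runif(n) * max_pos)
    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_off <- sample.int(3L, n, replace = TRUE)
    alt_i <- ((ref_i - 1L + alt_off) %% 4L) + 1L
    keys <- duplicate_keys(n, dup_rate, list(acc = acc, chrom = chrom, pos = pos))
  })
  # numeric (double) columns throughout, matching what decode_records() yields
  tibble(accession = as.numeric(keys$acc), chromosome = as.numeric(keys$chrom),
         position = as.numeric(keys$pos),
         ref = bases[ref_i], alt = bases[alt_i])
}

#' Generate synthetic HERV-hit records
#'
#' Hit intervals are uniform over the configured chromosome space with lengths
#' up to `herv_len_max`; fragment-local coordinates stay within the 2-byte key
#' widths; E-values are log-uniform over `10^evalue_log10_range`, snapped to
#' the nearest float32 (the stored precision). Duplicate keys as in
#' [gen_snps()].
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param n_chromosomes Chromosomes 1..n_chromosomes (default 24).
#' @param max_pos Largest chromosome position (default 2.5e8).
#' @param n_hervs Fragment ids 1..n_hervs (default 7000).
#' @param herv_len_max Largest hit length in fragment coordinates
#'   (default 10000).
#' @param dup_rate Duplicate-key probability (default 0).
#' @param evalue_log10_range Two numbers: log10 bounds of the E-value
#'   distribution (default `c(-60, -20)`, bracketing the usual acceptance and
#'   filtering thresholds).
#' @return A tibble with columns `chromosome`, `chrom_start`, `chrom_end`,
#'   `herv_start`, `herv_end`, `herv_id`, `strand`, `evalue`.
#' @export
#' @examples
#' gen_herv(5, seed = 1)
gen_herv <- function(n, seed, n_chromosomes = 24L, max_pos = 2.5e8,
                     n_hervs = 7000L, herv_len_max = 10000L, dup_rate = 0,
                     evalue_log10_range = c(-60, -20)) {
  stopifnot(n >= 0, herv_len_max <= 60000)
  if (n == 0L) return(empty_records(herv_schema()))
  withr::with_seed(seed, {
    chrom <- sample.int(n_chromosomes, n, replace = TRUE)
    len <- sample.int(herv_len_max, n, replace = TRUE)
    cstart <- ceiling(stats::runif(n) * (max_pos - herv_len_max))
    cend <- cstart + len
    hstart <- sample.int(65535L - herv_len_max, n, replace = TRUE)
    hend <- hstart + len
    hid <- sample.int(n_hervs, n, replace = TRUE)
    strand <- sample(0:1, n, replace = TRUE)
    ev <- float32_round(10^stats::runif(n, evalue_log10_range[1],
                                        evalue_log10_range[2]))
    keys <- duplicate_keys(n, dup_rate,
                           list(chrom = chrom, cstart = cstart, cend = cend,
                                hstart = hstart, hend = hend, hid = hid,
                                strand = strand))
  })
  tibble(chromosome = as.numeric(keys$chrom),
         chrom_start = as.numeric(keys$cstart),
         chrom_end = as.numeric(keys$cend),
         herv_start = as.numeric(keys$hstart),
         herv_end = as.numeric(keys$hend),
         herv_id = as.numeric(keys$hid),
         strand = as.numeric(keys$strand),
         evalue = ev)
}

# Re-point a `dup_rate` fraction of rows (2..n) at the *final* key of a
# uniformly chosen earlier row. Chains (a duplicate of a duplicate) are
# resolved by pointer jumping so every flagged row really repeats an earlier
# emitted key.
duplicate_keys <- function(n, dup_rate, cols) {
  if (dup_rate <= 0 || n < 2L) return(cols)
  dup <- c(FALSE, stats::runif(n - 1) < dup_rate)
  src <- c(1L, ceiling(stats::runif(n - 1) * (seq_len(n - 1))))
  root <- seq_len(n)
  root[dup] <- src[dup]
  while (any(dup[root])) {
    sel <- which(dup[root])
    root[sel] <- src[root[sel]]
  }
  lapply(cols, function(x) { x[dup] <- x[root[dup]]; x })
}

# Snap to the nearest IEEE-754 float32 (the precision at which float32 value
# fields are stored).
float32_round <- function(x) {
  cxx_decode(cxx_encode(list(x = as.numeric(x)), 4L, 2L, "x"), 4L, 2L)[[1]]
}
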