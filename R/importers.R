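# Importers for the two tab-separated source formats. The binary schemas
# store compact integer ids while the files carry names ("acc1", "Chr1",
# "herv_17"), so importers intern names into a dictionary that can be
# persisted next to the store (names.tsv) and reused across files.

#' Name -> id dictionaries
#'
#' A dictionary is a tibble with columns `kind`, `name`, `id`. `intern_names()`
#' maps a vector of names of one kind to dense integer ids, appending new
#' names; accession ids start at 0, other kinds at 1. Chromosome tokens are
#' normalised ("Chr1", "chr1" and "1" intern to the same entry) but never
#' parsed numerically, so "X" works too.
#'
#' @param dict A dictionary tibble, or `NULL` for a fresh one.
#' @return `name_dict()`: an empty dictionary. `intern_names()`: a list with
#'   `ids` (integer vector) and `dict` (the updated dictionary).
#' @export
name_dict <- function() {
  tibble(kind = character(0), name = character(0), id = integer(0))
}

#' @rdname name_dict
#' @param kind Dictionary namespace: `"accession"`, `"chromosome"`, ...
#' @param names Character vector of names to intern.
#' @export
intern_names <- function(dict, kind, names) {
  if (is.null(dict)) dict <- name_dict()
  if (kind == "chromosome")
    names <- sub("^[Cc]hr", "", names)
  have <- dict[dict$kind == kind, , drop = FALSE]
  new <- setdiff(unique(names), have$name)
  if (length(new)) {
    base <- if (kind == "accession") 0L else 1L
    start <- if (nrow(have)) max(have$id) + 1L else base
    dict <- dplyr::bind_rows(dict, tibble(kind = kind, name = new,
                                          id = seq(start, by = 1L,
                                                   length.out = length(new))))
    have <- dict[dict$kind == kind, , drop = FALSE]
  }
  list(ids = have$id[match(names, have$name)], dict = dict)
}

#' @rdname name_dict
#' @param store An open `rs_store` (the dictionary lives in `names.tsv` inside
#'   the store directory).
#' @export
write_name_dict <- function(store, dict) {
  readr::write_tsv(dict, file.path(store$path, "names.tsv"))
  invisible(dict)
}

#' @rdname name_dict
#' @export
read_name_dict <- function(store) {
  p <- file.path(store$path, "names.tsv")
  if (!file.exists(p)) return(name_dict())
  readr::read_tsv(p, col_types = readr::cols(kind = "c", name = "c", id = "i"),
                  progress = FALSE)
}

import_abort_or_skip <- function(bad, lines, what, strict) {
  if (!any(bad)) return(invisible(0L))
  if (strict)
    abort(sprintf("%s on line(s) %s", what,
                  paste(utils::head(lines[bad], 5L), collapse = ", ")),
          class = "rangestore_import_error")
  length(which(bad))
}

#' Import a tab-separated SNP table
#'
#' Expects tab-separated lines with five columns -- accession name,
#' chromosome, 1-based position, reference nucleotide, mutated nucleotide --
#' in the order given by `col_order`; lines starting with `#` are skipped.
#' Accession and chromosome names are interned to dense integer ids.
#' Nucleotides are uppercase-normalised and must be one of A/C/G/T/N.
#'
#' @param path File path.
#' @param col_order Column-name permutation mapping file columns to
#'   `c("accession", "chromosome", "position", "ref", "alt")`.
#' @param dict A name dictionary to extend, or `NULL`.
#' @param strict If `TRUE` (default) malformed lines abort with their line
#'   numbers; otherwise they are skipped and counted in the `n_skipped`
#'   attribute.
#' @return A tibble of SNP rows (columns as [gen_snps()]), with attributes
#'   `dict` (the updated dictionary) and `n_skipped`.
#' @export
parse_snp_tsv <- function(path,
                          col_order = c("accession", "chromosome", "position",
                                        "ref", "alt"),
                          dict = NULL, strict = TRUE) {
  stopifnot(setequal(col_order, c("accession", "chromosome", "position",
                                  "ref", "alt")))
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  n_skipped <- 0L
  if (!length(lines)) {
    out <- gen_snps(0, 1)
    attr(out, "dict") <- dict %||% name_dict()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_arity <- lengths(parts) < length(col_order)
  n_skipped <- n_skipped + import_abort_or_skip(bad_arity, lineno,
                                                "too few columns", strict)
  parts <- parts[!bad_arity]; lineno <- lineno[!bad_arity]
  m <- do.call(rbind, parts)
  col <- function(f) m[, match(f, col_order)]
  pos <- suppressWarnings(as.numeric(col("position")))
  ref <- toupper(col("ref"))
  alt <- toupper(col("alt"))
  bad <- is.na(pos) | pos < 1 | pos != floor(pos) |
    !ref %in% c("A", "C", "G", "T", "N") | !alt %in% c("A", "C", "G", "T", "N")
  n_skipped <- n_skipped + import_abort_or_skip(bad, lineno,
                                                "bad position or nucleotide",
                                                strict)
  ok <- !bad
  acc <- intern_names(dict, "accession", col("accession")[ok])
  chr <- intern_names(acc$dict, "chromosome", col("chromosome")[ok])
  out <- tibble(accession = acc$ids, chromosome = chr$ids,
                position = pos[ok], ref = ref[ok], alt = alt[ok])
  attr(out, "dict") <- chr$dict
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Import BLAST tabular hits as HERV records
#'
#' Expects tab-separated columns query id, subject id, query start, query end,
#' subject start, subject end, E-value (`#` comment lines skipped). The query
#' is the retroviral fragment, the subject the genome: subject ids intern as
#' chromosomes, query ids as fragment ids. A hit whose subject coordinates are
#' reversed is a minus-strand hit: coordinates are normalised to ascending and
#' `strand` set to 1. Only hits with E-value strictly below `evalue_cutoff`
#' are kept.
#'
#' @param path File path.
#' @param evalue_cutoff Keep hits with `evalue < evalue_cutoff`
#'   (default 1e-20, the usual acceptance threshold for putative fragment
#'   hits).
#' @param dict,strict As in [parse_snp_tsv()].
#' @return A tibble of HERV rows (columns as [gen_herv()]), with attributes
#'   `dict`, `n_skipped` and `n_filtered` (hits dropped by the cutoff).
#' @export
parse_blast_tab <- function(path, evalue_cutoff = 1e-20, dict = NULL,
                            strict = TRUE) {
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]; lineno <- lineno[keep]
  n_skipped <- 0L
  if (!length(lines)) {
    out <- gen_herv(0, 1)
    attr(out, "dict") <- dict %||% name_dict()
    attr(out, "n_skipped") <- 0L
    attr(out, "n_filtered") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_arity <- lengths(parts) < 7L
  n_skipped <- n_skipped + import_abort_or_skip(bad_arity, lineno,
                                                "too few columns", strict)
  parts <- parts[!bad_arity]; lineno <- lineno[!bad_arity]
  m <- do.call(rbind, parts)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  qs <- num(3); qe <- num(4); ss <- num(5); se <- num(6); ev <- num(7)
  bad <- is.na(qs) | is.na(qe) | is.na(ss) | is.na(se) | is.na(ev) |
    qs < 1 | qe < 1 | ss < 1 | se < 1 | ev < 0
  n_skipped <- n_skipped + import_abort_or_skip(bad, lineno,
                                                "bad coordinates or E-value",
                                                strict)
  ok <- !bad
  qs <- qs[ok]; qe <- qe[ok]; ss <- ss[ok]; se <- se[ok]; ev <- ev[ok]
  strand <- as.integer(ss > se)
  cstart <- pmin(ss, se); cend <- pmax(ss, se)
  hstart <- pmin(qs, qe); hend <- pmax(qs, qe)
  pass <- ev < evalue_cutoff
  hid <- intern_names(dict, "herv", m[ok, 1][pass])
  chr <- intern_names(hid$dict, "chromosome", m[ok, 2][pass])
  out <- tibble(chromosome = chr$ids, chrom_start = cstart[pass],
                chrom_end = cend[pass], herv_start = hstart[pass],
                herv_end = hend[pass], herv_id = hid$ids,
                strand = strand[pass], evalue = float32_round(ev[pass]))
  attr(out, "dict") <- chr$dict
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_filtered") <- sum(!pass)
  out
}

#' Import SNPs from a (plain-text) VCF
#'
#' Convenience importer reading CHROM/POS/REF/ALT of an uncompressed VCF into
#' SNP rows for a single accession. Multi-base or multi-allelic records are
#' skipped (full VCF semantics are out of scope).
#'
#' @param path Path to an uncompressed VCF.
#' @param accession Accession name the calls belong to.
#' @param dict A name dictionary to extend, or `NULL`.
#' @return A tibble of SNP rows with attributes `dict` and `n_skipped`.
#' @export
read_vcf_snps <- function(path, accession, dict = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    out <- gen_snps(0, 1)
    attr(out, "dict") <- dict %||% name_dict()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) p[1:5]))
  pos <- suppressWarnings(as.numeric(m[, 2]))
  ref <- toupper(m[, 4]); alt <- toupper(m[, 5])
  ok <- !is.na(pos) & ref %in% c("A", "C", "G", "T", "N") &
    alt %in% c("A", "C", "G", "T", "N")
  acc <- intern_names(dict, "accession", rep(accession, sum(ok)))
  chr <- intern_names(acc$dict, "chromosome", m[ok, 1])
  out <- tibble(accession = acc$ids, chromosome = chr$ids, position = pos[ok],
                ref = ref[ok], alt = alt[ok])
  attr(out, "dict") <- chr$dict
  attr(out, "n_skipped") <- length(lines) - sum(ok)
  out
}

#' Insert imported rows and persist their name dictionary
#'
#' @param store An open `rs_store`.
#' @param rows A tibble from one of the importers (its `dict` attribute, if
#'   present, is merged into the store's `names.tsv`).
#' @return The store, invisibly.
#' @export
store_import <- function(store, rows) {
  check_open(store)
  d <- attr(rows, "dict")
  if (!is.null(d)) {
    existing <- read_name_dict(store)
    merged <- dplyr::distinct(dplyr::bind_rows(existing, d))
    write_name_dict(store, merged)
  }
  store_insert(store, rows)
}
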