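#' Read a GWAS summary-association table
#'
#' Reads a tab-separated table of per-variant summary associations for a
#' single trait.  The expected dialect is tab-separated with a `.` decimal
#' separator and `NA` for missing values.  Required columns are
#' `snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`; `pval` and `n` are optional.
#'
#' Effect sizes are per copy of the effect allele: in trait standard
#' deviation units for a quantitative exposure, on the log-odds scale for
#' a binary outcome.
#'
#' @param path Path to the TSV file.
#' @param trait_label Character label attached to every record.
#' @return A `data.frame` with one row per variant and columns
#'   `snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`, `trait`.
#' @seealso [write_gwas_table()], [harmonize()], [select_region()]
#' @examples
#' path <- system.file("extdata", "fabp4_scallop_instruments.tsv",
#'                     package = "epimr")
#' exposure <- read_gwas_table(path, trait_label = "FABP-4")
#' @export
read_gwas_table <- function(path, trait_label) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE,
                           na.strings = "NA",
                           check.names = FALSE)
  required <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c("pval", "n")
  for (col in setdiff(optional, names(raw))) {
    raw[[col]] <- rep(NA_character_, nrow(raw))
  }
  raw <- raw[, c(required, optional)]

  out <- data.frame(snp = raw$snp,
                    chr = raw$chr,
                    effect_allele = toupper(raw$effect_allele),
                    other_allele = toupper(raw$other_allele),
                    stringsAsFactors = FALSE)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable numeric in field '%s' at row %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[[col]] <- num
  }
  out <- out[, c("snp", "chr", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")]
  out$trait <- rep(trait_label, nrow(out))
  validate_gwas_table(out)
  out
}

validate_gwas_table <- function(tab) {
  if (nrow(tab) == 0L) return(invisible(tab))
  check <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0L) {
      stop(sprintf("invalid record (%s) at row %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check(!is.na(tab$snp) & nzchar(tab$snp), "missing variant id")
  check(!is.na(tab$pos) & tab$pos >= 1, "position must be >= 1")
  check(!is.na(tab$eaf) & tab$eaf >= 0 & tab$eaf <= 1,
        "effect-allele frequency outside [0, 1]")
  check(!is.na(tab$se) & tab$se > 0, "standard error must be positive")
  check(!is.na(tab$beta), "missing beta")
  check(tab$effect_allele != tab$other_allele,
        "effect and other allele identical")
  invisible(tab)
}

#' Write a GWAS summary-association table
#'
#' Inverse of [read_gwas_table()]: writes the declared tab-separated
#' dialect (`.` decimals, `NA` for missing) such that reading the file
#' back reproduces the records.
#'
#' @param tab A table as returned by [read_gwas_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(tab, path) {
  cols <- c("snp", "chr", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pval", "n")
  out <- tab[, cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Subset summary associations to a genomic window
#'
#' Retains records whose position lies within `window` base pairs of
#' `center` (closed interval, 1-based positions), optionally restricted
#' to one chromosome.  Used for the gene-region scans of cis-MR
#' (+/- 100 kb) and colocalization (+/- 50 kb around the lead variant).
#'
#' @param assocs GWAS table as returned by [read_gwas_table()].
#' @param center Center position in base pairs.
#' @param window Half-width of the window in base pairs (>= 0).
#' @param chromosome Optional chromosome label; when supplied, only
#'   records on that chromosome are considered.
#' @return The subset of `assocs` inside the window.
#' @export
select_region <- function(assocs, center, window, chromosome = NULL) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(window), length(window) == 1L)
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  keep <- abs(assocs$pos - center) <= window
  if (!is.null(chromosome)) {
    keep <- keep & assocs$chr == as.character(chromosome)
  }
  assocs[which(keep), , drop = FALSE]
}
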