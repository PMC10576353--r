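COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

allele_complement <- function(a) {
  out <- COMPLEMENT[a]
  out[is.na(out)] <- NA_character_
  unname(out)
}

is_palindromic <- function(ea, oa) {
  !is.na(allele_complement(ea)) & allele_complement(ea) == oa
}

#' Construct an instrument set
#'
#' Bundles allele-aligned exposure/outcome instrument records with an
#' optional instrument correlation matrix (signed genotype correlations,
#' unit diagonal), as required by [mr_ivw_correlated()].
#'
#' @param instruments `data.frame` with columns `snp`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf_exposure`,
#'   `flipped`.
#' @param correlation Optional square numeric matrix of pairwise
#'   instrument correlations, symmetric positive definite with unit
#'   diagonal and dimension equal to the instrument count.
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(instruments, correlation = NULL) {
  needed <- c("snp", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome", "eaf_exposure", "flipped")
  missing_cols <- setdiff(needed, names(instruments))
  if (length(missing_cols) > 0L) {
    stop("instruments table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    k <- nrow(instruments)
    if (nrow(correlation) != k || ncol(correlation) != k) {
      stop("correlation matrix dimension does not match instrument count",
           call. = FALSE)
    }
    if (max(abs(correlation - t(correlation))) > 1e-8) {
      stop("correlation matrix is not symmetric", call. = FALSE)
    }
    if (max(abs(diag(correlation) - 1)) > 1e-8) {
      stop("correlation matrix diagonal must be 1", call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("correlation matrix is not positive definite", call. = FALSE)
    }
  }
  structure(list(instruments = instruments, correlation = correlation),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s)%s\n",
              nrow(x$instruments),
              if (is.null(x$correlation)) "" else
                " with correlation matrix"))
  print(x$instruments, row.names = FALSE)
  invisible(x)
}

#' Harmonize exposure and outcome summary associations
#'
#' Aligns the outcome associations to the exposure's effect allele so
#' that every estimator sees effects of the same allele on both traits.
#' Variants present in only one trait are dropped.  When the outcome
#' lists the alleles swapped relative to the exposure (directly or on
#' the complementary strand), the outcome beta is sign-flipped and its
#' allele frequency complemented.  Variants with incompatible alleles
#' are dropped and recorded.
#'
#' Palindromic variants (A/T or G/C) cannot be resolved by strand
#' matching.  Under the default `"drop"` policy an ambiguous palindromic
#' variant — minor-allele frequency above `ambiguity_threshold` — is
#' excluded; otherwise (and always under `"eaf_infer"`) the orientation
#' is inferred by comparing allele frequencies between the two traits.
#'
#' @param exposure,outcome GWAS tables as returned by
#'   [read_gwas_table()].
#' @param palindrome_policy `"drop"` (default) or `"eaf_infer"`.
#' @param ambiguity_threshold Minor-allele-frequency cut-off above which
#'   a palindromic variant is considered ambiguous under the `"drop"`
#'   policy (default 0.42).
#' @return An [instrument_set()] whose `instruments` carry the aligned
#'   coefficients; the attribute `"dropped"` records excluded variants
#'   and the reason for each.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "eaf_infer"),
                      ambiguity_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) {
    stop("no overlapping variants between exposure and outcome",
         call. = FALSE)
  }
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  flipped <- logical(length(shared))
  keep <- rep(TRUE, length(shared))
  reason <- character(length(shared))

  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (is_palindromic(ea_x, oa_x)) {
      maf <- min(ex$eaf[i], 1 - ex$eaf[i])
      ambiguous <- !is.na(maf) && maf > ambiguity_threshold
      if (palindrome_policy == "drop" && ambiguous) {
        keep[i] <- FALSE
        reason[i] <- "palindromic with ambiguous allele frequency"
        next
      }
      # orient by allele frequency: frequencies on matching alleles
      # should fall on the same side of 0.5
      same_side <- (ex$eaf[i] < 0.5) == (ou$eaf[i] < 0.5)
      flipped[i] <- !same_side
    } else if (ea_y == ea_x && oa_y == oa_x) {
      flipped[i] <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flipped[i] <- TRUE
    } else if (identical(allele_complement(ea_y), ea_x) &&
               identical(allele_complement(oa_y), oa_x)) {
      flipped[i] <- FALSE
    } else if (identical(allele_complement(ea_y), oa_x) &&
               identical(allele_complement(oa_y), ea_x)) {
      flipped[i] <- TRUE
    } else {
      keep[i] <- FALSE
      reason[i] <- "incompatible alleles"
    }
  }

  instruments <- data.frame(
    snp = shared,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    beta_outcome = ifelse(flipped, -ou$beta, ou$beta),
    se_outcome = ou$se,
    eaf_exposure = ex$eaf,
    flipped = flipped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(instruments) <- NULL
  if (nrow(instruments) == 0L) {
    stop("no variants remain after harmonization", call. = FALSE)
  }

  dropped <- data.frame(snp = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  set <- instrument_set(instruments)
  attr(set, "dropped") <- dropped
  set
}

#' Express a harmonized instrument set as per-trait GWAS tables
#'
#' Rebuilds minimal exposure/outcome association tables from an
#' [instrument_set()], both expressed on the exposure's effect allele.
#' Useful to verify that harmonization is idempotent.
#'
#' @param set An [instrument_set()].
#' @param exposure Original exposure table supplying alleles/positions.
#' @return A list with components `exposure` and `outcome`.
#' @export
as_gwas_tables <- function(set, exposure) {
  ins <- set$instruments
  ex <- exposure[match(ins$snp, exposure$snp), ]
  outcome <- ex
  outcome$beta <- ins$beta_outcome
  outcome$se <- ins$se_outcome
  outcome$eaf <- ins$eaf_exposure
  outcome$trait <- "outcome"
  exposure2 <- ex
  exposure2$beta <- ins$beta_exposure
  exposure2$se <- ins$se_exposure
  list(exposure = exposure2, outcome = outcome)
}
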