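#' Packaged FABP-4 instrument summary statistics
#'
#' The three published genome-wide significant FABP-4 instruments
#' (one cis variant near *FABP4*, two trans variants near *PPARG* and
#' *CRB2*) with their per-allele associations on circulating FABP-4
#' (SD units, discovery GWAS n = 20,436) and on colorectal cancer
#' (log-odds, 58,131 cases / 67,347 controls), shipped as two TSV
#' files under `extdata` and returned here as a harmonized
#' [instrument_set()] (or as the raw per-trait tables).
#'
#' The published coefficients are printed at two-decimal precision;
#' estimates computed from them therefore carry that rounding, which
#' matters when comparing against results derived from the unrounded
#' source data.
#'
#' @param harmonized If `FALSE`, return a list with the raw `exposure`
#'   and `outcome` tables instead of an [instrument_set()].
#' @return An [instrument_set()] of the three instruments, or the raw
#'   tables.
#' @examples
#' set <- fabp4_instruments()
#' mr_ivw(set)
#' @export
fabp4_instruments <- function(harmonized = TRUE) {
  exposure <- read_gwas_table(
    system.file("extdata", "fabp4_scallop_instruments.tsv",
                package = "epimr", mustWork = TRUE),
    trait_label = "FABP-4 (SD units)")
  outcome <- read_gwas_table(
    system.file("extdata", "fabp4_crc_outcome.tsv",
                package = "epimr", mustWork = TRUE),
    trait_label = "colorectal cancer (log-odds)")
  if (!harmonized) {
    return(list(exposure = exposure, outcome = outcome))
  }
  harmonize(exposure, outcome)
}
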