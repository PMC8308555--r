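#' Load the packaged five-variant homocysteine instrument set
#'
#' Returns the packaged exposure (KARE log-homocysteine GWAS) and outcome
#' (merged HEXA+CAVAS metabolic-syndrome logistic) summary statistics for
#' the five instruments rs12567136, rs1801133, rs2336377, rs1624230 and
#' rs1836883. Outcome log-odds and SEs are reconstructed from the
#' published OR and 95% CI via [or_to_beta()] (flagged in the `derived`
#' column); effect-allele frequencies are approximate public-database
#' annotations, used only for palindromic screening.
#'
#' @return A list with `exposure` and `outcome` summary-statistics
#'   tibbles.
#' @examples
#' fx <- hcy_instruments()
#' harmonize(fx$exposure, fx$outcome)
#' @export
hcy_instruments <- function() {
  expo <- readr::read_tsv(
    system.file("extdata", "hcy_exposure_kare.tsv", package = "hcymr"),
    show_col_types = FALSE)
  out_raw <- readr::read_tsv(
    system.file("extdata", "mets_outcome_hexa_cavas.tsv",
                package = "hcymr"),
    show_col_types = FALSE)
  derived <- or_to_beta(out_raw$or, out_raw$ci_low, out_raw$ci_high)
  outcome <- dplyr::bind_cols(out_raw, derived) |>
    dplyr::mutate(derived = "beta,se from published OR and 95% CI") |>
    dplyr::select("snp_id", "effect_allele", "other_allele", "eaf",
                  "beta", "se", "p", "n", "trait", "or", "ci_low",
                  "ci_high", "derived")
  list(exposure = expo, outcome = outcome)
}
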