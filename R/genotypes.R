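#' Genotype dosage tables
#'
#' A `geno_tbl` is a tibble with a `sample_id` column and one column per
#' variant holding effect-allele dosages in \{0, 1, 2, NA\}. Variant
#' metadata (id, chromosome, 1-based position, effect allele, other allele)
#' travels as the `"variants"` attribute so the table itself stays tidy and
#' pipe-friendly.
#'
#' @param dosage Numeric matrix, samples x variants, values 0/1/2/NA.
#' @param variants Tibble with columns `snp_id`, `effect_allele`,
#'   `other_allele` and optionally `chr`, `pos`, `freq`.
#' @param sample_ids Optional character vector; defaults to `"S1"..."Sn"`.
#' @return A `geno_tbl` tibble.
#' @examples
#' g <- geno_tbl(matrix(c(0, 1, 2, 1), 2), tibble::tibble(
#'   snp_id = c("rs1", "rs2"), effect_allele = c("A", "T"),
#'   other_allele = c("G", "C")))
#' geno_variants(g)
#' @export
geno_tbl <- function(dosage, variants, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  variants <- as_tibble(variants)
  assert_cols(variants, c("snp_id", "effect_allele", "other_allele"),
              "variants")
  if (anyDuplicated(variants$snp_id)) {
    abort("variant ids must be unique", class = "hcymr_validation_error")
  }
  if (ncol(dosage) != nrow(variants)) {
    abort("dosage columns must match variant rows",
          class = "hcymr_validation_error")
  }
  if (any(variants$effect_allele == variants$other_allele)) {
    abort("effect allele must differ from other allele",
          class = "hcymr_validation_error")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) {
    abort("dosages must be 0, 1, 2 or NA", class = "hcymr_validation_error")
  }
  sample_ids <- sample_ids %||% paste0("S", seq_len(nrow(dosage)))
  out <- as_tibble(dosage, .name_repair = "minimal")
  names(out) <- variants$snp_id
  out <- dplyr::bind_cols(tibble(sample_id = sample_ids), out)
  new_geno_tbl(out, variants)
}

new_geno_tbl <- function(tbl, variants) {
  structure(tbl, variants = as_tibble(variants),
            class = c("geno_tbl", class(tibble())))
}

#' @rdname geno_tbl
#' @param g A `geno_tbl`.
#' @export
geno_variants <- function(g) {
  v <- attr(g, "variants", exact = TRUE)
  if (is.null(v)) abort("not a geno_tbl: no variant metadata")
  v
}

#' @rdname geno_tbl
#' @export
geno_dosage <- function(g) {
  v <- geno_variants(g)
  m <- as.matrix(as.data.frame(g)[, v$snp_id, drop = FALSE])
  rownames(m) <- g$sample_id
  m
}

# keep only the given variants, preserving metadata
geno_subset <- function(g, keep) {
  v <- geno_variants(g)
  v <- v[v$snp_id %in% keep, , drop = FALSE]
  tbl <- as_tibble(as.data.frame(g)[, c("sample_id", v$snp_id), drop = FALSE])
  new_geno_tbl(tbl, v)
}

#' @export
print.geno_tbl <- function(x, ...) {
  v <- attr(x, "variants", exact = TRUE)
  cat(sprintf("<geno_tbl: %d samples x %d variants>\n",
              nrow(x), if (is.null(v)) ncol(x) - 1L else nrow(v)))
  NextMethod()
}

# per-variant mean imputation of missing dosages
impute_dosage <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2L]]
  m
}

#' Read and write genotype, phenotype and summary-statistic tables
#'
#' Tables are tab-separated with a header row; missing dosages are written
#' as `NA`. Genotypes are stored as two files: the dosage table
#' (`sample_id` + one column per variant) and a variant metadata sidecar.
#' Summary-statistics files must carry the mandatory columns
#' `snp_id, effect_allele, other_allele, beta, se, p, n, trait`.
#'
#' @param g A `geno_tbl`.
#' @param path Output/input path for the dosage table.
#' @param variants_path Path of the variant metadata sidecar
#'   (default `paste0(path, ".variants.tsv")`).
#' @return `read_genotypes()` returns a `geno_tbl`; `read_sumstats()` and
#'   `read_phenotypes()` return tibbles; writers return the input invisibly.
#' @export
write_genotypes <- function(g, path,
                            variants_path = paste0(path, ".variants.tsv")) {
  readr::write_tsv(as_tibble(as.data.frame(g)), path, na = "NA")
  readr::write_tsv(geno_variants(g), variants_path, na = "NA")
  invisible(g)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path,
                           variants_path = paste0(path, ".variants.tsv")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  v <- readr::read_tsv(variants_path, show_col_types = FALSE)
  geno_tbl(as.matrix(tbl[, setdiff(names(tbl), "sample_id")]), v,
           sample_ids = as.character(tbl$sample_id))
}

#' @rdname write_genotypes
#' @param x A tibble to write.
#' @export
write_phenotypes <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(x)
}

#' @rdname write_genotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

.sumstats_cols <- c("snp_id", "effect_allele", "other_allele",
                    "beta", "se", "p", "n", "trait")

#' @rdname write_genotypes
#' @export
write_sumstats <- function(x, path) {
  assert_cols(x, .sumstats_cols, "sumstats")
  readr::write_tsv(x, path, na = "NA")
  invisible(x)
}

#' @rdname write_genotypes
#' @export
read_sumstats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(x, .sumstats_cols, basename(path))
  x
}
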