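test_that("HWE test matches the closed-form chi-square exhaustively and at the anchors", {
  # perfect HWE triple: statistic exactly 0
  expect_equal(as.numeric(hwe_test(c(25, 50, 25))), 1.0)
  # complete heterozygote deficit at n = 100: statistic = n
  p_deficit <- as.numeric(hwe_test(c(50, 0, 50)))
  expect_equal(p_deficit, pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(p_deficit, 1e-6)
  # monomorphic: defined as 1 and flagged
  mono <- hwe_test(c(0, 0, 10))
  expect_equal(as.numeric(mono), 1.0)
  expect_true(attr(mono, "monomorphic"))
  expect_error(hwe_test(c(0, 0, 0)), class = "hcymr_validation_error")

  # exhaustive: all polymorphic triples with total <= 50 equal the
  # closed form computed independently here
  grid <- expand.grid(n_aa = 0:50, n_ab = 0:50, n_bb = 0:50)
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 50, ]
  tot <- rowSums(grid)
  f <- (2 * grid$n_bb + grid$n_ab) / (2 * tot)
  poly <- f > 0 & f < 1
  grid <- grid[poly, ]
  tot <- tot[poly]
  f <- f[poly]
  expected_p <- pchisq(
    (grid$n_aa - tot * (1 - f)^2)^2 / (tot * (1 - f)^2) +
      (grid$n_ab - tot * 2 * f * (1 - f))^2 / (tot * 2 * f * (1 - f)) +
      (grid$n_bb - tot * f^2)^2 / (tot * f^2),
    df = 1, lower.tail = FALSE)
  got_p <- vapply(seq_len(nrow(grid)), function(i) {
    as.numeric(hwe_test(as.numeric(grid[i, ])))
  }, numeric(1))
  expect_equal(got_p, unname(expected_p), tolerance = 1e-12)

  # exact mid-p option: sane range, tiny under gross deviation
  expect_lt(hwe_test(c(50, 0, 50), method = "exact"), 1e-6)
  p_ex <- hwe_test(c(30, 48, 22), method = "exact")
  expect_true(p_ex > 0 && p_ex <= 1)
})

test_that("QC filter removes planted violations in the documented order and is idempotent", {
  n <- 1000
  withr::with_seed(5, {
    good <- rbinom(n, 2, 0.4)
    missingy <- rbinom(n, 2, 0.4)
    missingy[sample(n, 25)] <- NA            # 2.5% missing
    mono <- rep(0, n)                        # monomorphic
    hwe_bad <- sample(rep(c(0, 2), n / 2))   # no heterozygotes
  })
  g <- geno_tbl(cbind(good, missingy, mono, hwe_bad),
                tibble::tibble(snp_id = c("good", "missingy", "mono",
                                          "hwe_bad"),
                               effect_allele = "A", other_allele = "G"))
  res <- qc_filter(g, max_missing = 0.01, hwe_alpha = 1e-6)
  expect_equal(res$report$retained, "good")
  expect_equal(res$report$n_removed_missingness, 1L)
  expect_equal(res$report$n_removed_monomorphic, 1L)
  expect_equal(res$report$n_removed_hwe, 1L)
  expect_equal(
    res$report$removed$reason[match(c("missingy", "mono", "hwe_bad"),
                                    res$report$removed$snp_id)],
    c("missingness", "monomorphic", "hwe"))

  # idempotence: filtering the filtered matrix removes nothing
  res2 <- qc_filter(res$genotypes)
  expect_equal(res2$report$n_input, 1L)
  expect_equal(length(res2$report$retained), 1L)
  expect_equal(res2$report$n_removed_missingness +
                 res2$report$n_removed_monomorphic +
                 res2$report$n_removed_hwe, 0L)

  # all removed -> explicit error
  g_bad <- geno_tbl(cbind(mono), tibble::tibble(
    snp_id = "mono", effect_allele = "A", other_allele = "G"))
  expect_error(qc_filter(g_bad), class = "hcymr_empty_error")

  # a perfect-HWE variant (counts 25/50/25) is retained
  g_hwe <- geno_tbl(cbind(rep(c(0, 1, 1, 2), 25)), tibble::tibble(
    snp_id = "perfect", effect_allele = "A", other_allele = "G"))
  expect_equal(qc_filter(g_hwe)$report$retained, "perfect")
})

test_that("linear association scan: exact fit, allele-recoding invariance, ML agreement", {
  withr::with_seed(21, {
    d <- rbinom(200, 2, 0.4)
    g <- geno_tbl(cbind(d), tibble::tibble(
      snp_id = "s1", effect_allele = "A", other_allele = "G"))
    # perfect fit: beta exactly 2, se ~ 0
    res <- linear_assoc(g, 2 * d)
    expect_equal(res$beta, 2, tolerance = 1e-10)
    expect_lt(res$se, 1e-10)

    # recoding the effect allele flips beta, |z| unchanged
    y <- 0.3 * d + rnorm(200)
    g_flip <- geno_tbl(cbind(2 - d), tibble::tibble(
      snp_id = "s1", effect_allele = "G", other_allele = "A"))
    r1 <- linear_assoc(g, y)
    r2 <- linear_assoc(g_flip, y)
    expect_equal(r2$beta, -r1$beta, tolerance = 1e-10)
    expect_equal(abs(r2$beta / r2$se), abs(r1$beta / r1$se),
                 tolerance = 1e-10)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)

    # rank-deficient covariates are refused with the column named
    covs <- data.frame(a = rnorm(200))
    covs$b <- 2 * covs$a
    expect_error(linear_assoc(g, y, covariates = covs), "collinear")
  })
})

test_that("null calibration: permuted dosage rarely reaches |z| > 4", {
  withr::with_seed(31, {
    n <- 1000
    d <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    g_of <- function(dd) geno_tbl(cbind(dd), tibble::tibble(
      snp_id = "s1", effect_allele = "A", other_allele = "G"))
    z <- vapply(seq_len(1000), function(i) {
      r <- linear_assoc(g_of(sample(d)), y)
      r$beta / r$se
    }, numeric(1))
    expect_gte(sum(abs(z) < 4), 999)
  })
})

test_that("logistic association scan matches contingency-table and ML oracles", {
  # 2x2 collapse: carrier indicator with counts giving OR = 20*20/(10*10) = 4
  carrier <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  case <- c(rep(1, 30), rep(0, 30))
  g <- geno_tbl(cbind(carrier), tibble::tibble(
    snp_id = "s1", effect_allele = "A", other_allele = "G"))
  res <- logistic_assoc(g, case)
  expect_equal(exp(res$beta), 4.0, tolerance = 1e-6)

  # brute-force ML oracle agreement (n <= 200, k <= 3) to 6 significant digits
  withr::with_seed(41, {
    n <- 200
    d <- rbinom(n, 2, 0.35)
    cov1 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.4 * d + 0.3 * cov1))
    res <- logistic_assoc(geno_tbl(cbind(d), tibble::tibble(
      snp_id = "s1", effect_allele = "A", other_allele = "G")),
      y, covariates = data.frame(cov1 = cov1))
    x <- cbind(1, cov1, d)
    ml <- oracle_logistic_mle(x, y)
    expect_equal(res$beta, ml[3], tolerance = 1e-6)
  })

  # null: OR ~ 1 at large n
  withr::with_seed(43, {
    n <- 20000
    d <- rbinom(n, 2, 0.5)
    y <- rbinom(n, 1, 0.3)
    res <- logistic_assoc(geno_tbl(cbind(d), tibble::tibble(
      snp_id = "s1", effect_allele = "A", other_allele = "G")), y)
    expect_lt(abs(res$beta), 4 * res$se)
  })

  # per-allele log-OR recovered within 2 SE at n = 50000
  withr::with_seed(47, {
    n <- 50000
    d <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-0.5 - 0.052 * d))
    res <- logistic_assoc(geno_tbl(cbind(d), tibble::tibble(
      snp_id = "s1", effect_allele = "A", other_allele = "G")), y)
    expect_lt(abs(res$beta - (-0.052)), 2 * res$se)
  })

  # complete separation is refused with a diagnostic
  sep_d <- c(rep(0, 30), rep(2, 30))
  sep_y <- c(rep(0, 30), rep(1, 30))
  expect_error(logistic_assoc(geno_tbl(cbind(sep_d), tibble::tibble(
    snp_id = "s1", effect_allele = "A", other_allele = "G")), sep_y),
    class = "hcymr_separation_error")
})

test_that("observational ORs: affine equivariance, null coverage, generative recovery", {
  withr::with_seed(51, {
    n <- 4000
    x <- rnorm(n, 2.5, 0.3)
    mets <- rbinom(n, 1, 0.35)
    pheno <- tibble::tibble(log_hcy = x, mets = mets,
                            age = rnorm(n, 58, 9),
                            sex = sample(c("M", "F"), n, TRUE),
                            area = sample(c("u", "r"), n, TRUE))
    sets <- list(univariate = character(),
                 adjusted = c("age", "sex", "area"))
    r1 <- observational_or(pheno, sets)
    # null: both CIs cover 1 (probabilistic but overwhelmingly likely at z<3.9)
    expect_true(all(abs(r1$beta) < 3.9 * r1$se))

    # doubling the exposure scale halves the log-OR exactly
    pheno2 <- dplyr::mutate(pheno, log_hcy = 2 * log_hcy)
    r2 <- observational_or(pheno2, sets)
    expect_equal(r2$beta, r1$beta / 2, tolerance = 1e-8)

    # per-SD scale is exposed as an alternative unit convention
    r_sd <- observational_or(pheno, sets, scale = "sd")
    expect_equal(r_sd$beta[1], r1$beta[1] * sd(x), tolerance = 1e-8)
  })

  # generative OR 1.06 per unit exposure recovered within 2 SE
  withr::with_seed(53, {
    n <- 50000
    x <- rnorm(n, 19, 7)   # exposure on a wide unit scale
    y <- rbinom(n, 1, plogis(-1.6 + log(1.06) * x))
    r <- observational_or(tibble::tibble(log_hcy = x, mets = y),
                          list(univariate = character()))
    expect_lt(abs(r$beta - log(1.06)), 2 * r$se)
  })
})

test_that("quartile summaries: assignment, boundary p-values, shape", {
  # 4 distinct values -> one per quartile
  p4 <- tibble::tibble(log_hcy = c(1, 2, 3, 4), bmi = c(20, 21, 22, 23))
  qs <- quartile_summary(p4, variables = "bmi")
  expect_equal(qs$n, rep(1L, 4))

  withr::with_seed(61, {
    n <- 400
    pheno <- tibble::tibble(
      log_hcy = seq_len(n),                 # quartiles = blocks of 100
      bmi = rep(c(20, 25, 30, 35), n / 4),  # identical group means
      smoking = rbinom(n, 1, 0.2))
    qs <- quartile_summary(pheno)
    # identical group means: F = 0 puts the ANOVA p at its boundary of 1
    expect_equal(qs$anova_p[qs$variable == "bmi"][1], 1,
                 tolerance = 1e-9)
    # binary trait summarized with a chi-square p
    expect_true(all(is.finite(
      qs$chisq_p[qs$variable == "smoking"])))
    expect_equal(nrow(qs), 8L)  # 2 variables x 4 quartiles
  })
  expect_error(quartile_summary(tibble::tibble(log_hcy = rep(1, 10))),
               class = "hcymr_validation_error")
})
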