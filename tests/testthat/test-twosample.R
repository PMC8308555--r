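test_that("fixed-effect meta-analysis: closed forms, symmetry, allele alignment", {
  mk <- function(beta, se, ea = "A", oa = "G") tibble::tibble(
    snp_id = "s1", effect_allele = ea, other_allele = oa,
    beta = beta, se = se, n = 100)
  # two identical records: same beta, se / sqrt(2)
  m <- meta_fixed(list(mk(0.1, 0.2), mk(0.1, 0.2)))
  expect_equal(m$beta, 0.1)
  expect_equal(m$se, 0.2 / sqrt(2))
  # symmetric betas cancel
  m2 <- meta_fixed(list(mk(0.1, 0.15), mk(-0.1, 0.15)))
  expect_equal(m2$beta, 0)
  # swapped alleles are flipped before pooling
  m3 <- meta_fixed(list(mk(0.1, 0.15), mk(-0.1, 0.15, ea = "G", oa = "A")))
  expect_equal(m3$beta, 0.1)
  expect_error(meta_fixed(list(mk(0.1, 0.1), mk(0.1, 0.1, ea = "C",
                                                oa = "T"))),
               "allele mismatch")
  # random instances match the brute-force weighted mean
  withr::with_seed(101, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      betas <- rnorm(k)
      ses <- runif(k, 0.05, 0.5)
      records <- purrr::map2(betas, ses, mk)
      got <- meta_fixed(records)
      want <- oracle_meta_fixed(betas, ses)
      expect_equal(got$beta, want$beta, tolerance = 1e-12)
      expect_equal(got$se, want$se, tolerance = 1e-12)
    }
  })
  # pooled se never exceeds the best cohort; pooled beta between extremes
  m4 <- meta_fixed(list(mk(0.05, 0.1), mk(0.25, 0.3)))
  expect_lte(m4$se, 0.1)
  expect_true(m4$beta >= 0.05 && m4$beta <= 0.25)
})

test_that("IVW reduces to the Wald ratio at k = 1 and is exact on consistent ratios", {
  one <- tibble::tibble(beta_x = 0.12, se_x = 0.01,
                        beta_y = 0.08, se_y = 0.03)
  r <- ivw(one)
  w <- wald_ratio(0.12, 0.01, 0.08, 0.03)
  expect_equal(r$estimate, w$estimate, tolerance = 1e-12)
  expect_equal(r$se, 0.03 / 0.12, tolerance = 1e-12)

  # all ratios equal theta: estimate exactly theta, Q = 0
  consistent <- tibble::tibble(
    beta_x = c(0.05, 0.1, 0.2), se_x = 0.005,
    beta_y = 0.7 * c(0.05, 0.1, 0.2), se_y = c(0.02, 0.05, 0.04))
  rc <- ivw(consistent)
  expect_equal(rc$estimate, 0.7, tolerance = 1e-12)
  expect_equal(rc$Q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(consistent, 0.7)$p, 1)

  expect_error(ivw(consistent[0, ]), class = "hcymr_validation_error")
})

test_that("weighted median: interpolation rule, breakdown, range invariant", {
  # equal weights, ratios (0.1, 0.7, 2.0): midpoint CDF hits 0.5 at 0.7
  instr <- tibble::tibble(beta_x = c(0.1, 0.1, 0.1), se_x = 0.005,
                          beta_y = c(0.01, 0.07, 0.2), se_y = 0.05)
  wm <- weighted_median(instr, n_boot = 50, seed = 1)
  expect_equal(wm$estimate, 0.7, tolerance = 1e-12)

  # a SNP at the median position holding > 50% of weight forces its ratio
  heavy <- tibble::tibble(
    beta_x = c(0.1, 0.1, 0.1),
    se_x = 0.005,
    beta_y = c(0.02, 0.09, 0.3),
    se_y = c(0.05, 0.05 / sqrt(4), 0.05))  # middle weight 4x the others
  wmh <- weighted_median(heavy, n_boot = 50, seed = 1)
  expect_equal(wmh$estimate, 0.9, tolerance = 1e-12)

  # estimate always inside the ratio range; bootstrap reproducible
  withr::with_seed(103, {
    for (i in 1:25) {
      inst <- random_instruments(sample(3:10, 1), seed = 5000 + i)
      est <- weighted_median(inst, n_boot = 20, seed = 2)$estimate
      ratios <- inst$beta_y / inst$beta_x
      expect_gte(est, min(ratios))
      expect_lte(est, max(ratios))
      expect_equal(est, oracle_weighted_median(
        ratios, inst$beta_x^2 / inst$se_y^2), tolerance = 1e-12)
    }
  })
  b1 <- weighted_median(instr, n_boot = 100, seed = 7)
  b2 <- weighted_median(instr, n_boot = 100, seed = 7)
  expect_equal(b1$se, b2$se)
  expect_error(weighted_median(instr[1:2, ]),
               class = "hcymr_validation_error")
})

test_that("MR-Egger recovers exact affine structure and reports diagnostics", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  instr <- tibble::tibble(beta_x = bx, se_x = 0.005,
                          beta_y = 0.05 + 0.7 * bx,
                          se_y = c(0.02, 0.03, 0.025, 0.04))
  r <- mr_egger(instr)
  expect_equal(r$estimate, 0.7, tolerance = 1e-10)
  expect_equal(r$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(instr[1:2, ]), class = "hcymr_validation_error")
})

test_that("Cochran Q and I2GX match brute-force evaluation and their bounds", {
  withr::with_seed(107, {
    for (i in 1:25) {
      inst <- random_instruments(sample(3:12, 1), seed = 6000 + i)
      theta <- rnorm(1)
      got <- cochran_q(inst, theta)
      expect_equal(got$Q, oracle_cochran_q(
        inst$beta_x, inst$beta_y, inst$se_y, theta), tolerance = 1e-10)
      expect_gte(got$Q, 0)
      # permutation invariance
      perm <- inst[sample(nrow(inst)), ]
      expect_equal(cochran_q(perm, theta)$Q, got$Q, tolerance = 1e-12)

      i2 <- as.numeric(i2_gx(inst))
      expect_equal(i2, oracle_i2gx(inst$beta_x, inst$se_x),
                   tolerance = 1e-12)
      expect_gte(i2, 0)
      expect_lt(i2, 1)
    }
  })
  # identical exposure betas: Q_GX = 0 -> I2GX truncated to 0
  same <- tibble::tibble(beta_x = rep(0.1, 4), se_x = 0.01,
                         beta_y = rnorm(4), se_y = 0.05)
  expect_equal(as.numeric(i2_gx(same)), 0)
  # vanishing measurement error with distinct betas: I2GX -> 1
  tight <- tibble::tibble(beta_x = c(0.05, 0.1, 0.2), se_x = 1e-6,
                          beta_y = rnorm(3), se_y = 0.05)
  expect_gt(as.numeric(i2_gx(tight)), 0.999)
  zero <- tibble::tibble(beta_x = c(0.05, 0.1), se_x = 0,
                         beta_y = c(0, 0), se_y = 0.05)
  expect_equal(as.numeric(i2_gx(zero)), 1)
})

test_that("all estimators are invariant to allele recoding and instrument order", {
  inst <- random_instruments(8, seed = 109)
  flip <- withr::with_seed(110, sample(c(TRUE, FALSE), 8, TRUE))
  recoded <- inst
  recoded$beta_x[flip] <- -recoded$beta_x[flip]
  recoded$beta_y[flip] <- -recoded$beta_y[flip]
  recoded <- recoded[withr::with_seed(111, sample(8)), ]

  expect_equal(ivw(recoded)$estimate, ivw(inst)$estimate,
               tolerance = 1e-12)
  expect_equal(ivw(recoded)$se, ivw(inst)$se, tolerance = 1e-12)
  expect_equal(weighted_median(recoded, 10, 1)$estimate,
               weighted_median(inst, 10, 1)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(recoded)$estimate, mr_egger(inst)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(recoded)$egger_intercept,
               mr_egger(inst)$egger_intercept, tolerance = 1e-12)
  expect_equal(as.numeric(i2_gx(recoded)), as.numeric(i2_gx(inst)),
               tolerance = 1e-12)
})

test_that("run_twosample produces a full report and supports both pooling modes", {
  withr::with_seed(113, {
    k <- 6
    bx <- runif(k, 0.1, 0.2)
    expo <- tibble::tibble(
      snp_id = sprintf("s%d", 1:k), effect_allele = "A",
      other_allele = "G", beta = bx, se = 0.005, p = 1e-10, n = 5000,
      trait = "exposure")
    mk_cohort <- function(n) tibble::tibble(
      snp_id = expo$snp_id, effect_allele = "A", other_allele = "G",
      beta = rnorm(k, 0.7 * bx, 0.03), se = 0.03, p = 0.01, n = n,
      trait = "outcome")
    rep1 <- run_twosample(expo, list(mk_cohort(3000), mk_cohort(1800)),
                          n_boot = 100, seed = 3)
    expect_s3_class(rep1, "mr_report")
    expect_setequal(rep1$results$method,
                    c("weighted_median", "ivw_fixed", "mr_egger"))
    expect_true(all(is.finite(rep1$results$estimate)))
    expect_true(all(is.finite(c(rep1$Q$Q, rep1$i2_gx))))

    rep2 <- run_twosample(expo, list(mk_cohort(3000), mk_cohort(1800)),
                          n_boot = 100, seed = 3, mode = "pool_mr")
    expect_true(all(is.finite(rep2$results$estimate)))
    # both modes agree on the direction and rough size of the effect
    expect_lt(abs(rep1$results$estimate[2] - rep2$results$estimate[2]),
              0.3)

    g <- glance(rep1)
    expect_true(all(c("Q", "egger_intercept", "i2_gx") %in% names(g)))
    td <- tidy(rep1)
    expect_true("intercept" %in% td$term)
  })
})

test_that("directional pleiotropy biases IVW while the Egger intercept gains power", {
  k <- 25
  reps <- 60
  res <- vapply(seq_len(reps), function(r) {
    # strong all-positive direct outcome effects
    pleio <- seq(0.1, 0.2, length.out = k)
    inst <- draw_summary_instance(k, theta = 0, pleio = pleio,
                                  seed = 7000 + r)
    null_inst <- draw_summary_instance(k, theta = 0, seed = 8000 + r)
    c(ivw(inst)$estimate,
      mr_egger(inst)$intercept_p < 0.05,
      ivw(null_inst)$estimate)
  }, numeric(3))
  expect_gt(abs(mean(res[1, ])), 3 * abs(sd(res[1, ]) / sqrt(reps)))
  expect_gt(mean(res[2, ]), 0.5)        # intercept test power
  expect_lt(abs(mean(res[3, ])), 0.02)  # no pleiotropy: IVW unbiased
})

test_that("plots build from harmonized instruments", {
  inst <- random_instruments(6, seed = 115)
  p1 <- plot_mr_scatter(inst)
  p2 <- plot_mr_funnel(inst)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
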