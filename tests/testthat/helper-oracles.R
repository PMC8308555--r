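# Independent brute-force oracles for the MR estimators. These deliberately
# use different code paths (stats::lm with weights, stats::optim likelihood
# maximization, stats::approx interpolation, explicit loops) than the
# package implementations they check.

oracle_ivw <- function(bx, by, sy) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sy^2)
  est <- unname(coef(fit))
  se <- sqrt(1 / sum(bx^2 / sy^2))
  list(estimate = est, se = se)
}

oracle_egger <- function(bx, by, sy) {
  w <- 1 / sy^2
  flip <- bx < 0
  by[flip] <- -by[flip]
  bx[flip] <- -bx[flip]
  fit <- stats::lm(by ~ bx, weights = w)
  k <- length(bx)
  rss_w <- sum(w * resid(fit)^2)
  phi <- rss_w / (k - 2)
  xw <- cbind(1, bx) * sqrt(w)
  covm <- solve(t(xw) %*% xw) * phi
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       intercept_se = sqrt(covm[1, 1]), slope_se = sqrt(covm[2, 2]))
}

oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(x = s, y = r, xout = 0.5, ties = "ordered")$y
}

oracle_cochran_q <- function(bx, by, sy, theta) {
  q <- 0
  for (i in seq_along(bx)) {
    q <- q + (bx[i]^2 / sy[i]^2) * (by[i] / bx[i] - theta)^2
  }
  q
}

oracle_i2gx <- function(bx, sx) {
  bx <- abs(bx)
  bbar <- stats::weighted.mean(bx, 1 / sx^2)
  qgx <- sum((bx - bbar)^2 / sx^2)
  max(0, (qgx - (length(bx) - 1)) / qgx)
}

oracle_meta_fixed <- function(betas, ses) {
  w <- 1 / ses^2
  list(beta = stats::weighted.mean(betas, w), se = sqrt(1 / sum(w)))
}

# direct likelihood maximization (BFGS on the negative log-likelihood)
oracle_logistic_mle <- function(x, y) {
  nll <- function(b) {
    eta <- drop(x %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(rep(0, ncol(x)), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

oracle_nested_f <- function(y, iv, covs = NULL) {
  df <- if (is.null(covs)) data.frame(y = y) else data.frame(y = y, covs)
  df$iv_mat <- as.matrix(iv)
  base_form <- if (is.null(covs)) y ~ 1 else
    stats::as.formula(paste("y ~", paste(names(covs), collapse = "+")))
  base_fit <- stats::lm(base_form, data = df)
  full_fit <- stats::update(base_fit, . ~ . + iv_mat)
  stats::anova(base_fit, full_fit)$F[2]
}

# random harmonized-instrument instances for oracle-equivalence sweeps
random_instruments <- function(k, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      snp_id = sprintf("s%02d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      beta_x = stats::runif(k, 0.02, 0.2) *
        sample(c(-1, 1), k, replace = TRUE),
      se_x = stats::runif(k, 0.002, 0.02),
      beta_y = stats::rnorm(k, 0, 0.1),
      se_y = stats::runif(k, 0.01, 0.1)
    )
  })
}

# summary-level generative draw: k instruments, true effect theta,
# optional per-instrument direct (pleiotropic) outcome effects
draw_summary_instance <- function(k, theta, sx = 0.004, sy = 0.03,
                                  pleio = rep(0, k), seed = NULL) {
  draw <- function() {
    bx_true <- stats::runif(k, 0.1, 0.2)
    bx <- stats::rnorm(k, bx_true, sx)
    by <- stats::rnorm(k, theta * bx_true + pleio, sy)
    tibble::tibble(snp_id = sprintf("s%02d", seq_len(k)),
                   beta_x = bx, se_x = sx, beta_y = by, se_y = sy)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
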