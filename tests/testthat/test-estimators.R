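test_that("Wald ratios divide outcome by exposure effects with delta-method SE", {
  s <- hcy_pcos_instruments("finngen")
  wr <- wald_ratio(s)
  i <- which(wr$variant_id == "rs1801133")
  expect_equal(wr$estimate[i], 0.1196 / 0.1583, tolerance = 1e-10)
  expect_equal(wr$estimate[i], 0.7556, tolerance = 1e-4)
  expect_equal(wr$se[i], 0.0536 / 0.1583, tolerance = 1e-10)
  expect_equal(wr$se[i], 0.3386, tolerance = 1e-4)

  # null outcome effect and scale invariance
  s0 <- make_set(bx = c(0.1, 0.2, 0.1), by = c(0, 0.1, 0.05),
                 sy = c(0.03, 0.03, 0.03))
  expect_equal(wald_ratio(s0)$estimate[1], 0)
  s2 <- make_set(bx = 2 * c(0.1, 0.2, 0.1), by = 2 * c(0, 0.1, 0.05),
                 sy = c(0.03, 0.03, 0.03))
  expect_equal(wald_ratio(s2)$estimate, wald_ratio(s0)$estimate)

  # second-order SE adds the exposure-variance term
  wr2 <- wald_ratio(s, second_order = TRUE)
  expect_true(all(wr2$se > wr$se))
  expect_error(wald_ratio(make_set(bx = c(0, 0.1, 0.1), by = rep(0.1, 3),
                                   sy = rep(0.03, 3))), "zero exposure")
})

test_that("IVW is the inverse-variance-weighted mean of Wald ratios", {
  for (seed in 1:5) {
    s <- random_set(J = 10, seed = seed)
    wr <- wald_ratio(s)
    oracle <- sum(wr$weight * wr$estimate) / sum(wr$weight)
    expect_equal(mr_ivw(s, model = "fixed")$estimate, oracle)
    expect_equal(mr_ivw(s, model = "fixed")$se, 1 / sqrt(sum(wr$weight)))
    # the multiplicative random-effects model shares the point estimate
    expect_equal(mr_ivw(s, model = "multiplicative_random")$estimate, oracle)
  }
})

test_that("IVW degenerates to the Wald ratio for one instrument and the mean for equal weights", {
  one <- make_set(bx = 0.1, by = 0.05, sy = 0.02)
  est <- mr_ivw(one)
  wr <- wald_ratio(one)
  expect_equal(est$estimate, wr$estimate)
  expect_equal(est$se, wr$se)
  expect_equal(est$method, "wald")

  # equal weights: |bx| and sy identical, so IVW = arithmetic mean
  two <- make_set(bx = c(0.1, 0.1), by = c(0.02, 0.06), sy = c(0.03, 0.03))
  expect_equal(mr_ivw(two, model = "fixed")$estimate, mean(c(0.2, 0.6)))
  expect_error(mr_ivw(make_set(0.1, 0.1, 0.1)$instruments[0, ]), "empty")
})

test_that("MR-Egger matches an independent weighted-least-squares oracle", {
  for (seed in 1:5) {
    s <- random_set(J = 10, seed = seed + 10)
    d <- s$instruments
    flip <- ifelse(d$beta_exposure < 0, -1, 1)
    X <- cbind(1, d$beta_exposure * flip)
    y <- d$beta_outcome * flip
    W <- diag(1 / d$se_outcome^2)
    coefs <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)  # normal equations
    fit <- mr_egger(s)
    expect_equal(fit$intercept$estimate, coefs[1], tolerance = 1e-10)
    expect_equal(fit$slope$estimate, coefs[2], tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact linear relation and guards preconditions", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  s <- make_set(bx = bx, by = 0.7 * bx + 0.01, sy = rep(0.03, 4))
  fit <- mr_egger(s)
  expect_equal(fit$slope$estimate, 0.7, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, 0.01, tolerance = 1e-10)
  expect_error(mr_egger(make_set(bx = c(0.1, 0.2), by = c(0.1, 0.1),
                                 sy = c(0.03, 0.03))), ">= 3")
  expect_error(mr_egger(make_set(bx = rep(0.1, 4), by = rep(0.05, 4),
                                 sy = rep(0.03, 4))), "degenerate")
  # t reference gives larger p-values than the normal reference here
  expect_gte(mr_egger(s, p_reference = "t")$intercept$p_value,
             mr_egger(s)$intercept$p_value)
})

test_that("constraining the Egger intercept to zero reproduces the fixed-effect IVW slope", {
  for (study in hcy_pcos_studies()) {
    s <- hcy_pcos_instruments(study)
    d <- s$instruments
    flip <- ifelse(d$beta_exposure < 0, -1, 1)
    through_origin <- lm(I(d$beta_outcome * flip) ~ 0 + I(d$beta_exposure * flip),
                         weights = 1 / d$se_outcome^2)
    expect_equal(unname(coef(through_origin)),
                 mr_ivw(s, model = "fixed")$estimate, tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights, odd J: the middle order statistic
  s <- make_set(bx = rep(0.1, 5), by = c(0.05, 0.01, 0.03, 0.09, 0.07),
                sy = rep(0.03, 5))
  expect_equal(mr_weighted_median(s, n_boot = 100)$estimate,
               median(c(0.05, 0.01, 0.03, 0.09, 0.07) / 0.1))

  # loop-based scan over the cumulative-weight step function as oracle
  scan_median <- function(theta, w) {
    o <- order(theta)
    theta <- theta[o]; w <- w[o]
    s_std <- (cumsum(w) - w / 2) / sum(w)
    for (j in seq_len(length(theta) - 1)) {
      if (s_std[j] <= 0.5 && 0.5 <= s_std[j + 1]) {
        return(theta[j] + (theta[j + 1] - theta[j]) *
                 (0.5 - s_std[j]) / (s_std[j + 1] - s_std[j]))
      }
    }
    stop("0.5 not bracketed")
  }
  for (seed in 1:5) {
    st <- random_set(J = 7, seed = seed + 20)
    wr <- wald_ratio(st)
    expect_equal(mr_weighted_median(st, n_boot = 100)$estimate,
                 scan_median(wr$estimate, wr$weight))
  }
})

test_that("weighted median lies within the Wald-ratio range and ignores ordering", {
  s <- random_set(J = 9, seed = 99)
  wr <- wald_ratio(s)
  est <- mr_weighted_median(s, n_boot = 500)
  expect_gte(est$estimate, min(wr$estimate))
  expect_lte(est$estimate, max(wr$estimate))
  perm <- subset_instruments(s, sample(9))
  expect_equal(mr_weighted_median(perm, n_boot = 500)$estimate, est$estimate)
  expect_equal(mr_weighted_median(s, n_boot = 500)$se, est$se)  # seeded bootstrap
  expect_error(mr_weighted_median(s, n_boot = 0), "n_boot")
})

test_that("Cochran's Q matches term-by-term summation and grows with duplicates", {
  s <- hcy_pcos_instruments("day")
  wr <- wald_ratio(s)
  theta <- sum(wr$weight * wr$estimate) / sum(wr$weight)
  oracle <- 0
  for (j in seq_len(nrow(wr))) {
    oracle <- oracle + wr$weight[j] * (wr$estimate[j] - theta)^2
  }
  q <- cochran_q(s)
  expect_equal(q$q_statistic, oracle)
  expect_equal(q$df, 13)
  expect_equal(q$p_value, pchisq(oracle, 13, lower.tail = FALSE))

  # identical ratios: Q = 0, p = 1
  bx <- c(0.1, 0.2, 0.4)
  hom <- make_set(bx = bx, by = 0.5 * bx, sy = rep(0.03, 3))
  qh <- cochran_q(hom)
  expect_equal(qh$q_statistic, 0)
  expect_equal(qh$p_value, 1)

  # duplicating an instrument never decreases Q
  d <- s$instruments
  dup <- d[c(seq_len(nrow(d)), 1), ]
  dup$variant_id[15] <- "rs_dup"
  expect_gte(cochran_q(instrument_set(dup))$q_statistic, q$q_statistic)
})

test_that("estimators are equivariant under joint sign flips", {
  s <- random_set(J = 8, seed = 7)
  neg <- s
  neg$instruments$beta_exposure <- -neg$instruments$beta_exposure
  neg$instruments$beta_outcome <- -neg$instruments$beta_outcome
  expect_equal(mr_ivw(neg)$estimate, mr_ivw(s)$estimate)
  expect_equal(mr_ivw(neg)$se, mr_ivw(s)$se)
  expect_equal(mr_egger(neg)$slope$estimate, mr_egger(s)$slope$estimate)
  expect_equal(mr_egger(neg)$intercept$estimate, mr_egger(s)$intercept$estimate)
  expect_equal(mr_weighted_median(neg, n_boot = 200)$estimate,
               mr_weighted_median(s, n_boot = 200)$estimate)

  # flipping only the outcome negates the causal estimate, same SE
  flip_y <- s
  flip_y$instruments$beta_outcome <- -flip_y$instruments$beta_outcome
  expect_equal(mr_ivw(flip_y)$estimate, -mr_ivw(s)$estimate)
  expect_equal(mr_ivw(flip_y)$se, mr_ivw(s)$se)
})
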