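#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' For each variant j the leave-one-out fixed-effect IVW estimate
#' `theta_-j` is computed from the remaining instruments and the variant's
#' weighted squared residual `RSS_j = (beta_outcome_j - theta_-j *
#' beta_exposure_j)^2 / se_outcome_j^2` measured against it; the observed
#' global statistic is the sum over variants. The null distribution comes
#' from parametric simulation: outcome betas are redrawn from
#' `Normal(theta_-j * beta_exposure_j, se_outcome_j)` (and, when
#' `resample_exposure = TRUE`, exposure betas from their own sampling
#' distribution) and the same statistic recomputed `n_sim` times. Empirical
#' p-values use the `(r + 1)/(n_sim + 1)` correction. Per-variant residuals
#' are tested the same way and flagged as outliers when below the
#' Bonferroni-adjusted level `significance / J`. When outliers are found, the
#' distortion test compares the all-instrument IVW estimate with the
#' outlier-free one against a resampling distribution of the same contrast.
#'
#' @inheritParams wald_ratio
#' @param n_sim number of simulated null datasets (>= 1000).
#' @param seed RNG seed; results are bit-reproducible given
#'   `(data, n_sim, seed)`.
#' @param significance family-wise outlier alpha before Bonferroni division.
#' @param resample_exposure also perturb exposure betas in the null draws.
#' @return A list of class `presso_result`: `global_rss_observed`,
#'   `global_p`, `outlier_table` (variant, residual RSS, empirical p, flag),
#'   `outliers`, `distortion_coefficient`, `distortion_p` (both `NA` when no
#'   outlier is flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(instruments, n_sim = 5000, seed = 20240507,
                      significance = 0.05, resample_exposure = FALSE) {
  d <- inst_table(instruments)
  J <- nrow(d)
  if (J < 4) stop("MR-PRESSO needs >= 4 instruments", call. = FALSE)
  if (n_sim < 1000) stop("n_sim must be >= 1000", call. = FALSE)

  inv_v <- 1 / d$se_outcome^2
  loo_theta <- function(bx, by) {
    # leave-one-out fixed-effect IVW for every variant at once
    s1 <- sum(bx * by * inv_v)
    s2 <- sum(bx^2 * inv_v)
    (s1 - bx * by * inv_v) / (s2 - bx^2 * inv_v)
  }
  th_obs <- loo_theta(d$beta_exposure, d$beta_outcome)
  rss_obs <- (d$beta_outcome - th_obs * d$beta_exposure)^2 * inv_v

  sim <- with_seed(seed, {
    bx_mat <- if (resample_exposure) {
      matrix(stats::rnorm(n_sim * J, rep(d$beta_exposure, each = n_sim),
                          rep(d$se_exposure, each = n_sim)), n_sim, J)
    } else {
      matrix(d$beta_exposure, n_sim, J, byrow = TRUE)
    }
    by_mat <- matrix(stats::rnorm(n_sim * J,
                                  rep(th_obs * d$beta_exposure, each = n_sim),
                                  rep(d$se_outcome, each = n_sim)), n_sim, J)
    ivm <- matrix(inv_v, n_sim, J, byrow = TRUE)
    s1 <- rowSums(bx_mat * by_mat * ivm)
    s2 <- rowSums(bx_mat^2 * ivm)
    th <- (s1 - bx_mat * by_mat * ivm) / (s2 - bx_mat^2 * ivm)
    (by_mat - th * bx_mat)^2 * ivm
  })

  global_p <- (1 + sum(rowSums(sim) >= sum(rss_obs))) / (n_sim + 1)
  outlier_p <- (1 + colSums(sim >= rep(rss_obs, each = n_sim))) / (n_sim + 1)
  flagged <- outlier_p < significance / J

  # Refinement: a gross outlier biases the leave-one-out estimates used to
  # test every other variant, which can spill over into false flags on
  # strong instruments. Re-test all variants against estimates computed with
  # the currently flagged set excluded, iterating until the flag set is
  # stable (clean data never enter this loop).
  iter <- 0
  while (any(flagged) && !all(flagged) && iter < 5) {
    iter <- iter + 1
    inl <- !flagged
    th_ref <- vapply(seq_len(J), function(j) {
      use <- inl
      use[j] <- FALSE
      sum(d$beta_exposure[use] * d$beta_outcome[use] * inv_v[use]) /
        sum(d$beta_exposure[use]^2 * inv_v[use])
    }, numeric(1))
    rss_ref <- (d$beta_outcome - th_ref * d$beta_exposure)^2 * inv_v
    sim_ref <- with_seed(seed + iter, {
      by_mat <- matrix(stats::rnorm(n_sim * J,
                                    rep(th_ref * d$beta_exposure, each = n_sim),
                                    rep(d$se_outcome, each = n_sim)), n_sim, J)
      bx_mat <- matrix(d$beta_exposure, n_sim, J, byrow = TRUE)
      ivm <- matrix(inv_v, n_sim, J, byrow = TRUE)
      inm <- matrix(inl, n_sim, J, byrow = TRUE)
      s1 <- rowSums(bx_mat * by_mat * ivm * inm)
      s2 <- rowSums(bx_mat^2 * ivm * inm)
      th <- (s1 - bx_mat * by_mat * ivm * inm) / (s2 - bx_mat^2 * ivm * inm)
      (by_mat - th * bx_mat)^2 * ivm
    })
    p_ref <- (1 + colSums(sim_ref >= rep(rss_ref, each = n_sim))) / (n_sim + 1)
    new_flagged <- p_ref < significance / J
    if (identical(new_flagged, flagged)) break
    flagged <- new_flagged
    outlier_p <- p_ref
  }
  outliers <- d$variant_id[flagged]

  distortion_coef <- NA_real_
  distortion_p <- NA_real_
  if (any(flagged) && !all(flagged)) {
    th_all <- mr_ivw(d, model = "fixed")$estimate
    th_in <- mr_ivw(d[!flagged, ], model = "fixed")$estimate
    distortion_coef <- 100 * (th_all - th_in) / abs(th_in)
    n_out <- sum(flagged)
    inliers <- which(!flagged)
    sims <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        pick <- sample(inliers, n_out, replace = TRUE)
        th_mix <- mr_ivw(d[c(inliers, pick), ], model = "fixed")$estimate
        100 * (th_mix - th_in) / abs(th_in)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(sims) >= abs(distortion_coef))) / (n_sim + 1)
  }

  structure(
    list(global_rss_observed = sum(rss_obs),
         global_p = global_p,
         outlier_table = data.frame(variant_id = d$variant_id,
                                    rss = rss_obs, p_value = outlier_p,
                                    outlier = flagged,
                                    stringsAsFactors = FALSE),
         outliers = outliers,
         distortion_coefficient = distortion_coef,
         distortion_p = distortion_p,
         n_sim = n_sim, seed = seed,
         significance = significance),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS %.3f, global p = %.4g (n_sim = %d)\n",
              x$global_rss_observed, x$global_p, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion %.1f%%, p = %.3g\n",
                x$distortion_coefficient, x$distortion_p))
  } else {
    cat("  no outlier flagged; distortion test not applicable\n")
  }
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. Per variant, explained variance is
#' approximated from the squared z-score: `r2 = F / (F + N - 2)`. For a
#' case-control outcome the effective sample size
#' `4 / (1/n_cases + 1/n_controls)` is used. The causal direction
#' exposure -> outcome is supported when the summed exposure r-squared
#' exceeds the summed outcome r-squared; the difference is tested with a
#' Fisher z-transform two-sample test on the implied correlations.
#'
#' @param instruments an [instrument_set()] carrying `n_exposure` and either
#'   case/control counts or an effective outcome size.
#' @param n_outcome_effective optional override for the effective outcome
#'   sample size.
#' @return A list of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction_correct`, `p_value`, and the sample sizes used.
#' @export
mr_steiger <- function(instruments, n_outcome_effective = NULL) {
  stopifnot(inherits(instruments, "instrument_set"))
  d <- instruments$instruments
  n_exp <- instruments$n_exposure
  if (is.na(n_exp)) stop("exposure sample size missing", call. = FALSE)
  if (is.null(n_outcome_effective)) {
    if (is.na(instruments$n_outcome_cases) || is.na(instruments$n_outcome_controls)) {
      stop("outcome sample sizes missing", call. = FALSE)
    }
    n_out <- 4 / (1 / instruments$n_outcome_cases +
                  1 / instruments$n_outcome_controls)
  } else {
    n_out <- n_outcome_effective
  }
  f_exp <- (d$beta_exposure / d$se_exposure)^2
  f_out <- (d$beta_outcome / d$se_outcome)^2
  r2_exp <- sum(f_exp / (f_exp + n_exp - 2))
  r2_out <- sum(f_out / (f_out + n_out - 2))
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(
    list(r2_exposure = r2_exp, r2_outcome = r2_out,
         direction_correct = r2_exp > r2_out,
         p_value = 2 * stats::pnorm(-abs(z)),
         n_exposure = n_exp, n_outcome_effective = n_out),
    class = "steiger_result"
  )
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> r2 exposure %.4f vs outcome %.5f; direction %s (p = %.3g)\n",
              x$r2_exposure, x$r2_outcome,
              if (x$direction_correct) "TRUE" else "FALSE", x$p_value))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimate J times, each time omitting one instrument, to
#' expose variants that single-handedly drive the pooled estimate.
#'
#' @inheritParams mr_ivw
#' @return A list of class `loo_result`: `table` (one row per omitted
#'   variant with the re-fitted estimate, SE, CI and p) and `full_estimate`
#'   (the all-instrument `mr_estimate`).
#' @export
mr_leave_one_out <- function(instruments, model = "auto") {
  d <- inst_table(instruments)
  J <- nrow(d)
  if (J < 3) stop("leave-one-out needs >= 3 instruments", call. = FALSE)
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(d[-j, , drop = FALSE], model = model)
    cbind(variant_id = d$variant_id[j], as.data.frame(est))
  })
  structure(
    list(table = do.call(rbind, rows),
         full_estimate = mr_ivw(d, model = model)),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  rng <- range(x$table$estimate)
  cat(sprintf("<loo_result> %d refits; estimates span %.4f to %.4f (full: %.4f)\n",
              nrow(x$table), rng[1], rng[2], x$full_estimate$estimate))
  invisible(x)
}
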