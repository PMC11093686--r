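Z95 <- 1.959964

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

mr_estimate <- function(method, estimate, se, n_instruments,
                        p_value = 2 * stats::pnorm(-abs(estimate / se))) {
  structure(
    list(method = method, estimate = estimate, se = se,
         ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
         p_value = p_value, n_instruments = n_instruments,
         odds_ratio = exp(estimate),
         or_ci_low = exp(estimate - Z95 * se),
         or_ci_high = exp(estimate + Z95 * se)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (J = %d)\n", x$method, x$n_instruments))
  cat(sprintf("  log-odds %.4f (95%% CI %.4f, %.4f), SE %.4f, p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$se, x$p_value))
  cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f)\n",
              x$odds_ratio, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             n_instruments = x$n_instruments, odds_ratio = x$odds_ratio,
             or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             stringsAsFactors = FALSE)
}

inst_table <- function(x) {
  if (inherits(x, "instrument_set")) x$instruments else as.data.frame(x)
}

# First-order Wald ratio point estimates and delta-method SEs, vectorized.
wald_components <- function(bx, sx, by, sy, second_order = FALSE) {
  est <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    abs(sy / bx)
  }
  list(estimate = est, se = se, weight = 1 / se^2)
}

#' Per-variant Wald ratio causal estimates
#'
#' The Wald ratio for one instrument is the variant-outcome effect divided by
#' the variant-exposure effect. The default standard error is the first-order
#' delta-method approximation `|se_outcome / beta_exposure|`, which ignores
#' the (here negligible, F >> 10) uncertainty in the exposure effect;
#' `second_order = TRUE` adds the exposure-variance term.
#'
#' @param instruments an [instrument_set()] (or its instrument table).
#' @param second_order use the second-order delta-method SE.
#' @return A data.frame with one row per variant: `variant_id`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p_value`, `weight` (inverse-variance).
#' @export
wald_ratio <- function(instruments, second_order = FALSE) {
  d <- inst_table(instruments)
  if (any(d$beta_exposure == 0)) {
    stop("zero exposure beta for: ",
         paste(d$variant_id[d$beta_exposure == 0], collapse = ", "),
         call. = FALSE)
  }
  w <- wald_components(d$beta_exposure, d$se_exposure,
                       d$beta_outcome, d$se_outcome, second_order)
  data.frame(variant_id = d$variant_id, estimate = w$estimate, se = w$se,
             ci_low = w$estimate - Z95 * w$se, ci_high = w$estimate + Z95 * w$se,
             p_value = 2 * stats::pnorm(-abs(w$estimate / w$se)),
             weight = w$weight, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-variant Wald ratios with first-order inverse-variance weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`. The fixed-effect SE is
#' `1/sqrt(sum(w))`; the multiplicative random-effects model inflates it by
#' `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's Q, and never deflates it.
#' `model = "auto"` (default) uses multiplicative random effects when four or
#' more instruments are available and the fixed-effect model otherwise.
#' A single instrument degenerates to its Wald ratio.
#'
#' @inheritParams wald_ratio
#' @param model `"auto"`, `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_estimate` (method `ivw_fe` or `ivw_mre`) with the
#'   heterogeneity test attached as attribute `"heterogeneity"` when J >= 2.
#' @export
mr_ivw <- function(instruments, model = c("auto", "fixed", "multiplicative_random"),
                   second_order = FALSE) {
  model <- match.arg(model)
  d <- inst_table(instruments)
  J <- nrow(d)
  if (J < 1) stop("empty instrument set", call. = FALSE)
  wr <- wald_ratio(d, second_order = second_order)
  w <- wr$weight
  est <- sum(w * wr$estimate) / sum(w)
  se_fe <- 1 / sqrt(sum(w))
  if (J == 1) return(mr_estimate("wald", est, se_fe, 1L))
  Q <- sum(w * (wr$estimate - est)^2)
  use_mre <- switch(model,
                    fixed = FALSE,
                    multiplicative_random = TRUE,
                    auto = J >= 4)
  se <- if (use_mre) se_fe * max(1, sqrt(Q / (J - 1))) else se_fe
  out <- mr_estimate(if (use_mre) "ivw_mre" else "ivw_fe", est, se, as.integer(J))
  attr(out, "heterogeneity") <- heterogeneity_result(Q, J - 1L)
  out
}

heterogeneity_result <- function(Q, df) {
  structure(list(q_statistic = Q, df = df,
                 p_value = stats::pchisq(Q, df, lower.tail = FALSE),
                 i_squared = max(0, (Q - df) / Q)),
            class = "heterogeneity_result")
}

#' Cochran's Q heterogeneity test across Wald ratios
#'
#' `Q = sum(w_j * (theta_j - theta)^2)` over per-variant causal estimates,
#' referred to a chi-square distribution with J - 1 degrees of freedom.
#'
#' @inheritParams wald_ratio
#' @param theta the pooled estimate the per-variant estimates are compared
#'   against; defaults to the fixed-effect IVW estimate.
#' @return A `heterogeneity_result`: `q_statistic`, `df`, `p_value`,
#'   `i_squared` (`max(0, (Q - df)/Q)`).
#' @export
cochran_q <- function(instruments, theta = NULL) {
  d <- inst_table(instruments)
  if (nrow(d) < 2) stop("heterogeneity needs >= 2 instruments", call. = FALSE)
  wr <- wald_ratio(d)
  if (is.null(theta)) theta <- sum(wr$weight * wr$estimate) / sum(wr$weight)
  heterogeneity_result(sum(wr$weight * (wr$estimate - theta)^2),
                       nrow(d) - 1L)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with a
#' free intercept and weights `1/se_outcome^2`, after orienting all exposure
#' betas non-negative (flipping exposure and outcome beta jointly where the
#' exposure beta is negative, so the intercept is identified). The slope is
#' the pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. Standard errors use the multiplicative
#' overdispersion model: the residual scale is applied only when it exceeds 1
#' (`max(1, sigma)`), so uncertainty is never shrunk below the fixed-effect
#' level. P-values and CIs use the normal reference by default;
#' `p_reference = "t"` switches to Student's t with J - 2 degrees of freedom.
#'
#' @inheritParams wald_ratio
#' @param p_reference `"normal"` (default) or `"t"`.
#' @return A list of class `mr_egger_fit` with elements `slope` and
#'   `intercept`, both `mr_estimate` objects (methods `egger_slope`,
#'   `egger_intercept`).
#' @export
mr_egger <- function(instruments, p_reference = c("normal", "t")) {
  p_reference <- match.arg(p_reference)
  d <- inst_table(instruments)
  J <- nrow(d)
  if (J < 3) stop("MR-Egger needs >= 3 instruments", call. = FALSE)
  flip <- ifelse(d$beta_exposure < 0, -1, 1)
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  if (stats::sd(bx) == 0) stop("degenerate design: all exposure betas equal",
                               call. = FALSE)
  fit <- stats::lm(by ~ bx, weights = 1 / d$se_outcome^2)
  s <- summary(fit)
  # rescale lm's model-based SEs to the multiplicative max(1, sigma) model
  se <- stats::coef(s)[, "Std. Error"] / s$sigma * max(1, s$sigma)
  pfun <- if (p_reference == "t") {
    function(z) 2 * stats::pt(-abs(z), df = J - 2)
  } else {
    function(z) 2 * stats::pnorm(-abs(z))
  }
  coefs <- stats::coef(fit)
  structure(
    list(slope = mr_estimate("egger_slope", coefs[["bx"]], se[["bx"]],
                             as.integer(J), pfun(coefs[["bx"]] / se[["bx"]])),
         intercept = mr_estimate("egger_intercept", coefs[["(Intercept)"]],
                                 se[["(Intercept)"]], as.integer(J),
                                 pfun(coefs[["(Intercept)"]] / se[["(Intercept)"]])),
         sigma = s$sigma, p_reference = p_reference),
    class = "mr_egger_fit"
  )
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat("<mr_egger_fit>\n  slope: ")
  cat(sprintf("%.4f (%.4f, %.4f), p = %.3g\n", x$slope$estimate,
              x$slope$ci_low, x$slope$ci_high, x$slope$p_value))
  cat(sprintf("  intercept: %.4f (%.4f, %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$ci_low, x$intercept$ci_high,
              x$intercept$p_value))
  invisible(x)
}

# Weighted median of values `x` with weights `w`: sort, standardize
# cumulative weights to s_j = (cum_j - w_j/2)/sum(w), linearly interpolate at
# s = 0.5.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-variant Wald ratios, consistent as long as
#' instruments carrying at least half of the total inverse-variance weight
#' are valid. The standard error comes from a parametric bootstrap:
#' exposure and outcome betas are resampled from their normal sampling
#' distributions `n_boot` times and the SD of the resulting weighted medians
#' is reported.
#'
#' @inheritParams wald_ratio
#' @param n_boot bootstrap replicates for the SE (default 10000).
#' @param seed RNG seed for the bootstrap; fixed by default so estimates are
#'   reproducible.
#' @return An `mr_estimate` (method `weighted_median`).
#' @export
mr_weighted_median <- function(instruments, n_boot = 10000, seed = 20240507) {
  d <- inst_table(instruments)
  J <- nrow(d)
  if (J < 3) stop("weighted median needs >= 3 instruments", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be positive", call. = FALSE)
  wr <- wald_ratio(d)
  est <- weighted_median_point(wr$estimate, wr$weight)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(J, d$beta_outcome, d$se_outcome)
      wc <- wald_components(bx, d$se_exposure, by, d$se_outcome)
      weighted_median_point(wc$estimate, wc$weight)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boot), as.integer(J))
}

#' Tidy table of MR estimates
#'
#' Binds `mr_estimate` objects (and the two halves of `mr_egger_fit`s) into
#' one tidy data.frame, the machine-readable analogue of a forest plot.
#'
#' @param ... `mr_estimate` / `mr_egger_fit` objects, optionally named.
#' @param study study label recycled across rows.
#' @return data.frame with columns `study`, `method`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n_instruments`, `odds_ratio`,
#'   `or_ci_low`, `or_ci_high`.
#' @export
mr_estimate_table <- function(..., study = NA_character_) {
  items <- list(...)
  rows <- lapply(items, function(x) {
    if (inherits(x, "mr_egger_fit")) {
      rbind(as.data.frame(x$slope), as.data.frame(x$intercept))
    } else {
      as.data.frame(x)
    }
  })
  out <- do.call(rbind, rows)
  cbind(study = study, out, stringsAsFactors = FALSE)
}
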