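#' Pool per-study causal estimates by inverse-variance meta-analysis
#'
#' Fixed-effect pooling (default) weights each study's log-odds estimate by
#' the inverse of its squared standard error; the pooled SE is
#' `1/sqrt(sum(1/se^2))`. `model = "random"` applies DerSimonian-Laird
#' between-study variance on top of the same weights. Between-study
#' heterogeneity (Cochran's Q over studies) is always reported. When both
#' Tyrmi et al. and FinnGen cohorts appear among the studies a warning notes
#' their partially overlapping samples; no covariance correction is applied.
#'
#' @param estimates a list of `mr_estimate` objects, or a data.frame with
#'   columns `estimate` and `se` (log-odds scale).
#' @param labels study labels; taken from `names(estimates)` or a `study`
#'   column when absent.
#' @param model `"fixed"` (default) or `"random"` (DerSimonian-Laird).
#' @return A list of class `meta_result`: pooled estimate/SE/CI/p on the
#'   log-odds and odds-ratio scales, normalized `per_study_weights`,
#'   `q_between` with its p-value, `tau2` (0 under fixed effect), `model`,
#'   and `forest` — the per-study + combined forest-plot table.
#' @export
meta_fixed <- function(estimates, labels = NULL, model = c("fixed", "random")) {
  model <- match.arg(model)
  if (is.data.frame(estimates)) {
    est <- estimates$estimate
    se <- estimates$se
    if (is.null(labels)) labels <- estimates$study
  } else {
    est <- vapply(estimates, function(x) x$estimate, numeric(1))
    se <- vapply(estimates, function(x) x$se, numeric(1))
    if (is.null(labels)) labels <- names(estimates)
  }
  k <- length(est)
  if (k < 2) stop("meta-analysis needs >= 2 studies", call. = FALSE)
  if (any(!is.finite(est)) || any(!is.finite(se)) || any(se <= 0)) {
    stop("estimates and standard errors must be finite with se > 0",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("study", seq_len(k))
  if (any(grepl("tyrmi", labels, ignore.case = TRUE)) &&
      any(grepl("finngen", labels, ignore.case = TRUE))) {
    warning("Tyrmi et al. and FinnGen samples partially overlap; ",
            "pooled SE ignores their covariance", call. = FALSE)
  }

  w_fe <- 1 / se^2
  pooled_fe <- sum(w_fe * est) / sum(w_fe)
  q <- sum(w_fe * (est - pooled_fe)^2)
  tau2 <- 0
  w <- w_fe
  if (model == "random") {
    c_const <- sum(w_fe) - sum(w_fe^2) / sum(w_fe)
    tau2 <- max(0, (q - (k - 1)) / c_const)
    w <- 1 / (se^2 + tau2)
  }
  pooled <- sum(w * est) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  p <- 2 * stats::pnorm(-abs(pooled / pooled_se))

  forest <- data.frame(
    study = c(labels, "combined"),
    estimate = c(est, pooled),
    se = c(se, pooled_se),
    odds_ratio = exp(c(est, pooled)),
    or_ci_low = exp(c(est, pooled) - Z95 * c(se, pooled_se)),
    or_ci_high = exp(c(est, pooled) + Z95 * c(se, pooled_se)),
    weight = c(w / sum(w), NA),
    p_value = c(2 * stats::pnorm(-abs(est / se)), p),
    stringsAsFactors = FALSE
  )

  structure(
    list(pooled_estimate = pooled, se = pooled_se,
         ci_low = pooled - Z95 * pooled_se,
         ci_high = pooled + Z95 * pooled_se,
         p_value = p,
         odds_ratio = exp(pooled),
         or_ci_low = exp(pooled - Z95 * pooled_se),
         or_ci_high = exp(pooled + Z95 * pooled_se),
         per_study_weights = stats::setNames(w / sum(w), labels),
         q_between = q,
         q_p_value = stats::pchisq(q, k - 1, lower.tail = FALSE),
         tau2 = tau2, model = model, forest = forest),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s-effect pooling of %d studies\n", x$model,
              length(x$per_study_weights)))
  cat(sprintf("  OR %.3f (95%% CI %.3f, %.3f), p = %.3f\n",
              x$odds_ratio, x$or_ci_low, x$or_ci_high, x$p_value))
  cat(sprintf("  between-study Q = %.2f (p = %.3f)\n", x$q_between, x$q_p_value))
  invisible(x)
}
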