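#' Configuration for the two-sample summary-statistics generator
#'
#' The generator draws true per-variant exposure effects `bX_j` uniformly
#' over a magnitude band with random signs, builds true outcome effects
#' `bY_j = theta * bX_j + alpha_j` under a chosen pleiotropy regime, and
#' returns observed betas with independent normal measurement noise at the
#' stated standard errors — the data-generating process assumed by a
#' two-sample MR with independent instruments. Defaults are calibrated to
#' the homocysteine instrument table: 14 instruments with exposure SEs of
#' 0.008 and outcome SEs of 0.035, so simulated F statistics span roughly
#' 25-400.
#'
#' Direct effects are expressed relative to each variant's
#' exposure-increasing allele (they enter the outcome as
#' `sign(bX_j) * alpha_j`), so a positive `directional_mean` biases causal
#' estimates upward whichever allele a variant happens to be coded on.
#'
#' Pleiotropy regimes for the direct effects `alpha_j`:
#' `"none"` (all zero), `"balanced"` (`Normal(0, pleiotropy_scale)`,
#' InSIDE holds), `"directional"` (`Normal(directional_mean,
#' pleiotropy_scale)`), and `"inside_violated"` (directional effects
#' proportional to instrument strength, `alpha_j = directional_mean *
#' |bX_j| / mean(|bX|) + Normal(0, pleiotropy_scale)`, breaking the
#' independence between pleiotropy and instrument strength that MR-Egger
#' relies on).
#'
#' @param n_instruments number of variants J (>= 2).
#' @param true_theta causal effect of exposure on outcome (log-odds per SD).
#' @param beta_x_range magnitude band for the true exposure effects.
#' @param se_x,se_y sampling-error scales, scalar or per-variant.
#' @param pleiotropy_mode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violated"`.
#' @param pleiotropy_scale SD of the direct effects.
#' @param directional_mean mean direct effect under the directional modes.
#' @param n_outliers number of variants whose observed outcome beta is
#'   displaced by `outlier_shift` outcome SEs.
#' @param outlier_shift displacement of planted outliers, in units of the
#'   outcome SE.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_instruments = 14,
                              true_theta = 0,
                              beta_x_range = c(0.04, 0.16),
                              se_x = 0.008,
                              se_y = 0.035,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional", "inside_violated"),
                              pleiotropy_scale = 0,
                              directional_mean = 0,
                              n_outliers = 0,
                              outlier_shift = 10,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_instruments < 2) stop("need at least 2 instruments", call. = FALSE)
  if (any(c(se_x, se_y) < 0) || pleiotropy_scale < 0) {
    stop("scales must be >= 0", call. = FALSE)
  }
  if (n_outliers > n_instruments) {
    stop("n_outliers cannot exceed n_instruments", call. = FALSE)
  }
  if (length(beta_x_range) != 2 || beta_x_range[1] <= 0 ||
      diff(beta_x_range) < 0) {
    stop("beta_x_range must be an increasing positive pair", call. = FALSE)
  }
  structure(
    list(n_instruments = as.integer(n_instruments), true_theta = true_theta,
         beta_x_range = beta_x_range, se_x = se_x, se_y = se_y,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_scale = pleiotropy_scale,
         directional_mean = directional_mean,
         n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

draw_alpha <- function(cfg, bx_true) {
  J <- cfg$n_instruments
  switch(cfg$pleiotropy_mode,
         none = rep(0, J),
         balanced = stats::rnorm(J, 0, cfg$pleiotropy_scale),
         directional = stats::rnorm(J, cfg$directional_mean, cfg$pleiotropy_scale),
         inside_violated = cfg$directional_mean * abs(bx_true) /
           mean(abs(bx_true)) + stats::rnorm(J, 0, cfg$pleiotropy_scale))
}

#' Simulate one harmonized two-sample instrument set
#'
#' @param config a [simulation_config()].
#' @param label study label for the resulting set.
#' @return An [instrument_set()] whose `"truth"` attribute records the true
#'   exposure/outcome effects, direct effects, causal effect and planted
#'   outlier indices.
#' @export
simulate_instrument_set <- function(config = simulation_config(), label = "simulated") {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_instrument_set_impl(config, label))
}

simulate_instrument_set_impl <- function(cfg, label) {
  J <- cfg$n_instruments
  se_x <- rep_len(cfg$se_x, J)
  se_y <- rep_len(cfg$se_y, J)
  bx_true <- stats::runif(J, cfg$beta_x_range[1], cfg$beta_x_range[2]) *
    sample(c(-1, 1), J, replace = TRUE)
  alpha <- draw_alpha(cfg, bx_true)
  by_true <- cfg$true_theta * bx_true + sign(bx_true) * alpha
  bx_obs <- bx_true + stats::rnorm(J, 0, se_x)
  by_obs <- by_true + stats::rnorm(J, 0, se_y)
  outlier_idx <- integer()
  if (cfg$n_outliers > 0) {
    outlier_idx <- sample.int(J, cfg$n_outliers)
    by_obs[outlier_idx] <- by_obs[outlier_idx] +
      cfg$outlier_shift * se_y[outlier_idx]
  }
  inst <- data.frame(
    variant_id = sprintf("sim%03d", seq_len(J)),
    chromosome = NA_character_, nearby_gene = NA_character_,
    effect_allele = "A",
    beta_exposure = bx_obs, se_exposure = se_x,
    p_exposure = 2 * stats::pnorm(-abs(bx_obs / se_x)),
    beta_outcome = by_obs, se_outcome = se_y,
    p_outcome = 2 * stats::pnorm(-abs(by_obs / se_y)),
    stringsAsFactors = FALSE
  )
  out <- instrument_set(inst, label = label)
  attr(out, "truth") <- list(
    beta_x_true = bx_true, beta_y_true = by_true, alpha = alpha,
    true_theta = cfg$true_theta, outlier_idx = sort(outlier_idx),
    config = cfg
  )
  out
}

#' Simulate a shared exposure with three outcome cohorts
#'
#' Mirrors a one-exposure, multi-outcome design: a single draw of exposure
#' effects is shared, while each outcome study gets an independent outcome
#' draw at its own SE scale and an optional availability mask dropping named
#' variants (as when a cohort lacks some instruments).
#'
#' @param config a [simulation_config()]; its `se_y` is overridden per study.
#' @param studies a named list; each element is a list with optional fields
#'   `se_y` (outcome SE scale) and `drop` (integer or `simNNN` variant ids to
#'   mask out of that study).
#' @return A named list of [instrument_set()]s sharing the exposure columns,
#'   each carrying the common `"truth"` attribute.
#' @export
replicate_study_trio <- function(config = simulation_config(),
                                 studies = list(
                                   study_a = list(),
                                   study_b = list(),
                                   study_c = list(drop = 1:3))) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    J <- config$n_instruments
    se_x <- rep_len(config$se_x, J)
    bx_true <- stats::runif(J, config$beta_x_range[1], config$beta_x_range[2]) *
      sample(c(-1, 1), J, replace = TRUE)
    alpha <- draw_alpha(config, bx_true)
    by_true <- config$true_theta * bx_true + sign(bx_true) * alpha
    bx_obs <- bx_true + stats::rnorm(J, 0, se_x)
    ids <- sprintf("sim%03d", seq_len(J))
    truth <- list(beta_x_true = bx_true, beta_y_true = by_true, alpha = alpha,
                  true_theta = config$true_theta, config = config)
    out <- lapply(names(studies), function(nm) {
      st <- studies[[nm]]
      se_y <- rep_len(if (is.null(st$se_y)) config$se_y else st$se_y, J)
      by_obs <- by_true + stats::rnorm(J, 0, se_y)
      keep <- rep(TRUE, J)
      if (!is.null(st$drop)) {
        drop_idx <- if (is.character(st$drop)) match(st$drop, ids) else st$drop
        if (any(is.na(drop_idx)) || any(drop_idx < 1 | drop_idx > J)) {
          stop("invalid availability mask for study ", nm, call. = FALSE)
        }
        keep[drop_idx] <- FALSE
      }
      inst <- data.frame(
        variant_id = ids[keep],
        chromosome = NA_character_, nearby_gene = NA_character_,
        effect_allele = "A",
        beta_exposure = bx_obs[keep], se_exposure = se_x[keep],
        p_exposure = 2 * stats::pnorm(-abs(bx_obs[keep] / se_x[keep])),
        beta_outcome = by_obs[keep], se_outcome = se_y[keep],
        p_outcome = 2 * stats::pnorm(-abs(by_obs[keep] / se_y[keep])),
        stringsAsFactors = FALSE
      )
      set <- instrument_set(inst, label = nm)
      attr(set, "truth") <- truth
      set
    })
    names(out) <- names(studies)
    out
  })
}

#' Write an instrument set back to delimited summary-statistics tables
#'
#' Emits the same format [read_summary_stats()] consumes: one file for the
#' exposure associations and one for the outcome associations, sharing the
#' effect-allele convention of the set.
#'
#' @param x an [instrument_set()].
#' @param exposure_path,outcome_path output file paths (TSV).
#' @return Invisibly, the two paths.
#' @export
write_summary_stats <- function(x, exposure_path, outcome_path) {
  stopifnot(inherits(x, "instrument_set"))
  d <- x$instruments
  ex <- data.frame(variant_id = d$variant_id, chromosome = d$chromosome,
                   effect_allele = d$effect_allele, beta = d$beta_exposure,
                   se = d$se_exposure, p_value = d$p_exposure,
                   stringsAsFactors = FALSE)
  ou <- ex
  ou$beta <- d$beta_outcome
  ou$se <- d$se_outcome
  ou$p_value <- d$p_outcome
  utils::write.table(ex, exposure_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ou, outcome_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(exposure = exposure_path, outcome = outcome_path))
}
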