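#' Configure the end-to-end MR pipeline
#'
#' @param exposure a `variant_assoc` table or a file path readable by
#'   [read_summary_stats()].
#' @param outcomes a named list, one element per outcome study; each element
#'   a list with `data` (a `variant_assoc` table or file path) and optional
#'   `n_cases`, `n_controls`.
#' @param n_exposure exposure-study sample size (needed for the Steiger test).
#' @param column_map passed to [read_summary_stats()] when paths are given.
#' @param selection optional [selection_config()] applied to the exposure
#'   candidates (with `ld_matrix` / `pleiotropy_flags`) before harmonization.
#' @param ld_matrix,pleiotropy_flags see [select_instruments()].
#' @param ivw_model,n_boot,presso_n_sim,seed estimator options, recorded in
#'   the run log.
#' @param output_dir optional directory; when set, every result table is
#'   written there as TSV along with `run_log.txt`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure, outcomes, n_exposure = NA_integer_,
                            column_map = NULL, selection = NULL,
                            ld_matrix = NULL, pleiotropy_flags = NULL,
                            ivw_model = "auto", n_boot = 10000,
                            presso_n_sim = 5000, seed = 20240507,
                            output_dir = NULL) {
  if (length(outcomes) < 1) stop("need at least one outcome study", call. = FALSE)
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop("outcomes must be a named list", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_assoc <- function(x, column_map, stage) {
  out <- tryCatch({
    if (is.character(x) && length(x) == 1) {
      if (is.null(column_map)) stop("column_map required to read a file")
      read_summary_stats(x, column_map)
    } else {
      validate_variant_associations(as.data.frame(x))
    }
  }, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
  out
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full Mendelian randomization pipeline
#'
#' Per outcome study: harmonization (with audit log), instrument-strength F
#' table, IVW / MR-Egger / weighted-median estimates, Cochran's Q, MR-PRESSO,
#' Steiger directionality and leave-one-out analysis. Across studies the
#' per-study IVW estimates are pooled by fixed-effect meta-analysis; with a
#' single outcome study the meta stage is skipped with an explanatory log
#' line. Every seed and option is recorded in the run log, and identical
#' configurations yield byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `mr_report`: `estimates` (tidy per-study method
#'   table), `heterogeneity`, `presso`, `steiger`, `leave_one_out`, `forest`
#'   (per-variant Wald ratios per study), `meta`, `audit`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("seed = %d; ivw_model = %s; n_boot = %d; presso_n_sim = %d",
                   config$seed, config$ivw_model, config$n_boot,
                   config$presso_n_sim))
  exposure <- resolve_assoc(config$exposure, config$column_map, "exposure input")

  if (!is.null(config$selection)) {
    sel <- run_stage("instrument selection",
                     select_instruments(exposure, config$selection,
                                        config$ld_matrix,
                                        config$pleiotropy_flags))
    log <- c(log, sprintf("selection: %d of %d candidates retained",
                          nrow(sel$selected), nrow(exposure)), sel$log)
    exposure <- sel$selected
  }

  studies <- names(config$outcomes)
  estimates <- list()
  het <- list()
  presso <- list()
  steiger <- list()
  loo <- list()
  forest <- list()
  audit <- character()
  per_study_ivw <- data.frame()

  for (st in studies) {
    spec <- config$outcomes[[st]]
    out_assoc <- resolve_assoc(spec$data, config$column_map,
                               paste("outcome input:", st))
    set <- run_stage(paste("harmonization:", st), harmonize(
      exposure, out_assoc, label = st,
      n_exposure = config$n_exposure,
      n_outcome_cases = if (is.null(spec$n_cases)) NA_integer_ else spec$n_cases,
      n_outcome_controls = if (is.null(spec$n_controls)) NA_integer_ else spec$n_controls
    ))
    audit <- c(audit, if (length(set$audit)) paste(st, set$audit, sep = "\t"))
    log <- c(log, sprintf("%s: %d instruments after harmonization", st,
                          length(set)))

    ivw <- run_stage(paste("ivw:", st), mr_ivw(set, model = config$ivw_model))
    egg <- run_stage(paste("egger:", st), mr_egger(set))
    wm <- run_stage(paste("weighted median:", st),
                    mr_weighted_median(set, n_boot = config$n_boot,
                                       seed = config$seed))
    estimates[[st]] <- mr_estimate_table(ivw, egg, wm, study = st)
    per_study_ivw <- rbind(per_study_ivw,
                           cbind(study = st, as.data.frame(ivw)))

    q <- attr(ivw, "heterogeneity")
    het[[st]] <- data.frame(study = st, q_statistic = q$q_statistic,
                            df = q$df, p_value = q$p_value,
                            i_squared = q$i_squared)
    pr <- run_stage(paste("presso:", st),
                    mr_presso(set, n_sim = config$presso_n_sim,
                              seed = config$seed))
    presso[[st]] <- data.frame(study = st,
                               global_rss = pr$global_rss_observed,
                               global_p = pr$global_p,
                               n_outliers = length(pr$outliers),
                               outliers = paste(pr$outliers, collapse = ","),
                               stringsAsFactors = FALSE)
    stg <- run_stage(paste("steiger:", st), mr_steiger(set))
    steiger[[st]] <- data.frame(study = st, r2_exposure = stg$r2_exposure,
                                r2_outcome = stg$r2_outcome,
                                direction_correct = stg$direction_correct,
                                p_value = stg$p_value)
    lo <- run_stage(paste("leave-one-out:", st),
                    mr_leave_one_out(set, model = config$ivw_model))
    loo[[st]] <- cbind(study = st, lo$table)
    f_tab <- wald_ratio(set)
    forest[[st]] <- cbind(study = st, f_tab,
                          f_statistic = set$instruments$f_statistic)
  }

  meta <- NULL
  if (length(studies) >= 2) {
    meta <- run_stage("meta-analysis", meta_fixed(per_study_ivw))
    log <- c(log, sprintf("meta-analysis (%s): OR %.3f (%.3f, %.3f), p = %.3f",
                          meta$model, meta$odds_ratio, meta$or_ci_low,
                          meta$or_ci_high, meta$p_value))
  } else {
    log <- c(log, "meta-analysis skipped: a single outcome study cannot be pooled")
  }

  report <- structure(
    list(estimates = do.call(rbind, c(estimates, make.row.names = FALSE)),
         heterogeneity = do.call(rbind, c(het, make.row.names = FALSE)),
         presso = do.call(rbind, c(presso, make.row.names = FALSE)),
         steiger = do.call(rbind, c(steiger, make.row.names = FALSE)),
         leave_one_out = do.call(rbind, c(loo, make.row.names = FALSE)),
         forest = do.call(rbind, c(forest, make.row.names = FALSE)),
         meta = meta, audit = audit, log = log),
    class = "mr_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("<mr_report>\n")
  cat("  studies:", paste(unique(x$estimates$study), collapse = ", "), "\n")
  if (!is.null(x$meta)) {
    cat(sprintf("  combined OR %.3f (95%% CI %.3f, %.3f), p = %.3f\n",
                x$meta$odds_ratio, x$meta$or_ci_low, x$meta$or_ci_high,
                x$meta$p_value))
  }
  invisible(x)
}

#' Write an `mr_report` as tidy TSV tables
#'
#' @param report an `mr_report` from [run_pipeline()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(d, name) {
    utils::write.table(d, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  emit(report$estimates, "estimates")
  emit(report$heterogeneity, "heterogeneity")
  emit(report$presso, "presso")
  emit(report$steiger, "steiger")
  emit(report$leave_one_out, "leave_one_out")
  emit(report$forest, "forest")
  if (!is.null(report$meta)) emit(report$meta$forest, "meta")
  writeLines(report$audit, file.path(dir, "harmonization_audit.txt"))
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Reproduce the homocysteine-PCOS analysis from the packaged fixture
#'
#' Convenience wrapper: runs [run_pipeline()] on the packaged instrument
#' table against all three outcome studies with default options.
#'
#' @param output_dir optional directory for the TSV report bundle.
#' @param presso_n_sim,seed forwarded to [pipeline_config()].
#' @return The `mr_report`.
#' @export
run_hcy_pcos_analysis <- function(output_dir = NULL, presso_n_sim = 5000,
                                  seed = 20240507) {
  outcomes <- lapply(hcy_pcos_studies(), function(st) {
    meta <- STUDY_META[[st]]
    list(data = pcos_outcome(st), n_cases = meta$cases,
         n_controls = meta$controls)
  })
  names(outcomes) <- vapply(hcy_pcos_studies(),
                            function(st) STUDY_META[[st]]$label, character(1))
  cfg <- pipeline_config(exposure = hcy_exposure(), outcomes = outcomes,
                         n_exposure = HCY_N_EXPOSURE,
                         presso_n_sim = presso_n_sim, seed = seed,
                         output_dir = output_dir)
  run_pipeline(cfg)
}
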