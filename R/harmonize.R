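#' @rdname harmonize
#' @export
instrument_set <- function(instruments, label = "study",
                           n_exposure = NA_integer_,
                           n_outcome_cases = NA_integer_,
                           n_outcome_controls = NA_integer_,
                           audit = character()) {
  stopifnot(is.data.frame(instruments))
  needed <- c("variant_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  missing_cols <- setdiff(needed, names(instruments))
  if (length(missing_cols)) {
    stop("instrument table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(instruments) < 1) stop("instrument set is empty", call. = FALSE)
  if (anyDuplicated(instruments$variant_id)) {
    stop("duplicated variant_id in instrument set", call. = FALSE)
  }
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  sizes <- c(n_exposure, n_outcome_cases, n_outcome_controls)
  if (any(!is.na(sizes) & sizes <= 0)) {
    stop("sample sizes must be positive when supplied", call. = FALSE)
  }
  instruments$f_statistic <-
    f_statistic(instruments$beta_exposure, instruments$se_exposure)
  structure(
    list(label = label,
         instruments = instruments,
         n_exposure = n_exposure,
         n_outcome_cases = n_outcome_cases,
         n_outcome_controls = n_outcome_controls,
         audit = audit),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments\n", x$label,
              nrow(x$instruments)))
  cat(sprintf("  F statistics: %.1f-%.1f (min-max)\n",
              min(x$instruments$f_statistic), max(x$instruments$f_statistic)))
  if (!is.na(x$n_exposure)) {
    cat(sprintf("  exposure N = %d; outcome %s cases / %s controls\n",
                x$n_exposure, format(x$n_outcome_cases, big.mark = ","),
                format(x$n_outcome_controls, big.mark = ",")))
  }
  if (length(x$audit)) cat("  audit:", length(x$audit), "filtered variant(s)\n")
  invisible(x)
}

#' @export
length.instrument_set <- function(x) nrow(x$instruments)

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Matches variants present in both studies and aligns the outcome effect to
#' the exposure's effect allele. When the outcome is coded on a different,
#' non-complementary allele the outcome beta sign is flipped. A complementary
#' coding (A vs T, C vs G) cannot be distinguished from a strand flip without
#' the non-effect allele, so such palindromic-ambiguous variants are excluded
#' by default. Variants absent from the outcome study are dropped; every
#' exclusion is recorded in the audit log with a reason code
#' (`MISSING_IN_OUTCOME`, `PALINDROMIC_AMBIGUOUS`, `ALLELE_FLIP` for sign
#' flips that were applied).
#'
#' @param exposure,outcome `variant_assoc` tables for the exposure and
#'   outcome study.
#' @param palindromic what to do with complementary-allele matches:
#'   `"exclude"` (default, conservative), `"keep"` (assume strand flip, keep
#'   beta as is) or `"flip"` (assume allele swap, negate outcome beta).
#' @param label,n_exposure,n_outcome_cases,n_outcome_controls metadata stored
#'   on the resulting set (see [instrument_set()]).
#'
#' @return An `instrument_set`: harmonized per-variant exposure and outcome
#'   betas/SEs, per-variant F statistics, study metadata and the audit log.
#' @export
harmonize <- function(exposure, outcome, palindromic = c("exclude", "keep", "flip"),
                      label = "study", n_exposure = NA_integer_,
                      n_outcome_cases = NA_integer_,
                      n_outcome_controls = NA_integer_) {
  palindromic <- match.arg(palindromic)
  exposure <- validate_variant_associations(as.data.frame(exposure))
  outcome <- validate_variant_associations(as.data.frame(outcome))

  audit <- character()
  absent <- setdiff(exposure$variant_id, outcome$variant_id)
  if (length(absent)) {
    audit <- c(audit, sprintf("%s\tMISSING_IN_OUTCOME\tnot present in outcome study",
                              absent))
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  same <- ou$effect_allele == ex$effect_allele
  compl <- ou$effect_allele == COMPLEMENT[ex$effect_allele]
  flip <- !same & !compl

  sign_mult <- ifelse(flip, -1, 1)
  keep <- rep(TRUE, length(shared))
  if (any(compl)) {
    if (palindromic == "exclude") {
      keep[compl] <- FALSE
      audit <- c(audit, sprintf(
        "%s\tPALINDROMIC_AMBIGUOUS\toutcome allele %s is complement of exposure allele %s",
        ex$variant_id[compl], ou$effect_allele[compl], ex$effect_allele[compl]))
      warning(sum(compl), " palindromic-ambiguous variant(s) excluded: ",
              paste(ex$variant_id[compl], collapse = ", "), call. = FALSE)
    } else if (palindromic == "flip") {
      sign_mult[compl] <- -1
    }
  }
  if (any(flip)) {
    audit <- c(audit, sprintf(
      "%s\tALLELE_FLIP\toutcome beta sign flipped (%s -> %s)",
      ex$variant_id[flip], ou$effect_allele[flip], ex$effect_allele[flip]))
  }

  if (!any(keep)) stop("no variants left after harmonization", call. = FALSE)
  inst <- data.frame(
    variant_id = ex$variant_id[keep],
    chromosome = ex$chromosome[keep],
    nearby_gene = ex$nearby_gene[keep],
    effect_allele = ex$effect_allele[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    p_exposure = ex$p_value[keep],
    beta_outcome = (ou$beta * sign_mult)[keep],
    se_outcome = ou$se[keep],
    p_outcome = ou$p_value[keep],
    stringsAsFactors = FALSE
  )
  instrument_set(inst, label = label, n_exposure = n_exposure,
                 n_outcome_cases = n_outcome_cases,
                 n_outcome_controls = n_outcome_controls, audit = audit)
}

#' Subset an instrument set by variant
#'
#' @param x an `instrument_set`.
#' @param keep logical, integer or character (rsID) index of instruments to
#'   retain.
#' @return A new `instrument_set` with the same metadata.
#' @export
subset_instruments <- function(x, keep) {
  stopifnot(inherits(x, "instrument_set"))
  idx <- if (is.character(keep)) match(keep, x$instruments$variant_id) else keep
  out <- x
  out$instruments <- x$instruments[idx, , drop = FALSE]
  rownames(out$instruments) <- NULL
  out
}
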