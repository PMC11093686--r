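#' Instrument-selection thresholds
#'
#' @param gwas_p_threshold genome-wide significance cutoff on the exposure
#'   association p-value. Default `5e-8`.
#' @param ld_r2_threshold pairwise r-squared above which two variants are
#'   treated as correlated during pruning. Default `0.05`.
#' @param proxy_r2_threshold minimum r-squared for a proxy substitute of a
#'   variant missing from the outcome study. Default `0.8`.
#' @param excluded_variants named character vector: rsID -> reason, applied
#'   before any other filter (an explicit drop list).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(gwas_p_threshold = 5e-8,
                             ld_r2_threshold = 0.05,
                             proxy_r2_threshold = 0.8,
                             excluded_variants = character()) {
  thr <- c(gwas_p_threshold, ld_r2_threshold, proxy_r2_threshold)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)", call. = FALSE)
  structure(list(gwas_p_threshold = gwas_p_threshold,
                 ld_r2_threshold = ld_r2_threshold,
                 proxy_r2_threshold = proxy_r2_threshold,
                 excluded_variants = excluded_variants),
            class = "selection_config")
}

#' Select independent, exposure-specific instruments
#'
#' Applies, in order: the explicit drop list, the genome-wide significance
#' filter, pleiotropy-annotation removal, and greedy LD pruning. Pruning
#' walks candidates in order of increasing exposure p-value (ties broken by
#' lexicographic rsID) and keeps a variant only if its r-squared with every
#' already-kept variant is below `ld_r2_threshold`, so within each correlated
#' group the variant with the smallest p-value survives. The result is
#' therefore invariant to the input ordering when p-values are distinct.
#'
#' @param candidates a `variant_assoc` table of exposure associations.
#' @param config a [selection_config()].
#' @param ld_matrix optional symmetric matrix of pairwise r-squared values
#'   with rsID dimnames; variants absent from it are assumed independent,
#'   but a matrix naming unknown variants is an error. `NULL` skips pruning.
#' @param pleiotropy_flags optional named character vector rsID -> associated
#'   secondary trait; flagged variants are removed.
#'
#' @return A list with `selected` (a `variant_assoc` table ordered by
#'   significance) and `log` (character, one line per removal with reason
#'   codes `EXCLUDED`, `NOT_SIGNIFICANT`, `PLEIOTROPY`, `LD_PRUNED`).
#' @export
select_instruments <- function(candidates, config = selection_config(),
                               ld_matrix = NULL, pleiotropy_flags = NULL) {
  x <- validate_variant_associations(as.data.frame(candidates))
  log <- character()

  if (length(config$excluded_variants)) {
    drop <- x$variant_id %in% names(config$excluded_variants)
    if (any(drop)) {
      log <- c(log, sprintf("%s\tEXCLUDED\t%s", x$variant_id[drop],
                            config$excluded_variants[x$variant_id[drop]]))
      x <- x[!drop, ]
    }
  }

  weak <- is.na(x$p_value) | x$p_value >= config$gwas_p_threshold
  if (any(weak)) {
    log <- c(log, sprintf("%s\tNOT_SIGNIFICANT\tp = %s >= %g",
                          x$variant_id[weak], format(x$p_value[weak]),
                          config$gwas_p_threshold))
    x <- x[!weak, ]
  }

  if (!is.null(pleiotropy_flags) && length(pleiotropy_flags)) {
    drop <- x$variant_id %in% names(pleiotropy_flags)
    if (any(drop)) {
      log <- c(log, sprintf("%s\tPLEIOTROPY\tassociated with %s",
                            x$variant_id[drop],
                            pleiotropy_flags[x$variant_id[drop]]))
      x <- x[!drop, ]
    }
  }

  if (!is.null(ld_matrix) && nrow(x) > 1) {
    ids <- rownames(ld_matrix)
    if (is.null(ids) || !identical(ids, colnames(ld_matrix))) {
      stop("ld_matrix needs identical rsID rownames and colnames", call. = FALSE)
    }
    unknown <- setdiff(ids, candidates$variant_id)
    if (length(unknown)) {
      stop("ld_matrix references unknown variants: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ord <- order(x$p_value, x$variant_id)
    kept <- character()
    pruned <- character()
    for (i in ord) {
      id <- x$variant_id[i]
      partners <- intersect(kept, ids)
      r2 <- if (id %in% ids && length(partners)) ld_matrix[id, partners] else 0
      if (any(r2 >= config$ld_r2_threshold, na.rm = TRUE)) {
        hit <- partners[which(r2 >= config$ld_r2_threshold)[1]]
        log <- c(log, sprintf("%s\tLD_PRUNED\tr2 = %.3g with retained %s",
                              id, ld_matrix[id, hit], hit))
        pruned <- c(pruned, id)
      } else {
        kept <- c(kept, id)
      }
    }
    x <- x[!x$variant_id %in% pruned, ]
  }

  x <- x[order(x$p_value, x$variant_id), ]
  rownames(x) <- NULL
  list(selected = x, log = log)
}
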