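#' Construct a table of per-variant GWAS associations
#'
#' A variant-association table holds one study's summary statistics for a set
#' of variants: one row per SNP with its effect allele, per-allele effect
#' estimate (SD units for a quantitative exposure, log-odds for a binary
#' outcome), standard error and optional p-value.
#'
#' @param variant_id character vector of rsIDs.
#' @param effect_allele single-nucleotide effect allele (A/C/G/T) per variant.
#' @param beta per-allele effect estimate.
#' @param se standard error of `beta`; must be strictly positive.
#' @param p_value optional association p-value in (0, 1].
#' @param chromosome optional chromosome label (carried, never parsed).
#' @param nearby_gene optional gene annotation.
#'
#' @return A `data.frame` of class `variant_assoc` with columns
#'   `variant_id`, `chromosome`, `nearby_gene`, `effect_allele`, `beta`,
#'   `se`, `p_value`.
#' @export
variant_associations <- function(variant_id, effect_allele, beta, se,
                                 p_value = NA_real_,
                                 chromosome = NA_character_,
                                 nearby_gene = NA_character_) {
  n <- length(variant_id)
  x <- data.frame(
    variant_id = as.character(variant_id),
    chromosome = rep_len(as.character(chromosome), n),
    nearby_gene = rep_len(as.character(nearby_gene), n),
    effect_allele = toupper(as.character(effect_allele)),
    beta = as.numeric(beta),
    se = as.numeric(se),
    p_value = rep_len(as.numeric(p_value), n),
    stringsAsFactors = FALSE
  )
  validate_variant_associations(x)
}

validate_variant_associations <- function(x) {
  if (anyDuplicated(x$variant_id)) {
    stop("duplicated variant_id: ",
         paste(unique(x$variant_id[duplicated(x$variant_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_allele <- !x$effect_allele %in% c("A", "C", "G", "T")
  if (any(bad_allele)) {
    stop("effect_allele must be a single nucleotide (A/C/G/T); offending rows: ",
         paste(x$variant_id[bad_allele], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$beta))) {
    stop("non-finite beta for: ",
         paste(x$variant_id[!is.finite(x$beta)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$se) | x$se <= 0)) {
    stop("se must be finite and > 0; offending rows: ",
         paste(x$variant_id[!is.finite(x$se) | x$se <= 0], collapse = ", "),
         call. = FALSE)
  }
  pv <- x$p_value[!is.na(x$p_value)]
  if (any(pv <= 0 | pv > 1)) {
    stop("p_value must lie in (0, 1]", call. = FALSE)
  }
  class(x) <- c("variant_assoc", "data.frame")
  x
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited summary-statistics table and maps its
#' columns onto the fields of [variant_associations()]. Rows with missing
#' effect size or standard error are rejected with an informative error,
#' never silently dropped.
#'
#' @param path file path of a delimited text table with a header row.
#' @param column_map named character vector mapping field names
#'   (`variant_id`, `effect_allele`, `beta`, `se`, and optionally `p_value`,
#'   `chromosome`, `nearby_gene`) to column names in the file.
#' @param delim field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#'
#' @return A `variant_assoc` table, one row per data row of the file.
#' @export
read_summary_stats <- function(path, column_map, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "."))
  required <- c("variant_id", "effect_allele", "beta", "se")
  missing_fields <- setdiff(required, names(column_map))
  if (length(missing_fields)) {
    stop("column_map lacks required fields: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  unmapped <- setdiff(unname(column_map), names(raw))
  if (length(unmapped)) {
    stop("columns not present in ", path, ": ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  get <- function(field, default = NA) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]] else default
  }
  if (nrow(raw) == 0) {
    return(variant_associations(character(), character(), numeric(), numeric()))
  }
  beta <- suppressWarnings(as.numeric(get("beta")))
  se <- suppressWarnings(as.numeric(get("se")))
  incomplete <- which(is.na(beta) | is.na(se))
  if (length(incomplete)) {
    stop("missing or non-numeric beta/se in row(s) ",
         paste(incomplete, collapse = ", "), " of ", path,
         " (variant ", paste(get("variant_id")[incomplete], collapse = ", "), ")",
         call. = FALSE)
  }
  variant_associations(
    variant_id = get("variant_id"),
    effect_allele = get("effect_allele"),
    beta = beta,
    se = se,
    p_value = suppressWarnings(as.numeric(get("p_value", NA_real_))),
    chromosome = get("chromosome", NA_character_),
    nearby_gene = get("nearby_gene", NA_character_)
  )
}

#' Instrument-strength F statistic
#'
#' The single-SNP F statistic is the squared z-score of the variant-exposure
#' association, `(beta/se)^2`. Values below 10 conventionally indicate a weak
#' instrument.
#'
#' @param beta_exposure per-allele effect on the exposure.
#' @param se_exposure its standard error (> 0).
#' @return numeric vector of F values.
#' @export
f_statistic <- function(beta_exposure, se_exposure) {
  if (any(!is.finite(se_exposure) | se_exposure <= 0)) {
    stop("se_exposure must be finite and > 0", call. = FALSE)
  }
  (beta_exposure / se_exposure)^2
}
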