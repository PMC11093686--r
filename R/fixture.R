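#' The packaged 14-SNP homocysteine instrument table
#'
#' The package ships, as plain text under `extdata`, the per-variant summary
#' statistics used throughout the analysis: 14 SNPs associated with plasma
#' homocysteine (Hcy) at genome-wide significance in a meta-GWAS of 44,147
#' Europeans, together with their associations with polycystic ovary
#' syndrome (PCOS) in three outcome GWAS — Day et al. (4,138 cases / 20,129
#' controls), Tyrmi et al. (3,609 / 229,788) and FinnGen release 7
#' (994 / 165,817). Three SNPs (rs7422339, rs234709, rs2851391) are absent
#' from FinnGen and carry `NA` outcome columns there.
#'
#' `hcy_pcos_table1()` returns the raw wide table; `hcy_exposure()` and
#' `pcos_outcome()` return per-study [variant_associations()] tables;
#' `hcy_pcos_instruments()` returns the ready-to-analyse harmonized
#' [instrument_set()] for one outcome study, with cohort sizes attached.
#'
#' @param study one of `"day"`, `"tyrmi"`, `"finngen"`.
#' @return See above; `hcy_pcos_studies()` returns the vector of study keys.
#' @export
hcy_pcos_table1 <- function() {
  path <- system.file("extdata", "hcy_pcos_table1.tsv", package = "hcymr",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname hcy_pcos_table1
#' @export
hcy_pcos_studies <- function() c("day", "tyrmi", "finngen")

STUDY_META <- list(
  day = list(label = "Day et al.", cases = 4138L, controls = 20129L),
  tyrmi = list(label = "Tyrmi et al.", cases = 3609L, controls = 229788L),
  finngen = list(label = "FinnGen", cases = 994L, controls = 165817L)
)
HCY_N_EXPOSURE <- 44147L

#' @rdname hcy_pcos_table1
#' @export
hcy_exposure <- function() {
  t1 <- hcy_pcos_table1()
  variant_associations(
    variant_id = t1$variant_id, effect_allele = t1$effect_allele,
    beta = t1$beta_hcy, se = t1$se_hcy, p_value = t1$p_hcy,
    chromosome = t1$chromosome, nearby_gene = t1$nearby_gene
  )
}

#' @rdname hcy_pcos_table1
#' @export
pcos_outcome <- function(study = c("day", "tyrmi", "finngen")) {
  study <- match.arg(study)
  t1 <- hcy_pcos_table1()
  beta <- t1[[paste0("beta_", study)]]
  avail <- !is.na(beta)
  variant_associations(
    variant_id = t1$variant_id[avail], effect_allele = t1$effect_allele[avail],
    beta = beta[avail], se = t1[[paste0("se_", study)]][avail],
    p_value = t1[[paste0("p_", study)]][avail],
    chromosome = t1$chromosome[avail], nearby_gene = t1$nearby_gene[avail]
  )
}

#' @rdname hcy_pcos_table1
#' @export
hcy_pcos_instruments <- function(study = c("day", "tyrmi", "finngen")) {
  study <- match.arg(study)
  meta <- STUDY_META[[study]]
  harmonize(hcy_exposure(), pcos_outcome(study),
            label = meta$label, n_exposure = HCY_N_EXPOSURE,
            n_outcome_cases = meta$cases, n_outcome_controls = meta$controls)
}
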