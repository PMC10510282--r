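# Rule-based transcript classification. All thresholds are the published
# constants: p < 0.05 (strict), |log2FC| > 0.58 (~1.5-fold, strict, the
# printed 0.58 rather than log2(1.5)), a rescue must move the fold change
# at least 0.5 closer to zero, and the relaxed shared-module magnitude is
# |log2FC| > 0.5. Raw (not BH-adjusted) p-values feed the rules.

default_thresholds <- function() {
  list(p_thresh = 0.05, lfc_thresh = 0.58,
       reversion_delta = 0.5, relaxed_lfc = 0.5)
}

#' Is a transcript rescued by one ICD?
#'
#' True iff (1) the rescue p-value is below `p_thresh`, (2) the baseline
#' |log2FC| versus WT exceeds `lfc_thresh`, and (3) the |log2FC| versus WT
#' with the ICD is at least `reversion_delta` closer to zero than without
#' it. Overshooting past zero still counts as rescued (the criterion is a
#' reduction in magnitude, not a sign constraint).
#'
#' @param rescue_p Combined rescue p-value(s), see [rescue_pvalue()].
#' @param lfc_base log2FC of genotype:Cre vs WT:Cre.
#' @param lfc_icd_vs_wt log2FC of genotype:ICD vs WT:Cre.
#' @param p_thresh,lfc_thresh,reversion_delta Published thresholds
#'   (0.05, 0.58, 0.5).
#' @return Logical vector; `NA` where any required input is missing
#'   (unclassifiable, reported as such rather than `FALSE`).
#' @export
classify_rescued <- function(rescue_p, lfc_base, lfc_icd_vs_wt,
                             p_thresh = 0.05, lfc_thresh = 0.58,
                             reversion_delta = 0.5) {
  rescue_p < p_thresh &
    abs(lfc_base) > lfc_thresh &
    abs(lfc_icd_vs_wt) <= abs(lfc_base) - reversion_delta
}

#' Is a transcript affected by one ICD, and in which direction?
#'
#' True iff (1) the effect p-value OR the rescue p-value is below
#' `p_thresh` and (2) the ICD-treated group's |log2FC| exceeds `lfc_thresh`
#' against both WT and the genotype baseline. Direction is the sign of the
#' fold change versus the genotype baseline.
#'
#' @param effect_p,rescue_p Combined p-values for this (genotype, ICD).
#' @param lfc_icd_vs_wt log2FC of genotype:ICD vs WT:Cre.
#' @param lfc_icd_vs_base log2FC of genotype:ICD vs genotype:Cre.
#' @param p_thresh,lfc_thresh Published thresholds (0.05, 0.58).
#' @return Character vector `"up"`/`"down"`/`"none"`; `NA` where
#'   unclassifiable (both p-values missing, or a needed fold change
#'   missing).
#' @export
classify_effected <- function(effect_p, rescue_p, lfc_icd_vs_wt,
                              lfc_icd_vs_base,
                              p_thresh = 0.05, lfc_thresh = 0.58) {
  n <- length(lfc_icd_vs_base)
  effect_p <- rep_len(effect_p, n); rescue_p <- rep_len(rescue_p, n)
  # OR with NA as "unavailable": significant if either defined value passes
  sig <- (!is.na(effect_p) & effect_p < p_thresh) |
    (!is.na(rescue_p) & rescue_p < p_thresh)
  sig[is.na(effect_p) & is.na(rescue_p)] <- NA
  hit <- sig & abs(lfc_icd_vs_wt) > lfc_thresh &
    abs(lfc_icd_vs_base) > lfc_thresh
  out <- ifelse(hit, ifelse(lfc_icd_vs_base > 0, "up", "down"), "none")
  out[is.na(hit)] <- NA_character_
  out
}

#' Basal classification of a transcript in one genotype
#'
#' `"up"`/`"down"` per the sign of the baseline fold change iff
#' |log2FC| > `lfc_thresh` and the smallest available of {baseline p,
#' rescue p (either ICD), vWT p (either ICD)} is below `p_thresh`;
#' otherwise `"none"`. Any transcript classified rescued is basal by
#' construction (its rescue p-value is one of the routes).
#'
#' @param lfc_base,p_base Baseline contrast (genotype:Cre vs WT:Cre).
#' @param rescue_p_icd19,rescue_p_icdd19 Per-ICD rescue p-values (`NA` ok).
#' @param vwt_p_icd19,vwt_p_icdd19 Per-ICD vWT p-values (`NA` ok).
#' @param p_thresh,lfc_thresh Published thresholds (0.05, 0.58).
#' @return Character vector `"up"`/`"down"`/`"none"`; `NA` where the
#'   baseline contrast itself is untested.
#' @export
classify_basal <- function(lfc_base, p_base,
                           rescue_p_icd19 = NA_real_, rescue_p_icdd19 = NA_real_,
                           vwt_p_icd19 = NA_real_, vwt_p_icdd19 = NA_real_,
                           p_thresh = 0.05, lfc_thresh = 0.58) {
  n <- length(lfc_base)
  pm <- cbind(rep_len(p_base, n),
              rep_len(rescue_p_icd19, n), rep_len(rescue_p_icdd19, n),
              rep_len(vwt_p_icd19, n), rep_len(vwt_p_icdd19, n))
  all_na <- rowSums(!is.na(pm)) == 0
  min_p <- rep(Inf, n)
  min_p[!all_na] <- apply(pm[!all_na, , drop = FALSE], 1, min, na.rm = TRUE)
  sig <- !is.na(lfc_base) & abs(lfc_base) > lfc_thresh & min_p < p_thresh
  out <- ifelse(sig, ifelse(lfc_base > 0, "up", "down"), "none")
  out[is.na(lfc_base) | is.na(p_base)] <- NA_character_
  out
}

#' Full classification table: one row per gene x mutant genotype
#'
#' Applies [classify_rescued()], [classify_effected()] and
#' [classify_basal()] to a [combined_stats()] table and appends the label
#' columns plus the shared-module flag from [shared_module_set()].
#' Ordering is deterministic (gene id, then genotype).
#'
#' @param cs A [combined_stats()] data frame.
#' @param thresholds List with `p_thresh`, `lfc_thresh`, `reversion_delta`,
#'   `relaxed_lfc` (defaults 0.05, 0.58, 0.5, 0.5).
#' @return `cs` with added columns `basal`, `rescued_ICD19`,
#'   `rescued_ICDd19`, `rescued_both`, `effected_ICD19`, `effected_ICDd19`
#'   and `shared_module`.
#' @export
classify_genes <- function(cs, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  for (icd in ICD_TREATMENTS) {
    cs[[paste0("rescued_", icd)]] <- classify_rescued(
      cs[[paste0("rescue_p_", icd)]], cs$lfc_base,
      cs[[paste0("lfc_", icd, "_vs_wt")]],
      th$p_thresh, th$lfc_thresh, th$reversion_delta)
    cs[[paste0("effected_", icd)]] <- classify_effected(
      cs[[paste0("effect_p_", icd)]], cs[[paste0("rescue_p_", icd)]],
      cs[[paste0("lfc_", icd, "_vs_wt")]], cs[[paste0("lfc_", icd, "_vs_base")]],
      th$p_thresh, th$lfc_thresh)
  }
  cs$rescued_both <- cs$rescued_ICD19 & cs$rescued_ICDd19
  cs$basal <- classify_basal(cs$lfc_base, cs$p_base,
                             cs$rescue_p_ICD19, cs$rescue_p_ICDd19,
                             cs$vwt_p_ICD19, cs$vwt_p_ICDd19,
                             th$p_thresh, th$lfc_thresh)
  sm <- shared_module_set(cs, relaxed_lfc = th$relaxed_lfc)
  cs$shared_module <- cs$gene_id %in% c(sm$up, sm$down)
  cs <- cs[order(cs$gene_id, cs$genotype), , drop = FALSE]
  rownames(cs) <- NULL
  cs
}

#' Shared regulatory module under the relaxed criterion
#'
#' Genes basal-significant under the full criteria in at least one mutant
#' genotype whose baseline fold change versus WT exceeds the relaxed
#' magnitude (default |log2FC| > 0.5) with a consistent sign in all three
#' mutant genotypes.
#'
#' @param cls A classification (or [combined_stats()]) table carrying
#'   `gene_id`, `genotype`, `lfc_base` and a `basal` column (computed here
#'   if absent).
#' @param relaxed_lfc Relaxed magnitude threshold (default 0.5).
#' @return List with character vectors `up` and `down` (sorted gene ids).
#' @export
shared_module_set <- function(cls, relaxed_lfc = 0.5) {
  if (is.null(cls$basal))
    cls$basal <- classify_basal(cls$lfc_base, cls$p_base,
                                cls$rescue_p_ICD19, cls$rescue_p_ICDd19,
                                cls$vwt_p_ICD19, cls$vwt_p_ICDd19)
  split_g <- split(cls, cls$gene_id)
  pick <- function(sub, dir) {
    if (nrow(sub) != length(MUTANT_GENOTYPES)) return(FALSE)
    if (!any(!is.na(sub$basal) & sub$basal != "none")) return(FALSE)
    if (anyNA(sub$lfc_base)) return(FALSE)
    all(dir * sub$lfc_base > relaxed_lfc)
  }
  up <- vapply(split_g, pick, logical(1), dir = 1)
  down <- vapply(split_g, pick, logical(1), dir = -1)
  list(up = sort(names(split_g)[up]), down = sort(names(split_g)[down]))
}

#' Per-genotype label counts
#'
#' Quick summary for comparison with published prose: counts of basal
#' up/down transcripts, rescued (by both / by exactly one ICD / by a given
#' ICD), affected per ICD, and shared-module membership, per genotype.
#'
#' @param cls A [classify_genes()] table.
#' @return Data frame, one row per mutant genotype.
#' @export
summarize_classification <- function(cls) {
  do.call(rbind, lapply(split(cls, cls$genotype), function(sub) {
    r19 <- !is.na(sub$rescued_ICD19) & sub$rescued_ICD19
    rd19 <- !is.na(sub$rescued_ICDd19) & sub$rescued_ICDd19
    data.frame(
      genotype = sub$genotype[1],
      basal_up = sum(sub$basal == "up", na.rm = TRUE),
      basal_down = sum(sub$basal == "down", na.rm = TRUE),
      rescued_both = sum(r19 & rd19),
      rescued_ICD19_only = sum(r19 & !rd19),
      rescued_ICDd19_only = sum(rd19 & !r19),
      effected_ICD19 = sum(sub$effected_ICD19 %in% c("up", "down")),
      effected_ICDd19 = sum(sub$effected_ICDd19 %in% c("up", "down")),
      shared_module = sum(sub$shared_module),
      unclassifiable = sum(is.na(sub$basal)),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}
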