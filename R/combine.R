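# Additive (Edgington) combination of p-values. The combined significance of
# k p-values is the probability that a sum of k independent uniforms falls
# at or below the observed sum s = sum(p). Two modes:
#   paper  - (s^k)/k!, truncated at 1. This equals the exact tail whenever
#            s <= 1 but exceeds it (eventually passing 1) for larger sums.
#   exact  - the Irwin-Hall CDF, valid for all s.

#' Irwin-Hall cumulative distribution function
#'
#' P(U1 + ... + Uk <= s) for independent uniform(0,1) variables, via the
#' inclusion-exclusion closed form
#' `sum_{j=0}^{floor(s)} (-1)^j C(k,j) (s-j)^k / k!`.
#'
#' @param s Numeric vector of sums (clamped into \[0, k\]).
#' @param k Number of uniforms (positive integer).
#' @return P(sum <= s), in \[0, 1\].
#' @export
irwin_hall_cdf <- function(s, k) {
  stopifnot(k >= 1, k == round(k))
  s <- pmin(pmax(s, 0), k)
  out <- numeric(length(s))
  for (j in 0:k) {
    term <- (-1)^j * choose(k, j) * pmax(s - j, 0)^k / factorial(k)
    out <- out + term
  }
  pmin(pmax(out, 0), 1)
}

#' Additively combine k p-values
#'
#' @param pvals Numeric vector of k p-values in \[0, 1\] (k >= 1).
#' @param mode `"paper"` for the truncated power formula
#'   `min(1, (sum p)^k / k!)`; `"exact"` for the Irwin-Hall CDF of the sum.
#'   The modes agree exactly whenever `sum(pvals) <= 1`.
#' @return Combined p-value in \[0, 1\]; `NA` if any input is `NA`.
#' @export
additive_combine <- function(pvals, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  k <- length(pvals)
  if (k < 1) stop("need at least one p-value")
  if (anyNA(pvals)) return(NA_real_)
  if (any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  s <- sum(pvals)
  if (mode == "paper") min(1, s^k / factorial(k)) else irwin_hall_cdf(s, k)
}

# Elementwise k=2 combination for vectorized pipeline use; NA propagates.
combine_pair <- function(p1, p2, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  ok <- !is.na(p1) & !is.na(p2)
  if (any((p1[ok] < 0) | (p1[ok] > 1) | (p2[ok] < 0) | (p2[ok] > 1)))
    stop("p-values must lie in [0, 1]")
  s <- p1 + p2
  out <- rep(NA_real_, length(s))
  if (mode == "paper") {
    out[ok] <- pmin(1, s[ok]^2 / 2)
  } else {
    out[ok] <- ifelse(s[ok] <= 1, s[ok]^2 / 2, 1 - (2 - s[ok])^2 / 2)
  }
  out
}

#' Rescue p-value for one (genotype, ICD)
#'
#' Combines the basal contrast (genotype:Cre vs WT:Cre) with the
#' within-genotype ICD contrast (genotype:ICD vs genotype:Cre): small when
#' the genotype departs from wild type AND the ICD moves it.
#'
#' @param p_baseline P-value(s) of genotype:Cre vs WT:Cre.
#' @param p_icd_vs_baseline P-value(s) of genotype:ICD vs genotype:Cre.
#' @param mode Combination mode, see [additive_combine()].
#' @return Combined p-value(s); `NA` where either input is missing
#'   (untested genes propagate as missing, never as 1).
#' @export
rescue_pvalue <- function(p_baseline, p_icd_vs_baseline,
                          mode = c("paper", "exact")) {
  combine_pair(p_baseline, p_icd_vs_baseline, match.arg(mode))
}

#' Effect p-value for one (genotype, ICD)
#'
#' Combines the vs-wild-type ICD contrast (genotype:ICD vs WT:Cre) with the
#' within-genotype ICD contrast (genotype:ICD vs genotype:Cre): small when
#' the ICD-treated group differs from both references.
#'
#' @param p_icd_vs_wt P-value(s) of genotype:ICD vs WT:Cre.
#' @param p_icd_vs_baseline P-value(s) of genotype:ICD vs genotype:Cre.
#' @param mode Combination mode.
#' @return Combined p-value(s); `NA` where either input is missing.
#' @export
effect_pvalue <- function(p_icd_vs_wt, p_icd_vs_baseline,
                          mode = c("paper", "exact")) {
  combine_pair(p_icd_vs_wt, p_icd_vs_baseline, match.arg(mode))
}

#' vWT p-value for one (genotype, ICD)
#'
#' Combines the two vs-wild-type contrasts (genotype:Cre vs WT:Cre and
#' genotype:ICD vs WT:Cre), but only where both fold changes versus wild
#' type exceed the magnitude gate and share sign; otherwise undefined (`NA`).
#'
#' @param p_baseline,p_icd_vs_wt P-values of the two vs-WT contrasts.
#' @param lfc_baseline,lfc_icd_vs_wt Their log2 fold changes.
#' @param lfc_thresh Magnitude gate on both |log2FC| (default 0.58).
#' @param mode Combination mode.
#' @return Combined p-value(s) or `NA` where the direction/magnitude gate
#'   fails or inputs are missing.
#' @export
vwt_pvalue <- function(p_baseline, p_icd_vs_wt, lfc_baseline, lfc_icd_vs_wt,
                       lfc_thresh = 0.58, mode = c("paper", "exact")) {
  gate <- !is.na(lfc_baseline) & !is.na(lfc_icd_vs_wt) &
    abs(lfc_baseline) > lfc_thresh & abs(lfc_icd_vs_wt) > lfc_thresh &
    sign(lfc_baseline) == sign(lfc_icd_vs_wt)
  out <- combine_pair(p_baseline, p_icd_vs_wt, match.arg(mode))
  out[!gate] <- NA_real_
  out
}

#' Both-ICD combined p-value
#'
#' Combines the two single-ICD rescue (or effect) p-values into one test of
#' whether both ICD variants rescue/affect the transcript. Default is the
#' nested k=2 combination of the already-combined values.
#'
#' @param p_icd19,p_icdd19 Single-ICD combined p-values.
#' @param mode Combination mode.
#' @return Combined p-value(s); `NA` where either input is undefined.
#' @export
both_icd_pvalue <- function(p_icd19, p_icdd19, mode = c("paper", "exact")) {
  combine_pair(p_icd19, p_icdd19, match.arg(mode))
}

# p / lfc aligned to gene_ids by id match; untested genes become NA so a
# missing test never silently enters a combination as 1
aligned_p <- function(res, gene_ids) {
  i <- match(gene_ids, res$gene_id)
  ifelse(!is.na(i) & res$tested[i], res$p[i], NA_real_)
}
aligned_lfc <- function(res, gene_ids) {
  i <- match(gene_ids, res$gene_id)
  ifelse(!is.na(i) & res$tested[i], res$log2fc[i], NA_real_)
}

#' Combined rescue/effect/vWT statistics for every gene x mutant genotype
#'
#' Assembles, from per-contrast result tables, one row per gene per mutant
#' genotype carrying the underlying fold changes and p-values together with
#' the per-ICD rescue, effect and vWT combined p-values and the both-ICD
#' combinations.
#'
#' @param results Named list of ContrastResult data frames as produced by
#'   [run_de()] (names from [standard_contrasts()]); externally produced
#'   tables normalized with [as_contrast_result()] are accepted.
#' @param mode Combination mode, `"paper"` (default) or `"exact"`.
#' @param both_mode `"nested"` (default): both-ICD p combines the two
#'   single-ICD combined values with k=2. `"flat"`: k=4 over the raw
#'   contrast p-values entering the two combinations (for rescue this
#'   counts the shared baseline contrast twice).
#' @param lfc_thresh Magnitude gate for the vWT definition (default 0.58).
#' @return Data frame, one row per gene x genotype, with columns
#'   `gene_id`, `genotype`, `lfc_base`, `p_base`, and per ICD
#'   `lfc_<icd>_vs_wt`, `lfc_<icd>_vs_base`, `p_<icd>_vs_wt`,
#'   `p_<icd>_vs_base`, `rescue_p_<icd>`, `effect_p_<icd>`, `vwt_p_<icd>`,
#'   plus `both_rescue_p`, `both_effect_p`, `k` and `mode`.
#' @export
combined_stats <- function(results, mode = c("paper", "exact"),
                           both_mode = c("nested", "flat"),
                           lfc_thresh = 0.58) {
  mode <- match.arg(mode)
  both_mode <- match.arg(both_mode)
  gene_ids <- results[[1]]$gene_id
  rows <- lapply(MUTANT_GENOTYPES, function(g) {
    base_key <- contrast_key(paste0(g, ":Cre"), REFERENCE_GROUP)
    base <- results[[base_key]]
    if (is.null(base)) stop("missing contrast: ", base_key)
    p_base <- aligned_p(base, gene_ids)
    lfc_base <- aligned_lfc(base, gene_ids)
    out <- data.frame(gene_id = gene_ids, genotype = g,
                      lfc_base = lfc_base, p_base = p_base,
                      stringsAsFactors = FALSE)
    raw <- list()
    for (icd in ICD_TREATMENTS) {
      vswt_key <- contrast_key(paste0(g, ":", icd), REFERENCE_GROUP)
      within_key <- contrast_key(paste0(g, ":", icd), paste0(g, ":Cre"))
      vswt <- results[[vswt_key]]
      within <- results[[within_key]]
      if (is.null(vswt) || is.null(within))
        stop("missing contrast(s) for ", g, " ", icd)
      p_vswt <- aligned_p(vswt, gene_ids)
      p_within <- aligned_p(within, gene_ids)
      lfc_vswt <- aligned_lfc(vswt, gene_ids)
      lfc_within <- aligned_lfc(within, gene_ids)
      out[[paste0("lfc_", icd, "_vs_wt")]] <- lfc_vswt
      out[[paste0("lfc_", icd, "_vs_base")]] <- lfc_within
      out[[paste0("p_", icd, "_vs_wt")]] <- p_vswt
      out[[paste0("p_", icd, "_vs_base")]] <- p_within
      out[[paste0("rescue_p_", icd)]] <- rescue_pvalue(p_base, p_within, mode)
      out[[paste0("effect_p_", icd)]] <- effect_pvalue(p_vswt, p_within, mode)
      out[[paste0("vwt_p_", icd)]] <-
        vwt_pvalue(p_base, p_vswt, lfc_base, lfc_vswt, lfc_thresh, mode)
      raw[[icd]] <- list(p_vswt = p_vswt, p_within = p_within)
    }
    if (both_mode == "nested") {
      out$both_rescue_p <- both_icd_pvalue(out$rescue_p_ICD19,
                                           out$rescue_p_ICDd19, mode)
      out$both_effect_p <- both_icd_pvalue(out$effect_p_ICD19,
                                           out$effect_p_ICDd19, mode)
    } else {
      comb4 <- function(a, b, c, d) {
        s <- a + b + c + d
        res <- rep(NA_real_, length(s))
        ok <- !is.na(s)
        res[ok] <- if (mode == "paper") pmin(1, s[ok]^4 / 24)
                   else irwin_hall_cdf(s[ok], 4)
        res
      }
      out$both_rescue_p <- comb4(p_base, raw$ICD19$p_within,
                                 p_base, raw$ICDd19$p_within)
      out$both_effect_p <- comb4(raw$ICD19$p_vswt, raw$ICD19$p_within,
                                 raw$ICDd19$p_vswt, raw$ICDd19$p_within)
    }
    out
  })
  out <- do.call(rbind, rows)
  out$k <- if (both_mode == "nested") 2L else 4L
  out$mode <- mode
  out <- out[order(out$gene_id, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
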