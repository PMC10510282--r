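# End-to-end driver: differential testing over all design contrasts,
# additive combination, classification, summaries, deterministic TSVs.

#' Run the full translatome analysis pipeline
#'
#' Executes the differential stage over [standard_contrasts()], combines
#' p-values into rescue/effect/vWT statistics, classifies every gene per
#' mutant genotype, derives the relaxed shared module, and (optionally)
#' writes all result tables as deterministic TSVs. Identical inputs and
#' settings give byte-identical outputs; the pipeline itself draws no
#' random numbers.
#'
#' @param counts A [count_matrix()].
#' @param out_dir Output directory for TSVs, or `NULL` to skip writing.
#' @param p_thresh,lfc_thresh,reversion_delta,relaxed_lfc Classification
#'   thresholds; defaults are the published constants 0.05, 0.58, 0.5, 0.5.
#' @param combine_mode `"paper"` (truncated power formula, default) or
#'   `"exact"` (Irwin-Hall).
#' @param both_mode `"nested"` (default) or `"flat"`, see [combined_stats()].
#' @param contrasts Named list of [contrast_spec()]s; the default covers
#'   every contrast the classification rules consume.
#' @return List with `size_factors`, `dispersions`, `contrasts` (per-contrast
#'   result tables), `combined`, `classification`, `shared_module`,
#'   `summary` and `settings`.
#' @export
run_pipeline <- function(counts, out_dir = NULL,
                         p_thresh = 0.05, lfc_thresh = 0.58,
                         reversion_delta = 0.5, relaxed_lfc = 0.5,
                         combine_mode = c("paper", "exact"),
                         both_mode = c("nested", "flat"),
                         contrasts = standard_contrasts()) {
  stopifnot(inherits(counts, "count_matrix"))
  combine_mode <- match.arg(combine_mode)
  both_mode <- match.arg(both_mode)
  thresholds <- list(p_thresh = p_thresh, lfc_thresh = lfc_thresh,
                     reversion_delta = reversion_delta,
                     relaxed_lfc = relaxed_lfc)

  de <- run_de(counts, contrasts)
  cs <- combined_stats(de$results, mode = combine_mode,
                       both_mode = both_mode, lfc_thresh = lfc_thresh)
  cls <- classify_genes(cs, thresholds)
  shared <- shared_module_set(cls, relaxed_lfc = relaxed_lfc)
  summary_tab <- summarize_classification(cls)

  out <- list(size_factors = de$size_factors,
              dispersions = de$dispersions,
              contrasts = de$results,
              combined = cs,
              classification = cls,
              shared_module = shared,
              summary = summary_tab,
              settings = c(thresholds,
                           list(combine_mode = combine_mode,
                                both_mode = both_mode)))
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir)
  invisible(out)
}

#' Write pipeline results as deterministic TSVs
#'
#' Layout: `size_factors.tsv`, `contrasts/<name>.tsv`, `classification.tsv`
#' (the long-format table, one row per gene x genotype with every p, lfc
#' and label), `shared_module.tsv`, `summary.tsv` and `settings.tsv`.
#'
#' @param res A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(file.path(out_dir, "contrasts"), recursive = TRUE,
             showWarnings = FALSE)
  write_tsv(data.frame(sample_id = names(res$size_factors),
                       size_factor = unname(res$size_factors),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "size_factors.tsv"))
  for (nm in names(res$contrasts))
    write_tsv(res$contrasts[[nm]],
              file.path(out_dir, "contrasts", paste0(nm, ".tsv")))
  write_tsv(res$classification, file.path(out_dir, "classification.tsv"))
  sm <- res$shared_module
  write_tsv(data.frame(gene_id = c(sm$up, sm$down),
                       direction = rep(c("up", "down"),
                                       c(length(sm$up), length(sm$down))),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "shared_module.tsv"))
  write_tsv(res$summary, file.path(out_dir, "summary.tsv"))
  st <- res$settings
  write_tsv(data.frame(setting = names(st),
                       value = vapply(st, function(x) as.character(x)[1], ""),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "settings.tsv"))
  invisible(out_dir)
}
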