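# Planted gene classes. Basal classes carry a genotype effect at the Cre
# baseline in all three mutant genotypes; "rescued" means ICD reintroduction
# moves the fold change back toward wild type.
SIM_CLASSES <- c("null",
                 "basal_up_rescued_both", "basal_down_rescued_both",
                 "basal_rescued_p19_only", "basal_rescued_d19_only",
                 "basal_not_rescued", "effect_only")

default_class_proportions <- function() {
  c(null = 0.70,
    basal_up_rescued_both = 0.05,
    basal_down_rescued_both = 0.05,
    basal_rescued_p19_only = 0.05,
    basal_rescued_d19_only = 0.05,
    basal_not_rescued = 0.05,
    effect_only = 0.05)
}

#' Configuration for the TRAP-Seq count simulator
#'
#' Defaults describe a realistic, moderately deep bulk TRAP-Seq experiment
#' after standard independent filtering: gene means log-uniform on
#' \[100, 10000\] normalized counts, a DESeq2-style mean-dependent dispersion
#' trend alpha(mu) = a0 + a1/mu with asymptotic biological CV
#' sqrt(a0) ~ 14%, five replicates per group (within the study's 4-9 range),
#' and planted effects of |log2FC| = 1.5 fully reverted by a rescuing ICD.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_group Either a single integer (same for every group)
#'   or a named vector keyed by `"genotype:treatment"` covering the full
#'   4 x 3 grid; every group needs >= 2 replicates.
#' @param baseline_mean_log_range Natural-log bounds for the log-uniform
#'   draw of gene baseline means (normalized scale).
#' @param dispersion_intercept,dispersion_slope Trend coefficients a0, a1 of
#'   alpha(mu) = a0 + a1/mu (both > 0 so alpha > 0 for all mu > 0).
#' @param class_proportions Named fractions over the planted classes,
#'   summing to 1 (tolerance 1e-9).
#' @param lfc_magnitude Planted baseline |log2FC| versus WT (default 1.5).
#' @param rescue_reversion Fraction of the baseline log2FC removed by a
#'   rescuing ICD, in \[0, 1\] (default 1 = full reversion).
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       replicates_per_group = 5,
                       baseline_mean_log_range = c(log(100), log(10000)),
                       dispersion_intercept = 0.02,
                       dispersion_slope = 2,
                       class_proportions = default_class_proportions(),
                       lfc_magnitude = 1.5,
                       rescue_reversion = 1.0,
                       seed = 1L) {
  grid <- as.vector(outer(GENOTYPES, TREATMENTS, paste, sep = ":"))
  if (length(replicates_per_group) == 1L && is.null(names(replicates_per_group))) {
    replicates_per_group <- stats::setNames(rep(as.integer(replicates_per_group),
                                                length(grid)), grid)
  }
  cfg <- list(n_genes = as.integer(n_genes),
              replicates_per_group = replicates_per_group,
              baseline_mean_log_range = baseline_mean_log_range,
              dispersion_intercept = dispersion_intercept,
              dispersion_slope = dispersion_slope,
              class_proportions = class_proportions,
              lfc_magnitude = lfc_magnitude,
              rescue_reversion = rescue_reversion,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  grid <- as.vector(outer(GENOTYPES, TREATMENTS, paste, sep = ":"))
  miss <- setdiff(grid, names(cfg$replicates_per_group))
  if (length(miss))
    stop("replicates_per_group must cover the full 4x3 grid; missing: ",
         paste(miss, collapse = ", "))
  if (any(cfg$replicates_per_group[grid] < 2))
    stop("every (genotype, treatment) group needs >= 2 replicates")
  if (length(cfg$baseline_mean_log_range) != 2 ||
      diff(cfg$baseline_mean_log_range) < 0)
    stop("baseline_mean_log_range must be an increasing pair")
  if (!is.finite(exp(cfg$baseline_mean_log_range[1])) ||
      exp(cfg$baseline_mean_log_range[1]) <= 0)
    stop("baseline means must be positive and finite")
  if (cfg$dispersion_intercept <= 0 || cfg$dispersion_slope <= 0)
    stop("dispersion trend coefficients must be positive so alpha(mu) > 0")
  pr <- cfg$class_proportions
  bad <- setdiff(names(pr), SIM_CLASSES)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(SIM_CLASSES, collapse = ", "))
  if (any(pr < 0)) stop("class proportions must be non-negative")
  if (abs(sum(pr) - 1) > 1e-9)
    stop("class_proportions must sum to 1 (got ", format(sum(pr), digits = 12), ")")
  if (cfg$rescue_reversion < 0 || cfg$rescue_reversion > 1)
    stop("rescue_reversion must be in [0, 1]")
  if (cfg$lfc_magnitude <= 0) stop("lfc_magnitude must be positive")
  invisible(cfg)
}

#' Read a simulator configuration from a JSON key-value file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults. `replicates_per_group` and `class_proportions` may be JSON
#' objects (named maps).
#'
#' @param path JSON file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  raw$replicates_per_group <- if (!is.null(raw$replicates_per_group))
    unlist(raw$replicates_per_group)
  raw$class_proportions <- if (!is.null(raw$class_proportions))
    unlist(raw$class_proportions)
  do.call(sim_config, raw[!vapply(raw, is.null, logical(1))])
}

# Largest-remainder quota so class counts match proportions exactly
# (deterministic, no sampling noise in the class mix).
quota_counts <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    top <- order(frac, seq_along(props), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  base
}

# Expected log2FC (vs WT:Cre) per gene x group for the planted classes.
expected_lfc_matrix <- function(class_label, sign, L, reversion) {
  grid <- as.vector(outer(GENOTYPES, TREATMENTS, paste, sep = ":"))
  n <- length(class_label)
  lfc <- matrix(0, n, length(grid), dimnames = list(NULL, grid))
  resc <- L * (1 - reversion)
  basal <- class_label %in% c("basal_up_rescued_both", "basal_down_rescued_both",
                              "basal_rescued_p19_only", "basal_rescued_d19_only",
                              "basal_not_rescued")
  for (g in MUTANT_GENOTYPES) {
    lfc[basal, paste0(g, ":Cre")] <- sign[basal] * L
    for (icd in ICD_TREATMENTS) {
      col <- paste0(g, ":", icd)
      rescued_here <-
        class_label %in% c("basal_up_rescued_both", "basal_down_rescued_both") |
        (class_label == "basal_rescued_p19_only" & icd == "ICD19") |
        (class_label == "basal_rescued_d19_only" & icd == "ICDd19")
      lfc[basal & rescued_here, col] <- sign[basal & rescued_here] * resc
      lfc[basal & !rescued_here, col] <- sign[basal & !rescued_here] * L
    }
  }
  eff <- class_label == "effect_only"
  for (g in GENOTYPES) for (icd in ICD_TREATMENTS)
    lfc[eff, paste0(g, ":", icd)] <- sign[eff] * L
  lfc
}

#' Simulate a TRAP-Seq experiment with planted ground truth
#'
#' Draws gene baseline means log-uniformly, plants per-class log2 fold
#' changes relative to the `WT:Cre` reference, scales by log-uniform
#' library-size factors in \[0.5, 2\], and generates counts as a
#' gamma-Poisson (negative binomial) mixture with `size = 1/alpha(mu)`,
#' `alpha(mu) = a0 + a1/mu` evaluated at each gene x sample mean.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `truth` (data frame:
#'   `gene_id`, `class`, one `lfc_<genotype>_<treatment>` column per group),
#'   `size_factors` (the planted per-sample scalings) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  grid <- as.vector(outer(GENOTYPES, TREATMENTS, paste, sep = ":"))
  reps <- config$replicates_per_group[grid]

  # samples, in fixed grid order
  samples <- do.call(rbind, lapply(grid, function(g) {
    gt <- strsplit(g, ":", fixed = TRUE)[[1]]
    data.frame(sample_id = sprintf("%s_%s_r%d", gt[1], gt[2],
                                   seq_len(reps[[g]])),
               genotype = gt[1], treatment = gt[2],
               stringsAsFactors = FALSE)
  }))
  group_of <- paste(samples$genotype, samples$treatment, sep = ":")
  n_samp <- nrow(samples)

  # planted classes by exact quota, in fixed gene order
  props <- config$class_proportions
  counts_per_class <- quota_counts(n, props)
  class_label <- rep(names(props), counts_per_class)
  gene_id <- sprintf("gene_%05d", seq_len(n))

  # per-gene effect sign: fixed by label for the up/down rescued classes,
  # random for classes whose direction the rules do not pin down
  sign <- integer(n)
  sign[class_label == "basal_up_rescued_both"] <- 1L
  sign[class_label == "basal_down_rescued_both"] <- -1L
  free <- !(class_label %in% c("null", "basal_up_rescued_both",
                               "basal_down_rescued_both"))
  sign[free] <- sample(c(-1L, 1L), sum(free), replace = TRUE)

  lfc <- expected_lfc_matrix(class_label, sign, config$lfc_magnitude,
                             config$rescue_reversion)
  baseline <- exp(stats::runif(n, config$baseline_mean_log_range[1],
                               config$baseline_mean_log_range[2]))
  size_f <- exp(stats::runif(n_samp, log(0.5), log(2)))
  names(size_f) <- samples$sample_id

  mu <- baseline * 2^lfc[, group_of, drop = FALSE] *
    rep(size_f, each = n)
  if (any(mu <= 0)) stop("non-positive expected count encountered")
  alpha <- config$dispersion_intercept + config$dispersion_slope / mu
  cnt <- matrix(stats::rnbinom(n * n_samp, mu = mu, size = 1 / alpha),
                n, n_samp, dimnames = list(gene_id, samples$sample_id))

  truth <- data.frame(gene_id = gene_id, class = class_label,
                      stringsAsFactors = FALSE)
  colnames(lfc) <- sub(":", "_", paste0("lfc_", colnames(lfc)), fixed = TRUE)
  truth <- cbind(truth, as.data.frame(lfc))

  list(counts = count_matrix(cnt, samples),
       truth = truth,
       size_factors = size_f,
       config = config)
}

#' Write simulation ground truth as TSV
#'
#' @param truth The `truth` data frame from [simulate_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) write_tsv(truth, path)
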