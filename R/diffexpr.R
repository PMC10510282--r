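# Two-group negative-binomial Wald test: a deliberately simple, documented
# stand-in for the DESeq2 stage the downstream combination/classification
# rules were designed around. Median-of-ratios normalization, method-of-
# moments gene-wise dispersions shrunk toward an a0 + a1/mu trend, and a
# delta-method Wald test on the log2 ratio of group means. No log2FC
# shrinkage, no outlier handling, no independent filtering.

#' Median-of-ratios size factors
#'
#' DESeq2-convention normalization: for every gene expressed in all samples,
#' take the ratio of each sample's count to the gene's geometric mean; a
#' sample's factor is the median of its ratios. Factors are rescaled to
#' geometric mean 1.
#'
#' @param counts A [count_matrix()] or a numeric matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has nonzero counts in every sample; filter the count ",
         "matrix to expressed genes before normalization")
  lg <- log(m[pos, , drop = FALSE])
  centered <- lg - rowMeans(lg)
  f <- exp(apply(centered, 2, stats::median))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

#' Gene-wise trended dispersion estimates
#'
#' Method-of-moments dispersion per gene on normalized counts, with
#' variances pooled within `genotype:treatment` groups so planted group
#' effects do not inflate the estimate:
#' `alpha_raw = max(alpha_min, (var - mean)/mean^2)`. A trend
#' `a0 + a1/mean` is fitted across informative genes by least squares and
#' each gene is shrunk 50/50 on the log scale toward the trend. Degenerate
#' genes (zero mean or zero pooled variance) get `alpha_min` outright and
#' are excluded from the trend fit.
#'
#' @param counts A [count_matrix()] (its sample sheet defines the groups).
#' @param factors Size factors from [size_factors()].
#' @param alpha_min Dispersion floor (default 1e-8).
#' @return List with `alpha` (named per-gene vector), `alpha_raw`,
#'   `mean` (per-gene grand mean of normalized counts) and `trend_coef`
#'   (`c(a0, a1)`).
#' @export
estimate_dispersions <- function(counts, factors, alpha_min = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  stopifnot(all(colnames(m) %in% names(factors)))
  norm <- sweep(m, 2, factors[colnames(m)], "/")
  grp <- group_keys(counts)
  groups <- unique(grp)

  gmean <- rowMeans(norm)
  ssq <- numeric(nrow(m))  # pooled within-group sum of squares
  df <- 0L
  for (g in groups) {
    cols <- which(grp == g)
    if (length(cols) < 2) next
    mg <- rowMeans(norm[, cols, drop = FALSE])
    ssq <- ssq + rowSums((norm[, cols, drop = FALSE] - mg)^2)
    df <- df + length(cols) - 1L
  }
  if (df == 0L) stop("need at least one group with >= 2 samples")
  v <- ssq / df

  degenerate <- gmean <= 0 | v <= 0
  alpha_raw <- rep(alpha_min, nrow(m))
  ok <- !degenerate
  alpha_raw[ok] <- pmax(alpha_min, (v[ok] - gmean[ok]) / gmean[ok]^2)

  # trend fit over informative genes; falls back to a flat trend at the
  # median when too few genes or no mean spread
  fit_genes <- ok & alpha_raw > alpha_min
  a0 <- max(alpha_min, stats::median(alpha_raw[ok]))
  a1 <- 0
  if (sum(fit_genes) >= 10 && stats::var(1 / gmean[fit_genes]) > 0) {
    co <- stats::coef(stats::lm(alpha_raw[fit_genes] ~ I(1 / gmean[fit_genes])))
    if (all(is.finite(co))) {
      a0 <- max(co[1], alpha_min)
      a1 <- max(co[2], 0)
    }
  }
  trend <- pmax(alpha_min, a0 + a1 / pmax(gmean, .Machine$double.eps))

  alpha <- alpha_raw
  alpha[ok] <- pmax(alpha_min, exp((log(alpha_raw[ok]) + log(trend[ok])) / 2))
  list(alpha = stats::setNames(alpha, rownames(m)),
       alpha_raw = stats::setNames(alpha_raw, rownames(m)),
       mean = stats::setNames(gmean, rownames(m)),
       trend_coef = c(a0 = unname(a0), a1 = unname(a1)))
}

#' Specify a two-group contrast
#'
#' Convention: `log2fc` reports group B relative to group A, so A is the
#' reference (e.g. A = `WT:Cre`, B = `cKO:Cre` gives the basal cKO effect).
#'
#' @param name Contrast label used in result tables.
#' @param group_a,group_b `"genotype:treatment"` keys or
#'   `c(genotype, treatment)` pairs.
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group_a, group_b) {
  norm_grp <- function(g) {
    if (length(g) == 2) g <- paste(g, collapse = ":")
    gt <- strsplit(g, ":", fixed = TRUE)[[1]]
    if (length(gt) != 2 || !gt[1] %in% GENOTYPES || !gt[2] %in% TREATMENTS)
      stop("invalid group '", g, "'; expected genotype:treatment from the design grid")
    g
  }
  structure(list(name = name, group_a = norm_grp(group_a),
                 group_b = norm_grp(group_b)),
            class = "contrast_spec")
}

#' All contrasts required by the rescue/effect/vWT analysis
#'
#' For each mutant genotype G: the basal contrast `G:Cre` vs `WT:Cre`, the
#' within-genotype ICD contrasts `G:ICD` vs `G:Cre`, and the vs-wild-type
#' ICD contrasts `G:ICD` vs `WT:Cre`; plus the ICD overexpression contrasts
#' within wild type, `WT:ICD` vs `WT:Cre`.
#'
#' @return Named list of [contrast_spec()] objects (17 contrasts).
#' @export
standard_contrasts <- function() {
  cts <- list()
  add <- function(a, b) {
    nm <- paste0(sub(":", ".", b, fixed = TRUE), "_vs_",
                 sub(":", ".", a, fixed = TRUE))
    cts[[nm]] <<- contrast_spec(nm, a, b)
  }
  for (g in MUTANT_GENOTYPES) add(REFERENCE_GROUP, paste0(g, ":Cre"))
  for (g in MUTANT_GENOTYPES) for (icd in ICD_TREATMENTS) {
    add(paste0(g, ":Cre"), paste0(g, ":", icd))
    add(REFERENCE_GROUP, paste0(g, ":", icd))
  }
  for (icd in ICD_TREATMENTS) add(REFERENCE_GROUP, paste0("WT:", icd))
  cts
}

contrast_key <- function(group_b, group_a) {
  paste0(sub(":", ".", group_b, fixed = TRUE), "_vs_",
         sub(":", ".", group_a, fixed = TRUE))
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' Group means are computed on normalized counts; the fold change is
#' `log2fc = log2((mean_b + 0.5)/(mean_a + 0.5))` (pseudocount 0.5 keeps
#' zero-mean genes finite). The standard error comes from the delta method
#' applied to the NB variance `mu + alpha*mu^2` of each group mean, and
#' `p` is the two-sided normal tail of `log2fc/se`. Genes with all-zero
#' counts in both groups are flagged `tested = FALSE` with `p = 1`,
#' `log2fc = 0`. BH-adjusted p-values are reported across tested genes for
#' transparency; downstream classification uses the raw p-values.
#'
#' @param counts A [count_matrix()].
#' @param factors Size factors.
#' @param alphas Per-gene dispersions (e.g. `estimate_dispersions(...)$alpha`).
#' @param contrast A [contrast_spec()]; both groups need >= 2 samples.
#' @return Data frame: `gene_id`, `base_mean`, `log2fc`, `se`, `p`, `padj`,
#'   `tested`, with attribute `"contrast"`.
#' @export
wald_test <- function(counts, factors, alphas, contrast) {
  stopifnot(inherits(counts, "count_matrix"), inherits(contrast, "contrast_spec"))
  m <- counts$counts
  grp <- group_keys(counts)
  ia <- which(grp == contrast$group_a)
  ib <- which(grp == contrast$group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("contrast '", contrast$name, "' needs >= 2 samples per group (",
         contrast$group_a, ": ", length(ia), ", ",
         contrast$group_b, ": ", length(ib), ")")
  f <- factors[colnames(m)]
  alphas <- alphas[rownames(m)]
  norm <- sweep(m, 2, f, "/")

  mean_grp <- function(idx) rowMeans(norm[, idx, drop = FALSE])
  # Var(mean of normalized counts) = (1/n^2) sum_i (mu/s_i + alpha mu^2)
  var_grp <- function(mu, idx) {
    n <- length(idx)
    (mu * sum(1 / f[idx])) / n^2 + alphas * mu^2 / n
  }
  ma <- mean_grp(ia); mb <- mean_grp(ib)
  tested <- rowSums(m[, c(ia, ib), drop = FALSE]) > 0

  log2fc <- log2((mb + 0.5) / (ma + 0.5))
  se2 <- (var_grp(ma, ia) / (ma + 0.5)^2 + var_grp(mb, ib) / (mb + 0.5)^2) /
    log(2)^2
  se <- sqrt(se2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)

  log2fc[!tested] <- 0
  p[!tested] <- 1
  se[!tested] <- NA_real_
  padj <- rep(NA_real_, nrow(m))
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")

  res <- data.frame(gene_id = rownames(m),
                    base_mean = rowMeans(norm[, c(ia, ib), drop = FALSE]),
                    log2fc = log2fc, se = se, p = p, padj = padj,
                    tested = tested, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  res
}

#' Run the differential stage over a set of contrasts
#'
#' @param counts A [count_matrix()].
#' @param contrasts Named list of [contrast_spec()]s
#'   (default [standard_contrasts()]).
#' @param factors,dispersions Optional precomputed normalization/dispersion;
#'   estimated from `counts` when `NULL`.
#' @return List with `size_factors`, `dispersions` and `results` (named list
#'   of per-contrast data frames).
#' @export
run_de <- function(counts, contrasts = standard_contrasts(),
                   factors = NULL, dispersions = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, factors)
  alphas <- if (is.list(dispersions)) dispersions$alpha else dispersions
  results <- lapply(contrasts, function(ct)
    wald_test(counts, factors, alphas, ct))
  names(results) <- vapply(contrasts, `[[`, "", "name")
  list(size_factors = factors, dispersions = dispersions, results = results)
}

#' Validate an externally produced per-contrast result table
#'
#' Lets users substitute real DESeq2 (or other) output for the built-in
#' Wald stand-in: any data frame with `gene_id`, `log2fc` and `p` columns
#' is accepted; `tested` defaults to `TRUE` where `p` is non-missing.
#'
#' @param df Data frame with at least `gene_id`, `log2fc`, `p`.
#' @return Normalized ContrastResult data frame.
#' @export
as_contrast_result <- function(df) {
  req <- c("gene_id", "log2fc", "p")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("contrast table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in contrast table")
  pv <- df$p[!is.na(df$p)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(df$tested)) df$tested <- !is.na(df$p)
  if (is.null(df$base_mean)) df$base_mean <- NA_real_
  if (is.null(df$se)) df$se <- NA_real_
  if (is.null(df$padj)) {
    df$padj <- NA_real_
    df$padj[df$tested] <- stats::p.adjust(df$p[df$tested], method = "BH")
  }
  df[, c("gene_id", "base_mean", "log2fc", "se", "p", "padj", "tested")]
}
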