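# Shared fixture builders: everything is generated in code at test time.

# Tiny valid count matrix with arbitrary entries.
toy_cm <- function(counts = NULL, genotype = c("WT", "WT", "cKO", "cKO"),
                   treatment = rep("Cre", length(genotype))) {
  n_samp <- length(genotype)
  if (is.null(counts)) {
    counts <- matrix(seq_len(3 * n_samp), nrow = 3,
                     dimnames = list(paste0("g", 1:3),
                                     paste0("s", seq_len(n_samp))))
  }
  samples <- data.frame(sample_id = colnames(counts),
                        genotype = genotype, treatment = treatment,
                        stringsAsFactors = FALSE)
  count_matrix(counts, samples)
}

# Two-group null NB matrix (no true differences), WT:Cre vs cKO:Cre.
null_two_group_cm <- function(n_genes, n_per_group, alpha, seed,
                              mu_log_range = c(log(100), log(10000))) {
  set.seed(seed)
  mu <- exp(runif(n_genes, mu_log_range[1], mu_log_range[2]))
  n_samp <- 2 * n_per_group
  cnt <- matrix(rnbinom(n_genes * n_samp, mu = rep(mu, n_samp),
                        size = 1 / alpha),
                n_genes, n_samp,
                dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samp))))
  samples <- data.frame(sample_id = colnames(cnt),
                        genotype = rep(c("WT", "cKO"), each = n_per_group),
                        treatment = "Cre", stringsAsFactors = FALSE)
  list(cm = count_matrix(cnt, samples), mu = mu)
}
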