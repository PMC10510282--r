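test_that("median-of-ratios size factors match hand computations", {
  # identical samples -> all factors 1
  cnt <- matrix(rep(c(10L, 100L, 7L), 3), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  cm <- toy_cm(cnt, genotype = c("WT", "WT", "cKO"))
  expect_equal(unname(size_factors(cm)), rep(1, 3))

  # 2-gene, 2-sample [[10,20],[100,200]] -> factors proportional to (1, 2)
  cnt <- matrix(c(10L, 100L, 20L, 200L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- size_factors(toy_cm(cnt, genotype = c("WT", "cKO")))
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)  # rescaled to geometric mean 1

  # tripling a sample's counts triples its factor relative to the original
  set.seed(1)
  base <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  trip <- cbind(base, s5 = base[, 1] * 3L)
  f <- size_factors(toy_cm(trip, genotype = c("WT", "WT", "cKO", "cKO", "WT")))
  expect_equal(unname(f["s5"] / f["s1"]), 3)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "filter")
})

test_that("dispersion estimation recovers planted overdispersion", {
  # NB genes at alpha = 0.2, mu = 100, n = 50 -> median alpha in [0.1, 0.4]
  set.seed(21)
  cnt <- matrix(rnbinom(300 * 50, mu = 100, size = 5), 300, 50,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:50)))
  cm <- toy_cm(cnt, genotype = rep("WT", 50))
  disp <- estimate_dispersions(cm, size_factors(cm))
  expect_gt(median(disp$alpha), 0.1)
  expect_lt(median(disp$alpha), 0.4)
})

test_that("Poisson and degenerate genes collapse to the dispersion floor", {
  set.seed(22)
  cnt <- matrix(rpois(200 * 40, 100), 200, 40,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:40)))
  cnt[1, ] <- 50L  # constant gene
  cm <- toy_cm(cnt, genotype = rep("WT", 40))
  disp <- estimate_dispersions(cm, rep(1, 40) |> stats::setNames(colnames(cnt)))
  expect_identical(unname(disp$alpha[1]), 1e-8)  # degenerate: floor exactly
  expect_lt(median(disp$alpha[-1]), 0.01)        # Poisson: near the floor
})

test_that("group effects do not leak into within-group dispersion", {
  # two groups with a planted 4x shift; pooling within groups must not
  # register the shift as overdispersion
  set.seed(23)
  cnt <- cbind(matrix(rpois(200 * 10, 50), 200, 10),
               matrix(rpois(200 * 10, 200), 200, 10))
  dimnames(cnt) <- list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:20))
  cm <- toy_cm(cnt, genotype = rep(c("WT", "cKO"), each = 10))
  disp <- estimate_dispersions(cm, stats::setNames(rep(1, 20), colnames(cnt)))
  expect_lt(median(disp$alpha), 0.02)
})

test_that("Wald test handles identity, antisymmetry and untested genes", {
  set.seed(31)
  sim <- null_two_group_cm(150, 4, alpha = 0.1, seed = 31)
  cm <- sim$cm
  cm$counts[1, ] <- 0L  # all-zero gene
  f <- size_factors(cm)
  al <- estimate_dispersions(cm, f)$alpha
  fwd <- wald_test(cm, f, al, contrast_spec("fwd", "WT:Cre", "cKO:Cre"))
  rev <- wald_test(cm, f, al, contrast_spec("rev", "cKO:Cre", "WT:Cre"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p)
  expect_false(fwd$tested[1])
  expect_equal(fwd$p[1], 1)
  expect_equal(fwd$log2fc[1], 0)
  expect_true(all(fwd$p >= 0 & fwd$p <= 1))
  expect_true(all(fwd$se[fwd$tested] > 0))

  # identical groups (samples duplicated) -> log2fc exactly 0, p = 1
  dup <- cbind(cm$counts[, 1:4], cm$counts[, 1:4])
  colnames(dup) <- paste0("d", 1:8)
  cm2 <- toy_cm(dup, genotype = rep(c("WT", "cKO"), each = 4))
  r <- wald_test(cm2, stats::setNames(rep(1, 8), colnames(dup)),
                 al, contrast_spec("id", "WT:Cre", "cKO:Cre"))
  expect_true(all(r$log2fc == 0))
  expect_true(all(r$p == 1))

  expect_error(wald_test(cm, f, al, contrast_spec("bad", "WT:Cre", "WT:ICD19")),
               ">= 2 samples")
})

test_that("large-count limit agrees with a Gaussian z-test on log2 counts", {
  set.seed(32)
  n <- 60
  mu <- 10000
  cnt <- matrix(rnbinom(n * 12, mu = mu, size = 1e4), n, 12,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:12)))
  cm <- toy_cm(cnt, genotype = rep(c("WT", "cKO"), each = 6))
  f <- stats::setNames(rep(1, 12), colnames(cnt))
  al <- stats::setNames(rep(1e-8, n), rownames(cnt))
  r <- wald_test(cm, f, al, contrast_spec("z", "WT:Cre", "cKO:Cre"))
  # independent oracle: two-sample z-test on log2 counts per gene
  lg <- log2(cnt)
  z_oracle <- apply(lg, 1, function(x) {
    a <- x[1:6]; b <- x[7:12]
    (mean(b) - mean(a)) / sqrt(var(a) / 6 + var(b) / 6)
  })
  p_oracle <- 2 * pnorm(abs(z_oracle), lower.tail = FALSE)
  # agreement within order of magnitude on the log10 scale
  expect_lt(median(abs(log10(r$p) - log10(p_oracle))), 1)
})

test_that("power at planted |log2FC| = 1.5 is high for mu >= 50", {
  # balanced planted effects in 20% of genes so normalization stays honest
  set.seed(33)
  n <- 2000; n_rep <- 5
  mu_a <- exp(runif(n, log(50), log(5000)))
  lfc <- rep(0, n)
  planted <- seq_len(n * 0.2)
  lfc[planted] <- rep(c(1.5, -1.5), length.out = length(planted))
  mu_b <- mu_a * 2^lfc
  cnt <- cbind(matrix(rnbinom(n * n_rep, mu = rep(mu_a, n_rep), size = 20),
                      n, n_rep),
               matrix(rnbinom(n * n_rep, mu = rep(mu_b, n_rep), size = 20),
                      n, n_rep))
  dimnames(cnt) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:(2 * n_rep)))
  cm <- toy_cm(cnt, genotype = rep(c("WT", "cKO"), each = n_rep))
  f <- size_factors(cm)
  al <- estimate_dispersions(cm, f)$alpha
  r <- wald_test(cm, f, al, contrast_spec("pw", "WT:Cre", "cKO:Cre"))
  expect_gte(mean(r$p[planted] < 0.05), 0.9)
})

test_that("external DE tables are normalized and validated", {
  ext <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1, -2),
                    p = c(0.01, 0.5))
  out <- as_contrast_result(ext)
  expect_identical(names(out),
                   c("gene_id", "base_mean", "log2fc", "se", "p", "padj",
                     "tested"))
  expect_true(all(out$tested))
  expect_error(as_contrast_result(data.frame(gene_id = "g", p = 0.1)),
               "log2fc")
  expect_error(as_contrast_result(data.frame(gene_id = "g", log2fc = 1,
                                             p = 1.2)), "\\[0, 1\\]")
})
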