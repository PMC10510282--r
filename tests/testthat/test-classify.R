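# Independent rule oracle, coded directly from the published criteria with
# plain scalar if/else logic (no shared code with the implementation).
oracle_rescued <- function(p, base, icd) {
  if (is.na(p) || is.na(base) || is.na(icd)) return(NA)
  if (!(p < 0.05)) return(FALSE)
  if (!(abs(base) > 0.58)) return(FALSE)
  abs(icd) <= abs(base) - 0.5
}
oracle_effected <- function(ep, rp, vs_wt, vs_base) {
  if ((is.na(ep) && is.na(rp)) || is.na(vs_wt) || is.na(vs_base)) return(NA_character_)
  sig <- (!is.na(ep) && ep < 0.05) || (!is.na(rp) && rp < 0.05)
  if (!sig) return("none")
  if (abs(vs_wt) > 0.58 && abs(vs_base) > 0.58) {
    if (vs_base > 0) "up" else "down"
  } else "none"
}
oracle_basal <- function(lfc, p, r1, r2, v1, v2) {
  if (is.na(lfc) || is.na(p)) return(NA_character_)
  ps <- c(p, r1, r2, v1, v2)
  ps <- ps[!is.na(ps)]
  if (abs(lfc) > 0.58 && length(ps) && min(ps) < 0.05) {
    if (lfc > 0) "up" else "down"
  } else "none"
}

test_that("rescue calls match the stated criteria on the exhaustive grid", {
  # (rescue_p, lfc_base, lfc_icd_vs_wt) over the full stated grid
  grid <- expand.grid(p = c(0.01, 0.1),
                      base = c(-1, -0.3, 0.3, 1),
                      icd = c(-1.2, -0.6, 0, 0.6, 1.2))
  got <- classify_rescued(grid$p, grid$base, grid$icd)
  want <- mapply(oracle_rescued, grid$p, grid$base, grid$icd)
  expect_identical(got, unlist(want))
  # spelled-out spot checks
  expect_true(classify_rescued(0.01, 1.0, 0.3))
  expect_false(classify_rescued(0.01, 1.0, 0.7))   # only 0.3 closer to zero
  expect_false(classify_rescued(0.10, 1.0, 0.3))   # p gate
  expect_true(classify_rescued(0.01, 1.0, -0.2))   # overshoot still rescued
  expect_true(is.na(classify_rescued(0.01, NA, 0.3)))
})

test_that("effect calls and directions match the oracle on the grid", {
  grid <- expand.grid(ep = c(0.01, 0.1), rp = c(0.01, 0.1),
                      vs_wt = c(-1, -0.3, 0.3, 1),
                      vs_base = c(-1.2, -0.6, 0, 0.6, 1.2))
  got <- classify_effected(grid$ep, grid$rp, grid$vs_wt, grid$vs_base)
  want <- mapply(oracle_effected, grid$ep, grid$rp, grid$vs_wt, grid$vs_base)
  expect_identical(got, unname(unlist(want)))
  expect_identical(classify_effected(0.04, 1, 0.8, 0.9), "up")
  expect_identical(classify_effected(0.04, 1, 0.8, 0.2), "none")  # magnitude
  expect_identical(classify_effected(1, 0.04, 0.8, -0.9), "down") # rescue route
})

test_that("basal labels follow any available significance route", {
  expect_identical(classify_basal(1.0, 0.20, rescue_p_icd19 = 0.03), "up")
  expect_identical(classify_basal(0.4, 0.001), "none")       # magnitude gate
  expect_identical(classify_basal(-0.9, 0.2, vwt_p_icdd19 = 0.01), "down")
  expect_identical(classify_basal(-0.9, 0.2), "none")
  expect_true(is.na(classify_basal(NA, NA)))
  # random tables against the oracle
  set.seed(71)
  n <- 1000
  lfc <- runif(n, -2, 2)
  p <- runif(n)
  maybe <- function(n) ifelse(runif(n) < 0.3, NA, runif(n))
  r1 <- maybe(n); r2 <- maybe(n); v1 <- maybe(n); v2 <- maybe(n)
  got <- classify_basal(lfc, p, r1, r2, v1, v2)
  want <- unname(mapply(oracle_basal, lfc, p, r1, r2, v1, v2))
  expect_identical(got, want)
})

test_that("rescued implies basal for every gene, genotype and run", {
  for (seed in c(81, 82)) {
    sim <- simulate_experiment(sim_config(n_genes = 400,
                                          replicates_per_group = 3,
                                          seed = seed))
    cls <- classify_genes(combined_stats(run_de(sim$counts)$results))
    rescued_any <- (!is.na(cls$rescued_ICD19) & cls$rescued_ICD19) |
      (!is.na(cls$rescued_ICDd19) & cls$rescued_ICDd19)
    expect_true(all(cls$basal[rescued_any] %in% c("up", "down")))
  }
})

test_that("the relaxed shared module applies the stated rule", {
  mk <- function(lfc, basal) {
    data.frame(gene_id = "g", genotype = c("cKO", "D16p19", "D16d19"),
               lfc_base = lfc, basal = basal, stringsAsFactors = FALSE)
  }
  # significant in cKO only, consistent lfc > 0.5 everywhere -> up-set
  sm <- shared_module_set(mk(c(0.9, 0.55, 0.6), c("up", "none", "none")))
  expect_identical(sm$up, "g")
  expect_identical(sm$down, character(0))
  # sign disagreement -> excluded
  sm <- shared_module_set(mk(c(0.9, 0.55, -0.6), c("up", "none", "none")))
  expect_identical(sm$up, character(0))
  # no genotype significant under full criteria -> excluded
  sm <- shared_module_set(mk(c(0.9, 0.55, 0.6), c("none", "none", "none")))
  expect_identical(sm$up, character(0))
  # magnitude exactly at the relaxed threshold is excluded (strict >)
  sm <- shared_module_set(mk(c(0.9, 0.5, 0.6), c("up", "none", "none")))
  expect_identical(sm$up, character(0))
  # downward module
  sm <- shared_module_set(mk(c(-0.9, -0.55, -0.6), c("down", "none", "none")))
  expect_identical(sm$down, "g")
})

test_that("a planted shared module is recovered on simulation", {
  # 100 genes with strong consistent basal effects across genotypes
  cfg <- sim_config(n_genes = 1000, replicates_per_group = 4,
                    class_proportions = c(null = 0.9,
                                          basal_up_rescued_both = 0.05,
                                          basal_down_rescued_both = 0.05),
                    seed = 91)
  sim <- simulate_experiment(cfg)
  cls <- classify_genes(combined_stats(run_de(sim$counts)$results))
  sm <- shared_module_set(cls)
  planted <- sim$truth$gene_id[sim$truth$class != "null"]
  found <- c(sm$up, sm$down)
  expect_gte(length(intersect(found, planted)), 80)
  expect_lte(length(setdiff(found, planted)) / max(1, length(found)), 0.10)
  # direction agrees with the planted sign
  up_true <- sim$truth$gene_id[sim$truth$class == "basal_up_rescued_both"]
  expect_true(all(sm$up %in% up_true))
})

test_that("classification table is complete, deterministic and consistent", {
  sim <- simulate_experiment(sim_config(n_genes = 200,
                                        replicates_per_group = 3, seed = 95))
  de <- run_de(sim$counts)
  cls <- classify_genes(combined_stats(de$results))
  expect_equal(nrow(cls), 200 * 3)
  expect_identical(cls, classify_genes(combined_stats(de$results)))
  # labels in the table equal labels from individual classify calls
  set.seed(96)
  for (i in sample(nrow(cls), 50)) {
    row <- cls[i, ]
    expect_identical(row$rescued_ICDd19,
                     classify_rescued(row$rescue_p_ICDd19, row$lfc_base,
                                      row$lfc_ICDd19_vs_wt))
    expect_identical(row$effected_ICD19,
                     classify_effected(row$effect_p_ICD19, row$rescue_p_ICD19,
                                       row$lfc_ICD19_vs_wt,
                                       row$lfc_ICD19_vs_base))
    expect_identical(row$basal,
                     classify_basal(row$lfc_base, row$p_base,
                                    row$rescue_p_ICD19, row$rescue_p_ICDd19,
                                    row$vwt_p_ICD19, row$vwt_p_ICDd19))
  }
})

test_that("classification is invariant to gene and sample permutations", {
  sim <- simulate_experiment(sim_config(n_genes = 150,
                                        replicates_per_group = 3, seed = 97))
  cm <- sim$counts
  cls1 <- classify_genes(combined_stats(run_de(cm)$results))
  set.seed(98)
  gperm <- sample(nrow(cm$counts))
  sperm <- sample(ncol(cm$counts))
  cm2 <- count_matrix(cm$counts[gperm, sperm], cm$samples[sperm, ])
  cls2 <- classify_genes(combined_stats(run_de(cm2)$results))
  expect_equal(cls1, cls2)
})
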