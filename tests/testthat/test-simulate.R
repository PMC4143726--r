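test_that("pedigree templates give the expected deterministic structure", {
  cfg <- sim_config(n_pedigrees = 20, generations = 3, sibship = 3,
                    n_marry = 2, seed = 1)
  peds <- simulate_pedigrees(cfg)
  expect_length(peds, 20)
  expect_equal(length(unique(vapply(peds, function(p) p$family_id,
                                    character(1)))), 20L)
  # 2 grandparents + 3 children + 2 spouses + 2 x 3 grandchildren = 13
  expect_equal(nrow(peds[[1]]$members), 13L)
  expect_equal(sum(peds[[1]]$members$founder), 4L)
  # identical under the same config
  peds2 <- simulate_pedigrees(cfg)
  expect_identical(peds, peds2)
  expect_error(sim_config(sibship = 2, n_marry = 3), "template")
  expect_error(sim_config(h2 = 0.8, qtl = list(marker = "M", var_frac = 0.4)),
               "variance budget")
})

test_that("gene dropping is Hardy-Weinberg at the founders and
           Mendelian-consistent with its own descent", {
  cfg <- sim_config(n_pedigrees = 250, generations = 2, sibship = 1,
                    n_marry = 0, seed = 2)
  peds <- simulate_pedigrees(cfg)   # 250 trios -> 500 founders
  gd <- gene_drop(peds, c(M1 = 0.5), seed = 2)
  founders <- unlist(lapply(peds, ped_founders))
  g <- gd$ms$geno[founders, "M1"]
  n <- length(g)
  for (k in 0:2) {
    p0 <- c(0.25, 0.5, 0.25)[k + 1]
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(g == k) - p0), 3 * se + 1e-12)
  }
  # genotypes re-derivable from descent labels and founder types
  for (fam in names(gd$truth$descent$M1)[1:5]) {
    lab <- gd$truth$descent$M1[[fam]]
    ft <- gd$truth$founder_types$M1[[fam]]
    expect_equal(unname(ft[lab[, 1]] + ft[lab[, 2]]),
                 unname(gd$ms$geno[rownames(lab), "M1"]))
  }
  expect_identical(gene_drop(peds, c(M1 = 0.5), seed = 2)$ms$geno,
                   gd$ms$geno)
  expect_error(gene_drop(peds, c(M1 = 0.7)), "\\(0, 0.5]")
})

test_that("a linked marker pair shares descent in proportion to the
           recombination fraction", {
  cfg <- sim_config(n_pedigrees = 60, generations = 3, sibship = 3, seed = 3)
  peds <- simulate_pedigrees(cfg)
  lk <- data.frame(a = 1, b = 2, theta = 0.05)
  gd <- gene_drop(peds, c(Q = 0.3, M = 0.3), linkage = lk, seed = 3)
  # correlations are taken on deviations from the 2*phi prior, since raw
  # sharing co-varies with pair relatedness at any two markers
  kin <- kinship_list(peds)
  dev_cor <- function(gdx) {
    sapply(names(gdx$truth$descent$Q), function(fam) {
      k2 <- 2 * kin[[fam]]
      p1 <- ibd_from_descent(gdx$truth$descent$Q[[fam]]) - k2
      p2 <- ibd_from_descent(gdx$truth$descent$M[[fam]]) - k2
      suppressWarnings(cor(p1[upper.tri(p1)], p2[upper.tri(p2)]))
    })
  }
  expect_gt(mean(dev_cor(gd), na.rm = TRUE), 0.7)
  # and essentially unrelated for an unlinked pair
  gd0 <- gene_drop(peds, c(Q = 0.3, M = 0.3), seed = 3)
  expect_lt(abs(mean(dev_cor(gd0), na.rm = TRUE)), 0.2)
})

test_that("phenotype simulation honours its variance and censoring
           settings", {
  # no genetic signal: sib-pair phenotypic correlation near zero
  cfg0 <- sim_config(n_pedigrees = 150, generations = 2, sibship = 2,
                     h2 = 0, tau_ped = 0, n_exams = 1,
                     censoring = list(enabled = FALSE), seed = 4)
  peds0 <- simulate_pedigrees(cfg0)
  sim0 <- simulate_phenotypes(peds0, cfg0, seed = 4)
  tr <- sim0$truth
  sib1 <- tr$true_sbp1[grepl("_I003$", tr$id)]
  sib2 <- tr$true_sbp1[grepl("_I004$", tr$id)]
  r <- cor(sib1, sib2)
  expect_lt(abs(r), 3 / sqrt(length(sib1)))
  expect_true(all(sim0$records$med == "no"))
  # QTL variance fraction shows up as dosage-regression R^2
  cfgq <- sim_config(n_pedigrees = 100, h2 = 0.2, tau_ped = 0, n_exams = 1,
                     censoring = list(enabled = FALSE), beta_sex = 0,
                     beta_age = 0, beta_smoke = 0,
                     qtl = list(marker = "M1", var_frac = 0.3), seed = 5)
  pedsq <- simulate_pedigrees(cfgq)
  gdq <- gene_drop(pedsq, c(M1 = 0.3), seed = 5)
  r2 <- replicate(5, {
    simq <- simulate_phenotypes(pedsq, cfgq, geno = gdq$ms,
                                seed = sample.int(1e6, 1))
    summary(lm(simq$truth$true_sbp1 ~ gdq$ms$geno[simq$truth$id, "M1"]))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.3), 3 * sd(r2) / sqrt(5) + 0.02)
  # medication marks high underlying values and lowers the observed ones
  cfgc <- sim_config(n_pedigrees = 50, n_exams = 1, seed = 6)
  pedsc <- simulate_pedigrees(cfgc)
  simc <- simulate_phenotypes(pedsc, cfgc, seed = 6)
  med <- simc$records$med == "yes"
  expect_equal(mean(med), 0.3, tolerance = 0.02)
  expect_true(all(simc$records$sbp[med] < simc$truth$true_sbp1[med]))
  expect_gt(mean(simc$truth$true_sbp1[med]), mean(simc$truth$true_sbp1[!med]))
  # byte-reproducible under the seed
  simc2 <- simulate_phenotypes(pedsc, cfgc, seed = 6)
  expect_identical(simc, simc2)
})
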