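test_that("block profile likelihood matches a dense multivariate-normal
           oracle", {
  set.seed(8)
  peds <- list(ped_trio(), ped_sibs(3))
  kin <- kinship_list(peds)
  R <- sim_R_direct(peds, kin, sig2a = 0.5, sig2e = 0.5, seed = 8)
  blocks <- famscan:::vc_blocks(R, peds, kin)
  for (s in list(c(0.4, 0.6), c(1.2, 0.1), c(0, 1))) {
    got <- famscan:::vc_profile_ll_cpp(blocks, s)
    Sl <- lapply(blocks, function(b) s[1] * b$G[[1]] + s[2] * b$G[[2]])
    want <- dense_vc_loglik(lapply(blocks, `[[`, "y"),
                            lapply(blocks, `[[`, "X"), Sl)
    expect_equal(got$loglik, want, tolerance = 1e-8)
  }
})

test_that("polygenic fit pins the additive variance for unrelated
           individuals", {
  founders_only <- lapply(1:30, function(i)
    Pedigree(paste0("u", i), id = paste0("u", i, "_1"),
             father = NA_character_, mother = NA_character_, sex = "male"))
  kin <- kinship_list(founders_only)
  set.seed(3)
  R <- data.frame(id = unlist(lapply(founders_only, ped_ids)),
                  R = rnorm(30, 0, 2))
  fit <- fit_polygenic_null(R, founders_only, kin)
  expect_equal(fit$sigma2_a, 0)
  expect_true(fit$confounded)
  expect_equal(fit$sigma2_e, mean((R$R - mean(R$R))^2), tolerance = 1e-6)
})

test_that("variance estimates are scale-equivariant and the LOD is scale
           invariant", {
  cfg <- sim_config(n_pedigrees = 15, h2 = 0.4, tau_ped = 0, n_exams = 1,
                    censoring = list(enabled = FALSE), beta_sex = 0,
                    beta_age = 0, beta_smoke = 0, seed = 9)
  peds <- simulate_pedigrees(cfg)
  kin <- kinship_list(peds)
  R <- sim_R_direct(peds, kin, sig2a = 0.4, sig2e = 0.6, seed = 9)
  gd <- gene_drop(peds, c(M1 = 0.3), seed = 10)
  ibd <- lapply(gd$truth$descent$M1, ibd_from_descent)
  f1 <- fit_vc_linkage(R, peds, kin, ibd, marker_id = "M1")
  R2 <- transform(R, R = 10 * R)
  f2 <- fit_vc_linkage(R2, peds, kin, ibd, marker_id = "M1")
  expect_equal(f2$sigma2_a, 100 * f1$sigma2_a, tolerance = 2e-2)
  expect_equal(f2$sigma2_e, 100 * f1$sigma2_e, tolerance = 2e-2)
  expect_equal(f2$lod, f1$lod, tolerance = 1e-3)
  expect_gte(f1$loglik_alt, f1$loglik_null)
  expect_gte(f1$lod, 0)
})

test_that("an IBD matrix identical to the kinship prior is confounded and
           scores LOD zero", {
  cfg <- sim_config(n_pedigrees = 10, n_exams = 1,
                    censoring = list(enabled = FALSE), seed = 2)
  peds <- simulate_pedigrees(cfg)
  kin <- kinship_list(peds)
  R <- sim_R_direct(peds, kin, sig2a = 0.4, sig2e = 0.6, seed = 2)
  ibd <- lapply(kin, function(k) 2 * k)
  fit <- fit_vc_linkage(R, peds, kin, ibd, marker_id = "conf")
  expect_identical(fit$lod, 0)
  expect_true(fit$confounded)
})

test_that("polygenic heritability is recovered in simulation", {
  cfg <- sim_config(n_pedigrees = 30, h2 = 0.4, tau_ped = 0, n_exams = 1,
                    censoring = list(enabled = FALSE), seed = 5)
  peds <- simulate_pedigrees(cfg)
  kin <- kinship_list(peds)
  h2 <- replicate(20, {
    R <- sim_R_direct(peds, kin, sig2a = 0.4, sig2e = 0.6)
    fit_polygenic_null(R, peds, kin)$h2
  })
  expect_lt(abs(mean(h2) - 0.4), 3 * sd(h2) / sqrt(length(h2)))
})

test_that("region selection groups, merges and peaks correctly", {
  fits <- data.frame(marker = c("a", "b", "c"), chrom = "3",
                     pos = c(5e6, 6e6, 5e7), lod = c(1.3, 1.25, 0.4))
  reg <- select_regions(fits, lod_threshold = 1.2, merge_bp = 1e7)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$peak_marker, "a")
  expect_equal(reg$start_bp, 5e6)
  expect_equal(reg$end_bp, 6e6)
  expect_equal(reg$n_markers, 2L)
  # nothing above threshold
  low <- transform(fits, lod = c(1.1, 0.9, 0.2))
  expect_equal(nrow(select_regions(low, 1.2, 1e7)), 0L)
  expect_equal(nrow(select_regions(fits[0, ], 1.2, 1e7)), 0L)
  # far-apart markers split into separate regions
  wide <- data.frame(marker = c("a", "b"), chrom = "3",
                     pos = c(1e6, 5e7), lod = c(1.5, 1.4))
  expect_equal(nrow(select_regions(wide, 1.2, 1e7)), 2L)
})

test_that("published two-point LOD values all pass the 1.2 rule they were
           reported under", {
  lods <- c(1.24, 1.25, 1.43, 1.22, 1.23, 1.29, 1.44, 1.24, 1.34, 1.50,
            1.20, 1.25, 1.38, 1.25, 1.63, 1.41, 1.39, 1.30)
  pos <- c(4.51744, 6.28766, 60.64305, 73.18624, 74.10858, 82.55674,
           86.16787, 86.28946, 94.00416, 100.25710, 100.27040, 101.28150,
           108.49870, 151.92760, 152.70880, 153.68720, 166.34160,
           181.11490) * 1e6
  fits <- data.frame(marker = sprintf("t%02d", seq_along(lods)),
                     chrom = "3", pos = pos, lod = lods)
  reg <- select_regions(fits, lod_threshold = 1.2, merge_bp = 1e7)
  expect_equal(sum(reg$n_markers), 18L)
  expect_equal(max(reg$peak_lod), 1.63)
})
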