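test_that("exact IBD reproduces closed-form sharing for simple pairs", {
  sibs <- ped_sibs(2)
  # parent-offspring: exactly one allele IBD by transmission, any data
  for (dos in list(NULL, c(fa = 1L, mo = 1L, s1 = 2L, s2 = 0L))) {
    pi <- compute_ibd_exact(sibs, dos, maf = 0.2)
    expect_equal(pi["fa", "s1"], 0.5)
    expect_equal(pi["mo", "s2"], 0.5)
  }
  # untyped marker: prior expectation = 2 * kinship
  pi0 <- compute_ibd_exact(sibs, maf = 0.3)
  expect_equal(pi0, 2 * compute_kinship(sibs), ignore_attr = TRUE)
  expect_equal(pi0["s1", "s2"], 0.5)
  # both parental transmissions traced: het parents, both sibs hom minor
  pi1 <- compute_ibd_exact(sibs, c(fa = 1L, mo = 1L, s1 = 2L, s2 = 2L),
                           maf = 0.1)
  expect_equal(pi1["s1", "s2"], 1.0)
  # opposite homozygotes from het parents share zero alleles
  pi2 <- compute_ibd_exact(sibs, c(fa = 1L, mo = 1L, s1 = 0L, s2 = 2L),
                           maf = 0.1)
  expect_equal(pi2["s1", "s2"], 0.0)
})

test_that("exact IBD equals brute-force founder-allele enumeration", {
  # untyped, partially typed and fully typed configurations on every
  # fixture pedigree (all of <= 12 members)
  set.seed(41)
  for (p in fixture_peds()) {
    ids <- ped_ids(p)
    gd <- gene_drop(list(p), c(M1 = 0.25), seed = 17)
    full <- gd$ms$geno[ids, "M1"]
    names(full) <- ids
    part <- full
    part[sample(length(part), ceiling(length(part) / 3))] <- NA
    for (dos in list(NULL, part, full)) {
      expect_lt(max(abs(compute_ibd_exact(p, dos, maf = 0.25) -
                          bf_ibd(p, dos, maf = 0.25))), 1e-10)
    }
  }
  # the derived case: full sibs both hom minor, parents untyped
  sibs <- ped_sibs(2)
  dos <- c(s1 = 2L, s2 = 2L)
  expect_lt(max(abs(compute_ibd_exact(sibs, dos, maf = 0.1) -
                      bf_ibd(sibs, dos, maf = 0.1))), 1e-10)
  expect_gt(compute_ibd_exact(sibs, dos, maf = 0.1)["s1", "s2"], 0.5)
})

test_that("Monte-Carlo IBD agrees with exact and is seed-reproducible", {
  p <- ped_3gen()
  gd <- gene_drop(list(p), c(M1 = 0.3), seed = 23)
  dos <- gd$ms$geno[ped_ids(p), "M1"]
  ex <- compute_ibd_exact(p, dos, maf = 0.3)
  mc <- compute_ibd_montecarlo(p, dos, maf = 0.3, n_samples = 20000,
                               seed = 7)
  se <- attr(mc, "se")
  expect_true(all(abs(mc - ex) <= 3 * se + 1e-12))
  mc2 <- compute_ibd_montecarlo(p, dos, maf = 0.3, n_samples = 20000,
                                seed = 7)
  expect_identical(unclass(mc), unclass(mc2))
  # untyped marker: matches the 2*kinship prior within 3 MC s.e.
  mc0 <- compute_ibd_montecarlo(p, maf = 0.3, n_samples = 20000, seed = 11)
  expect_true(all(abs(mc0 - 2 * compute_kinship(p)) <=
                    3 * attr(mc0, "se") + 1e-12))
})

test_that("descent-determining genotypes leave zero Monte-Carlo variance", {
  # het parents with opposite-homozygote sibs pin every transmission, so
  # MC and exact agree exactly and the MC standard error is zero
  sibs <- ped_sibs(2)
  dos <- c(fa = 1L, mo = 1L, s1 = 0L, s2 = 2L)
  mc <- compute_ibd_montecarlo(sibs, dos, maf = 0.2, n_samples = 500,
                               seed = 3)
  ex <- compute_ibd_exact(sibs, dos, maf = 0.2)
  expect_lt(max(abs(mc - ex)), 1e-12)
  expect_equal(max(attr(mc, "se")[c("s1", "s2"), c("s1", "s2")]), 0)
})

test_that("Mendelian inconsistency errors name pedigree and marker, and the
           prior policy blanks to 2*kinship with a warning", {
  trio <- ped_trio()
  bad <- c(fa = 0L, mo = 0L, ch = 2L)
  expect_error(compute_ibd_exact(trio, bad, maf = 0.2, marker_id = "rsX"),
               "trio.*rsX")
  expect_error(compute_ibd_montecarlo(trio, bad, maf = 0.2, n_samples = 200,
                                      seed = 1),
               "trio")
  expect_error(compute_ibd(list(trio), bad, 0.2, mendel_policy = "error"),
               "Mendelian")
  expect_warning(res <- compute_ibd(list(trio), bad, 0.2,
                                    mendel_policy = "prior"),
                 "blanked to prior")
  expect_equal(res$trio, 2 * compute_kinship(trio))
})

test_that("the exact engine defers to Monte Carlo above the state limit", {
  p <- ped_3gen()   # 6 non-founders
  expect_error(compute_ibd_exact(p, maf = 0.3, state_limit = 4^5),
               "compute_ibd_montecarlo")
  res <- compute_ibd(list(p), dosage = NULL, maf = 0.3, state_limit = 4^5,
                     n_samples = 2000, seed = 5)
  expect_false(is.null(attr(res$g3, "se")))   # took the MC path
})

test_that("gene-dropped markers average to the kinship prior", {
  # mean realized IBD over unlinked markers converges to 2*phi
  p <- ped_3gen()
  M <- 400
  gd <- gene_drop(list(p), setNames(rep(0.5, M), sprintf("M%03d", 1:M)),
                  seed = 31)
  ids <- ped_ids(p)
  acc <- matrix(0, length(ids), length(ids))
  acc2 <- acc
  for (m in names(gd$truth$descent)) {
    pim <- ibd_from_descent(gd$truth$descent[[m]]$g3)[ids, ids]
    acc <- acc + pim
    acc2 <- acc2 + pim^2
  }
  mn <- acc / M
  se <- sqrt(pmax(acc2 / M - mn^2, 0) / M)
  expect_true(all(abs(mn - 2 * compute_kinship(p)) <= 3 * se + 1e-12))
})
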