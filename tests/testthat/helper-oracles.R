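# Independent oracles and shared fixtures, implemented without reusing the
# package's computational paths.

# ---- fixture pedigrees (built in code) --------------------------------

ped_trio <- function() {
  Pedigree("trio", id = c("fa", "mo", "ch"), father = c(NA, NA, "fa"),
           mother = c(NA, NA, "mo"),
           sex = c("male", "female", "female"))
}

ped_sibs <- function(k = 2) {
  n <- k + 2
  Pedigree("sibs",
           id = c("fa", "mo", paste0("s", seq_len(k))),
           father = c(NA, NA, rep("fa", k)),
           mother = c(NA, NA, rep("mo", k)),
           sex = c("male", "female",
                   rep(c("male", "female"), length.out = k)))
}

# three generations: grandparents, two children married to founders, three
# grandchildren (10 members, 4 founders)
ped_3gen <- function() {
  Pedigree("g3",
           id = c("gf", "gm", "c1", "c2", "w1", "h2", "x1", "x2", "x3", "x4"),
           father = c(NA, NA, "gf", "gf", NA, NA, "c1", "c1", "h2", "h2"),
           mother = c(NA, NA, "gm", "gm", NA, NA, "w1", "w1", "c2", "c2"),
           sex = c("male", "female", "male", "female", "female", "male",
                   "male", "female", "male", "female"))
}

# first cousins: the x-children of ped_3gen across the two sibships
# 12 members, 5 founders, 7 non-founders (4th generation via y1)
ped_12 <- function() {
  Pedigree("p12",
           id = c("gf", "gm", "c1", "c2", "w1", "h2", "x1", "x2", "x3",
                  "x4", "w3", "y1"),
           father = c(NA, NA, "gf", "gf", NA, NA, "c1", "c1", "h2", "h2",
                      NA, "x1"),
           mother = c(NA, NA, "gm", "gm", NA, NA, "w1", "w1", "c2", "c2",
                      NA, "w3"),
           sex = c("male", "female", "male", "female", "female", "male",
                   "male", "female", "male", "female", "female", "male"))
}

# full-sib mating: offspring of sib x sib (inbred, f = 1/4)
ped_inbred <- function() {
  Pedigree("inb", id = c("fa", "mo", "s1", "s2", "k"),
           father = c(NA, NA, "fa", "fa", "s1"),
           mother = c(NA, NA, "mo", "mo", "s2"),
           sex = c("male", "female", "male", "female", "male"))
}

fixture_peds <- function() {
  list(ped_trio(), ped_sibs(2), ped_sibs(3), ped_3gen(), ped_inbred(),
       ped_12())
}

# ---- brute-force single-marker IBD oracle -----------------------------
# Enumerates founder-allele type vectors and transmission vectors directly,
# computing genotypes forward and realized sharing from the labels; no
# graph colouring, no shared code with the package engine.
bf_ibd <- function(ped, dosage = NULL, maf = 0.5) {
  m <- ped$members
  n <- nrow(m)
  ord <- ped$topo
  fi <- ped$father_idx
  mi <- ped$mother_idx
  founders <- which(m$founder)
  nonf <- ord[!ord %in% founders]
  FN <- length(founders)
  NF <- length(nonf)
  nall <- 2L * FN
  obs <- rep(NA_integer_, n)
  if (!is.null(dosage)) obs <- as.integer(dosage[m$id])
  # all founder-allele type vectors with Hardy-Weinberg weights
  Tm <- as.matrix(expand.grid(rep(list(0:1), nall)))
  wT <- apply(Tm, 1, function(t) prod(ifelse(t == 1, maf, 1 - maf)))
  lab0 <- matrix(0L, n, 2)
  lab0[founders, 1] <- 2L * seq_len(FN) - 1L
  lab0[founders, 2] <- 2L * seq_len(FN)
  num <- matrix(0, n, n)
  W <- 0
  for (v in 0:(4^NF - 1)) {
    bits <- (v %/% 4^(seq_len(NF) - 1)) %% 4
    lab <- lab0
    for (k in seq_len(NF)) {
      j <- nonf[k]
      lab[j, 1] <- lab[fi[j], bits[k] %% 2 + 1]
      lab[j, 2] <- lab[mi[j], bits[k] %/% 2 + 1]
    }
    G <- Tm[, lab[, 1], drop = FALSE] + Tm[, lab[, 2], drop = FALSE]
    keep <- rep(TRUE, nrow(Tm))
    for (i in which(!is.na(obs))) keep <- keep & (G[, i] == obs[i])
    wv <- sum(wT[keep])
    if (wv == 0) next
    pi_v <- matrix(0, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        pi_v[i, j] <- 0.5 * (sum(lab[i, 1] == lab[j, ]) +
                               sum(lab[i, 2] == lab[j, ]))
    num <- num + wv * pi_v
    W <- W + wv
  }
  if (W == 0) stop("oracle: inconsistent genotypes")
  out <- num / W
  dimnames(out) <- list(m$id, m$id)
  out
}

# ---- Monte-Carlo gene-dropping kinship oracle -------------------------
# phi_ij estimated as the probability that one allele drawn at random from
# i and one from j are copies of the same founder allele; vectorised over
# replicates.
mc_kinship <- function(ped, nrep = 50000, seed = 1) {
  set.seed(seed)
  m <- ped$members
  n <- nrow(m)
  ord <- ped$topo
  fi <- ped$father_idx
  mi <- ped$mother_idx
  L1 <- matrix(0L, nrep, n)
  L2 <- matrix(0L, nrep, n)
  nal <- 0L
  for (j in ord) {
    if (is.na(fi[j])) {
      L1[, j] <- nal + 1L
      L2[, j] <- nal + 2L
      nal <- nal + 2L
    } else {
      pick1 <- runif(nrep) < 0.5
      pick2 <- runif(nrep) < 0.5
      L1[, j] <- ifelse(pick1, L1[, fi[j]], L2[, fi[j]])
      L2[, j] <- ifelse(pick2, L1[, mi[j]], L2[, mi[j]])
    }
  }
  phi <- matrix(0, n, n)
  se <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in i:n) {
      x <- ((L1[, i] == L1[, j]) + (L1[, i] == L2[, j]) +
              (L2[, i] == L1[, j]) + (L2[, i] == L2[, j])) / 4
      phi[i, j] <- phi[j, i] <- mean(x)
      se[i, j] <- se[j, i] <- sd(x) / sqrt(nrep)
    }
  dimnames(phi) <- dimnames(se) <- list(m$id, m$id)
  list(phi = phi, se = se)
}

# ---- dense multivariate-normal log-likelihood oracle ------------------
# direct evaluation via solve() and determinant(), with GLS beta computed
# by ordinary matrix algebra
dense_vc_loglik <- function(yl, Xl, Sl) {
  XtSiX <- 0; XtSiy <- 0
  for (b in seq_along(yl)) {
    Si <- solve(Sl[[b]])
    XtSiX <- XtSiX + t(Xl[[b]]) %*% Si %*% Xl[[b]]
    XtSiy <- XtSiy + t(Xl[[b]]) %*% Si %*% yl[[b]]
  }
  beta <- solve(XtSiX, XtSiy)
  ll <- 0
  for (b in seq_along(yl)) {
    r <- yl[[b]] - Xl[[b]] %*% beta
    Si <- solve(Sl[[b]])
    ld <- as.numeric(determinant(Sl[[b]], logarithm = TRUE)$modulus)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) + ld +
                        t(r) %*% Si %*% r)
  }
  as.numeric(ll)
}

# quick direct trait simulator on the R scale (for genetic-phase tests):
# R = qtl effect + polygenic (2*Phi*sig2a) + N(0, sig2e)
sim_R_direct <- function(peds, kin, sig2a, sig2e, qtl_dos = NULL,
                         qtl_beta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(peds, function(p) {
    ids <- ped_ids(p)
    n <- length(ids)
    a <- if (sig2a > 0)
      as.numeric(crossprod(chol(2 * kin[[p$family_id]] + diag(1e-10, n)),
                           rnorm(n))) * sqrt(sig2a)
    else numeric(n)
    q <- if (!is.null(qtl_dos)) qtl_beta * as.numeric(qtl_dos[ids]) else 0
    data.frame(id = ids, R = a + q + rnorm(n, 0, sqrt(sig2e)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
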