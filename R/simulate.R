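#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic pedigree study
#' generator.  The defaults emulate a family study of systolic blood
#' pressure: multiple multigeneration pedigrees, up to four exams with
#' exam-specific age, sex and smoking covariates, antihypertensive
#' medication acting as right-censoring correlated with high underlying
#' SBP, a polygenic background, and optional causal QTLs and population
#' stratification.
#'
#' @param n_pedigrees number of pedigrees (default 20).
#' @param generations,sibship,n_marry pedigree template: number of
#'   generations, children per couple, and how many children per sibship
#'   marry (a married-in founder spouse) and reproduce.
#' @param n_exams exams per individual (default 3; at most 4).
#' @param sigma_total per-exam standard deviation (mmHg) of the
#'   non-covariate trait part (QTL + polygenic + exam noise), default 15.
#' @param h2 polygenic fraction of `sigma_total^2` (default 0.4).
#' @param qtl `NULL` or list with `marker` (name in the gene-dropped set)
#'   and `var_frac` (fraction of `sigma_total^2` explained) or `beta`
#'   (mmHg per minor allele).
#' @param tau_ped pedigree random-intercept standard deviation (mmHg),
#'   default 5.
#' @param intercept,beta_sex,beta_age,beta_smoke fixed effects (mmHg; sex
#'   effect is for males, age per year), defaults 115, 5, 0.5, 5.
#' @param smoke_prev smoking prevalence (default 0.25).
#' @param base_age,age_step,exam_spacing age model: age at exam 1 equals
#'   `base_age - age_step * generation_depth` plus jitter; exams are
#'   `exam_spacing` years apart.
#' @param censoring list: `enabled`, `threshold_q` (quantile of true SBP
#'   above which medication may be assigned, default 0.7), `p_med`
#'   (medication probability above the threshold, default 1), `p_base`
#'   (below, default 0), `effect_meanlog`, `effect_sdlog` (lognormal
#'   treatment effect subtracted from the true value of medicated exams),
#'   `assignment`: `"threshold_quantile"` (default; medication probability
#'   steps up above the threshold quantile of true SBP) or `"random"`
#'   (Bernoulli `p_med` everywhere, i.e. fully noninformative assignment,
#'   used in calibration checks);
#'   and `observed`: `"treated"` (default; observed = true minus treatment
#'   effect) or `"threshold"` (observed = the censoring bound itself,
#'   classical Type-I censoring under which the censored-normal likelihood
#'   is exactly specified -- used for estimator calibration checks).
#' @param strat list: `n_strata` (default 1 = homogeneous), `maf` (vector
#'   of stratum allele frequencies for stratified markers), `shift` (vector
#'   of stratum trait mean shifts, mmHg); whole pedigrees are assigned to
#'   strata round-robin.
#' @param seed base seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pedigrees = 20, generations = 3, sibship = 3,
                       n_marry = 2, n_exams = 3, sigma_total = 15,
                       h2 = 0.4, qtl = NULL, tau_ped = 5, intercept = 115,
                       beta_sex = 5, beta_age = 0.5, beta_smoke = 5,
                       smoke_prev = 0.25, base_age = 65, age_step = 22,
                       exam_spacing = 2,
                       censoring = list(enabled = TRUE, threshold_q = 0.7,
                                        p_med = 1, p_base = 0,
                                        effect_meanlog = log(10),
                                        effect_sdlog = 0.3),
                       strat = list(n_strata = 1, maf = NULL, shift = 0),
                       seed = 1L) {
  qtl_frac <- if (is.null(qtl)) 0 else qtl$var_frac %||% NA_real_
  if (!is.na(qtl_frac) && (qtl_frac < 0 || qtl_frac > 1))
    stop("qtl var_frac must be in [0, 1]")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  if (!is.na(qtl_frac) && h2 + qtl_frac > 1)
    stop("variance budget exceeded: h2 + qtl var_frac > 1")
  if (n_exams < 1 || n_exams > 4) stop("n_exams must be in 1..4")
  if (generations < 2) stop("pedigree template needs >= 2 generations")
  if (sibship < 1 || n_marry < 0 || n_marry > sibship)
    stop("impossible pedigree template: need 0 <= n_marry <= sibship")
  structure(list(n_pedigrees = n_pedigrees, generations = generations,
                 sibship = sibship, n_marry = n_marry, n_exams = n_exams,
                 sigma_total = sigma_total, h2 = h2, qtl = qtl,
                 tau_ped = tau_ped, intercept = intercept,
                 beta_sex = beta_sex, beta_age = beta_age,
                 beta_smoke = beta_smoke, smoke_prev = smoke_prev,
                 base_age = base_age, age_step = age_step,
                 exam_spacing = exam_spacing, censoring = censoring,
                 strat = strat, seed = seed),
            class = "sim_config")
}

#' Simulate pedigree structures
#'
#' Builds `n_pedigrees` non-inbred multigeneration pedigrees from the
#' template in `cfg`: a founding couple, `sibship` children per couple, the
#' first `n_marry` children of each sibship marrying a married-in founder
#' spouse and reproducing, for `generations` generations.  The structure is
#' deterministic given the template; IDs are globally unique
#' (`F<ped>_I<member>`).
#'
#' @param cfg a [sim_config].
#' @return list of [Pedigree] objects.
#' @export
simulate_pedigrees <- function(cfg) {
  out <- vector("list", cfg$n_pedigrees)
  for (f in seq_len(cfg$n_pedigrees)) {
    fam <- sprintf("F%02d", f)
    nid <- 0L
    newid <- function() {
      nid <<- nid + 1L
      sprintf("%s_I%03d", fam, nid)
    }
    id <- character(0); father <- character(0); mother <- character(0)
    sex <- character(0)
    add <- function(s, fa = NA_character_, mo = NA_character_) {
      i <- newid()
      id <<- c(id, i); father <<- c(father, fa); mother <<- c(mother, mo)
      sex <<- c(sex, s)
      i
    }
    pa <- add("male"); ma <- add("female")
    couples <- list(c(pa, ma))
    for (g in seq_len(cfg$generations - 1L)) {
      nxt <- list()
      for (cp in couples) {
        kids <- character(cfg$sibship)
        for (k in seq_len(cfg$sibship))
          kids[k] <- add(if (k %% 2 == 1) "male" else "female",
                         fa = cp[1], mo = cp[2])
        if (g < cfg$generations - 1L) {
          for (k in seq_len(cfg$n_marry)) {
            ksex <- if (k %% 2 == 1) "male" else "female"
            sp <- add(if (ksex == "male") "female" else "male")
            nxt[[length(nxt) + 1L]] <-
              if (ksex == "male") c(kids[k], sp) else c(sp, kids[k])
          }
        }
      }
      couples <- nxt
    }
    out[[f]] <- Pedigree(fam, id, father, mother, sex)
  }
  names(out) <- vapply(out, function(p) p$family_id, character(1))
  out
}

#' Gene-drop genotypes through pedigrees
#'
#' Assigns each founder two uniquely labelled alleles with Hardy-Weinberg
#' minor-allele types at the marker's frequency, transmits alleles by
#' Mendelian sampling, and records the full descent paths.  Markers are
#' unlinked unless `linkage` specifies pairs: for a pair `(a, b, theta)`
#' marker `b` reuses marker `a`'s transmission choices, flipping each with
#' recombination probability `theta` (creating "linked but not associated"
#' scenarios; the founder allele types remain independent, i.e. linkage
#' equilibrium).
#'
#' @param peds list of [Pedigree] objects.
#' @param mafs numeric vector of founder minor allele frequencies in
#'   `(0, 0.5]`; names become marker names (default `M0001`, ...).
#' @param chrom,start_bp,spacing_bp map coordinates assigned to the markers.
#' @param linkage optional data.frame with columns `a`, `b`, `theta`
#'   (marker indices and recombination fraction).
#' @param maf_by_ped optional markers x pedigrees matrix of founder allele
#'   frequencies overriding `mafs` per pedigree (population stratification).
#' @param seed integer seed.
#' @return list with `ms` (a [marker_set]) and `truth`: per-marker,
#'   per-pedigree descent label matrices (`descent[[marker]][[fam]]`, rows =
#'   members, columns = the two allele slots) and the founder allele types.
#' @export
gene_drop <- function(peds, mafs, chrom = "3", start_bp = 1e6,
                      spacing_bp = 1e5, linkage = NULL, maf_by_ped = NULL,
                      seed = NULL) {
  if (any(mafs <= 0 | mafs > 0.5)) stop("mafs must lie in (0, 0.5]")
  M <- length(mafs)
  if (is.null(names(mafs))) names(mafs) <- sprintf("M%04d", seq_len(M))
  mnames <- names(mafs)
  with_seed(seed, {
    all_ids <- unlist(lapply(peds, ped_ids), use.names = FALSE)
    geno <- matrix(NA_integer_, length(all_ids), M,
                   dimnames = list(all_ids, mnames))
    descent <- lapply(mnames, function(m) vector("list", length(peds)))
    names(descent) <- mnames
    types <- descent
    for (pi in seq_along(peds)) {
      ped <- peds[[pi]]
      fam <- ped$family_id
      n <- nrow(ped$members)
      ord <- ped$topo
      fi <- ped$father_idx
      mi <- ped$mother_idx
      founders <- which(ped$members$founder)
      lab <- matrix(0L, n, 2)
      lab[founders, 1] <- 2L * seq_along(founders) - 1L
      lab[founders, 2] <- 2L * seq_along(founders)
      nall <- 2L * length(founders)
      nonf <- ord[!ord %in% founders]
      prev_bits <- NULL
      for (m in seq_len(M)) {
        p <- if (!is.null(maf_by_ped)) maf_by_ped[m, pi] else mafs[m]
        ft <- rbinom(nall, 1, p)
        lk <- if (!is.null(linkage)) linkage[linkage$b == m, , drop = FALSE]
        else NULL
        if (!is.null(lk) && nrow(lk) == 1L && !is.null(prev_bits[[lk$a]])) {
          bits <- prev_bits[[lk$a]]
          flip <- matrix(runif(length(bits)) < lk$theta, nrow(bits))
          bits <- (bits + flip) %% 2
        } else {
          bits <- matrix(as.integer(runif(2 * length(nonf)) < 0.5),
                         ncol = 2)
        }
        if (is.null(prev_bits)) prev_bits <- vector("list", M)
        prev_bits[[m]] <- bits
        labm <- lab
        for (k in seq_along(nonf)) {
          j <- nonf[k]
          labm[j, 1] <- labm[fi[j], bits[k, 1] + 1L]
          labm[j, 2] <- labm[mi[j], bits[k, 2] + 1L]
        }
        rownames(labm) <- ped$members$id
        descent[[m]][[pi]] <- labm
        types[[m]][[pi]] <- ft
        geno[ped$members$id, m] <- ft[labm[, 1]] + ft[labm[, 2]]
      }
    }
    for (m in mnames) names(descent[[m]]) <-
      vapply(peds, function(p) p$family_id, character(1))
    for (m in mnames) names(types[[m]]) <- names(descent[[m]])
    info <- data.frame(marker = mnames, chrom = chrom,
                       pos = as.integer(start_bp +
                                          spacing_bp * (seq_len(M) - 1L)),
                       true_maf = unname(mafs), stringsAsFactors = FALSE)
    list(ms = marker_set(geno, info),
         truth = list(descent = descent, founder_types = types))
  })
}

#' Realized IBD sharing from recorded descent
#'
#' For a fully informative view of a gene-dropped marker, the realized
#' proportion of alleles shared IBD for every pair is computed directly
#' from the descent labels: `pi_ij = (1/2) sum_kl 1{a_ik == a_jl}` (diagonal
#' `1 + f`).
#'
#' @param labm descent label matrix for one pedigree (rows = members,
#'   2 columns), as in `gene_drop()$truth$descent[[marker]][[fam]]`.
#' @return Symmetric realized-sharing matrix with member IDs as dimnames.
#' @export
ibd_from_descent <- function(labm) {
  n <- nrow(labm)
  m1 <- outer(labm[, 1], labm[, 1], "==") + outer(labm[, 1], labm[, 2], "==")
  m2 <- outer(labm[, 2], labm[, 1], "==") + outer(labm[, 2], labm[, 2], "==")
  pi <- 0.5 * (m1 + m2)
  dimnames(pi) <- list(rownames(labm), rownames(labm))
  pi
}

#' Simulate longitudinal phenotypes over pedigrees
#'
#' Generates exam records under the model the analysis assumes: true SBP at
#' exam e is
#' `intercept + beta_sex male + beta_age age_e + beta_smoke smoke + QTL
#' effect x dosage + polygenic value + pedigree shift + stratum shift +
#' exam noise`,
#' where the polygenic values are multivariate normal with covariance
#' `2 Phi sigma_a^2` per pedigree.  Medication is assigned per the
#' censoring spec (probability increasing in the true value above a
#' threshold quantile) and the observed SBP of a medicated exam is the true
#' value minus a positive lognormal treatment effect, so medication behaves
#' as right-censoring of the underlying trait.
#'
#' @param peds list of [Pedigree] objects.
#' @param cfg a [sim_config].
#' @param geno optional [marker_set] holding the QTL marker's dosages
#'   (required when `cfg$qtl` is set).
#' @param kin optional precomputed kinship list.
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `records` (data.frame `id, fam, exam, sbp, age, sex,
#'   smoke, med`) and `truth` (data.frame `id, fam, genetic_value,
#'   qtl_value, polygenic, ped_shift, stratum`, plus per-exam true SBP
#'   columns `true_sbp1`...).
#' @export
simulate_phenotypes <- function(peds, cfg, geno = NULL, kin = NULL,
                                seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(kin)) kin <- kinship_list(peds)
  s2 <- cfg$sigma_total^2
  qtl_frac <- 0
  qtl_beta <- 0
  qtl_dos <- NULL
  if (!is.null(cfg$qtl)) {
    if (is.null(geno)) stop("cfg$qtl set but no genotypes supplied")
    mk <- cfg$qtl$marker
    if (!mk %in% colnames(geno$geno)) stop("QTL marker not in genotype set")
    qtl_dos <- geno$geno[, mk]
    qtl_maf <- cfg$qtl$maf %||% mean(qtl_dos, na.rm = TRUE) / 2
    if (!is.null(cfg$qtl$beta)) {
      qtl_beta <- cfg$qtl$beta
      qtl_frac <- qtl_beta^2 * 2 * qtl_maf * (1 - qtl_maf) / s2
    } else {
      qtl_frac <- cfg$qtl$var_frac
      qtl_beta <- sqrt(qtl_frac * s2 / (2 * qtl_maf * (1 - qtl_maf)))
    }
    if (cfg$h2 + qtl_frac > 1)
      stop("variance budget exceeded: h2 + QTL fraction > 1")
  }
  sig_a <- sqrt(cfg$h2 * s2)
  sig_e <- sqrt(max(1 - cfg$h2 - qtl_frac, 0) * s2)
  with_seed(seed, {
    tr_rows <- list()
    rec_rows <- list()
    nstr <- cfg$strat$n_strata %||% 1
    for (pi in seq_along(peds)) {
      ped <- peds[[pi]]
      fam <- ped$family_id
      ids <- ped_ids(ped)
      n <- length(ids)
      stratum <- ((pi - 1L) %% nstr) + 1L
      a <- if (sig_a > 0) {
        L <- chol(2 * kin[[fam]] + diag(1e-10, n))
        as.numeric(crossprod(L, rnorm(n))) * sig_a
      } else numeric(n)
      qv <- if (!is.null(qtl_dos)) {
        # centred at the population mean dosage, not the pedigree mean,
        # so between-family QTL variance is retained
        qtl_beta * (qtl_dos[ids] - 2 * qtl_maf)
      } else numeric(n)
      shift <- rnorm(1, 0, cfg$tau_ped) +
        (cfg$strat$shift %||% 0)[min(stratum, length(cfg$strat$shift))]
      depth <- ped_generation_depth(ped)
      age1 <- cfg$base_age - cfg$age_step * depth + runif(n, -3, 3)
      smoke <- rbinom(n, 1, cfg$smoke_prev)
      male <- as.numeric(ped$members$sex == "male")
      tr <- data.frame(id = ids, fam = fam, genetic_value = a + qv,
                       qtl_value = qv, polygenic = a, ped_shift = shift,
                       stratum = stratum, stringsAsFactors = FALSE)
      for (e in seq_len(cfg$n_exams)) {
        age <- age1 + (e - 1) * cfg$exam_spacing
        eps <- rnorm(n, 0, sig_e)
        true_sbp <- cfg$intercept + cfg$beta_sex * male +
          cfg$beta_age * age + cfg$beta_smoke * smoke + a + qv + shift + eps
        tr[[paste0("true_sbp", e)]] <- true_sbp
        rec_rows[[length(rec_rows) + 1L]] <-
          data.frame(id = ids, fam = fam, exam = e, sbp = true_sbp,
                     age = age, sex = ifelse(male == 1, "male", "female"),
                     smoke = ifelse(smoke == 1, "yes", "no"), med = "no",
                     stringsAsFactors = FALSE)
      }
      tr_rows[[pi]] <- tr
    }
    records <- do.call(rbind, rec_rows)
    truth <- do.call(rbind, tr_rows)
    cs <- cfg$censoring
    if (isTRUE(cs$enabled)) {
      thr <- quantile(records$sbp, cs$threshold_q %||% 0.7)
      pmed <- if ((cs$assignment %||% "threshold_quantile") == "random")
        rep(cs$p_med %||% 0.3, nrow(records))   # noninformative assignment
      else ifelse(records$sbp > thr, cs$p_med %||% 1, cs$p_base %||% 0)
      med <- runif(nrow(records)) < pmed
      records$med[med] <- "yes"
      if ((cs$observed %||% "treated") == "threshold") {
        # classical Type-I censoring: the bound itself is observed, so the
        # censored-normal likelihood is exactly specified (calibration use)
        records$sbp[med] <- thr
      } else {
        # realistic mechanism: treatment lowers the observed value by a
        # positive lognormal effect (observed < underlying, as the
        # censoring model assumes, but the bound is stochastic)
        effect <- rlnorm(sum(med), cs$effect_meanlog %||% log(10),
                         cs$effect_sdlog %||% 0.3)
        records$sbp[med] <- records$sbp[med] - effect
      }
    }
    rownames(records) <- NULL
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

# generation depth per member: founders with children take the depth just
# above their eldest child; initial founders are 0
ped_generation_depth <- function(ped) {
  n <- nrow(ped$members)
  depth <- rep(0L, n)
  for (j in ped$topo)
    if (!is.na(ped$father_idx[j]))
      depth[j] <- max(depth[ped$father_idx[j]], depth[ped$mother_idx[j]]) + 1L
  for (j in which(ped$members$founder)) {
    ch <- which(ped$father_idx == j | ped$mother_idx == j)
    if (length(ch)) depth[j] <- min(depth[ch]) - 1L
  }
  depth
}

#' Export a simulated study to the pipeline's file formats
#'
#' Writes ped, phenotype CSV, genotype matrix + map, and a truth JSON, the
#' same formats the pipeline consumes.
#'
#' @param peds list of [Pedigree] objects.
#' @param records exam records from [simulate_phenotypes].
#' @param ms a [marker_set].
#' @param truth truth object (serialisable parts are written).
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(peds, records, ms, truth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(peds, file.path(dir, "pedigree.ped"))
  utils::write.table(records[c("id", "exam", "sbp", "age", "sex", "smoke",
                               "med", "fam")],
                     file.path(dir, "phenotypes.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  write_marker_matrix(ms, file.path(dir, "genotypes.txt"),
                      file.path(dir, "genotypes.map"))
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
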