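#' Between/within-family decomposition of marker genotypes
#'
#' Splits each individual's minor-allele dosage `g` into a between-family
#' component `b` and a within-family component `w = g - b` (so `b + w = g`
#' exactly).  `b` is the parental-mean dosage when both parents are
#' genotyped; otherwise the mean dosage among the genotyped members of the
#' individual's sibship cluster (same father and mother, including self);
#' otherwise the individual's own `g` (making `w = 0`, which carries no
#' within-family information).  Individuals with missing genotype are
#' excluded.
#'
#' @param dosage named integer vector of dosages (0/1/2/NA).
#' @param peds list of [Pedigree] objects.
#' @return data.frame with columns `id`, `fam`, `g`, `b`, `w`, `cluster`
#'   (`"parental"`, `"sibship"` or `"self"`).
#' @export
decompose_genotype <- function(dosage, peds) {
  rows <- list()
  for (p in peds) {
    m <- p$members
    ids <- m$id[m$id %in% names(dosage)]
    g <- dosage[ids]
    ids <- ids[!is.na(g)]
    if (!length(ids)) next
    g <- as.numeric(dosage[ids])
    names(g) <- ids
    sub <- m[match(ids, m$id), , drop = FALSE]
    b <- numeric(length(ids))
    cluster <- character(length(ids))
    sibkey <- paste(sub$father, sub$mother, sep = "|")
    for (i in seq_along(ids)) {
      fa <- sub$father[i]; mo <- sub$mother[i]
      if (!is.na(fa) && fa %in% ids && mo %in% ids) {
        b[i] <- (g[fa] + g[mo]) / 2
        cluster[i] <- "parental"
      } else if (!is.na(fa)) {
        sibs <- ids[sibkey == sibkey[i]]
        b[i] <- mean(g[sibs])
        cluster[i] <- if (length(sibs) > 1) "sibship" else "self"
      } else {
        b[i] <- g[i]
        cluster[i] <- "self"
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(id = ids, fam = p$family_id, g = g, b = b, w = g - b,
                 cluster = cluster, stringsAsFactors = FALSE,
                 row.names = NULL)
  }
  if (!length(rows)) stop("no genotyped individuals at this marker")
  do.call(rbind, rows)
}

# shared fitting core for MG / QTDT: LRT of the last column(s) of X1 vs X0
assoc_lrt <- function(R, peds, kin, X1, X0, ibd = NULL) {
  K <- if (is.null(ibd)) 2L else 3L
  b1 <- vc_blocks(R, peds, kin, ibd = ibd, X = X1)
  b0 <- vc_blocks(R, peds, kin, ibd = ibd, X = X0)
  f1 <- vc_ml(b1, K, restarts = 1)
  f0 <- vc_ml(b0, K, restarts = 1)
  ll1 <- max(f1$loglik, f0$loglik)   # alternative nests the null
  stat <- 2 * (ll1 - f0$loglik)
  list(p = pchisq(stat, df = 1, lower.tail = FALSE),
       stat = stat, fit1 = f1, fit0 = f0,
       loglik_alt = ll1, loglik_null = f0$loglik,
       n = length(attr(b1, "ids")))
}

#' Measured-genotype (MG) association test
#'
#' Mixed-model association of the adjusted phenotype on minor-allele dosage
#' under the constraint that the between- and within-family slopes are
#' equal: \eqn{E[R] = \mu + \beta g} with random polygenic covariance
#' \eqn{2\Phi\sigma^2_a} (plus, when `ibd` is given, a marker-specific
#' linkage variance component \eqn{\Pi\sigma^2_{qtl}}) and error.  The
#' p-value is a 1-df likelihood-ratio test of \eqn{\beta = 0}.
#'
#' @inheritParams fit_polygenic_null
#' @param decomp data.frame from [decompose_genotype].
#' @param ibd optional named per-pedigree list of IBD matrices at the tested
#'   marker (the "linkage variance component").
#' @param min_n minimum phenotyped+genotyped individuals (default 20).
#' @return list with `beta`, `p`, `loglik_alt`, `loglik_null`, `n`,
#'   `sigma2`, `flag` (`"ok"`, `"noninformative"`, `"failed"`).
#' @export
fit_mg <- function(R, peds, kin, decomp, ibd = NULL, min_n = 20) {
  ids <- intersect(decomp$id, R$id)
  if (length(ids) < min_n)
    return(list(beta = NA_real_, p = NA_real_, n = length(ids),
                flag = "noninformative"))
  d <- decomp[match(ids, decomp$id), ]
  if (var(d$g) < .Machine$double.eps * 100)
    return(list(beta = NA_real_, p = NA_real_, n = length(ids),
                flag = "noninformative"))
  X1 <- cbind(intercept = 1, g = d$g)
  rownames(X1) <- ids
  X0 <- X1[, 1, drop = FALSE]
  out <- tryCatch({
    r <- assoc_lrt(R, peds, kin, X1, X0, ibd)
    list(beta = r$fit1$beta[2], p = r$p, loglik_alt = r$loglik_alt,
         loglik_null = r$loglik_null, n = r$n, sigma2 = r$fit1$s,
         flag = "ok")
  }, error = function(e) list(beta = NA_real_, p = NA_real_,
                              n = length(ids), flag = "failed"))
  out
}

#' Quantitative transmission disequilibrium test (QTDT)
#'
#' Fits \eqn{E[R] = \mu + \beta_b b + \beta_w w} with both slopes free,
#' under the same random-effect structure as [fit_mg], and tests
#' \eqn{\beta_w = 0} by a 1-df likelihood-ratio test.  Because only the
#' within-family component enters the test, it is robust to population
#' stratification.  A marker with no within-family dosage variance is
#' flagged non-informative; a constant between-family component (e.g. a
#' single cluster) is dropped from the design, reducing the model to a
#' within-family regression.
#'
#' @inheritParams fit_mg
#' @return list with `beta_b`, `beta_w`, `p`, `loglik_alt`, `loglik_null`,
#'   `n`, `sigma2`, `flag`.
#' @export
fit_qtdt <- function(R, peds, kin, decomp, ibd = NULL, min_n = 20) {
  ids <- intersect(decomp$id, R$id)
  if (length(ids) < min_n)
    return(list(beta_b = NA_real_, beta_w = NA_real_, p = NA_real_,
                n = length(ids), flag = "noninformative"))
  d <- decomp[match(ids, decomp$id), ]
  if (var(d$w) < .Machine$double.eps * 100)
    return(list(beta_b = NA_real_, beta_w = NA_real_, p = NA_real_,
                n = length(ids), flag = "noninformative"))
  drop_b <- var(d$b) < .Machine$double.eps * 100
  X1 <- if (drop_b) cbind(intercept = 1, w = d$w)
  else cbind(intercept = 1, b = d$b, w = d$w)
  rownames(X1) <- ids
  X0 <- X1[, -ncol(X1), drop = FALSE]
  out <- tryCatch({
    r <- assoc_lrt(R, peds, kin, X1, X0, ibd)
    list(beta_b = if (drop_b) NA_real_ else r$fit1$beta[2],
         beta_w = r$fit1$beta[ncol(X1)], p = r$p,
         loglik_alt = r$loglik_alt, loglik_null = r$loglik_null,
         n = r$n, sigma2 = r$fit1$s, flag = "ok")
  }, error = function(e) list(beta_b = NA_real_, beta_w = NA_real_,
                              p = NA_real_, n = length(ids),
                              flag = "failed"))
  out
}

#' Family-based association scan over a set of variants
#'
#' For each marker: estimate MAF (founders-only), decompose genotypes into
#' between/within components, run MG and QTDT, and optionally include the
#' marker-specific linkage variance component (single-marker IBD at the
#' tested variant).
#'
#' @inheritParams fit_mg
#' @param ms a [marker_set].
#' @param markers marker names to test (default all).
#' @param linkage_vc include the marker-specific IBD variance component.
#' @param ibd_list optional named list (marker -> per-pedigree IBD list)
#'   used when `linkage_vc = TRUE` instead of computing IBD from genotypes.
#' @param state_limit,n_samples,seed,mendel_policy passed to [compute_ibd].
#' @return data.frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `maf`, `maf_class`, `beta_b`, `beta_w`, `beta_mg`, `p_mg`, `p_qtdt`,
#'   `n`, `linkage_vc`, `sigma2_qtl_at_marker`, `flag_mg`, `flag_qtdt`.
#' @export
assoc_scan <- function(R, peds, kin, ms, markers = NULL, linkage_vc = FALSE,
                       ibd_list = NULL, min_n = 20, state_limit = 2^22,
                       n_samples = 10000, seed = NULL,
                       mendel_policy = c("error", "prior")) {
  mendel_policy <- match.arg(mendel_policy)
  if (is.null(markers)) markers <- ms$info$marker
  if (is.null(ms$info$maf)) stop("marker set has no maf; run set_maf() first")
  rows <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    info <- ms$info[ms$info$marker == mk, ]
    dos <- ms$geno[, mk]
    row <- data.frame(marker = mk, chrom = info$chrom, pos = info$pos,
                      maf = info$maf,
                      maf_class = as.character(classify_maf(info$maf)),
                      beta_b = NA_real_, beta_w = NA_real_,
                      beta_mg = NA_real_, p_mg = NA_real_,
                      p_qtdt = NA_real_, n = NA_integer_,
                      linkage_vc = linkage_vc,
                      sigma2_qtl_at_marker = NA_real_,
                      flag_mg = "skipped", flag_qtdt = "skipped",
                      stringsAsFactors = FALSE)
    ok <- tryCatch({
      decomp <- decompose_genotype(dos, peds)
      ibd <- NULL
      if (linkage_vc) {
        ibd <- if (!is.null(ibd_list)) ibd_list[[mk]]
        else compute_ibd(peds, dos, info$maf, state_limit = state_limit,
                         n_samples = n_samples,
                         seed = if (is.null(seed)) NULL else seed + i,
                         marker_id = mk, mendel_policy = mendel_policy)
      }
      mg <- fit_mg(R, peds, kin, decomp, ibd = ibd, min_n = min_n)
      qt <- fit_qtdt(R, peds, kin, decomp, ibd = ibd, min_n = min_n)
      row$beta_mg <- mg$beta
      row$p_mg <- mg$p
      row$beta_b <- qt$beta_b
      row$beta_w <- qt$beta_w
      row$p_qtdt <- qt$p
      row$n <- mg$n
      if (linkage_vc && identical(mg$flag, "ok"))
        row$sigma2_qtl_at_marker <- mg$sigma2[1]
      row$flag_mg <- mg$flag
      row$flag_qtdt <- qt$flag
      TRUE
    }, error = function(e) FALSE)
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Q-Q diagnostics and genomic inflation
#'
#' Summarises a set of association p-values: the genomic inflation factor
#' \eqn{\lambda} (median of the implied 1-df chi-square statistics divided
#' by its null median 0.4549) and a table of expected versus observed
#' \eqn{-\log_{10} p} order statistics.  `lambda` near 1 indicates nominal
#' calibration; a degenerate set (all p = 1) yields `lambda = 0` and is
#' flagged deflated.
#'
#' @param p numeric vector of p-values in `(0, 1]` (at least 100).
#' @return list with `lambda`, `deflated` flag, `n`, and `qq` (data.frame
#'   `expected`, `observed` in `-log10` scale).
#' @export
qq_diagnostics <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100)
    stop("qq_diagnostics needs at least 100 p-values; got ", length(p))
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq) / qchisq(0.5, df = 1)
  obs <- sort(-log10(p))
  expd <- sort(-log10(stats::ppoints(length(p))))
  list(lambda = lambda, deflated = lambda < 0.8, n = length(p),
       qq = data.frame(expected = expd, observed = obs))
}

#' Plot regional association results
#'
#' `-log10 p` by position, coloured by MAF class (rare / low / common),
#' for MG or QTDT p-values.
#'
#' @param res data.frame from [assoc_scan].
#' @param which `"p_mg"` or `"p_qtdt"`.
#' @param ... passed to [graphics::plot].
#' @export
plot_assoc_region <- function(res, which = c("p_mg", "p_qtdt"), ...) {
  which <- match.arg(which)
  cols <- c(rare = "red", low = "darkgreen", common = "blue")
  p <- res[[which]]
  keep <- !is.na(p)
  graphics::plot(res$pos[keep] / 1e6, -log10(p[keep]), pch = 16, cex = 0.6,
                 col = cols[res$maf_class[keep]], xlab = "Position (Mb)",
                 ylab = expression(-log[10](p)), ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   cex = 0.8)
  invisible(NULL)
}
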