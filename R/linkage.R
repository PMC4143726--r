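#' Polygenic null model
#'
#' Maximum-likelihood fit of the additive polygenic model
#' \deqn{R \sim N(\mu \mathbf{1},\ 2\Phi\,\sigma^2_a + I\,\sigma^2_e)}
#' with pedigree-block-diagonal covariance, the null model of the two-point
#' variance-components linkage analysis.  Variances are boundary-constrained
#' at zero.  When no two phenotyped members are related (all off-diagonal
#' kinship zero), the additive variance is unidentifiable and is pinned to
#' zero, leaving the ML sample variance as the environmental component.
#'
#' @param R data.frame with columns `id`, `R` (adjusted phenotype).
#' @param peds list of [Pedigree] objects.
#' @param kin named list of kinship matrices (see [kinship_list]).
#' @return A `vc_fit` list: `mu`, `sigma2_a`, `sigma2_e`, `h2`, `loglik`,
#'   `n`, `confounded` flag.
#' @export
fit_polygenic_null <- function(R, peds, kin) {
  blocks <- vc_blocks(R, peds, kin)
  offmax <- max(vapply(blocks, function(b) {
    K2 <- b$G[[1]]
    if (nrow(K2) < 2) 0 else max(abs(K2[upper.tri(K2)]))
  }, numeric(1)))
  if (offmax < 1e-10) {
    y <- unlist(lapply(blocks, `[[`, "y"))
    n <- length(y)
    s2 <- mean((y - mean(y))^2)
    ll <- -0.5 * n * (log(2 * pi * s2) + 1)
    return(structure(list(mu = mean(y), sigma2_a = 0, sigma2_e = s2,
                          h2 = 0, loglik = ll, n = n, confounded = TRUE),
                     class = "vc_fit"))
  }
  fit <- vc_ml(blocks, K = 2)
  structure(list(mu = fit$beta[1], sigma2_a = fit$s[1], sigma2_e = fit$s[2],
                 h2 = fit$s[1] / sum(fit$s), loglik = fit$loglik,
                 n = length(attr(blocks, "ids")), confounded = FALSE),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Polygenic fit: n =", x$n, " sigma2_a =", signif(x$sigma2_a, 5),
      " sigma2_e =", signif(x$sigma2_e, 5), " h2 =", round(x$h2, 4),
      " logLik =", format(x$loglik), "\n")
  invisible(x)
}

#' Two-point variance-components linkage fit at one marker
#'
#' Fits \eqn{\Sigma = \Pi\,\sigma^2_{qtl} + 2\Phi\,\sigma^2_a +
#' I\,\sigma^2_e} by ML with \eqn{\sigma^2_{qtl} \ge 0} and computes the LOD
#' score \eqn{(\ell_{alt} - \ell_{null}) / \ln 10} against the polygenic
#' null.  The LOD is 0 exactly when the QTL variance estimate sits at the
#' zero boundary, and the fit is declared confounded (LOD 0) when the
#' marker's IBD matrix is numerically identical to `2 * kinship` in every
#' pedigree (an uninformative marker adds no new structure).
#'
#' @inheritParams fit_polygenic_null
#' @param ibd named list (per pedigree) of single-marker IBD matrices.
#' @param null optional precomputed [fit_polygenic_null] result for this
#'   phenotype (fitted here when `NULL`).
#' @param marker_id,chrom,pos marker annotation carried into the result.
#' @param maf optional minor allele frequency carried into the result.
#' @return A one-row data.frame: `marker`, `chrom`, `pos`, `maf`,
#'   `sigma2_qtl`, `sigma2_a`, `sigma2_e`, `mu`, `loglik_null`,
#'   `loglik_alt`, `lod`, `confounded`.
#' @export
fit_vc_linkage <- function(R, peds, kin, ibd, null = NULL,
                           marker_id = NA_character_, chrom = NA_character_,
                           pos = NA_integer_, maf = NA_real_) {
  if (is.null(null)) null <- fit_polygenic_null(R, peds, kin)
  blocks <- vc_blocks(R, peds, kin, ibd = ibd)
  confounded <- all(vapply(blocks, function(b)
    max(abs(b$G[[1]] - b$G[[2]])) < 1e-10, logical(1)))
  if (confounded) {
    return(data.frame(marker = marker_id, chrom = chrom, pos = pos,
                      maf = maf, sigma2_qtl = 0,
                      sigma2_a = null$sigma2_a, sigma2_e = null$sigma2_e,
                      mu = null$mu, loglik_null = null$loglik,
                      loglik_alt = null$loglik, lod = 0, confounded = TRUE,
                      stringsAsFactors = FALSE))
  }
  vtot <- vc_total_var(blocks)
  fit <- vc_ml(blocks, K = 3,
               start = c(0.05 * vtot, max(null$sigma2_a, 0.05 * vtot),
                         max(null$sigma2_e, 0.1 * vtot)), restarts = 1)
  ll_alt <- max(fit$loglik, null$loglik)
  lod <- (ll_alt - null$loglik) / log(10)
  if (fit$s[1] <= 1e-8 * vtot || lod < 0) lod <- 0
  data.frame(marker = marker_id, chrom = chrom, pos = pos, maf = maf,
             sigma2_qtl = fit$s[1], sigma2_a = fit$s[2],
             sigma2_e = fit$s[3], mu = fit$beta[1],
             loglik_null = null$loglik, loglik_alt = ll_alt, lod = lod,
             confounded = FALSE, stringsAsFactors = FALSE)
}

#' Two-point linkage scan over a set of markers
#'
#' For each marker: estimate the minor allele frequency (founders-only),
#' compute per-pedigree single-marker IBD (exact engine below the state
#' limit, Monte Carlo above), and fit the three-component linkage model.
#' The polygenic null is fitted once and reused for every marker.
#'
#' @inheritParams fit_vc_linkage
#' @param ms a [marker_set].
#' @param markers marker names to scan (default: all in `ms`).
#' @param ibd_list optional named list (marker -> per-pedigree IBD list) to
#'   use instead of computing IBD from genotypes (e.g. realized descent from
#'   a simulation).
#' @param state_limit,n_samples,seed,mendel_policy passed to [compute_ibd].
#' @return data.frame with one row per marker (see [fit_vc_linkage]).
#' @export
linkage_scan <- function(R, peds, kin, ms = NULL, markers = NULL,
                         ibd_list = NULL, null = NULL, state_limit = 2^22,
                         n_samples = 10000, seed = NULL,
                         mendel_policy = c("error", "prior")) {
  mendel_policy <- match.arg(mendel_policy)
  if (is.null(null)) null <- fit_polygenic_null(R, peds, kin)
  if (is.null(markers))
    markers <- if (!is.null(ms)) ms$info$marker else names(ibd_list)
  rows <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    info <- if (!is.null(ms)) ms$info[ms$info$marker == mk, ] else NULL
    maf <- if (!is.null(info) && !is.null(info$maf)) info$maf else NA_real_
    ibd <- if (!is.null(ibd_list)) ibd_list[[mk]]
    else {
      dos <- ms$geno[, mk]
      compute_ibd(peds, dos, maf, state_limit = state_limit,
                  n_samples = n_samples,
                  seed = if (is.null(seed)) NULL else seed + i,
                  marker_id = mk, mendel_policy = mendel_policy)
    }
    rows[[i]] <- fit_vc_linkage(R, peds, kin, ibd, null = null,
                                marker_id = mk,
                                chrom = if (!is.null(info)) info$chrom else
                                  NA_character_,
                                pos = if (!is.null(info)) info$pos else
                                  NA_integer_,
                                maf = maf)
  }
  do.call(rbind, rows)
}

#' Select linkage regions above a LOD threshold
#'
#' Markers with `lod > lod_threshold` are grouped into regions: markers on
#' the same chromosome within `merge_bp` of each other share a region; each
#' region records its peak marker and LOD.  The comparison allows a small
#' numerical tolerance so that a LOD equal to the threshold at working
#' precision (e.g. a value reported as 1.20 against a 1.2 rule) is kept.
#'
#' @param fits data.frame from [linkage_scan] (columns `marker`, `chrom`,
#'   `pos`, `lod`).
#' @param lod_threshold LOD cutoff (default 1.2, strict inequality).
#' @param merge_bp merge distance in bp (default 10 Mb).
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `peak_marker`, `peak_lod`, `n_markers`; zero rows when nothing exceeds
#'   the threshold.
#' @export
select_regions <- function(fits, lod_threshold = 1.2, merge_bp = 1e7) {
  empty <- data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), peak_marker = character(),
                      peak_lod = numeric(), n_markers = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(fits)) return(empty)
  sel <- fits[fits$lod > lod_threshold - sqrt(.Machine$double.eps), ,
              drop = FALSE]
  if (!nrow(sel)) return(empty)
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(sel$chrom)) {
    sub <- sel[sel$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$pos) > merge_bp))
    for (g in unique(grp)) {
      r <- sub[grp == g, , drop = FALSE]
      pk <- which.max(r$lod)
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start_bp = min(r$pos), end_bp = max(r$pos),
                   peak_marker = r$marker[pk], peak_lod = r$lod[pk],
                   n_markers = nrow(r), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Plot a two-point LOD profile
#'
#' Position (Mb) against LOD with the selection threshold marked, in the
#' style of a chromosome-wide linkage scan figure.
#'
#' @inheritParams select_regions
#' @param ... passed to [graphics::plot].
#' @export
plot_lod_profile <- function(fits, lod_threshold = 1.2, ...) {
  ord <- order(fits$pos)
  graphics::plot(fits$pos[ord] / 1e6, fits$lod[ord], type = "p", pch = 16,
                 cex = 0.5, xlab = "Position (Mb)", ylab = "LOD", ...)
  graphics::abline(h = lod_threshold, col = "grey50", lty = 2)
  invisible(NULL)
}
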