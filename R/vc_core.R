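# Shared machinery for pedigree-block variance-component normal models
#   y ~ N(X beta, sum_k s_k G_k)  per pedigree block,
# with beta profiled by GLS and the variances estimated by bound-constrained
# maximum likelihood (ML, not REML: LOD and LRT comparisons need full
# likelihoods).

# Assemble per-pedigree blocks.  R: data.frame(id, R); kin: named list of
# kinship matrices; ibd: optional named list (per pedigree) of IBD matrices;
# X: optional fixed-effect matrix with rownames = individual ids (an
# intercept-only design is used when NULL).  Individuals lacking phenotype,
# kinship row or any X entry are dropped; blocks with < 1 member are dropped.
vc_blocks <- function(R, peds, kin, ibd = NULL, X = NULL) {
  blocks <- list()
  ids_used <- character(0)
  for (p in peds) {
    fam <- p$family_id
    ids <- intersect(ped_ids(p), R$id)
    if (!is.null(X)) ids <- intersect(ids, rownames(X))
    if (length(ids) < 1L) next
    y <- R$R[match(ids, R$id)]
    K2 <- 2 * kin[[fam]][ids, ids, drop = FALSE]
    G <- list()
    if (!is.null(ibd)) {
      Pi <- ibd[[fam]]
      if (is.null(Pi) || !all(ids %in% rownames(Pi)))
        stop("IBD matrix for pedigree '", fam,
             "' missing or not covering phenotyped members")
      G <- c(G, list(Pi[ids, ids, drop = FALSE]))
    }
    G <- c(G, list(K2), list(diag(length(ids))))
    Xb <- if (is.null(X)) matrix(1, length(ids), 1,
                                 dimnames = list(ids, "intercept"))
    else X[ids, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- list(y = y, X = Xb, G = G, ids = ids,
                                          fam = fam)
    ids_used <- c(ids_used, ids)
  }
  if (!length(blocks)) stop("no phenotyped pedigree members to analyse")
  attr(blocks, "ids") <- ids_used
  blocks
}

vc_total_var <- function(blocks) {
  y <- unlist(lapply(blocks, `[[`, "y"))
  max(mean((y - mean(y))^2), .Machine$double.eps)
}

# bound-constrained ML over the variance vector s (length = #structures);
# returns s, beta, loglik, convergence
vc_ml <- function(blocks, K, start = NULL, restarts = 2) {
  vtot <- vc_total_var(blocks)
  lower <- c(rep(0, K - 1), 1e-8 * vtot)
  nll <- function(s) {
    r <- vc_profile_ll_cpp(blocks, s)
    if (!isTRUE(r$ok) || !is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  starts <- list(if (is.null(start)) rep(vtot / K, K) else pmax(start, 0))
  if (restarts >= 1)
    starts <- c(starts, list(c(rep(0.1 * vtot, K - 1), 0.9 * vtot)))
  if (restarts >= 2)
    starts <- c(starts, list(rep(vtot / K, K) *
                               exp(0.4 * (-1)^seq_len(K))))
  best <- NULL
  for (st in starts) {
    st <- pmax(st, lower)
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B", lower = lower,
                   control = list(parscale = rep(vtot, K), maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("variance-component optimisation failed (singular covariance or ",
         "non-convergence)")
  r <- vc_profile_ll_cpp(blocks, best$par)
  list(s = best$par, beta = as.numeric(r$beta), loglik = r$loglik,
       XtSiX = r$XtSiX, convergence = best$convergence, vtot = vtot)
}

# near-zero-variance columns (other than the first/intercept) make a design
# unidentifiable; callers use this to flag non-informative tests
vc_degenerate_cols <- function(X) {
  apply(X, 2, function(col) stats::var(col) < .Machine$double.eps * 100) &
    seq_len(ncol(X)) > 1L
}
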