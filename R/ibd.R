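#' Single-marker IBD sharing in a pedigree
#'
#' Computes, for every pair of pedigree members, the expected proportion of
#' alleles shared identical by descent at one marker, conditional on all
#' observed genotypes at that marker:
#' \deqn{\pi_{ij} = E\!\left[\tfrac12 \sum_{k,l \in \{1,2\}}
#'   1\{a_{ik} \equiv a_{jl}\} \,\middle|\, G\right],}
#' where \eqn{a_{ik}} are the founder-allele origins.  Founder genotypes are
#' Hardy-Weinberg at the supplied minor allele frequency, transmissions are
#' Mendelian, and missing genotypes are marginalised.  The diagonal is
#' `1 + f_i` (inbreeding-adjusted self-sharing); for an untyped marker the
#' matrix reduces to twice the kinship matrix.  The exact engine enumerates
#' all inheritance vectors (two bits per non-founder), evaluating the
#' genotype likelihood of each by a founder-allele graph colouring; it is
#' exact but exponential in the number of non-founders, so a state limit
#' routes larger pedigrees to the Monte-Carlo estimator.
#'
#' @param ped a [Pedigree].
#' @param dosage named integer vector of minor-allele dosages (0/1/2/NA)
#'   covering any subset of the members; members absent from `dosage` are
#'   treated as untyped.
#' @param maf minor allele frequency in `(0, 1)` used for founder genotype
#'   priors.
#' @param state_limit maximum number of inheritance vectors
#'   (`4 ^ n_nonfounders`) the exact engine will enumerate; default `2^22`.
#' @param marker_id optional marker name used in error messages.
#' @return A symmetric matrix with member IDs as dimnames; attribute
#'   `likelihood` holds the marginal probability of the observed genotypes.
#' @export
compute_ibd_exact <- function(ped, dosage = NULL, maf = 0.5,
                              state_limit = 2^22, marker_id = NULL) {
  enc <- ibd_encode(ped, dosage)
  n_nonf <- sum(!is.na(enc$fa))
  if (4^n_nonf > state_limit)
    stop("pedigree '", ped$family_id, "' has ", n_nonf, " non-founders (",
         format(4^n_nonf, scientific = TRUE), " inheritance vectors) ",
         "exceeding state_limit; use compute_ibd_montecarlo()")
  res <- ibd_exact_cpp(enc$fa0, enc$mo0, enc$geno, maf)
  if (res$weight <= 0)
    stop("Mendelian-inconsistent genotypes in pedigree '", ped$family_id,
         "'", if (!is.null(marker_id)) paste0(" at marker '", marker_id, "'"),
         ": observed genotype configuration has likelihood zero")
  pi <- ibd_decode(res$pi, ped, enc)
  attr(pi, "likelihood") <- res$weight
  pi
}

#' @rdname compute_ibd_exact
#' @param n_samples number of sampled inheritance vectors (importance
#'   sampling from the Mendelian prior, weighted by the genotype likelihood).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return For the Monte-Carlo variant, the matrix additionally carries an
#'   `se` attribute (per-entry Monte-Carlo standard errors) and
#'   `n_accepted` (samples with positive likelihood).
#' @export
compute_ibd_montecarlo <- function(ped, dosage = NULL, maf = 0.5,
                                   n_samples = 10000, seed = NULL,
                                   marker_id = NULL) {
  stopifnot(n_samples >= 1)
  enc <- ibd_encode(ped, dosage)
  res <- with_seed(seed, ibd_mc_cpp(enc$fa0, enc$mo0, enc$geno, maf,
                                    as.integer(n_samples)))
  if (res$weight <= 0)
    stop("Monte-Carlo IBD failed to accept any inheritance vector for ",
         "pedigree '", ped$family_id, "'",
         if (!is.null(marker_id)) paste0(" at marker '", marker_id, "'"),
         " after ", n_samples, " samples (Mendelian inconsistency or ",
         "too few samples)")
  pi <- ibd_decode(res$pi, ped, enc)
  se <- ibd_decode(res$se, ped, enc)
  attr(pi, "se") <- se
  attr(pi, "n_accepted") <- res$n_accepted
  pi
}

#' Marker-wise IBD for several pedigrees
#'
#' Dispatches each pedigree to the exact engine when its inheritance-vector
#' count fits under `state_limit` and to Monte Carlo otherwise.  On a
#' Mendelian inconsistency the behaviour follows `mendel_policy`: `"error"`
#' rethrows, `"prior"` replaces that pedigree's matrix by its prior `2 *
#' kinship` with a warning.
#'
#' @inheritParams compute_ibd_exact
#' @param peds list of [Pedigree] objects.
#' @param kin optional named list of kinship matrices (computed if missing).
#' @param mendel_policy `"error"` or `"prior"`.
#' @inheritParams compute_ibd_montecarlo
#' @return Named list of IBD matrices, one per pedigree.
#' @export
compute_ibd <- function(peds, dosage, maf, kin = NULL, state_limit = 2^22,
                        n_samples = 10000, seed = NULL, marker_id = NULL,
                        mendel_policy = c("error", "prior")) {
  mendel_policy <- match.arg(mendel_policy)
  out <- vector("list", length(peds))
  for (i in seq_along(peds)) {
    ped <- peds[[i]]
    n_nonf <- sum(!is.na(ped$father_idx))
    res <- tryCatch({
      if (4^n_nonf <= state_limit)
        compute_ibd_exact(ped, dosage, maf, state_limit, marker_id)
      else
        compute_ibd_montecarlo(ped, dosage, maf, n_samples,
                               seed = if (is.null(seed)) NULL else seed + i,
                               marker_id = marker_id)
    }, error = function(e) {
      if (mendel_policy == "prior" &&
          grepl("Mendelian", conditionMessage(e))) {
        warning("pedigree '", ped$family_id, "'",
                if (!is.null(marker_id))
                  paste0(" marker '", marker_id, "'"),
                ": Mendelian inconsistency; IBD blanked to prior 2*kinship",
                call. = FALSE)
        k <- if (!is.null(kin)) kin[[ped$family_id]] else compute_kinship(ped)
        2 * k
      } else stop(e)
    })
    out[[i]] <- res
  }
  names(out) <- vapply(peds, function(p) p$family_id, character(1))
  out
}

# encode pedigree (topologically ordered, 0-based parents) + genotypes
ibd_encode <- function(ped, dosage) {
  ord <- ped$topo
  n <- length(ord)
  pos <- match(seq_len(n), ord)      # member index -> position in topo order
  fa0 <- ifelse(is.na(ped$father_idx[ord]), -1L,
                pos[ped$father_idx[ord]] - 1L)
  mo0 <- ifelse(is.na(ped$mother_idx[ord]), -1L,
                pos[ped$mother_idx[ord]] - 1L)
  ids <- ped$members$id[ord]
  g <- rep(NA_integer_, n)
  if (!is.null(dosage)) {
    hit <- match(ids, names(dosage))
    g <- as.integer(dosage[hit])
  }
  list(fa0 = as.integer(fa0), mo0 = as.integer(mo0), geno = g,
       fa = ifelse(fa0 < 0, NA_integer_, fa0), ord = ord, ids = ids)
}

# map a topo-ordered matrix back to member storage order
ibd_decode <- function(mat, ped, enc) {
  dimnames(mat) <- list(enc$ids, enc$ids)
  mat[ped$members$id, ped$members$id]
}

#' Write per-marker IBD matrices as a triplet table
#'
#' Upper-triangle (including diagonal) entries as rows `id_i`, `id_j`, `pi`,
#' preceded by a header line naming the marker and pedigree.
#'
#' @param ibd named list of IBD matrices (per pedigree).
#' @param marker_id marker name for the header.
#' @param path output file; appended to if it exists.
#' @export
write_ibd_triplets <- function(ibd, marker_id, path) {
  con <- file(path, open = "a")
  on.exit(close(con))
  for (fam in names(ibd)) {
    m <- ibd[[fam]]
    writeLines(paste0("# marker=", marker_id, " pedigree=", fam), con)
    ids <- rownames(m)
    for (i in seq_along(ids))
      for (j in i:length(ids))
        writeLines(paste(ids[i], ids[j], format(m[i, j], digits = 10),
                         sep = "\t"), con)
  }
  invisible(path)
}
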