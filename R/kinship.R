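#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficient phi_ij (the probability that one allele
#' drawn at random from i and one from j are identical by descent) by the
#' standard recursion, processing members in topological order so that every
#' non-founder's parents are visited first:
#' \deqn{\phi_{ij} = \tfrac12(\phi_{i,father(j)} + \phi_{i,mother(j)}),\qquad
#'       \phi_{jj} = \tfrac12(1 + \phi_{father(j),mother(j)}),}
#' with founders unrelated and non-inbred (\eqn{\phi_{ii} = 1/2}).  The
#' recursion is exact for inbred and looped pedigrees.  The additive genetic
#' covariance structure used downstream is `2 * compute_kinship(ped)`.
#'
#' @param ped a [Pedigree].
#' @return A symmetric matrix with dimnames equal to the member IDs in their
#'   stored order; diagonal `0.5 * (1 + f)` where `f` is the inbreeding
#'   coefficient.
#' @export
compute_kinship <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  n <- nrow(ped$members)
  fi <- ped$father_idx
  mi <- ped$mother_idx
  phi <- matrix(0, n, n)
  done <- integer(0)
  for (j in ped$topo) {
    if (is.na(fi[j])) {
      phi[j, j] <- 0.5
    } else {
      phi[j, j] <- 0.5 * (1 + phi[fi[j], mi[j]])
      for (i in done) {
        if (i == j) next
        v <- 0.5 * (phi[i, fi[j]] + phi[i, mi[j]])
        phi[i, j] <- v
        phi[j, i] <- v
      }
    }
    done <- c(done, j)
  }
  dimnames(phi) <- list(ped$members$id, ped$members$id)
  phi
}

#' Kinship for a list of pedigrees
#'
#' @param peds list of [Pedigree] objects.
#' @return Named list of kinship matrices, one per pedigree.
#' @export
kinship_list <- function(peds) {
  out <- lapply(peds, compute_kinship)
  names(out) <- vapply(peds, function(p) p$family_id, character(1))
  out
}
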