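#' Pairwise kinship coefficients from pedigree structure
#'
#' Computes the kinship coefficient phi for every pair of pedigree members
#' by the standard recursion, processing individuals in an order where
#' parents precede children: founders have phi_ii = 1/2 and phi_ij = 0 to
#' everyone already placed; a child k with parents f and m has
#' phi_ki = (phi_fi + phi_mi) / 2 for i != k and
#' phi_kk = (1 + phi_fm) / 2.  Founders are assumed mutually unrelated and
#' non-inbred; inbreeding enters only through pedigree loops.  Members of
#' different families always have phi = 0.
#'
#' @param ped a `pedigree` data frame (see [generate_pedigrees()]).
#' @return A symmetric matrix of class `kinship_matrix`, rows and columns
#'   named and ordered as the pedigree rows.
#' @export
kinship_from_pedigree <- function(ped) {
  ord <- validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  father <- stats::setNames(ped$father, ids)
  mother <- stats::setNames(ped$mother, ids)
  done <- character(0)
  for (k in ord) {
    if (is.na(father[[k]])) {
      phi[k, k] <- 0.5
    } else {
      f <- father[[k]]; m <- mother[[k]]
      if (length(done)) {
        phi[k, done] <- (phi[f, done] + phi[m, done]) / 2
        phi[done, k] <- phi[k, done]
      }
      phi[k, k] <- 0.5 * (1 + phi[f, m])
    }
    done <- c(done, k)
  }
  structure(phi, class = c("kinship_matrix", "matrix", "array"))
}

#' Cache the eigendecomposition of the relationship matrix 2*Phi
#'
#' The polygenic model repeatedly rotates data by the eigenvectors of
#' 2*Phi; computing the decomposition once per pedigree and passing the
#' cached object to [fit_polygenic()] avoids redundant O(n^3) work when
#' thousands of genes share one kinship structure.  Eigenvalues below
#' -1e-8 raise a structural error (2*Phi must be positive semi-definite);
#' small negative values from round-off are clamped to zero.
#'
#' @param kinship a `kinship_matrix` (or any symmetric kinship matrix).
#' @return An object of class `kinship_eigen` with elements `values`,
#'   `vectors`, `ids`.
#' @export
kinship_eigen <- function(kinship) {
  K <- unclass(kinship)
  if (!isSymmetric(K, tol = 1e-8)) {
    stop_structural("kinship matrix is not symmetric")
  }
  e <- eigen(2 * K, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop_structural(sprintf(
      "relationship matrix 2*Phi is not positive semi-definite (min eigenvalue %.3g)",
      min(e$values)))
  }
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = rownames(K)),
            class = "kinship_eigen")
}
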