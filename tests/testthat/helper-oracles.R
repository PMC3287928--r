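# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: dense linear algebra instead of the rotated
# profile likelihood, explicit allele counting instead of the vectorised
# classifier, and label-dropping instead of the kinship recursion.

# Dense generalized-least-squares grid search over the heritability ratio.
# V(h) = h * 2Phi + (1 - h) I; ML variance profiled out; 1000 grid points.
gls_grid_oracle <- function(y, x, K2, grid_n = 1000) {
  n <- length(y)
  X <- cbind(1, x)
  hs <- seq(0, 0.999, length.out = grid_n)
  best <- list(ll = -Inf)
  for (h in hs) {
    V <- h * K2 + (1 - h) * diag(n)
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    q <- as.numeric(t(r) %*% Vi %*% r)
    s2 <- max(q / n, 1e-12)
    ll <- as.numeric(-0.5 * (n * log(2 * pi * s2) + q / s2 +
                               determinant(V)$modulus))
    if (ll > best$ll) best <- list(ll = ll, beta = b[length(b)], h = h)
  }
  best
}

# Closed-form Gaussian ML log-likelihood of a simple/multiple regression,
# computed from explicit normal equations.
ols_oracle <- function(y, x) {
  n <- length(y)
  bx <- cov(x, y) * (n - 1) / (var(x) * (n - 1))
  a <- mean(y) - bx * mean(x)
  rss1 <- sum((y - a - bx * x)^2)
  rss0 <- sum((y - mean(y))^2)
  ll <- function(rss) -0.5 * n * (log(2 * pi * rss / n) + 1)
  list(beta = bx, lrt = 2 * (ll(rss1) - ll(rss0)), loglik = ll(rss1))
}

# Monte-Carlo IBD estimate of the kinship matrix: founders carry uniquely
# labelled alleles, labels are dropped through the pedigree, and phi_ij is
# the average probability that one allele sampled from each of i and j is
# identical by descent.  Vectorised across replicates.
mc_ibd_kinship <- function(ped, n_rep) {
  ord <- synthcorr::validate_pedigree(ped)
  n <- nrow(ped)
  lab <- 0L
  a1 <- list(); a2 <- list()
  father <- stats::setNames(ped$father, ped$id)
  mother <- stats::setNames(ped$mother, ped$id)
  for (who in ord) {
    if (is.na(father[[who]])) {
      a1[[who]] <- rep(lab + 1L, n_rep)
      a2[[who]] <- rep(lab + 2L, n_rep)
      lab <- lab + 2L
    } else {
      pick_f <- runif(n_rep) < 0.5
      pick_m <- runif(n_rep) < 0.5
      a1[[who]] <- ifelse(pick_f, a1[[father[[who]]]], a2[[father[[who]]]])
      a2[[who]] <- ifelse(pick_m, a1[[mother[[who]]]], a2[[mother[[who]]]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ii <- ped$id[i]; jj <- ped$id[j]
      p <- (mean(a1[[ii]] == a1[[jj]]) + mean(a1[[ii]] == a2[[jj]]) +
              mean(a2[[ii]] == a1[[jj]]) + mean(a2[[ii]] == a2[[jj]])) / 4
      phi[i, j] <- phi[j, i] <- p
    }
  }
  phi
}

# Genotype-level Mendelian consistency: each transmitted haplotype must
# equal one of the parent's two haplotypes over every whole gene.
check_mendelian <- function(fam_geno) {
  ped <- fam_geno$pedigree
  ann <- fam_geno$annotation
  hapA <- fam_geno$haplotypes$A
  hapB <- fam_geno$haplotypes$B
  gene_cols <- split(seq_len(nrow(ann)), ann$gene)
  ok <- TRUE
  for (i in which(!ped$founder)) {
    child <- ped$id[i]; fa <- ped$father[i]; mo <- ped$mother[i]
    for (cols in gene_cols) {
      ok <- ok &&
        (identical(hapA[child, cols], hapA[fa, cols]) ||
           identical(hapA[child, cols], hapB[fa, cols])) &&
        (identical(hapB[child, cols], hapA[mo, cols]) ||
           identical(hapB[child, cols], hapB[mo, cols]))
      if (!ok) return(FALSE)
    }
  }
  ok
}

# Small fixed annotation builder for hand-made genes.
tiny_annotation <- function(gene, n_variants, func_type = NULL) {
  data.frame(
    variant_id = sprintf("%sV%02d", gene, seq_len(n_variants)),
    gene = gene,
    func_type = func_type %||% rep_len(c("nonsynonymous", "synonymous"),
                                       n_variants),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a
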