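#' Build the CVGS / SRVGS score pair for one gene
#'
#' For a selected gene, draws one common variant uniformly at random among
#' the gene's common variants (the common variant genotype score, CVGS, is
#' that variant's minor-allele count per individual) and sums the
#' minor-allele counts over the gene's rare variants in the requested
#' functional stratum (the sum of rare variant genotype scores, SRVGS --
#' an unweighted burden score).  One common variant is drawn per gene and
#' shared across strata; pass `common_variant` to reuse a previous draw.
#'
#' @param gene gene ID (must appear in the classification).
#' @param classification a `variant_classification` for the analysis sample.
#' @param genotypes minor-allele-oriented score matrix (see
#'   [orient_minor()]).
#' @param stratum `"nonsynonymous"`, `"synonymous"` or `"all"`: which rare
#'   variants enter the burden sum.
#' @param common_variant optional variant ID overriding the random draw.
#' @param seed optional seed for the draw (ignored when `common_variant`
#'   is given); when NULL the current RNG stream is used.
#' @return An object of class `score_pair`: `gene`, `common_variant_id`,
#'   `common_func_type`, `rare_stratum`, `cvgs`, `srvgs`, `n_rare`,
#'   `rare_variant_ids`.  An empty stratum yields `n_rare = 0` and an
#'   all-zero SRVGS (flagged as skipped by the model fits), not an error.
#' @export
build_scores <- function(gene, classification, genotypes,
                         stratum = c("nonsynonymous", "synonymous", "all"),
                         common_variant = NULL, seed = NULL) {
  stratum <- match.arg(stratum)
  rows <- classification[classification$gene == gene, , drop = FALSE]
  if (!nrow(rows)) stop_data(sprintf("build_scores: gene '%s' not in classification", gene))
  common_ids <- rows$variant_id[rows$category == "common"]
  if (is.null(common_variant)) {
    if (!length(common_ids)) {
      stop_data(sprintf("build_scores: gene '%s' has no common variant", gene))
    }
    if (!is.null(seed)) set.seed(as.integer(seed))
    common_variant <- common_ids[sample.int(length(common_ids), 1L)]
  }
  if (!common_variant %in% rows$variant_id) {
    stop_data(sprintf("build_scores: variant '%s' is not in gene '%s'",
                      common_variant, gene))
  }
  keep <- rows$category == "rare"
  if (stratum != "all") keep <- keep & rows$func_type == stratum
  rare_ids <- rows$variant_id[keep]
  srvgs <- if (length(rare_ids)) {
    rowSums(genotypes[, rare_ids, drop = FALSE])
  } else {
    rep(0, nrow(genotypes))
  }
  structure(
    list(gene = gene,
         common_variant_id = common_variant,
         common_func_type = rows$func_type[rows$variant_id == common_variant],
         rare_stratum = stratum,
         cvgs = genotypes[, common_variant],
         srvgs = srvgs,
         n_rare = length(rare_ids),
         rare_variant_ids = rare_ids),
    class = "score_pair"
  )
}

new_regression_result <- function(model, status,
                                  beta = NA_real_, lrt = NA_real_,
                                  p_value = NA_real_, loglik = NA_real_,
                                  sigma2_g = NA_real_, sigma2_e = NA_real_,
                                  h2 = NA_real_, n = NA_integer_) {
  structure(
    list(beta = beta, lrt = lrt, p_value = p_value, loglik = loglik,
         sigma2_g = sigma2_g, sigma2_e = sigma2_e, h2 = h2,
         model = model, status = status, n = n),
    class = "regression_result"
  )
}

# Gaussian maximum-likelihood log-likelihood for a linear fit with
# residual sum of squares `rss` on n observations; the ML variance
# estimate rss/n is floored at 1e-12 so exact fits on degenerate toy
# inputs stay finite.
gauss_loglik <- function(rss, n) {
  s2 <- max(rss / n, 1e-12)
  -0.5 * n * (log(2 * pi * s2) + rss / (n * s2))
}

ols_rss <- function(X, y) {
  fit <- qr(X)
  if (fit$rank < ncol(X)) return(NULL)
  sum(qr.resid(fit, y)^2)
}

#' OLS regression of CVGS on SRVGS
#'
#' Fits the Gaussian maximum-likelihood regression of the common-variant
#' genotype score on an intercept, optional covariates, and the rare-variant
#' burden score, and tests the burden coefficient with a likelihood-ratio
#' statistic: lrt = 2 (l_full - l_null), where the null model drops only
#' the SRVGS term; p-values come from the upper tail of chi-square with 1
#' degree of freedom.
#'
#' @param cvgs response vector of common-variant scores.
#' @param srvgs predictor vector (rare-variant burden).
#' @param covariates optional numeric matrix of nuisance covariates (e.g.
#'   principal-component scores).
#' @return A `regression_result` with `beta`, `lrt`, `p_value`, `loglik`
#'   (full model), `model = "ols"` and `status`.  A constant SRVGS (e.g.
#'   every rare variant monomorphic in the sample) or a constant CVGS
#'   yields `status = "skipped_monomorphic"` with the estimates absent.
#' @export
fit_ols <- function(cvgs, srvgs, covariates = NULL) {
  n <- length(cvgs)
  if (n < 3L) stop_data("fit_ols: need at least 3 individuals")
  if (length(srvgs) != n) stop_data("fit_ols: cvgs and srvgs lengths differ")
  if (stats::sd(srvgs) == 0 || stats::sd(cvgs) == 0) {
    return(new_regression_result("ols", "skipped_monomorphic", n = n))
  }
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  rss0 <- ols_rss(X0, cvgs)
  if (is.null(rss0)) stop_numerical("fit_ols: covariate matrix is rank-deficient")
  X1 <- cbind(X0, srvgs = srvgs)
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    # srvgs collinear with covariates: no information on the burden term
    return(new_regression_result("ols", "skipped_monomorphic", n = n))
  }
  beta <- qr.coef(q1, cvgs)[["srvgs"]]
  rss1 <- sum(qr.resid(q1, cvgs)^2)
  ll1 <- gauss_loglik(rss1, n)
  ll0 <- gauss_loglik(rss0, n)
  lrt <- max(0, 2 * (ll1 - ll0))
  new_regression_result("ols", "ok", beta = beta, lrt = lrt,
                        p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
                        loglik = ll1, n = n)
}

# Profiled negative log-likelihood of the rotated variance-component model
# at heritability ratio h.  `xs` is the rotated design, `ys` the rotated
# response, `d` the eigenvalues of 2*Phi.  Returns -loglik, with the
# GLS coefficient vector as attribute "coef".
polygenic_negll <- function(h, xs, ys, d) {
  n <- length(ys)
  w <- h * d + (1 - h)
  sw <- 1 / sqrt(w)
  fit <- qr(xs * sw)
  if (fit$rank < ncol(xs)) return(structure(Inf, coef = NULL))
  ysw <- ys * sw
  rss <- sum(qr.resid(fit, ysw)^2)
  s2 <- max(rss / n, 1e-12)
  nll <- 0.5 * (n * log(2 * pi * s2) + rss / s2 + sum(log(w)))
  structure(nll, coef = qr.coef(fit, ysw))
}

maximize_profile <- function(xs, ys, d) {
  f <- function(h) as.numeric(polygenic_negll(h, xs, ys, d))
  upper <- 1 - 1e-6
  cands <- list(list(par = 0, value = f(0)))
  for (start in c(0.1, 0.5, 0.9)) {
    opt <- tryCatch(
      stats::optim(start, f, method = "L-BFGS-B", lower = 0, upper = upper,
                   control = list(factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      cands[[length(cands) + 1L]] <- opt
    }
  }
  vals <- vapply(cands, `[[`, numeric(1), "value")
  if (all(!is.finite(vals))) return(NULL)
  best <- cands[[which.min(vals)]]
  list(h = best$par, negll = best$value)
}

#' Kinship variance-component (polygenic) regression
#'
#' Fits, by maximum likelihood, the mixed model
#' `y = alpha + covariates gamma + beta * SRVGS + g + e` with
#' `cov(g) = 2 Phi sigma2_g` and `cov(e) = I sigma2_e`, where Phi is the
#' pedigree kinship matrix.  The eigendecomposition of 2*Phi rotates the
#' model to independent observations with variance
#' `sigma2 * (h * d_i + 1 - h)`, where `h = sigma2_g / (sigma2_g +
#' sigma2_e)` is profiled by bounded one-dimensional optimization on
#' [0, 1) started from 0.1, 0.5 and 0.9 (plus the h = 0 boundary).  The
#' burden coefficient is tested by a likelihood-ratio statistic against the
#' null model without SRVGS, whose variance components are re-estimated;
#' p-values come from chi-square with 1 df.  ML (not REML) estimation is
#' used throughout so the fixed-effect LRT is valid.
#'
#' @param cvgs response vector, ordered as the kinship matrix rows.
#' @param srvgs burden predictor vector.
#' @param kinship a `kinship_matrix` or a cached [kinship_eigen()] (pass
#'   the cached form when fitting many genes on one pedigree).
#' @param covariates optional numeric covariate matrix.
#' @return A `regression_result` with `beta`, `lrt`, `p_value`, `loglik`,
#'   the variance components `sigma2_g`, `sigma2_e`, their ratio `h2`, and
#'   `model = "polygenic"`.  Constant SRVGS or CVGS give
#'   `status = "skipped_monomorphic"`; optimizer failure gives
#'   `status = "not_converged"`.
#' @export
fit_polygenic <- function(cvgs, srvgs, kinship, covariates = NULL) {
  n <- length(cvgs)
  ke <- if (inherits(kinship, "kinship_eigen")) kinship else kinship_eigen(kinship)
  if (length(ke$values) != n) {
    stop_data("fit_polygenic: kinship dimension does not match the number of individuals")
  }
  if (length(srvgs) != n) stop_data("fit_polygenic: cvgs and srvgs lengths differ")
  if (stats::sd(srvgs) == 0 || stats::sd(cvgs) == 0) {
    return(new_regression_result("polygenic", "skipped_monomorphic", n = n))
  }
  U <- ke$vectors
  d <- ke$values
  X1 <- cbind(`(Intercept)` = rep(1, n), covariates, srvgs = srvgs)
  rot <- crossprod(U, cbind(X1, y = cvgs))
  xs1 <- rot[, -ncol(rot), drop = FALSE]
  xs0 <- xs1[, -ncol(xs1), drop = FALSE]
  ys <- rot[, ncol(rot)]

  full <- maximize_profile(xs1, ys, d)
  null <- maximize_profile(xs0, ys, d)
  if (is.null(full) || is.null(null)) {
    return(new_regression_result("polygenic", "not_converged", n = n))
  }
  at_opt <- polygenic_negll(full$h, xs1, ys, d)
  coefs <- attr(at_opt, "coef")
  if (is.null(coefs)) {
    return(new_regression_result("polygenic", "skipped_monomorphic", n = n))
  }
  ll1 <- -full$negll
  ll0 <- -null$negll
  lrt <- max(0, 2 * (ll1 - ll0))
  # total variance at the optimum
  w <- full$h * d + (1 - full$h)
  resid <- ys - xs1 %*% coefs
  s2 <- max(sum(resid^2 / w) / n, 1e-12)
  new_regression_result("polygenic", "ok",
                        beta = coefs[["srvgs"]], lrt = lrt,
                        p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
                        loglik = ll1,
                        sigma2_g = full$h * s2, sigma2_e = (1 - full$h) * s2,
                        h2 = full$h, n = n)
}

#' Principal-component stratification covariates
#'
#' Computes principal components of the genotype matrix restricted to
#' synonymous variants (so the covariates index ancestry, not the
#' functional variation under study), after dropping monomorphic columns
#' and centering each column; columns are not rescaled.  Individual scores
#' on the first `k` components are returned for use as regression
#' covariates.
#'
#' @param geno a `geno_data` or score matrix.
#' @param classification variant table with `func_type` (taken from `geno`
#'   when it is a `geno_data` and omitted).
#' @param k number of components (default 4); `k = 0` returns an empty
#'   covariate matrix, leaving downstream fits uncorrected.
#' @return Numeric matrix (individuals x k) with columns `PC1..PCk`.
#' @export
pca_covariates <- function(geno, classification = NULL, k = 4L) {
  if (inherits(geno, "geno_data")) {
    classification <- classification %||% geno$annotation
    geno <- geno$genotypes
  }
  if (k < 0) stop_config("pca_covariates: 'k' must be >= 0")
  if (k == 0L) return(matrix(numeric(0), nrow(geno), 0))
  syn <- classification$variant_id[classification$func_type == "synonymous"]
  x <- geno[, intersect(colnames(geno), syn), drop = FALSE]
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(x) < k) {
    stop_data(sprintf(
      "pca_covariates: only %d usable (polymorphic synonymous) variants for k = %d",
      ncol(x), k))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Run the CVGS-on-SRVGS regression over every selected gene
#'
#' The per-gene pipeline: classify variants within the analysis sample,
#' orient scores to minor-allele counts, select analyzable genes, draw one
#' common variant per gene (iterating genes in sorted order from a single
#' seeded stream, so results do not depend on storage order), and fit the
#' requested model per rare-variant stratum.
#'
#' @param geno a `geno_data` cohort.
#' @param model `"ols"` for unrelated samples or `"polygenic"` for family
#'   samples (requires `kinship`, or a pedigree attached to `geno`).
#' @param kinship `kinship_matrix` or [kinship_eigen()]; computed from the
#'   attached pedigree when missing and `model = "polygenic"`.
#' @param covariates optional covariate matrix (e.g. [pca_covariates()]).
#' @param stratify if TRUE (default) SRVGS is computed separately for rare
#'   nonsynonymous and rare synonymous variants; otherwise a single
#'   `"all"` stratum is used.
#' @param seed seed for the common-variant draws.
#' @param maf_common,maf_rare,min_variants,max_variants,count_all filter
#'   settings passed to [classify_variants()] and [select_genes()].
#' @param classification,selection,common_draws optional precomputed
#'   inputs; supplying the `selection` and `common_draws` of a reference
#'   run pins the family analysis to the same genes and common variants as
#'   the unrelated analysis (rare sets are still re-derived from this
#'   sample's classification).
#' @return A data frame with one row per (gene, stratum): `gene`,
#'   `common_variant_id`, `common_func_type`, `rare_stratum`, `n_rare`,
#'   `model`, `beta`, `lrt`, `p_value`, `sigma2_g`, `sigma2_e`, `status`.
#'   The classification, gene selection and common-variant draws are
#'   attached as attributes of the same names.
#' @export
run_gene_tests <- function(geno, model = c("ols", "polygenic"),
                           kinship = NULL, covariates = NULL,
                           stratify = TRUE, seed = 1L,
                           maf_common = 0.10, maf_rare = 0.01,
                           min_variants = 10L, max_variants = 50L,
                           count_all = TRUE,
                           classification = NULL, selection = NULL,
                           common_draws = NULL) {
  model <- match.arg(model)
  if (is.null(classification)) {
    classification <- classify_variants(geno, maf_common = maf_common,
                                        maf_rare = maf_rare)
  }
  oriented <- orient_minor(geno, classification)
  if (is.null(selection)) {
    selection <- select_genes(classification, min_variants, max_variants,
                              count_all)
  }
  if (model == "polygenic") {
    if (is.null(kinship)) {
      if (is.null(geno$pedigree)) {
        stop_config("run_gene_tests: polygenic model needs 'kinship' or a pedigree")
      }
      kinship <- kinship_from_pedigree(geno$pedigree)
    }
    if (!inherits(kinship, "kinship_eigen")) kinship <- kinship_eigen(kinship)
  }
  strata <- if (stratify) c("nonsynonymous", "synonymous") else "all"
  genes <- sort(selection$gene)
  cls_rows <- split(seq_len(nrow(classification)), classification$gene)

  if (is.null(common_draws)) {
    set.seed(as.integer(seed))
    common_draws <- vapply(genes, function(g) {
      rows <- classification[cls_rows[[g]], ]
      ids <- rows$variant_id[rows$category == "common"]
      ids[sample.int(length(ids), 1L)]
    }, character(1))
  } else {
    if (!all(genes %in% names(common_draws))) {
      stop_data("run_gene_tests: 'common_draws' does not cover every selected gene")
    }
    common_draws <- common_draws[genes]
  }

  rows <- vector("list", length(genes) * length(strata))
  i <- 0L
  for (g in genes) {
    cls_g <- classification[cls_rows[[g]], ]
    for (st in strata) {
      sp <- build_scores(g, cls_g, oriented, stratum = st,
                         common_variant = common_draws[[g]])
      res <- if (model == "ols") {
        fit_ols(sp$cvgs, sp$srvgs, covariates)
      } else {
        fit_polygenic(sp$cvgs, sp$srvgs, kinship, covariates)
      }
      i <- i + 1L
      rows[[i]] <- data.frame(
        gene = g, common_variant_id = sp$common_variant_id,
        common_func_type = sp$common_func_type, rare_stratum = st,
        n_rare = sp$n_rare, model = model,
        beta = res$beta, lrt = res$lrt, p_value = res$p_value,
        sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e,
        status = res$status, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), common_variant_id = character(),
                      common_func_type = character(), rare_stratum = character(),
                      n_rare = integer(), model = character(), beta = numeric(),
                      lrt = numeric(), p_value = numeric(), sigma2_g = numeric(),
                      sigma2_e = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "classification") <- classification
  attr(out, "selection") <- selection
  attr(out, "common_draws") <- common_draws
  out
}
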