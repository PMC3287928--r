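#' Absolute genotype-score correlation between two variants
#'
#' The composite (phase-free) LD measure used throughout: the absolute
#' Pearson correlation of the two minor-allele count vectors.  Haplotype r
#' is deliberately not used -- phase is unavailable in real genotype data.
#'
#' @param g1,g2 equal-length genotype score vectors.
#' @return `|rho|` in [0, 1], or `NA` when either vector is constant
#'   (correlation undefined; such pairs are excluded from gene means).
#' @export
abs_rho <- function(g1, g2) {
  if (length(g1) != length(g2)) stop_data("abs_rho: vectors differ in length")
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(NA_real_)
  abs(stats::cor(g1, g2))
}

#' Within-gene LD summary for a selected common variant
#'
#' Mean `|rho|` between the common variant's scores and each rare variant's
#' scores; pairs where either member is monomorphic are excluded from the
#' mean and reflected in `n_pairs`.
#'
#' @param common_scores score vector of the selected common variant.
#' @param rare_matrix individuals x rare-variants score matrix (0 columns
#'   allowed).
#' @return List with `mean_abs_rho` (NA when no pair is defined) and
#'   `n_pairs` (number of rare variants with defined correlation).
#' @export
gene_ld_summary <- function(common_scores, rare_matrix) {
  if (is.null(rare_matrix) || ncol(rare_matrix) == 0L) {
    return(list(mean_abs_rho = NA_real_, n_pairs = 0L))
  }
  rhos <- apply(rare_matrix, 2, function(g) abs_rho(common_scores, g))
  n_pairs <- sum(!is.na(rhos))
  list(mean_abs_rho = if (n_pairs) mean(rhos, na.rm = TRUE) else NA_real_,
       n_pairs = n_pairs)
}

#' LD summaries for every (gene, stratum) of a regression run
#'
#' Recomputes, for each row of a [run_gene_tests()] result, the mean
#' absolute genotype correlation between the selected common variant and
#' the rare variants of the stratum (`mode = "common-rare"`, the default,
#' matching the regression structure), or among all pairs within the
#' selected set including rare-rare pairs (`mode = "within-set"`).
#'
#' @param geno the `geno_data` the results were computed on.
#' @param results a [run_gene_tests()] result (its attached classification
#'   and draws are reused).
#' @param mode pair set, see above.
#' @return Data frame: `gene`, `common_variant_id`, `rare_stratum`,
#'   `mean_abs_rho`, `n_pairs`.
#' @export
ld_table <- function(geno, results, mode = c("common-rare", "within-set")) {
  mode <- match.arg(mode)
  classification <- attr(results, "classification")
  if (is.null(classification)) {
    stop_data("ld_table: results carry no classification attribute")
  }
  oriented <- orient_minor(geno, classification)
  out <- results[, c("gene", "common_variant_id", "rare_stratum")]
  out$mean_abs_rho <- NA_real_
  out$n_pairs <- 0L
  for (i in seq_len(nrow(out))) {
    sp <- build_scores(out$gene[i], classification, oriented,
                       stratum = out$rare_stratum[i],
                       common_variant = out$common_variant_id[i])
    if (mode == "common-rare") {
      s <- gene_ld_summary(sp$cvgs,
                           oriented[, sp$rare_variant_ids, drop = FALSE])
      out$mean_abs_rho[i] <- s$mean_abs_rho
      out$n_pairs[i] <- s$n_pairs
    } else {
      set_ids <- c(out$common_variant_id[i], sp$rare_variant_ids)
      if (length(set_ids) >= 2L) {
        cm <- oriented[, set_ids, drop = FALSE]
        rhos <- c()
        for (a in seq_len(ncol(cm) - 1L)) {
          for (b in seq((a + 1L), ncol(cm))) {
            rhos <- c(rhos, abs_rho(cm[, a], cm[, b]))
          }
        }
        np <- sum(!is.na(rhos))
        out$mean_abs_rho[i] <- if (np) mean(rhos, na.rm = TRUE) else NA_real_
        out$n_pairs[i] <- np
      }
    }
  }
  rownames(out) <- NULL
  out
}
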