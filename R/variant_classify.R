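#' Minor-allele frequency of one genotype column
#'
#' Genotype scores are counts of a reference-coded allele (the allele coded
#' 1, e.g. the VCF ALT allele).  If that allele's sample frequency exceeds
#' 0.5 the column is deemed major-coded and flagged for flipping
#' (score -> 2 - score) so that downstream scores always count the minor
#' allele; a tie (frequency exactly 0.5) resolves to the coded allele as
#' minor.
#'
#' @param g integer vector of scores in {0, 1, 2}.
#' @param na_action `"error"` (default) rejects missing genotypes;
#'   `"impute"` computes the frequency from observed alleles (downstream
#'   mean imputation is applied by [classify_variants()]).
#' @return A list with `maf` (in [0, 0.5]), `has_minor_homozygote`, and
#'   `flipped` (TRUE if the input counts the major allele).
#' @export
compute_maf <- function(g, na_action = c("error", "impute")) {
  na_action <- match.arg(na_action)
  if (!length(g)) stop_data("compute_maf: empty genotype column")
  if (anyNA(g)) {
    if (na_action == "error") {
      stop_data("compute_maf: missing genotypes present and imputation disabled")
    }
    g <- g[!is.na(g)]
    if (!length(g)) stop_data("compute_maf: no observed genotypes")
  }
  if (any(g < 0 | g > 2)) stop_data("compute_maf: scores must lie in {0, 1, 2}")
  f1 <- sum(g) / (2 * length(g))
  flipped <- f1 > 0.5
  maf <- min(f1, 1 - f1)
  hom <- if (flipped) any(g == 0) else any(g == 2)
  list(maf = maf, has_minor_homozygote = hom, flipped = flipped)
}

#' Assign rare/common/excluded categories
#'
#' A variant is common iff its MAF strictly exceeds `maf_common`; rare iff
#' its MAF is strictly below `maf_rare` but positive and no minor-allele
#' homozygote is present; everything else -- the boundary values
#' themselves, the in-between band, and sites monomorphic in the sample
#' (MAF = 0, e.g. rare variants lost to founder effects in a family
#' cohort) -- is excluded.
#'
#' @param maf minor-allele frequency vector, each in [0, 0.5].
#' @param has_minor_homozygote logical vector.
#' @param maf_common,maf_rare the category thresholds (defaults 0.10, 0.01).
#' @return Character vector in {"common", "rare", "excluded"}.
#' @export
classify_variant <- function(maf, has_minor_homozygote,
                             maf_common = 0.10, maf_rare = 0.01) {
  if (any(maf < 0 | maf > 0.5)) {
    stop_data("classify_variant: maf must lie in [0, 0.5]")
  }
  out <- rep("excluded", length(maf))
  out[maf > maf_common] <- "common"
  out[maf > 0 & maf < maf_rare & !has_minor_homozygote] <- "rare"
  out
}

#' Classify every variant of a cohort
#'
#' Computes per-variant MAF, minor-allele orientation and rarity category
#' within the supplied sample.  MAFs are always computed in the analysis
#' sample itself, so an unrelated cohort and a gene-dropped family cohort
#' built from the same founders will generally classify variants
#' differently (founder effects change frequencies, and rare variants may
#' go monomorphic in families).
#'
#' @param geno a `geno_data` or a plain individuals x variants score matrix.
#' @param annotation variant annotation (`variant_id`, `gene`,
#'   `func_type`); taken from `geno` when it is a `geno_data`.
#' @param maf_common,maf_rare category thresholds.
#' @param impute if TRUE, missing genotypes are tolerated (frequencies from
#'   observed alleles); default FALSE rejects them.
#' @return A data frame of class `variant_classification` with one row per
#'   variant: `variant_id`, `gene`, `func_type`, `maf`,
#'   `has_minor_homozygote`, `flipped`, `category`.
#' @export
classify_variants <- function(geno, annotation = NULL,
                              maf_common = 0.10, maf_rare = 0.01,
                              impute = FALSE) {
  if (inherits(geno, "geno_data")) {
    annotation <- annotation %||% geno$annotation
    geno <- geno$genotypes
  }
  if (is.null(annotation)) stop_config("classify_variants: 'annotation' required")
  if (!identical(colnames(geno), annotation$variant_id)) {
    stop_data("classify_variants: genotype columns do not match annotation variant_id order")
  }
  if (anyNA(geno) && !impute) {
    stop_data("classify_variants: missing genotypes present and imputation disabled")
  }
  if (any(geno < 0 | geno > 2, na.rm = TRUE)) {
    stop_data("classify_variants: scores must lie in {0, 1, 2}")
  }
  # vectorised equivalent of compute_maf() per column
  n_obs <- colSums(!is.na(geno))
  if (any(n_obs == 0)) stop_data("classify_variants: variant with no observed genotypes")
  f1 <- colSums(geno, na.rm = TRUE) / (2 * n_obs)
  flipped <- f1 > 0.5
  maf <- pmin(f1, 1 - f1)
  hom <- ifelse(flipped, colSums(geno == 0, na.rm = TRUE) > 0,
                colSums(geno == 2, na.rm = TRUE) > 0)
  out <- data.frame(
    variant_id = annotation$variant_id,
    gene = annotation$gene,
    func_type = annotation$func_type,
    maf = maf,
    has_minor_homozygote = hom,
    flipped = flipped,
    category = classify_variant(maf, hom, maf_common, maf_rare),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_classification", "data.frame")
  out
}

#' Orient a score matrix so every column counts the minor allele
#'
#' Applies the per-variant flips recorded by [classify_variants()]
#' (score -> 2 - score for major-coded columns).  Missing genotypes, if
#' tolerated at classification time, are mean-imputed per variant after
#' orientation.
#'
#' @param geno score matrix or `geno_data`.
#' @param classification the matching `variant_classification`.
#' @return A numeric matrix of minor-allele counts.
#' @export
orient_minor <- function(geno, classification) {
  if (inherits(geno, "geno_data")) geno <- geno$genotypes
  if (!identical(colnames(geno), classification$variant_id)) {
    stop_data("orient_minor: column order does not match classification")
  }
  flip <- classification$flipped
  out <- geno
  if (any(flip)) out[, flip] <- 2 - out[, flip]
  if (anyNA(out)) {
    means <- colMeans(out, na.rm = TRUE)
    for (j in which(colSums(is.na(out)) > 0)) {
      out[is.na(out[, j]), j] <- means[j]
    }
  }
  out
}

#' Select analyzable genes
#'
#' A gene is retained when its variant count lies in
#' [`min_variants`, `max_variants`] and it carries at least one common
#' variant.  By default the count includes every variant in the gene
#' regardless of category; `count_all = FALSE` counts only rare + common
#' variants (the excluded band dropped first).
#'
#' @param classification a `variant_classification`.
#' @param min_variants,max_variants variant-count bounds (defaults 10, 50).
#' @param count_all whether the count includes excluded-band variants.
#' @return A data frame ordered by gene ID: `gene`, `n_variants`,
#'   `n_common`, `n_rare`, `n_rare_nonsynonymous`, `n_rare_synonymous`.
#' @export
select_genes <- function(classification, min_variants = 10L,
                         max_variants = 50L, count_all = TRUE) {
  cl <- classification
  genes <- sort(unique(cl$gene))
  idx_by_gene <- split(seq_len(nrow(cl)), cl$gene)
  per <- lapply(genes, function(g) {
    rows <- cl[idx_by_gene[[g]], ]
    counted <- if (count_all) nrow(rows) else sum(rows$category != "excluded")
    data.frame(
      gene = g,
      n_variants = counted,
      n_common = sum(rows$category == "common"),
      n_rare = sum(rows$category == "rare"),
      n_rare_nonsynonymous = sum(rows$category == "rare" &
                                   rows$func_type == "nonsynonymous"),
      n_rare_synonymous = sum(rows$category == "rare" &
                                rows$func_type == "synonymous"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per)
  out <- out[out$n_variants >= min_variants & out$n_variants <= max_variants &
               out$n_common >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
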