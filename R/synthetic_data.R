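#' Population model for synthetic exome-like genotype data
#'
#' Describes the statistical structure from which founder haplotypes are
#' simulated: a Balding-Nichols style model in which each variant has an
#' ancestral minor-allele frequency and per-population frequencies are drawn
#' from a beta distribution around it, with spread controlled by a single
#' divergence parameter (the F of the Balding-Nichols model).  Genes are
#' abstract sets of variants; each gene receives a variant count drawn
#' uniformly from `n_variants_range`, and each variant is assigned to the
#' rare- or common-frequency regime with probability `rare_fraction`.
#'
#' @param n_populations number of populations (>= 1).
#' @param pop_weights sampling probabilities per population; default uniform.
#'   Must sum to 1.
#' @param divergence Balding-Nichols F, a nonnegative real in [0, 1).
#'   0 means no population structure (all populations share the ancestral
#'   frequency).
#' @param n_variants_range integer range (length 2) of variants per gene.
#' @param rare_fraction probability a variant's ancestral frequency is drawn
#'   from the rare regime rather than the common regime.
#' @param rare_maf_range,common_maf_range uniform ranges for ancestral
#'   minor-allele frequencies in the two regimes.
#' @param nonsyn_prob probability a variant is labelled nonsynonymous
#'   (functional labels are independent of frequency).
#' @param coupling probability that a haplotype drawn to carry a rare minor
#'   allele is forced to also carry the minor allele of the gene's anchor
#'   common variant.  0 gives linkage equilibrium among founders (null
#'   genes); positive values create known rare-common correlation (positive
#'   controls).
#'
#' @return An object of class `pop_model`.
#' @export
pop_model <- function(n_populations = 1L,
                      pop_weights = NULL,
                      divergence = 0,
                      n_variants_range = c(10L, 50L),
                      rare_fraction = 0.75,
                      rare_maf_range = c(0.001, 0.009),
                      common_maf_range = c(0.12, 0.45),
                      nonsyn_prob = 0.5,
                      coupling = 0) {
  if (!is.numeric(n_populations) || length(n_populations) != 1L ||
      n_populations < 1 || n_populations != round(n_populations)) {
    stop_config("pop_model: 'n_populations' must be a positive integer")
  }
  n_populations <- as.integer(n_populations)
  if (is.null(pop_weights)) pop_weights <- rep(1 / n_populations, n_populations)
  if (length(pop_weights) != n_populations || any(pop_weights < 0)) {
    stop_config("pop_model: 'pop_weights' must be nonnegative, one per population")
  }
  if (abs(sum(pop_weights) - 1) > 1e-12) {
    stop_config("pop_model: 'pop_weights' must sum to 1 (tolerance 1e-12)")
  }
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      divergence < 0 || divergence >= 1) {
    stop_config("pop_model: 'divergence' must be in [0, 1)")
  }
  if (length(n_variants_range) != 2L || any(n_variants_range < 1) ||
      n_variants_range[1] > n_variants_range[2] ||
      any(n_variants_range != round(n_variants_range))) {
    stop_config("pop_model: 'n_variants_range' must be an increasing integer pair >= 1")
  }
  for (nm in c("rare_fraction", "nonsyn_prob", "coupling")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_config(sprintf("pop_model: '%s' must be a probability in [0, 1]", nm))
    }
  }
  for (nm in c("rare_maf_range", "common_maf_range")) {
    v <- get(nm)
    if (length(v) != 2L || any(v < 0) || any(v > 0.5) || v[1] > v[2]) {
      stop_config(sprintf("pop_model: '%s' must be an increasing pair in [0, 0.5]", nm))
    }
  }
  structure(
    list(
      n_populations = n_populations,
      pop_weights = as.numeric(pop_weights),
      divergence = divergence,
      n_variants_range = as.integer(n_variants_range),
      rare_fraction = rare_fraction,
      rare_maf_range = as.numeric(rare_maf_range),
      common_maf_range = as.numeric(common_maf_range),
      nonsyn_prob = nonsyn_prob,
      coupling = coupling
    ),
    class = "pop_model"
  )
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population model:", x$n_populations, "population(s), divergence F =",
      x$divergence, "\n")
  cat("  variants/gene in [", x$n_variants_range[1], ",", x$n_variants_range[2],
      "], rare fraction", x$rare_fraction, ", coupling", x$coupling, "\n")
  invisible(x)
}

# Draw per-population frequencies around ancestral p with Balding-Nichols
# Beta(p(1-F)/F, (1-p)(1-F)/F); degenerate cases (F = 0, p in {0, 1})
# return p itself.
bn_pop_freqs <- function(p, n_pop, F) {
  if (F == 0 || p <= 0 || p >= 1) return(rep(p, n_pop))
  stats::rbeta(n_pop, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a structured-population genotype cohort
#'
#' Draws per-gene variant panels (ancestral frequencies, functional labels,
#' per-population frequencies) and phased founder haplotypes for
#' `n_individuals` individuals sampled from the model's populations.
#' Haplotypes are assembled per gene by independent Bernoulli draws per
#' variant (linkage equilibrium), optionally modified by the model's
#' `coupling` knob which places rare minor alleles preferentially on
#' haplotypes carrying the minor allele of the gene's anchor common variant.
#' Genotype scores are minor-allele counts, the sum of the two haplotypes.
#'
#' @param model a [pop_model()].
#' @param n_genes number of genes to simulate.
#' @param n_individuals cohort size (>= 2).
#' @param seed integer RNG seed; results are fully reproducible for a fixed
#'   seed.
#'
#' @return An object of class `geno_data`: a list with elements
#'   `genotypes` (individuals x variants integer matrix of 0/1/2 scores),
#'   `annotation` (data frame: `variant_id`, `gene`, `func_type`),
#'   `pop` (integer population label per individual),
#'   `haplotypes` (list of two 0/1 matrices `A`, `B`), and `pedigree`
#'   (`NULL` for an unrelated cohort).  The per-population frequency matrix
#'   is attached as attribute `pop_freqs`.
#' @export
simulate_population <- function(model, n_genes, n_individuals, seed) {
  if (!inherits(model, "pop_model")) stop_config("'model' must be a pop_model")
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop_config("'n_individuals' must be >= 2")
  }
  if (!is.numeric(n_genes) || n_genes < 1) stop_config("'n_genes' must be >= 1")
  n_genes <- as.integer(n_genes)
  n_individuals <- as.integer(n_individuals)
  set.seed(as.integer(seed))

  pop <- sample.int(model$n_populations, n_individuals,
                    replace = TRUE, prob = model$pop_weights)

  gene_sizes <- sample.int(model$n_variants_range[2] - model$n_variants_range[1] + 1L,
                           n_genes, replace = TRUE) + model$n_variants_range[1] - 1L
  m <- sum(gene_sizes)
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  gene_of <- rep(gene_names, gene_sizes)
  variant_ids <- paste0(gene_of, "V",
                        formatC(unlist(lapply(gene_sizes, seq_len)), width = 2, flag = "0"))

  is_rare_regime <- stats::runif(m) < model$rare_fraction
  ancestral <- ifelse(is_rare_regime,
                      stats::runif(m, model$rare_maf_range[1], model$rare_maf_range[2]),
                      stats::runif(m, model$common_maf_range[1], model$common_maf_range[2]))
  func_type <- ifelse(stats::runif(m) < model$nonsyn_prob,
                      "nonsynonymous", "synonymous")

  pop_freqs <- matrix(0, model$n_populations, m,
                      dimnames = list(NULL, variant_ids))
  for (v in seq_len(m)) {
    pop_freqs[, v] <- pmin(pmax(
      bn_pop_freqs(ancestral[v], model$n_populations, model$divergence), 0), 1)
  }

  # Haplotypes: Bernoulli(per-population frequency) per variant and
  # chromosome; each individual's two haplotypes are independent.
  pmat <- pop_freqs[pop, , drop = FALSE]
  hapA <- matrix((stats::runif(n_individuals * m) < pmat) * 1L, n_individuals, m)
  hapB <- matrix((stats::runif(n_individuals * m) < pmat) * 1L, n_individuals, m)

  if (model$coupling > 0) {
    col0 <- 0L
    for (g in seq_len(n_genes)) {
      cols <- col0 + seq_len(gene_sizes[g])
      col0 <- col0 + gene_sizes[g]
      anchor <- cols[!is_rare_regime[cols]][1]
      if (is.na(anchor)) next
      rare_cols <- cols[is_rare_regime[cols]]
      if (!length(rare_cols)) next
      # any haplotype carrying a rare minor allele gets the anchor minor
      # allele with probability `coupling`, independently per rare allele
      for (which_h in 1:2) {
        h <- if (which_h == 1) hapA else hapB
        carriers <- which(rowSums(h[, rare_cols, drop = FALSE]) > 0)
        if (length(carriers)) {
          n_rare_alleles <- rowSums(h[carriers, rare_cols, drop = FALSE])
          hit <- stats::runif(length(carriers)) <
            1 - (1 - model$coupling)^n_rare_alleles
          h[carriers[hit], anchor] <- 1L
          if (which_h == 1) hapA <- h else hapB <- h
        }
      }
    }
  }

  ids <- sprintf("IND%05d", seq_len(n_individuals))
  dimnames(hapA) <- dimnames(hapB) <- list(ids, variant_ids)
  geno <- hapA + hapB
  ann <- data.frame(variant_id = variant_ids, gene = gene_of,
                    func_type = func_type, stringsAsFactors = FALSE)
  out <- new_geno_data(geno, ann, pop = stats::setNames(pop, ids),
                       haplotypes = list(A = hapA, B = hapB))
  attr(out, "pop_freqs") <- pop_freqs
  attr(out, "ancestral_freqs") <- stats::setNames(ancestral, variant_ids)
  out
}

new_geno_data <- function(genotypes, annotation, pop = NULL,
                          haplotypes = NULL, pedigree = NULL) {
  stopifnot(is.matrix(genotypes),
            identical(colnames(genotypes), annotation$variant_id))
  structure(
    list(genotypes = genotypes, annotation = annotation, pop = pop,
         haplotypes = haplotypes, pedigree = pedigree),
    class = "geno_data"
  )
}

#' Assemble a `geno_data` object from explicit haplotypes
#'
#' Mainly useful for constructing small fixed examples: supply two phased
#' 0/1 haplotype matrices (individuals x variants) and a variant annotation
#' table; genotype scores are their sum.
#'
#' @param hapA,hapB 0/1 matrices of identical dimension, columns named by
#'   variant ID.
#' @param annotation data frame with columns `variant_id`, `gene`,
#'   `func_type` matching the haplotype columns.
#' @return A `geno_data` object.
#' @export
make_geno_data <- function(hapA, hapB, annotation) {
  hapA <- as.matrix(hapA); hapB <- as.matrix(hapB)
  if (!identical(dim(hapA), dim(hapB))) {
    stop_data("make_geno_data: haplotype matrices must have identical dimensions")
  }
  if (is.null(colnames(hapA))) colnames(hapA) <- annotation$variant_id
  colnames(hapB) <- colnames(hapA)
  if (is.null(rownames(hapA))) {
    rownames(hapA) <- rownames(hapB) <- sprintf("IND%05d", seq_len(nrow(hapA)))
  }
  if (!all(hapA %in% 0:1) || !all(hapB %in% 0:1)) {
    stop_data("make_geno_data: haplotypes must be 0/1")
  }
  new_geno_data(hapA + hapB, annotation,
                haplotypes = list(A = hapA, B = hapB))
}

#' @export
print.geno_data <- function(x, ...) {
  cat("geno_data:", nrow(x$genotypes), "individuals x", ncol(x$genotypes),
      "variants in", length(unique(x$annotation$gene)), "genes\n")
  if (!is.null(x$pedigree)) cat("  with pedigree (", nrow(x$pedigree), "members )\n")
  invisible(x)
}

#' Subset a genotype cohort by individuals
#'
#' @param geno a `geno_data` object.
#' @param idx row indices (or individual IDs) to keep.
#' @return A `geno_data` with the selected individuals; annotation unchanged.
#' @export
subset_individuals <- function(geno, idx) {
  stopifnot(inherits(geno, "geno_data"))
  haps <- geno$haplotypes
  if (!is.null(haps)) {
    haps <- list(A = haps$A[idx, , drop = FALSE], B = haps$B[idx, , drop = FALSE])
  }
  new_geno_data(geno$genotypes[idx, , drop = FALSE], geno$annotation,
                pop = geno$pop[idx], haplotypes = haps)
}

#' Describe a family structure template
#'
#' @param type `"nuclear"` (two founder parents and their children) or
#'   `"threegen"` (a founder grandparental couple, their children each
#'   married to a founder spouse, and one set of grandchildren per couple).
#' @param n_children number of children per mated couple (>= 1).
#' @return An object of class `family_template`.
#' @export
family_template <- function(type = c("nuclear", "threegen"), n_children = 2L) {
  type <- tryCatch(match.arg(type),
                   error = function(e) stop_config(
                     "family_template: 'type' must be \"nuclear\" or \"threegen\""))
  if (!is.numeric(n_children) || length(n_children) != 1L ||
      n_children < 1 || n_children != round(n_children)) {
    stop_config("family_template: 'n_children' must be a positive integer")
  }
  structure(list(type = type, n_children = as.integer(n_children)),
            class = "family_template")
}

one_family <- function(famid, template) {
  k <- template$n_children
  id <- function(i) sprintf("%s_%02d", famid, i)
  if (template$type == "nuclear") {
    data.frame(
      fam = famid,
      id = id(seq_len(2L + k)),
      father = c(NA, NA, rep(id(1), k)),
      mother = c(NA, NA, rep(id(2), k)),
      sex = c(1L, 2L, rep_len(c(1L, 2L), k)),
      stringsAsFactors = FALSE
    )
  } else {
    # threegen: 1 = grandfather, 2 = grandmother; 3..(2+k) their children;
    # (3+k)..(2+2k) founder spouses; then k grandchildren per couple.
    n_gen2 <- k
    gen2 <- 2L + seq_len(n_gen2)
    spouse <- 2L + n_gen2 + seq_len(n_gen2)
    gen2_sex <- rep_len(c(1L, 2L), n_gen2)
    rows <- list(data.frame(
      fam = famid,
      id = id(c(1:2, gen2, spouse)),
      father = c(NA, NA, rep(id(1), n_gen2), rep(NA, n_gen2)),
      mother = c(NA, NA, rep(id(2), n_gen2), rep(NA, n_gen2)),
      sex = c(1L, 2L, gen2_sex, 3L - gen2_sex),
      stringsAsFactors = FALSE
    ))
    next_id <- 2L + 2L * n_gen2
    for (j in seq_len(n_gen2)) {
      fa <- if (gen2_sex[j] == 1L) id(gen2[j]) else id(spouse[j])
      mo <- if (gen2_sex[j] == 1L) id(spouse[j]) else id(gen2[j])
      rows[[j + 1L]] <- data.frame(
        fam = famid, id = id(next_id + seq_len(k)),
        father = fa, mother = mo, sex = rep_len(c(1L, 2L), k),
        stringsAsFactors = FALSE
      )
      next_id <- next_id + k
    }
    do.call(rbind, rows)
  }
}

#' Generate a pedigree forest from a family template
#'
#' @param n_families number of independent families (0 gives an empty
#'   pedigree).
#' @param template a [family_template()].
#' @param seed unused placeholder for template types with random structure;
#'   the built-in templates are deterministic.
#' @return A data frame of class `pedigree` with columns `fam`, `id`,
#'   `father`, `mother` (NA for founders), `sex` (1 = male, 2 = female) and
#'   `founder` (TRUE iff both parents absent).
#' @export
generate_pedigrees <- function(n_families,
                               template = family_template("nuclear", 2L),
                               seed = NULL) {
  if (!inherits(template, "family_template")) {
    stop_config("generate_pedigrees: 'template' must be a family_template")
  }
  if (!is.numeric(n_families) || n_families < 0 ||
      n_families != round(n_families)) {
    stop_config("generate_pedigrees: 'n_families' must be a nonnegative integer")
  }
  n_families <- as.integer(n_families)
  if (n_families == 0L) {
    ped <- data.frame(fam = character(), id = character(),
                      father = character(), mother = character(),
                      sex = integer(), founder = logical(),
                      stringsAsFactors = FALSE)
    class(ped) <- c("pedigree", "data.frame")
    return(ped)
  }
  fams <- lapply(seq_len(n_families), function(f) {
    one_family(sprintf("FAM%03d", f), template)
  })
  ped <- do.call(rbind, fams)
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks ID uniqueness, that referenced parents exist, that each individual
#' has either both parents or neither, and that the parent-child graph is
#' acyclic.  Called internally by [kinship_from_pedigree()] and
#' [gene_drop()]; errors carry class `synthcorr_structural_error` or
#' `synthcorr_data_error`.
#'
#' @param ped a pedigree data frame (`fam`, `id`, `father`, `mother`).
#' @return The topological order of individual IDs, invisibly.
#' @export
validate_pedigree <- function(ped) {
  need <- c("fam", "id", "father", "mother")
  if (!all(need %in% names(ped))) {
    stop_data(paste("pedigree is missing columns:",
                    paste(setdiff(need, names(ped)), collapse = ", ")))
  }
  if (anyDuplicated(ped$id)) {
    stop_data(paste("duplicate individual IDs:",
                    paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  has_f <- !is.na(ped$father); has_m <- !is.na(ped$mother)
  if (any(has_f != has_m)) {
    stop_data(paste("individuals with exactly one parent recorded:",
                    paste(ped$id[has_f != has_m], collapse = ", ")))
  }
  parents <- unique(c(ped$father[has_f], ped$mother[has_m]))
  unknown <- setdiff(parents, ped$id)
  if (length(unknown)) {
    stop_data(paste("parent IDs not present in pedigree:",
                    paste(unknown, collapse = ", ")))
  }
  invisible(topo_order(ped))
}

# Kahn topological sort, parents before children, ties broken by ID.
topo_order <- function(ped) {
  n <- nrow(ped)
  if (n == 0L) return(character())
  idx <- stats::setNames(seq_len(n), ped$id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        children[[j]] <- c(children[[j]], i)
        indeg[i] <- indeg[i] + 1L
      }
    }
  }
  ready <- sort(ped$id[indeg == 0L])
  out <- character(0)
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (ch in children[[idx[[v]]]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ped$id[ch]))
    }
  }
  if (length(out) != n) {
    stop_structural("pedigree contains a cycle (an individual is its own ancestor)")
  }
  out
}

#' Drop founder haplotypes through a pedigree
#'
#' Assigns each pedigree founder a pair of phased gene-level haplotypes from
#' the founder pool (founders sorted by ID are matched to pool rows in
#' order), then simulates Mendelian transmission: every non-founder
#' receives, per gene, one whole haplotype chosen uniformly at random from
#' each parent's two haplotypes.  Choices are independent across genes and
#' meioses; there is no recombination within genes.
#'
#' @param pedigree a `pedigree` data frame (see [generate_pedigrees()]).
#' @param founders a `geno_data` with phased haplotypes and at least as many
#'   individuals as the pedigree has founders.
#' @param seed integer RNG seed.
#' @return A `geno_data` for all pedigree members (rows in pedigree order),
#'   with phased haplotypes and the pedigree attached.
#' @export
gene_drop <- function(pedigree, founders, seed) {
  stopifnot(inherits(founders, "geno_data"))
  if (is.null(founders$haplotypes)) {
    stop_data("gene_drop: founder pool carries no phased haplotypes")
  }
  ord <- validate_pedigree(pedigree)
  founder_ids <- sort(pedigree$id[pedigree$founder])
  nf <- length(founder_ids)
  if (nrow(founders$genotypes) < nf) {
    missing_from <- founder_ids[nrow(founders$genotypes) + 1L]
    stop_data(sprintf(
      "gene_drop: founder pool has %d individuals but pedigree needs %d (no haplotypes for founder '%s')",
      nrow(founders$genotypes), nf, missing_from))
  }
  set.seed(as.integer(seed))

  ann <- founders$annotation
  m <- nrow(ann)
  genes <- unique(ann$gene)
  gene_sizes <- as.integer(table(factor(ann$gene, levels = genes)))
  n_genes <- length(genes)

  n <- nrow(pedigree)
  ids <- pedigree$id
  hapA <- matrix(0L, n, m, dimnames = list(ids, ann$variant_id))
  hapB <- hapA
  row_of <- stats::setNames(seq_len(n), ids)
  hapA[founder_ids, ] <- founders$haplotypes$A[seq_len(nf), , drop = FALSE]
  hapB[founder_ids, ] <- founders$haplotypes$B[seq_len(nf), , drop = FALSE]

  father_of <- stats::setNames(pedigree$father, ids)
  mother_of <- stats::setNames(pedigree$mother, ids)
  is_founder <- stats::setNames(pedigree$founder, ids)
  for (who in ord) {
    if (is_founder[[who]]) next
    fa <- row_of[[father_of[[who]]]]
    mo <- row_of[[mother_of[[who]]]]
    pickA <- rep(stats::runif(n_genes) < 0.5, gene_sizes)
    pickB <- rep(stats::runif(n_genes) < 0.5, gene_sizes)
    i <- row_of[[who]]
    hapA[i, ] <- ifelse(pickA, hapA[fa, ], hapB[fa, ])
    hapB[i, ] <- ifelse(pickB, hapA[mo, ], hapB[mo, ])
  }

  new_geno_data(hapA + hapB, ann,
                haplotypes = list(A = hapA, B = hapB),
                pedigree = pedigree)
}
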