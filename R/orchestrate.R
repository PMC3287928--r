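#' Tally nominally significant regressions
#'
#' Cross-classifies status-ok tests by (common variant functional type x
#' rare-variant stratum) and counts those with p below `alpha`, mirroring
#' the "N significant / N total / % significant" layout of synthetic
#' association surveys.  Cell and overall LRT means and SDs are reported
#' alongside.
#'
#' @param results a [run_gene_tests()] result data frame.
#' @param alpha nominal significance level in (0, 1); default 0.05.
#' @return Data frame with one row per cell: `common_func_type`,
#'   `rare_stratum`, `n_significant`, `n_total`, `pct_significant`,
#'   `mean_lrt`, `sd_lrt`.  The overall summary (counts, fraction, LRT
#'   mean/SD over all ok tests) is attached as attribute `overall`.
#' @export
tally_significant <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("tally_significant: 'alpha' must be in (0, 1)")
  }
  empty <- data.frame(common_func_type = character(),
                      rare_stratum = character(),
                      n_significant = integer(), n_total = integer(),
                      pct_significant = numeric(),
                      mean_lrt = numeric(), sd_lrt = numeric(),
                      stringsAsFactors = FALSE)
  ok <- results[results$status == "ok", , drop = FALSE]
  if (!nrow(ok)) {
    warning("tally_significant: no status-ok tests to tally")
    attr(empty, "overall") <- list(n_total = 0L, n_significant = 0L,
                                   pct_significant = NA_real_,
                                   mean_lrt = NA_real_, sd_lrt = NA_real_)
    return(empty)
  }
  cells <- unique(ok[, c("common_func_type", "rare_stratum")])
  cells <- cells[order(cells$common_func_type, cells$rare_stratum), ,
                 drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- ok$common_func_type == cells$common_func_type[i] &
      ok$rare_stratum == cells$rare_stratum[i]
    sub <- ok[sel, , drop = FALSE]
    ns <- sum(sub$p_value < alpha)
    data.frame(common_func_type = cells$common_func_type[i],
               rare_stratum = cells$rare_stratum[i],
               n_significant = ns, n_total = nrow(sub),
               pct_significant = 100 * ns / nrow(sub),
               mean_lrt = mean(sub$lrt),
               sd_lrt = if (nrow(sub) > 1) stats::sd(sub$lrt) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- list(
    n_total = nrow(ok),
    n_significant = sum(ok$p_value < alpha),
    pct_significant = 100 * mean(ok$p_value < alpha),
    mean_lrt = mean(ok$lrt),
    sd_lrt = stats::sd(ok$lrt)
  )
  out
}

#' Paired comparison of unrelated and family regression results
#'
#' Joins the two runs on (gene, rare stratum), reports each sample's
#' rare-variant count and regression estimates, and flags the rows whose
#' rare-variant ID sets are identical in both samples (the only rows where
#' the burden predictor is built from exactly the same variants, hence
#' directly comparable).  Both runs must cover the same genes and share
#' their common-variant draws.
#'
#' @param results_unrelated,results_family [run_gene_tests()] results.
#' @param classification_unrelated,classification_family the matching
#'   variant classifications; taken from the results' attributes when
#'   omitted.
#' @return Data frame: `gene`, `common_variant_id`, `rare_stratum`,
#'   `n_rare_unrelated`, `n_rare_family`, `beta_unrelated`,
#'   `lrt_unrelated`, `beta_family`, `lrt_family`, `identical_rare_set`.
#' @export
compare_samples <- function(results_unrelated, results_family,
                            classification_unrelated = NULL,
                            classification_family = NULL) {
  classification_unrelated <- classification_unrelated %||%
    attr(results_unrelated, "classification")
  classification_family <- classification_family %||%
    attr(results_family, "classification")
  if (is.null(classification_unrelated) || is.null(classification_family)) {
    stop_data("compare_samples: classifications unavailable")
  }
  gu <- unique(results_unrelated$gene)
  gf <- unique(results_family$gene)
  if (!setequal(gu, gf)) {
    stop_structural("compare_samples: the two runs cover different gene universes")
  }
  key <- function(df) paste(df$gene, df$rare_stratum, sep = "\r")
  mf <- results_family[match(key(results_unrelated), key(results_family)), ,
                       drop = FALSE]
  if (any(!is.na(mf$common_variant_id) &
            mf$common_variant_id != results_unrelated$common_variant_id)) {
    stop_structural("compare_samples: the two runs drew different common variants")
  }
  rare_ids <- function(cl, gene, stratum) {
    keep <- cl$gene == gene & cl$category == "rare"
    if (stratum != "all") keep <- keep & cl$func_type == stratum
    cl$variant_id[keep]
  }
  out <- data.frame(
    gene = results_unrelated$gene,
    common_variant_id = results_unrelated$common_variant_id,
    rare_stratum = results_unrelated$rare_stratum,
    n_rare_unrelated = results_unrelated$n_rare,
    n_rare_family = mf$n_rare,
    beta_unrelated = results_unrelated$beta,
    lrt_unrelated = results_unrelated$lrt,
    beta_family = mf$beta,
    lrt_family = mf$lrt,
    stringsAsFactors = FALSE
  )
  out$identical_rare_set <- vapply(seq_len(nrow(out)), function(i) {
    ru <- rare_ids(classification_unrelated, out$gene[i], out$rare_stratum[i])
    rf <- rare_ids(classification_family, out$gene[i], out$rare_stratum[i])
    length(ru) > 0 && setequal(ru, rf)
  }, logical(1))
  rownames(out) <- NULL
  out
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    thresholds = list(maf_common = 0.10, maf_rare = 0.01,
                      min_variants = 10L, max_variants = 50L,
                      count_all = TRUE),
    model = list(stratify = TRUE, alpha = 0.05),
    pca = list(n_pcs = 0L),
    ld = TRUE
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

in_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "synthcorr_error") && !grepl("^\\[", conditionMessage(e))) {
      e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
      stop(e)
    }
  })
}

#' Run the full rare-to-common prediction pipeline
#'
#' Executes simulate (optional) -> classify -> select genes -> draw common
#' variants -> regress (OLS for the unrelated cohort, kinship
#' variance-component model for the family cohort) -> LD -> tally ->
#' paired comparison, from a single configuration.  When a family cohort
#' is requested, the unrelated individuals and the pedigree founders are
#' drawn from one population simulation so the two cohorts share their
#' variant panel, genes are selected on the unrelated sample, and the
#' family run reuses the unrelated run's gene list and common-variant
#' draws (rare sets are re-derived within the family sample, where founder
#' effects change frequencies).
#'
#' @param config a named list, or the path of a YAML file, with blocks:
#'   \describe{
#'     \item{seed}{integer; drives every random stage.}
#'     \item{simulate}{`n_genes`, `n_unrelated`, `model` (arguments of
#'       [pop_model()]), optional `families` (`n_families`, `template`
#'       = "nuclear"/"threegen", `n_children`).}
#'     \item{input}{alternative to `simulate`: `genotypes` + `annotation`
#'       TSV paths, optional `family_genotypes` + `pedigree` (PED).}
#'     \item{thresholds}{`maf_common`, `maf_rare`, `min_variants`,
#'       `max_variants`, `count_all`.}
#'     \item{model}{`stratify`, `alpha`.}
#'     \item{pca}{`n_pcs` (0 disables the stratification correction).}
#'     \item{ld}{logical; compute per-gene LD summaries.}
#'   }
#' @param out_dir optional directory; when given, every table is written
#'   as TSV together with a `manifest.yaml` echoing the configuration,
#'   seed, package version, per-stage counts and common-variant draws.
#' @return A list: `unrelated` (classification, selection, results, tally,
#'   ld), `family` (or NULL), `comparison` (or NULL) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("run_pipeline: 'config' must be a list or YAML path")
  cfg <- merge_config(pipeline_defaults(), config)
  seed <- as.integer(cfg$seed)
  th <- cfg$thresholds

  ped <- NULL; fam_geno <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    model <- in_stage("simulate", do.call(pop_model, sim$model %||% list()))
    fams <- sim$families
    if (!is.null(fams)) {
      tmpl <- family_template(fams$template %||% "nuclear",
                              fams$n_children %||% 2L)
      ped <- in_stage("simulate", generate_pedigrees(fams$n_families, tmpl))
      if (!nrow(ped)) ped <- NULL
    }
    n_founders <- if (is.null(ped)) 0L else sum(ped$founder)
    pool <- in_stage("simulate", simulate_population(
      model, sim$n_genes, sim$n_unrelated + n_founders,
      seed = derive_seed(seed, 1L)))
    unrel <- subset_individuals(pool, seq_len(sim$n_unrelated))
    if (!is.null(ped)) {
      founders <- subset_individuals(pool, sim$n_unrelated + seq_len(n_founders))
      fam_geno <- in_stage("simulate",
                           gene_drop(ped, founders, seed = derive_seed(seed, 2L)))
    }
  } else if (!is.null(cfg$input)) {
    inp <- cfg$input
    unrel <- in_stage("input", read_geno_tsv(inp$genotypes, inp$annotation))
    if (!is.null(inp$pedigree)) {
      ped <- in_stage("input", read_ped(inp$pedigree))
      fam_geno <- in_stage("input",
                           read_geno_tsv(inp$family_genotypes, inp$annotation))
      fam_geno$pedigree <- ped
    }
  } else {
    stop_config("run_pipeline: config needs a 'simulate' or 'input' block")
  }

  cls_u <- in_stage("classify", classify_variants(
    unrel, maf_common = th$maf_common, maf_rare = th$maf_rare))
  sel <- in_stage("select", select_genes(
    cls_u, th$min_variants, th$max_variants, th$count_all))
  if (!nrow(sel)) stop_data("[select] no genes passed the variant-count/common-variant filters")

  covar <- NULL
  if ((cfg$pca$n_pcs %||% 0L) > 0L) {
    covar <- in_stage("pca", pca_covariates(unrel, cls_u, k = cfg$pca$n_pcs))
  }

  res_u <- in_stage("regress-unrelated", run_gene_tests(
    unrel, model = "ols", covariates = covar,
    stratify = isTRUE(cfg$model$stratify), seed = derive_seed(seed, 3L),
    classification = cls_u, selection = sel))
  tally_u <- tally_significant(res_u, cfg$model$alpha)
  ld_u <- if (isTRUE(cfg$ld)) in_stage("ld", ld_table(unrel, res_u)) else NULL

  family <- NULL; comparison <- NULL
  if (!is.null(fam_geno)) {
    cls_f <- in_stage("classify", classify_variants(
      fam_geno, maf_common = th$maf_common, maf_rare = th$maf_rare))
    kin <- in_stage("kinship", kinship_eigen(kinship_from_pedigree(ped)))
    res_f <- in_stage("regress-family", run_gene_tests(
      fam_geno, model = "polygenic", kinship = kin,
      stratify = isTRUE(cfg$model$stratify),
      classification = cls_f, selection = sel,
      common_draws = attr(res_u, "common_draws")))
    tally_f <- tally_significant(res_f, cfg$model$alpha)
    ld_f <- if (isTRUE(cfg$ld)) in_stage("ld", ld_table(fam_geno, res_f)) else NULL
    comparison <- in_stage("compare", compare_samples(res_u, res_f))
    family <- list(classification = cls_f, results = res_f,
                   tally = tally_f, ld = ld_f, pedigree = ped)
  }

  manifest <- list(
    package = "synthcorr",
    version = as.character(utils::packageVersion("synthcorr")),
    seed = seed,
    config = cfg,
    counts = list(
      n_variants = nrow(cls_u),
      n_genes_total = length(unique(cls_u$gene)),
      n_genes_selected = nrow(sel),
      n_tests_unrelated = nrow(res_u),
      n_tests_family = if (is.null(family)) 0L else nrow(family$results)
    ),
    common_draws = as.list(attr(res_u, "common_draws"))
  )

  bundle <- list(
    unrelated = list(classification = cls_u, selection = sel,
                     results = res_u, tally = tally_u, ld = ld_u),
    family = family,
    comparison = comparison,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir)
  bundle
}

#' Write a pipeline bundle to a directory of TSVs
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_plain(bundle$unrelated$classification, p("classification_unrelated.tsv"))
  write_tsv_plain(bundle$unrelated$selection, p("gene_selection.tsv"))
  write_tsv_plain(bundle$unrelated$results, p("results_unrelated.tsv"))
  write_tsv_plain(bundle$unrelated$tally, p("tally_unrelated.tsv"))
  if (!is.null(bundle$unrelated$ld)) {
    write_tsv_plain(bundle$unrelated$ld, p("ld_unrelated.tsv"))
  }
  if (!is.null(bundle$family)) {
    write_tsv_plain(bundle$family$classification, p("classification_family.tsv"))
    write_tsv_plain(bundle$family$results, p("results_family.tsv"))
    write_tsv_plain(bundle$family$tally, p("tally_family.tsv"))
    if (!is.null(bundle$family$ld)) {
      write_tsv_plain(bundle$family$ld, p("ld_family.tsv"))
    }
    write_ped(bundle$family$pedigree, p("pedigree.ped"))
  }
  if (!is.null(bundle$comparison)) {
    write_tsv_plain(bundle$comparison, p("comparison.tsv"))
  }
  yaml::write_yaml(bundle$manifest, p("manifest.yaml"))
  invisible(out_dir)
}
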