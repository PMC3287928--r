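# Plain-text readers and writers.  Genotypes travel as TSV score matrices
# (individuals x variants) or VCF; annotation, classification, results and
# kinship as TSV; pedigrees as 6-column PED/FAM.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write / read a genotype score matrix as TSV
#'
#' The first column (`id`) holds individual IDs; remaining columns are
#' variant IDs with 0/1/2 minor-allele counts.
#'
#' @param geno a `geno_data` or score matrix.
#' @param path file path.
#' @export
write_geno_tsv <- function(geno, path) {
  g <- if (inherits(geno, "geno_data")) geno$genotypes else geno
  df <- data.frame(id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_geno_tsv
#' @param annotation_path TSV with columns `variant_id`, `gene`,
#'   `func_type`.
#' @return `read_geno_tsv` returns a `geno_data` (without phase).
#' @export
read_geno_tsv <- function(path, annotation_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("variant_id", "gene", "func_type")
  if (!all(need %in% names(ann))) {
    stop_data(paste("annotation file lacks columns:",
                    paste(setdiff(need, names(ann)), collapse = ", ")))
  }
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df$id
  if (!identical(colnames(g), ann$variant_id)) {
    if (!setequal(colnames(g), ann$variant_id)) {
      stop_data("genotype columns and annotation variant_id do not match")
    }
    ann <- ann[match(colnames(g), ann$variant_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  new_geno_data(g, ann)
}

#' Write / read a pedigree as PED/FAM
#'
#' Columns: family, individual, father, mother, sex (1/2), phenotype
#' (always 0 here); missing parents are coded "0"; no header.
#'
#' @param ped a `pedigree` data frame.
#' @param path file path.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    fam = ped$fam, id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ped$sex, phenotype = 0L, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_ped
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("fam", "id", "father", "mother",
                                        "sex", "phenotype"))
  df$id <- as.character(df$id)
  df$father <- ifelse(df$father == "0", NA_character_, as.character(df$father))
  df$mother <- ifelse(df$mother == "0", NA_character_, as.character(df$mother))
  ped <- df[, c("fam", "id", "father", "mother", "sex")]
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Write genotypes as a minimal VCF
#'
#' Emits VCFv4.2 with one record per variant (placeholder chromosome 1 and
#' sequential positions, REF = A, ALT = T) and a GT field per individual.
#' When the cohort carries phased haplotypes the genotypes are written
#' phased (`a|b`), otherwise unphased (`a/b`).
#'
#' @param geno a `geno_data`.
#' @param path file path.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_data"))
  g <- geno$genotypes
  phased <- !is.null(geno$haplotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=synthcorr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  ), con)
  sep <- if (phased) "|" else "/"
  for (j in seq_len(ncol(g))) {
    gt <- if (phased) {
      paste(geno$haplotypes$A[, j], geno$haplotypes$B[, j], sep = sep)
    } else {
      c("0/0", "0/1", "1/1")[g[, j] + 1L]
    }
    writeLines(paste(c("1", j, colnames(g)[j], "A", "T", ".", ".", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Uses the vcfR package to parse the file and converts GT to minor-allele
#' (ALT-allele) counts.  Multi-allelic records are rejected.
#'
#' @param path VCF path.
#' @param annotation data frame (`variant_id`, `gene`, `func_type`)
#'   covering the VCF's variant IDs.
#' @return A `geno_data`.
#' @export
read_vcf_geno <- function(path, annotation) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("read_vcf_geno requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    stop_data("read_vcf_geno: multi-allelic records are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[|/]")[[1]]))
  })
  g <- t(counts)
  colnames(g) <- vcfR::getID(v)
  ann <- annotation[match(colnames(g), annotation$variant_id), , drop = FALSE]
  if (anyNA(ann$variant_id)) {
    stop_data("read_vcf_geno: annotation does not cover every VCF variant")
  }
  rownames(ann) <- NULL
  new_geno_data(g, ann)
}

#' Write a kinship matrix as TSV
#'
#' @param kinship a `kinship_matrix`.
#' @param path file path.
#' @param format `"triplet"` (id1, id2, phi for the upper triangle
#'   including the diagonal) or `"dense"` (full matrix with an `id`
#'   column).
#' @export
write_kinship_tsv <- function(kinship, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  K <- unclass(kinship)
  if (format == "dense") {
    write_tsv_plain(data.frame(id = rownames(K), K, check.names = FALSE), path)
  } else {
    ut <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
    write_tsv_plain(data.frame(id1 = rownames(K)[ut[, 1]],
                               id2 = colnames(K)[ut[, 2]],
                               phi = K[ut]), path)
  }
  invisible(path)
}
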