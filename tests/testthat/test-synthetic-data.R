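test_that("pop_model validates its fields and names the offender", {
  expect_error(pop_model(n_populations = 0), "n_populations",
               class = "synthcorr_config_error")
  expect_error(pop_model(pop_weights = c(0.6, 0.6), n_populations = 2),
               "pop_weights", class = "synthcorr_config_error")
  expect_error(pop_model(divergence = 1), "divergence",
               class = "synthcorr_config_error")
  expect_error(pop_model(rare_fraction = 1.2), "rare_fraction",
               class = "synthcorr_config_error")
  expect_error(pop_model(n_variants_range = c(5, 3)), "n_variants_range",
               class = "synthcorr_config_error")
})

test_that("simulated cohorts respect the model's structural invariants", {
  m <- pop_model(n_populations = 3, divergence = 0.05,
                 n_variants_range = c(12, 18))
  g <- simulate_population(m, n_genes = 30, n_individuals = 100, seed = 1)
  freqs <- attr(g, "pop_freqs")
  expect_true(all(freqs >= 0 & freqs <= 1))
  sizes <- table(g$annotation$gene)
  expect_true(all(sizes >= 12 & sizes <= 18))
  # genotype scores reconstruct from the two haplotypes
  expect_identical(g$genotypes, g$haplotypes$A + g$haplotypes$B)
  expect_true(all(g$genotypes %in% 0:2))
  expect_true(all(g$pop %in% 1:3))
})

test_that("with no structure, empirical MAFs converge to ancestral frequencies", {
  m <- pop_model(n_populations = 1, divergence = 0,
                 n_variants_range = c(10, 15), rare_fraction = 0.3)
  g <- simulate_population(m, n_genes = 5, n_individuals = 5000, seed = 2)
  p <- attr(g, "ancestral_freqs")
  phat <- colMeans(g$genotypes) / 2
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(phat - p) <= 3 * se + 1e-12))
})

test_that("a zero ancestral frequency yields all-zero genotype scores", {
  m <- pop_model(rare_fraction = 1, rare_maf_range = c(0, 0))
  g <- simulate_population(m, n_genes = 3, n_individuals = 50, seed = 3)
  expect_true(all(g$genotypes == 0))
})

test_that("between-population divergence matches a direct beta-draw oracle", {
  # fix the ancestral frequency at 0.3 so the oracle draws from exactly
  # one beta distribution
  F <- 0.2
  m <- pop_model(n_populations = 2, divergence = F, rare_fraction = 0,
                 common_maf_range = c(0.3, 0.3), n_variants_range = c(30, 30))
  g <- simulate_population(m, n_genes = 100, n_individuals = 2, seed = 4)
  freqs <- attr(g, "pop_freqs")
  sim_diff <- mean(abs(freqs[1, ] - freqs[2, ]))
  set.seed(1234)
  a <- 0.3 * (1 - F) / F; b <- 0.7 * (1 - F) / F
  oracle_diff <- mean(abs(rbeta(10000, a, b) - rbeta(10000, a, b)))
  expect_lt(abs(sim_diff - oracle_diff) / oracle_diff, 0.02)
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  m <- pop_model(n_populations = 2, divergence = 0.02)
  g1 <- simulate_population(m, 10, 60, seed = 7)
  g2 <- simulate_population(m, 10, 60, seed = 7)
  g3 <- simulate_population(m, 10, 60, seed = 8)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$annotation, g2$annotation)
  expect_false(identical(g1$genotypes, g3$genotypes))
})

test_that("pedigree templates produce the expected founder/non-founder counts", {
  ped <- generate_pedigrees(3, family_template("nuclear", 2))
  expect_equal(sum(ped$founder), 6)
  expect_equal(sum(!ped$founder), 6)
  expect_false(anyDuplicated(ped$id) > 0)

  empty <- generate_pedigrees(0)
  expect_s3_class(empty, "pedigree")
  expect_equal(nrow(empty), 0)

  tg <- generate_pedigrees(2, family_template("threegen", 2))
  # founder flag true exactly for individuals without parents
  expect_identical(tg$founder, is.na(tg$father) & is.na(tg$mother))
  # grandparents + one founder spouse per second-generation child
  expect_equal(sum(tg$founder), 2 * (2 + 2))
  expect_error(generate_pedigrees(2, template = list(type = "nuclear")),
               class = "synthcorr_config_error")
})

test_that("gene dropping is Mendelian, reproducible, and preserves monomorphism", {
  m <- pop_model(n_variants_range = c(10, 12))
  ped <- generate_pedigrees(4, family_template("threegen", 2))
  founders <- simulate_population(m, 5, sum(ped$founder), seed = 11)
  fam <- gene_drop(ped, founders, seed = 12)
  expect_true(check_mendelian(fam))
  fam2 <- gene_drop(ped, founders, seed = 12)
  expect_identical(fam$genotypes, fam2$genotypes)

  # founder-pool monomorphic variants stay monomorphic in all descendants
  mono <- colSums(subset_individuals(founders,
                                     seq_len(sum(ped$founder)))$genotypes) == 0
  expect_true(any(mono))
  expect_true(all(fam$genotypes[, mono] == 0))
})

test_that("a het x hom-major cross transmits the minor allele half the time", {
  n_fam <- 10000
  ped <- generate_pedigrees(n_fam, family_template("nuclear", 1))
  ann <- tiny_annotation("G1", 1)
  nf <- sum(ped$founder)
  # odd founders (fathers) het (1|0), even founders (mothers) hom major
  hapA <- matrix(rep(c(1L, 0L), length.out = nf), ncol = 1)
  hapB <- matrix(0L, nf, 1)
  founders <- make_geno_data(hapA, hapB, ann)
  fam <- gene_drop(ped, founders, seed = 21)
  kids <- fam$genotypes[!fam$pedigree$founder, 1]
  expect_true(all(kids %in% 0:1))
  se <- sqrt(0.25 / n_fam)
  expect_lt(abs(mean(kids == 1) - 0.5), 3 * se)
})

test_that("descendant allele frequency is a martingale of the founder frequency", {
  m <- pop_model(rare_fraction = 0, common_maf_range = c(0.2, 0.2),
                 n_variants_range = c(10, 10))
  ped <- generate_pedigrees(1000, family_template("nuclear", 2))
  founders <- simulate_population(m, 1, sum(ped$founder), seed = 31)
  fam <- gene_drop(ped, founders, seed = 32)
  kids <- fam$genotypes[!fam$pedigree$founder, , drop = FALSE]
  f_founder <- colMeans(founders$genotypes) / 2
  f_kids <- colMeans(kids) / 2
  # each child genotype is one draw per parent; 2000 children
  se <- sqrt(f_founder * (1 - f_founder) / (2 * nrow(kids)))
  expect_true(all(abs(f_kids - f_founder) <= 3 * se))
})

test_that("singleton rare alleles are lost in a positive fraction of small pedigrees", {
  n_fam <- 300
  ped <- generate_pedigrees(n_fam, family_template("nuclear", 2))
  ann <- tiny_annotation("G1", 1)
  nf <- sum(ped$founder)
  hapA <- matrix(0L, nf, 1); hapA[seq(1, nf, by = 2), 1] <- 1L # one carrier parent per family
  founders <- make_geno_data(hapA, matrix(0L, nf, 1), ann)
  fam <- gene_drop(ped, founders, seed = 41)
  lost <- vapply(split(seq_len(nrow(ped)), ped$fam), function(rows) {
    kids <- rows[!ped$founder[rows]]
    all(fam$genotypes[kids, 1] == 0)
  }, logical(1))
  expect_gt(mean(lost), 0) # founder effect: monomorphization happens
  expect_lt(mean(lost), 1) # ...but not always
})

test_that("gene_drop identifies a founder missing from the pool", {
  ped <- generate_pedigrees(2, family_template("nuclear", 1))
  ann <- tiny_annotation("G1", 2)
  founders <- make_geno_data(matrix(0L, 2, 2), matrix(0L, 2, 2), ann)
  expect_error(gene_drop(ped, founders, seed = 1), "FAM002",
               class = "synthcorr_data_error")
})
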