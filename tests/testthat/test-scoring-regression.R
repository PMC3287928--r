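make_gene_fixture <- function(n = 40, n_common = 4, n_rare = 6, seed = 2) {
  set.seed(seed)
  n_var <- n_common + n_rare
  ann <- tiny_annotation("G1", n_var)
  geno <- cbind(
    matrix(sample(0:2, n * n_common, replace = TRUE, prob = c(.5, .4, .1)),
           n, n_common),
    matrix(rbinom(n * n_rare, 1, 0.04), n, n_rare)
  )
  colnames(geno) <- ann$variant_id
  rownames(geno) <- sprintf("I%03d", seq_len(n))
  cl <- ann
  cl$maf <- c(rep(0.3, n_common), rep(0.005, n_rare))
  cl$has_minor_homozygote <- FALSE
  cl$flipped <- FALSE
  cl$category <- c(rep("common", n_common), rep("rare", n_rare))
  list(geno = geno, cl = cl)
}

test_that("build_scores sums the stratum's rare variants and respects bounds", {
  fx <- make_gene_fixture()
  sp <- build_scores("G1", fx$cl, fx$geno, stratum = "all", seed = 1)
  expect_equal(sp$srvgs, rowSums(fx$geno[, fx$cl$category == "rare"]),
               ignore_attr = TRUE)
  expect_true(all(sp$srvgs >= 0 & sp$srvgs <= 2 * sp$n_rare))
  expect_equal(sp$n_rare, 6)

  # an individual with rare-stratum scores (0,1,0,1) has burden 2
  geno1 <- fx$geno
  rare_ids <- fx$cl$variant_id[fx$cl$category == "rare"]
  geno1[1, rare_ids] <- c(0, 1, 0, 1, 0, 0)
  sp1 <- build_scores("G1", fx$cl, geno1, stratum = "all", seed = 1)
  expect_equal(unname(sp1$srvgs[1]), 2)

  # stratified sums use only the matching functional type
  sp_ns <- build_scores("G1", fx$cl, fx$geno, stratum = "nonsynonymous", seed = 1)
  ns_ids <- fx$cl$variant_id[fx$cl$category == "rare" &
                               fx$cl$func_type == "nonsynonymous"]
  expect_equal(sp_ns$srvgs, rowSums(fx$geno[, ns_ids, drop = FALSE]),
               ignore_attr = TRUE)
})

test_that("the common variant draw is uniform over the gene's common variants", {
  fx <- make_gene_fixture()
  only_one <- fx$cl
  only_one$category[2:4] <- "excluded"
  for (s in c(3, 17, 4242)) {
    expect_equal(build_scores("G1", only_one, fx$geno, seed = s)$common_variant_id,
                 "G1V01")
  }
  set.seed(77)
  draws <- replicate(10000,
    build_scores("G1", fx$cl, fx$geno, stratum = "all")$common_variant_id)
  freq <- table(draws) / 10000
  expect_equal(length(freq), 4)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) <= 3 * se))
})

test_that("fit_ols matches a closed-form oracle and guards degenerate inputs", {
  set.seed(3)
  x <- rpois(20, 1); x[1] <- 3
  y <- 0.4 * x + rnorm(20)
  fit <- fit_ols(y, x)
  o <- ols_oracle(y, x)
  expect_equal(fit$beta, o$beta, tolerance = 1e-8)
  expect_equal(fit$lrt, o$lrt, tolerance = 1e-8)
  expect_equal(fit$p_value, pchisq(o$lrt, 1, lower.tail = FALSE))

  # a perfect fit is guarded, not infinite
  idfit <- fit_ols(x, x)
  expect_equal(idfit$beta, 1, tolerance = 1e-10)
  expect_lt(idfit$p_value, 1e-12)
  expect_true(is.finite(idfit$lrt))

  # all-zero burden (the family monomorphization case) is skipped
  sk <- fit_ols(y, rep(0, 20))
  expect_equal(sk$status, "skipped_monomorphic")
  expect_true(is.na(sk$beta) && is.na(sk$lrt) && is.na(sk$p_value))

  expect_error(fit_ols(y, x, covariates = cbind(1, rep(2, 20))),
               class = "synthcorr_numerical_error")
})

test_that("adding a constant to the response moves only the intercept", {
  set.seed(4)
  x <- rpois(60, 0.7); y <- 0.2 * x + rnorm(60)
  f1 <- fit_ols(y, x); f2 <- fit_ols(y + 5, x)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-8)

  ped <- generate_pedigrees(10, family_template("nuclear", 2))
  ke <- kinship_eigen(kinship_from_pedigree(ped))
  yk <- y[1:40]; xk <- x[1:40]
  p1 <- fit_polygenic(yk, xk, ke); p2 <- fit_polygenic(yk + 5, xk, ke)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-8)
  expect_equal(p1$lrt, p2$lrt, tolerance = 1e-6)
})

test_that("with identity-like kinship the polygenic fit collapses to OLS", {
  set.seed(5)
  n <- 50
  x <- rpois(n, 1); y <- rnorm(n)
  K <- diag(0.5, n)
  dimnames(K) <- list(sprintf("I%02d", 1:n), sprintf("I%02d", 1:n))
  pf <- fit_polygenic(y, x, K)
  of <- fit_ols(y, x)
  expect_equal(pf$lrt, of$lrt, tolerance = 1e-6)
  expect_equal(pf$beta, of$beta, tolerance = 1e-6)
})

test_that("data without a genetic variance component land near the h = 0 boundary", {
  set.seed(6)
  ped <- generate_pedigrees(100, family_template("nuclear", 2))
  ke <- kinship_eigen(kinship_from_pedigree(ped))
  n <- nrow(ped)
  x <- rpois(n, 0.5)
  y <- 0.3 * x + rnorm(n) # iid residuals: sigma2_g = 0
  pf <- fit_polygenic(y, x, ke)
  of <- fit_ols(y, x)
  expect_lt(pf$h2, 0.15)
  expect_equal(pf$lrt, of$lrt, tolerance = 0.3)
  expect_equal(pf$beta, of$beta, tolerance = 0.02)
})

test_that("stronger founder coupling yields larger burden LRTs", {
  run_mean_lrt <- function(coupling) {
    m <- pop_model(coupling = coupling, n_variants_range = c(15, 25))
    g <- simulate_population(m, 200, 400, seed = 100 + round(100 * coupling))
    res <- run_gene_tests(g, "ols", stratify = FALSE, seed = 1)
    mean(res$lrt[res$status == "ok"])
  }
  expect_gt(run_mean_lrt(0.5), run_mean_lrt(0.2))
})

test_that("principal components recover population labels and respect k", {
  m <- pop_model(n_populations = 2, divergence = 0.05, nonsyn_prob = 0,
                 n_variants_range = c(28, 32))
  g <- simulate_population(m, 70, 400, seed = 8)
  pcs <- pca_covariates(g, k = 4)
  expect_equal(dim(pcs), c(400, 4))
  expect_gt(abs(cor(pcs[, 1], g$pop)), 0.9)

  mono <- matrix(0, 10, 5,
                 dimnames = list(NULL, paste0("V", 1:5)))
  ann <- data.frame(variant_id = paste0("V", 1:5), gene = "G",
                    func_type = "synonymous")
  expect_error(pca_covariates(mono, ann, k = 2),
               class = "synthcorr_data_error")

  # k = 0 leaves downstream fits identical to the uncorrected analysis
  set.seed(9)
  x <- rpois(50, 1); y <- rnorm(50)
  empty <- matrix(numeric(0), 50, 0)
  expect_equal(fit_ols(y, x, empty)$lrt, fit_ols(y, x)$lrt)
})

test_that("run_gene_tests is deterministic and its draws reproducible", {
  m <- pop_model()
  g <- simulate_population(m, 25, 200, seed = 10)
  r1 <- run_gene_tests(g, "ols", seed = 3)
  r2 <- run_gene_tests(g, "ols", seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$rare_stratum %in% c("nonsynonymous", "synonymous")))
  expect_true(all(r1$status %in% c("ok", "skipped_monomorphic", "not_converged")))
  expect_true(all(is.na(r1$p_value[r1$status != "ok"])))
  expect_true(all(r1$p_value[r1$status == "ok"] ==
                    pchisq(r1$lrt[r1$status == "ok"], 1, lower.tail = FALSE)))
})
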