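test_that("relatedness matrix obeys shared-allele boundary cases", {
  g <- rbind(s1 = c(0L, 2L, 1L), s2 = c(0L, 2L, 1L), s3 = c(0L, 2L, 1L))
  colnames(g) <- c("x", "y", "z")
  V <- relatedness_matrix(g, ridge = 0)
  expect_equal(unname(diag(V)), rep(1, 3))
  expect_equal(V["x", "y"], 0)   # dosages (0,2) at every SNP
  expect_equal(V["x", "z"], 0.5)
  V2 <- relatedness_matrix(rbind(s1 = c(1L, 1L), s2 = c(1L, 1L),
                                 s3 = c(1L, 1L)), ridge = 0)
  expect_equal(unname(V2[1, 2]), 1)  # (1,1) everywhere shares one allele pair fully
  # symmetry and range on simulated data
  st <- tiny_study(seed = 71, n_snps = 150, n_genes = 20, n_per_pop = 8)
  V3 <- relatedness_matrix(st$truth_genotypes, st$metadata, ridge = 0)
  expect_equal(V3, t(V3))
  expect_true(all(V3 >= 0 & V3 <= 1))
})

test_that("genotype codings map dosages to the three genetic models", {
  expect_equal(genotype_coding(0:2, "additive"), c(0, 1, 2))
  expect_equal(genotype_coding(0:2, "dominance"), c(0, 1, 1))
  expect_equal(genotype_coding(0:2, "recessive"), c(0, 0, 1))
  expect_true(is.na(genotype_coding(NA_integer_, "additive")))
  expect_error(genotype_coding(3L, "additive"))
})

test_that("GLS with identity covariance equals OLS to 10 decimals", {
  set.seed(31)
  x <- rep(c(0, 1, 2), each = 10) + 0
  y <- 0.5 + 0.8 * x + rnorm(30)
  fit <- gls_fit(y, x, V = diag(30))
  ref <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$beta, ref["x", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$se, ref["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$p, ref["x", "Pr(>|t|)"], tolerance = 1e-10)
  # V = NULL is the same reduction
  fit0 <- gls_fit(y, x)
  expect_equal(fit0$beta, fit$beta, tolerance = 1e-12)
  # constant response
  flat <- gls_fit(rep(2, 30), x)
  expect_equal(flat$beta, 0)
  expect_equal(flat$p, 1)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_identical(td$term[2], "x")
  expect_equal(td$estimate[2], fit$beta)
  expect_equal(glance(fit)$nobs, 30L)
})

test_that("GLS recovers an additive effect under simulated kinship", {
  set.seed(32)
  n <- 60
  # block-structured kinship: two families plus noise
  V <- 0.5 * diag(n) + 0.5 * kronecker(diag(2), matrix(1, n / 2, n / 2))
  L <- chol(V)
  x <- rbinom(n, 2, 0.5) + 0
  betas <- replicate(200, {
    y <- 0.8 * x + drop(t(L) %*% rnorm(n))
    gls_fit(y, x, V)$beta
  })
  expect_lt(abs(mean(betas) - 0.8), 0.1)
})

test_that("nearest-gene assignment uses midpoint distance with low-coordinate ties", {
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          scaffold = c("s", "s", "t"),
                          start = c(100L, 500L, 100L), end = c(200L, 600L, 200L))
  snps <- tibble::tibble(snp = c("a", "b", "c"),
                         scaffold = c("s", "s", "u"),
                         pos = c(120L, 325L, 50L))
  map <- nearest_gene_map(snps, genes)
  expect_identical(map$gene[map$snp == "a"], "g1")
  # position 325 is equidistant from both midpoints (150, 550): lower start wins
  expect_identical(map$gene[map$snp == "b"], "g1")
  expect_false("c" %in% map$snp)
})

test_that("the eQTL screen applies eligibility, FDR and sign-consistency rules", {
  st <- tiny_study(seed = 72, n_snps = 200, n_genes = 150, n_per_pop = 15,
                   n_eqtl_pairs = 10, eqtl_beta = 1)
  lc <- log_cpm(st$counts)
  g <- st$truth_genotypes
  res <- screen_eqtl(lc, g, st$snp_gene_map, st$metadata)
  add <- res[res$coding == "additive", ]
  truth_keys <- paste(st$truth$eqtl$snp, st$truth$eqtl$gene)
  hit <- add[paste(add$snp, add$gene) %in% truth_keys, ]
  expect_gt(sum(hit$accepted), 0.5 * nrow(st$truth$eqtl))
  # accepted implies FDR < 0.05 somewhere and a consistent slope sign
  expect_true(all(res$n_significant[res$accepted] >= 1))
  expect_true(all(res$sign_consistent[res$accepted]))

  # a pair lacking a genotype class in every population is not tested
  g2 <- g
  g2[st$truth$eqtl$snp[1], ] <- 0L
  res2 <- screen_eqtl(lc, g2, st$snp_gene_map, st$metadata)
  expect_false(st$truth$eqtl$snp[1] %in% res2$snp)

  # restricting to landscape-differentiated SNPs narrows the tested set
  res3 <- screen_eqtl(lc, g, st$snp_gene_map, st$metadata,
                      differentiated_snps = st$truth$eqtl$snp[1:3])
  expect_true(all(res3$snp %in% st$truth$eqtl$snp[1:3]))
})

test_that("opposite slope signs across populations are rejected", {
  set.seed(33)
  n_per <- 20
  md <- tibble::tibble(
    individual = paste0("i", 1:(2 * n_per)),
    population = rep(c("A", "B"), each = n_per),
    landscape = rep(c("fragmented", "continuous"), each = n_per))
  dos <- matrix(rep(rep(0:2, length.out = n_per), 2), 1,
                dimnames = list("s1", md$individual))
  storage.mode(dos) <- "integer"
  expr <- matrix(NA_real_, 1, 2 * n_per, dimnames = list("g1", md$individual))
  expr[1, 1:n_per] <- 2 * dos[1, 1:n_per] + rnorm(n_per, 0, 0.1)
  expr[1, (n_per + 1):(2 * n_per)] <- -2 * dos[1, (n_per + 1):(2 * n_per)] +
    rnorm(n_per, 0, 0.1)
  map <- tibble::tibble(snp = "s1", gene = "g1")
  V <- diag(2 * n_per)
  dimnames(V) <- list(md$individual, md$individual)
  res <- screen_eqtl(expr, dos, map, md, V = V)
  add <- res[res$coding == "additive", ]
  expect_gte(add$n_significant, 1)
  expect_false(add$sign_consistent)
  expect_false(add$accepted)
})
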