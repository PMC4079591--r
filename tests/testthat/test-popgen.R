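# Hand-built panel with explicit per-population allele copy counts.
make_panel <- function(alt, ref, pops, landscape) {
  snps <- sprintf("s%03d", seq_len(nrow(alt)))
  tbl <- tibble::tibble(snp = snps)
  for (k in seq_along(pops)) {
    tbl[[paste0("alt_", pops[k])]] <- alt[, k]
    tbl[[paste0("ref_", pops[k])]] <- ref[, k]
  }
  md <- tibble::tibble(individual = paste0("i", seq_along(pops)),
                       population = pops, landscape = landscape)
  structure(list(snps = tbl, metadata = md), class = "ml_snp_panel")
}

test_that("Fisher pairwise matches brute-force hypergeometric enumeration", {
  pops <- c("A", "B")
  land <- c("fragmented", "continuous")
  panel <- make_panel(alt = rbind(c(10, 10), c(0, 20), c(5, 0)),
                      ref = rbind(c(10, 10), c(20, 0), c(9, 0)),
                      pops, land)
  res <- fisher_pairwise(panel, "A", "B")
  expect_equal(res$p[1], 1.0)
  # fully separated 20/20 table: two-sided p = 2 / choose(40, 20)
  expect_equal(res$p[2], fisher_two_sided_brute(rbind(c(20, 0), c(0, 20))))
  expect_equal(res$p[2], 2 / choose(40, 20), tolerance = 1e-10)
  # zero counts in one group: p undefined
  expect_true(is.na(res$p[3]))
})

test_that("Fisher p is invariant to group swap and allele swap", {
  st <- tiny_study(seed = 41, n_snps = 60, n_genes = 20, n_per_pop = 10)
  panel <- call_snps(st$allele_counts, st$metadata)
  a <- fisher_pairwise(panel, c("F1", "F2"), c("C1", "C2"))
  b <- fisher_pairwise(panel, c("C1", "C2"), c("F1", "F2"))
  expect_equal(a$p, b$p)
  # swap ref/alt columns in the panel
  panel2 <- panel
  pops <- unique(panel$metadata$population)
  for (p in pops) {
    panel2$snps[[paste0("alt_", p)]] <- panel$snps[[paste0("ref_", p)]]
    panel2$snps[[paste0("ref_", p)]] <- panel$snps[[paste0("alt_", p)]]
  }
  c2 <- fisher_pairwise(panel2, c("F1", "F2"), c("C1", "C2"))
  expect_equal(a$p, c2$p)
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, NA, 0.5)), c(p.adjust(c(0.01, NA, 0.5), "BH")))
  expect_error(bh_fdr(c(0.5, 1.5)))
})

test_that("permutation test gives p = 1 for null differences and constants", {
  # identical genotype columns in both landscape groups: zero difference
  g <- matrix(rep(c(0L, 1L, 2L, 1L), each = 8), 4, 8, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("i", 1:8)))
  md <- tibble::tibble(individual = paste0("i", 1:8),
                       population = rep(c("A", "B"), each = 4),
                       landscape = rep(c("fragmented", "continuous"), each = 4))
  res <- landscape_permutation_test(g, md, n_perm = 200, seed = 1)
  expect_true(all(res$p == 1))
})

test_that("permutation p-values are reproducible, valid and superuniform under the null", {
  pops <- c("F1", "F2", "C1", "C2")
  cfg <- study_config(n_snps = 2000, n_genes = 10, n_individuals_per_population = 15,
                      fst_tree = list(terminal = setNames(rep(1e-6, 4), pops)),
                      n_differentiated_snps = 0, landscape_freq_shift = 0,
                      n_landscape_de_genes = 0, n_sex_de_genes = 0,
                      n_eqtl_pairs = 0, n_mixture_genes = 0, seed = 44)
  st <- simulate_study(cfg)
  panel <- call_snps(st$allele_counts, st$metadata)
  r1 <- landscape_permutation_test(panel$genotypes, st$metadata,
                                   n_perm = 300, seed = 7)
  r2 <- landscape_permutation_test(panel$genotypes, st$metadata,
                                   n_perm = 300, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 301))
  # validity: empirical rejection never materially exceeds the nominal level
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    emp <- mean(r1$p <= alpha)
    expect_lt(emp, alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(r1)))
  }
  # non-degeneracy: small p-values do occur
  expect_gt(mean(r1$p <= 0.1), 0.02)
})

test_that("permutation flags cover most Fisher flags on differentiated data", {
  st <- tiny_study(seed = 45, n_snps = 600, n_genes = 10, n_per_pop = 15,
                   n_differentiated_snps = 200, landscape_freq_shift = 0.35)
  panel <- call_snps(st$allele_counts, st$metadata)
  fish <- fisher_pairwise(panel, c("F1", "F2"), c("C1", "C2"))
  perm <- landscape_permutation_test(panel$genotypes, st$metadata,
                                     n_perm = 2000, seed = 5)
  f_sig <- fish$snp[!is.na(fish$q) & fish$q < 0.05]
  p_sig <- perm$snp[perm$q < 0.05]
  expect_gt(length(f_sig), 20)
  # the permutation test is less conservative: it recovers most Fisher hits
  expect_gt(mean(f_sig %in% p_sig), 0.8)
  expect_gte(length(p_sig), 0.8 * length(f_sig))
})

test_that("venn partition counts disjoint significance regions", {
  mk <- function(q) tibble::tibble(snp = paste0("s", seq_along(q)), q = q)
  none <- venn_partition(list(a = mk(rep(0.9, 4)), b = mk(rep(0.9, 4)),
                              c = mk(rep(0.9, 4))))
  expect_true(all(none$count == 0))
  all3 <- venn_partition(list(a = mk(c(0.01, 0.9)), b = mk(c(0.01, 0.9)),
                              c = mk(c(0.01, 0.9))))
  expect_identical(all3$count[all3$region == "111"], 1L)
  expect_identical(sum(all3$count), 1L)
  expect_error(venn_partition(list(mk(0.5), mk(0.5),
                                   tibble::tibble(snp = "x", q = 0.5))),
               "differ")
})

test_that("landscape pairing dominates the Venn on landscape-shifted data", {
  st <- tiny_study(seed = 46, n_snps = 800, n_genes = 10, n_per_pop = 15,
                   n_differentiated_snps = 250, landscape_freq_shift = 0.35)
  panel <- call_snps(st$allele_counts, st$metadata)
  fish <- list(
    landscape = fisher_pairwise(panel, c("F1", "F2"), c("C1", "C2")),
    cross1 = fisher_pairwise(panel, c("F1", "C1"), c("F2", "C2")),
    cross2 = fisher_pairwise(panel, c("F1", "C2"), c("F2", "C1"))
  )
  venn <- venn_partition(fish)
  only <- function(region) venn$count[venn$region == region]
  expect_gt(only("100"), only("010"))
  expect_gt(only("100"), only("001"))
})

test_that("diversity ranking finds the most polymorphic population", {
  # construct allele counts where population A segregates at twice as
  # many SNPs as the others
  set.seed(99)
  pops <- c("A", "B", "C", "D")
  n_per <- 14; n_snp <- 300
  md <- tibble::tibble(
    individual = sprintf("%s%02d", rep(pops, each = n_per), rep(1:n_per, 4)),
    population = rep(pops, each = n_per),
    landscape = rep(c("fragmented", "continuous"), each = 2 * n_per))
  seg <- cbind(A = runif(n_snp) < 0.6, B = runif(n_snp) < 0.3,
               C = runif(n_snp) < 0.3, D = runif(n_snp) < 0.3)
  dosage <- matrix(0L, n_snp, nrow(md))
  for (k in seq_len(nrow(md))) {
    s <- seg[, md$population[k]]
    dosage[s, k] <- rbinom(sum(s), 2L, 0.5)
  }
  dimnames(dosage) <- list(sprintf("s%03d", 1:n_snp), md$individual)
  depth <- matrix(rpois(length(dosage), 25), nrow(dosage))
  altc <- matrix(rbinom(length(dosage), as.vector(depth), as.vector(dosage) / 2),
                 nrow(dosage))
  tbl <- counts_tbl(depth - altc, altc, snps = rownames(dosage),
                    inds = colnames(dosage))
  rk <- diversity_ranking(tbl, md, subsample = 10, reps = 100, seed = 3)
  first_a <- rk$times[rk$population == "A" & rk$rank == 1]
  expect_gt(first_a, 80)
  # each rank is awarded exactly once per replicate
  expect_true(all(tapply(rk$times, rk$rank, sum) >= 100))
  expect_identical(sum(rk$times[rk$rank == 1]), sum(rk$times[rk$rank == 4]))

  # determinism at fixed seed
  r1 <- diversity_ranking(tbl, md, subsample = 10, reps = 1, seed = 11)
  r2 <- diversity_ranking(tbl, md, subsample = 10, reps = 1, seed = 11)
  expect_identical(r1, r2)
})

test_that("genotype dissimilarity satisfies its boundary and symmetry contracts", {
  g <- rbind(s1 = c(0L, 0L, 2L), s2 = c(1L, 1L, 0L), s3 = c(2L, 2L, 1L),
             s4 = c(NA, 1L, 1L))
  colnames(g) <- c("x", "y", "z")
  expect_equal(genotype_dissimilarity(g, "x", "y"), 0)
  expect_equal(genotype_dissimilarity(g, "x", "z"), 1)
  expect_equal(genotype_dissimilarity(g, "y", "z"),
               genotype_dissimilarity(g, "z", "y"))
  g2 <- rbind(s1 = c(NA, 1L), s2 = c(1L, NA))
  colnames(g2) <- c("x", "y")
  expect_error(genotype_dissimilarity(g2, "x", "y"), "undefined")
})
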