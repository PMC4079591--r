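test_that("binomial category test reproduces its closed forms", {
  # hexamerins: 4 of 7 significant at the genome-wide DE frequency of
  # 0.11 (1841/16667, quoted to two decimals)
  rate <- round(1841 / 16667, 2)
  expect_equal(signif(binomial_category_test(4, 7, rate), 2), 0.0039)
  # with the unrounded fraction the tail is within 2%
  expect_equal(binomial_category_test(4, 7, 1841 / 16667), 0.0039,
               tolerance = 0.02)
  expect_equal(binomial_category_test(0, 12, 0.3), 1.0)
  expect_equal(binomial_category_test(7, 7, 0.5), 0.5^7)
  # exact complement identity
  for (k in 0:7) {
    expect_equal(binomial_category_test(k, 7, 0.11) +
                   pbinom(k - 1, 7, 0.11), 1, tolerance = 1e-12)
  }
  # oracle: direct summation of the binomial mass
  expect_equal(binomial_category_test(4, 7, 0.11),
               sum(dbinom(4:7, 7, 0.11)), tolerance = 1e-12)
})

test_that("fraction test equals brute-force hypergeometric summation", {
  # the Notch pathway counts: 9 significant of 35 against 1841/16667
  expect_equal(fraction_test(9, 35, 1841, 16667),
               hyper_upper_brute(9, 1841, 35, 16667), tolerance = 1e-10)
  # random small tables
  set.seed(41)
  for (r in 1:200) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fraction_test(k, n, K, N), hyper_upper_brute(k, K, n, N),
                 tolerance = 1e-10)
  }
  # matches one-sided fisher.test
  expect_equal(fraction_test(9, 35, 1841, 16667),
               fisher.test(rbind(c(9, 35 - 9), c(1841 - 9, 16667 - 35 - 1841 + 9)),
                           alternative = "greater")$p.value, tolerance = 1e-9)
  # no enrichment when category matches the universe rate
  expect_gte(fraction_test(5, 50, 100, 1000), 0.5)
  expect_equal(fraction_test(0, 0, 100, 1000), 1)
  expect_error(fraction_test(10, 5, 100, 1000))
})

test_that("concordance gene filters use strict inequalities", {
  genes <- paste0("g", 1:5)
  lcpm <- setNames(c(1.0, 1.5, 2, 3, 0.5), genes)
  ratio <- setNames(c(2, 1.0, 1.5, -2, 3), genes)
  kept <- filter_concordance_genes(genes, lcpm, lcpm, ratio)
  # g1 at logCPM exactly 1 excluded; g2 at |ratio| exactly 1 excluded
  expect_setequal(kept, c("g3", "g4"))
  steps <- attr(kept, "steps")
  expect_equal(unname(steps), c(5, 3, 2))
  # no-op floors return the set unchanged
  all_kept <- filter_concordance_genes(genes, lcpm, lcpm, ratio,
                                       cpm_floor = -Inf, ratio_floor = 0)
  expect_setequal(all_kept, genes[abs(ratio) > 0])
})

test_that("concordance correlation satisfies its boundary contracts", {
  d <- setNames(c(1, -2, 0.5, 3, -1), paste0("g", 1:5))
  same <- concordance_test(d, d)
  expect_equal(same$estimate, 1)
  opp <- concordance_test(d, -d)
  expect_equal(opp$estimate, -1)
  # symmetry of the estimate
  set.seed(42)
  b <- setNames(d + rnorm(5), names(d))
  expect_equal(concordance_test(d, b)$estimate,
               concordance_test(b, d)$estimate)
  expect_error(concordance_test(d[1:2], b[1:2]), "fewer than 3")
  expect_error(concordance_test(d, setNames(rep(1, 5), names(d))), "variance")
  expect_identical(nrow(tidy(same)), 5L)
  expect_equal(glance(same)$estimate, 1)
})

test_that("shared truth genes drive a positive cross-contrast concordance", {
  st <- tiny_study(seed = 81, n_snps = 20, n_genes = 250, n_per_pop = 15,
                   n_landscape_de_genes = 60, landscape_log2_effect = 1.2)
  lc <- log_cpm(st$counts)
  full <- landscape_delta(lc, st$metadata)
  # leave one fragmented population out and recompute, as in the
  # independent-contrast check
  loo <- landscape_delta(lc, st$metadata, exclude_population = "F1")
  tr <- st$truth$de_genes$gene
  res <- concordance_test(full[tr], loo[tr])
  expect_gt(res$estimate, 0.5)
  expect_lt(res$p, 0.01)
})

test_that("flight-baseline concordance reports the direction table", {
  set.seed(43)
  genes <- paste0("g", 1:40)
  ld <- setNames(rnorm(40), genes)
  fr <- tibble::tibble(gene = genes, log2fc = ld + rnorm(40, 0, 0.2))
  res <- flight_baseline_concordance(fr, ld)
  expect_gt(res$correlation, 0.5)
  expect_true(is.na(res$correlation_p))  # withheld unless forced
  forced <- flight_baseline_concordance(fr, ld, force_p = TRUE)
  expect_false(is.na(forced$correlation_p))
  # identical direction vectors: off-diagonal zeros
  fr2 <- tibble::tibble(gene = genes, log2fc = ld)
  tab <- flight_baseline_concordance(fr2, ld)$direction_table
  expect_equal(tab["FALSE", "TRUE"][[1]], 0)
  expect_equal(tab["TRUE", "FALSE"][[1]], 0)
  # zero-variance baseline flagged
  res0 <- flight_baseline_concordance(fr, setNames(rep(0, 40), genes))
  expect_true(is.na(res0$correlation))
  expect_identical(res0$note, "landscape differences have zero variance")
  # per-sex stratification
  fr$sex <- rep(c("female", "male"), 20)
  res_sex <- flight_baseline_concordance(fr, ld)
  expect_named(res_sex$per_sex, c("female", "male"))
  expect_error(flight_baseline_concordance(
    tibble::tibble(gene = "zzz", log2fc = 1), ld), "shared")
})
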