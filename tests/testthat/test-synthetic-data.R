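test_that("config validation rejects degenerate parameters", {
  pops <- c("F1", "F2", "C1", "C2")
  expect_error(study_config(fst_tree = list(terminal = setNames(rep(0, 4), pops))),
               "drift")
  expect_error(study_config(fst_tree = list(terminal = setNames(rep(1, 4), pops))),
               "drift")
  expect_error(study_config(nb_dispersion_range = c(-0.1, 0.2)), "dispersion")
  expect_error(study_config(landscape_of_population = setNames(
    rep("fragmented", 4), pops)), "landscape")
  expect_s3_class(study_config(), "ml_config")
})

test_that("zero-drift limit returns ancestral frequencies and no landscape shift", {
  pops <- c("F1", "F2", "C1", "C2")
  cfg <- study_config(n_snps = 500, n_individuals_per_population = 5,
                      fst_tree = list(terminal = setNames(rep(1e-9, 4), pops)),
                      n_differentiated_snps = 0, landscape_freq_shift = 0,
                      seed = 2)
  g <- simulate_genotypes(cfg)
  expect_lt(max(abs(g$freqs - g$ancestral)), 1e-3)

  # with a landscape shift of zero, the expected frequency difference
  # between landscape groups is zero up to Monte-Carlo error
  cfg2 <- study_config(n_snps = 4000, n_individuals_per_population = 5,
                       landscape_freq_shift = 0, seed = 3)
  g2 <- simulate_genotypes(cfg2)
  d <- rowMeans(g2$freqs[, c("F1", "F2")]) - rowMeans(g2$freqs[, c("C1", "C2")])
  expect_lt(abs(mean(d)), 0.005)
  expect_equal(nrow(g2$differentiated_snps), 0)
})

test_that("terminal drift 0.05 yields Weir-Cockerham F_ST near 0.05", {
  pops <- c("F1", "F2", "C1", "C2")
  cfg <- study_config(n_snps = 10000, n_genes = 10,
                      n_individuals_per_population = 15,
                      fst_tree = list(terminal = setNames(rep(0.05, 4), pops)),
                      n_differentiated_snps = 0, landscape_freq_shift = 0,
                      seed = 5)
  g <- simulate_genotypes(cfg)
  pop <- rep(pops, each = 15)
  fst <- wc_fst(g$dosage, pop)
  expect_lt(abs(fst - 0.05), 0.02)
})

test_that("allele reads follow dosage and depth contracts", {
  dosage <- matrix(c(0L, 1L, 2L), 3, 4,
                   dimnames = list(paste0("s", 1:3), paste0("i", 1:4)))
  cfg <- study_config(n_snps = 3, n_individuals_per_population = 1,
                      mean_coverage_per_snp = 30, seed = 1)
  reads <- simulate_allele_reads(dosage, cfg)
  hom_ref <- reads[reads$snp == "s1", ]
  expect_true(all(hom_ref$alt_count == 0))
  hom_alt <- reads[reads$snp == "s3", ]
  expect_true(all(hom_alt$ref_count == 0))

  cfg0 <- study_config(n_snps = 3, n_individuals_per_population = 1,
                       mean_coverage_per_snp = 0, seed = 1)
  reads0 <- simulate_allele_reads(dosage, cfg0)
  expect_true(all(reads0$ref_count + reads0$alt_count == 0))

  # heterozygote at very deep coverage: alternate fraction near 1/2
  deep <- study_config(n_snps = 1, n_individuals_per_population = 1,
                       mean_coverage_per_snp = 2e4, seed = 6)
  het <- matrix(1L, 1, 1, dimnames = list("s1", "i1"))
  r <- simulate_allele_reads(het, deep)
  frac <- r$alt_count / (r$alt_count + r$ref_count)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2e4) / sqrt(1) * 3 + 0.02)
})

test_that("expression counts approach Poisson in the small-dispersion limit", {
  cfg <- study_config(n_snps = 10, n_genes = 300,
                      n_individuals_per_population = 50,
                      nb_dispersion_range = c(1e-6, 2e-6),
                      library_size_range = c(1e6, 1e6 + 1),
                      n_landscape_de_genes = 0, n_sex_de_genes = 0,
                      n_eqtl_pairs = 0, n_mixture_genes = 0, seed = 8)
  st <- simulate_study(cfg)
  m <- rowMeans(st$counts)
  v <- apply(st$counts, 1L, var)
  keep <- m > 20
  ratio <- v[keep] / m[keep]
  expect_gt(sum(keep), 50)
  expect_lt(abs(median(ratio) - 1), 0.15)
})

test_that("landscape effect of one log2 unit doubles group mean CPM at large n", {
  cfg <- study_config(n_snps = 10, n_genes = 60,
                      n_individuals_per_population = 125,
                      n_landscape_de_genes = 30, landscape_log2_effect = 1,
                      n_sex_de_genes = 0, n_eqtl_pairs = 0, n_mixture_genes = 0,
                      nb_dispersion_range = c(0.05, 0.1), seed = 9)
  st <- simulate_study(cfg)
  cpm <- sweep(st$counts, 2L, st$library_sizes / 1e6, "/")
  frag <- st$metadata$individual[st$metadata$landscape == "fragmented"]
  cont <- st$metadata$individual[st$metadata$landscape == "continuous"]
  tr <- st$truth$de_genes
  ratio <- rowMeans(cpm[tr$gene, frag]) / rowMeans(cpm[tr$gene, cont])
  # signed effect: ratio should be near 2 for up genes, 1/2 for down genes
  expect_lt(median(abs(log2(ratio) - tr$log2_effect)), 0.15)
})

test_that("with eqtl_beta = 0 the dosage regression recovers a null slope", {
  cfg <- study_config(n_snps = 100, n_genes = 60,
                      n_individuals_per_population = 30,
                      n_landscape_de_genes = 0, n_sex_de_genes = 0,
                      n_eqtl_pairs = 20, eqtl_beta = 0, n_mixture_genes = 0,
                      seed = 10)
  st <- simulate_study(cfg)
  lc <- log_cpm(st$counts)
  betas <- vapply(seq_len(nrow(st$truth$eqtl)), function(k) {
    y <- lc[st$truth$eqtl$gene[k], ]
    x <- st$truth_genotypes[st$truth$eqtl$snp[k], colnames(lc)]
    unname(coef(lm(y ~ x))[2])
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.1)
})

test_that("simulation is reproducible and truth lists are consistent subsets", {
  cfg <- study_config(n_snps = 80, n_genes = 60, n_individuals_per_population = 6,
                      n_landscape_de_genes = 10, n_sex_de_genes = 5,
                      n_eqtl_pairs = 3, n_mixture_genes = 5, seed = 33)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth_genotypes, b$truth_genotypes)
  expect_identical(a$allele_counts, b$allele_counts)

  expect_true(all(a$truth$de_genes$gene %in% rownames(a$counts)))
  expect_true(all(a$truth$eqtl$gene %in% rownames(a$counts)))
  expect_true(all(a$truth$eqtl$snp %in% rownames(a$truth_genotypes)))
  expect_true(all(a$truth$differentiated_snps$snp %in% rownames(a$truth_genotypes)))
  # effect gene sets are disjoint
  expect_length(intersect(a$truth$de_genes$gene, a$truth$mixture_genes), 0)
})

test_that("studies round-trip losslessly through VCF/TSV", {
  st <- tiny_study(seed = 21, n_snps = 40, n_genes = 30, n_per_pop = 4)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$counts, st$counts)
  expect_identical(back$truth_genotypes, st$truth_genotypes)
  expect_equal(as.data.frame(dplyr::arrange(back$allele_counts, snp, individual)),
               as.data.frame(dplyr::arrange(st$allele_counts, snp, individual)))
  expect_identical(back$metadata$individual, st$metadata$individual)
  expect_equal(back$truth$de_genes$gene, st$truth$de_genes$gene)

  # missing genotype is emitted as ./. and read back as NA
  st2 <- st
  st2$truth_genotypes[1, 1] <- NA_integer_
  dir2 <- withr::local_tempdir()
  write_study(st2, dir2)
  vcf_lines <- readLines(file.path(dir2, "genotypes.vcf"))
  expect_true(any(grepl("\\./\\.", vcf_lines)))
  expect_true(is.na(read_study(dir2)$truth_genotypes[1, 1]))
})

test_that("an empty study writes a header-only VCF", {
  st <- tiny_study(seed = 22, n_snps = 40, n_genes = 20, n_per_pop = 4)
  st$truth_genotypes <- st$truth_genotypes[0, , drop = FALSE]
  st$allele_counts <- st$allele_counts[0, ]
  st$snp_positions <- st$snp_positions[0, ]
  dir <- withr::local_tempdir()
  write_study(st, dir)
  lines <- readLines(file.path(dir, "genotypes.vcf"))
  expect_true(all(startsWith(lines, "#")))
  expect_true(any(grepl("fileformat=VCFv4.2", lines)))
})
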