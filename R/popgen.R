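# Allele-frequency differentiation between populations and landscape
# types, and within-population diversity ranking.

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over [stats::p.adjust()] that propagates missing
#' p-values as missing.
#'
#' @param p numeric vector of p-values (may contain `NA`).
#' @return vector of BH step-up q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-8, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pmin(pmax(p, 0), 1), method = "BH")
}

group_allele_counts <- function(panel, groups) {
  pops <- unique(panel$metadata$population)
  missing_pop <- setdiff(groups, pops)
  if (length(missing_pop) > 0) {
    abort(paste0("unknown population(s): ", paste(missing_pop, collapse = ", ")))
  }
  alt <- rowSums(as.matrix(panel$snps[paste0("alt_", groups)]))
  ref <- rowSums(as.matrix(panel$snps[paste0("ref_", groups)]))
  list(alt = alt, ref = ref)
}

#' Fisher exact test of allele-count differences
#'
#' For every SNP in the panel, a two-sided Fisher exact test on the 2x2
#' table of (ref, alt) allele copies in one group of populations versus
#' another. Allele copies come from scored genotypes (two per called
#' individual); SNPs with zero total copies in either group get a
#' missing p-value.
#'
#' @param panel an `ml_snp_panel` from [call_snps()].
#' @param group_a,group_b disjoint character vectors of population labels.
#' @return tibble with columns `snp`, `p`, `q` (BH FDR over non-missing p).
#' @export
fisher_pairwise <- function(panel, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0 ||
      length(group_a) == 0 || length(group_b) == 0) {
    abort("groups must be non-empty and disjoint")
  }
  a <- group_allele_counts(panel, group_a)
  b <- group_allele_counts(panel, group_b)
  n <- length(a$alt)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tot_a <- a$ref[i] + a$alt[i]
    tot_b <- b$ref[i] + b$alt[i]
    if (tot_a == 0 || tot_b == 0) next
    tab <- matrix(c(a$ref[i], a$alt[i], b$ref[i], b$alt[i]), 2L)
    p[i] <- fisher.test(tab)$p.value
  }
  tibble(snp = panel$snps$snp, p = p, q = bh_fdr(p))
}

#' Landscape permutation test for allele-frequency differences
#'
#' Statistic: the absolute difference in (genotype-derived) alternate
#' allele frequency between the fragmented and continuous landscape
#' groups. The null distribution is built by permuting individual
#' landscape labels; p-values use the add-one estimator
#' `(1 + #permuted >= observed) / (1 + n_perm)` and are converted to
#' BH q-values across SNPs. Constant SNPs get p = 1.
#'
#' @param genotypes dosage matrix (SNP x individual), e.g.
#'   `panel$genotypes`.
#' @param metadata per-individual metadata with a `landscape` column.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return tibble with `snp`, `statistic`, `p`, `q`.
#' @export
landscape_permutation_test <- function(genotypes, metadata, n_perm = 10000, seed = 1) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  metadata <- check_metadata(metadata, colnames(genotypes))
  land <- metadata$landscape
  if (length(unique(land)) != 2) abort("two landscape groups are required")
  frag <- land == "fragmented"
  g <- genotypes
  called <- !is.na(g)
  g0 <- g; g0[!called] <- 0L
  freq_diff <- function(is_frag) {
    alt_f <- rowSums(g0[, is_frag, drop = FALSE])
    n_f <- rowSums(called[, is_frag, drop = FALSE])
    alt_c <- rowSums(g0[, !is_frag, drop = FALSE])
    n_c <- rowSums(called[, !is_frag, drop = FALSE])
    abs(alt_f / (2 * n_f) - alt_c / (2 * n_c))
  }
  obs <- freq_diff(frag)
  exceed <- integer(nrow(g))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample(frag)
      stat <- freq_diff(perm)
      exceed <- exceed + (!is.na(stat) & !is.na(obs) & stat >= obs)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  constant <- apply(g, 1L, function(r) length(unique(r[!is.na(r)])) <= 1L)
  p[constant | is.na(obs)] <- 1
  obs[is.na(obs)] <- NA_real_
  tibble(snp = rownames(g), statistic = obs, p = p, q = bh_fdr(p))
}

#' Disjoint Venn regions of pairing-specific significant SNPs
#'
#' Four populations admit three pairings into two pairs; given the
#' differentiation results (with q-values) of the three group-vs-group
#' comparisons on the same SNP set, counts the SNPs falling in each
#' disjoint region of the three significance sets.
#'
#' @param results named list of three tibbles with `snp` and `q` columns.
#' @param alpha_fdr FDR significance cutoff.
#' @return tibble with `region` (membership pattern such as `"110"`,
#'   ordered as the input list), per-pairing logical columns, and `count`.
#' @export
venn_partition <- function(results, alpha_fdr = 0.05) {
  if (length(results) != 3) abort("exactly three pairings are required")
  snps <- results[[1]]$snp
  for (r in results) {
    if (!identical(sort(r$snp), sort(snps))) abort("SNP sets differ between pairings")
  }
  labs <- names(results) %||% paste0("pairing", 1:3)
  sig <- sapply(results, function(r) {
    s <- !is.na(r$q) & r$q < alpha_fdr
    s[match(snps, r$snp)]
  })
  patterns <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE), c = c(TRUE, FALSE))
  patterns <- patterns[rowSums(patterns) > 0, ]
  out <- tibble(
    region = apply(patterns, 1L, function(x) paste(as.integer(x), collapse = "")),
    count = as.integer(apply(patterns, 1L, function(x) {
      sum(sig[, 1] == x[1] & sig[, 2] == x[2] & sig[, 3] == x[3])
    }))
  )
  out[[labs[1]]] <- patterns$a
  out[[labs[2]]] <- patterns$b
  out[[labs[3]]] <- patterns$c
  out[c("region", labs, "count")]
}

#' Rank populations by subsampled SNP diversity
#'
#' Repeatedly samples the same number of individuals from every
#' population without replacement, counts SNPs polymorphic within the
#' subsample (both alleles detected, an allele counting as detected in
#' an individual when supported by at least `detect_threshold` reads),
#' ranks the populations by that count, and tabulates how often each
#' population attains each rank.
#'
#' @param counts allele-count tibble.
#' @param metadata per-individual metadata.
#' @param subsample individuals drawn per population (default 10).
#' @param reps number of resampling replicates (default 100).
#' @param detect_threshold reads required to detect an allele (1--3 is
#'   the usual sensitivity range).
#' @param seed integer seed.
#' @return tibble `population`, `rank`, `times` (rank 1 = most diverse;
#'   ties share the smallest rank).
#' @export
diversity_ranking <- function(counts, metadata, subsample = 10, reps = 100,
                              detect_threshold = 1, seed = 1) {
  metadata <- check_metadata(metadata, unique(counts$individual))
  pops <- unique(metadata$population)
  sizes <- table(metadata$population)
  if (any(sizes[pops] < subsample)) {
    abort("every population needs at least `subsample` individuals")
  }
  snps <- unique(counts$snp)
  inds <- unique(counts$individual)
  ref_seen <- alt_seen <- matrix(FALSE, length(snps), length(inds),
                                 dimnames = list(snps, inds))
  idx <- cbind(match(counts$snp, snps), match(counts$individual, inds))
  ref_seen[idx] <- counts$ref_count >= detect_threshold
  alt_seen[idx] <- counts$alt_count >= detect_threshold
  rank_counts <- matrix(0L, length(pops), length(pops),
                        dimnames = list(pops, paste0("rank", seq_along(pops))))
  with_seed(seed, {
    for (b in seq_len(reps)) {
      n_poly <- vapply(pops, function(p) {
        ids <- sample(metadata$individual[metadata$population == p], subsample)
        sum(rowSums(ref_seen[, ids, drop = FALSE]) > 0 &
              rowSums(alt_seen[, ids, drop = FALSE]) > 0)
      }, numeric(1))
      rk <- rank(-n_poly, ties.method = "min")
      for (p in seq_along(pops)) {
        rank_counts[p, rk[p]] <- rank_counts[p, rk[p]] + 1L
      }
    }
  })
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble(population = pops), as_tibble(as.data.frame(rank_counts))),
    -"population", names_to = "rank", values_to = "times",
    names_prefix = "rank", names_transform = list(rank = as.integer))
}

#' Genotype dissimilarity between two individuals
#'
#' The number of SNPs with different genotype calls divided by the
#' number of SNPs called in both individuals.
#'
#' @param genotypes dosage matrix (SNP x individual) with `NA` missing.
#' @param individual_i,individual_j column names or indices.
#' @return a single number in \[0, 1\]; errors when the pair shares no
#'   called SNP.
#' @export
genotype_dissimilarity <- function(genotypes, individual_i, individual_j) {
  gi <- genotypes[, individual_i]
  gj <- genotypes[, individual_j]
  shared <- !is.na(gi) & !is.na(gj)
  if (!any(shared)) abort("individuals share no called SNP: dissimilarity undefined")
  mean(gi[shared] != gj[shared])
}
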