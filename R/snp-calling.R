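# SNP panel derivation and genotype scoring from per-individual allele
# read depths.

#' Minor-allele-count retention threshold
#'
#' The global minor allele count required to retain a SNP, defined as a
#' fraction of the number of sampled individuals rounded up: with 174
#' individuals and the default 5%, the threshold is 9.
#'
#' @param n_individuals number of individuals in the pooled sample.
#' @param fraction fraction of individuals, in (0, 1).
#' @return integer threshold, `ceiling(fraction * n_individuals)`.
#' @examples
#' mac_threshold(174, 0.05) # 9
#' @export
mac_threshold <- function(n_individuals, fraction = 0.05) {
  assert_scalar_number(n_individuals, "n_individuals", lower = 1)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1)")
  }
  as.integer(ceiling(fraction * n_individuals))
}

#' Score genotypes from allele read counts
#'
#' A SNP is scored heterozygous in an individual if at least
#' `het_min_each` reads support each allele, and homozygous if only one
#' allele is observed with at least `hom_min` reads; in all other cases
#' the call is missing.
#'
#' @param counts allele-count tibble with columns `snp`, `individual`,
#'   `ref_count`, `alt_count` (as produced by [simulate_allele_reads()]).
#' @param het_min_each minimum reads per allele for a heterozygous call.
#' @param hom_min minimum reads for a homozygous call.
#' @return integer matrix (SNP x individual) of alternate-allele dosages
#'   0/1/2 with `NA` for missing calls.
#' @export
score_genotypes <- function(counts, het_min_each = 3, hom_min = 10) {
  r <- counts$ref_count
  a <- counts$alt_count
  call <- rep(NA_integer_, length(r))
  call[r >= het_min_each & a >= het_min_each] <- 1L
  call[a == 0L & r >= hom_min] <- 0L
  call[r == 0L & a >= hom_min] <- 2L
  snps <- unique(counts$snp)
  inds <- unique(counts$individual)
  g <- matrix(NA_integer_, length(snps), length(inds),
              dimnames = list(snps, inds))
  g[cbind(match(counts$snp, snps), match(counts$individual, inds))] <- call
  g
}

# Per-population alternate/reference allele copy counts from scored
# genotypes (2 copies per called individual).
pop_allele_counts <- function(genotypes, metadata) {
  metadata <- check_metadata(metadata, colnames(genotypes))
  pops <- unique(metadata$population)
  alt <- sapply(pops, function(p) {
    cols <- metadata$individual[metadata$population == p]
    rowSums(genotypes[, cols, drop = FALSE], na.rm = TRUE)
  })
  called <- sapply(pops, function(p) {
    cols <- metadata$individual[metadata$population == p]
    rowSums(!is.na(genotypes[, cols, drop = FALSE]))
  })
  if (nrow(genotypes) == 1L) {
    alt <- matrix(alt, 1L, dimnames = list(rownames(genotypes), pops))
    called <- matrix(called, 1L, dimnames = list(rownames(genotypes), pops))
  }
  list(alt = alt, ref = 2L * called - alt, n_called = called)
}

#' Derive the retained SNP panel
#'
#' Applies three order-independent filters to an allele-count matrix:
#' (a) the SNP is biallelic in the pooled data (both alleles observed in
#' reads), (b) every population has at least `min_individuals_per_pop`
#' individuals with read depth at least `min_base_depth`, and (c) the
#' pooled minor allele count, computed over genotype-derived allele
#' copies, reaches [mac_threshold()] of the total individuals.
#'
#' @param counts allele-count tibble (`snp`, `individual`, `ref_count`,
#'   `alt_count`).
#' @param metadata per-individual metadata with `individual`,
#'   `population`, `landscape` columns.
#' @param min_individuals_per_pop per-population coverage requirement.
#' @param mac_fraction fraction handed to [mac_threshold()].
#' @param min_base_depth read depth for an individual to count as covered.
#' @param het_min_each,hom_min genotype-scoring thresholds used for the
#'   allele-count accounting (see [score_genotypes()]).
#' @return object of class `ml_snp_panel`: list with `snps` (tibble of
#'   retained SNPs with per-population alt/ref allele copy counts),
#'   `dropped` (tibble snp/filter naming the first filter that removed
#'   each dropped SNP), `genotypes` (dosage matrix restricted to retained
#'   SNPs) and `metadata`.
#' @export
call_snps <- function(counts, metadata,
                      min_individuals_per_pop = 10,
                      mac_fraction = 0.05,
                      min_base_depth = 1,
                      het_min_each = 3, hom_min = 10) {
  if (nrow(counts) == 0) {
    warn("empty allele-count matrix: returning an empty panel")
    return(structure(list(snps = tibble(snp = character()),
                          dropped = tibble(snp = character(), filter = character()),
                          genotypes = matrix(NA_integer_, 0, 0),
                          metadata = metadata),
                     class = "ml_snp_panel"))
  }
  metadata <- check_metadata(metadata, unique(counts$individual))
  if (length(unique(metadata$population)) < 2) {
    abort("at least two populations are required")
  }
  depth <- counts$ref_count + counts$alt_count
  pooled <- dplyr::summarise(
    dplyr::group_by(counts, .data$snp),
    ref_reads = sum(.data$ref_count), alt_reads = sum(.data$alt_count),
    .groups = "drop")
  biallelic_ok <- setNames(pooled$ref_reads > 0 & pooled$alt_reads > 0, pooled$snp)

  covered <- counts[depth >= min_base_depth, c("snp", "individual")]
  covered$population <- metadata$population[match(covered$individual, metadata$individual)]
  cov_tab <- dplyr::count(covered, .data$snp, .data$population)
  pops <- unique(metadata$population)
  cov_ok_tbl <- dplyr::summarise(
    dplyr::group_by(cov_tab, .data$snp),
    ok = dplyr::n() == length(pops) & min(.data$n) >= min_individuals_per_pop,
    .groups = "drop")
  coverage_ok <- setNames(rep(FALSE, length(biallelic_ok)), names(biallelic_ok))
  coverage_ok[cov_ok_tbl$snp] <- cov_ok_tbl$ok

  genotypes <- score_genotypes(counts, het_min_each = het_min_each, hom_min = hom_min)
  genotypes <- genotypes[names(biallelic_ok), , drop = FALSE]
  acounts <- pop_allele_counts(genotypes, metadata)
  alt_total <- rowSums(acounts$alt)
  ref_total <- rowSums(acounts$ref)
  mac <- pmin(alt_total, ref_total)
  thr <- mac_threshold(nrow(metadata), mac_fraction)
  mac_ok <- mac >= thr

  keep <- biallelic_ok & coverage_ok & mac_ok
  first_filter <- ifelse(!biallelic_ok, "biallelic",
                  ifelse(!coverage_ok, "coverage",
                  ifelse(!mac_ok, "mac", NA_character_)))
  snp_tbl <- tibble(
    snp = names(keep),
    mac = as.integer(mac),
    biallelic = unname(biallelic_ok),
    coverage = unname(coverage_ok),
    mac_pass = unname(mac_ok)
  )
  for (p in colnames(acounts$alt)) {
    snp_tbl[[paste0("alt_", p)]] <- as.integer(acounts$alt[, p])
    snp_tbl[[paste0("ref_", p)]] <- as.integer(acounts$ref[, p])
  }
  structure(list(
    snps = snp_tbl[keep, , drop = FALSE],
    dropped = tibble(snp = names(keep)[!keep],
                     filter = first_filter[!keep]),
    genotypes = genotypes[keep, , drop = FALSE],
    metadata = metadata,
    mac_threshold = thr
  ), class = "ml_snp_panel")
}

#' @export
print.ml_snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x$snps), "retained,", nrow(x$dropped),
      "dropped (MAC threshold", x$mac_threshold, ")\n")
  invisible(x)
}

# Population allele frequencies (alt) from a panel.
panel_pop_freqs <- function(panel) {
  pops <- unique(panel$metadata$population)
  alt <- as.matrix(panel$snps[paste0("alt_", pops)])
  ref <- as.matrix(panel$snps[paste0("ref_", pops)])
  f <- alt / (alt + ref)
  rownames(f) <- panel$snps$snp
  colnames(f) <- pops
  f
}

#' Robustness of allele-frequency differences to depth thresholds
#'
#' Recomputes population allele frequencies restricting to individuals
#' whose read depth at the SNP reaches each candidate threshold, and
#' reports the Spearman correlation of the per-SNP landscape
#' (fragmented minus continuous) frequency difference between every pair
#' of threshold settings. Stable correlations indicate that the
#' frequency differences are robust to the coverage filter.
#'
#' @param counts allele-count tibble.
#' @param metadata per-individual metadata.
#' @param thresholds integer vector of minimum depths (each >= 1).
#' @return list with `differences` (tibble snp x threshold of landscape
#'   frequency differences) and `correlations` (tibble threshold_a,
#'   threshold_b, spearman).
#' @export
threshold_robustness_scan <- function(counts, metadata, thresholds = 1:10) {
  if (length(thresholds) == 0 || any(thresholds < 1)) {
    abort("`thresholds` must be a non-empty vector of depths >= 1")
  }
  metadata <- check_metadata(metadata, unique(counts$individual))
  frag <- metadata$individual[metadata$landscape == "fragmented"]
  cont <- metadata$individual[metadata$landscape == "continuous"]
  depth <- counts$ref_count + counts$alt_count
  diffs <- lapply(thresholds, function(t) {
    kept <- counts[depth >= t, ]
    by_group <- function(ids) {
      sub <- kept[kept$individual %in% ids, ]
      agg <- dplyr::summarise(dplyr::group_by(sub, .data$snp),
                              alt = sum(.data$alt_count),
                              tot = sum(.data$alt_count + .data$ref_count),
                              .groups = "drop")
      setNames(agg$alt / agg$tot, agg$snp)
    }
    ff <- by_group(frag); fc <- by_group(cont)
    shared <- intersect(names(ff), names(fc))
    setNames(ff[shared] - fc[shared], shared)
  })
  snps <- sort(unique(counts$snp))
  mat <- sapply(diffs, function(d) d[snps])
  rownames(mat) <- snps
  colnames(mat) <- make.unique(paste0("t", thresholds))
  undefined <- colSums(!is.na(mat)) == 0
  if (any(undefined)) {
    warn(paste0("thresholds with no covered individuals (frequencies undefined): ",
                paste(thresholds[undefined], collapse = ", ")))
  }
  pairs <- expand.grid(i = seq_along(thresholds), j = seq_along(thresholds))
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  cors <- tibble(
    threshold_a = thresholds[pairs$i],
    threshold_b = thresholds[pairs$j],
    spearman = mapply(function(i, j) {
      ok <- stats::complete.cases(mat[, c(i, j)])
      if (sum(ok) < 2) return(NA_real_)
      cor(mat[ok, i], mat[ok, j], method = "spearman")
    }, pairs$i, pairs$j)
  )
  diff_tbl <- as_tibble(as.data.frame(mat))
  diff_tbl <- dplyr::bind_cols(tibble(snp = snps), diff_tbl)
  list(differences = diff_tbl, correlations = cors)
}
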