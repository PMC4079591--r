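# Independent oracles and small fixture builders used across the suite.

# Weir-Cockerham multi-population F_ST estimator from dosage genotypes
# (variance components a, b, c; standard two-allele formulation).
wc_fst <- function(dosage, pop) {
  pop <- as.factor(pop)
  r <- nlevels(pop)
  a_sum <- 0; abc_sum <- 0
  for (s in seq_len(nrow(dosage))) {
    d <- dosage[s, ]
    ok <- !is.na(d)
    n_i <- tapply(ok, pop, sum)
    if (any(n_i == 0)) next
    p_i <- tapply(d[ok], pop[ok], sum) / (2 * n_i)
    h_i <- tapply(d[ok] == 1, pop[ok], sum) / n_i
    n_bar <- mean(n_i)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    a <- n_bar / n_c * (s2 - 1 / (n_bar - 1) *
                          (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    if (is.finite(a) && is.finite(b) && is.finite(cc)) {
      a_sum <- a_sum + a
      abc_sum <- abc_sum + a + b + cc
    }
  }
  a_sum / abc_sum
}

# Numerical double integration of the Normal-Gamma evidence over
# (mean m, precision p); independent of the closed form under test.
ng_marginal_numeric <- function(x, mu0 = 0, kappa0 = 1, alpha0 = 1, beta0 = 1) {
  inner <- function(p) {
    vapply(p, function(pp) {
      f <- function(m) {
        exp(colSums(dnorm(matrix(x, length(x), length(m)),
                          rep(m, each = length(x)), 1 / sqrt(pp), log = TRUE))) *
          dnorm(m, mu0, 1 / sqrt(kappa0 * pp))
      }
      integrate(f, -Inf, Inf, rel.tol = 1e-10)$value *
        dgamma(pp, alpha0, rate = beta0)
    }, numeric(1))
  }
  log(integrate(inner, 0, Inf, rel.tol = 1e-10)$value)
}

# Brute-force two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with the margins whose probability does
# not exceed the observed table's.
fisher_two_sided_brute <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force hypergeometric upper tail for category enrichment.
hyper_upper_brute <- function(k, K, n, N) {
  sum(vapply(k:min(n, K), function(i) {
    exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }, numeric(1)))
}

# Small study used by several files; memoized per (seed, size).
tiny_study <- local({
  cache <- list()
  function(seed = 42, n_snps = 200, n_genes = 120, n_per_pop = 12,
           null = FALSE, ...) {
    key <- paste(seed, n_snps, n_genes, n_per_pop, null, ...)
    if (is.null(cache[[key]])) {
      extra <- list(...)
      args <- c(list(n_snps = n_snps, n_genes = n_genes,
                     n_individuals_per_population = n_per_pop, seed = seed),
                extra)
      if (null) {
        args <- utils::modifyList(list(
          n_snps = n_snps, n_genes = n_genes,
          n_individuals_per_population = n_per_pop, seed = seed,
          n_differentiated_snps = 0, landscape_freq_shift = 0,
          n_landscape_de_genes = 0, n_sex_de_genes = 0,
          n_eqtl_pairs = 0, n_mixture_genes = 0), extra)
      } else if (!("n_landscape_de_genes" %in% names(extra))) {
        args$n_landscape_de_genes <- 20
        args$n_sex_de_genes <- 5
        args$n_eqtl_pairs <- 5
        args$n_mixture_genes <- 10
      }
      cache[[key]] <<- simulate_study(do.call(study_config, args))
    }
    cache[[key]]
  }
})

# Allele-count tibble for hand-built scenarios.
counts_tbl <- function(ref, alt, snps = NULL, inds = NULL) {
  n_snp <- nrow(ref); n_ind <- ncol(ref)
  snps <- snps %||% sprintf("s%03d", seq_len(n_snp))
  inds <- inds %||% sprintf("i%03d", seq_len(n_ind))
  tibble::tibble(
    snp = rep(snps, times = n_ind),
    individual = rep(inds, each = n_snp),
    ref_count = as.integer(as.vector(ref)),
    alt_count = as.integer(as.vector(alt))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
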