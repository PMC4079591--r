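# Variational-Bayes univariate Gaussian mixtures for screening
# within-population expression heterogeneity, with ELBO-based model
# selection over K = 1..k_max.

gamma_entropy <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)

#' Fit a univariate Bayesian Gaussian mixture by variational Bayes
#'
#' Mean-field VB for a K-component univariate Gaussian mixture with a
#' symmetric Dirichlet(1) prior on the mixing weights and a
#' Normal-Gamma(0, 1, 1, 1) prior on each component's mean and
#' precision; inputs are assumed standardized (zero mean, unit
#' variance) so the same uninformative priors suit every gene.
#' Responsibilities are initialized from k-means under the given seed;
#' the evidence lower bound (ELBO) is non-decreasing across iterations
#' and convergence is declared when its change drops below `tol`.
#'
#' @param x numeric vector of standardized values (length >= K).
#' @param K number of mixture components.
#' @param seed integer seed for the k-means initialization.
#' @param tol ELBO convergence tolerance.
#' @param max_iter iteration cap.
#' @param prior an [ng_prior()] for the component parameters.
#' @param alpha0 symmetric Dirichlet concentration.
#' @return object of class `ml_vbgmm`: list with `K`, `weights`
#'   (posterior expected mixing weights), `means`, `precisions`
#'   (posterior expectations), `responsibilities` (n x K),
#'   `elbo`, `elbo_trace`, `converged`, `n_iter`,
#'   `n_effective_components` (components with expected occupancy
#'   >= 0.5 observations).
#' @export
fit_vbgmm <- function(x, K, seed = 1, tol = 1e-6, max_iter = 500,
                      prior = ng_prior(), alpha0 = 1) {
  n <- length(x)
  if (K < 1) abort("K must be >= 1")
  if (K > n) abort("K exceeds the number of observations")
  m0 <- prior$mu0; k0 <- prior$kappa0; a0 <- prior$alpha0; b0 <- prior$beta0

  r <- matrix(0, n, K)
  if (K == 1) {
    r[, 1] <- 1
  } else {
    cl <- with_seed(seed, {
      if (length(unique(x)) >= K) {
        tryCatch(kmeans(x, centers = K, nstart = 1)$cluster,
                 error = function(e) as.integer(cut(rank(x, ties.method = "first"),
                                                    K, labels = FALSE)))
      } else {
        as.integer(cut(rank(x, ties.method = "first"), K, labels = FALSE))
      }
    })
    r[cbind(seq_len(n), cl)] <- 1
  }

  elbo_trace <- numeric(0)
  elbo_old <- -Inf
  converged <- FALSE
  ak <- bk <- kk <- mk <- alpha <- rep(NA_real_, K)
  for (iter in seq_len(max_iter)) {
    # M-like step: update q(pi), q(mu, tau) from responsibilities
    Nk <- colSums(r)
    xbar <- ifelse(Nk > 0, colSums(r * x) / pmax(Nk, 1e-12), 0)
    Sk <- colSums(r * (outer(x, xbar, "-"))^2) / pmax(Nk, 1e-12)
    alpha <- alpha0 + Nk
    kk <- k0 + Nk
    mk <- (k0 * m0 + Nk * xbar) / kk
    ak <- a0 + Nk / 2
    bk <- b0 + 0.5 * (Nk * Sk + k0 * Nk * (xbar - m0)^2 / kk)

    # E step: update q(Z)
    elnpi <- digamma(alpha) - digamma(sum(alpha))
    elntau <- digamma(ak) - log(bk)
    etau <- ak / bk
    quad <- outer(rep(1, n), 1 / kk) +
      (outer(x, mk, "-"))^2 * outer(rep(1, n), etau)
    lrho <- outer(rep(1, n), elnpi + 0.5 * elntau - 0.5 * log(2 * pi)) - 0.5 * quad
    lmax <- apply(lrho, 1L, max)
    r <- exp(lrho - lmax)
    r <- r / rowSums(r)

    # ELBO with the new q(Z) and new q(params)
    Nk2 <- colSums(r)
    xbar2 <- ifelse(Nk2 > 0, colSums(r * x) / pmax(Nk2, 1e-12), 0)
    Sk2 <- colSums(r * (outer(x, xbar2, "-"))^2) / pmax(Nk2, 1e-12)
    t1 <- sum(0.5 * Nk2 * (elntau - log(2 * pi) - 1 / kk -
                             etau * (Sk2 + (xbar2 - mk)^2)))
    t2 <- sum(Nk2 * elnpi)
    t3 <- lgamma(K * alpha0) - K * lgamma(alpha0) + (alpha0 - 1) * sum(elnpi)
    t4 <- sum(0.5 * log(k0 / (2 * pi)) + 0.5 * elntau -
                0.5 * k0 * (1 / kk + etau * (mk - m0)^2) +
                a0 * log(b0) - lgamma(a0) + (a0 - 1) * elntau - b0 * etau)
    t5 <- -sum(r[r > 0] * log(r[r > 0]))
    t6 <- -(lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elnpi))
    t7 <- -sum(0.5 * elntau + 0.5 * log(kk / (2 * pi)) - 0.5 -
                 gamma_entropy(ak, bk))
    elbo <- t1 + t2 + t3 + t4 + t5 + t6 + t7
    elbo_trace <- c(elbo_trace, elbo)
    if (is.finite(elbo_old) && abs(elbo - elbo_old) < tol) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  Nk <- colSums(r)
  structure(list(
    K = K,
    weights = alpha / sum(alpha),
    means = mk,
    precisions = ak / bk,
    responsibilities = r,
    elbo = elbo_trace[length(elbo_trace)],
    elbo_trace = elbo_trace,
    converged = converged,
    n_iter = length(elbo_trace),
    n_effective_components = sum(Nk >= 0.5),
    occupancy = Nk
  ), class = "ml_vbgmm")
}

#' @export
print.ml_vbgmm <- function(x, ...) {
  cat("VB Gaussian mixture: K =", x$K,
      "(", x$n_effective_components, "occupied ), ELBO =",
      format(x$elbo, digits = 6),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' Select the number of mixture components by marginal likelihood
#'
#' Fits K = 1..`k_max` mixtures with [fit_vbgmm()] and returns the K with
#' the highest ELBO (the variational surrogate for the marginal
#' likelihood). Components left empty by the fit are pruned before the
#' comparison: each candidate is scored at its effective K, and the
#' smallest K attaining the best bound wins ties.
#'
#' @param x standardized values (length >= k_max recommended; K is
#'   capped at the sample size).
#' @param k_max largest number of components to try.
#' @param seed integer seed (passed per-K to the k-means init).
#' @param ... further arguments for [fit_vbgmm()].
#' @return list with `best_k` (effective components of the winning fit),
#'   `best_fit`, `fits` (all fits), `elbo` (tibble K, elbo,
#'   effective_k).
#' @export
select_components <- function(x, k_max = 5, seed = 1, ...) {
  ks <- seq_len(min(k_max, length(x)))
  fits <- lapply(ks, function(k) fit_vbgmm(x, k, seed = seed + k, ...))
  elbos <- vapply(fits, function(f) f$elbo, numeric(1))
  eff <- vapply(fits, function(f) f$n_effective_components, numeric(1))
  best <- order(-elbos, ks)[1]
  list(best_k = as.integer(eff[best]),
       best_fit = fits[[best]],
       fits = fits,
       elbo = tibble(K = ks, elbo = elbos, effective_k = as.integer(eff)))
}

#' Hard component labels from a mixture fit
#'
#' @param fit an `ml_vbgmm` fit.
#' @return integer vector of per-individual labels (argmax posterior
#'   responsibility).
#' @export
classify_components <- function(fit) {
  stopifnot(inherits(fit, "ml_vbgmm"))
  apply(fit$responsibilities, 1L, which.max)
}

#' Association between mixture components and a covariate
#'
#' For each gene, a Fisher exact test on the contingency table of hard
#' component labels versus a categorical covariate (e.g. sex), with BH
#' FDR across genes. Degenerate tables (a zero margin, or a single
#' label) give p = 1.
#'
#' @param labels matrix (genes x individuals) of component labels, or a
#'   single vector for one gene.
#' @param covariate factor/character vector aligned with individuals.
#' @param alpha_fdr significance cutoff recorded in the output flag.
#' @return tibble with `gene`, `p`, `q`, `significant`.
#' @export
component_association <- function(labels, covariate, alpha_fdr = 0.05) {
  if (is.null(dim(labels))) labels <- matrix(labels, 1L, dimnames = list("gene1"))
  if (ncol(labels) != length(covariate)) {
    abort("covariate length must match the number of individuals")
  }
  p <- apply(labels, 1L, function(l) {
    tab <- table(l, covariate)
    if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
  })
  q <- unname(bh_fdr(p))
  tibble(gene = rownames(labels) %||% as.character(seq_len(nrow(labels))),
         p = unname(p), q = q, significant = q < alpha_fdr)
}

#' Screen genes for multi-component expression
#'
#' Runs [select_components()] on every row of a standardized expression
#' matrix and reports the selected K per gene.
#'
#' @param z standardized matrix from [standardize_expression()].
#' @param k_max largest K to try.
#' @param seed integer seed; each gene uses `seed + row index`.
#' @param ... passed to [fit_vbgmm()].
#' @return tibble `gene`, `best_k`, `elbo_best`, plus a `labels`
#'   attribute (genes x individuals hard labels of the winning fits).
#' @export
heterogeneity_screen <- function(z, k_max = 5, seed = 1, ...) {
  genes <- rownames(z) %||% as.character(seq_len(nrow(z)))
  labels <- matrix(NA_integer_, nrow(z), ncol(z), dimnames = dimnames(z))
  best_k <- integer(nrow(z)); elbo_best <- numeric(nrow(z))
  for (g in seq_len(nrow(z))) {
    sel <- select_components(z[g, ], k_max = k_max, seed = seed + g, ...)
    best_k[g] <- sel$best_k
    elbo_best[g] <- sel$best_fit$elbo
    labels[g, ] <- classify_components(sel$best_fit)
  }
  out <- tibble(gene = genes, best_k = best_k, elbo_best = elbo_best)
  attr(out, "labels") <- labels
  out
}
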