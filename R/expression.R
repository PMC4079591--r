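# Normalization and the dual differential-expression procedure:
# an NB-GLM likelihood-ratio test for the landscape contrast intersected
# with a group-consistency permutation test.

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors computed as the precision-weighted
#' doubly trimmed mean of per-gene log2 ratios (M) against a reference
#' individual, trimming `trim_m` of the M distribution and `trim_a` of
#' the average-abundance (A) distribution from each tail. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts gene x individual matrix of non-negative counts.
#' @param ref_individual column name or index of the reference; by
#'   default the individual whose upper-quartile scaled count is closest
#'   to the mean upper quartile.
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @param lib_sizes library sizes; defaults to column sums.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, ref_individual = NULL,
                        trim_m = 0.30, trim_a = 0.05, lib_sizes = NULL) {
  if (ncol(counts) < 2) abort("at least two individuals are required")
  lib <- lib_sizes %||% colSums(counts)
  if (any(lib == 0)) abort("individual with all-zero counts")
  if (is.null(ref_individual)) {
    uq <- apply(counts, 2L, function(y) quantile(y / sum(y), 0.75))
    ref_individual <- which.min(abs(uq - mean(uq)))
  }
  ref <- counts[, ref_individual]
  nref <- lib[[ref_individual]]
  one_factor <- function(obs, nobs) {
    pr_o <- obs / nobs
    pr_r <- ref / nref
    fin <- obs > 0 & ref > 0
    m <- log2(pr_o[fin] / pr_r[fin])
    a <- (log2(pr_o[fin]) + log2(pr_r[fin])) / 2
    w <- (nobs - obs[fin]) / (nobs * obs[fin]) + (nref - ref[fin]) / (nref * ref[fin])
    n <- length(m)
    if (n == 0) return(1)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
    if (!any(keep)) return(1)
    f <- sum(m[keep] / w[keep]) / sum(1 / w[keep])
    if (!is.finite(f)) return(1)
    2^f
  }
  f <- vapply(seq_len(ncol(counts)), function(k) one_factor(counts[, k], lib[[k]]),
              numeric(1))
  f <- f / geometric_mean(f)
  setNames(f, colnames(counts))
}

#' Normalized log2 counts per million
#'
#' @param counts gene x individual count matrix.
#' @param factors TMM factors (computed if `NULL`).
#' @param lib_sizes library sizes; defaults to column sums.
#' @param prior_cpm constant added to CPM before taking log2 (avoids
#'   log of zero).
#' @return gene x individual matrix of `log2(CPM + prior_cpm)` where CPM
#'   uses the effective (factor-adjusted) library size.
#' @export
log_cpm <- function(counts, factors = NULL, lib_sizes = NULL, prior_cpm = 0.5) {
  lib <- lib_sizes %||% colSums(counts)
  f <- factors %||% tmm_factors(counts, lib_sizes = lib)
  eff <- lib * f
  log2(sweep(counts, 2L, eff / 1e6, "/") + prior_cpm)
}

# ---- NB GLM machinery -----------------------------------------------------

# IRLS fit of an NB GLM with log link, fixed dispersion phi, offset o.
nb_irls <- function(y, X, offset, phi, max_iter = 50, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu) - offset
  beta <- tryCatch(qr.solve(X, eta), error = function(e) rep(0, ncol(X)))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    xtw <- t(X * w)
    beta_new <- tryCatch(solve(xtw %*% X, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    mu_new <- exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30))
    ll <- sum(dnbinom(y, size = 1 / phi, mu = mu_new, log = TRUE))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu,
       loglik = sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)),
       weights = mu / (1 + phi * mu))
}

# Cox-Reid adjusted profile log-likelihood of dispersion phi.
nb_apl <- function(y, X, offset, phi) {
  fit <- nb_irls(y, X, offset, phi)
  xtwx <- t(X * fit$weights) %*% X
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  fit$loglik - 0.5 * as.numeric(ld)
}

#' Negative-binomial GLM likelihood-ratio test for the landscape contrast
#'
#' Fits, per gene, an NB GLM with one mean per population (offsets = log
#' effective library size) and tests the contrast "mean of fragmented
#' population means minus mean of continuous population means" with a
#' likelihood-ratio test against chi-squared(1). Gene-wise dispersions
#' are estimated by Cox--Reid adjusted profile likelihood and moderated
#' toward an abundance-trended value with strength `prior_df`
#' (log-scale weighted average with weights residual df : prior df).
#'
#' @param counts gene x individual integer matrix.
#' @param metadata per-individual metadata (`population`, `landscape`).
#' @param factors TMM factors; computed if `NULL`.
#' @param prior_df prior degrees of freedom of the dispersion moderation.
#' @param dispersion optional fixed dispersion (scalar or per-gene),
#'   bypassing estimation.
#' @return tibble of class `ml_de_lrt` with per-gene `gene`, `log_cpm`
#'   (average), population mean log2-CPMs, `log2fc` (fragmented minus
#'   continuous), `dispersion`, `lrt_stat`, `p`, `q`. Genes with all-zero
#'   counts get missing p.
#' @export
nb_glm_lrt <- function(counts, metadata, factors = NULL, prior_df = 10,
                       dispersion = NULL) {
  metadata <- check_metadata(metadata, colnames(counts))
  pop <- population_factor(metadata)
  pops <- levels(pop)
  if (any(table(pop) < 2)) abort("at least two individuals per population required")
  land_of_pop <- vapply(pops, function(p) {
    metadata$landscape[match(p, metadata$population)]
  }, character(1))
  frag_pops <- land_of_pop == "fragmented"
  ctr <- ifelse(frag_pops, 1 / sum(frag_pops), -1 / sum(!frag_pops))

  X <- sapply(pops, function(p) as.numeric(pop == p))
  # null design spans {beta : ctr' beta = 0}
  proj <- diag(length(pops)) - outer(ctr, ctr) / sum(ctr^2)
  B <- svd(proj)$u[, seq_len(length(pops) - 1), drop = FALSE]
  Xn <- X %*% B

  f <- factors %||% tmm_factors(counts)
  offset <- log(colSums(counts) * f)
  genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  ave_lcpm <- rowMeans(log_cpm(counts, factors = f))

  n <- ncol(counts)
  resid_df <- n - length(pops)
  lo <- log(1e-4); hi <- log(4)
  est_disp <- is.null(dispersion)
  if (!est_disp) {
    disp <- rep_len(dispersion, nrow(counts))
  } else {
    disp_hat <- rep(NA_real_, nrow(counts))
    for (g in seq_len(nrow(counts))) {
      y <- counts[g, ]
      if (sum(y) == 0) next
      opt <- optimize(function(lp) nb_apl(y, X, offset, exp(lp)),
                      c(lo, hi), maximum = TRUE, tol = 1e-3)
      disp_hat[g] <- exp(opt$maximum)
    }
    ok <- !is.na(disp_hat)
    if (sum(ok) >= 10) {
      lw <- stats::lowess(ave_lcpm[ok], log(disp_hat[ok]), f = 0.5)
      trend <- stats::approx(lw$x, lw$y, xout = ave_lcpm, rule = 2)$y
    } else {
      trend <- rep(log(median(disp_hat[ok], na.rm = TRUE) %||% 0.1), nrow(counts))
    }
    disp <- exp((resid_df * log(disp_hat) + prior_df * trend) /
                  (resid_df + prior_df))
    disp[!ok] <- exp(trend[!ok])
  }

  stat <- p <- l2fc <- rep(NA_real_, nrow(counts))
  pop_means <- matrix(NA_real_, nrow(counts), length(pops),
                      dimnames = list(genes, pops))
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    if (sum(y) == 0) next
    full <- nb_irls(y, X, offset, disp[g])
    null <- nb_irls(y, Xn, offset, disp[g])
    s <- max(0, 2 * (full$loglik - null$loglik))
    stat[g] <- s
    p[g] <- pchisq(s, df = 1, lower.tail = FALSE)
    l2fc[g] <- sum(ctr * full$beta) / log(2)
    pop_means[g, ] <- full$beta / log(2)
  }
  if (any(!is.na(stat) & stat == 0)) {
    # genes with identical mean in all groups: statistic exactly 0, p = 1
    p[!is.na(stat) & stat == 0] <- 1
  }
  out <- tibble(gene = genes, log_cpm = ave_lcpm, log2fc = l2fc,
                dispersion = disp, lrt_stat = stat, p = p, q = bh_fdr(p))
  for (pp in pops) out[[paste0("mean_", pp)]] <- pop_means[, pp]
  class(out) <- c("ml_de_lrt", class(out))
  out
}

#' Consistency-constrained permutation test for landscape differences
#'
#' Per gene the statistic is the absolute difference between the mean
#' log-normalized count of fragmented-landscape individuals and that of
#' continuous-landscape individuals, but only when the population means
#' are consistent: both fragmented population means strictly above both
#' continuous ones, or strictly below. Inconsistent genes are declared
#' non-significant (p = 1). The null permutes individual labels; a
#' permuted replicate violating the consistency condition contributes
#' statistic 0. p-values use the add-one estimator and are BH-adjusted.
#'
#' @param log_counts gene x individual matrix of log2 normalized counts
#'   (see [log_cpm()]).
#' @param metadata per-individual metadata.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param batch permutations evaluated per matrix multiplication.
#' @return tibble of class `ml_de_perm`: `gene`, `statistic`,
#'   `consistent`, `p`, `q`.
#' @export
consistency_permutation_test <- function(log_counts, metadata, n_perm = 1e5,
                                         seed = 1, batch = 200) {
  metadata <- check_metadata(metadata, colnames(log_counts))
  pop <- population_factor(metadata)
  pops <- levels(pop)
  land_of_pop <- vapply(pops, function(p) {
    metadata$landscape[match(p, metadata$population)]
  }, character(1))
  if (sum(land_of_pop == "fragmented") < 1 || sum(land_of_pop == "continuous") < 1) {
    abort("both landscape types must be present")
  }
  n <- ncol(log_counts)
  W <- sapply(pops, function(p) as.numeric(pop == p) / sum(pop == p))
  frag_ind <- metadata$landscape == "fragmented"
  w_land <- cbind(frag = frag_ind / sum(frag_ind),
                  cont = (!frag_ind) / sum(!frag_ind))
  Wfull <- cbind(W, w_land)  # n x (npop + 2)
  frag_cols <- which(land_of_pop == "fragmented")
  cont_cols <- which(land_of_pop == "continuous")

  stat_of <- function(res) {
    pm <- res[, seq_along(pops), drop = FALSE]
    fmin <- do.call(pmin, lapply(frag_cols, function(j) pm[, j]))
    fmax <- do.call(pmax, lapply(frag_cols, function(j) pm[, j]))
    cmin <- do.call(pmin, lapply(cont_cols, function(j) pm[, j]))
    cmax <- do.call(pmax, lapply(cont_cols, function(j) pm[, j]))
    cons <- (fmin > cmax) | (fmax < cmin)
    d <- abs(res[, length(pops) + 1] - res[, length(pops) + 2])
    list(stat = ifelse(cons, d, 0), cons = cons)
  }
  obs <- stat_of(log_counts %*% Wfull)
  exceed <- numeric(nrow(log_counts))
  done <- 0L
  with_seed(seed, {
    while (done < n_perm) {
      b <- min(batch, n_perm - done)
      Wb <- matrix(0, n, ncol(Wfull) * b)
      for (k in seq_len(b)) {
        Wb[, (k - 1) * ncol(Wfull) + seq_len(ncol(Wfull))] <- Wfull[sample.int(n), ]
      }
      res <- log_counts %*% Wb
      for (k in seq_len(b)) {
        st <- stat_of(res[, (k - 1) * ncol(Wfull) + seq_len(ncol(Wfull)), drop = FALSE])
        exceed <- exceed + (st$stat >= obs$stat)
      }
      done <- done + b
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p[!obs$cons] <- 1
  constant <- apply(log_counts, 1L, function(r) max(r) == min(r))
  p[constant] <- 1
  out <- tibble(gene = rownames(log_counts) %||% as.character(seq_len(nrow(log_counts))),
                statistic = unname(obs$stat),
                consistent = unname(obs$cons & !constant),
                p = unname(p), q = unname(bh_fdr(p)))
  class(out) <- c("ml_de_perm", class(out))
  out
}

#' Landscape differentially expressed genes (intersection rule)
#'
#' A gene is declared differentially expressed between the landscape
#' types only when it is significant (FDR < `alpha`) in both the NB-GLM
#' likelihood-ratio test and the consistency permutation test.
#'
#' @param lrt result of [nb_glm_lrt()].
#' @param perm result of [consistency_permutation_test()] on the same genes.
#' @param alpha FDR cutoff applied to both tests.
#' @return tibble of class `ml_de`: per gene `gene`, `log2fc`, `lrt_q`,
#'   `perm_q`, `consistent`, `de` (final flag) and `direction` (+1 up in
#'   fragmented, -1 down, for flagged genes).
#' @export
landscape_de_genes <- function(lrt, perm, alpha = 0.05) {
  if (!setequal(lrt$gene, perm$gene)) abort("the two tests cover different genes")
  merged <- dplyr::inner_join(
    dplyr::select(lrt, "gene", "log_cpm", "log2fc", lrt_q = "q"),
    dplyr::select(perm, "gene", perm_q = "q", "consistent"),
    by = "gene")
  merged$de <- !is.na(merged$lrt_q) & merged$lrt_q < alpha &
    merged$perm_q < alpha
  merged$direction <- ifelse(merged$de, sign(merged$log2fc), NA_real_)
  class(merged) <- c("ml_de", class(merged))
  merged
}
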