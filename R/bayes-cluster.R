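# Marginal-likelihood scoring of population set partitions under a
# conjugate Normal-Gamma model of standardized expression.

#' Enumerate set partitions of a label set
#'
#' All ways of dividing the labels into disjoint non-empty blocks,
#' including the finest (every label its own block) and the coarsest
#' (all merged); the count is the Bell number of the label count
#' (Bell(4) = 15). Canonical ordering: by number of blocks, then
#' lexicographically on the block structure.
#'
#' @param labels character vector (at most 12 labels).
#' @return list of partitions; each partition is a list of character
#'   vectors (blocks).
#' @examples
#' length(enumerate_partitions(c("F1", "F2", "C1", "C2"))) # 15
#' @export
enumerate_partitions <- function(labels) {
  n <- length(labels)
  if (n < 1 || n > 12) abort("between 1 and 12 labels are supported")
  parts <- list(list(labels[1]))
  if (n > 1) {
    for (i in 2:n) {
      parts <- unlist(lapply(parts, function(p) {
        grown <- lapply(seq_along(p), function(b) {
          p[[b]] <- c(p[[b]], labels[i]); p
        })
        c(grown, list(c(p, list(labels[i]))))
      }), recursive = FALSE)
    }
  }
  canon <- function(p) {
    p <- lapply(p, function(b) b[order(match(b, labels))])
    p[order(vapply(p, function(b) match(b[1], labels), integer(1)))]
  }
  parts <- lapply(parts, canon)
  key <- vapply(parts, function(p) {
    paste(vapply(p, paste, character(1), collapse = ","), collapse = "|")
  }, character(1))
  parts <- parts[!duplicated(key)]
  key <- key[!duplicated(key)]
  nb <- vapply(parts, length, integer(1))
  parts[order(nb, key)]
}

#' Normal-Gamma prior
#'
#' Conjugate prior for a Gaussian's mean and precision: precision
#' `p ~ Gamma(alpha0, beta0)` (the default `Gamma(1, 1)` is the Exp(1)
#' prior) and mean `m | p ~ N(mu0, 1/(kappa0 * p))`.
#'
#' @param mu0 prior mean.
#' @param kappa0 prior mean-precision scale (> 0).
#' @param alpha0,beta0 Gamma shape and rate (> 0).
#' @return list of class `ml_ng_prior`.
#' @export
ng_prior <- function(mu0 = 0, kappa0 = 1, alpha0 = 1, beta0 = 1) {
  if (kappa0 <= 0 || alpha0 <= 0 || beta0 <= 0) {
    abort("kappa0, alpha0 and beta0 must be positive")
  }
  structure(list(mu0 = mu0, kappa0 = kappa0, alpha0 = alpha0, beta0 = beta0),
            class = "ml_ng_prior")
}

#' Normal-Gamma log marginal likelihood
#'
#' Closed-form log evidence of i.i.d. Gaussian observations under the
#' conjugate Normal-Gamma prior, integrating out mean and precision.
#'
#' @param x numeric vector of observations (length >= 1).
#' @param prior an [ng_prior()].
#' @return the log marginal likelihood (natural log).
#' @export
ng_log_marginal <- function(x, prior = ng_prior()) {
  if (length(x) < 1) abort("at least one observation is required")
  n <- length(x)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  ng_log_marginal_suff(n, xbar, ss, prior)
}

ng_log_marginal_suff <- function(n, xbar, ss, prior) {
  k0 <- prior$kappa0; a0 <- prior$alpha0; b0 <- prior$beta0; mu0 <- prior$mu0
  kn <- k0 + n
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + k0 * n * (xbar - mu0)^2 / (2 * kn)
  lgamma(an) - lgamma(a0) + a0 * log(b0) - an * log(bn) +
    0.5 * (log(k0) - log(kn)) - (n / 2) * log(2 * pi)
}

#' Standardize expression for partition scoring
#'
#' TMM-normalizes, log-transforms ([log_cpm()]) and scales each gene to
#' zero mean and unit variance (unbiased SD) over all individuals.
#' Zero-variance genes are dropped and recorded in the `"dropped"`
#' attribute.
#'
#' @param counts gene x individual count matrix.
#' @param factors optional TMM factors.
#' @return standardized matrix (genes x individuals).
#' @export
standardize_expression <- function(counts, factors = NULL) {
  lc <- log_cpm(counts, factors = factors)
  mu <- rowMeans(lc)
  s <- apply(lc, 1L, sd)
  keep <- s > 0
  z <- (lc[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(z, "dropped") <- rownames(lc)[!keep]
  z
}

#' Score all population partitions by total log marginal likelihood
#'
#' For each set partition of the populations, the score is the sum over
#' clusters and genes of the Normal-Gamma log marginal likelihood of the
#' standardized expression values of the individuals in the cluster.
#' Partitions are ranked in descending score; ties are broken in favour
#' of fewer blocks (the coarser model).
#'
#' @param z standardized expression matrix from [standardize_expression()].
#' @param metadata per-individual metadata (for population labels), or a
#'   character vector of population labels aligned with `colnames(z)`.
#' @param prior an [ng_prior()].
#' @return tibble of class `ml_partitions`: `partition` (string such as
#'   `"F1+F2 | C1 | C2"`), `n_blocks`, `log_ml`, `rank`; the list of
#'   partitions is attached as attribute `"partitions"`.
#' @export
score_partitions <- function(z, metadata, prior = ng_prior()) {
  pop <- if (is.data.frame(metadata)) {
    check_metadata(metadata, colnames(z))$population
  } else {
    as.character(metadata)
  }
  pops <- unique(pop)
  if (any(table(pop) < 1)) abort("every population needs at least one individual")
  parts <- enumerate_partitions(pops)
  cluster_score <- function(members) {
    cols <- pop %in% members
    xs <- z[, cols, drop = FALSE]
    n <- ncol(xs)
    xbar <- rowMeans(xs)
    ss <- rowSums((xs - xbar)^2)
    sum(ng_log_marginal_suff(n, xbar, ss, prior))
  }
  # every cluster is a subset of populations; score each subset once
  cache <- new.env(parent = emptyenv())
  score_block <- function(members) {
    key <- paste(sort(members), collapse = ",")
    if (is.null(cache[[key]])) cache[[key]] <- cluster_score(members)
    cache[[key]]
  }
  log_ml <- vapply(parts, function(p) sum(vapply(p, score_block, numeric(1))),
                   numeric(1))
  nb <- vapply(parts, length, integer(1))
  out <- tibble(
    partition = vapply(parts, function(p) {
      paste(vapply(p, paste, character(1), collapse = "+"), collapse = " | ")
    }, character(1)),
    n_blocks = nb, log_ml = log_ml
  )
  ord <- order(-out$log_ml, out$n_blocks)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), ]
  attr(out, "partitions") <- parts[ord]
  class(out) <- c("ml_partitions", class(out))
  out
}
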