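# Kinship-aware GLS association between SNP genotypes and expression of
# the nearest gene, with eligibility and sign-consistency filters.

#' Shared-allele relatedness matrix
#'
#' Pairwise similarity between individuals computed from genotype
#' dosages: for each jointly-called SNP the shared-allele fraction is
#' `1 - |dosage_i - dosage_j| / 2`, and the entry is the mean over SNPs.
#' The diagonal is forced to 1 and a small ridge is added so the matrix
#' is positive definite. Pairs with no jointly-called SNP are imputed
#' with the mean similarity of their population pair (with a warning).
#'
#' @param genotypes dosage matrix (SNP x individual) with `NA` missing.
#' @param metadata optional metadata used for imputing missing pairs.
#' @param ridge diagonal ridge added for positive definiteness.
#' @return individuals x individuals similarity matrix.
#' @export
relatedness_matrix <- function(genotypes, metadata = NULL, ridge = 1e-6) {
  n <- ncol(genotypes)
  if (n < 2) abort("at least two individuals are required")
  d <- genotypes
  called <- !is.na(d)
  # sum over shared SNPs of |di - dj|, expanded over the dosage classes:
  # |di - dj| is 1 for {0,1} and {1,2} pairs and 2 for {0,2} pairs.
  A0 <- (called & d == 0L) + 0; A1 <- (called & d == 1L) + 0
  A2 <- (called & d == 2L) + 0
  A0[is.na(A0)] <- 0; A1[is.na(A1)] <- 0; A2[is.na(A2)] <- 0
  S01 <- crossprod(A0, A1); S12 <- crossprod(A1, A2); S02 <- crossprod(A0, A2)
  absdiff <- S01 + t(S01) + S12 + t(S12) + 2 * (S02 + t(S02))
  shared <- crossprod(called + 0)
  V <- 1 - absdiff / (2 * shared)
  V[shared == 0] <- NA_real_
  dimnames(V) <- list(colnames(d), colnames(d))
  if (anyNA(V)) {
    warn("pairs with no shared SNPs: imputed with the population-pair mean similarity")
    pop <- if (!is.null(metadata)) {
      check_metadata(metadata, colnames(d))$population
    } else rep("all", n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (is.na(V[i, j])) {
        block <- V[pop == pop[i], pop == pop[j], drop = FALSE]
        V[i, j] <- mean(block, na.rm = TRUE)
      }
    }
  }
  diag(V) <- 1
  V + diag(ridge, n)
}

#' Numeric genotype coding under a genetic model
#'
#' @param dosage integer alternate-allele dosage in \{0, 1, 2\} (`NA`
#'   propagates).
#' @param model `"additive"` (0/1/2), `"dominance"` (0/1/1) or
#'   `"recessive"` (0/0/1).
#' @return numeric predictor.
#' @export
genotype_coding <- function(dosage, model = c("additive", "dominance", "recessive")) {
  model <- match.arg(model)
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) abort("dosages must be 0, 1, 2 or missing")
  switch(model,
         additive = as.numeric(dosage),
         dominance = as.numeric(dosage >= 1),
         recessive = as.numeric(dosage == 2))
}

#' Generalized least squares with a relatedness covariance
#'
#' Fits `y = intercept + beta * x` with error covariance proportional to
#' `V` by whitening with the Cholesky factor of `V`; with `V` the
#' identity this reduces exactly to ordinary least squares. The slope is
#' tested two-sided against a t distribution with n - p degrees of
#' freedom.
#'
#' @param y response (expression values).
#' @param x coded genotype predictor.
#' @param V covariance structure (individuals x individuals); `NULL`
#'   for the identity.
#' @param covariates optional numeric matrix of extra columns (e.g. sex).
#' @return object of class `ml_gls`: list with `beta` (slope), `se`,
#'   `t`, `p`, `df`, `n`, `coefficients`.
#' @export
gls_fit <- function(y, x, V = NULL, covariates = NULL) {
  ok <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- y[ok]; x <- x[ok]
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ok, , drop = FALSE])
  n <- length(y)
  if (n <= ncol(X)) abort("too few observations for the GLS fit")
  if (var(y) == 0) {
    return(structure(list(beta = 0, se = NA_real_, t = 0, p = 1,
                          df = n - ncol(X), n = n,
                          coefficients = setNames(c(mean(y), rep(0, ncol(X) - 1)),
                                                  colnames(X))),
                     class = "ml_gls"))
  }
  if (!is.null(V)) {
    V <- V[ok, ok, drop = FALSE]
    L <- chol(V)
    y <- backsolve(L, y, transpose = TRUE)
    X <- backsolve(L, X, transpose = TRUE)
    colnames(X) <- c("(Intercept)", "x",
                     if (!is.null(covariates)) colnames(as.matrix(covariates)))
  }
  xtx <- crossprod(X)
  xty <- crossprod(X, y)
  coef <- drop(solve(xtx, xty))
  resid <- y - drop(X %*% coef)
  df <- n - ncol(X)
  s2 <- sum(resid^2) / df
  cov_beta <- s2 * solve(xtx)
  se <- sqrt(cov_beta["x", "x"])
  tval <- coef[["x"]] / se
  structure(list(beta = coef[["x"]], se = se, t = tval,
                 p = 2 * pt(abs(tval), df, lower.tail = FALSE),
                 df = df, n = n,
                 coefficients = setNames(coef, colnames(X))),
            class = "ml_gls")
}

#' @export
print.ml_gls <- function(x, ...) {
  cat("GLS fit: beta =", format(x$beta, digits = 4),
      " t =", format(x$t, digits = 4), " p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

#' Map each SNP to its nearest gene
#'
#' Nearest-gene assignment by distance from the SNP position to the
#' gene midpoint on the same scaffold; ties go to the gene with the
#' lower start coordinate. Coordinates are 1-based.
#'
#' @param snp_positions tibble `snp`, `scaffold`, `pos`.
#' @param gene_positions tibble `gene`, `scaffold`, `start`, `end`.
#' @return tibble `snp`, `gene`, `distance` (SNPs on scaffolds with no
#'   gene are omitted).
#' @export
nearest_gene_map <- function(snp_positions, gene_positions) {
  gp <- dplyr::mutate(gene_positions, mid = (.data$start + .data$end) / 2)
  joined <- dplyr::inner_join(snp_positions, gp, by = "scaffold",
                              relationship = "many-to-many")
  joined <- dplyr::mutate(joined, distance = abs(.data$pos - .data$mid))
  joined <- dplyr::arrange(joined, .data$snp, .data$distance, .data$start)
  out <- dplyr::slice_head(dplyr::group_by(joined, .data$snp), n = 1L)
  dplyr::select(dplyr::ungroup(out), "snp", "gene", "distance")
}

#' Screen SNP-gene pairs for cis-eQTL
#'
#' For each (SNP, nearest gene) pair and genetic coding, fits
#' [gls_fit()] separately within each population using that
#' population's block of the relatedness matrix, provided all three
#' genotype classes occur in the population. p-values are BH-adjusted
#' within each population across all tested pairs. A pair is accepted
#' when (optionally) the SNP is landscape-differentiated, FDR < `alpha`
#' in at least one population, and the slope has the same sign in every
#' population with a defined fit.
#'
#' @param expression gene x individual matrix of log-normalized values.
#' @param genotypes dosage matrix (SNP x individual).
#' @param snp_gene_map tibble `snp`, `gene` (see [nearest_gene_map()]).
#' @param metadata per-individual metadata.
#' @param V relatedness matrix from [relatedness_matrix()]; computed
#'   from `genotypes` if `NULL`.
#' @param differentiated_snps optional character vector; when supplied,
#'   only these SNPs are eligible (the landscape-differentiation
#'   requirement).
#' @param codings genetic codings to fit.
#' @param alpha per-population FDR cutoff.
#' @param sex_covariate include sex as a covariate in the mean model.
#' @return tibble of class `ml_eqtl`: one row per (snp, gene, coding)
#'   with per-population `beta_*`/`p_*`/`q_*` columns, `n_pops_tested`,
#'   `n_significant`, `sign_consistent` and `accepted`.
#' @export
screen_eqtl <- function(expression, genotypes, snp_gene_map, metadata,
                        V = NULL, differentiated_snps = NULL,
                        codings = c("additive", "dominance", "recessive"),
                        alpha = 0.05, sex_covariate = FALSE) {
  metadata <- check_metadata(metadata, colnames(expression))
  pops <- unique(metadata$population)
  if (is.null(V)) V <- relatedness_matrix(genotypes, metadata)
  map <- snp_gene_map[snp_gene_map$snp %in% rownames(genotypes) &
                        snp_gene_map$gene %in% rownames(expression), , drop = FALSE]
  if (!is.null(differentiated_snps)) {
    map <- map[map$snp %in% differentiated_snps, , drop = FALSE]
  }
  rows <- list()
  for (coding in codings) {
    for (k in seq_len(nrow(map))) {
      snp <- map$snp[k]; gene <- map$gene[k]
      dos <- genotypes[snp, metadata$individual]
      rec <- list(snp = snp, gene = gene, coding = coding)
      tested_any <- FALSE
      for (p in pops) {
        in_pop <- metadata$population == p
        dp <- dos[in_pop]
        classes <- sort(unique(dp[!is.na(dp)]))
        if (!identical(classes, c(0L, 1L, 2L)) &&
            !identical(as.numeric(classes), c(0, 1, 2))) {
          rec[[paste0("beta_", p)]] <- NA_real_
          rec[[paste0("p_", p)]] <- NA_real_
          next
        }
        ids <- metadata$individual[in_pop]
        xv <- genotype_coding(dp, coding)
        cov <- if (sex_covariate) {
          cbind(sex = as.numeric(metadata$sex[in_pop] == "female"))
        } else NULL
        fit <- tryCatch(
          gls_fit(expression[gene, ids], xv, V[ids, ids, drop = FALSE], cov),
          error = function(e) NULL)
        if (is.null(fit)) {
          rec[[paste0("beta_", p)]] <- NA_real_
          rec[[paste0("p_", p)]] <- NA_real_
        } else {
          rec[[paste0("beta_", p)]] <- fit$beta
          rec[[paste0("p_", p)]] <- fit$p
          tested_any <- TRUE
        }
      }
      rec$tested <- tested_any
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0) {
    return(structure(tibble(snp = character(), gene = character(),
                            coding = character(), accepted = logical()),
                     class = c("ml_eqtl", class(tibble()))))
  }
  out <- dplyr::bind_rows(lapply(rows, as_tibble))
  out <- out[out$tested, , drop = FALSE]
  for (p in pops) {
    out[[paste0("q_", p)]] <- bh_fdr(out[[paste0("p_", p)]])
  }
  beta_mat <- as.matrix(out[paste0("beta_", pops)])
  q_mat <- as.matrix(out[paste0("q_", pops)])
  out$n_pops_tested <- rowSums(!is.na(beta_mat))
  out$n_significant <- rowSums(q_mat < alpha, na.rm = TRUE)
  sgn <- sign(beta_mat)
  out$sign_consistent <- apply(sgn, 1L, function(s) {
    s <- s[!is.na(s)]
    length(s) > 0 && (all(s > 0) || all(s < 0))
  })
  out$accepted <- out$n_significant >= 1 & out$sign_consistent
  out$tested <- NULL
  class(out) <- c("ml_eqtl", class(out))
  out
}
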