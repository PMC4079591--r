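# broom-style tidy()/glance() methods for fitted objects.

#' @rdname gls_fit
#' @param x an `ml_gls` object.
#' @param ... unused.
#' @export
tidy.ml_gls <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = c(NA_real_, x$se, rep(NA_real_, length(x$coefficients) - 2)),
         statistic = c(NA_real_, x$t, rep(NA_real_, length(x$coefficients) - 2)),
         p.value = c(NA_real_, x$p, rep(NA_real_, length(x$coefficients) - 2)))
}

#' @rdname gls_fit
#' @export
glance.ml_gls <- function(x, ...) {
  tibble(nobs = x$n, df.residual = x$df, statistic = x$t, p.value = x$p)
}

#' @rdname fit_vbgmm
#' @param x an `ml_vbgmm` object.
#' @param ... unused.
#' @export
tidy.ml_vbgmm <- function(x, ...) {
  tibble(component = seq_len(x$K),
         weight = x$weights,
         mean = x$means,
         precision = x$precisions,
         occupancy = x$occupancy)
}

#' @rdname fit_vbgmm
#' @export
glance.ml_vbgmm <- function(x, ...) {
  tibble(K = x$K, effective_k = x$n_effective_components,
         elbo = x$elbo, converged = x$converged, n_iter = x$n_iter)
}

#' @rdname score_partitions
#' @param x an `ml_partitions` object.
#' @param ... unused.
#' @export
tidy.ml_partitions <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "partitions") <- NULL
  out
}

#' @rdname score_partitions
#' @export
glance.ml_partitions <- function(x, ...) {
  tibble(n_partitions = nrow(x),
         best_partition = x$partition[x$rank == 1],
         best_log_ml = x$log_ml[x$rank == 1],
         margin = x$log_ml[x$rank == 1] - max(x$log_ml[x$rank != 1]))
}

#' @rdname concordance_test
#' @param x an `ml_concordance` object.
#' @param ... unused.
#' @export
tidy.ml_concordance <- function(x, ...) x$data

#' @rdname concordance_test
#' @export
glance.ml_concordance <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p, nobs = x$n, method = x$method)
}
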