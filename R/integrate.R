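# Category enrichment tests and cross-dataset concordance analyses.

#' Upper-tail binomial category test
#'
#' Probability of observing at least `k` significant genes in a category
#' of `n` genes when each is significant independently with the
#' background rate: `P(X >= k)` for `X ~ Binomial(n, rate)`. With the
#' background DE rate 1841/16667 and the 7 hexamerin genes of which 4
#' were significant, the probability is 0.0039.
#'
#' @param k observed significant genes in the category.
#' @param n category size.
#' @param rate background significance rate.
#' @return upper-tail probability.
#' @examples
#' binomial_category_test(4, 7, 1841 / 16667)
#' @export
binomial_category_test <- function(k, n, rate) {
  if (k < 0 || n < 0 || k > n) abort("need 0 <= k <= n")
  if (rate < 0 || rate > 1) abort("`rate` must lie in [0, 1]")
  if (k == 0) return(1)
  pbinom(k - 1, n, rate, lower.tail = FALSE)
}

#' One-sided Fisher test of category over-representation
#'
#' Hypergeometric upper-tail test of whether a category contains more
#' significant genes than expected from the universe-wide fraction.
#'
#' @param members_significant significant genes inside the category.
#' @param members_total category size.
#' @param universe_significant significant genes in the whole universe
#'   (category included).
#' @param universe_total universe size.
#' @return one-sided (greater) Fisher exact p-value.
#' @export
fraction_test <- function(members_significant, members_total,
                          universe_significant, universe_total) {
  if (members_total > universe_total ||
      members_significant > universe_significant ||
      members_significant > members_total ||
      universe_significant > universe_total) {
    abort("inconsistent counts: category must be contained in the universe")
  }
  if (members_total == 0) return(1)
  # P(X >= members_significant), X hypergeometric over the 2x2 margins
  phyper(members_significant - 1, universe_significant,
         universe_total - universe_significant, members_total,
         lower.tail = FALSE)
}

#' Filter a DE gene set for concordance analyses
#'
#' Keeps genes with adequate coverage in both data sets
#' (`log_cpm > cpm_floor`, strict, in each) and a large landscape
#' expression difference (`|log2 ratio| > ratio_floor`, strict).
#'
#' @param de_set character vector of gene identifiers.
#' @param log_cpm_a,log_cpm_b named numeric vectors of per-gene log-CPM
#'   in the two data sets.
#' @param log2_ratio named numeric vector of the landscape log2 ratio.
#' @param cpm_floor,ratio_floor strict lower bounds.
#' @return character subset of `de_set`; per-step counts in the
#'   `"steps"` attribute.
#' @export
filter_concordance_genes <- function(de_set, log_cpm_a, log_cpm_b, log2_ratio,
                                     cpm_floor = 1, ratio_floor = 1) {
  g0 <- de_set
  g1 <- g0[!is.na(log_cpm_a[g0]) & log_cpm_a[g0] > cpm_floor &
             !is.na(log_cpm_b[g0]) & log_cpm_b[g0] > cpm_floor]
  g2 <- g1[!is.na(log2_ratio[g1]) & abs(log2_ratio[g1]) > ratio_floor]
  attr(g2, "steps") <- c(input = length(g0), after_cpm = length(g1),
                         after_ratio = length(g2))
  g2
}

#' Per-gene landscape expression difference
#'
#' Mean log-normalized expression of fragmented-landscape individuals
#' minus that of continuous-landscape individuals, optionally excluding
#' one population's individuals (for leave-one-population-out
#' recomputation).
#'
#' @param log_counts gene x individual matrix of log2 normalized counts.
#' @param metadata per-individual metadata.
#' @param exclude_population optional population label to drop.
#' @param individuals optional subset of individuals to use.
#' @return named numeric vector of per-gene differences.
#' @export
landscape_delta <- function(log_counts, metadata, exclude_population = NULL,
                            individuals = NULL) {
  metadata <- check_metadata(metadata, colnames(log_counts))
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(exclude_population)) keep <- metadata$population != exclude_population
  if (!is.null(individuals)) keep <- keep & metadata$individual %in% individuals
  md <- metadata[keep, ]
  if (length(unique(md$landscape)) < 2) {
    abort("both landscape types must remain after exclusion")
  }
  lf <- log_counts[, md$individual[md$landscape == "fragmented"], drop = FALSE]
  lc <- log_counts[, md$individual[md$landscape == "continuous"], drop = FALSE]
  rowMeans(lf) - rowMeans(lc)
}

#' Correlation concordance between two expression contrasts
#'
#' Correlates two per-gene log2 contrasts over the same gene set and
#' reports the correlation with its two-sided test p-value.
#'
#' @param delta_a,delta_b named numeric vectors, or a data frame holding
#'   both as its first two numeric columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `ml_concordance`: list with `data` (tibble
#'   gene, delta_a, delta_b), `estimate`, `p`, `n`, `method`.
#' @export
concordance_test <- function(delta_a, delta_b = NULL,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(delta_a)) {
    df <- delta_a
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    genes <- if ("gene" %in% names(df)) df$gene else as.character(seq_len(nrow(df)))
    delta_b <- setNames(df[[num[2]]], genes)
    delta_a <- setNames(df[[num[1]]], genes)
  }
  shared <- intersect(names(delta_a) %||% seq_along(delta_a),
                      names(delta_b) %||% seq_along(delta_b))
  a <- delta_a[shared]; b <- delta_b[shared]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("fewer than 3 genes: correlation undefined")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance in a contrast: correlation undefined")
  }
  ct <- suppressWarnings(cor.test(a, b, method = method))
  structure(list(
    data = tibble(gene = as.character(shared[ok]), delta_a = unname(a),
                  delta_b = unname(b)),
    estimate = unname(ct$estimate), p = ct$p.value, n = length(a),
    method = method
  ), class = "ml_concordance")
}

#' @export
print.ml_concordance <- function(x, ...) {
  cat("Concordance over", x$n, "genes:", x$method, "r =",
      format(x$estimate, digits = 3), ", p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Concordance of flight-induced change with landscape baseline
#'
#' Compares per-gene flight-induced expression changes with the
#' baseline fragmented-minus-continuous landscape difference over the
#' shared genes: a direction-agreement 2x2 table with a Fisher exact
#' p-value, and the correlation of the two log2 changes. Because the
#' direction table is the primary display, the correlation p-value is
#' reported only when `force_p = TRUE`. When `sex` labels accompany the
#' flight responses (a `sex` column), results are additionally computed
#' per sex.
#'
#' @param flight_response tibble with columns `gene`, `log2fc` (flight
#'   minus control) and optionally `sex`.
#' @param landscape_delta named per-gene landscape difference (see
#'   [landscape_delta()]).
#' @param force_p report the correlation p-value.
#' @return object of class `ml_flight_concordance`: list with
#'   `direction_table`, `fisher_p`, `correlation`, `correlation_p`
#'   (NA unless forced), `n`, and `per_sex` (list, possibly empty).
#' @export
flight_baseline_concordance <- function(flight_response, landscape_delta,
                                        force_p = FALSE) {
  shared <- intersect(flight_response$gene, names(landscape_delta))
  if (length(shared) == 0) abort("no shared genes between the two data sets")
  one <- function(fr) {
    fr <- fr[fr$gene %in% shared, ]
    ld <- landscape_delta[fr$gene]
    if (sd(ld) == 0) {
      return(list(direction_table = table(flight = sign(fr$log2fc), baseline = sign(ld)),
                  fisher_p = NA_real_, correlation = NA_real_,
                  correlation_p = NA_real_, n = nrow(fr),
                  note = "landscape differences have zero variance"))
    }
    dir_tab <- table(flight_up = fr$log2fc > 0, baseline_up = ld > 0)
    fp <- if (nrow(dir_tab) == 2 && ncol(dir_tab) == 2) {
      fisher.test(dir_tab)$p.value
    } else NA_real_
    ct <- suppressWarnings(cor.test(fr$log2fc, ld))
    list(direction_table = dir_tab, fisher_p = fp,
         correlation = unname(ct$estimate),
         correlation_p = if (force_p) ct$p.value else NA_real_,
         n = nrow(fr))
  }
  res <- one(flight_response)
  per_sex <- list()
  if ("sex" %in% names(flight_response)) {
    for (s in unique(flight_response$sex)) {
      per_sex[[s]] <- one(flight_response[flight_response$sex == s, ])
    }
  }
  structure(c(res, list(per_sex = per_sex)), class = "ml_flight_concordance")
}

#' @export
print.ml_flight_concordance <- function(x, ...) {
  cat("Flight-vs-baseline concordance over", x$n, "genes\n")
  print(x$direction_table)
  cat("direction-agreement Fisher p =", format(x$fisher_p, digits = 3),
      "; correlation r =", format(x$correlation, digits = 3), "\n")
  if (!is.na(x$correlation_p)) {
    cat("correlation p =", format(x$correlation_p, digits = 3), "\n")
  }
  invisible(x)
}
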