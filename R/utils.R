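# Internal helpers shared across modules.

# Derive a reproducible per-stage seed from a single study seed, so each
# simulation stage can be regenerated independently.  Kept below 2^31.
substream_seed <- function(seed, stage) {
  stages <- c(
    genotypes = 1L, reads = 2L, expression = 3L, permutation = 4L,
    diversity = 5L, gmm = 6L, pipeline = 7L
  )
  idx <- stages[[stage]]
  as.integer((as.numeric(seed) * 48271 + idx * 10007) %% 2147483647)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

geometric_mean <- function(x) exp(mean(log(x)))

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Population labels for a metadata tibble, as a factor in first-appearance order.
population_factor <- function(metadata) {
  factor(metadata$population, levels = unique(metadata$population))
}

check_metadata <- function(metadata, individuals = NULL) {
  required <- c("individual", "population", "landscape")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(metadata$individual)) {
    abort("metadata has duplicated individual IDs")
  }
  if (!is.null(individuals)) {
    absent <- setdiff(individuals, metadata$individual)
    if (length(absent) > 0) {
      abort(paste0("individuals absent from metadata: ",
                   paste(head(absent, 5), collapse = ", ")))
    }
    metadata <- metadata[match(individuals, metadata$individual), , drop = FALSE]
  }
  metadata
}
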