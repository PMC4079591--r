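#' Configuration for a synthetic metapopulation study
#'
#' Builds and validates the parameter set from which [simulate_study()]
#' generates a complete synthetic study: four regional populations (two per
#' landscape type by default), drift-structured biallelic SNPs, and
#' negative-binomially distributed gene expression counts with landscape,
#' sex, eQTL and mixture effects planted as recorded truth.
#'
#' Defaults mirror the sampling design the pipeline targets: 15 individuals
#' per population, two fragmented and two continuous populations, a SNP
#' panel of 10^4 biallelic sites and 16,667 gene models.
#'
#' @param n_populations number of populations.
#' @param populations character vector of population labels.
#' @param landscape_of_population named character vector mapping every
#'   population to `"fragmented"` or `"continuous"`.
#' @param n_individuals_per_population integer vector (recycled) of
#'   per-population sample sizes.
#' @param n_snps,n_genes panel sizes.
#' @param fst_tree list with element `terminal` (per-population drift
#'   parameters in (0,1), Balding--Nichols F) and optional `internal`
#'   (named per-landscape drift for a shared landscape ancestor; `NULL`
#'   gives a star tree).
#' @param n_differentiated_snps number of SNPs receiving an extra
#'   landscape-correlated allele-frequency shift.
#' @param landscape_freq_shift total fragmented-vs-continuous allele
#'   frequency shift applied to differentiated SNPs.
#' @param n_landscape_de_genes,landscape_log2_effect number of truth
#'   landscape-DE genes and their log2 fold change (random sign per gene).
#' @param n_sex_de_genes number of genes with a sex effect (1 log2 unit).
#' @param n_eqtl_pairs,eqtl_beta number of cis-eQTL pairs and the additive
#'   effect per alternate allele on the natural-log scale.
#' @param n_mixture_genes,mixture_delta number of genes with a latent
#'   two-component expression mixture and the separation of the component
#'   means in units of the gene's biological standard deviation.
#' @param nb_dispersion_range range of gene-wise NB dispersions (uniform).
#' @param library_size_range range of library sizes (log-uniform), spanning
#'   the >10-fold spread typical of unnormalized RNA-seq libraries.
#' @param mean_coverage_per_snp Poisson mean read depth per SNP per
#'   individual.
#' @param seed single integer; expanded into per-stage substreams.
#'
#' @return An object of class `ml_config` (a validated list).
#' @seealso [simulate_study()]
#' @export
study_config <- function(n_populations = 4,
                         populations = NULL,
                         landscape_of_population = NULL,
                         n_individuals_per_population = 15,
                         n_snps = 10000,
                         n_genes = 16667,
                         fst_tree = NULL,
                         n_differentiated_snps = 500,
                         landscape_freq_shift = 0.2,
                         n_landscape_de_genes = 200,
                         landscape_log2_effect = 1,
                         n_sex_de_genes = 50,
                         n_eqtl_pairs = 20,
                         eqtl_beta = 1,
                         n_mixture_genes = 100,
                         mixture_delta = 4,
                         nb_dispersion_range = c(0.05, 0.4),
                         library_size_range = c(1e6, 2e7),
                         mean_coverage_per_snp = 20,
                         seed = 1) {
  if (is.null(populations)) {
    populations <- if (n_populations == 4) {
      c("F1", "F2", "C1", "C2")
    } else {
      paste0("P", seq_len(n_populations))
    }
  }
  n_populations <- length(populations)
  if (is.null(landscape_of_population)) {
    if (n_populations %% 2 != 0) {
      abort("supply `landscape_of_population` when populations cannot be split evenly")
    }
    landscape_of_population <- setNames(
      rep(c("fragmented", "continuous"), each = n_populations / 2), populations)
  }
  if (!setequal(names(landscape_of_population), populations) ||
      !all(landscape_of_population %in% c("fragmented", "continuous"))) {
    abort("`landscape_of_population` must map every population to fragmented/continuous")
  }
  if (length(unique(landscape_of_population)) < 2) {
    abort("both landscape types must be represented")
  }
  if (is.null(fst_tree)) {
    fst_tree <- list(terminal = setNames(rep(0.05, n_populations), populations),
                     internal = NULL)
  }
  drift <- c(fst_tree$terminal, fst_tree$internal)
  if (any(drift <= 0 | drift >= 1)) {
    abort("drift parameters must lie strictly in (0, 1)")
  }
  if (!setequal(names(fst_tree$terminal), populations)) {
    abort("`fst_tree$terminal` must name every population")
  }
  n_ind <- as.integer(rep_len(n_individuals_per_population, n_populations))
  for (nm in c("n_snps", "n_genes")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  if (any(n_ind <= 0)) abort("sample sizes must be positive")
  assert_scalar_number(landscape_freq_shift, "landscape_freq_shift", 0, 1)
  assert_scalar_number(mean_coverage_per_snp, "mean_coverage_per_snp", 0)
  if (length(nb_dispersion_range) != 2 || any(nb_dispersion_range <= 0)) {
    abort("`nb_dispersion_range` must be a positive interval (dispersion <= 0 is invalid)")
  }
  if (length(library_size_range) != 2 || any(library_size_range <= 0)) {
    abort("`library_size_range` must be a positive interval")
  }
  cfg <- list(
    populations = populations,
    landscape_of_population = landscape_of_population,
    n_individuals_per_population = setNames(n_ind, populations),
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    fst_tree = fst_tree,
    n_differentiated_snps = as.integer(min(n_differentiated_snps, n_snps)),
    landscape_freq_shift = landscape_freq_shift,
    n_landscape_de_genes = as.integer(n_landscape_de_genes),
    landscape_log2_effect = landscape_log2_effect,
    n_sex_de_genes = as.integer(n_sex_de_genes),
    n_eqtl_pairs = as.integer(n_eqtl_pairs), eqtl_beta = eqtl_beta,
    n_mixture_genes = as.integer(n_mixture_genes), mixture_delta = mixture_delta,
    nb_dispersion_range = as.numeric(nb_dispersion_range),
    library_size_range = as.numeric(library_size_range),
    mean_coverage_per_snp = mean_coverage_per_snp,
    seed = as.integer(seed)
  )
  structure(cfg, class = "ml_config")
}

#' @export
print.ml_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  populations:", paste0(x$populations, " (", substr(x$landscape_of_population, 1, 4),
                               ", n=", x$n_individuals_per_population, ")", collapse = ", "), "\n")
  cat("  SNPs:", x$n_snps, " genes:", x$n_genes, " seed:", x$seed, "\n")
  invisible(x)
}

balding_nichols <- function(p, f) {
  # Beta draw centred on p with variance f * p * (1 - p)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

snp_ids <- function(n) sprintf("snp%05d", seq_len(n))
gene_ids <- function(n) sprintf("g%05d", seq_len(n))

individual_ids <- function(config) {
  unlist(lapply(config$populations, function(p) {
    sprintf("%s_%02d", p, seq_len(config$n_individuals_per_population[[p]]))
  }), use.names = FALSE)
}

#' Simulate drift-structured genotypes
#'
#' Draws ancestral allele frequencies uniform on (0.05, 0.95), population
#' frequencies from a Balding--Nichols Beta along the configured drift tree,
#' and individual genotypes as binomial(2) dosages. A configured subset of
#' SNPs receives an additional landscape-correlated frequency shift
#' (fragmented populations up, continuous down, or vice versa with random
#' sign), emulating loci differentiated between the landscape types.
#'
#' @param config an [study_config()] object.
#' @return list with `dosage` (SNP x individual integer matrix of alternate
#'   allele counts 0/1/2), `freqs` (SNP x population allele frequencies
#'   after the landscape shift), `ancestral`, and `differentiated_snps`
#'   (tibble of shifted SNPs and their signed shift).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "ml_config"))
  with_seed(substream_seed(config$seed, "genotypes"), {
    pops <- config$populations
    n_snps <- config$n_snps
    p0 <- runif(n_snps, 0.05, 0.95)
    internal <- config$fst_tree$internal
    freqs <- matrix(NA_real_, n_snps, length(pops), dimnames = list(snp_ids(n_snps), pops))
    anc <- list()
    for (pop in pops) {
      base <- p0
      land <- config$landscape_of_population[[pop]]
      if (!is.null(internal) && !is.null(internal[[land]])) {
        if (is.null(anc[[land]])) anc[[land]] <- balding_nichols(p0, internal[[land]])
        base <- anc[[land]]
      }
      freqs[, pop] <- balding_nichols(base, config$fst_tree$terminal[[pop]])
    }
    diff_tbl <- tibble(snp = character(), shift = numeric())
    if (config$n_differentiated_snps > 0 && config$landscape_freq_shift > 0) {
      idx <- sample.int(n_snps, config$n_differentiated_snps)
      sign <- sample(c(-1, 1), length(idx), replace = TRUE)
      shift <- sign * config$landscape_freq_shift / 2
      frag <- pops[config$landscape_of_population[pops] == "fragmented"]
      cont <- setdiff(pops, frag)
      freqs[idx, frag] <- pmin(pmax(freqs[idx, frag] + shift, 0.01), 0.99)
      freqs[idx, cont] <- pmin(pmax(freqs[idx, cont] - shift, 0.01), 0.99)
      diff_tbl <- tibble(snp = rownames(freqs)[idx], shift = 2 * shift)
    }
    ids <- individual_ids(config)
    pop_of <- rep(pops, config$n_individuals_per_population[pops])
    dosage <- matrix(0L, n_snps, length(ids), dimnames = list(rownames(freqs), ids))
    for (pop in pops) {
      cols <- which(pop_of == pop)
      dosage[, cols] <- rbinom(n_snps * length(cols), 2L, freqs[, pop])
    }
    list(dosage = dosage, freqs = freqs, ancestral = p0,
         differentiated_snps = diff_tbl)
  })
}

#' Simulate per-SNP allele read counts
#'
#' Total depth per (SNP, individual) is Poisson with the configured mean;
#' alternate reads are binomial with success probability dosage/2.
#' Zero-depth entries are retained (low-coverage regions are a feature of
#' unnormalized RNA-seq libraries).
#'
#' @param genotypes result of [simulate_genotypes()] or a dosage matrix.
#' @param config an [study_config()] object.
#' @return tibble with columns `snp`, `individual`, `ref_count`, `alt_count`.
#' @export
simulate_allele_reads <- function(genotypes, config) {
  dosage <- if (is.list(genotypes)) genotypes$dosage else genotypes
  if (config$mean_coverage_per_snp < 0) abort("mean coverage must be non-negative")
  with_seed(substream_seed(config$seed, "reads"), {
    n <- length(dosage)
    depth <- rpois(n, config$mean_coverage_per_snp)
    alt <- rbinom(n, depth, as.vector(dosage) / 2)
    tibble(
      snp = rep(rownames(dosage), times = ncol(dosage)),
      individual = rep(colnames(dosage), each = nrow(dosage)),
      ref_count = as.integer(depth - alt),
      alt_count = as.integer(alt)
    )
  })
}

#' Simulate gene expression counts with planted structure
#'
#' Counts for gene g in individual i are negative binomial with mean
#' `L_i * q_g * exp(effects)` and gene-wise dispersion `phi_g`; effects
#' cover landscape (truth DE genes, random sign), sex, additive cis-eQTL
#' (`beta * dosage`), and for mixture genes a latent Bernoulli(0.5)
#' two-component mean shift independent of population.
#'
#' @param config an [study_config()] object.
#' @param genotypes result of [simulate_genotypes()]; needed to plant
#'   eQTL effects and pick suitable (common, landscape-differentiated)
#'   eQTL SNPs.
#' @param metadata per-individual metadata (from [simulate_study()]);
#'   built if omitted.
#' @return list with `counts` (gene x individual integer matrix),
#'   `library_sizes`, `dispersions`, and `truth` (lists of planted
#'   landscape-DE genes with signs, sex genes, eQTL pairs with betas,
#'   mixture genes and component labels).
#' @export
simulate_expression <- function(config, genotypes, metadata = NULL) {
  stopifnot(inherits(config, "ml_config"))
  if (is.null(metadata)) metadata <- make_metadata(config)
  dosage <- genotypes$dosage
  with_seed(substream_seed(config$seed, "expression"), {
    n_genes <- config$n_genes
    n_ind <- nrow(metadata)
    genes <- gene_ids(n_genes)
    q <- exp(rnorm(n_genes, 0, 1.5))
    q <- q / sum(q)
    phi <- runif(n_genes, config$nb_dispersion_range[1], config$nb_dispersion_range[2])
    lsr <- log(config$library_size_range)
    lib <- round(exp(runif(n_ind, lsr[1], lsr[2])))

    pool <- seq_len(n_genes)
    take <- function(k) {
      k <- min(k, length(pool))
      if (k == 0) return(integer(0))
      picked <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      picked
    }
    de_idx <- take(config$n_landscape_de_genes)
    sex_idx <- take(config$n_sex_de_genes)
    mix_idx <- take(config$n_mixture_genes)
    eqtl_gene_idx <- take(config$n_eqtl_pairs)

    de_sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    sex_sign <- sample(c(-1, 1), length(sex_idx), replace = TRUE)

    # eQTL SNPs: prefer landscape-differentiated, common SNPs so all three
    # genotype classes occur and the pairs survive the screen's filters.
    maf <- rowMeans(genotypes$freqs)
    common <- rownames(dosage)[maf > 0.25 & maf < 0.75]
    pref <- intersect(genotypes$differentiated_snps$snp, common)
    candidates <- unique(c(pref, common, rownames(dosage)))
    eqtl_snps <- head(candidates, length(eqtl_gene_idx))

    is_frag <- metadata$landscape == "fragmented"
    is_female <- metadata$sex == "female"
    eta <- matrix(0, n_genes, n_ind)
    if (length(de_idx)) {
      eta[de_idx, is_frag] <- eta[de_idx, is_frag] +
        de_sign * log(2) * config$landscape_log2_effect
    }
    if (length(sex_idx)) {
      eta[sex_idx, is_female] <- eta[sex_idx, is_female] + sex_sign * log(2)
    }
    mix_component <- NULL
    if (length(mix_idx)) {
      mix_component <- matrix(
        rbinom(length(mix_idx) * n_ind, 1L, 0.5), length(mix_idx), n_ind,
        dimnames = list(genes[mix_idx], metadata$individual))
      # separation in units of the gene's biological SD (sqrt phi on log scale)
      eta[mix_idx, ] <- eta[mix_idx, ] +
        mix_component * (config$mixture_delta * sqrt(phi[mix_idx]))
    }
    if (length(eqtl_gene_idx)) {
      dos <- dosage[eqtl_snps, metadata$individual, drop = FALSE]
      eta[eqtl_gene_idx, ] <- eta[eqtl_gene_idx, ] + config$eqtl_beta * dos
    }
    mu <- (q * exp(eta)) * rep(lib, each = n_genes)
    counts <- matrix(
      rnbinom(n_genes * n_ind, mu = as.vector(mu), size = rep(1 / phi, n_ind)),
      n_genes, n_ind, dimnames = list(genes, metadata$individual))
    storage.mode(counts) <- "integer"
    truth <- list(
      de_genes = tibble(gene = genes[de_idx],
                        sign = de_sign,
                        log2_effect = de_sign * config$landscape_log2_effect),
      sex_genes = tibble(gene = genes[sex_idx], sign = sex_sign),
      eqtl = tibble(snp = eqtl_snps, gene = genes[eqtl_gene_idx],
                    beta = config$eqtl_beta),
      mixture_genes = genes[mix_idx],
      mixture_component = mix_component
    )
    list(counts = counts, library_sizes = setNames(lib, metadata$individual),
         dispersions = setNames(phi, genes), truth = truth)
  })
}

make_metadata <- function(config) {
  pops <- config$populations
  ids <- individual_ids(config)
  pop_of <- rep(pops, config$n_individuals_per_population[pops])
  with_seed(substream_seed(config$seed, "genotypes") + 1L, {
    tibble(
      individual = ids,
      population = pop_of,
      landscape = unname(config$landscape_of_population[pop_of]),
      sex = sample(c("female", "male"), length(ids), replace = TRUE),
      age_class = sample(c("new", "old"), length(ids), replace = TRUE, prob = c(0.25, 0.75)),
      flight = sample(c("control", "flown"), length(ids), replace = TRUE)
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genotypes()], [simulate_allele_reads()] and
#' [simulate_expression()] under per-stage substreams of the configured
#' seed and assembles the study object consumed by the analysis stages.
#'
#' @param config an [study_config()] object.
#' @return object of class `ml_study`: a list with `config`, `metadata`,
#'   `allele_counts` (long tibble), `truth_genotypes` (dosage matrix),
#'   `counts` (gene x individual matrix), `snp_positions`,
#'   `gene_positions`, `snp_gene_map` and `truth`.
#' @examples
#' cfg <- study_config(n_snps = 50, n_genes = 30,
#'                     n_individuals_per_population = 5, seed = 7)
#' study <- simulate_study(cfg)
#' dim(study$counts)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "ml_config"))
  geno <- simulate_genotypes(config)
  metadata <- make_metadata(config)
  reads <- simulate_allele_reads(geno, config)
  expr <- simulate_expression(config, geno, metadata)

  # deterministic genome layout: 100 genes per scaffold, genes 10 kb apart,
  # each SNP placed inside the span of one gene chosen round-robin.
  n_genes <- config$n_genes
  genes <- gene_ids(n_genes)
  gene_positions <- tibble(
    gene = genes,
    scaffold = sprintf("scf%03d", (seq_len(n_genes) - 1L) %/% 100L + 1L),
    start = ((seq_len(n_genes) - 1L) %% 100L) * 10000L + 1L,
    end = ((seq_len(n_genes) - 1L) %% 100L) * 10000L + 3000L
  )
  snps <- rownames(geno$dosage)
  host_gene <- integer(length(snps))
  host_gene[] <- ((seq_along(snps) - 1L) %% n_genes) + 1L
  # eQTL SNPs must sit in their target gene
  eq <- expr$truth$eqtl
  if (nrow(eq) > 0) host_gene[match(eq$snp, snps)] <- match(eq$gene, genes)
  snp_positions <- tibble(
    snp = snps,
    scaffold = gene_positions$scaffold[host_gene],
    pos = gene_positions$start[host_gene] + 100L + (seq_along(snps) %% 1000L)
  )
  snp_gene_map <- tibble(snp = snps, gene = genes[host_gene],
                         distance = abs(snp_positions$pos -
                                          (gene_positions$start[host_gene] +
                                             gene_positions$end[host_gene]) / 2))
  truth <- c(expr$truth,
             list(differentiated_snps = geno$differentiated_snps,
                  population_freqs = geno$freqs))
  structure(list(
    config = config, metadata = metadata,
    allele_counts = reads, truth_genotypes = geno$dosage,
    counts = expr$counts, library_sizes = expr$library_sizes,
    dispersions = expr$dispersions,
    snp_positions = snp_positions, gene_positions = gene_positions,
    snp_gene_map = snp_gene_map, truth = truth
  ), class = "ml_study")
}

#' @export
print.ml_study <- function(x, ...) {
  cat("Synthetic metapopulation study\n")
  cat("  ", nrow(x$metadata), "individuals in", length(x$config$populations),
      "populations;", nrow(x$truth_genotypes), "SNPs;", nrow(x$counts), "genes\n")
  invisible(x)
}
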