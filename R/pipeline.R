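# End-to-end orchestration of the synthetic study and analysis stages,
# with a deterministic manifest.

#' Validate study input files
#'
#' Checks a study directory (as written by [write_study()]) for matrix
#' dimension consistency, ID concordance between the count matrix, VCF
#' and metadata, duplicated IDs and negative counts.
#'
#' @param dir study directory.
#' @return tibble with columns `severity` (`"fatal"`) and `message`;
#'   zero rows when the inputs are concordant.
#' @export
validate_inputs <- function(dir) {
  violations <- list()
  bad <- function(msg) violations[[length(violations) + 1L]] <<- msg
  study <- tryCatch(read_study(dir), error = function(e) {
    bad(paste0("cannot read study: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(study)) {
    md_ids <- study$metadata$individual
    if (anyDuplicated(md_ids)) bad("duplicated individual IDs in metadata")
    if (anyDuplicated(rownames(study$counts))) bad("duplicated gene IDs in counts")
    cnt_ids <- colnames(study$counts)
    if (!setequal(cnt_ids, md_ids)) {
      bad(paste0("count-matrix individuals do not match metadata (",
                 length(setdiff(cnt_ids, md_ids)), " unmatched in counts, ",
                 length(setdiff(md_ids, cnt_ids)), " missing from counts)"))
    }
    if (ncol(study$truth_genotypes) > 0 &&
        !setequal(colnames(study$truth_genotypes), md_ids)) {
      bad("VCF individuals do not match metadata")
    }
    if (any(study$counts < 0)) bad("negative expression counts")
    if (any(study$allele_counts$ref_count < 0 | study$allele_counts$alt_count < 0)) {
      bad("negative allele read counts")
    }
  }
  tibble(severity = rep("fatal", length(violations)),
         message = unlist(violations) %||% character(0))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the enabled stages in dependency order -- simulate, SNP
#' calling, population genetics, differential expression, partition
#' scoring, mixture screening, eQTL, integration -- writing each
#' stage's tables under `out_dir` and a deterministic `manifest.json`
#' recording parameters, seeds and per-stage row counts. Two runs with
#' the same config and seed produce byte-identical manifests.
#'
#' @param config an [study_config()]; its `seed` drives every stage.
#' @param out_dir output directory (created).
#' @param stages character vector of stages to run.
#' @param alpha FDR cutoff shared by the testing stages.
#' @param n_perm permutations for the permutation tests.
#' @param gmm_max_genes cap on the number of genes screened by the
#'   mixture stage (truth mixture genes are screened first).
#' @return the manifest (named list), invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "snps", "popgen", "de",
                                    "partitions", "gmm", "eqtl", "integrate"),
                         alpha = 0.05, n_perm = 10000, gmm_max_genes = 100) {
  stopifnot(inherits(config, "ml_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(
    package = "metaland",
    version = as.character(utils::packageVersion("metaland")),
    seed = config$seed, alpha = alpha, n_perm = n_perm,
    stages = stages, counts = list()
  )
  note <- function(stage, n) manifest$counts[[stage]] <<- n
  tsv <- function(x, name) {
    write.table(x, file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  study <- panel <- perm_snps <- de <- lcpm <- NULL

  if ("simulate" %in% stages) {
    study <- simulate_study(config)
    write_study(study, file.path(out_dir, "study"))
    note("simulate", nrow(study$metadata))
  } else if (length(stages) > 0) {
    study <- read_study(file.path(out_dir, "study"))
  }
  md <- study$metadata

  if ("snps" %in% stages) {
    panel <- call_snps(study$allele_counts, md)
    tsv(panel$snps, "snp_panel.tsv")
    tsv(panel$dropped, "snp_dropped.tsv")
    note("snps", nrow(panel$snps))
  }
  if ("popgen" %in% stages && !is.null(panel)) {
    perm <- landscape_permutation_test(panel$genotypes, md, n_perm = max(n_perm, 100),
                                       seed = substream_seed(config$seed, "permutation"))
    tsv(perm, "landscape_permutation.tsv")
    perm_snps <- perm$snp[!is.na(perm$q) & perm$q < alpha]
    pops <- unique(md$population)
    frag <- pops[vapply(pops, function(p) {
      md$landscape[match(p, md$population)] == "fragmented"
    }, logical(1))]
    cont <- setdiff(pops, frag)
    pairings <- list()
    if (length(pops) == 4) {
      pairings <- list(
        landscape = list(c(frag[1], frag[2]), c(cont[1], cont[2])),
        cross1 = list(c(frag[1], cont[1]), c(frag[2], cont[2])),
        cross2 = list(c(frag[1], cont[2]), c(frag[2], cont[1]))
      )
      fish <- lapply(pairings, function(pr) fisher_pairwise(panel, pr[[1]], pr[[2]]))
      venn <- venn_partition(fish, alpha_fdr = alpha)
      tsv(fish$landscape, "fisher_landscape.tsv")
      jsonlite::write_json(venn, file.path(out_dir, "venn_counts.json"),
                           dataframe = "rows", pretty = TRUE)
    }
    div <- diversity_ranking(study$allele_counts, md,
                             subsample = min(10, min(table(md$population))),
                             seed = substream_seed(config$seed, "diversity"))
    tsv(div, "diversity_ranking.tsv")
    note("popgen", length(perm_snps))
  }
  if ("de" %in% stages) {
    f <- tmm_factors(study$counts)
    lcpm <- log_cpm(study$counts, factors = f)
    lrt <- nb_glm_lrt(study$counts, md, factors = f)
    perm_de <- consistency_permutation_test(
      lcpm, md, n_perm = n_perm,
      seed = substream_seed(config$seed, "permutation") + 1L)
    de <- landscape_de_genes(lrt, perm_de, alpha = alpha)
    tsv(lrt, "de_lrt.tsv")
    tsv(perm_de, "de_permutation.tsv")
    tsv(de, "de_genes.tsv")
    note("de", sum(de$de))
  }
  if ("partitions" %in% stages) {
    z <- standardize_expression(study$counts)
    scores <- score_partitions(z, md)
    jsonlite::write_json(
      lapply(seq_len(nrow(scores)), function(i) {
        list(partition = attr(scores, "partitions")[[i]],
             log_ml = scores$log_ml[i])
      }),
      file.path(out_dir, "partition_scores.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tsv(dplyr::select(scores, "partition", "n_blocks", "log_ml", "rank"),
        "partition_scores.tsv")
    note("partitions", nrow(scores))
  }
  if ("gmm" %in% stages) {
    z <- standardize_expression(study$counts)
    pick <- unique(c(intersect(study$truth$mixture_genes, rownames(z)),
                     rownames(z)))
    pick <- head(pick, gmm_max_genes)
    het <- heterogeneity_screen(z[pick, , drop = FALSE],
                                seed = substream_seed(config$seed, "gmm"))
    labels <- attr(het, "labels")
    assoc <- component_association(labels, md$sex)
    tsv(het, "gmm_selection.tsv")
    tsv(assoc, "gmm_sex_association.tsv")
    note("gmm", sum(het$best_k > 1))
  }
  if ("eqtl" %in% stages && !is.null(panel)) {
    if (is.null(lcpm)) lcpm <- log_cpm(study$counts)
    map <- nearest_gene_map(study$snp_positions, study$gene_positions)
    eq <- screen_eqtl(lcpm, panel$genotypes, map, md,
                      differentiated_snps = perm_snps, alpha = alpha)
    tsv(eq, "eqtl_records.tsv")
    note("eqtl", sum(eq$accepted))
  }
  if ("integrate" %in% stages && !is.null(de) && !is.null(lcpm)) {
    de_set <- de$gene[de$de]
    # background-rate category machinery on the truth mixture category
    rate <- length(de_set) / nrow(de)
    ld_all <- landscape_delta(lcpm, md)
    new_old <- tryCatch({
      frag_md <- md[md$landscape == "fragmented", ]
      stats_by_age <- rowMeans(lcpm[, frag_md$individual[frag_md$age_class == "new"],
                                    drop = FALSE]) -
        rowMeans(lcpm[, frag_md$individual[frag_md$age_class == "old"], drop = FALSE])
      filtered <- filter_concordance_genes(
        de_set, rowMeans(lcpm), rowMeans(lcpm), ld_all)
      if (length(filtered) >= 3) {
        concordance_test(ld_all[filtered], stats_by_age[filtered])
      } else NULL
    }, error = function(e) NULL)
    integ <- list(background_rate = rate,
                  n_de = length(de_set),
                  concordance = if (!is.null(new_old)) {
                    list(r = new_old$estimate, p = new_old$p, n = new_old$n)
                  } else NULL)
    jsonlite::write_json(integ, file.path(out_dir, "integration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("integrate", length(de_set))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
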