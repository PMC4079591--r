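# Reading and writing synthetic studies: VCF 4.2 (GT + AD) for genotypes
# and allele depths, TSV matrices for expression, TSV metadata and truth
# tables, YAML config.

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

gt_to_dosage <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

write_vcf_gt_ad <- function(path, snp_positions, dosage, ad) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=metaland",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage)), collapse = "\t")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dosage) > 0) {
    gt <- matrix(dosage_to_gt(dosage), nrow(dosage), ncol(dosage))
    body <- matrix(paste0(gt, ":", ad), nrow(dosage), ncol(dosage))
    pos <- snp_positions[match(rownames(dosage), snp_positions$snp), ]
    lines <- paste(pos$scaffold, pos$pos, pos$snp, "A", "G", ".", "PASS", ".",
                   "GT:AD",
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

write_matrix_tsv <- function(mat, path, id_col) {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write a synthetic study to a directory
#'
#' Emits genotypes and allele depths as a plain-text VCF 4.2 file (one
#' record per SNP, GT and AD FORMAT fields; missing genotypes as `./.`),
#' expression as a gene x individual TSV of integer counts, metadata and
#' truth tables as TSV, and the configuration as YAML. The files
#' round-trip losslessly through [read_study()].
#'
#' @param study an `ml_study` from [simulate_study()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ml_study"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(paste0("cannot create directory: ", dir))
  }
  ac <- study$allele_counts
  dosage <- study$truth_genotypes
  ad <- matrix("0,0", nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  ad[cbind(match(ac$snp, rownames(ad)), match(ac$individual, colnames(ad)))] <-
    paste0(ac$ref_count, ",", ac$alt_count)
  write_vcf_gt_ad(file.path(dir, "genotypes.vcf"), study$snp_positions, dosage, ad)
  write_matrix_tsv(study$counts, file.path(dir, "counts.tsv"), "gene")
  write.table(study$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$snp_gene_map, file.path(dir, "snp_gene_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$gene_positions, file.path(dir, "gene_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- study$truth
  write.table(tr$de_genes, file.path(dir, "truth_de_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$eqtl, file.path(dir, "truth_eqtl.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tibble(gene = tr$mixture_genes), file.path(dir, "truth_mixture_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$differentiated_snps, file.path(dir, "truth_differentiated_snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(study$config)
  cfg$landscape_of_population <- as.list(cfg$landscape_of_population)
  cfg$n_individuals_per_population <- as.list(cfg$n_individuals_per_population)
  cfg$fst_tree$terminal <- as.list(cfg$fst_tree$terminal)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a study directory
#'
#' Reads the files written by [write_study()]; the VCF is parsed with
#' \pkg{vcfR}. Returns an `ml_study` whose matrices are identical to the
#' ones written (truth components are reattached from the truth TSVs).
#'
#' @param dir directory produced by [write_study()].
#' @return an `ml_study` list.
#' @export
read_study <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("no such directory: ", dir))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- study_config(
    populations = as.character(cfg$populations),
    landscape_of_population = unlist(cfg$landscape_of_population),
    n_individuals_per_population = unlist(cfg$n_individuals_per_population),
    n_snps = cfg$n_snps, n_genes = cfg$n_genes,
    fst_tree = list(terminal = unlist(cfg$fst_tree$terminal),
                    internal = cfg$fst_tree$internal),
    n_differentiated_snps = cfg$n_differentiated_snps,
    landscape_freq_shift = cfg$landscape_freq_shift,
    n_landscape_de_genes = cfg$n_landscape_de_genes,
    landscape_log2_effect = cfg$landscape_log2_effect,
    n_sex_de_genes = cfg$n_sex_de_genes,
    n_eqtl_pairs = cfg$n_eqtl_pairs, eqtl_beta = cfg$eqtl_beta,
    n_mixture_genes = cfg$n_mixture_genes, mixture_delta = cfg$mixture_delta,
    nb_dispersion_range = unlist(cfg$nb_dispersion_range),
    library_size_range = unlist(cfg$library_size_range),
    mean_coverage_per_snp = cfg$mean_coverage_per_snp,
    seed = cfg$seed
  )
  vcf_path <- file.path(dir, "genotypes.vcf")
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@fix) > 0) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ad <- vcfR::extract.gt(vcf, element = "AD")
    dosage <- matrix(gt_to_dosage(gt), nrow(gt), ncol(gt), dimnames = dimnames(gt))
    storage.mode(dosage) <- "integer"
    parts <- strsplit(as.vector(ad), ",", fixed = TRUE)
    refc <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    altc <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    allele_counts <- tibble(
      snp = rep(rownames(ad), times = ncol(ad)),
      individual = rep(colnames(ad), each = nrow(ad)),
      ref_count = refc, alt_count = altc
    )
    snp_positions <- tibble(snp = vcf@fix[, "ID"],
                            scaffold = vcf@fix[, "CHROM"],
                            pos = as.integer(vcf@fix[, "POS"]))
  } else {
    dosage <- matrix(integer(0), 0, 0)
    allele_counts <- tibble(snp = character(), individual = character(),
                            ref_count = integer(), alt_count = integer())
    snp_positions <- tibble(snp = character(), scaffold = character(), pos = integer())
  }
  counts <- read_matrix_tsv(file.path(dir, "counts.tsv"))
  storage.mode(counts) <- "integer"
  metadata <- as_tibble(read.delim(file.path(dir, "metadata.tsv"),
                                   stringsAsFactors = FALSE))
  truth <- list(
    de_genes = as_tibble(read.delim(file.path(dir, "truth_de_genes.tsv"),
                                    stringsAsFactors = FALSE)),
    eqtl = as_tibble(read.delim(file.path(dir, "truth_eqtl.tsv"),
                                stringsAsFactors = FALSE)),
    mixture_genes = read.delim(file.path(dir, "truth_mixture_genes.tsv"),
                               stringsAsFactors = FALSE)$gene,
    differentiated_snps = as_tibble(read.delim(
      file.path(dir, "truth_differentiated_snps.tsv"), stringsAsFactors = FALSE))
  )
  structure(list(
    config = config, metadata = metadata, allele_counts = allele_counts,
    truth_genotypes = dosage, counts = counts,
    snp_positions = snp_positions,
    gene_positions = as_tibble(read.delim(file.path(dir, "gene_positions.tsv"),
                                          stringsAsFactors = FALSE)),
    snp_gene_map = as_tibble(read.delim(file.path(dir, "snp_gene_map.tsv"),
                                        stringsAsFactors = FALSE)),
    truth = truth
  ), class = "ml_study")
}
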