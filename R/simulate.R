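## Synthetic inputs: genome annotation, reference panel, curated gene list
## and index SNPs with controllable planted proximity enrichment.

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe a
#' compact two-chromosome genome whose gene density (one gene per ~86 kb)
#' and panel density (one SNP per ~2.4 kb) give window gene counts and
#' nearest-gene distances on the scale of a dense human annotation, at a
#' size where full analyses run in seconds.
#'
#' @param n_chroms Number of autosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_genes Total number of genes (placed without overlap,
#'   uniformly along the genome).
#' @param gene_length_min,gene_length_max Uniform bounds on gene span
#'   length in bp.
#' @param n_panel_snps Reference panel size.
#' @param maf_shape1,maf_shape2 Beta shape parameters of the allele
#'   frequency distribution; draws are folded to (0, 0.5] and floored at
#'   0.001, mimicking an imputation panel restricted to MAF >= 0.1%.
#' @param n_index_snps Number of index (lead) SNPs.
#' @param planted_fraction Fraction of index SNPs placed near flagged
#'   (dominant-labelled) disease genes; 0 gives a pure null.
#' @param planted_max_distance Maximum point-to-span distance (bp) of a
#'   planted SNP from its flagged gene.
#' @param n_dd_genes Number of genes labelled as disease genes.
#' @param fraction_dominant Fraction of disease genes given a monoallelic
#'   (dominant) requirement; the rest are biallelic.
#' @param seed Integer seed; the generated quadruple is a pure function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 6e7, n_genes = 1400,
                       gene_length_min = 1e4, gene_length_max = 6e4,
                       n_panel_snps = 50000, maf_shape1 = 0.4,
                       maf_shape2 = 2.0, n_index_snps = 50,
                       planted_fraction = 0, planted_max_distance = 5000,
                       n_dd_genes = 200, fraction_dominant = 0.35,
                       seed = 1) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length_min = as.integer(gene_length_min),
              gene_length_max = as.integer(gene_length_max),
              n_panel_snps = as.integer(n_panel_snps),
              maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
              n_index_snps = as.integer(n_index_snps),
              planted_fraction = planted_fraction,
              planted_max_distance = as.integer(planted_max_distance),
              n_dd_genes = as.integer(n_dd_genes),
              fraction_dominant = fraction_dominant,
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms > 0, cfg$chrom_length > 0, cfg$n_genes > 0,
            cfg$gene_length_min > 0,
            cfg$gene_length_max >= cfg$gene_length_min,
            cfg$n_panel_snps > 0, cfg$n_index_snps > 0,
            cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
            cfg$planted_max_distance >= 0,
            cfg$n_dd_genes > 0, cfg$n_dd_genes <= cfg$n_genes,
            cfg$fraction_dominant >= 0, cfg$fraction_dominant <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' @keywords internal
## Folded, floored allele frequency draws.
.sim_maf <- function(n, shape1, shape2) {
  f <- stats::rbeta(n, shape1, shape2)
  f[f > 0.5] <- 1 - f[f > 0.5]
  pmin(pmax(f, 0.001), 0.5)
}

#' @keywords internal
## Place n non-overlapping intervals of the given lengths uniformly on
## [1, L] via a stars-and-bars draw of the inter-gene gaps.
.place_genes <- function(lengths, L) {
  n <- length(lengths)
  free <- L - sum(lengths)
  if (free < 0) {
    stop("infeasible packing: total gene length exceeds chromosome length",
         call. = FALSE)
  }
  comb <- sort(sample.int(free + n, n))
  gaps <- comb - seq_len(n)            # cumulative gap before gene i
  starts <- gaps + c(0, cumsum(lengths[-n])) + 1
  data.frame(start = as.integer(starts),
             end = as.integer(starts + lengths - 1))
}

#' Simulate a full set of analysis inputs
#'
#' Generates a gene annotation (non-overlapping spans placed uniformly),
#' a reference SNP panel (uniform positions, Beta-distributed folded
#' MAF), a curated disease-gene list split dominant/recessive, and a set
#' of index SNPs. A `planted_fraction` of index SNPs is placed uniformly
#' within `planted_max_distance` of a uniformly chosen dominant-labelled
#' disease gene (positional enrichment); the remainder are drawn from
#' the panel at random. Fully reproducible from the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_inputs` with elements `annotation`
#'   ([gene_annotation()]), `panel` (SNP data.frame), `gene_rows`
#'   (curated-list data.frame), `gene_lists` ([derive_gene_lists()] set)
#'   and `index_snps` (SNP data.frame).
#' @export
simulate_inputs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chroms))
  per <- rep(config$n_genes %/% config$n_chroms, config$n_chroms)
  if (config$n_genes %% config$n_chroms > 0) {
    per[seq_len(config$n_genes %% config$n_chroms)] <-
      per[seq_len(config$n_genes %% config$n_chroms)] + 1
  }
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    lens <- sample(config$gene_length_min:config$gene_length_max, per[ci],
                   replace = TRUE)
    sp <- .place_genes(lens, config$chrom_length)
    data.frame(chrom = chroms[ci], start = sp$start, end = sp$end,
               stringsAsFactors = FALSE)
  }))
  genes$symbol <- sprintf("G%05d", seq_len(nrow(genes)))
  ann <- gene_annotation(genes)

  panel <- data.frame(
    rsid = sprintf("snp%07d", seq_len(config$n_panel_snps)),
    chrom = sample(chroms, config$n_panel_snps, replace = TRUE),
    pos = sample.int(config$chrom_length, config$n_panel_snps,
                     replace = TRUE),
    maf = .sim_maf(config$n_panel_snps, config$maf_shape1,
                   config$maf_shape2),
    classification = "none", stringsAsFactors = FALSE)

  dd_syms <- sample(genes$symbol, config$n_dd_genes)
  n_dom <- round(config$fraction_dominant * config$n_dd_genes)
  req <- c(rep("monoallelic", n_dom),
           rep("biallelic", config$n_dd_genes - n_dom))
  gene_rows <- data.frame(
    symbol = dd_syms, allelic_requirement = req,
    chrom = genes$chrom[match(dd_syms, genes$symbol)],
    stringsAsFactors = FALSE)
  gene_lists <- derive_gene_lists(gene_rows)

  n_planted <- round(config$planted_fraction * config$n_index_snps)
  flagged <- gene_rows$symbol[gene_rows$allelic_requirement %in%
                                c("monoallelic", "both")]
  if (n_planted > 0 && length(flagged) == 0) {
    stop("planted enrichment requested but no dominant-labelled genes",
         call. = FALSE)
  }
  ## effect-origin labels in the observed proportions of a fetal-effect
  ## lead-SNP set (fetal only : fetal+maternal : unclassified ~ 62:35:62)
  class_pool <- c("fetal_only", "fetal_and_maternal_same", "unclassified")
  class_prob <- c(62, 35, 62) / 159
  planted <- NULL
  if (n_planted > 0) {
    gi <- match(sample(flagged, n_planted, replace = TRUE), genes$symbol)
    d <- config$planted_max_distance
    lo <- pmax(genes$start[gi] - d, 1)
    hi <- pmin(genes$end[gi] + d, config$chrom_length)
    pos <- lo + floor(stats::runif(n_planted) * (hi - lo + 1))
    planted <- data.frame(
      rsid = sprintf("idx%04d", seq_len(n_planted)),
      chrom = genes$chrom[gi], pos = as.integer(pos),
      maf = .sim_maf(n_planted, config$maf_shape1, config$maf_shape2),
      classification = sample(class_pool, n_planted, replace = TRUE,
                              prob = class_prob),
      stringsAsFactors = FALSE)
  }
  n_rand <- config$n_index_snps - n_planted
  random <- NULL
  if (n_rand > 0) {
    random <- panel[sample.int(nrow(panel), n_rand), , drop = FALSE]
    random$classification <- sample(class_pool, n_rand, replace = TRUE,
                                    prob = class_prob)
  }
  index <- rbind(planted, random)
  rownames(index) <- NULL

  out <- list(annotation = ann, panel = panel, gene_rows = gene_rows,
              gene_lists = gene_lists, index_snps = index, config = config)
  class(out) <- "sim_inputs"
  out
}

#' @export
print.sim_inputs <- function(x, ...) {
  cat(sprintf("sim_inputs: %d genes, %d panel SNPs, %d index SNPs (%d planted), %d disease genes\n",
              nrow(x$annotation$genes), nrow(x$panel), nrow(x$index_snps),
              round(x$config$planted_fraction * x$config$n_index_snps),
              nrow(x$gene_rows)))
  invisible(x)
}

#' Write a simulated input bundle to disk
#'
#' Writes the four analysis inputs in their interchange dialects:
#' gene annotation as BED4, panel and index SNPs as TSV SNP tables, and
#' the curated gene list as TSV.
#'
#' @param sim A [simulate_inputs()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_inputs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(annotation = file.path(dir, "genes.bed"),
             panel = file.path(dir, "panel.tsv"),
             gene_list = file.path(dir, "gene_list.tsv"),
             index_snps = file.path(dir, "index_snps.tsv"))
  g <- sim$annotation$genes
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chrom, g$start - 1L, g$end,
                     g$symbol), paths["annotation"])
  write_snp_table(sim$panel, paths["panel"])
  utils::write.table(sim$gene_rows, paths["gene_list"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_snp_table(sim$index_snps, paths["index_snps"])
  paths
}

#' Draw negative-control SNPs from the panel
#'
#' Uniform seeded sample without replacement from the reference panel,
#' used as a negative-control index set (no expected proximity
#' enrichment).
#'
#' @param panel Panel SNP data.frame.
#' @param n Number of SNPs to draw (`<=` panel size).
#' @param seed Integer seed.
#' @return SNP data.frame of `n` rows.
#' @export
negative_control_snps <- function(panel, n, seed) {
  if (n > nrow(panel)) stop("n exceeds panel size", call. = FALSE)
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- panel[sample.int(nrow(panel), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
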