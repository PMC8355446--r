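## Input/output: SNP tables, reference panels, gene annotations, curated gene
## lists, and results tables.

.ALLOWED_CHROMS <- c(as.character(1:22), "X")

.CLASSIFICATIONS <- c("fetal_only", "maternal_only", "fetal_and_maternal_same",
                      "fetal_and_maternal_opposite", "unclassified", "none")

#' @keywords internal
.normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  bad <- !(chrom %in% .ALLOWED_CHROMS)
  if (any(bad)) {
    stop("unsupported chromosome label(s): ",
         paste(unique(chrom[bad]), collapse = ", "),
         " (allowed: 1-22, X)", call. = FALSE)
  }
  chrom
}

#' @keywords internal
.normalize_classification <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "none"
  key <- tolower(trimws(x))
  key <- gsub("[^a-z]+", "_", key)
  key <- gsub("^_+|_+$", "", key)
  key[key == ""] <- "none"
  out <- character(length(key))
  out[key %in% c("fetal_only", "fetal")] <- "fetal_only"
  out[key %in% c("maternal_only", "maternal")] <- "maternal_only"
  same <- grepl("fetal", key) & grepl("maternal", key) & !grepl("opposite", key)
  out[same] <- "fetal_and_maternal_same"
  opp <- grepl("fetal", key) & grepl("maternal", key) & grepl("opposite", key)
  out[opp] <- "fetal_and_maternal_opposite"
  out[key == "unclassified"] <- "unclassified"
  out[key == "none"] <- "none"
  canon <- key %in% .CLASSIFICATIONS
  out[canon] <- key[canon]
  if (any(out == "")) {
    stop("unrecognized SNP classification value(s): ",
         paste(unique(x[out == ""]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @keywords internal
.validate_snp_frame <- function(df, context = "SNP table") {
  req <- c("rsid", "chrom", "pos", "maf")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop(context, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$rsid <- as.character(df$rsid)
  if (any(is.na(df$rsid) | df$rsid == "")) {
    stop(context, ": empty rsid", call. = FALSE)
  }
  df$chrom <- .normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos) | df$pos < 1)) {
    stop(context, ": positions must be positive integers", call. = FALSE)
  }
  df$maf <- as.numeric(df$maf)
  if (any(is.na(df$maf) | df$maf <= 0 | df$maf >= 1)) {
    stop(context, ": allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  high <- df$maf > 0.5
  if (any(high)) {
    warning(context, ": ", sum(high),
            " allele frequencies > 0.5 folded to 1 - f", call. = FALSE)
    df$maf[high] <- 1 - df$maf[high]
  }
  if ("classification" %in% names(df)) {
    df$classification <- .normalize_classification(df$classification)
  } else {
    df$classification <- rep("none", nrow(df))
  }
  df[, c("rsid", "chrom", "pos", "maf", "classification")]
}

#' Read a SNP table
#'
#' Reads a tab-separated SNP table with header columns `rsid`, `chrom`,
#' `pos`, `maf` and an optional `classification` column (fetal/maternal
#' effect origin labels as free text; normalized to canonical tokens).
#' Allele frequencies above 0.5 are folded to `1 - f` with a warning, so
#' the stored value is always a minor allele frequency in (0, 0.5].
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `rsid`, `chrom`, `pos`, `maf`,
#'   `classification`.
#' @export
load_snp_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "chrom")))
  .validate_snp_frame(df, context = basename(path))
}

#' Write a SNP table
#'
#' Inverse of [load_snp_table()]; round-trips records exactly in value space.
#'
#' @param snps A SNP data.frame.
#' @param path Output path.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference SNP panel
#'
#' Loads the genome-wide reference SNP panel used to draw matched null
#' SNPs, either as a TSV in the [load_snp_table()] dialect or as a
#' sites-only VCF (`INFO/AF` is folded to a minor allele frequency).
#' SNPs below the panel frequency floor are removed; the default floor of
#' 0.1% mirrors the common imputation-panel convention.
#'
#' @param path Path to the panel file.
#' @param format `"tsv"` or `"vcf_sites"`.
#' @param min_maf Minimum minor allele frequency retained (inclusive).
#' @return A SNP data.frame as for [load_snp_table()].
#' @export
load_reference_panel <- function(path, format = c("tsv", "vcf_sites"),
                                 min_maf = 0.001) {
  format <- match.arg(format)
  stopifnot(is.numeric(min_maf), length(min_maf) == 1,
            min_maf >= 0, min_maf <= 0.5)
  if (format == "tsv") {
    df <- load_snp_table(path)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("reading VCF sites files requires the VariantAnnotation package",
           call. = FALSE)
    }
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    af <- VariantAnnotation::info(vcf)$AF
    if (is.null(af)) stop("VCF has no INFO/AF field", call. = FALSE)
    af <- vapply(as.list(af), function(v) as.numeric(v[1]), numeric(1))
    ids <- names(rr)
    if (is.null(ids)) ids <- paste0(GenomicRanges::seqnames(rr), ":",
                                    GenomicRanges::start(rr))
    df <- data.frame(rsid = ids,
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     maf = af,
                     stringsAsFactors = FALSE)
    df <- .validate_snp_frame(df, context = basename(path))
  }
  keep <- df$maf >= min_maf
  if (any(!keep)) {
    message(sum(!keep), " panel SNPs below MAF floor ", min_maf, " excluded")
  }
  df[keep, , drop = FALSE]
}

## ---- gene annotation ------------------------------------------------------

#' @keywords internal
.precheck_bed <- function(lines) {
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || grepl("^(#|track|browser)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      stop("malformed BED line ", i, ": ", ln, call. = FALSE)
    }
  }
}

#' @keywords internal
.precheck_gtf <- function(lines) {
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || grepl("^#", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 || is.na(suppressWarnings(as.numeric(f[4]))) ||
        is.na(suppressWarnings(as.numeric(f[5])))) {
      stop("malformed GTF line ", i, ": ", ln, call. = FALSE)
    }
  }
}

#' Construct a gene annotation from a data.frame
#'
#' One record per gene symbol; records sharing a symbol are merged to the
#' union span. Internal coordinates are 1-based inclusive.
#'
#' @param genes data.frame with columns `symbol`, `chrom`, `start`, `end`.
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes) {
  stopifnot(all(c("symbol", "chrom", "start", "end") %in% names(genes)))
  if (nrow(genes) == 0) {
    ann <- list(genes = data.frame(symbol = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   stringsAsFactors = FALSE),
                gr = GenomicRanges::GRanges())
    class(ann) <- "gene_annotation"
    return(ann)
  }
  genes$symbol <- as.character(genes$symbol)
  genes$chrom <- .normalize_chrom(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end) || any(genes$start < 1)) {
    stop("gene spans must satisfy 1 <= start <= end", call. = FALSE)
  }
  chrom_by_sym <- tapply(genes$chrom, genes$symbol,
                         function(x) length(unique(x)))
  if (any(chrom_by_sym > 1)) {
    stop("gene symbol(s) on multiple chromosomes: ",
         paste(names(chrom_by_sym)[chrom_by_sym > 1], collapse = ", "),
         call. = FALSE)
  }
  merged <- do.call(rbind, lapply(split(genes, genes$symbol), function(g) {
    data.frame(symbol = g$symbol[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start, merged$symbol), ]
  rownames(merged) <- NULL
  gr <- GenomicRanges::GRanges(merged$chrom,
                               IRanges::IRanges(merged$start, merged$end),
                               symbol = merged$symbol)
  ann <- list(genes = merged, gr = gr)
  class(ann) <- "gene_annotation"
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Load a gene annotation from BED or GTF
#'
#' BED input (0-based half-open; name column = gene symbol) is converted
#' to internal 1-based inclusive coordinates. GTF input uses the
#' `gene_name` attribute (falling back to `gene_id`); all records sharing
#' a symbol are merged to one union span, so the gene model is one span
#' per symbol.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` or `"gtf"`.
#' @param drop_chroms Optional character vector of chromosome labels to
#'   exclude (e.g. `"X"`); non-autosomal records are retained by default.
#' @return A [gene_annotation()] object.
#' @export
load_gene_annotation <- function(path, format = c("bed", "gtf"),
                                 drop_chroms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  content <- lines[!(lines == "" | grepl("^(#|track|browser)", lines))]
  if (length(content) == 0) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(gene_annotation(data.frame(symbol = character(),
                                      chrom = character(),
                                      start = integer(), end = integer())))
  }
  if (format == "bed") {
    .precheck_bed(lines)
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name)) stop("BED file lacks a name column", call. = FALSE)
    df <- data.frame(symbol = gr$name,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  } else {
    .precheck_gtf(lines)
    gr <- rtracklayer::import(path, format = "GTF")
    sym <- as.character(gr$gene_name)
    if (is.null(gr$gene_name)) sym <- rep(NA_character_, length(gr))
    if (!is.null(gr$gene_id)) {
      sym[is.na(sym) | sym == ""] <- as.character(gr$gene_id)[is.na(sym) | sym == ""]
    }
    if (any(is.na(sym) | sym == "")) {
      stop("GTF records without gene_name/gene_id", call. = FALSE)
    }
    df <- data.frame(symbol = sym,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(drop_chroms)) {
    df <- df[!(sub("^chr", "", df$chrom) %in% drop_chroms), , drop = FALSE]
  }
  gene_annotation(df)
}

## ---- curated gene lists ---------------------------------------------------

#' @keywords internal
.normalize_allelic_requirement <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("^_+|_+$", "", key)
  out <- character(length(key))
  out[key %in% c("monoallelic", "monoallelic_autosomal", "dominant")] <- "monoallelic"
  out[key %in% c("biallelic", "biallelic_autosomal", "recessive")] <- "biallelic"
  out[key %in% c("both", "dominant_recessive", "monoallelic_biallelic",
                 "biallelic_monoallelic")] <- "both"
  if (any(out == "")) {
    stop("unrecognized allelic requirement value(s): ",
         paste(unique(x[out == ""]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a curated disease-gene list
#'
#' Reads a minimal TSV export of a clinician-curated gene list with
#' columns `symbol`, `allelic_requirement` and `chrom`. Verbose
#' allelic-requirement vocabulary (e.g. `monoallelic_autosomal`,
#' `dominant/recessive`) is mapped to `monoallelic` / `biallelic` /
#' `both`. A gene appearing with conflicting requirements is merged to
#' `both`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `symbol`, `allelic_requirement`,
#'   `chrom`, one row per gene symbol.
#' @export
load_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "chrom")))
  req <- c("symbol", "allelic_requirement", "chrom")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("gene list: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$symbol <- as.character(df$symbol)
  df$allelic_requirement <- .normalize_allelic_requirement(df$allelic_requirement)
  df$chrom <- .normalize_chrom(df$chrom)
  .merge_gene_rows(df)
}

#' @keywords internal
.merge_gene_rows <- function(df) {
  out <- do.call(rbind, lapply(split(df, df$symbol), function(g) {
    ar <- unique(g$allelic_requirement)
    merged <- if (length(ar) > 1 || ar == "both") "both" else ar
    chrom <- unique(g$chrom)
    if (length(chrom) > 1) {
      stop("gene ", g$symbol[1], " listed on multiple chromosomes",
           call. = FALSE)
    }
    data.frame(symbol = g$symbol[1], allelic_requirement = merged,
               chrom = chrom, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Derive the four analysis gene lists
#'
#' Splits a curated gene list by mode of inheritance into the four sets
#' used in the enrichment analyses: dominant (monoallelic or both),
#' recessive (biallelic or both), recessive excluding dominant, and the
#' full list. Genes on excluded chromosomes (the X chromosome by
#' default, where dominant/recessive classification is ambiguous) are
#' absent from every set.
#'
#' @param rows data.frame as from [load_gene_list()].
#' @param exclude_chroms Chromosome labels to drop (default `"X"`).
#' @return An object of class `gene_list_set`: a list with character
#'   vectors `all`, `dominant`, `recessive`, `recessive_only`.
#' @export
derive_gene_lists <- function(rows, exclude_chroms = "X") {
  if (is.null(rows) || nrow(rows) == 0) {
    out <- list(all = character(), dominant = character(),
                recessive = character(), recessive_only = character())
    class(out) <- "gene_list_set"
    return(out)
  }
  rows <- .merge_gene_rows(rows)
  rows <- rows[!(rows$chrom %in% exclude_chroms), , drop = FALSE]
  dom <- sort(rows$symbol[rows$allelic_requirement %in% c("monoallelic", "both")])
  rec <- sort(rows$symbol[rows$allelic_requirement %in% c("biallelic", "both")])
  rec_only <- setdiff(rec, dom)
  out <- list(all = sort(union(dom, rec)), dominant = dom,
              recessive = rec, recessive_only = rec_only)
  class(out) <- "gene_list_set"
  out
}

#' @export
print.gene_list_set <- function(x, ...) {
  cat(sprintf("gene_list_set: all %d | dominant %d | recessive %d | recessive_only %d\n",
              length(x$all), length(x$dominant), length(x$recessive),
              length(x$recessive_only)))
  invisible(x)
}

#' Filter lead SNPs for analysis
#'
#' Order-preserving filter of the lead-SNP table: drops SNPs whose effect
#' classification is in `drop_classifications` (maternal-only effects by
#' default, which act through the intrauterine environment rather than
#' the fetal genome) and SNPs on dropped chromosomes (X by default).
#'
#' @param snps SNP data.frame.
#' @param drop_classifications Character vector of classification tokens
#'   to drop. For the sensitivity analysis add `"unclassified"`.
#' @param drop_chroms Chromosome labels to drop.
#' @return The filtered SNP data.frame.
#' @export
select_lead_snps <- function(snps, drop_classifications = "maternal_only",
                             drop_chroms = "X") {
  n0 <- nrow(snps)
  by_class <- snps$classification %in% drop_classifications
  by_chrom <- snps$chrom %in% drop_chroms
  if (any(by_class)) {
    message(sum(by_class), " SNPs dropped by classification (",
            paste(drop_classifications, collapse = ", "), ")")
  }
  if (any(by_chrom)) {
    message(sum(by_chrom), " SNPs dropped on chromosome(s) ",
            paste(drop_chroms, collapse = ", "))
  }
  out <- snps[!(by_class | by_chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- results --------------------------------------------------------------

#' Format an empirical p-value
#'
#' Renders an empirical p-value the way the results tables print it:
#' scientific notation with two decimals, and a floor rendering
#' `"<1.00E-4"` (the magnitude of `1/n_lists`, exponent unpadded) when
#' no null value reached the observed statistic.
#'
#' @param p Numeric p-value (from `r / n_lists`).
#' @param n_lists Number of null lists behind the empirical distribution.
#' @return A character scalar.
#' @export
format_empirical_p <- function(p, n_lists) {
  if (p == 0) {
    floor_str <- sprintf("%.2E", 1 / n_lists)
    floor_str <- sub("E([+-])0(\\d)$", "E\\1\\2", floor_str)
    paste0("<", floor_str)
  } else {
    sprintf("%.2E", p)
  }
}

#' @keywords internal
.window_label <- function(w) {
  ifelse(w %% 1000 == 0, paste0(w / 1000, "kb"), paste0(w, "bp"))
}

#' Assemble a wide results table
#'
#' One row per gene list; gene-level count and p-value columns for the
#' nearest-gene mode and each window, followed by the SNP-level columns.
#'
#' @param results A list of `enrichment_result` objects (or an
#'   `enrichment_results` collection) sharing a window specification.
#' @return A data.frame.
#' @export
results_table <- function(results) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  stopifnot(length(results) > 0 || is.list(results))
  if (length(results) == 0) {
    return(data.frame(gene_list = character(), stringsAsFactors = FALSE))
  }
  modes <- unique(vapply(results, function(r) r$mode, character(1)))
  lists <- unique(vapply(results, function(r) r$gene_list_name, character(1)))
  lab <- function(mode) {
    if (mode == "nearest") "nearest" else .window_label(as.numeric(mode))
  }
  rows <- lapply(lists, function(gl) {
    row <- list(gene_list = gl)
    for (lev in c("genes", "snps")) {
      for (m in modes) {
        r <- Filter(function(x) x$gene_list_name == gl && x$mode == m, results)
        stopifnot(length(r) == 1)
        r <- r[[1]]
        ep <- if (lev == "genes") r$p_genes else r$p_snps
        row[[paste0("n_", lev, "_", lab(m))]] <- ep$observed
        row[[paste0("p_", lev, "_", lab(m))]] <- ep$formatted
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the enrichment results table
#'
#' @param results A list of `enrichment_result` objects or a data.frame
#'   from [results_table()].
#' @param path Output path (TSV).
#' @export
write_results_table <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotated SNPs to TSV
#'
#' @param prox An annotated SNP table from [annotate_snps()].
#' @param path Output path.
#' @export
write_annotated_snps <- function(prox, path) {
  windows <- attr(prox, "windows")
  df <- prox[, c("rsid", "chrom", "pos", "maf", "nearest_gene",
                 "nearest_distance")]
  for (w in windows) {
    df[[paste0("n_genes_", .fmt_w(w))]] <- prox[[paste0("n_genes_", .fmt_w(w))]]
    df[[paste0("genes_", .fmt_w(w))]] <-
      vapply(prox[[paste0("genes_", .fmt_w(w))]], paste, character(1),
             collapse = ",")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
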