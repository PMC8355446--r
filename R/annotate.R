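## Proximity annotation: nearest gene, distance, per-window gene sets.
##
## Distance is point-to-interval: 0 if the SNP lies within the gene span,
## otherwise the distance to the closer span boundary. A gene is in a
## window of half-width w if its span overlaps [pos - w, pos + w] (closed
## intervals). Both definitions compose: nearest_distance <= w implies the
## nearest gene is in the w-window.

#' Default gene-window half-widths
#'
#' The four half-widths (in bp) used by the multi-window analyses:
#' 19, 94, 138 and 258 kb, summary statistics of observed distances from
#' birth-weight lead SNPs to placenta eQTL target genes. Supplied as a
#' constant so results do not depend on the quartile convention used by
#' [derive_window_sizes()].
#'
#' @return Ascending numeric vector of window half-widths in bp.
#' @export
default_windows <- function() c(19000, 94000, 138000, 258000)

#' @keywords internal
## Window sizes rendered for column names; avoids scientific notation.
.fmt_w <- function(w) format(w, scientific = FALSE, trim = TRUE)

#' @keywords internal
.validate_windows <- function(windows) {
  windows <- as.numeric(windows)
  if (length(windows) == 0 || any(!is.finite(windows)) ||
      any(windows <= 0) || any(diff(windows) <= 0)) {
    stop("window sizes must be strictly increasing and positive",
         call. = FALSE)
  }
  windows
}

#' Derive window half-widths from a distance vector
#'
#' Computes the lower quartile, median, mean and upper quartile of a
#' vector of SNP-to-gene distances (quartiles by linear interpolation
#' between order statistics, `stats::quantile` type 7), rounds to whole
#' base pairs, and returns the ascending de-duplicated values. This is
#' the objective rule used to pick window sizes from observed distances
#' between lead SNPs and their regulatory target genes.
#'
#' @param distances Numeric vector of distances in bp, all `>= 0`.
#' @return Ascending numeric vector of window half-widths.
#' @export
derive_window_sizes <- function(distances) {
  if (length(distances) == 0) stop("no distances supplied", call. = FALSE)
  distances <- as.numeric(distances)
  if (any(!is.finite(distances) | distances < 0)) {
    stop("distances must be finite and >= 0", call. = FALSE)
  }
  q <- stats::quantile(distances, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  sizes <- sort(unique(round(c(q[1], q[2], mean(distances), q[3]))))
  sizes[sizes > 0]
}

#' @keywords internal
.snp_granges <- function(chrom, pos, ann) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  lv <- union(GenomeInfoDb::seqlevels(gr), GenomeInfoDb::seqlevels(ann$gr))
  GenomeInfoDb::seqlevels(gr) <- lv
  gr
}

#' @keywords internal
.harmonized_gene_gr <- function(ann, gr_snps) {
  gg <- ann$gr
  lv <- union(GenomeInfoDb::seqlevels(gr_snps), GenomeInfoDb::seqlevels(gg))
  GenomeInfoDb::seqlevels(gg) <- lv
  gg
}

#' @keywords internal
## Vectorized nearest-gene scan; returns data.frame(symbol, distance) with
## NA rows for SNPs whose chromosome carries no gene. Containment is
## resolved by interval stabbing (findOverlaps); flank distances by
## findInterval over sorted span boundaries. All genes achieving the
## minimum point distance are considered and the lexicographically
## smallest symbol wins, so annotation is deterministic.
.nearest_genes <- function(chrom, pos, ann) {
  n <- length(pos)
  out <- data.frame(symbol = rep(NA_character_, n),
                    distance = rep(NA_real_, n), stringsAsFactors = FALSE)
  if (nrow(ann$genes) == 0 || n == 0) return(out)

  ## genes containing the SNP position (distance 0)
  gr_s <- .snp_granges(chrom, pos, ann)
  gg <- .harmonized_gene_gr(ann, gr_s)
  ov <- GenomicRanges::findOverlaps(gr_s, gg, ignore.strand = TRUE)
  ov_sym <- rep(NA_character_, n)
  if (length(ov) > 0) {
    osym <- ann$genes$symbol[S4Vectors::subjectHits(ov)]
    oq <- S4Vectors::queryHits(ov)
    o <- order(oq, osym, method = "radix")
    keep <- !duplicated(oq[o])
    ov_sym[oq[o][keep]] <- osym[o][keep]
  }

  for (ch in unique(chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, , drop = FALSE]
    si <- which(chrom == ch)
    if (nrow(g) == 0) next
    p <- pos[si]
    ## left flank: largest gene end strictly below pos
    oe <- order(g$end, g$symbol, method = "radix")
    ends <- g$end[oe]
    ## match() returns the first index of a value; with the secondary
    ## symbol sort that is the smallest symbol sharing the boundary
    li <- findInterval(p - 1, ends)
    d_left <- ifelse(li >= 1, p - ends[pmax(li, 1)], Inf)
    sym_left <- ifelse(li >= 1,
                       g$symbol[oe][match(ends[pmax(li, 1)], ends)],
                       NA_character_)
    ## right flank: smallest gene start strictly above pos
    os <- order(g$start, g$symbol, method = "radix")
    starts <- g$start[os]
    ri <- findInterval(p, starts) + 1
    d_right <- ifelse(ri <= length(starts), starts[pmin(ri, length(starts))] - p,
                      Inf)
    sym_right <- ifelse(ri <= length(starts),
                        g$symbol[os][match(starts[pmin(ri, length(starts))],
                                           starts)],
                        NA_character_)
    dmin <- pmin(d_left, d_right)
    sym <- ifelse(
      d_left < d_right, sym_left,
      ifelse(d_right < d_left, sym_right, pmin(sym_left, sym_right)))
    inside <- !is.na(ov_sym[si])
    out$distance[si] <- ifelse(inside, 0, dmin)
    out$symbol[si] <- ifelse(inside, ov_sym[si], sym)
  }
  out
}

#' Nearest gene to a SNP
#'
#' Returns the gene whose span is closest to the SNP position on the same
#' chromosome (distance 0 if the position lies within the span), with
#' equidistant ties broken by lexicographic gene symbol. Genes on other
#' chromosomes are never considered.
#'
#' @param snp A single-row SNP data.frame, or a list with `chrom` and `pos`.
#' @param ann A [gene_annotation()] object.
#' @return A list with elements `symbol` and `distance`; both `NA` (with
#'   a warning) when no gene is annotated on the SNP's chromosome.
#' @export
nearest_gene <- function(snp, ann) {
  res <- .nearest_genes(as.character(snp$chrom[1]), as.numeric(snp$pos[1]), ann)
  if (is.na(res$symbol[1])) {
    warning("no gene annotated on chromosome ", snp$chrom[1],
            "; SNP excluded from nearest-gene analyses", call. = FALSE)
  }
  list(symbol = res$symbol[1], distance = res$distance[1])
}

#' @keywords internal
## Vectorized window query; returns list of sorted symbol vectors.
.window_genes <- function(chrom, pos, ann, w) {
  n <- length(pos)
  if (nrow(ann$genes) == 0 || n == 0) return(rep(list(character()), n))
  win <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(pmax(pos - w, 1), pos + w))
  lv <- union(GenomeInfoDb::seqlevels(win), GenomeInfoDb::seqlevels(ann$gr))
  GenomeInfoDb::seqlevels(win) <- lv
  gg <- .harmonized_gene_gr(ann, win)
  ov <- GenomicRanges::findOverlaps(win, gg, ignore.strand = TRUE)
  sp <- split(ann$genes$symbol[S4Vectors::subjectHits(ov)],
              factor(S4Vectors::queryHits(ov), levels = seq_len(n)))
  lapply(sp, function(g) sort(unique(g)))
}

#' Genes within a window around a SNP
#'
#' Returns the symbols of genes whose span overlaps the closed interval
#' `[pos - w, pos + w]` on the SNP's chromosome.
#'
#' @param snp A single-row SNP data.frame, or a list with `chrom` and `pos`.
#' @param ann A [gene_annotation()] object.
#' @param w Window half-width in bp (`> 0`).
#' @return Sorted character vector of gene symbols.
#' @export
genes_in_window <- function(snp, ann, w) {
  stopifnot(is.numeric(w), length(w) == 1, w > 0)
  .window_genes(as.character(snp$chrom[1]), as.numeric(snp$pos[1]), ann, w)[[1]]
}

#' Annotate SNPs with nearest gene and per-window gene sets
#'
#' For each SNP, records the nearest gene and its point-to-interval
#' distance, plus the set and count of genes overlapping each window.
#' SNPs on chromosomes without annotated genes get `NA` nearest fields
#' (with a warning) but keep their (empty) window annotations.
#'
#' @param snps SNP data.frame with `rsid`, `chrom`, `pos` (and typically
#'   `maf`, `classification`).
#' @param ann A [gene_annotation()] object.
#' @param windows Ascending vector of window half-widths in bp.
#' @return A data.frame of class `snp_prox` with columns `nearest_gene`,
#'   `nearest_distance`, and per window `w` a count column `n_genes_<w>`
#'   and a list column `genes_<w>`; the window vector is stored in
#'   `attr(, "windows")`.
#' @export
annotate_snps <- function(snps, ann, windows = default_windows()) {
  windows <- .validate_windows(windows)
  prox <- snps
  nn <- .nearest_genes(snps$chrom, snps$pos, ann)
  if (any(is.na(nn$symbol))) {
    warning(sum(is.na(nn$symbol)),
            " SNP(s) on chromosomes without annotated genes; nearest-gene ",
            "fields set to NA", call. = FALSE)
  }
  prox$nearest_gene <- nn$symbol
  prox$nearest_distance <- nn$distance
  for (w in windows) {
    gl <- .window_genes(snps$chrom, snps$pos, ann, w)
    prox[[paste0("genes_", .fmt_w(w))]] <- I(unname(gl))
    prox[[paste0("n_genes_", .fmt_w(w))]] <- lengths(gl)
  }
  attr(prox, "windows") <- windows
  class(prox) <- c("snp_prox", "data.frame")
  prox
}

#' Build a pre-annotated panel index
#'
#' Annotates every reference-panel SNP against the same gene annotation
#' and windows as the index SNPs and stores sorted views for fast
#' matched-candidate queries (MAF range; nearest-distance range; exact
#' per-window gene count). Panel SNPs without a gene on their chromosome
#' are excluded from the nearest-distance pool but retained in the window
#' pools.
#'
#' @param panel Panel SNP data.frame (e.g. from [load_reference_panel()]).
#' @param ann A [gene_annotation()] object.
#' @param windows Window half-widths in bp.
#' @return An object of class `panel_index`.
#' @export
build_panel_index <- function(panel, ann, windows = default_windows()) {
  if (is.null(panel) || nrow(panel) == 0) stop("empty panel", call. = FALSE)
  prox <- annotate_snps(panel, ann, windows)
  n_no_gene <- sum(is.na(prox$nearest_distance))
  if (n_no_gene > 0) {
    message(n_no_gene, " panel SNP(s) lack a gene on their chromosome; ",
            "available for window matching only")
  }
  ord <- order(prox$maf, method = "radix")
  idx <- list(prox = prox, windows = windows,
              ord_maf = ord, maf_sorted = prox$maf[ord])
  class(idx) <- "panel_index"
  idx
}

#' @export
print.panel_index <- function(x, ...) {
  cat("panel_index:", nrow(x$prox), "panel SNPs, windows:",
      paste(.window_label(x$windows), collapse = " "), "\n")
  invisible(x)
}

#' @keywords internal
## Candidate row indices with maf in [lo, hi] via the sorted-MAF view.
.panel_maf_range <- function(panel, lo, hi) {
  i1 <- findInterval(lo, panel$maf_sorted, left.open = TRUE) + 1
  i2 <- findInterval(hi, panel$maf_sorted)
  if (i1 > i2) return(integer())
  panel$ord_maf[i1:i2]
}
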