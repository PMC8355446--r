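## Enrichment statistics, empirical p-values, and the full analysis
## orchestration across gene lists, windows and sensitivity modes.

#' Nearest-gene enrichment statistic
#'
#' Computes the two observed quantities of the nearest-gene analysis:
#' `n_snps`, the number of SNPs whose nearest gene is in the gene list,
#' and `n_genes`, the number of distinct list genes that are the nearest
#' gene of at least one SNP.
#'
#' @param prox Annotated SNPs from [annotate_snps()] (or any data.frame
#'   with a `nearest_gene` column; `NA` entries are ignored).
#' @param genes Character vector of gene symbols.
#' @return A list with integer fields `n_genes` and `n_snps`.
#' @export
stat_nearest <- function(prox, genes) {
  ng <- prox$nearest_gene
  list(n_genes = length(intersect(unique(ng[!is.na(ng)]), genes)),
       n_snps = sum(ng %in% genes))
}

#' Gene-window enrichment statistic
#'
#' Computes the two observed quantities of a window analysis at
#' half-width `w`: `n_snps`, the number of SNPs with at least one list
#' gene in their window, and `n_genes`, the number of distinct list
#' genes falling in the window of at least one SNP.
#'
#' @param prox Annotated SNPs from [annotate_snps()].
#' @param genes Character vector of gene symbols.
#' @param w Window half-width in bp; must be among the annotated windows.
#' @return A list with integer fields `n_genes` and `n_snps`.
#' @export
stat_window <- function(prox, genes, w) {
  col <- paste0("genes_", .fmt_w(w))
  if (is.null(prox[[col]])) {
    stop("SNPs not annotated for window ", w, call. = FALSE)
  }
  gl <- prox[[col]]
  in_set <- vapply(gl, function(g) any(g %in% genes), logical(1))
  list(n_genes = length(intersect(unique(unlist(gl, use.names = FALSE)),
                                  genes)),
       n_snps = sum(in_set))
}

#' Empirical p-value from a null distribution
#'
#' One-sided upper-tail empirical p-value: the proportion of null values
#' at least as large as the observed statistic (`p = r / n`, ties count
#' toward the numerator). When no null value reaches the observed
#' statistic the formatted rendering is the floor `"<1/n_lists"` string
#' (e.g. `"<1.00E-4"` for 10000 lists). The `(r + 1) / (n + 1)`
#' estimator is available via `estimator = "plus_one"`.
#'
#' @param observed Observed integer statistic.
#' @param null_values Integer vector of null statistics.
#' @param estimator `"floor"` (default, `r / n`) or `"plus_one"`.
#' @return An object of class `empirical_p` with fields `observed`,
#'   `null_values`, `p`, `n_lists`, `formatted`.
#' @export
empirical_pvalue <- function(observed, null_values,
                             estimator = c("floor", "plus_one")) {
  estimator <- match.arg(estimator)
  if (length(null_values) == 0) stop("empty null distribution", call. = FALSE)
  n <- length(null_values)
  r <- sum(null_values >= observed)
  p <- if (estimator == "floor") r / n else (r + 1) / (n + 1)
  formatted <- if (estimator == "floor") format_empirical_p(p, n) else
    sprintf("%.2E", p)
  out <- list(observed = observed, null_values = null_values, p = p,
              n_lists = n, formatted = formatted)
  class(out) <- "empirical_p"
  out
}

#' @export
print.empirical_p <- function(x, ...) {
  cat("observed", x$observed, "| empirical p =", x$formatted,
      sprintf("(%d null lists)\n", x$n_lists))
  invisible(x)
}

#' @keywords internal
## Null statistics for every list in a null_sets matrix. The gene-level
## statistic for nulls uses each matched SNP's own annotation, exactly
## parallel to the observed computation.
.null_statistics <- function(panel_prox, nulls, genes, mode, w = NULL) {
  n_lists <- nrow(nulls)
  idx <- as.integer(nulls)
  if (mode == "nearest") {
    ids <- match(panel_prox$nearest_gene, genes)
    m <- matrix(ids[idx], nrow = n_lists)
    n_snps <- as.integer(rowSums(!is.na(m)))
    n_genes <- vapply(seq_len(n_lists), function(i) {
      v <- m[i, ]
      length(unique(v[!is.na(v)]))
    }, integer(1))
  } else {
    col <- paste0("genes_", .fmt_w(w))
    in_ids <- lapply(panel_prox[[col]], function(g) match(g[g %in% genes], genes))
    has <- lengths(in_ids) > 0
    n_snps <- as.integer(rowSums(matrix(has[idx], nrow = n_lists)))
    n_genes <- vapply(seq_len(n_lists), function(i) {
      length(unique(unlist(in_ids[nulls[i, ]], use.names = FALSE)))
    }, integer(1))
  }
  list(n_genes = n_genes, n_snps = n_snps)
}

#' @keywords internal
.as_gene_lists <- function(gene_lists) {
  if (inherits(gene_lists, "gene_list_set")) {
    return(list(all = gene_lists$all, dominant = gene_lists$dominant,
                recessive = gene_lists$recessive,
                recessive_only = gene_lists$recessive_only))
  }
  if (is.character(gene_lists)) return(list(genes = gene_lists))
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  gene_lists
}

#' Run the full proximity-enrichment analysis
#'
#' For each gene list and each analysis mode (nearest gene, then each
#' window), annotates the index SNPs, builds MAF- and proximity-matched
#' candidate pools from the reference panel, samples `n_lists` seeded
#' null SNP lists, computes the observed and null statistics, and
#' returns both empirical p-values. Identical inputs and seed yield
#' identical output.
#'
#' @param snps Lead SNP data.frame (already filtered, e.g. by
#'   [select_lead_snps()]).
#' @param annotation A [gene_annotation()] object.
#' @param gene_lists A [derive_gene_lists()] set, or a named list of
#'   symbol vectors.
#' @param panel Panel data.frame or a prebuilt [build_panel_index()].
#' @param windows Window half-widths in bp.
#' @param modes Analysis modes to run: `"nearest"` and/or window sizes
#'   (as numbers or numeric strings). Defaults to nearest plus every
#'   window.
#' @param n_lists Number of null lists (default 10000).
#' @param seed Integer seed for null sampling.
#' @param p_estimator `"floor"` or `"plus_one"` (see
#'   [empirical_pvalue()]).
#' @param maf_lower_factor,maf_upper_factor,distance_tolerance,exclude_self,relax_steps
#'   Matching criteria overrides, see [match_criteria()].
#' @return An object of class `enrichment_results`: a list of
#'   `enrichment_result` objects (one per gene list x mode) with a
#'   metadata attribute.
#' @export
run_enrichment <- function(snps, annotation, gene_lists, panel,
                           windows = default_windows(),
                           modes = NULL, n_lists = 10000, seed = 1,
                           p_estimator = c("floor", "plus_one"),
                           maf_lower_factor = 0.9, maf_upper_factor = 1.1,
                           distance_tolerance = 0.1, exclude_self = TRUE,
                           relax_steps = 0) {
  p_estimator <- match.arg(p_estimator)
  windows <- .validate_windows(windows)
  if (is.null(modes)) modes <- c("nearest", .fmt_w(windows))
  modes <- vapply(as.list(modes), function(m) {
    if (identical(as.character(m), "nearest")) "nearest" else .fmt_w(as.numeric(m))
  }, character(1))
  gls <- .as_gene_lists(gene_lists)
  if (nrow(snps) == 0) stop("no index SNPs supplied", call. = FALSE)
  if (!inherits(panel, "panel_index")) {
    panel <- build_panel_index(panel, annotation, windows)
  }
  index_prox <- annotate_snps(snps, annotation, windows)
  results <- list()
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    if (mode == "nearest") {
      keep <- !is.na(index_prox$nearest_distance)
      prox_m <- index_prox[keep, , drop = FALSE]
      if (nrow(prox_m) == 0) stop("no index SNPs usable in nearest mode",
                                  call. = FALSE)
      crit <- match_criteria("nearest",
                             maf_lower_factor = maf_lower_factor,
                             maf_upper_factor = maf_upper_factor,
                             distance_tolerance = distance_tolerance,
                             n_lists = n_lists, exclude_self = exclude_self,
                             relax_steps = relax_steps)
      w <- NULL
    } else {
      w <- as.numeric(mode)
      prox_m <- index_prox
      crit <- match_criteria("window", window = w,
                             maf_lower_factor = maf_lower_factor,
                             maf_upper_factor = maf_upper_factor,
                             n_lists = n_lists, exclude_self = exclude_self,
                             relax_steps = relax_steps)
    }
    pools <- candidate_pools(prox_m, panel, crit)
    nulls <- sample_null_sets(pools, n_lists, .column_seed(seed, 7919 * mi))
    for (gl_name in names(gls)) {
      genes <- gls[[gl_name]]
      obs <- if (mode == "nearest") stat_nearest(prox_m, genes) else
        stat_window(prox_m, genes, w)
      nstat <- .null_statistics(panel$prox, nulls, genes,
                                mode = if (mode == "nearest") "nearest" else "window",
                                w = w)
      res <- list(gene_list_name = gl_name, mode = mode, observed = obs,
                  p_genes = empirical_pvalue(obs$n_genes, nstat$n_genes,
                                             p_estimator),
                  p_snps = empirical_pvalue(obs$n_snps, nstat$n_snps,
                                            p_estimator),
                  n_index_snps = nrow(prox_m))
      class(res) <- "enrichment_result"
      results[[length(results) + 1]] <- res
    }
  }
  attr(results, "meta") <- list(seed = as.integer(seed),
                                n_lists = as.integer(n_lists),
                                windows = windows, modes = modes,
                                p_estimator = p_estimator,
                                maf_lower_factor = maf_lower_factor,
                                maf_upper_factor = maf_upper_factor,
                                distance_tolerance = distance_tolerance)
  class(results) <- "enrichment_results"
  results
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("[%s | %s] n_genes = %d (p %s), n_snps = %d (p %s)\n",
              x$gene_list_name,
              if (x$mode == "nearest") "nearest" else
                .window_label(as.numeric(x$mode)),
              x$observed$n_genes, x$p_genes$formatted,
              x$observed$n_snps, x$p_snps$formatted))
  invisible(x)
}

#' @export
print.enrichment_results <- function(x, ...) {
  meta <- attr(x, "meta")
  cat("enrichment_results:", length(x), "gene list x mode combinations,",
      meta$n_lists, "null lists, seed", meta$seed, "\n")
  for (r in x) print(r)
  invisible(x)
}

#' Sensitivity analysis excluding unclassified SNPs
#'
#' Repeats [run_enrichment()] after additionally removing SNPs with an
#' `unclassified` effect origin (a category that may hide
#' maternal-effect loci).
#'
#' @inheritParams run_enrichment
#' @param ... Passed on to [run_enrichment()].
#' @return An `enrichment_results` object.
#' @export
run_sensitivity <- function(snps, annotation, gene_lists, panel, ...) {
  snps <- snps[snps$classification != "unclassified", , drop = FALSE]
  if (nrow(snps) == 0) {
    stop("no SNPs remain after excluding unclassified", call. = FALSE)
  }
  run_enrichment(snps, annotation, gene_lists, panel, ...)
}
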