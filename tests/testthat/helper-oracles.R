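# Brute-force oracles (naive linear scans) and tiny random fixture
# generators, kept independent of the interval-query implementation.

bf_nearest <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(symbol = NA_character_, distance = NA_real_))
  d <- pmax(g$start - pos, pos - g$end, 0)
  o <- order(d, g$symbol)
  list(symbol = g$symbol[o[1]], distance = d[o[1]])
}

bf_window <- function(chrom, pos, genes, w) {
  g <- genes[genes$chrom == chrom & genes$start <= pos + w &
               genes$end >= pos - w, , drop = FALSE]
  sort(g$symbol)
}

# naive candidate pool: flat filter over the annotated panel data.frame
bf_pool <- function(index_row, panel_prox, crit) {
  maf <- index_row$maf
  ok <- panel_prox$maf >= maf * crit$maf_lower_factor - 1e-9 * maf &
    panel_prox$maf <= maf * crit$maf_upper_factor + 1e-9 * maf
  if (crit$mode == "nearest") {
    d <- index_row$nearest_distance
    pd <- panel_prox$nearest_distance
    ok <- ok & !is.na(pd) &
      pd >= d * (1 - crit$distance_tolerance) - 1e-9 * max(d, 1) &
      pd <= d * (1 + crit$distance_tolerance) + 1e-9 * max(d, 1)
  } else {
    col <- paste0("n_genes_", format(crit$window, scientific = FALSE))
    ok <- ok & panel_prox[[col]] == index_row[[col]]
  }
  if (crit$exclude_self) {
    ok <- ok & !(panel_prox$chrom == index_row$chrom &
                   panel_prox$pos == index_row$pos)
  }
  which(ok)
}

# naive double-loop statistics
bf_stat_nearest <- function(prox, genes) {
  hit_genes <- character()
  n_snps <- 0L
  for (i in seq_len(nrow(prox))) {
    ng <- prox$nearest_gene[i]
    if (!is.na(ng) && ng %in% genes) {
      n_snps <- n_snps + 1L
      hit_genes <- union(hit_genes, ng)
    }
  }
  list(n_genes = length(hit_genes), n_snps = n_snps)
}

bf_stat_window <- function(prox, genes, w) {
  col <- paste0("genes_", format(w, scientific = FALSE))
  hit_genes <- character()
  n_snps <- 0L
  for (i in seq_len(nrow(prox))) {
    gl <- intersect(prox[[col]][[i]], genes)
    if (length(gl) > 0) n_snps <- n_snps + 1L
    hit_genes <- union(hit_genes, gl)
  }
  list(n_genes = length(hit_genes), n_snps = n_snps)
}

# random small fixtures ------------------------------------------------------

random_genes <- function(n, n_chroms = 2, L = 100000) {
  data.frame(
    symbol = sprintf("T%03d", seq_len(n)),
    chrom = as.character(sample.int(n_chroms, n, replace = TRUE)),
    start = s <- sample.int(L - 200, n, replace = TRUE),
    end = s + sample.int(200, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
}

random_positions <- function(n, n_chroms = 2, L = 100000) {
  data.frame(
    rsid = sprintf("r%03d", seq_len(n)),
    chrom = as.character(sample.int(n_chroms, n, replace = TRUE)),
    pos = sample.int(L, n, replace = TRUE),
    maf = round(runif(n, 0.01, 0.5), 3),
    classification = "none",
    stringsAsFactors = FALSE)
}

small_sim <- function(seed, ...) {
  simulate_inputs(sim_config(n_chroms = 2, chrom_length = 2e6,
                             n_genes = 60, gene_length_min = 2000,
                             gene_length_max = 20000, n_panel_snps = 1500,
                             n_index_snps = 15, n_dd_genes = 20,
                             seed = seed, ...))
}
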