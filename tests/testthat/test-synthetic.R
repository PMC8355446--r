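test_that("simulation is a pure function of its seed", {
  s1 <- small_sim(5)
  s2 <- small_sim(5)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$annotation$genes, s2$annotation$genes)
  expect_identical(s1$index_snps, s2$index_snps)
  expect_identical(s1$gene_rows, s2$gene_rows)
  s3 <- small_sim(6)
  expect_false(identical(s1$panel, s3$panel))
})

test_that("simulated genes never overlap and respect length bounds", {
  sim <- small_sim(8)
  g <- sim$annotation$genes
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    gc <- gc[order(gc$start), ]
    expect_true(all(diff(gc$start) > (gc$end[-nrow(gc)] - gc$start[-nrow(gc)])))
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
  expect_true(all(g$end - g$start + 1 >= 2000 & g$end - g$start + 1 <= 20000))
  expect_error(
    simulate_inputs(sim_config(n_chroms = 1, chrom_length = 1e4,
                               n_genes = 10, gene_length_min = 5000,
                               gene_length_max = 5000, n_dd_genes = 5)),
    "infeasible packing")
})

test_that("unplanted index SNPs are a panel subset; planted SNPs sit near flagged genes", {
  null_sim <- small_sim(9, planted_fraction = 0)
  expect_true(all(null_sim$index_snps$rsid %in% null_sim$panel$rsid))

  planted <- small_sim(10, planted_fraction = 1, planted_max_distance = 1000)
  flagged <- planted$gene_lists$dominant
  g <- planted$annotation$genes[planted$annotation$genes$symbol %in% flagged, ]
  for (i in seq_len(nrow(planted$index_snps))) {
    d <- bf_nearest(planted$index_snps$chrom[i], planted$index_snps$pos[i], g)
    expect_lte(d$distance, 1000)
  }
})

test_that("simulated inputs survive an on-disk round trip", {
  sim <- small_sim(11)
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, dir)
  ann <- load_gene_annotation(paths["annotation"], "bed")
  reord <- function(df) {
    df <- df[order(df$symbol), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(reord(ann$genes), reord(sim$annotation$genes))
  suppressMessages(panel <- load_reference_panel(paths["panel"], "tsv"))
  expect_equal(panel, sim$panel)
  rows <- load_gene_list(paths["gene_list"])
  expect_setequal(rows$symbol, sim$gene_rows$symbol)
  expect_identical(derive_gene_lists(rows), sim$gene_lists)
  idx <- load_snp_table(paths["index_snps"])
  expect_equal(idx, sim$index_snps)
})

test_that("negative-control draws are seeded uniform samples without replacement", {
  sim <- small_sim(12)
  nc1 <- negative_control_snps(sim$panel, 30, seed = 4)
  nc2 <- negative_control_snps(sim$panel, 30, seed = 4)
  expect_identical(nc1, nc2)
  expect_equal(anyDuplicated(nc1$rsid), 0)
  whole <- negative_control_snps(sim$panel, nrow(sim$panel), seed = 4)
  expect_setequal(whole$rsid, sim$panel$rsid)
  expect_error(negative_control_snps(sim$panel, nrow(sim$panel) + 1, 1),
               "exceeds")
  # approximate uniformity of inclusion over repeated draws
  counts <- integer(nrow(sim$panel))
  for (s in 1:200) {
    nc <- negative_control_snps(sim$panel, 150, seed = s)
    counts[match(nc$rsid, sim$panel$rsid)] <-
      counts[match(nc$rsid, sim$panel$rsid)] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("the worked-example fixture is transcribed faithfully", {
  fx <- table9_fixture()
  expect_equal(nrow(fx$table), 36)
  expect_equal(nrow(fx$prox), 37)
  expect_length(fx$dominant_genes, 36)
  # one gene is tagged by two rsids in every analysis
  igf1r <- fx$table[fx$table$gene == "IGF1R", ]
  expect_equal(length(strsplit(igf1r$rsids, ";")[[1]]), 2)
  expect_equal(unname(unlist(igf1r[, c("nearest", "w19kb", "w94kb",
                                       "w138kb", "w258kb")])),
               rep(2L, 5))
  # one gene is flagged for nearest and the largest window only
  mafb <- fx$table[fx$table$gene == "MAFB", ]
  expect_equal(unname(unlist(mafb[, c("nearest", "w19kb", "w94kb",
                                      "w138kb", "w258kb")])),
               c(1L, 0L, 0L, 0L, 1L))
  # membership encoding is consistent with the flags
  expect_true(all(vapply(seq_len(nrow(fx$prox)), function(i) {
    all(fx$prox$genes_19000[[i]] %in% fx$prox$genes_258000[[i]])
  }, logical(1))))
})
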