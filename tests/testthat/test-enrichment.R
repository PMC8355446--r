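test_that("empirical p-values count upper-tail ties and render floors", {
  ep <- empirical_pvalue(3, c(1L, 2L, 3L, 4L))
  expect_equal(ep$p, 0.5)
  expect_equal(empirical_pvalue(10, rep(0L, 10000))$formatted, "<1.00E-4")
  expect_equal(empirical_pvalue(0, c(1L, 2L))$p, 1)
  expect_equal(empirical_pvalue(2, rep(2L, 100))$formatted, "1.00E+00")
  expect_equal(empirical_pvalue(3, c(1L, 2L, 3L, 4L), "plus_one")$p, 3 / 5)
  expect_error(empirical_pvalue(1, integer()), "empty")
})

test_that("statistics agree with a brute-force double loop", {
  set.seed(21)
  for (i in 1:150) {
    ann <- gene_annotation(random_genes(12))
    snps <- random_positions(8)
    w <- 5000
    prox <- suppressWarnings(annotate_snps(snps, ann, windows = w))
    genes <- sample(ann$genes$symbol, sample(1:8, 1))
    expect_identical(stat_nearest(prox, genes), bf_stat_nearest(prox, genes))
    expect_identical(stat_window(prox, genes, w), bf_stat_window(prox, genes, w))
  }
  # empty gene set
  ann <- gene_annotation(random_genes(5))
  prox <- suppressWarnings(annotate_snps(random_positions(3), ann, 5000))
  expect_equal(stat_nearest(prox, character()), list(n_genes = 0L, n_snps = 0L))
  expect_error(stat_window(prox, "X", 999), "not annotated")
})

test_that("both statistics are monotone non-decreasing in window size", {
  set.seed(31)
  for (i in 1:30) {
    ann <- gene_annotation(random_genes(15))
    snps <- random_positions(6)
    ws <- c(200, 2000, 20000)
    prox <- suppressWarnings(annotate_snps(snps, ann, windows = ws))
    genes <- sample(ann$genes$symbol, 6)
    stats <- lapply(ws, function(w) stat_window(prox, genes, w))
    for (k in 2:3) {
      expect_gte(stats[[k]]$n_genes, stats[[k - 1]]$n_genes)
      expect_gte(stats[[k]]$n_snps, stats[[k - 1]]$n_snps)
    }
  }
})

test_that("the full analysis is reproducible and respects the seed", {
  sim <- small_sim(61)
  run <- function(seed) suppressWarnings(suppressMessages(
    run_enrichment(sim$index_snps, sim$annotation, sim$gene_lists,
                   sim$panel, windows = c(5000, 20000), n_lists = 100,
                   seed = seed, relax_steps = 3)))
  r1 <- run(7)
  r2 <- run(7)
  expect_identical(results_table(r1), results_table(r2))
  r3 <- run(8)
  expect_false(identical(
    vapply(r1, function(x) x$p_genes$p, numeric(1)),
    vapply(r3, function(x) x$p_genes$p, numeric(1))))
  # one result per gene list x mode
  expect_length(r1, 4 * 3)
})

test_that("a single-list null gives degenerate p in {0, 1}", {
  sim <- small_sim(62)
  res <- suppressWarnings(suppressMessages(
    run_enrichment(sim$index_snps, sim$annotation,
                   list(dd = sim$gene_lists$all), sim$panel,
                   windows = 20000, modes = 20000, n_lists = 1,
                   seed = 3, relax_steps = 3)))
  expect_true(all(vapply(res, function(r) r$p_genes$p %in% c(0, 1),
                         logical(1))))
})

test_that("sensitivity mode equals the main analysis when all are classified", {
  sim <- small_sim(63)
  snps <- sim$index_snps
  snps$classification <- "fetal_only"
  args <- list(snps, sim$annotation, list(dd = sim$gene_lists$dominant),
               sim$panel, windows = 20000, modes = 20000, n_lists = 50,
               seed = 5, relax_steps = 3)
  main <- suppressWarnings(suppressMessages(do.call(run_enrichment, args)))
  sens <- suppressWarnings(suppressMessages(do.call(run_sensitivity, args)))
  expect_identical(results_table(main), results_table(sens))
  snps$classification <- "unclassified"
  expect_error(run_sensitivity(snps, sim$annotation, sim$gene_lists,
                               sim$panel),
               "no SNPs remain")
})
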