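test_that("nearest gene follows point-to-interval distance with symbol ties", {
  ann <- gene_annotation(data.frame(
    symbol = c("A", "B"), chrom = "1",
    start = c(1000, 2500), end = c(2000, 3000)))
  expect_equal(nearest_gene(list(chrom = "1", pos = 150 + 1000), ann),
               list(symbol = "A", distance = 0))
  # 2200 is 200 bp past A's end and 300 bp before B's start
  expect_equal(nearest_gene(list(chrom = "1", pos = 2200), ann),
               list(symbol = "A", distance = 200))
  # equidistant -> lexicographically smaller symbol
  tie <- gene_annotation(data.frame(symbol = c("B", "A"), chrom = "1",
                                    start = c(400, 100), end = c(500, 200)))
  expect_equal(nearest_gene(list(chrom = "1", pos = 300), tie),
               list(symbol = "A", distance = 100))
  # no gene on chromosome
  expect_warning(res <- nearest_gene(list(chrom = "2", pos = 10), ann),
                 "no gene")
  expect_true(is.na(res$symbol))
})

test_that("window membership uses closed-interval span overlap", {
  ann <- gene_annotation(data.frame(symbol = "A", chrom = "1",
                                    start = 100, end = 200))
  expect_equal(genes_in_window(list(chrom = "1", pos = 300), ann, 100), "A")
  expect_length(genes_in_window(list(chrom = "1", pos = 301), ann, 100), 0)
})

test_that("interval queries agree with a linear scan on random fixtures", {
  set.seed(101)
  for (i in 1:300) {
    genes <- random_genes(sample(3:15, 1))
    ann <- gene_annotation(genes)
    snps <- random_positions(sample(2:6, 1))
    w <- sample(c(50, 500, 5000, 50000), 1)
    prox <- suppressWarnings(annotate_snps(snps, ann, windows = w))
    merged <- ann$genes
    for (j in seq_len(nrow(snps))) {
      exp_n <- bf_nearest(snps$chrom[j], snps$pos[j], merged)
      expect_identical(prox$nearest_gene[j], exp_n$symbol)
      expect_identical(prox$nearest_distance[j], as.numeric(exp_n$distance))
      expect_identical(prox[[paste0("genes_", w)]][[j]],
                       bf_window(snps$chrom[j], snps$pos[j], merged, w))
    }
  }
})

test_that("window gene sets are monotone and consistent with nearest", {
  set.seed(77)
  for (i in 1:40) {
    ann <- gene_annotation(random_genes(10))
    snps <- random_positions(5)
    ws <- c(100, 1000, 10000, 60000)
    prox <- suppressWarnings(annotate_snps(snps, ann, windows = ws))
    for (j in seq_len(nrow(snps))) {
      sets <- lapply(ws, function(w) prox[[paste0("genes_", w)]][[j]])
      for (k in 2:length(ws)) {
        expect_true(all(sets[[k - 1]] %in% sets[[k]]))
      }
      for (k in seq_along(ws)) {
        expect_equal(prox[[paste0("n_genes_", ws[k])]][j],
                     length(sets[[k]]))
        d <- prox$nearest_distance[j]
        if (!is.na(d) && d <= ws[k]) {
          expect_true(prox$nearest_gene[j] %in% sets[[k]])
        }
      }
    }
  }
})

test_that("window-size derivation applies the documented quartile rule", {
  expect_equal(derive_window_sizes(rep(5000, 8)), 5000)
  # LQ 17.5, median 25, mean 25, UQ 32.5; rounded and de-duplicated
  expect_equal(derive_window_sizes(c(10, 20, 30, 40)), c(18, 25, 32))
  expect_error(derive_window_sizes(numeric()), "no distances")
  expect_equal(default_windows(), c(19000, 94000, 138000, 258000))
})

test_that("panel index annotates every SNP and is deterministic", {
  set.seed(12)
  panel <- random_positions(200)
  ann <- gene_annotation(random_genes(12))
  i1 <- suppressWarnings(suppressMessages(
    build_panel_index(panel, ann, windows = c(1000, 10000))))
  i2 <- suppressWarnings(suppressMessages(
    build_panel_index(panel, ann, windows = c(1000, 10000))))
  expect_identical(i1$prox, i2$prox)
  expect_equal(nrow(i1$prox), nrow(panel))
  expect_error(build_panel_index(panel[0, ], ann), "empty panel")
})
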