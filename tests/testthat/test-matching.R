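# A controlled five-SNP panel on a one-gene annotation, with hand-set
# MAFs and positions giving known nearest distances.
toy_panel_index <- function(windows = 1000) {
  ann <- gene_annotation(data.frame(symbol = "G1", chrom = "1",
                                    start = 10000, end = 20000))
  panel <- data.frame(
    rsid = c("p1", "p2", "p3", "p4", "p5"),
    chrom = "1",
    pos = c(15000, 20900, 21100, 22500, 9500),   # d = 0, 900, 1100, 2500, 500
    maf = c(0.20, 0.18, 0.22, 0.20, 0.30),
    classification = "none", stringsAsFactors = FALSE)
  list(ann = ann,
       panel = build_panel_index(panel, ann, windows = windows))
}

test_that("MAF bounds are closed multiplicative intervals", {
  tp <- toy_panel_index()
  index <- data.frame(rsid = "i1", chrom = "2", pos = 1, maf = 0.20,
                      nearest_distance = 1000, stringsAsFactors = FALSE)
  crit <- match_criteria("nearest")
  # distance band [900, 1100] + maf band [0.18, 0.22] (both boundaries in)
  pool <- candidate_pool(index, tp$panel, crit)
  expect_setequal(tp$panel$prox$rsid[pool$candidates], c("p2", "p3"))
})

test_that("zero index distance admits only intragenic panel SNPs", {
  tp <- toy_panel_index()
  index <- data.frame(rsid = "i1", chrom = "2", pos = 1, maf = 0.20,
                      nearest_distance = 0, stringsAsFactors = FALSE)
  pool <- candidate_pool(index, tp$panel, match_criteria("nearest"))
  expect_equal(tp$panel$prox$rsid[pool$candidates], "p1")
})

test_that("window mode requires exact gene-count equality", {
  tp <- toy_panel_index(windows = 1000)
  # p1 (inside G1) and p2 (900 bp away) have one gene in the 1 kb window
  index <- data.frame(rsid = "i1", chrom = "2", pos = 1, maf = 0.20,
                      n_genes_1000 = 1L, stringsAsFactors = FALSE)
  pool <- candidate_pool(index, tp$panel,
                         match_criteria("window", window = 1000))
  expect_setequal(tp$panel$prox$rsid[pool$candidates], c("p1", "p2"))
})

test_that("pools match a flat-filter enumeration on random fixtures", {
  set.seed(303)
  for (i in 1:60) {
    ann <- gene_annotation(random_genes(8))
    panel <- random_positions(120)
    w <- 2000
    pidx <- suppressWarnings(suppressMessages(
      build_panel_index(panel, ann, windows = w)))
    mode <- sample(c("nearest", "window"), 1)
    crit <- match_criteria(mode, window = if (mode == "window") w)
    usable <- which(!is.na(pidx$prox$nearest_distance))
    row <- pidx$prox[sample(usable, 1), , drop = FALSE]
    expected <- bf_pool(row, pidx$prox, crit)
    got <- tryCatch(candidate_pool(row, pidx, crit)$candidates,
                    proxenrich_matching_failure = function(e) integer())
    expect_setequal(got, expected)
  }
})

test_that("empty pools raise a matching failure naming the constraint", {
  tp <- toy_panel_index()
  index <- data.frame(rsid = "lonely", chrom = "2", pos = 1, maf = 0.05,
                      nearest_distance = 1000, stringsAsFactors = FALSE)
  err <- tryCatch(candidate_pool(index, tp$panel, match_criteria("nearest")),
                  proxenrich_matching_failure = function(e) e)
  expect_s3_class(err, "proxenrich_matching_failure")
  expect_match(conditionMessage(err), "lonely")
  expect_match(conditionMessage(err), "MAF")
  # stepped relaxation widens the MAF factors loudly
  # maf 0.25: band [0.225, 0.275] is empty; one relax step reaches p3
  index2 <- data.frame(rsid = "i2", chrom = "2", pos = 1, maf = 0.25,
                       nearest_distance = 1000, stringsAsFactors = FALSE)
  expect_error(candidate_pool(index2, tp$panel, match_criteria("nearest")),
               class = "proxenrich_matching_failure")
  expect_warning(
    pool <- candidate_pool(index2, tp$panel,
                           match_criteria("nearest", relax_steps = 2)),
    "RELAXED")
  expect_gt(length(pool$candidates), 0)
})

test_that("self-exclusion removes the index SNP's position from its pool", {
  tp <- toy_panel_index()
  index <- tp$panel$prox[2, , drop = FALSE]   # p2: maf 0.18, d = 900
  crit <- match_criteria("nearest", maf_lower_factor = 0.5,
                         maf_upper_factor = 2, distance_tolerance = 0.9)
  pool <- candidate_pool(index, tp$panel, crit)
  expect_false(2 %in% pool$candidates)
  crit_keep <- match_criteria("nearest", maf_lower_factor = 0.5,
                              maf_upper_factor = 2, distance_tolerance = 0.9,
                              exclude_self = FALSE)
  expect_true(2 %in% candidate_pool(index, tp$panel, crit_keep)$candidates)
})

test_that("null sampling is seeded, deterministic and uniform per pool", {
  tp <- toy_panel_index()
  index <- data.frame(rsid = "i1", chrom = "2", pos = 1, maf = 0.20,
                      nearest_distance = 1300, stringsAsFactors = FALSE)
  # wide bands: distance in [65, 2535], maf in [0.1, 0.4] -> p2..p5
  crit <- match_criteria("nearest", maf_lower_factor = 0.5,
                         maf_upper_factor = 2, distance_tolerance = 0.95)
  pool <- candidate_pool(index, tp$panel, crit)
  expect_length(pool$candidates, 4)
  n1 <- sample_null_sets(list(pool), 10000, seed = 42)
  n2 <- sample_null_sets(list(pool), 10000, seed = 42)
  expect_identical(unclass(n1), unclass(n2))
  expect_false(identical(unclass(n1),
                         unclass(sample_null_sets(list(pool), 10000, 43))))
  # per-candidate selection frequencies within 4 SE of 1/4
  freq <- tabulate(match(n1[, 1], pool$candidates), 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 4 * se))
  # degenerate single-candidate pools give constant lists
  p1 <- candidate_pool(data.frame(rsid = "i2", chrom = "2", pos = 1,
                                  maf = 0.20, nearest_distance = 0,
                                  stringsAsFactors = FALSE),
                       tp$panel, match_criteria("nearest"))
  expect_equal(unique(as.integer(sample_null_sets(list(p1), 50, 1))),
               p1$candidates)
  expect_error(sample_null_sets(list(pool), 0, 1), "positive")
})

test_that("null-set validation detects planted corruption", {
  tp <- toy_panel_index()
  index <- data.frame(rsid = "i1", chrom = "2", pos = 1, maf = 0.20,
                      nearest_distance = 1000, stringsAsFactors = FALSE)
  pool <- candidate_pool(index, tp$panel, match_criteria("nearest"))
  nulls <- sample_null_sets(list(pool), 200, 9)
  expect_equal(validate_null_sets(nulls, list(pool), tp$panel)$n_violations, 0)
  nulls[5, 1] <- 5L   # p5: maf 0.30 and d = 500, off-criteria
  rep <- validate_null_sets(nulls, list(pool), tp$panel)
  expect_equal(rep$n_violations, 1)
  expect_equal(rep$details$panel_rsid, "p5")
})
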