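## Matched null SNP construction: per-index candidate pools and seeded
## sampling of null lists forming the empirical distribution.

## Closed matching intervals are evaluated with a tiny relative tolerance so
## decimal boundaries (0.9 * 0.20 = 0.18) behave as written.
.MATCH_EPS <- 1e-9

#' Matching criteria for null SNP selection
#'
#' Defines how reference-panel SNPs are matched to an index SNP:
#' minor allele frequency within `[maf_lower_factor, maf_upper_factor]`
#' times the index MAF (0.9-1.1 by default), and either nearest-gene
#' distance within `±distance_tolerance` (±10% by default) of the index
#' distance (`mode = "nearest"`) or exactly the same number of genes in
#' the given window (`mode = "window"`). All intervals are closed.
#'
#' @param mode `"nearest"` or `"window"`.
#' @param window Window half-width in bp; required when `mode = "window"`.
#' @param maf_lower_factor,maf_upper_factor Multiplicative MAF bounds.
#' @param distance_tolerance Fractional tolerance on nearest-gene distance.
#' @param n_lists Number of null lists to draw (default 10000).
#' @param exclude_self Drop any panel SNP at the index SNP's position.
#' @param relax_steps Number of optional relaxation steps widening the MAF
#'   factors by ±0.05 each when a pool comes up empty (0 = hard error).
#' @return An object of class `match_criteria`.
#' @export
match_criteria <- function(mode = c("nearest", "window"), window = NULL,
                           maf_lower_factor = 0.9, maf_upper_factor = 1.1,
                           distance_tolerance = 0.1, n_lists = 10000,
                           exclude_self = TRUE, relax_steps = 0) {
  mode <- match.arg(mode)
  stopifnot(maf_lower_factor > 0, maf_lower_factor <= 1,
            maf_upper_factor >= 1,
            distance_tolerance >= 0, distance_tolerance < 1,
            n_lists >= 1, relax_steps >= 0)
  if (mode == "window") {
    if (is.null(window)) stop("window mode requires a window size",
                              call. = FALSE)
    stopifnot(is.numeric(window), length(window) == 1, window > 0)
  }
  out <- list(mode = mode, window = window,
              maf_lower_factor = maf_lower_factor,
              maf_upper_factor = maf_upper_factor,
              distance_tolerance = distance_tolerance,
              n_lists = as.integer(n_lists),
              exclude_self = isTRUE(exclude_self),
              relax_steps = as.integer(relax_steps))
  class(out) <- "match_criteria"
  out
}

#' @keywords internal
.matching_failure <- function(rsid, constraint, criteria) {
  stop(structure(
    class = c("proxenrich_matching_failure", "error", "condition"),
    list(message = paste0("no matching panel SNPs for index SNP ", rsid,
                          " (constraint emptying the pool: ", constraint, ")"),
         call = NULL, rsid = rsid, constraint = constraint,
         criteria = criteria)))
}

#' Build the matched candidate pool for one index SNP
#'
#' Selects all panel SNPs satisfying the matching criteria relative to
#' one annotated index SNP. An empty pool is a hard error naming the
#' index SNP and the constraint responsible, unless `relax_steps > 0`
#' in the criteria, in which case the MAF factors are widened by ±0.05
#' per step with a prominent warning.
#'
#' @param index A single-row annotated SNP (from [annotate_snps()]), or a
#'   list with fields `rsid`, `chrom`, `pos`, `maf`, `nearest_distance`
#'   and/or `n_genes_<w>`.
#' @param panel A [build_panel_index()] object.
#' @param criteria A [match_criteria()] object.
#' @return An object of class `candidate_pool` with the candidate panel
#'   row indices.
#' @export
candidate_pool <- function(index, panel, criteria) {
  stopifnot(inherits(panel, "panel_index"), inherits(criteria, "match_criteria"))
  maf <- as.numeric(index$maf[1])
  rsid <- as.character(index$rsid[1])
  pp <- panel$prox
  relax <- 0
  repeat {
    lo <- maf * (criteria$maf_lower_factor - 0.05 * relax)
    hi <- maf * (criteria$maf_upper_factor + 0.05 * relax)
    eps <- .MATCH_EPS * maf
    in_maf <- .panel_maf_range(panel, lo - eps, hi + eps)
    if (criteria$mode == "nearest") {
      d <- as.numeric(index$nearest_distance[1])
      if (is.na(d)) {
        stop("index SNP ", rsid, " has no nearest-gene distance; ",
             "cannot build a nearest-mode pool", call. = FALSE)
      }
      d_eps <- .MATCH_EPS * max(d, 1)
      pd <- pp$nearest_distance[in_maf]
      ok <- !is.na(pd) &
        pd >= d * (1 - criteria$distance_tolerance) - d_eps &
        pd <= d * (1 + criteria$distance_tolerance) + d_eps
    } else {
      col <- paste0("n_genes_", .fmt_w(criteria$window))
      if (is.null(index[[col]])) {
        stop("index SNP ", rsid, " lacks annotation for window ",
             criteria$window, call. = FALSE)
      }
      k <- as.integer(index[[col]][1])
      ok <- pp[[col]][in_maf] == k
    }
    cand <- in_maf[ok]
    if (criteria$exclude_self) {
      cand <- cand[!(pp$chrom[cand] == as.character(index$chrom[1]) &
                       pp$pos[cand] == as.numeric(index$pos[1]))]
    }
    if (length(cand) > 0) break
    if (relax >= criteria$relax_steps) {
      constraint <- if (length(in_maf) == 0) "MAF interval"
      else if (criteria$mode == "nearest") "nearest-gene distance interval"
      else "window gene-count equality"
      .matching_failure(rsid, constraint, criteria)
    }
    relax <- relax + 1
    warning("RELAXED MATCHING for index SNP ", rsid, ": MAF factors widened to [",
            round(criteria$maf_lower_factor - 0.05 * relax, 3), ", ",
            round(criteria$maf_upper_factor + 0.05 * relax, 3), "]",
            call. = FALSE)
  }
  out <- list(rsid = rsid, index = index, candidates = sort(cand),
              criteria = criteria, relax_used = relax)
  class(out) <- "candidate_pool"
  out
}

#' Build candidate pools for every index SNP
#'
#' @param index_prox Annotated index SNPs from [annotate_snps()].
#' @param panel A [build_panel_index()] object.
#' @param criteria A [match_criteria()] object.
#' @return List of [candidate_pool()] objects, one per index SNP.
#' @export
candidate_pools <- function(index_prox, panel, criteria) {
  lapply(seq_len(nrow(index_prox)), function(i) {
    candidate_pool(index_prox[i, , drop = FALSE], panel, criteria)
  })
}

#' @keywords internal
## Deterministic per-column seed stream: results do not depend on the order
## in which columns are drawn. Kept below 2^31 - 1.
.column_seed <- function(seed, j) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(j)) %% 2147483647)
}

#' Sample seeded null SNP sets
#'
#' Draws `n_lists` null SNP lists: each cell is drawn independently and
#' uniformly (with replacement across lists) from the candidate pool of
#' its index SNP. Each index SNP uses its own deterministic random
#' stream derived from the top-level seed, so the result is a pure
#' function of `(pools, n_lists, seed)`.
#'
#' @param pools List of [candidate_pool()] objects.
#' @param n_lists Number of null lists.
#' @param seed Integer seed.
#' @return An object of class `null_sets`: an `n_lists x n_index`
#'   integer matrix of panel row indices, with attributes `seed` and
#'   `criteria` and column names set to the index rsids.
#' @export
sample_null_sets <- function(pools, n_lists, seed) {
  if (n_lists <= 0) stop("n_lists must be positive", call. = FALSE)
  stopifnot(length(pools) > 0)
  n_lists <- as.integer(n_lists)
  mat <- matrix(NA_integer_, nrow = n_lists, ncol = length(pools))
  for (j in seq_along(pools)) {
    cand <- pools[[j]]$candidates
    old <- .Random.seed_backup()
    set.seed(.column_seed(seed, j))
    mat[, j] <- cand[sample.int(length(cand), n_lists, replace = TRUE)]
    .Random.seed_restore(old)
  }
  colnames(mat) <- vapply(pools, function(p) p$rsid, character(1))
  attr(mat, "seed") <- as.integer(seed)
  attr(mat, "criteria") <- pools[[1]]$criteria
  class(mat) <- c("null_sets", class(mat))
  mat
}

#' @keywords internal
.Random.seed_backup <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Validate sampled null sets against their matching criteria
#'
#' Re-checks every sampled entry against the matching criteria of its
#' index SNP, recomputed from the panel annotation (not merely membership
#' in the stored candidate list). Report-only: a correct sampler yields
#' zero violations.
#'
#' @param nulls A [sample_null_sets()] object.
#' @param pools The candidate pools used to draw `nulls`.
#' @param panel The [build_panel_index()] object behind the pools.
#' @return A list with `n_violations` and a data.frame `details` of the
#'   offending cells (empty when valid).
#' @export
validate_null_sets <- function(nulls, pools, panel) {
  stopifnot(ncol(nulls) == length(pools))
  pp <- panel$prox
  bad <- list()
  for (j in seq_along(pools)) {
    pool <- pools[[j]]
    crit <- pool$criteria
    idx <- nulls[, j]
    maf <- as.numeric(pool$index$maf[1])
    relax <- pool$relax_used
    lo <- maf * (crit$maf_lower_factor - 0.05 * relax)
    hi <- maf * (crit$maf_upper_factor + 0.05 * relax)
    eps <- .MATCH_EPS * maf
    ok <- pp$maf[idx] >= lo - eps & pp$maf[idx] <= hi + eps
    if (crit$mode == "nearest") {
      d <- as.numeric(pool$index$nearest_distance[1])
      d_eps <- .MATCH_EPS * max(d, 1)
      pd <- pp$nearest_distance[idx]
      ok <- ok & !is.na(pd) &
        pd >= d * (1 - crit$distance_tolerance) - d_eps &
        pd <= d * (1 + crit$distance_tolerance) + d_eps
    } else {
      col <- paste0("n_genes_", .fmt_w(crit$window))
      ok <- ok & pp[[col]][idx] == as.integer(pool$index[[col]][1])
    }
    if (crit$exclude_self) {
      ok <- ok & !(pp$chrom[idx] == as.character(pool$index$chrom[1]) &
                     pp$pos[idx] == as.numeric(pool$index$pos[1]))
    }
    if (any(!ok)) {
      bad[[length(bad) + 1]] <- data.frame(
        index_rsid = pool$rsid, list_row = which(!ok),
        panel_rsid = pp$rsid[idx[!ok]], stringsAsFactors = FALSE)
    }
  }
  details <- if (length(bad) > 0) do.call(rbind, bad) else
    data.frame(index_rsid = character(), list_row = integer(),
               panel_rsid = character(), stringsAsFactors = FALSE)
  list(n_violations = nrow(details), details = details)
}
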