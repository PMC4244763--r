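# The seven nestedness measures.
#
# NODF, MD, BR expect the matrix in its degree-sorted configuration; NTC
# re-sorts internally; JDM and SR are order-invariant.  The high-level
# wrapper nestedness_score() takes care of stripping, binarising and
# sorting; the individual functions score the matrix exactly as given.

MEASURE_IDS <- c("NODF", "MD", "NTC", "JDM", "BR", "WNODF", "SR")
BINARY_ONLY_MEASURES <- c("NODF", "MD", "NTC", "JDM", "BR")

require_binary <- function(m, what) {
  if (!is_binary_matrix(m))
    stop_validation(sprintf(
      "%s requires a binary matrix (binarise first, or use WNODF)", what))
  m
}

#' Nestedness based on overlap and decreasing fill (NODF)
#'
#' For every ordered pair of columns (k before l) with strictly decreasing
#' fill, the pair contributes 100 * |shared rows| / fill(l); likewise for
#' row pairs; NODF is the grand sum divided by the number of pairs,
#' n(n-1)/2 + m(m-1)/2.  Ranges over \[0, 100\]; 100 for a strictly nested
#' matrix; higher is more nested.  Pairs of equal fill contribute 0, so the
#' value is unchanged by the order chosen among tied-degree lines.
#'
#' @param m a binary biadjacency matrix, already in sorted configuration.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(m) {
  nodf_core(require_binary(as_biadjacency(m), "NODF"))
}

nodf_core <- function(m) {
  n <- nrow(m); mm <- ncol(m)
  npairs <- n * (n - 1) / 2 + mm * (mm - 1) / 2
  if (npairs == 0) return(0)
  (pair_sum_nodf(tcrossprod(m), rowSums(m)) +
     pair_sum_nodf(crossprod(m), colSums(m))) / npairs
}

pair_sum_nodf <- function(shared, fills) {
  k <- length(fills)
  if (k < 2L) return(0)
  den <- pmax(fills, 1)                     # empty lines share nothing anyway
  contrib <- 100 * sweep(shared, 2L, den, "/")
  mask <- upper.tri(shared) & outer(fills, fills, ">")
  sum(contrib[mask])
}

#' Weighted NODF (WNODF)
#'
#' As [nodf()], but a pair (k before l) with strictly decreasing fill
#' contributes 100 * (number of positions where 0 < w(l) < w(k)) / fill(l).
#' On a binary matrix the strict weight inequality never holds and WNODF
#' is 0.
#'
#' @param m a non-negative biadjacency matrix in sorted configuration.
#' @return WNODF in \[0, 100\].
#' @export
wnodf <- function(m) {
  wnodf_core(as_biadjacency(m))
}

wnodf_core <- function(m) {
  n <- nrow(m); mm <- ncol(m)
  npairs <- n * (n - 1) / 2 + mm * (mm - 1) / 2
  if (npairs == 0) return(0)
  (pair_sum_wnodf(m) + pair_sum_wnodf(t(m))) / npairs
}

pair_sum_wnodf <- function(m) {
  # pairs of rows of m
  fills <- unname(rowSums(m != 0))
  n <- nrow(m)
  total <- 0
  if (n < 2L) return(0)
  for (k in seq_len(n - 1L)) {
    for (l in (k + 1L):n) {
      if (fills[k] > fills[l]) {
        cnt <- sum(m[l, ] > 0 & m[l, ] < m[k, ])
        total <- total + 100 * cnt / fills[l]
      }
    }
  }
  total
}

#' Manhattan distance (MD)
#'
#' Sum over all presences of the cell's 0-based row and column offsets from
#' the top-left corner.  Lower is more nested: a packed nested matrix keeps
#' its presences close to the corner.  No normalisation is applied; the
#' normalised temperature of the significance stage supplies scale-freeness.
#'
#' @param m a binary biadjacency matrix in sorted configuration.
#' @return a non-negative integer-valued real.
#' @export
manhattan_distance <- function(m) {
  md_core(require_binary(as_biadjacency(m), "MD"))
}

md_core <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  sum(idx[, 1L] - 1L) + sum(idx[, 2L] - 1L)
}

#' Configuration-model disassortativity (JDM)
#'
#' Ratio of the total observed pairwise neighbourhood overlap (summed over
#' unordered row pairs and column pairs) to its expectation under the
#' configuration model, where a pair with degrees k_a, k_b on a side facing
#' s opposite nodes is expected to overlap by k_a * k_b / s.  Values above 1
#' indicate more overlap -- more nestedness -- than degrees alone predict.
#' Invariant to row/column order.
#'
#' @param m a binary biadjacency matrix.
#' @return a non-negative real; higher is more nested.
#' @export
jdm <- function(m) {
  jdm_core(require_binary(as_biadjacency(m), "JDM"))
}

jdm_core <- function(m) {
  n <- nrow(m); mm <- ncol(m)
  if (n < 2L && mm < 2L)
    stop_validation("JDM needs at least two rows or two columns")
  r <- rowSums(m); cc <- colSums(m)
  obs <- sum(tcrossprod(m)[upper.tri(diag(n))]) +
    sum(crossprod(m)[upper.tri(diag(mm))])
  expct <- sum(outer(r, r)[upper.tri(diag(n))]) / mm +
    sum(outer(cc, cc)[upper.tri(diag(mm))]) / n
  obs / expct
}

#' Discrepancy (BR)
#'
#' The number of presences that sit outside the maximally packed form of
#' the matrix: with columns in sorted order, row i's packed form places its
#' r_i presences in the leftmost r_i columns, and each presence elsewhere
#' counts 1.  Lower is more nested; 0 for any maximally packed matrix.
#'
#' @param m a binary biadjacency matrix in sorted configuration.
#' @return a non-negative integer.
#' @export
discrepancy <- function(m) {
  br_core(require_binary(as_biadjacency(m), "BR"))
}

br_core <- function(m) {
  r <- rowSums(m)
  total <- 0L
  for (i in seq_len(nrow(m))) {
    if (r[i] > 0)
      total <- total + as.integer(r[i] - sum(m[i, seq_len(r[i])]))
  }
  total
}

#' Spectral radius (SR)
#'
#' The largest eigenvalue of the symmetric (n+m) x (n+m) adjacency matrix
#' \[\[0, B\], \[B', 0\]\] of the bipartite graph, which equals the largest
#' singular value of the biadjacency matrix B.  Defined for binary and
#' weighted matrices; invariant to row/column order; higher is more nested.
#'
#' @param m a non-negative biadjacency matrix.
#' @return a non-negative real.
#' @export
spectral_radius <- function(m) {
  sr_core(as_biadjacency(m))
}

sr_core <- function(m) {
  svd(m, nu = 0L, nv = 0L)$d[1L]
}

#' Canonicalise a measure id
#'
#' @param measure a measure name (case-insensitive).
#' @return the canonical measure id.
#' @export
canonical_measure_id <- function(measure) {
  id <- toupper(as.character(measure))
  if (length(id) != 1L || !id %in% MEASURE_IDS)
    stop_validation(sprintf(
      "unknown measure '%s'; valid measures: %s",
      paste(measure, collapse = ","), paste(MEASURE_IDS, collapse = ", ")))
  id
}

measure_fun <- function(measure) {
  switch(measure,
         NODF = nodf,
         MD = manhattan_distance,
         NTC = function(m) ntc_temperature(m, sort = TRUE),
         JDM = jdm,
         BR = discrepancy,
         WNODF = wnodf,
         SR = spectral_radius,
         stop_validation(sprintf(
           "unknown measure '%s'; valid measures: %s",
           measure, paste(MEASURE_IDS, collapse = ", "))))
}

# validation-free variants for the ensemble hot path (input is a freshly
# generated, stripped, already-binarised-as-needed matrix)
measure_core <- function(measure) {
  switch(measure,
         NODF = nodf_core,
         MD = md_core,
         JDM = jdm_core,
         BR = br_core,
         WNODF = wnodf_core,
         SR = sr_core)
}

#' Score one nestedness measure on a matrix
#'
#' End-to-end scoring of a single measure: strips empty lines, binarises
#' when the measure is binary-only or a binary analysis is requested, sorts
#' into the maximal-nestedness configuration (degree sort; NTC re-sorts
#' internally) and evaluates the measure.  `sort = FALSE` relaxes the
#' context-free assumption and scores the arrangement as given.
#'
#' @param m a biadjacency matrix.
#' @param measure one of `"NODF"`, `"MD"`, `"NTC"`, `"JDM"`, `"BR"`,
#'   `"WNODF"`, `"SR"`.
#' @param sort sort into the maximal-nestedness configuration first?
#' @param binary force a binary analysis (binarise the matrix) even for
#'   measures that accept weights.
#' @return the measure value.
#' @export
nestedness_score <- function(m, measure, sort = TRUE, binary = FALSE) {
  measure <- canonical_measure_id(measure)
  m <- strip_empty(as_biadjacency(m))
  if (binary || measure %in% BINARY_ONLY_MEASURES) m <- binarise(m)
  if (sort && !measure %in% c("NTC")) {
    m <- degree_sort(m, use_weights = !is_binary_matrix(m))$matrix
  }
  if (measure == "NTC" && !sort) return(ntc_temperature(m, sort = FALSE))
  measure_fun(measure)(m)
}

#' Reference matrices for orienting a measure
#'
#' A strongly nested weighted matrix (10 x 10, entry 12 - i - j on the
#' anti-diagonal staircase i + j <= 11) and a strongly non-nested weighted
#' checkerboard (10 x 11, entry 4 wherever i + j is even).  Both have
#' exactly 55 nonzero entries summing to 220, so fill- and mass-sensitive
#' measures see identical totals and differ only through arrangement.
#'
#' @return a list with elements `nested` and `checkerboard`.
#' @export
direction_fixtures <- function() {
  nested <- matrix(0, 10L, 10L)
  for (i in 1:10) for (j in 1:10) if (i + j <= 11) nested[i, j] <- 12 - i - j
  checker <- matrix(0, 10L, 11L)
  for (i in 1:10) for (j in 1:11) if ((i + j) %% 2L == 0L) checker[i, j] <- 4
  list(nested = as_biadjacency(nested),
       checkerboard = as_biadjacency(checker))
}

#' Detect the direction of increasing nestedness for a measure
#'
#' Scores the two reference matrices of [direction_fixtures()] (binarised
#' for binary-only measures) and reports `"higher"` if the nested fixture
#' scores above the checkerboard, `"lower"` otherwise.  Detecting the
#' direction empirically, instead of hard-coding it, keeps the significance
#' machinery correct for any measure added later.  Results are memoised.
#'
#' @param measure a measure id.
#' @return `"higher"` or `"lower"` (is more nested).
#' @export
detect_direction <- function(measure) {
  measure <- canonical_measure_id(measure)
  key <- paste0("dir_", measure)
  hit <- .nk_cache[[key]]
  if (!is.null(hit)) return(hit)
  fx <- direction_fixtures()
  binary <- measure %in% BINARY_ONLY_MEASURES
  s_nested <- nestedness_score(fx$nested, measure, sort = TRUE, binary = binary)
  s_checker <- nestedness_score(fx$checkerboard, measure, sort = TRUE,
                                binary = binary)
  if (s_nested == s_checker)
    stop_validation(sprintf(
      "cannot orient measure %s: fixtures score identically", measure))
  dir <- if (s_nested > s_checker) "higher" else "lower"
  .nk_cache[[key]] <- dir
  dir
}
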