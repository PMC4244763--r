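# Maximal-nestedness sorting.
#
# Order-sensitive measures (NODF, MD, BR, NTC) only return a single,
# context-free score if the matrix is first brought into a canonical
# most-nested arrangement.  The primary key is always the line degree
# (number of nonzero entries, descending).  Tie-breaking is designed to be
# invariant under row/column permutations of the input, so that the sorted
# matrix -- and hence every score computed from it -- does not depend on the
# arbitrary order in which the data were stored:
#
#  * binary ties: lines are compared lexicographically (descending), read
#    against a canonical ordering of the opposite axis that is itself seeded
#    by degree profiles; final ties fall back to the original index.
#  * weighted ties: the line with larger weights on the majority of shared
#    (both-nonzero) positions ranks first; then larger total weight; then
#    original index.  These keys never reference positions, so they are
#    intrinsically permutation-invariant.

#' Sort a matrix by descending row and column degree
#'
#' Produces the degree-sorted (most nested, up to ties) configuration of a
#' biadjacency matrix.  See the package vignette for the exact tie-breaking
#' rules and their rationale.
#'
#' @param m a biadjacency matrix with no empty rows/columns (see
#'   [strip_empty()]).
#' @param use_weights break degree ties using interaction weights (for
#'   quantitative matrices); otherwise binary lexicographic tie-breaking.
#' @return an object of class `nested_config`: a list with elements
#'   `matrix` (the permuted view), `row_order` and `col_order` (permutations
#'   of the original indices).
#' @export
degree_sort <- function(m, use_weights = FALSE) {
  m <- as_biadjacency(m)
  ord <- degree_sort_orders(m, use_weights)
  new_nested_config(m, ord$rows, ord$cols)
}

# unvalidated core used by the ensemble hot path
degree_sort_orders <- function(m, use_weights = FALSE) {
  if (use_weights) {
    ro <- weighted_line_order(m)
    co <- weighted_line_order(t(m))
  } else {
    b <- if (is_binary_matrix(m)) m else binarise(m)
    rdeg <- rowSums(b)
    cdeg <- colSums(b)
    # pass 1: canonical column seed from degree + degree profile
    co <- order_by_keys(c(list(-cdeg), profile_keys(b, rdeg, margin = 2L),
                          list(seq_len(ncol(b)))))
    # pass 2: rows by degree, profile, then lexicographic over seeded columns
    ro <- order_by_keys(c(list(-rdeg), profile_keys(b, cdeg, margin = 1L),
                          lex_keys(b[, co, drop = FALSE], margin = 1L),
                          list(seq_len(nrow(b)))))
    # pass 3: final columns by degree, profile, lexicographic over final rows
    co <- order_by_keys(c(list(-cdeg), profile_keys(b, rdeg, margin = 2L),
                          lex_keys(b[ro, , drop = FALSE], margin = 2L),
                          list(seq_len(ncol(b)))))
  }
  list(rows = ro, cols = co)
}

new_nested_config <- function(m, row_order, col_order) {
  structure(list(matrix = m[row_order, col_order, drop = FALSE],
                 row_order = row_order,
                 col_order = col_order),
            class = "nested_config")
}

#' @export
print.nested_config <- function(x, ...) {
  cat(sprintf("nested configuration: %d x %d matrix\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("row order:", x$row_order, "\n")
  cat("col order:", x$col_order, "\n")
  t <- attr(x, "temperature")
  if (!is.null(t)) cat(sprintf("temperature: %.4f\n", t))
  invisible(x)
}

order_by_keys <- function(keys) {
  do.call(order, keys)
}

# descending-lexicographic keys for the lines along `margin`, packing runs of
# up to 50 binary entries into one double (exact below 2^53)
lex_keys <- function(b, margin) {
  v <- if (margin == 1L) b else t(b)
  L <- ncol(v)
  starts <- seq(1L, L, by = 50L)
  lapply(starts, function(s) {
    e <- min(s + 49L, L)
    w <- 2^((e - s):0)
    -as.vector(v[, s:e, drop = FALSE] %*% w)
  })
}

# permutation-invariant tie key: the sorted (descending) multiset of
# opposite-axis degrees over a line's presences, padded with -1
profile_keys <- function(b, opp_deg, margin) {
  v <- if (margin == 1L) b else t(b)
  L <- ncol(v)
  prof <- apply(v, 1L, function(row) {
    d <- sort(opp_deg[row != 0], decreasing = TRUE)
    c(d, rep(-1, L - length(d)))
  })
  prof <- if (is.matrix(prof)) prof else matrix(prof, nrow = 1L)
  lapply(seq_len(nrow(prof)), function(k) -prof[k, ])
}

# weighted ordering: degree-descending; ties resolved inside each block by a
# pairwise comparator (overlap majority, then total weight, then stability)
weighted_line_order <- function(m) {
  deg <- rowSums(m != 0)
  tot <- rowSums(m)
  ord <- order(-deg, -tot, seq_len(nrow(m)))
  blocks <- split(ord, deg[ord])
  for (blk in blocks) {
    if (length(blk) < 2L) next
    sorted <- insertion_sort_lines(blk, m)
    ord[match(blk, ord)] <- sorted
  }
  ord
}

# returns -1 if line a ranks before line b, +1 after, 0 undecided
compare_lines_weighted <- function(a, b) {
  ov <- a > 0 & b > 0
  na_ <- sum(a[ov] > b[ov])
  nb_ <- sum(b[ov] > a[ov])
  if (na_ != nb_) return(if (na_ > nb_) -1L else 1L)
  sa <- sum(a); sb <- sum(b)
  if (sa != sb) return(if (sa > sb) -1L else 1L)
  0L
}

insertion_sort_lines <- function(idx, m) {
  for (i in seq_along(idx)[-1L]) {
    j <- i
    while (j > 1L &&
           compare_lines_weighted(m[idx[j], ], m[idx[j - 1L], ]) < 0L) {
      tmp <- idx[j]; idx[j] <- idx[j - 1L]; idx[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  idx
}

#' Temperature-minimising sort
#'
#' Refines the degree-sorted configuration of a binary matrix by
#' deterministic hill-climbing over adjacent row-pair and column-pair swaps,
#' accepting a swap only when the nestedness temperature strictly decreases,
#' until a full pass leaves the arrangement unchanged.  This is the
#' arrangement against which the temperature measure (NTC) is reported.
#'
#' @param m a binary biadjacency matrix with no empty rows/columns.
#' @return a `nested_config` whose `temperature` attribute holds the
#'   temperature of the final arrangement.
#' @export
ntc_sort <- function(m) {
  m <- as_biadjacency(m)
  if (!is_binary_matrix(m))
    stop_validation("ntc_sort requires a binary matrix (binarise first)")
  if (length(m) < 4L)
    stop_validation("temperature is undefined for matrices smaller than 4 cells")
  fit <- ntc_minimise(m)
  out <- new_nested_config(m, fit$rows, fit$cols)
  attr(out, "temperature") <- fit$temperature
  out
}

# unvalidated core: adjacent-swap hill climb from the degree sort
ntc_minimise <- function(m) {
  ord <- degree_sort_orders(m, use_weights = FALSE)
  n <- nrow(m); mm <- ncol(m)
  grid <- temperature_grid(n, mm, sum(m != 0))
  ro <- ord$rows
  co <- ord$cols
  cur <- raw_temperature_sum(m[ro, co, drop = FALSE], grid)
  repeat {
    changed <- FALSE
    if (n > 1L) for (i in seq_len(n - 1L)) {
      cand <- ro
      cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
      s <- raw_temperature_sum(m[cand, co, drop = FALSE], grid)
      if (s < cur) { ro <- cand; cur <- s; changed <- TRUE }
    }
    if (mm > 1L) for (j in seq_len(mm - 1L)) {
      cand <- co
      cand[c(j, j + 1L)] <- cand[c(j + 1L, j)]
      s <- raw_temperature_sum(m[ro, cand, drop = FALSE], grid)
      if (s < cur) { co <- cand; cur <- s; changed <- TRUE }
    }
    if (!changed) break
  }
  list(rows = ro, cols = co,
       temperature = temperature_from_sum(cur, n, mm))
}

# unvalidated core: temperature of the arrangement as given
ntc_raw <- function(b) {
  grid <- temperature_grid(nrow(b), ncol(b), sum(b != 0))
  temperature_from_sum(raw_temperature_sum(b, grid), nrow(b), ncol(b))
}
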