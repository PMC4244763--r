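# Nestedness temperature.
#
# Cells are mapped to the unit square by their row/column midpoints
# (x along columns, y along rows, origin at the top-left corner where a
# nested matrix concentrates its presences).  An isocline of perfect order
# x^a + y^a = 1 separates an expected-presence region (top-left) from an
# expected-absence region; the exponent a is solved so that the presence
# side has area equal to the fill proportion p = F/(n*m).  Every unexpected
# presence (outside the isocline) and unexpected absence (inside it)
# contributes u = (d/D)^2, where d is the distance from the cell to the
# isocline along the cell's main-diagonal direction and D the full length
# of that diagonal chord across the unit square.  The temperature is
#
#   T = 100 * sum(u) / (U_MAX * n * m),       U_MAX = 0.04145,
#
# the classic normalisation that maps the expected maximal disorder to 100.

U_MAX <- 0.04145

.nk_cache <- new.env(parent = emptyenv())

# area of the region x^a + y^a < 1 in the unit square
isocline_area <- function(a) {
  stats::integrate(function(x) (1 - x^a)^(1 / a), 0, 1,
                   rel.tol = 1e-10, subdivisions = 400L)$value
}

# solve isocline_area(a) = p; p must be in (0, 1)
isocline_exponent <- function(p) {
  lo <- 0.02
  hi <- 2000
  if (p <= isocline_area(lo)) return(lo)
  if (p >= isocline_area(hi)) return(hi)
  exp(stats::uniroot(function(la) isocline_area(exp(la)) - p,
                     lower = log(lo), upper = log(hi), tol = 1e-12)$root)
}

# Precompute, for an n x m grid with fill F: which cell midpoints fall on
# the presence side of the isocline, and each cell's u = (d/D)^2 penalty.
# Cached: the grid depends only on (n, m, F), not on the arrangement, so
# re-sorting and hill-climbing reuse it.
temperature_grid <- function(n, m, F) {
  key <- paste(n, m, F, sep = "_")
  hit <- .nk_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- F / (n * m)
  if (p >= 1) {
    out <- list(inside = matrix(TRUE, n, m), u = matrix(0, n, m))
    .nk_cache[[key]] <- out
    return(out)
  }
  a <- isocline_exponent(p)
  x <- (seq_len(m) - 0.5) / m
  y <- (seq_len(n) - 0.5) / n
  inside <- matrix(FALSE, n, m)
  u <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      g <- x[j]^a + y[i]^a
      inside[i, j] <- g <= 1
      tlo <- -min(x[j], y[i])
      thi <- min(1 - x[j], 1 - y[i])
      tstar <- stats::uniroot(function(t) (x[j] + t)^a + (y[i] + t)^a - 1,
                              lower = tlo, upper = thi, tol = 1e-12)$root
      D <- thi - tlo
      u[i, j] <- (abs(tstar) / D)^2
    }
  }
  out <- list(inside = inside, u = u)
  .nk_cache[[key]] <- out
  out
}

# sum of u over unexpected cells for a 0/1 matrix in a given arrangement
raw_temperature_sum <- function(b, grid) {
  pres <- b != 0
  sum(grid$u[pres != grid$inside])
}

temperature_from_sum <- function(s, n, m) {
  100 * s / (U_MAX * n * m)
}

#' Nestedness temperature (NTC)
#'
#' The disorder of a binary matrix relative to an isocline of perfect order,
#' on a 0--100 scale: 0 for a perfectly nested arrangement, larger for more
#' disordered ones.  Lower values indicate more nestedness.  By default the
#' matrix is first brought into its temperature-minimal arrangement with
#' [ntc_sort()]; `sort = FALSE` scores the arrangement as given (for use
#' when the context-free assumption is deliberately relaxed).
#'
#' @param m a binary biadjacency matrix with no empty rows/columns.
#' @param sort minimise the temperature over arrangements first?
#' @return the temperature, a non-negative real.
#' @export
ntc_temperature <- function(m, sort = TRUE) {
  m <- as_biadjacency(m)
  if (!is_binary_matrix(m))
    stop_validation("temperature requires a binary matrix (binarise first)")
  if (length(m) < 4L)
    stop_validation("temperature is undefined for matrices smaller than 4 cells")
  if (sort) ntc_minimise(m)$temperature else ntc_raw(m)
}
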