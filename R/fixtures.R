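#' Generate synthetic test matrices
#'
#' Deterministic generators for the matrix archetypes used in tests and
#' demos.
#'
#' * `"nested"`: a perfectly nested binary staircase.  Cells are filled in
#'   order of increasing anti-diagonal `i + j` (then increasing row), so
#'   every prefix is a valid staircase and `fill = 55` on a 10 x 10 grid
#'   reproduces the support of the nested direction fixture.
#' * `"weighted_nested"`: the same support with weight
#'   `max(i + j) - (i + j) + 1`, decreasing towards the bottom-right; on
#'   10 x 10 with fill 55 this is exactly the nested direction fixture.
#' * `"checkerboard"`: 1 wherever `i + j` is even (`fill` ignored).
#' * `"random"`: `fill` cells placed uniformly at random.
#'
#' @param kind one of `"nested"`, `"weighted_nested"`, `"checkerboard"`,
#'   `"random"`.
#' @param nrow,ncol matrix dimensions.
#' @param fill number of nonzero cells (not used by `"checkerboard"`).
#' @param seed optional integer seed (only `"random"` draws random numbers).
#' @return a biadjacency matrix.
#' @export
make_fixture <- function(kind = c("nested", "weighted_nested", "checkerboard",
                                  "random"),
                         nrow, ncol, fill = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (nrow < 1L || ncol < 1L)
    stop_validation("fixture dimensions must be at least 1 x 1")
  if (kind != "checkerboard") {
    if (is.null(fill)) stop_validation("fill is required for this kind")
    if (fill < 1 || fill > nrow * ncol)
      stop_validation(sprintf("infeasible fill %d for a %d x %d matrix",
                              fill, nrow, ncol))
  }
  m <- matrix(0, nrow, ncol)
  if (kind == "checkerboard") {
    idx <- outer(seq_len(nrow), seq_len(ncol), "+") %% 2L == 0L
    m[idx] <- 1
  } else if (kind == "random") {
    if (!is.null(seed)) set.seed(seed)
    m[sample.int(nrow * ncol, fill)] <- 1
  } else {
    ij <- expand.grid(i = seq_len(nrow), j = seq_len(ncol))
    ij <- ij[order(ij$i + ij$j, ij$i), ]
    take <- ij[seq_len(fill), ]
    if (kind == "nested") {
      m[cbind(take$i, take$j)] <- 1
    } else {
      smax <- max(take$i + take$j)
      m[cbind(take$i, take$j)] <- smax - (take$i + take$j) + 1
    }
  }
  as_biadjacency(m)
}
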