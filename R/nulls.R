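# Null models.
#
# Binary schemes (operate on presence/absence matrices):
#   SS  - fill F placed uniformly at random; conserves shape and fill.
#   FF  - curveball trades; conserves shape, fill and both degree sequences.
#   CC  - F cells sampled without replacement with weight
#         (k_i/m + d_j/n)/2; conserves shape and fill exactly, degree
#         structure in tendency only.
#   DD  - independent Bernoulli draws with cell probability
#         (k_i/m + d_j/n)/2; conserves degrees in expectation.
#   EE  - independent Bernoulli draws with probability F/(n*m); conserves
#         fill in expectation.
# Weighted schemes (operate on quantitative matrices, zero pattern fixed):
#   SHUFFLE - permutes the multiset of nonzero weights over the fixed
#             positions; conserves positions and the weight multiset.
#   CRT     - redraws each row's weights over its occupied cells, scaled to
#             the original row total; conserves positions and row totals.
#   CCT     - the column-wise mirror of CRT.
#   RCTA    - elementwise mean of one CRT and one CCT draw; conserves
#             positions, and row/column totals in expectation.
#
# DD, EE (and in principle CC) can produce empty rows or columns; these are
# retained in the returned matrix so the conservation contracts stay
# literal, and stripped later by the ensemble pipeline.

BINARY_NULLS <- c("SS", "FF", "CC", "DD", "EE")
WEIGHTED_NULLS <- c("SHUFFLE", "CRT", "CCT", "RCTA")
NULL_IDS <- c(BINARY_NULLS, WEIGHTED_NULLS)

#' Canonicalise a null-model id
#'
#' Accepts model names (case-insensitive) or the numeric aliases 1--5 of
#' the binary models: 1 = SS, 2 = CC, 3 = FF, 4 = DD, 5 = EE.
#'
#' @param model a model id or alias.
#' @return the canonical model name.
#' @export
canonical_null_id <- function(model) {
  alias <- c("SS", "CC", "FF", "DD", "EE")
  if (is.numeric(model) ||
      (is.character(model) && grepl("^[0-9]+$", model))) {
    k <- as.integer(model)
    if (k < 1L || k > 5L)
      stop_validation(sprintf("numeric null-model alias out of range: %s",
                              model))
    return(alias[k])
  }
  id <- toupper(as.character(model))
  if (!id %in% NULL_IDS)
    stop_validation(sprintf("unknown null model '%s'; valid models: %s",
                            model, paste(NULL_IDS, collapse = ", ")))
  id
}

#' Draw matrices from a null model
#'
#' Generates `n` random matrices conserving the features of the chosen
#' scheme (see the model list above and the package vignette).  Draws are
#' reproducible: identical `seed` gives an identical sequence.  For FF the
#' draws form a single curveball chain: the first draw is reached by
#' 5 * max(nrow, ncol) trades from the observed matrix, and each subsequent
#' draw by the same number of further trades.
#'
#' @param m the observed biadjacency matrix, stripped of empty lines.
#'   Binary models require a binary matrix.
#' @param model a null-model id (see [canonical_null_id()]).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return a list of `n` matrices with the dimnames of `m`.
#' @export
generate_null <- function(m, model, n = 1L, seed = NULL) {
  m <- as_biadjacency(m)
  model <- canonical_null_id(model)
  if (!is.null(seed)) set.seed(seed)
  state <- null_state(m, model)
  lapply(seq_len(n), function(i) null_draw(state))
}

# A closure bundle: null_draw(state) advances any chain state internally.
null_state <- function(m, model) {
  if (model %in% BINARY_NULLS && !is_binary_matrix(m))
    stop_validation(sprintf(
      "null model %s requires a binary matrix (binarise first)", model))
  n <- nrow(m); mm <- ncol(m)
  env <- new.env(parent = emptyenv())
  env$m <- m
  env$model <- model
  env$dims <- c(n, mm)
  env$dimnames <- dimnames(m)
  if (model %in% BINARY_NULLS) {
    env$F <- sum(m != 0)
    env$rdeg <- rowSums(m != 0)
    env$cdeg <- colSums(m != 0)
    env$p_cell <- (matrix(env$rdeg / mm, n, mm) +
                     matrix(env$cdeg / n, n, mm, byrow = TRUE)) / 2
  }
  if (model == "FF") {
    if (n < 2L || mm < 2L)
      stop_validation("FF needs at least 2 rows and 2 columns")
    env$rows <- lapply(seq_len(n), function(i) which(m[i, ] != 0))
    env$trades <- 5L * max(n, mm)
  }
  env
}

null_draw <- function(state) {
  n <- state$dims[1L]; mm <- state$dims[2L]
  out <- switch(state$model,
    SS = {
      v <- numeric(n * mm)
      v[sample.int(n * mm, state$F)] <- 1
      matrix(v, n, mm)
    },
    CC = {
      v <- numeric(n * mm)
      v[sample.int(n * mm, state$F, prob = as.vector(state$p_cell))] <- 1
      matrix(v, n, mm)
    },
    DD = matrix(stats::rbinom(n * mm, 1L, as.vector(state$p_cell)), n, mm),
    EE = matrix(stats::rbinom(n * mm, 1L, state$F / (n * mm)), n, mm),
    FF = {
      state$rows <- curveball_trades(state$rows, state$trades)
      b <- matrix(0, n, mm)
      for (i in seq_len(n)) b[i, state$rows[[i]]] <- 1
      b
    },
    SHUFFLE = {
      pos <- which(state$m != 0)
      b <- matrix(0, n, mm)
      b[pos] <- sample(state$m[pos])
      b
    },
    CRT = crt_draw(state$m),
    CCT = t(crt_draw(t(state$m))),
    RCTA = (crt_draw(state$m) + t(crt_draw(t(state$m)))) / 2
  )
  dimnames(out) <- state$dimnames
  out
}

# one curveball trade: two random rows swap a random subset of their
# exclusive column sets, preserving both degree sequences
curveball_trades <- function(rows, ntrades) {
  n <- length(rows)
  for (t in seq_len(ntrades)) {
    ij <- sample.int(n, 2L)
    a <- rows[[ij[1L]]]
    b <- rows[[ij[2L]]]
    shared <- a[a %in% b]
    a_ex <- a[!a %in% shared]
    b_ex <- b[!b %in% shared]
    if (length(a_ex) == 0L || length(b_ex) == 0L) next
    pool <- sample(c(a_ex, b_ex))
    rows[[ij[1L]]] <- c(shared, pool[seq_along(a_ex)])
    rows[[ij[2L]]] <- c(shared, pool[-seq_along(a_ex)])
  }
  rows
}

# conserve each row's total over its occupied cells: integer rows get one
# unit per cell plus a uniform-multinomial remainder (exact, stays
# positive); other rows get Dirichlet(1) shares of the total (positive
# almost surely)
crt_draw <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    cells <- which(m[i, ] != 0)
    k <- length(cells)
    if (k == 0L) next
    w <- m[i, cells]
    total <- sum(w)
    if (all(w == round(w))) {
      extra <- as.vector(stats::rmultinom(1L, size = total - k,
                                          prob = rep(1, k)))
      out[i, cells] <- 1 + extra
    } else {
      shares <- stats::rexp(k)
      out[i, cells] <- total * shares / sum(shares)
    }
  }
  out
}
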