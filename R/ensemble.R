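# Null ensembles and significance statistics.
#
# One ensemble of null matrices serves every selected measure, so the
# per-measure results within a null model are directly comparable: each
# draw is stripped of empty lines, sorted, and scored by all measures.

#' Build a fixed-size null ensemble
#'
#' Generates `N` null matrices from one model, strips and sorts each, and
#' scores it with every selected measure.  A draw that collapses to an
#' all-zero matrix is redrawn; 1,000 consecutive failures abort.
#'
#' @param m the observed biadjacency matrix (stripped; binary for binary
#'   models).
#' @param model a null-model id.
#' @param measures character vector of measure ids.
#' @param N ensemble size (>= 1).
#' @param seed optional integer seed.
#' @param sort sort each null matrix before scoring (default `TRUE`).
#' @return an object of class `null_ensemble`: list with `model`, `scores`
#'   (named list, one numeric vector of length `N` per measure), `N`,
#'   `adaptive = FALSE` and `seed`.
#' @export
run_fixed_ensemble <- function(m, model, measures, N, seed = NULL,
                               sort = TRUE) {
  stopifnot(N >= 1L)
  measures <- vapply(measures, canonical_measure_id, character(1L),
                     USE.NAMES = FALSE)
  if (length(measures) == 0L) stop_validation("no measures selected")
  m <- strip_empty(as_biadjacency(m))
  model <- canonical_null_id(model)
  if (!is.null(seed)) set.seed(seed)
  state <- null_state(m, model)
  scores <- matrix(NA_real_, nrow = N, ncol = length(measures),
                   dimnames = list(NULL, measures))
  for (i in seq_len(N)) {
    scores[i, ] <- score_null_draw(state, measures, sort)
  }
  structure(list(model = model,
                 scores = lapply(seq_len(ncol(scores)),
                                 function(j) scores[, j]),
                 N = N, adaptive = FALSE, seed = seed),
            class = "null_ensemble") -> out
  names(out$scores) <- measures
  out
}

# draw one non-degenerate null matrix and score all measures on it
score_null_draw <- function(state, measures, sort) {
  for (attempt in seq_len(1000L)) {
    draw <- null_draw(state)
    keep_r <- rowSums(draw != 0) > 0
    keep_c <- colSums(draw != 0) > 0
    if (!any(keep_r) || !any(keep_c)) next
    if (!all(keep_r) || !all(keep_c))
      draw <- draw[keep_r, keep_c, drop = FALSE]
    return(score_all_measures(draw, measures, sort))
  }
  stop_validation("1000 consecutive null draws collapsed to an empty matrix")
}

# score a stripped matrix with each measure, sharing sorted configurations.
# NODF, MD, JDM, SR and WNODF do not depend on the order chosen among
# tied-degree lines, so when neither BR nor NTC is requested the cheap
# plain degree ordering replaces the full canonical tie-breaking.
score_all_measures <- function(m, measures, sort = TRUE) {
  sorted_bin <- NULL
  sorted_wt <- NULL
  cheap_ties <- !any(measures %in% c("BR", "NTC"))
  sort_mat <- function(mat, use_weights) {
    if (!sort) return(mat)
    if (cheap_ties && !use_weights) {
      mat[order(-rowSums(mat)), order(-colSums(mat)), drop = FALSE]
    } else {
      ord <- degree_sort_orders(mat, use_weights)
      mat[ord$rows, ord$cols, drop = FALSE]
    }
  }
  is_bin <- is_binary_matrix(m)
  vapply(measures, function(ms) {
    binary <- ms %in% BINARY_ONLY_MEASURES || is_bin
    if (ms == "NTC") {
      work <- if (is_bin) m else binarise(m)
      if (length(work) < 4L) return(NA_real_)
      return(if (sort) ntc_minimise(work)$temperature
             else ntc_raw(work))
    }
    if (binary) {
      if (is.null(sorted_bin))
        sorted_bin <<- sort_mat(if (is_bin) m else binarise(m),
                                use_weights = FALSE)
      measure_core(ms)(sorted_bin)
    } else {
      if (is.null(sorted_wt))
        sorted_wt <<- sort_mat(m, use_weights = TRUE)
      measure_core(ms)(sorted_wt)
    }
  }, numeric(1L))
}

#' Build an adaptively sized null ensemble
#'
#' Two score groups are grown in parallel from the same null model, 500
#' draws per group per round.  After each round a two-sample Mann-Whitney
#' U-test compares the groups on the first selected measure; as soon as its
#' null hypothesis (same distribution) cannot be rejected at the 10% level
#' the groups are deemed a faithful sample of the null distribution and are
#' merged into the final ensemble.  The minimum final size is therefore
#' 1,000 (so p-values down to 0.001 are assignable) and growth is capped at
#' 100,000 members in case the test always rejects.
#'
#' @inheritParams run_fixed_ensemble
#' @param min_group initial draws per group.
#' @param increment draws added to each group per round.
#' @param cap maximum combined ensemble size.
#' @param alpha significance level of the between-group test.
#' @param utest the two-sample test used to compare groups; any function
#'   `(x, y) -> p` (injectable for testing the cap behaviour).
#' @return a `null_ensemble` with `adaptive = TRUE`.
#' @export
run_adaptive_ensemble <- function(m, model, measures, seed = NULL,
                                  sort = TRUE, min_group = 500L,
                                  increment = 500L, cap = 100000L,
                                  alpha = 0.10, utest = mann_whitney_u) {
  measures <- vapply(measures, canonical_measure_id, character(1L),
                     USE.NAMES = FALSE)
  if (length(measures) == 0L) stop_validation("no measures selected")
  m <- strip_empty(as_biadjacency(m))
  model <- canonical_null_id(model)
  if (!is.null(seed)) set.seed(seed)
  state <- null_state(m, model)
  nm <- length(measures)
  grow <- function(block) {
    out <- matrix(NA_real_, nrow = block, ncol = nm)
    for (i in seq_len(block)) out[i, ] <- score_null_draw(state, measures, sort)
    out
  }
  a <- grow(min_group)
  b <- grow(min_group)
  repeat {
    total <- nrow(a) + nrow(b)
    p <- utest(a[, 1L], b[, 1L])
    if (p > alpha || total >= cap) break
    a <- rbind(a, grow(increment))
    b <- rbind(b, grow(increment))
  }
  merged <- rbind(a, b)
  scores <- lapply(seq_len(nm), function(j) unname(merged[, j]))
  names(scores) <- measures
  structure(list(model = model, scores = scores, N = nrow(merged),
                 adaptive = TRUE, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null ensemble: model %s, N = %d%s\n", x$model, x$N,
              if (x$adaptive) " (adaptive)" else ""))
  for (ms in names(x$scores))
    cat(sprintf("  %-6s mean %.4f  sd %.4f\n", ms,
                mean(x$scores[[ms]]), stats::sd(x$scores[[ms]])))
  invisible(x)
}

#' Two-sample Mann-Whitney U-test
#'
#' Two-sided p-value for the hypothesis that `x` and `y` come from the same
#' distribution.  Small untied samples are tested exactly; otherwise the
#' normal approximation with tie and continuity corrections is used (group
#' sizes in the adaptive ensemble are always >= 500).  Two groups with all
#' values identical are indistinguishable: p = 1.
#'
#' @param x,y numeric vectors (length >= 1).
#' @return the two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) return(1.0)
  exact <- length(x) < 50L && length(y) < 50L && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = TRUE)$p.value)
}

#' z-score of an observed value against an ensemble mean and SD
#'
#' @param observed observed measure value.
#' @param expected ensemble mean.
#' @param sd ensemble standard deviation.
#' @return `(observed - expected) / sd`.
#' @export
z_score <- function(observed, expected, sd) {
  (observed - expected) / sd
}

#' Normalised temperature of an observed value against an ensemble mean
#'
#' @param observed observed measure value.
#' @param expected ensemble mean.
#' @return `observed / expected`.
#' @export
normalised_temperature <- function(observed, expected) {
  observed / expected
}

#' Significance statistics of an observed score against a null ensemble
#'
#' The p-value is the frequency of ensemble members strictly more nested
#' than the observed score, where "more nested" follows the measure's
#' direction; when no member is more nested the conservative bound 1/N is
#' reported with `p_is_bound = TRUE`.  The mean, sample standard deviation
#' (N - 1 denominator), z-score and normalised temperature T =
#' observed/mean are attached.  A zero-variance ensemble leaves z undefined
#' (NA, with a warning); a zero mean leaves T undefined.
#'
#' @param observed the observed measure value.
#' @param ensemble numeric vector of null scores (length N >= 1).
#' @param direction `"higher"` or `"lower"` (is more nested), as returned
#'   by [detect_direction()].
#' @param measure,model optional ids carried into the result.
#' @return an object of class `comparison_stats`: a list with fields
#'   `measure`, `model`, `observed`, `N`, `mean`, `sd`, `z`, `T`, `p`,
#'   `p_is_bound`.
#' @export
compute_stats <- function(observed, ensemble, direction = c("higher", "lower"),
                          measure = NA_character_, model = NA_character_) {
  direction <- match.arg(direction)
  N <- length(ensemble)
  stopifnot(N >= 1L)
  mu <- mean(ensemble)
  sdev <- stats::sd(ensemble)           # NA when N = 1
  more <- if (direction == "higher") sum(ensemble > observed)
          else sum(ensemble < observed)
  if (more > 0L) {
    p <- more / N
    bound <- FALSE
  } else {
    p <- 1 / N
    bound <- TRUE
  }
  if (is.na(sdev) || sdev == 0) {
    warning("ensemble has zero variance: z-score undefined")
    z <- NA_real_
  } else {
    z <- z_score(observed, mu, sdev)
  }
  tval <- if (mu == 0) NA_real_ else normalised_temperature(observed, mu)
  structure(list(measure = measure, model = model, observed = observed,
                 N = N, mean = mu, sd = sdev, z = z, T = tval,
                 p = p, p_is_bound = bound),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("%s vs %s null (N = %d)\n", x$measure, x$model, x$N))
  cat(sprintf("  observed %.4f  mean %.4f  sd %.4f\n",
              x$observed, x$mean, x$sd))
  cat(sprintf("  z %.4f  T %.4f  p %s\n", x$z, x$T, format_p(x)))
  invisible(x)
}

# Table-style rendering of the p-value: the bound case prints "<1/N"
format_p <- function(stats) {
  if (stats$p_is_bound) paste0("<", format(1 / stats$N, digits = 7))
  else format(stats$p, digits = 7)
}
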