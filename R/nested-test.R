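#' Nestedness significance test for a bipartite matrix
#'
#' The end-to-end analysis: reads (or takes) a biadjacency matrix, strips
#' empty rows/columns, sorts it into its maximal-nestedness configuration,
#' scores it with the selected measures, and tests each score against
#' ensembles of null matrices from the selected null models.  One ensemble
#' per null model serves all measures, so results are directly comparable
#' across measures.
#'
#' @param x a biadjacency matrix, or a path to a CSV file (read with
#'   [read_biadjacency()]).
#' @param measures character vector of measure ids among `"NODF"`, `"MD"`,
#'   `"NTC"`, `"JDM"`, `"BR"`, `"WNODF"`, `"SR"`.
#' @param nulls vector of null-model ids (names or numeric aliases, see
#'   [canonical_null_id()]).
#' @param ensemble `"adaptive"` (the default) or `"fixed"`.
#' @param N ensemble size when `ensemble = "fixed"`.
#' @param binary analyse the presence/absence pattern (`TRUE`, the
#'   default) or the quantitative weights (`FALSE`).  Binary null models
#'   require `binary = TRUE`; weighted models require `binary = FALSE`;
#'   `WNODF` is unavailable in a binary analysis, while binary-only
#'   measures in a weighted analysis are computed on the binarised
#'   pattern.
#' @param sort sort into the maximal-nestedness configuration before
#'   scoring (default `TRUE`).  Disabling relaxes the context-free
#'   assumption: observed and null matrices are then scored as arranged.
#' @param seed optional integer seed.  Each null model uses its own
#'   substream derived from it by a fixed offset, so adding or removing
#'   models never perturbs the draws of the others.
#' @param has_headers when `x` is a path: does the CSV carry header row and
#'   column?
#' @param ... further arguments passed to [run_adaptive_ensemble()] or
#'   [run_fixed_ensemble()].
#' @return an object of class `nested_test`: a list with the stripped
#'   analysis matrix (`matrix`), its nested configuration (`config`),
#'   named observed scores (`observed`), per-model/measure statistics
#'   (`stats`, a list of [compute_stats()] results; `table`, the same as a
#'   data frame), the raw ensembles (`ensembles`), and the run settings.
#' @examples
#' m <- make_fixture("random", 8, 8, fill = 24, seed = 1)
#' fit <- nested_test(m, measures = c("NODF", "SR"), nulls = "SS",
#'                    ensemble = "fixed", N = 99, seed = 1)
#' fit
#' @export
nested_test <- function(x, measures = c("NODF", "SR"), nulls = c("SS"),
                        ensemble = c("adaptive", "fixed"), N = 1000L,
                        binary = TRUE, sort = TRUE, seed = NULL,
                        has_headers = TRUE, ...) {
  ensemble <- match.arg(ensemble)
  if (is.character(x) && length(x) == 1L)
    x <- read_biadjacency(x, has_headers = has_headers)
  m <- as_biadjacency(x)
  measures <- vapply(measures, canonical_measure_id, character(1L),
                     USE.NAMES = FALSE)
  nulls <- vapply(nulls, canonical_null_id, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(measures)) stop_validation("duplicated measures")
  if (anyDuplicated(nulls)) stop_validation("duplicated null models")
  # validate the measure/model/mode combination before any computation
  if (binary && "WNODF" %in% measures)
    stop_validation("WNODF needs a weighted analysis (binary = FALSE)")
  if (binary && any(nulls %in% WEIGHTED_NULLS))
    stop_validation(sprintf(
      "weighted null model(s) %s need a weighted analysis (binary = FALSE)",
      paste(intersect(nulls, WEIGHTED_NULLS), collapse = ", ")))
  if (!binary && any(nulls %in% BINARY_NULLS))
    stop_validation(sprintf(
      "binary null model(s) %s need a binary analysis (binary = TRUE)",
      paste(intersect(nulls, BINARY_NULLS), collapse = ", ")))
  if (binary) m <- binarise(m)
  m <- strip_empty(m)
  config <- if (sort) degree_sort(m, use_weights = !binary)
            else new_nested_config(m, seq_len(nrow(m)), seq_len(ncol(m)))

  observed <- vapply(measures, function(ms)
    nestedness_score(m, ms, sort = sort, binary = binary), numeric(1L))
  names(observed) <- measures
  directions <- vapply(measures, detect_direction, character(1L))
  names(directions) <- measures

  ensembles <- list()
  stats <- list()
  for (k in seq_along(nulls)) {
    mod <- nulls[k]
    seed_k <- if (is.null(seed)) NULL else seed + 10000L * k
    ens <- if (ensemble == "adaptive")
      run_adaptive_ensemble(m, mod, measures, seed = seed_k, sort = sort, ...)
    else
      run_fixed_ensemble(m, mod, measures, N = N, seed = seed_k,
                         sort = sort, ...)
    ensembles[[mod]] <- ens
    for (ms in measures) {
      stats[[paste(mod, ms, sep = ".")]] <-
        compute_stats(observed[[ms]], ens$scores[[ms]],
                      direction = directions[[ms]],
                      measure = ms, model = mod)
    }
  }
  structure(list(matrix = m, config = config, measures = measures,
                 nulls = nulls, observed = observed,
                 directions = directions, stats = stats,
                 table = stats_table(stats), ensembles = ensembles,
                 ensemble = ensemble, binary = binary, sort = sort,
                 seed = seed, call = match.call()),
            class = "nested_test")
}

stats_table <- function(stats) {
  do.call(rbind, lapply(stats, function(s) {
    data.frame(null_model = s$model, measure = s$measure,
               observed = s$observed, N = s$N, mean = s$mean, sd = s$sd,
               z = s$z, p = s$p, p_label = format_p(s), T = s$T,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' @export
print.nested_test <- function(x, digits = 4L, ...) {
  cat(sprintf("Nestedness test: %d x %d %s matrix (fill %d)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$binary) "binary" else "weighted",
              sum(x$matrix != 0)))
  cat(sprintf("Measures: %s | Null models: %s | %s ensemble\n\n",
              paste(x$measures, collapse = ", "),
              paste(x$nulls, collapse = ", "),
              x$ensemble))
  hdr <- c("Null model", "Nestedness measure", "Measure", "Ensemble Size",
           "Mean", "Standard Deviation", "z-score", "p-value",
           "Normalised Temperature")
  cols <- lapply(x$stats, function(s) {
    c(s$model, s$measure,
      formatC(s$observed, digits = digits, format = "f"),
      as.character(s$N),
      formatC(s$mean, digits = digits, format = "f"),
      formatC(s$sd, digits = digits, format = "f"),
      formatC(s$z, digits = digits, format = "f"),
      if (s$p_is_bound) paste0("<", format(1 / s$N)) else
        formatC(s$p, digits = digits, format = "f"),
      formatC(s$T, digits = digits, format = "f"))
  })
  tab <- cbind(hdr, do.call(cbind, cols))
  dimnames(tab) <- list(rep("", nrow(tab)), rep("", ncol(tab)))
  print(tab, quote = FALSE)
  invisible(x)
}

#' @export
summary.nested_test <- function(object, ...) {
  print(object, ...)
  cat("\nMost nested configuration (row order):",
      rownames(object$config$matrix), "\n")
  cat("Most nested configuration (col order):",
      colnames(object$config$matrix), "\n")
  invisible(object$table)
}

#' @export
as.data.frame.nested_test <- function(x, ...) {
  x$table
}

#' Histogram of a null ensemble with the observed score
#'
#' @param x a `nested_test` object.
#' @param model,measure which ensemble to plot (defaults: first of each).
#' @param ... passed to [graphics::hist()].
#' @export
plot.nested_test <- function(x, model = x$nulls[1L],
                             measure = x$measures[1L], ...) {
  scores <- x$ensembles[[model]]$scores[[measure]]
  graphics::hist(scores, breaks = 30L,
                 main = sprintf("%s under %s null", measure, model),
                 xlab = measure, ...)
  graphics::abline(v = x$observed[[measure]], col = "red", lwd = 2L)
  invisible(x)
}
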