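#' Write a significance report
#'
#' Serialises the per-(null model, measure) statistics of a nestedness test
#' to TSV or JSON.  Each record carries the observed measure value, the
#' ensemble size, the ensemble mean and standard deviation, the z-score,
#' the p-value (rendered `"<1/N"` when only the conservative bound can be
#' assigned) and the normalised temperature.
#'
#' @param x a `nested_test` object, or a list of `comparison_stats`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`; defaults to the file extension
#'   (`.json` gives JSON, anything else TSV).
#' @return invisibly, `path`.
#' @export
write_report <- function(x, path, format = NULL) {
  stats <- if (inherits(x, "nested_test")) x$stats
           else if (inherits(x, "comparison_stats")) list(x)
           else x
  if (length(stats) == 0L) stop_validation("no statistics to report")
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  format <- match.arg(format, c("tsv", "json"))
  tab <- stats_table(stats)
  ok <- tryCatch({
    if (format == "tsv") {
      out <- tab
      out$p <- out$p_label
      out$p_label <- NULL
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      records <- lapply(stats, function(s) {
        list(null_model = s$model, measure = s$measure,
             observed = s$observed, ensemble_size = s$N, mean = s$mean,
             sd = s$sd, z = s$z, p = s$p, p_is_bound = s$p_is_bound,
             p_label = format_p(s), normalised_temperature = s$T)
      })
      jsonlite::write_json(unname(records), path, auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
    }
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write report to %s", path))
  invisible(path)
}
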