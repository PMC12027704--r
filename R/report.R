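# Orchestration and reporting: one-call chart measurement, multi-device
# comparison tables, and machine-readable run logs.

# Append one JSON line describing a run to `log` (NULL = no logging).
.log_run <- function(log, event, config) {
  if (is.null(log)) return(invisible(NULL))
  line <- jsonlite::toJSON(list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "chromacal",
    version = as.character(utils::packageVersion("chromacal")),
    event = event, config = config), auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = log, append = TRUE)
  invisible(NULL)
}

#' Measure a chart photograph end to end
#'
#' Orchestrates detection, measurement and evaluation: load (or accept) the
#' image, locate the 24 patches, measure them, and compute deviation
#' metrics against the reference chart. Optionally writes the color table
#' CSV, the summary JSON, and a JSON-lines run log sufficient to reproduce
#' the run.
#'
#' @param image file path (PNG/TIFF/JPEG) or an H x W x 3 array.
#' @param reference a `reference_chart`; default the packaged values.
#' @param hint optional 4 x 2 chart corner matrix (see [detect_chart()]).
#' @param exclude patch indices excluded from the summary.
#' @param sensitivity,border_frac,margin,trim passed to [detect_chart()] and
#'   [measure_patches()].
#' @param out_table,out_summary optional output paths (CSV / JSON).
#' @param log optional JSON-lines log file to append to.
#' @return list with `table` and `summary` (as [evaluate_table()]).
#' @export
cmd_measure <- function(image, reference = reference_chart(), hint = NULL,
                        exclude = NULL, sensitivity = 0.7,
                        border_frac = 0.25, margin = 0.25, trim = 0.1,
                        out_table = NULL, out_summary = NULL, log = NULL) {
  path <- if (is.character(image)) image else NA_character_
  if (is.character(image)) image <- read_image(image)
  regions <- detect_chart(image, sensitivity = sensitivity, hint = hint,
                          border_frac = border_frac)
  tab <- measure_patches(image, regions, margin = margin, trim = trim)
  res <- evaluate_table(tab, reference, exclude = exclude)
  if (!is.null(out_table)) write_color_table(res$table, out_table)
  if (!is.null(out_summary)) write_summary_json(res$summary, out_summary)
  .log_run(log, "measure",
           list(image = path, exclude = exclude, sensitivity = sensitivity,
                border_frac = border_frac, margin = margin, trim = trim,
                hint = !is.null(hint),
                out_table = out_table, out_summary = out_summary))
  res
}

#' Device-by-condition comparison table
#'
#' Collects deviation summaries from several runs into one wide table in
#' the layout of a device x lighting-condition comparison: one row per
#' (device, condition) pair, ordered by device then condition, with
#' avg/min/max columns for each of the four metrics. Duplicate
#' (device, condition) keys are an error.
#'
#' @param entries list of `list(device =, condition =, summary =)` where
#'   `summary` is a `deviation_summary`.
#' @param out_csv optional CSV output (full precision).
#' @param out_markdown optional Markdown output (values to one decimal, the
#'   conventional presentation).
#' @return data.frame with columns `device`, `condition`, then
#'   `<metric>_avg`, `<metric>_min`, `<metric>_max` for dE76, dC76, dE00,
#'   dC00.
#' @export
cmd_report <- function(entries, out_csv = NULL, out_markdown = NULL) {
  if (!length(entries)) stop("no summaries to report")
  keys <- vapply(entries, function(e) paste(e$device, e$condition, sep = " / "),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (device, condition) key: ", keys[duplicated(keys)][1])
  rows <- lapply(entries, function(e) {
    s <- e$summary
    stopifnot(inherits(s, "deviation_summary"))
    row <- data.frame(device = e$device, condition = e$condition,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s))) {
      m <- s$metric[i]
      row[[paste0(m, "_avg")]] <- s$avg[i]
      row[[paste0(m, "_min")]] <- s$min[i]
      row[[paste0(m, "_max")]] <- s$max[i]
    }
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$device, out$condition), ]
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  if (!is.null(out_markdown)) {
    num <- vapply(out, is.numeric, TRUE)
    disp <- out
    disp[num] <- lapply(out[num], function(x) sprintf("%.1f", x))
    header <- paste0("| ", paste(names(disp), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
    body <- apply(disp, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), out_markdown)
  }
  out
}
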