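#' Write flow waveforms to CSV
#'
#' Two dialects are supported. Single-segment: comment headers
#' `# rr_s=<float>`, `# artery=<ICA|M1|M3|BA>`, `# side=<L|R|M>` followed by
#' `time_s,flow_ml_s` columns. Long format (when `long = TRUE` or more than
#' one waveform is given): columns
#' `subject_id,artery,side,rr_s,time_s,flow_ml_s`, one block of rows per
#' segment.
#'
#' @param waveforms A [flow_waveform] or a list of them. For long format,
#'   names of the list are used as `subject_id` (default `"S0001"`).
#' @param path Output file path.
#' @param long Force the long multi-segment dialect.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveforms, path, long = NULL) {
  if (is_flow_waveform(waveforms)) waveforms <- list(waveforms)
  if (!length(waveforms) || !all(vapply(waveforms, is_flow_waveform,
                                        logical(1)))) {
    stopf("waveforms must be flow_waveform objects")
  }
  if (is.null(long)) long <- length(waveforms) > 1
  side_code <- c(left = "L", right = "R", midline = "M", unknown = "M")
  if (!long) {
    wf <- waveforms[[1]]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# rr_s=%.17g", wf$rr_interval),
                 sprintf("# artery=%s", wf$artery),
                 sprintf("# side=%s", side_code[[wf$side]]),
                 "time_s,flow_ml_s"), con)
    writeLines(sprintf("%.17g,%.17g", wf$times, wf$flow_rates), con)
    return(invisible(path))
  }
  ids <- names(waveforms)
  if (is.null(ids)) ids <- rep("S0001", length(waveforms))
  ids[ids == ""] <- "S0001"
  rows <- do.call(rbind, lapply(seq_along(waveforms), function(i) {
    wf <- waveforms[[i]]
    data.frame(subject_id = ids[i], artery = wf$artery,
               side = side_code[[wf$side]], rr_s = wf$rr_interval,
               time_s = wf$times, flow_ml_s = wf$flow_rates)
  }))
  write.csv(format(rows, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

decode_side <- c(L = "left", R = "right", M = "midline")

#' Read flow waveforms from CSV
#'
#' Reads either waveform CSV dialect (see [write_waveform_csv()]):
#' comment-headed single-segment files, or long-format files with one
#' [flow_waveform] per `(subject_id, artery, side)` group. Malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return A named list of [flow_waveform] objects (names
#'   `subject.artery.side`).
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    return(read_waveform_csv_headered(path))
  }
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "artery", "side", "rr_s", "time_s", "flow_ml_s")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stopf("long-format waveform CSV missing columns: %s",
          paste(miss, collapse = ", "))
  }
  key <- paste(d$subject_id, d$artery, unname(decode_side[d$side]), sep = ".")
  out <- lapply(split(seq_len(nrow(d)), factor(key, levels = unique(key))),
                function(idx) {
    g <- d[idx, ]
    lines <- idx + 1  # header line offset
    if (length(unique(g$rr_s)) != 1) {
      stopf("inconsistent rr_s within group at lines %s",
            paste(head(lines, 3), collapse = ", "))
    }
    bad <- which(diff(g$time_s) <= 0)
    if (length(bad)) {
      stopf("times not strictly increasing at line %d of %s",
            lines[bad[1] + 1], path)
    }
    flow_waveform(g$time_s, g$flow_ml_s, g$rr_s[1],
                  artery = g$artery[1],
                  side = decode_side[[g$side[1]]])
  })
  out
}

read_waveform_csv_headered <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(paste0("^#\\s*", name, "\\s*="), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    sub(paste0("^#\\s*", name, "\\s*="), "", m[1])
  }
  rr <- get_field("rr_s")
  if (is.null(rr)) stopf("waveform CSV %s lacks the required '# rr_s=' header", path)
  artery <- get_field("artery")
  side <- get_field("side")
  body_start <- length(hdr) + 1
  d <- read.csv(text = paste(lines[body_start:length(lines)], collapse = "\n"),
                stringsAsFactors = FALSE)
  if (!all(c("time_s", "flow_ml_s") %in% names(d))) {
    stopf("waveform CSV %s must have time_s,flow_ml_s columns", path)
  }
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad)) {
    stopf("times not strictly increasing at line %d of %s",
          body_start + bad[1] + 1, path)
  }
  wf <- flow_waveform(d$time_s, d$flow_ml_s, as.numeric(rr),
                      artery = if (is.null(artery)) "ICA" else artery,
                      side = if (is.null(side)) "unknown"
                      else decode_side[[side]])
  setNames(list(wf), paste("S0001", wf$artery, wf$side, sep = "."))
}

#' Write / read a cohort table as CSV
#'
#' One row per subject; the generative-truth attribute is not stored in the
#' CSV (the pipeline writes it as a separate `--truth` JSON sidecar).
#'
#' @param cohort Cohort `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the cohort `data.frame` (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write the generative-truth sidecar
#'
#' @param cohort Cohort with a `"truth"` attribute (from
#'   [generate_cohort()]).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(cohort, path) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stopf("cohort carries no generative truth attribute")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
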