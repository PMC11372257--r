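#' Time-activity curve of one region
#'
#' Per-frame decay-corrected activity concentration for one region of one
#' scan.  Values may be negative (noise in low-uptake regions); they are
#' permitted but flagged with a message.
#'
#' @param region region label.
#' @param schedule the shared [frame_schedule()].
#' @param values numeric vector, one value per frame.
#' @param unit concentration unit, default `"SUV"`.
#' @param aggregation how the regional value was aggregated from voxels:
#'   `"mean"` for organs, `"peak"` for small structures such as lymph nodes.
#' @return An object of class `tac`.
#' @export
tac <- function(region, schedule, values, unit = "SUV",
                aggregation = c("mean", "peak")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != schedule$n)
    stop(sprintf("region '%s': %d values for %d frames", region,
                 length(values), schedule$n))
  if (any(!is.finite(values)))
    stop(sprintf("region '%s': non-finite activity values", region))
  n_neg <- sum(values < 0)
  if (n_neg > 0 && isTRUE(getOption("tbkin.verbose", FALSE)))
    message(sprintf("region '%s': %d negative frame value(s) (noise)",
                    region, n_neg))
  structure(list(region = as.character(region), schedule = schedule,
                 values = values, unit = unit, aggregation = aggregation,
                 n_negative = n_neg),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, %s (%s), range %.4g-%.4g\n",
              x$region, x$schedule$n, x$unit, x$aggregation,
              min(x$values), max(x$values)))
  invisible(x)
}

# blood-pool region labels required in every scan
.BLOOD_REGIONS <- c("aorta", "right_ventricle")

#' One dynamic scan: all regional TACs plus the two blood-pool TACs
#'
#' @param subject subject identifier.
#' @param scan scan identifier (e.g. `"pre"`, `"post"`, `"scan1"`).
#' @param tacs named list of [tac()] objects; must include the two blood-pool
#'   curves `aorta` and `right_ventricle` which drive the kinetic models
#'   (the right-ventricle curve stands in for pulmonary-artery blood and is
#'   used for lungs and lung-tumor subregions).
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(subject, scan, tacs) {
  if (is.null(names(tacs)) || any(names(tacs) == ""))
    names(tacs) <- vapply(tacs, function(t) t$region, character(1))
  missing_blood <- setdiff(.BLOOD_REGIONS, names(tacs))
  if (length(missing_blood))
    stop("scan is missing required blood-pool region(s): ",
         paste(missing_blood, collapse = ", "),
         " (required: ", paste(.BLOOD_REGIONS, collapse = ", "), ")")
  sch <- tacs[[1]]$schedule
  same <- vapply(tacs, function(t) {
    isTRUE(all.equal(t$schedule$start, sch$start)) &&
      isTRUE(all.equal(t$schedule$end, sch$end))
  }, logical(1))
  if (!all(same))
    stop("all TACs of a scan must share one frame schedule")
  structure(list(subject = as.character(subject), scan = as.character(scan),
                 schedule = sch, tacs = tacs),
            class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("Scan %s/%s: %d regions, %d frames (%.3g-%.4g min)\n",
              x$subject, x$scan, length(x$tacs), x$schedule$n,
              x$schedule$start[1], x$schedule$end[x$schedule$n]))
  invisible(x)
}

# Deterministic column order: blood first, then other regions alphabetically.
.region_order <- function(regions) {
  rest <- sort(setdiff(regions, .BLOOD_REGIONS))
  c(.BLOOD_REGIONS, rest)
}

#' Write a scan's TACs to a delimited text table
#'
#' Layout: comment header lines (`# key: value`) carrying unit, subject,
#' scan id and the list of peak-aggregated regions, then columns
#' `frame_start`, `frame_end` (seconds) and one column per region.  Blood
#' columns come first, remaining regions alphabetically, so output is
#' byte-stable across runs.
#'
#' @param scan a [scan_record()].
#' @param path output file path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(scan, path) {
  stopifnot(inherits(scan, "scan_record"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ord <- .region_order(names(scan$tacs))
  peak <- names(scan$tacs)[vapply(scan$tacs, function(t)
    t$aggregation == "peak", logical(1))]
  df <- data.frame(frame_start = scan$schedule$start * 60,
                   frame_end = scan$schedule$end * 60, check.names = FALSE)
  for (r in ord) df[[r]] <- scan$tacs[[r]]$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# unit: %s", scan$tacs[[1]]$unit),
    sprintf("# subject: %s", scan$subject),
    sprintf("# scan: %s", scan$scan),
    sprintf("# peak_regions: %s", paste(sort(peak), collapse = ";"))
  ), con)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TAC table written by [write_tac_table()]
#'
#' @param path file path (CSV or TSV, autodetected).
#' @param schedule optional [frame_schedule()]; when given, the file's frame
#'   times must match it (schema error otherwise).
#' @return A [scan_record()].
#' @export
read_tac_table <- function(path, schedule = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(unit = "SUV", subject = "unknown", scan = "scan1",
               peak_regions = "")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) stop("no data rows in ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- tryCatch(
    read.table(text = body, header = TRUE, sep = sep, check.names = FALSE,
               colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("frame_start", "frame_end")
  if (!all(need %in% names(df)))
    stop("table must have frame_start and frame_end columns")
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) stop("non-numeric column(s): ",
                        paste(names(df)[bad], collapse = ", "))
  sch <- frame_schedule(df$frame_start, df$frame_end, unit = "s")
  if (!is.null(schedule)) {
    if (sch$n != schedule$n ||
        !isTRUE(all.equal(sch$start, schedule$start)) ||
        !isTRUE(all.equal(sch$end, schedule$end)))
      stop("frame schedule of ", path, " does not match the expected schedule")
    sch <- schedule
  }
  regions <- setdiff(names(df), need)
  missing_blood <- setdiff(.BLOOD_REGIONS, regions)
  if (length(missing_blood))
    stop("table is missing required blood-pool region(s): ",
         paste(missing_blood, collapse = ", "),
         " (required: ", paste(.BLOOD_REGIONS, collapse = ", "), ")")
  peak <- strsplit(meta$peak_regions, ";", fixed = TRUE)[[1]]
  tacs <- lapply(regions, function(r)
    tac(r, sch, df[[r]], unit = meta$unit,
        aggregation = if (r %in% peak) "peak" else "mean"))
  names(tacs) <- regions
  scan_record(meta$subject, meta$scan, tacs)
}
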