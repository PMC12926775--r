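# Long-format repeated thickness measurements with day/session/scan structure.
#
# The canonical interchange is one row per scan x unit, where a unit is either
# a named ROI ("core"/"control") or a 0-based vertex index. The mixed model
# consumes these row-level observations directly.

SCAN_TABLE_COLUMNS <- c("participant", "timepoint", "day", "session", "scan",
                        "unit_type", "unit", "thickness_mm", "rmspm")

#' Construct a cluster-scan dataset
#'
#' Validates a long-format table of repeated per-scan cortical thickness
#' measurements and infers the study design (timepoints, days per timepoint,
#' sessions per day, scans per session) from its grouping structure.
#'
#' @param records A data frame with columns `participant`, `timepoint`,
#'   `day` (positive integer), `session` (positive integer, unique within
#'   day), `scan` (identifier, unique within session), `unit_type`
#'   (`"roi"` or `"vertex"`), `unit` (ROI name or 0-based vertex index),
#'   `thickness` (mm, positive) and `motion` (RMS displacement per minute,
#'   mm/min, non-negative; `NA` allowed until motion QC is run).
#' @param timepoint_levels Optional character vector fixing the (strict)
#'   ordering of timepoints; defaults to order of first appearance.
#' @return An object of class `cluster_scan_dataset` with elements `records`
#'   (validated data frame) and `design` (named integer vector
#'   `n_timepoints`, `n_days`, `n_sessions`, `n_scans`).
#' @export
cluster_scan_dataset <- function(records, timepoint_levels = NULL) {
  cs_assert(is.data.frame(records), "records must be a data frame")
  needed <- c("participant", "timepoint", "day", "session", "scan",
              "unit_type", "unit", "thickness", "motion")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    cs_abort("records is missing column(s): %s", paste(missing, collapse = ", "))
  }
  records <- as.data.frame(records)[needed]
  records$participant <- as.character(records$participant)
  if (is.null(timepoint_levels)) {
    timepoint_levels <- unique(as.character(records$timepoint))
  }
  cs_assert(anyDuplicated(timepoint_levels) == 0, "timepoint levels must be distinct")
  records$timepoint <- factor(as.character(records$timepoint), levels = timepoint_levels)
  cs_assert(!anyNA(records$timepoint), "timepoint outside declared levels")
  for (col in c("day", "session")) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 1 | v != round(v))
    if (length(bad) > 0) {
      cs_abort("column '%s' must hold positive integers (first offending row: %d)",
               col, bad[1])
    }
    records[[col]] <- as.integer(v)
  }
  records$scan <- as.character(records$scan)
  records$unit_type <- as.character(records$unit_type)
  bad_type <- which(!records$unit_type %in% c("roi", "vertex"))
  if (length(bad_type) > 0) {
    cs_abort("unit_type must be 'roi' or 'vertex' (first offending row: %d)", bad_type[1])
  }
  records$unit <- as.character(records$unit)
  vert <- records$unit_type == "vertex"
  if (any(vert)) {
    vi <- suppressWarnings(as.numeric(records$unit[vert]))
    bad <- which(!is.finite(vi) | vi < 0 | vi != round(vi))
    if (length(bad) > 0) {
      cs_abort("vertex units must be non-negative integers (first offending row: %d)",
               which(vert)[bad[1]])
    }
  }
  th <- records$thickness
  bad <- which(!is.finite(th) | th <= 0)
  if (length(bad) > 0) {
    cs_abort("thickness must be a positive real (first offending row: %d, value %s)",
             bad[1], format(th[bad[1]]))
  }
  mo <- records$motion
  bad <- which(!is.na(mo) & (!is.finite(mo) | mo < 0))
  if (length(bad) > 0) {
    cs_abort("motion must be non-negative (first offending row: %d)", bad[1])
  }
  key <- do.call(paste, c(records[c("participant", "timepoint", "day", "session",
                                    "scan", "unit_type", "unit")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    cs_abort("duplicate record key at row %d (participant/timepoint/day/session/scan/unit)",
             dup[1])
  }
  design <- infer_design(records)
  structure(list(records = records, design = design), class = "cluster_scan_dataset")
}

infer_design <- function(records) {
  g <- unique(records[c("participant", "timepoint", "day", "session", "scan")])
  n_timepoints <- nlevels(records$timepoint)
  per_tp <- table(unique(g[c("participant", "timepoint", "day")])$timepoint)
  per_day <- stats::aggregate(session ~ participant + timepoint + day,
                              data = unique(g[c("participant", "timepoint", "day", "session")]),
                              FUN = length)$session
  per_sess <- stats::aggregate(scan ~ participant + timepoint + day + session,
                               data = g, FUN = length)$scan
  cs_assert(all(per_sess >= 1), "every (timepoint, day, session) group needs >= 1 scan")
  c(n_timepoints = n_timepoints,
    n_days = as.integer(max(per_tp)),
    n_sessions = as.integer(max(per_day)),
    n_scans = as.integer(max(per_sess)))
}

#' @export
print.cluster_scan_dataset <- function(x, ...) {
  d <- x$design
  cat(sprintf(paste0("Cluster-scan dataset: %d records, %d participant(s)\n",
                     "  design: %d timepoint(s) x %d day(s) x %d session(s) x %d scan(s)\n"),
              nrow(x$records), length(unique(x$records$participant)),
              d["n_timepoints"], d["n_days"], d["n_sessions"], d["n_scans"]))
  cat(sprintf("  timepoints: %s\n", paste(levels(x$records$timepoint), collapse = " < ")))
  invisible(x)
}

#' @export
as.data.frame.cluster_scan_dataset <- function(x, ...) x$records

#' Read a cluster-scan table from CSV/TSV
#'
#' Expects the canonical header
#' `participant,timepoint,day,session,scan,unit_type,unit,thickness_mm,rmspm`.
#' The delimiter is inferred from the file extension (`.tsv` uses tabs).
#'
#' @param path Path to the file.
#' @param timepoint_levels Optional explicit timepoint ordering.
#' @return A [cluster_scan_dataset()].
#' @export
read_scan_table <- function(path, timepoint_levels = NULL) {
  cs_assert(file.exists(path), "scan table not found: %s", path)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing <- setdiff(SCAN_TABLE_COLUMNS, names(tab))
  if (length(missing) > 0) {
    cs_abort("scan table %s is missing column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  records <- data.frame(
    participant = tab$participant,
    timepoint = tab$timepoint,
    day = suppressWarnings(as.numeric(tab$day)),
    session = suppressWarnings(as.numeric(tab$session)),
    scan = tab$scan,
    unit_type = tab$unit_type,
    unit = tab$unit,
    thickness = suppressWarnings(as.numeric(tab$thickness_mm)),
    motion = suppressWarnings(as.numeric(tab$rmspm)),
    stringsAsFactors = FALSE
  )
  cluster_scan_dataset(records, timepoint_levels = timepoint_levels)
}

#' Write a cluster-scan dataset to CSV/TSV
#'
#' Inverse of [read_scan_table()]; a write-then-read round trip reproduces
#' the records exactly.
#'
#' @param dataset A `cluster_scan_dataset`.
#' @param path Output path (`.tsv` for tab-separated).
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(dataset, path) {
  cs_assert(inherits(dataset, "cluster_scan_dataset"),
            "dataset must be a cluster_scan_dataset")
  r <- dataset$records
  out <- data.frame(
    participant = r$participant,
    timepoint = as.character(r$timepoint),
    day = r$day,
    session = r$session,
    scan = r$scan,
    unit_type = r$unit_type,
    unit = r$unit,
    thickness_mm = sprintf("%.17g", r$thickness),
    rmspm = ifelse(is.na(r$motion), "NA", sprintf("%.17g", r$motion)),
    stringsAsFactors = FALSE
  )
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
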