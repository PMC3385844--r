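# Cohort CSV format: a small header block of '# key: value' comment lines
# (schema version, normalisation range, generation seed when synthetic)
# followed by one row per subject x time point.

.cohort_schema_version <- 1L

#' Write a cohort to CSV
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)
  if (any(df$F < 0 | df$F > 1 | df$U < 0 | df$U > 1)) {
    stop("refusing to write F or U outside [0, 1]")
  }
  header <- c(sprintf("# armdyn_cohort: %d", .cohort_schema_version))
  for (key in c("neglog_min", "neglog_max")) {
    v <- attr(x, key)
    if (!is.null(v)) header <- c(header, sprintf("# %s: %.17g", key, v))
  }
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    header <- c(header,
                sprintf("# seed: %d", cfg$seed),
                sprintf("# generator: %s + %s, noise_sd %.17g",
                        cfg$function_id, cfg$use_id, cfg$noise_sd))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  df$F <- sprintf("%.17g", df$F)
  df$U <- sprintf("%.17g", df$U)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    out[[key]] <- val
  }
  out
}

#' Read a cohort from CSV
#'
#' Validates the schema, rejects out-of-range values with a row-addressed
#' error, and excludes (with a message) subjects whose series do not have
#' the full complement of points for their group and phase -- only
#' complete series enter the analysis.
#'
#' @param path Path written by [write_cohort()].
#' @return A `cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- .parse_header(path)
  if (is.null(hdr$armdyn_cohort)) stop("not an armdyn cohort file: ", path)
  if (as.integer(hdr$armdyn_cohort) != .cohort_schema_version) {
    stop("unrecognised cohort schema version: ", hdr$armdyn_cohort)
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "phase", "time_months", "F", "U")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("F", "U")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad) > 0L) {
      stop(sprintf("row %d: column %s = %g outside [0, 1]",
                   bad[1], col, df[[col]][bad[1]]))
    }
  }
  if (!all(df$group %in% c("immediate", "delayed"))) {
    stop("'group' must be 'immediate' or 'delayed'")
  }
  if (!all(df$phase %in% c("pre", "post"))) {
    stop("'phase' must be 'pre' or 'post'")
  }
  series <- list()
  keyv <- paste(df$subject_id, df$phase, sep = "|")
  for (key in unique(keyv)) {
    sub <- df[keyv == key, , drop = FALSE]
    sub <- sub[order(sub$time_months), , drop = FALSE]
    expected <- if (sub$group[1] == "immediate") 7L else 4L
    ok <- nrow(sub) == expected &&
      all(abs(diff(sub$time_months) - 4) < 1e-9) &&
      !anyDuplicated(sub$time_months)
    if (!ok) {
      message(sprintf(
        "subject %s (%s phase) excluded: %d point(s), expected %d on the 4-month grid",
        sub$subject_id[1], sub$phase[1], nrow(sub), expected))
      next
    }
    series[[length(series) + 1L]] <- subject_series(
      sub$subject_id[1], sub$group[1], sub$phase[1],
      times = sub$time_months - sub$time_months[1], F = sub$F, U = sub$U)
  }
  nl_min <- if (!is.null(hdr$neglog_min)) as.numeric(hdr$neglog_min) else NULL
  nl_max <- if (!is.null(hdr$neglog_max)) as.numeric(hdr$neglog_max) else NULL
  cohort(series, neglog_min = nl_min, neglog_max = nl_max)
}
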