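#' Read an umbrella-sampling dataset in the WHAM metadata dialect
#'
#' The metadata file has one whitespace-delimited record per window:
#' `timeseries_path center spring [correl_time [temperature]]`, with
#' `#` comments; each timeseries file holds `time value` columns.
#' Relative timeseries paths are resolved against the metadata file's
#' directory. Spring constants are converted to the internal half
#' convention (`U = (k/2)(z - z0)^2`) according to the declared source
#' convention; files written for the reference WHAM implementation use
#' the half convention, while restraint constants quoted in AMBER input
#' conventions are `full` (`U = k (z - z0)^2`).
#'
#' @param path Metadata file path.
#' @param convention Convention of the spring constants in the file.
#' @return List with `schedule` ([window_schedule()], half convention)
#'   and `series` (list of [trajectory_series()]).
#' @export
read_wham_metadata <- function(path, convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (!file.exists(path)) stop("metadata file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("metadata file has no records: ", path)
  base <- dirname(path)
  windows <- list()
  series <- list()
  for (li in seq_along(lines)) {
    tok <- strsplit(lines[li], "[[:space:]]+")[[1]]
    if (length(tok) < 3L) {
      stop(sprintf("malformed metadata line %d: '%s'", li, lines[li]))
    }
    center <- suppressWarnings(as.numeric(tok[2]))
    k <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(center) || is.na(k)) {
      stop(sprintf("malformed metadata line %d: '%s'", li, lines[li]))
    }
    ts_path <- tok[1]
    if (!file.exists(ts_path)) ts_path <- file.path(base, tok[1])
    if (!file.exists(ts_path)) {
      stop(sprintf("timeseries file for window at z = %g not found: %s",
                   center, tok[1]))
    }
    d <- read.table(ts_path, comment.char = "#",
                    col.names = c("time", "value"))
    if (nrow(d) < 2L) stop("timeseries too short: ", ts_path)
    dts <- diff(d$time)
    if (any(dts <= 0)) {
      stop("non-monotonic time column in ", ts_path)
    }
    k_internal <- if (convention == "half") k else 2 * k
    windows[[length(windows) + 1L]] <-
      umbrella_window(center, k_internal, "half")
    series[[length(series) + 1L]] <-
      trajectory_series(d$value, dt = dts[1], t0 = d$time[1])
  }
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  list(schedule = window_schedule(windows[ord]), series = series[ord])
}

#' Write an umbrella-sampling dataset in the WHAM metadata dialect
#'
#' Inverse of [read_wham_metadata()]: writes one timeseries file per
#' window plus the metadata index, so the dataset can also drive the
#' reference WHAM implementation directly.
#'
#' @param schedule A [window_schedule()].
#' @param series List of [trajectory_series()], one per window.
#' @param dir Output directory (created if needed).
#' @param convention Spring-constant convention to write.
#' @param prefix Timeseries filename prefix.
#' @return The metadata file path, invisibly.
#' @export
write_wham_metadata <- function(schedule, series, dir,
                                convention = c("half", "full"),
                                prefix = "window") {
  convention <- match.arg(convention)
  stopifnot(inherits(schedule, "window_schedule"),
            length(series) == length(schedule))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "metadata.txt")
  recs <- character(length(schedule))
  for (w in seq_along(schedule$windows)) {
    win <- schedule$windows[[w]]
    ts_name <- sprintf("%s_%02d.txt", prefix, w)
    s <- series[[w]]
    t <- s$t0 + s$dt * (seq_along(s$values) - 1L)
    writeLines(
      c("# time[ps] z[A]",
        sprintf("%.6g %.10g", t, s$values)),
      file.path(dir, ts_name))
    k_out <- if (convention == "half") k_half(win) else k_half(win) / 2
    recs[w] <- sprintf("%s %.10g %.10g", ts_name, win$center, k_out)
  }
  writeLines(c(sprintf("# WHAM metadata (%s convention)", convention),
               recs), meta_path)
  invisible(meta_path)
}

#' Write a profile as a headered TSV
#'
#' @param p A [profile()].
#' @param path Output path.
#' @param what Short description put in the header.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(p, path, what = "profile") {
  stopifnot(inherits(p, "profile"))
  meta <- p$meta
  hdr <- c(sprintf("# %s", what),
           sprintf("# grid units: %s; value units: %s", p$grid_units,
                   p$units))
  if (length(meta)) {
    keep <- vapply(meta, function(m) is.atomic(m) && length(m) == 1,
                   logical(1))
    hdr <- c(hdr, sprintf("# %s: %s", names(meta)[keep],
                          unlist(meta[keep])))
  }
  d <- as.data.frame(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(d), collapse = "\t"), con)
  write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a profile written by [write_profile_tsv()]
#'
#' @param path TSV path.
#' @return A [profile()].
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  profile(d$grid, d$value,
          stderr = if ("stderr" %in% names(d)) d$stderr else NULL)
}

#' Write a permeability result as JSON
#'
#' @param result A [predict_permeability()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_permeability_json <- function(result, path) {
  stopifnot(inherits(result, "permeability_result"))
  out <- unclass(result)
  out$units <- "cm/s"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
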