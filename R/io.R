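#' Read one-cycle marker trajectories from a TRC or CSV file
#'
#' TRC dialect: the standard tab-separated motion-capture header (DataRate
#' line, marker labels with X/Y/Z sub-columns); the two configured axes carry
#' the planar data and millimeter units are converted via the header's
#' `Units` field. CSV dialect: one row per sample with a header of
#' `<marker>_x,<marker>_y` columns and an optional leading `time` column.
#' Timestamps, when present, must be uniform to 1e-6 s; the cycle period is
#' inferred as `N * dt`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"trc"`, or `"csv"`.
#' @param topology optional [linkage_topology()]; when given, the file must
#'   contain both markers of every link (missing ones are named in the
#'   error).
#' @param axes which two TRC axes hold the planar data (default X and Y).
#' @param period cycle duration override in seconds (needed for CSV files
#'   without a time column when derivatives will be taken).
#' @return a [marker_set()]; its grid carries the inferred period.
#' @export
read_markers <- function(path, format = c("auto", "trc", "csv"),
                         topology = NULL, axes = c("X", "Y"), period = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_markers: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  out <- if (format == "trc") read_trc(path, axes) else read_csv_markers(path)
  if (!is.null(period)) out$grid$period <- period
  marker_set(out$m, out$grid, topology)
}

check_uniform_time <- function(tm, tol = 1e-6) {
  if (length(tm) < 2) return(NULL)
  dt <- diff(tm)
  if (max(abs(dt - dt[1])) > tol)
    stop("read_markers: non-uniform timestamps (tolerance 1e-6 s)")
  dt[1]
}

read_trc <- function(path, axes) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("read_markers: truncated TRC file")
  hdr_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_keys)
  units <- if (!is.null(hdr$Units)) hdr$Units else "m"
  scale <- switch(tolower(units), mm = 1e-3, m = 1,
                  stop("read_markers: unsupported TRC Units: ", units))
  labels <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- labels[-(1:2)]
  labels <- labels[labels != ""]
  sub <- strsplit(lines[5], "\t", fixed = TRUE)[[1]][-(1:2)]
  axis_of <- toupper(substr(sub, 1, 1))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(strsplit(data_lines, "\t", fixed = TRUE),
                 function(x) suppressWarnings(as.numeric(x)))
  ncols <- 2 + 3 * length(labels)
  if (any(vapply(rows, length, 1L) < ncols))
    stop("read_markers: ragged TRC data rows (expected ", ncols, " columns)")
  dat <- do.call(rbind, lapply(rows, function(x) x[seq_len(ncols)]))
  dt <- check_uniform_time(dat[, 2])
  N <- nrow(dat)
  m <- list()
  for (i in seq_along(labels)) {
    cols <- 2 + (i - 1) * 3 + 1:3
    ax <- axis_of[(i - 1) * 3 + 1:3]
    ix <- cols[match(toupper(axes), ax)]
    if (any(is.na(ix)))
      stop("read_markers: TRC axes ", paste(axes, collapse = "/"),
           " not present for marker ", labels[i])
    m[[labels[i]]] <- dat[, ix] * scale
  }
  list(m = m, grid = cycle_grid(N, period = if (!is.null(dt)) N * dt))
}

read_csv_markers <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE)
  nm <- names(dat)
  tm <- NULL
  if (tolower(nm[1]) == "time") { tm <- dat[[1]]; dat <- dat[-1]; nm <- nm[-1] }
  xs <- grep("_x$", nm, value = TRUE)
  m <- list()
  for (cx in xs) {
    lab <- sub("_x$", "", cx)
    cy <- paste0(lab, "_y")
    if (!cy %in% nm) stop("read_markers: column ", cy, " missing for marker ", lab)
    m[[lab]] <- cbind(dat[[cx]], dat[[cy]])
  }
  if (!length(m)) stop("read_markers: no <marker>_x/<marker>_y columns found")
  dt <- if (!is.null(tm)) check_uniform_time(tm)
  N <- nrow(dat)
  list(m = m, grid = cycle_grid(N, period = if (!is.null(dt)) N * dt))
}

#' Write marker trajectories to a TRC or CSV file
#'
#' Inverse of [read_markers()]; round trips are lossless to full printed
#' precision. TRC output places the planar data on the two configured axes
#' and zeros on the third; units are meters.
#'
#' @param markers a [marker_set()].
#' @param path output path.
#' @param format `"auto"` (by extension), `"trc"`, or `"csv"`.
#' @param axes which two TRC axes receive the planar data.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, format = c("auto", "trc", "csv"),
                          axes = c("X", "Y")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  N <- markers$grid$N
  period <- if (!is.null(markers$grid$period)) markers$grid$period else N / 100
  tm <- (seq_len(N) - 1) * period / N
  rate <- N / period
  labs <- names(markers$m)
  if (format == "csv") {
    cols <- c(list(time = tm),
              stats::setNames(
                unlist(lapply(markers$m, function(x) list(x[, 1], x[, 2])),
                       recursive = FALSE),
                as.vector(rbind(paste0(labs, "_x"), paste0(labs, "_y")))))
    utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                     row.names = FALSE)
    return(invisible(path))
  }
  third <- setdiff(c("X", "Y", "Z"), toupper(axes))[1]
  ax_order <- c("X", "Y", "Z")
  hdr <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(format(rate), format(rate), N, length(labs), "m",
          format(rate), 1, N, sep = "\t"),
    paste(c("Frame#", "Time",
            as.vector(rbind(labs, "", ""))), collapse = "\t"),
    paste(c("", "",
            as.vector(vapply(seq_along(labs),
                             function(i) paste0(ax_order, i), character(3)))),
          collapse = "\t"))
  body <- vapply(seq_len(N), function(n) {
    vals <- unlist(lapply(markers$m, function(x) {
      v <- c(0, 0, 0)
      names(v) <- ax_order
      v[toupper(axes)] <- x[n, ]
      v
    }))
    paste(c(n, format(tm[n], digits = 17),
            format(vals, digits = 17, trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
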