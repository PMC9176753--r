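# Plate data model: the three-table structure (raw / processed / summary),
# parsing of the documented plate-reader dialect and contents grids, well
# exclusion, the plate diagnostic plot, exports, and the run log.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' All 96 canonical well identifiers ("A1".."H12")
#' @return Character vector of length 96.
#' @export
well_ids <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

.check_wells <- function(wells) {
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", wells)
  if (!all(ok)) stop("invalid well id(s): ", paste(wells[!ok], collapse = ", "),
                     call. = FALSE)
  invisible(wells)
}

.log_line <- function(op, params) {
  ptxt <- if (length(params))
    paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), ""), sep = "=", collapse = " ")
  else ""
  sprintf("%s %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), op, ptxt)
}

.append_log <- function(ds, op, params = list()) {
  ds$log <- c(ds$log, .log_line(op, params))
  ds
}

#' Parse a plate contents grid
#'
#' The contents file is an 8 x 12 grid (CSV or TSV), one cell per well, with
#' optional "A".."H" row labels and "1".."12" column headers. Each non-empty
#' cell reads \code{"STRAIN in CONDITION"}; the strain label \code{"null"}
#' marks a media-only well used for blank correction; an empty cell marks an
#' unused well.
#'
#' @param path Path to the grid file.
#' @return A data frame with columns \code{well}, \code{strain},
#'   \code{condition} covering the mapped wells only.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop("contents file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  cells <- lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]]))
  # optional header row of column numbers
  if (length(cells) && all(grepl("^[0-9]*$", cells[[1]][-1])) &&
      !grepl(" in ", paste(cells[[1]], collapse = " ")))
    cells <- cells[-1]
  has_rowlab <- all(vapply(cells, function(r) r[1] %in% PLATE_ROWS, TRUE))
  grid <- lapply(cells, function(r) {
    if (has_rowlab) r <- r[-1]
    length(r) <- 12L   # pad trailing empties
    r[is.na(r)] <- ""
    r
  })
  if (length(grid) != 8L)
    stop("contents grid must have 8 rows (got ", length(grid), ")")
  widths <- lengths(lapply(cells, function(r) if (has_rowlab) r[-1] else r))
  if (any(widths > 12L))
    stop("contents grid must have 12 columns (got ", max(widths), ")")
  out <- list()
  for (i in 1:8) for (j in 1:12) {
    cell <- grid[[i]][j]
    if (!nzchar(cell)) next
    m <- regmatches(cell, regexec("^(.*?)\\s+in\\s+(.*)$", cell))[[1]]
    if (length(m) != 3)
      stop("cannot parse contents cell '", cell, "' at well ",
           PLATE_ROWS[i], j, "; expected 'STRAIN in CONDITION'")
    out[[length(out) + 1L]] <- data.frame(
      well = paste0(PLATE_ROWS[i], j), strain = m[2], condition = m[3],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("contents grid maps no wells")
  do.call(rbind, out)
}

# time header token -> factor converting to hours
.time_factor <- function(token) {
  switch(tolower(token),
         "time_h" = 1, "time_hr" = 1, "time_hours" = 1,
         "time_min" = 1 / 60, "time_m" = 1 / 60,
         "time_s" = 1 / 3600, "time_sec" = 1 / 3600,
         stop("unrecognised time header '", token,
              "'; expected time_h, time_min or time_s"))
}

#' Read a plate-reader export in the documented block dialect
#'
#' The file holds one block per signal. A block starts with a header line
#' giving the signal name (optionally followed by wavelength annotation after
#' a separator), then a time row (\code{time_h}, \code{time_min} or
#' \code{time_s}, auto-converted to hours), then one row per well:
#' the well id followed by the readings.
#'
#' @param path Path to the data file.
#' @return Long data frame with columns \code{well}, \code{time} (hours),
#'   \code{signal}, \code{value}.
#' @export
read_plate_data <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    header <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
    signal <- trimws(header[1])
    i <- i + 1L
    if (i > length(lines)) stop("truncated block for signal ", signal)
    trow <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
    times <- as.numeric(trow[-1]) * .time_factor(trow[1])
    i <- i + 1L
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      r <- trimws(strsplit(lines[i], sep, fixed = TRUE)[[1]])
      well <- r[1]
      .check_wells(well)
      vals <- as.numeric(r[-1])
      if (length(vals) != length(times))
        stop("well ", well, " in block ", signal, " has ", length(vals),
             " readings for ", length(times), " times")
      out[[length(out) + 1L]] <- data.frame(
        well = well, time = times, signal = signal, value = vals,
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (!length(out)) stop("no data blocks found in ", path)
  do.call(rbind, out)
}

#' Assemble a plate dataset programmatically
#'
#' Builds the same annotated structure as [load_plate()] from an in-memory
#' long table -- the route for data from readers the package does not parse.
#'
#' @param data Data frame with columns \code{well}, \code{time} (hours),
#'   \code{signal}, \code{value}, and either \code{strain}/\code{condition}
#'   columns or a \code{map} to join them from.
#' @param map Optional data frame (\code{well}, \code{strain},
#'   \code{condition}).
#' @param experiment Experiment label (ignored when \code{data} already has
#'   an \code{experiment} column).
#' @return An object of class \code{"plate_dataset"}.
#' @export
plate_dataset <- function(data, map = NULL, experiment = "exp1") {
  stopifnot(is.data.frame(data),
            all(c("well", "time", "signal", "value") %in% names(data)))
  .check_wells(unique(data$well))
  if (!"experiment" %in% names(data)) data$experiment <- experiment
  if (!all(c("strain", "condition") %in% names(data))) {
    if (is.null(map)) stop("need strain/condition columns or a map")
    data <- merge(data, map, by = "well", sort = FALSE)
  }
  if (is.null(map))
    map <- unique(data[c("well", "strain", "condition")])
  dup <- duplicated(data[c("experiment", "well", "signal", "time")])
  if (any(dup))
    stop("duplicate timepoints for well(s) ",
         paste(unique(data$well[dup]), collapse = ", "))
  data <- data[order(data$experiment, data$signal, data$well, data$time),
               c("experiment", "well", "strain", "condition",
                 "time", "signal", "value")]
  rownames(data) <- NULL
  ds <- structure(list(raw = data, data = data, map = map,
                       summary = NULL, ignored = character(),
                       flags = list(media_corrected = FALSE,
                                    od_corrected = FALSE,
                                    auto_corrected = FALSE),
                       log = character()),
                  class = "plate_dataset")
  .append_log(ds, "plate_dataset",
              list(experiment = unique(data$experiment)))
}

#' Load a plate-reader run into an annotated dataset
#'
#' Builds the three-table structure: the raw table keeps the values exactly
#' as loaded, the processed table starts as a copy and is transformed by the
#' correction steps, and a summary table is attached later by
#' [get_growth_stats()]. Wells present in the data but absent from the
#' contents map are dropped with a warning.
#'
#' @param data_file Plate-reader export (see [read_plate_data()]).
#' @param contents_file Contents grid (see [read_plate_map()]).
#' @param experiment Label identifying this run.
#' @return An object of class \code{"plate_dataset"}.
#' @export
load_plate <- function(data_file, contents_file, experiment = "exp1") {
  map <- read_plate_map(contents_file)
  dat <- read_plate_data(data_file)

  dup <- duplicated(dat[c("well", "signal", "time")])
  if (any(dup))
    stop("duplicate timepoints for well(s) ",
         paste(unique(dat$well[dup]), collapse = ", "),
         "; duplicate readings indicate an instrument fault")
  for (key in split(dat, list(dat$well, dat$signal), drop = TRUE)) {
    if (is.unsorted(key$time, strictly = TRUE))
      stop("non-monotone times for well ", key$well[1],
           " signal ", key$signal[1])
  }

  unknown <- setdiff(unique(dat$well), map$well)
  if (length(unknown)) {
    warning("dropping wells absent from the contents map: ",
            paste(unknown, collapse = ", "))
    dat <- dat[!dat$well %in% unknown, ]
  }
  dat <- merge(dat, map, by = "well", sort = FALSE)
  dat <- dat[order(dat$signal, dat$well, dat$time), ]
  dat$experiment <- experiment
  dat <- dat[c("experiment", "well", "strain", "condition",
               "time", "signal", "value")]
  rownames(dat) <- NULL

  ds <- structure(list(raw = dat, data = dat, map = map,
                       summary = NULL, ignored = character(),
                       flags = list(media_corrected = FALSE,
                                    od_corrected = FALSE,
                                    auto_corrected = FALSE),
                       log = character()),
                  class = "plate_dataset")
  .append_log(ds, "load_plate",
              list(data_file = data_file, contents_file = contents_file,
                   experiment = experiment))
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat("plate_dataset:", length(unique(x$data$experiment)), "experiment(s),",
      length(unique(x$data$well)), "wells,",
      length(unique(x$data$signal)), "signals,",
      nrow(x$data), "processed rows\n")
  cat("  strains:   ", paste(unique(x$map$strain), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$map$condition), collapse = ", "), "\n")
  fl <- x$flags
  cat("  corrections: media=", fl$media_corrected, " od=", fl$od_corrected,
      " autofluorescence=", fl$auto_corrected, "\n", sep = "")
  if (length(x$ignored))
    cat("  ignored wells:", paste(x$ignored, collapse = ", "), "\n")
  if (!is.null(x$summary))
    cat("  summary table:", nrow(x$summary), "rows\n")
  invisible(x)
}

#' Remove corrupted wells from the analysis
#'
#' Drops all rows for the listed wells from the processed table (the raw
#' table is untouched) across every signal. Idempotent: ignoring a well twice
#' equals ignoring it once.
#'
#' @param ds A \code{plate_dataset}.
#' @param wells Character vector of well ids, e.g. \code{c("B3", "C7")}.
#' @return The modified dataset.
#' @export
ignore_wells <- function(ds, wells) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (!length(wells)) return(ds)
  .check_wells(wells)
  absent <- setdiff(wells, unique(ds$data$well))
  if (length(absent))
    warning("well(s) not present, nothing to ignore: ",
            paste(absent, collapse = ", "))
  ds$data <- ds$data[!ds$data$well %in% wells, ]
  ds$ignored <- sort(union(ds$ignored, wells))
  .append_log(ds, "ignore_wells", list(wells = wells))
}

#' Diagnostic plot of every well in plate layout
#'
#' Draws the chosen signal for all wells as an 8 x 12 grid of small traces so
#' corrupted wells (condensation, contamination) can be spotted by eye.
#' Media-only wells ("null" strain) get their own y-scale, since their signal
#' is far below that of growing cultures. Panels for ignored or unused wells
#' are left blank.
#'
#' @param ds A \code{plate_dataset}.
#' @param signal Signal name to plot (e.g. \code{"OD"}).
#' @return Invisibly, a list describing the panels drawn.
#' @export
plot_plate <- function(ds, signal = "OD") {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data[ds$data$signal == signal, ]
  if (!nrow(d)) stop("unknown signal '", signal, "'")
  media <- unique(d$well[d$strain == "null"])
  cells <- d[d$strain != "null", ]
  ycell <- if (nrow(cells)) range(cells$value) else c(0, 1)
  ymedia <- if (length(media)) range(d$value[d$well %in% media]) else ycell
  op <- graphics::par(mfrow = c(8, 12), mar = c(0.3, 0.3, 0.8, 0.3),
                      oma = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  drawn <- character()
  for (row in PLATE_ROWS) for (col in PLATE_COLS) {
    w <- paste0(row, col)
    wd <- d[d$well == w, ]
    if (!nrow(wd)) {
      graphics::plot.new()
      graphics::title(main = w, cex.main = 0.6, line = 0.1)
      next
    }
    ylim <- if (w %in% media) ymedia else ycell
    graphics::plot(wd$time, wd$value, type = "l", axes = FALSE, ylim = ylim,
                   xlab = "", ylab = "",
                   col = if (w %in% media) "grey40" else "steelblue")
    graphics::box(col = "grey70")
    graphics::title(main = w, cex.main = 0.6, line = 0.1)
    drawn <- c(drawn, w)
  }
  graphics::mtext(signal, outer = TRUE, cex = 0.9)
  invisible(list(signal = signal, wells = drawn, media_wells = media))
}

.fmt_num <- function(x) sprintf("%.17g", x)

.write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Export a dataset's tables
#'
#' Writes the raw, processed and (when present) summary tables. Formats:
#' \describe{
#'   \item{\code{"tsv"}}{tidy tab-separated text, one file per table,
#'     full numeric precision (lossless round trip via [import_dataset()]).}
#'   \item{\code{"json"}}{a single JSON document with one record array per
#'     table, full precision.}
#'   \item{\code{"csv-workbook"}}{a directory of CSV files, one per table --
#'     a spreadsheet-style workbook in plain text.}
#' }
#'
#' @param ds A non-empty \code{plate_dataset}.
#' @param path Output stem: \code{<path>_raw.tsv} etc. for \code{"tsv"},
#'   \code{<path>.json} for \code{"json"}, directory \code{<path>} for
#'   \code{"csv-workbook"}.
#' @param format One of \code{"tsv"}, \code{"json"}, \code{"csv-workbook"}.
#' @return Invisibly, the paths written.
#' @export
export_dataset <- function(ds, path, format = c("tsv", "json", "csv-workbook")) {
  stopifnot(inherits(ds, "plate_dataset"))
  format <- match.arg(format)
  if (!nrow(ds$data)) stop("dataset is empty; nothing to export")
  tables <- list(raw = ds$raw, processed = ds$data)
  if (!is.null(ds$summary)) tables$summary <- ds$summary
  written <- character()
  if (format == "tsv") {
    for (nm in names(tables)) {
      f <- paste0(path, "_", nm, ".tsv")
      .write_table_tsv(tables[[nm]], f)
      written <- c(written, f)
    }
  } else if (format == "json") {
    f <- paste0(path, ".json")
    jsonlite::write_json(tables, f, dataframe = "rows", digits = I(17),
                         na = "null")
    written <- f
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables)) {
      f <- file.path(path, paste0(nm, ".csv"))
      num <- vapply(tables[[nm]], is.numeric, TRUE)
      tb <- tables[[nm]]
      for (j in which(num)) tb[[j]] <- .fmt_num(tb[[j]])
      utils::write.csv(tb, f, row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Re-import tables written by [export_dataset()]
#'
#' @param path The stem or file given to [export_dataset()].
#' @param format \code{"tsv"} or \code{"json"}.
#' @return A list of data frames (\code{raw}, \code{processed}, and
#'   \code{summary} when it was exported).
#' @export
import_dataset <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- list()
    for (nm in c("raw", "processed", "summary")) {
      f <- paste0(path, "_", nm, ".tsv")
      if (file.exists(f))
        out[[nm]] <- utils::read.table(f, sep = "\t", header = TRUE,
                                       stringsAsFactors = FALSE)
    }
    out
  } else {
    lapply(jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE),
           as.data.frame)
  }
}

#' Write the run log
#'
#' Every analysis call on the dataset is recorded with its timestamp and
#' parameters, one line per call, and exported as plain text for
#' reproducibility.
#'
#' @param ds A \code{plate_dataset}.
#' @param path Output text file.
#' @return Invisibly, \code{path}.
#' @export
write_run_log <- function(ds, path) {
  stopifnot(inherits(ds, "plate_dataset"))
  writeLines(ds$log, path)
  invisible(path)
}
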