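# OD calibration: map measured OD onto a quantity proportional to cell number.
#
# Plate readers under-report OD at high density because multiply scattered
# light escapes the detector. A dilution series of a dense culture gives
# (measured OD, expected OD = dilution factor x reference OD) pairs; a GP
# through these pairs, rescaled to agree with the measurement at OD 0.3,
# defines the correction curve.

#' Read a dilution-series calibration file
#'
#' Two whitespace- or comma-separated columns: measured OD, dilution factor.
#' Lines starting with '#' are comments.
#'
#' @param path Path to the file.
#' @return Data frame with columns \code{measured}, \code{dilution}.
#' @export
read_dilution_series <- function(path) {
  if (!file.exists(path)) stop("dilution series file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "[, \t]+")[[1]]))
  if (any(lengths(parts) != 2) || anyNA(unlist(parts)))
    stop("dilution series must have two numeric columns ",
         "(measured OD, dilution factor)")
  m <- do.call(rbind, parts)
  data.frame(measured = m[, 1], dilution = m[, 2])
}

.check_dilution_series <- function(series) {
  if (!is.data.frame(series) || !all(c("measured", "dilution") %in% names(series)))
    series <- data.frame(measured = series[[1]], dilution = series[[2]])
  if (nrow(series) < 5)
    stop("insufficient data: a dilution series needs at least 5 points")
  if (any(series$measured <= 0) || any(series$dilution <= 0) ||
      any(series$dilution > 1))
    stop("measured ODs must be positive and dilution factors in (0, 1]")
  if (length(unique(series$dilution)) < 2 ||
      stats::sd(series$measured) < 1e-12)
    stop("degenerate dilution series: measurements carry no dilution signal")
  if (stats::cor(series$measured, series$dilution, method = "spearman") <= 0)
    stop("degenerate dilution series: measured OD does not increase ",
         "with dilution factor")
  series
}

#' Fit an OD calibration curve from a dilution series
#'
#' A squared-exponential GP is fitted with measured OD as input and expected
#' OD (dilution factor times the reference-culture OD, arbitrary units) as
#' target. The posterior mean, evaluated on a dense grid and projected onto
#' the monotone cone (isotonic regression), is rescaled by a single constant
#' so that corrected and measured OD agree at 0.3 -- removing the arbitrary
#' unit of the reference culture while restoring linearity at low OD.
#' Outside the calibrated range the curve continues linearly: through the
#' origin below, and with the terminal slope above.
#'
#' @param series Data frame from [read_dilution_series()] or
#'   [generate_dilution_series()] (>= 5 points).
#' @param anchor OD at which corrected equals measured (default 0.3).
#' @param grid_n Evaluation grid size for the monotone projection.
#' @param restarts,seed Passed to [fit_gp()].
#' @return An object of class \code{"calibration_curve"}; evaluate it with
#'   \code{predict(curve, od)}.
#' @export
fit_calibration <- function(series, anchor = 0.3, grid_n = 512,
                            restarts = 5, seed = 0) {
  series <- .check_dilution_series(series)
  expected <- series$dilution  # reference OD = 1 arbitrary unit
  fit <- fit_gp(series$measured, expected, kernel = "se",
                restarts = restarts, seed = seed)
  lo <- min(series$measured); hi <- max(series$measured)
  grid <- seq(lo, hi, length.out = grid_n)
  mu <- gp_posterior(fit, grid)$mean
  iso <- stats::isoreg(grid, mu)$yf      # monotone projection
  curve <- structure(list(grid = grid, value = iso, lo = lo, hi = hi,
                          anchor = anchor, scale = 1, gp = fit,
                          series = series),
                     class = "calibration_curve")
  raw_at_anchor <- .cal_eval(curve, anchor)
  if (!is.finite(raw_at_anchor) || raw_at_anchor <= 0)
    stop("degenerate fit: calibration curve is not positive at the anchor")
  curve$scale <- anchor / raw_at_anchor
  curve$value <- curve$value * curve$scale
  curve
}

# evaluate on [0, Inf): linear through origin below range, terminal slope above
.cal_eval <- function(curve, x) {
  g <- curve$grid; v <- curve$value
  y <- numeric(length(x))
  inr <- x >= curve$lo & x <= curve$hi
  if (any(inr)) y[inr] <- stats::approx(g, v, xout = x[inr])$y
  below <- x < curve$lo
  if (any(below)) y[below] <- x[below] * (v[1] / g[1])
  above <- x > curve$hi
  if (any(above)) {
    n <- length(g)
    slope <- (v[n] - v[n - 1]) / (g[n] - g[n - 1])
    y[above] <- v[n] + slope * (x[above] - g[n])
  }
  y
}

#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  # negative inputs (media-corrected blanks fluctuating around zero) fall on
  # the through-origin linear branch, preserving their sign and zero mean
  x <- as.numeric(newdata)
  out <- x < object$lo | x > object$hi
  if (any(out))
    warning(sum(out), " OD value(s) outside the calibrated range [",
            format(object$lo, digits = 3), ", ",
            format(object$hi, digits = 3), "]; extrapolating linearly")
  .cal_eval(object, x)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("OD calibration curve\n")
  cat("  calibrated range [", format(x$lo, digits = 3), ",",
      format(x$hi, digits = 3), "] from", nrow(x$series), "dilutions\n")
  cat("  fixed point: corrected(", x$anchor, ") = ", x$anchor, "\n", sep = "")
  invisible(x)
}

#' The packaged default dilution series
#'
#' A synthetic dilution series emulating a haploid budding-yeast culture in
#' glucose measured on a saturating plate reader; shipped so OD correction
#' works without a user-provided calibration file. It is generated data, not
#' an instrument export.
#'
#' @return Data frame with columns \code{measured}, \code{dilution}.
#' @export
default_dilution_series <- function() {
  read_dilution_series(system.file("extdata",
                                   "yeast_glucose_dilution_synthetic.txt",
                                   package = "platekit", mustWork = TRUE))
}

#' Correct all measured ODs of a dataset to be proportional to cell number
#'
#' Fits (or reuses) a calibration curve and replaces every OD value in the
#' processed table by its corrected value. Values outside the calibrated
#' range are extrapolated linearly with a warning. Correcting twice is an
#' error.
#'
#' @param ds A \code{plate_dataset}.
#' @param calibration A \code{calibration_curve}, a dilution-series data
#'   frame, a path to a dilution-series file, or \code{NULL} to use the
#'   packaged default series.
#' @param ... Passed to [fit_calibration()] when a curve must be fitted.
#' @return The dataset with corrected ODs and the \code{od_corrected} flag set.
#' @export
correct_od <- function(ds, calibration = NULL, ...) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (ds$flags$od_corrected)
    stop("ODs are already corrected; refusing to correct twice")
  curve <- if (inherits(calibration, "calibration_curve")) calibration
    else if (is.null(calibration)) fit_calibration(default_dilution_series(), ...)
    else if (is.character(calibration))
      fit_calibration(read_dilution_series(calibration), ...)
    else fit_calibration(calibration, ...)
  i <- ds$data$signal == "OD"
  if (!any(i)) stop("dataset has no OD signal")
  ds$data$value[i] <- predict(curve, ds$data$value[i])
  ds$flags$od_corrected <- TRUE
  .append_log(ds, "correct_od",
              list(n_points = nrow(curve$series), anchor = curve$anchor))
}
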