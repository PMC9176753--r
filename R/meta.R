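# Multi-plate meta-analysis: merging runs, a common time grid, averaging
# across experiments, and automatic numeric columns parsed from condition
# labels.

#' Merge several plate datasets into one
#'
#' Concatenates the raw and processed tables, preserving experiment
#' provenance. Experiment labels must be unique.
#'
#' @param ... \code{plate_dataset} objects, or a single list of them.
#' @return A combined \code{plate_dataset}.
#' @export
merge_experiments <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && !inherits(dss[[1]], "plate_dataset"))
    dss <- dss[[1]]
  stopifnot(all(vapply(dss, inherits, TRUE, "plate_dataset")))
  if (length(dss) == 1) return(dss[[1]])
  labs <- unlist(lapply(dss, function(d) unique(d$data$experiment)))
  if (anyDuplicated(labs))
    stop("duplicate experiment labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  out <- dss[[1]]
  out$raw <- do.call(rbind, lapply(dss, `[[`, "raw"))
  out$data <- do.call(rbind, lapply(dss, `[[`, "data"))
  out$map <- unique(do.call(rbind, lapply(dss, `[[`, "map")))
  out$summary <- {
    ss <- lapply(dss, `[[`, "summary")
    if (all(vapply(ss, is.null, TRUE))) NULL
    else do.call(rbind, ss[!vapply(ss, is.null, TRUE)])
  }
  out$ignored <- sort(unique(unlist(lapply(dss, `[[`, "ignored"))))
  fl <- lapply(dss, `[[`, "flags")
  out$flags <- lapply(stats::setNames(nm = names(out$flags)), function(n)
    all(vapply(fl, `[[`, TRUE, n)))
  out$log <- unlist(lapply(dss, `[[`, "log"))
  out$common <- NULL
  .append_log(out, "merge_experiments", list(experiments = labs))
}

#' Interpolate all experiments onto a common time grid
#'
#' Different runs sample at slightly different times even when programmed
#' identically. A common grid spanning the overlap of all experiments'
#' observed ranges is built (spacing defaults to the median sampling
#' interval) and every well/signal series is linearly interpolated onto it.
#' No extrapolation: the grid never leaves any experiment's observed range,
#' and within an experiment a well only contributes where it was observed.
#' Original rows are retained; the interpolated table is stored as
#' \code{ds$common}.
#'
#' @param ds A \code{plate_dataset}.
#' @param spacing Grid spacing in hours, or \code{NULL} for the median
#'   sampling interval across experiments.
#' @return The dataset with \code{$common} filled in.
#' @export
add_common_time <- function(ds, spacing = NULL) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data
  rng <- do.call(rbind, lapply(split(d$time, d$experiment), range))
  t0 <- max(rng[, 1]); t1 <- min(rng[, 2])
  if (t1 <= t0) stop("experiments have no overlapping time window")
  if (is.null(spacing)) {
    ivs <- unlist(lapply(split(d, list(d$experiment, d$well, d$signal),
                               drop = TRUE),
                         function(s) diff(sort(unique(s$time)))))
    spacing <- stats::median(ivs)
  }
  if (spacing <= 0) stop("spacing must be positive")
  grid <- seq(t0, t1, by = spacing)
  out <- lapply(split(d, list(d$experiment, d$well, d$signal), drop = TRUE),
                function(s) {
    if (nrow(s) < 2) return(NULL)
    g <- grid[grid >= min(s$time) & grid <= max(s$time)]
    if (!length(g)) return(NULL)
    data.frame(experiment = s$experiment[1], well = s$well[1],
               strain = s$strain[1], condition = s$condition[1],
               time = g, signal = s$signal[1],
               value = stats::approx(s$time, s$value, xout = g)$y)
  })
  ds$common <- do.call(rbind, c(out, make.row.names = FALSE))
  .append_log(ds, "add_common_time", list(spacing = spacing))
}

#' Average a signal over experiments on the common time grid
#'
#' At each common timepoint the replicate wells of each experiment are first
#' pooled into a per-experiment mean; the experiment means are then averaged
#' (each plate one vote) and their standard deviation taken over experiments
#' (denominator n-1; a single contributing experiment reports a missing sd).
#' Experiments lacking the group simply do not contribute.
#'
#' @param ds A \code{plate_dataset} with a common time grid
#'   (see [add_common_time()]).
#' @param strain,condition Group selectors.
#' @param signal Signal to average.
#' @return Data frame with columns \code{time}, \code{mean}, \code{sd},
#'   \code{n} and a comma-separated \code{experiments} provenance column.
#' @export
average_over_experiments <- function(ds, strain, condition, signal = "OD") {
  stopifnot(inherits(ds, "plate_dataset"))
  if (is.null(ds$common))
    stop("no common time grid; call add_common_time() first")
  d <- ds$common[ds$common$strain == strain &
                   ds$common$condition == condition &
                   ds$common$signal == signal, ]
  if (!nrow(d)) stop("group '", strain, "' / '", condition,
                     "' with signal '", signal, "' absent from all experiments")
  per_exp <- stats::aggregate(value ~ experiment + time, d, mean)
  agg <- lapply(split(per_exp, per_exp$time), function(s)
    data.frame(time = s$time[1], mean = mean(s$value),
               sd = if (nrow(s) > 1) stats::sd(s$value) else NA_real_,
               n = nrow(s),
               experiments = paste(sort(s$experiment), collapse = ",")))
  out <- do.call(rbind, c(agg, make.row.names = FALSE))
  out[order(out$time), ]
}

#' Parse a numeric column out of condition labels
#'
#' Extracts the numeral immediately preceding a unit token: with token
#' \code{"\% raf"}, the condition \code{"0.5\% raf"} yields 0.5 and
#' \code{"2\% glu + 1\% raf"} yields 1. Labels without a parseable match get
#' a missing value; their count is reported.
#'
#' @param ds A \code{plate_dataset}.
#' @param token Unit token, e.g. \code{"\% raf"}.
#' @param name Name of the new column (default derived from the token).
#' @return The dataset with the numeric column added to the processed table
#'   and, when present, the summary table. The number of unparseable labels
#'   is attached as \code{attr(ds, "parse_failures")}.
#' @export
add_numeric_column <- function(ds, token, name = NULL) {
  stopifnot(inherits(ds, "plate_dataset"))
  if (is.null(name))
    name <- gsub("^_+|_+$", "", gsub("[^A-Za-z0-9]+", "_", token))
  pat <- paste0("([+-]?[0-9]*\\.?[0-9]+)\\s*",
                gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", token))
  parse_one <- function(s) {
    m <- regmatches(s, gregexpr(pat, s))[[1]]
    if (length(m) != 1) return(NA_real_)
    as.numeric(sub(pat, "\\1", m))
  }
  labels <- unique(ds$data$condition)
  vals <- vapply(labels, parse_one, 0)
  failed <- sum(is.na(vals))
  if (failed)
    message(failed, " condition label(s) did not match token '", token, "'")
  lut <- stats::setNames(vals, labels)
  ds$data[[name]] <- unname(lut[ds$data$condition])
  if (!is.null(ds$summary))
    ds$summary[[name]] <- unname(lut[ds$summary$condition])
  attr(ds, "parse_failures") <- failed
  .append_log(ds, "add_numeric_column", list(token = token, name = name))
}
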