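# Media-blank subtraction and autofluorescence correction.
#
# Fluorescence measured from a well mixes the fluorophore's emission with
# cellular autofluorescence and the medium's background. Media wells give the
# background; the untagged strain gives the autofluorescence, either through
# two-channel linear unmixing (GFP) or by matching fluorescence at equal OD.

# Savitzky-Golay smoothing with graceful window shrink for short series.
.sg_smooth <- function(y, window = 11, order = 3) {
  n <- length(y)
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd")
  if (window > n) window <- max(3, if (n %% 2 == 1) n else n - 1)
  if (order >= window) order <- window - 1
  if (n < 3 || order < 1) return(y)
  as.numeric(signal::sgolayfilt(y, p = order, n = window))
}

.media_wells <- function(ds, condition) {
  unique(ds$data$well[ds$data$strain == "null" &
                        ds$data$condition == condition])
}

#' Subtract the media background from every well
#'
#' For each condition and signal, the mean trace of that condition's
#' media-only wells (strain \code{"null"}) is smoothed over time with a
#' Savitzky-Golay filter and subtracted pointwise from every well of the
#' condition -- including the media wells themselves, whose corrected traces
#' should then fluctuate around zero. Wells are assumed to share the plate's
#' clock, so traces are aligned by time value.
#'
#' @param ds A \code{plate_dataset}.
#' @param sg_window Odd filter window length in points (default 11, shrunk
#'   for shorter series).
#' @param sg_order Polynomial order of the filter (default 3).
#' @param pool \code{"condition"} (default) subtracts each condition's own
#'   media wells; \code{"all"} pools every media well on the plate -- the
#'   right choice when the media differ only in a solute that contributes
#'   negligible OD, since more blanks means less correlated blank noise
#'   passed into every corrected trace.
#' @return The dataset with media-corrected values and the
#'   \code{media_corrected} flag set.
#' @export
correct_media <- function(ds, sg_window = 11, sg_order = 3,
                          pool = c("condition", "all")) {
  stopifnot(inherits(ds, "plate_dataset"))
  pool <- match.arg(pool)
  if (sg_order >= sg_window) stop("sg_order must be smaller than sg_window")
  d <- ds$data
  d0 <- ds$data   # background always estimated from uncorrected values
  for (exp in unique(d$experiment)) {
    for (cond in unique(d$condition[d$experiment == exp])) {
      mw <- if (pool == "all") unique(d$well[d$strain == "null"])
            else .media_wells(ds, cond)
      if (!length(mw))
        stop("no media-only wells for condition '", cond,
             "'; media correction needs at least one 'null' well")
      sel_cond <- d$experiment == exp & d$condition == cond
      for (sig in unique(d$signal[sel_cond])) {
        sel <- sel_cond & d$signal == sig
        md <- d0[d0$experiment == exp & d0$signal == sig &
                   d0$well %in% mw, ]
        trace <- stats::aggregate(value ~ time, md, mean)
        trace <- trace[order(trace$time), ]
        trace$smooth <- .sg_smooth(trace$value, sg_window, sg_order)
        idx <- which(sel)
        bg <- stats::approx(trace$time, trace$smooth, xout = d$time[idx],
                            rule = 2)$y
        d$value[idx] <- d$value[idx] - bg
      }
    }
  }
  ds$data <- d
  ds$flags$media_corrected <- TRUE
  .append_log(ds, "correct_media",
              list(sg_window = sg_window, sg_order = sg_order))
}

# wide table (well x time) of one signal for given wells, aligned on time
.signal_matrix <- function(d, wells, sig) {
  sub <- d[d$well %in% wells & d$signal == sig, ]
  times <- sort(unique(sub$time))
  m <- vapply(wells, function(w) {
    ws <- sub[sub$well == w, ]
    stats::approx(ws$time, ws$value, xout = times, rule = 2)$y
  }, numeric(length(times)))
  list(times = times, m = matrix(m, nrow = length(times),
                                 dimnames = list(NULL, wells)))
}

.replicate_summary <- function(exp, strain, cond, times, fc, od) {
  nrep <- ncol(fc)
  per_od <- fc / od
  data.frame(experiment = exp, strain = strain, condition = cond,
             time = times,
             mean = rowMeans(fc),
             var = apply(fc, 1, stats::var),
             mean_per_od = rowMeans(per_od),
             var_per_od = apply(per_od, 1, stats::var),
             n = nrep)
}

#' Correct GFP fluorescence for autofluorescence by linear unmixing
#'
#' Emission is measured at 525 nm (GFP's band, \code{F525}) and 585 nm
#' (mostly autofluorescence, \code{F585}). The untagged strain's emission
#' ratio \eqn{r_a = f_{585}/f_{525}} is smoothed as a function of OD
#' (Savitzky-Golay) and interpolated to each tagged well's OD at each time;
#' GFP's own ratio \eqn{r_g} is a measured constant. The corrected
#' fluorescence of each replicate well is then
#' \deqn{f_{corr} = (r_a f_{525} - f_{585}) / (r_a - r_g),}
#' and its error the variance over replicates. Fluorescence per cell divides
#' each replicate's \eqn{f_{corr}} by that replicate's OD before averaging.
#' Negative corrected values are retained, so the untagged strain's corrected
#' signal is an unbiased around-zero consistency check.
#'
#' @param ds A \code{plate_dataset} (OD ideally already corrected; a warning
#'   is given otherwise).
#' @param tagged Strain label of the GFP-tagged strain.
#' @param untagged Strain label of the untagged (no-fluorophore) strain.
#' @param r_g GFP's emission ratio 585/525 nm (default 0; measurable and
#'   typically small).
#' @param sg_window,sg_order Savitzky-Golay parameters for smoothing
#'   \eqn{r_a} versus OD.
#' @param condition Restrict to one condition (default: all shared).
#' @return An object of class \code{"corrected_fluorescence"}: per-time
#'   replicate mean and variance of the corrected fluorescence and of the
#'   per-OD fluorescence, plus the per-replicate traces.
#' @export
correct_gfp <- function(ds, tagged, untagged, r_g = 0,
                        sg_window = 11, sg_order = 3, condition = NULL) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data
  if (!all(c("F525", "F585") %in% d$signal))
    stop("linear unmixing needs both F525 and F585 channels")
  if (!ds$flags$od_corrected)
    warning("ODs are not yet calibration-corrected; ",
            "per-OD fluorescence will be in measured-OD units")
  if (!untagged %in% d$strain)
    stop("untagged strain '", untagged, "' not present")
  if (r_g < 0) stop("r_g must be non-negative")
  conds <- if (is.null(condition)) {
    intersect(unique(d$condition[d$strain == tagged]),
              unique(d$condition[d$strain == untagged]))
  } else condition
  if (!length(conds))
    stop("no condition holds both tagged and untagged strains")
  out <- list(); reps <- list()
  for (exp in unique(d$experiment)) for (cond in conds) {
    sel <- d$experiment == exp & d$condition == cond
    uw <- unique(d$well[sel & d$strain == untagged])
    tw <- unique(d$well[sel & d$strain == tagged])
    if (length(uw) < 2)
      stop("need >= 2 replicate wells of the untagged strain in '",
           cond, "' (7 recommended)")
    if (length(tw) < 2)
      stop("need >= 2 replicate wells of the tagged strain in '",
           cond, "' (5 recommended)")
    dd <- d[sel, ]
    u_od <- .signal_matrix(dd, uw, "OD")
    u525 <- .signal_matrix(dd, uw, "F525")
    u585 <- .signal_matrix(dd, uw, "F585")
    # r_a versus OD as the ratio of the two Savitzky-Golay-smoothed
    # emissions, not the smoothed pointwise ratio: the pointwise ratio of
    # noisy emissions is biased upward (E[1/x] > 1/E[x]) exactly where the
    # signal is weakest, which would leak a spurious positive fluorescence
    # into every corrected trace
    ra_pts <- data.frame(od = as.vector(u_od$m),
                         f525 = as.vector(u525$m),
                         f585 = as.vector(u585$m))
    ra_pts <- ra_pts[order(ra_pts$od), ]
    s525 <- .sg_smooth(ra_pts$f525, sg_window, sg_order)
    s585 <- .sg_smooth(ra_pts$f585, sg_window, sg_order)
    if (any(abs(s525) < 1e-9))
      stop("cannot estimate r_a: smoothed 525 nm emission of the untagged ",
           "strain vanishes at some ODs")
    ra_pts$smooth <- s585 / s525
    ra_fun <- if (diff(range(ra_pts$od)) < 1e-12) {
      ra_const <- mean(ra_pts$smooth)
      function(od) rep(ra_const, length(od))
    } else function(od) stats::approx(ra_pts$od, ra_pts$smooth,
                                      xout = od, rule = 2, ties = mean)$y
    t_od <- .signal_matrix(dd, tw, "OD")
    t525 <- .signal_matrix(dd, tw, "F525")
    t585 <- .signal_matrix(dd, tw, "F585")
    ra <- apply(t_od$m, 2, ra_fun)
    if (any(abs(ra - r_g) < 0.05 * abs(ra)))
      stop("singular unmixing: |r_a - r_g| < 0.05 r_a at some timepoints; ",
           "the correction would amplify noise unboundedly")
    fcorr <- (ra * t525$m - t585$m) / (ra - r_g)
    out[[length(out) + 1L]] <-
      .replicate_summary(exp, tagged, cond, t_od$times, fcorr, t_od$m)
    for (w in tw)
      reps[[length(reps) + 1L]] <- data.frame(
        experiment = exp, well = w, strain = tagged, condition = cond,
        time = t_od$times, fcorr = fcorr[, w],
        fcorr_per_od = fcorr[, w] / t_od$m[, w])
  }
  structure(list(summary = do.call(rbind, out),
                 replicates = do.call(rbind, reps),
                 method = "unmix", r_g = r_g,
                 params = list(sg_window = sg_window, sg_order = sg_order)),
            class = "corrected_fluorescence")
}

#' Correct fluorescence by OD-matched autofluorescence subtraction
#'
#' The general single-channel alternative (suited to fluorophores such as
#' mCherry): the untagged strain's fluorescence, smoothed as a function of
#' its OD, estimates the autofluorescence; for each tagged well and time the
#' autofluorescence interpolated to that well's OD is subtracted. Tagged ODs
#' outside the untagged OD range use the nearest untagged value, with a
#' warning.
#'
#' @inheritParams correct_gfp
#' @param fluorophore Name of the single fluorescence channel.
#' @return A \code{"corrected_fluorescence"} object, as [correct_gfp()].
#' @export
correct_auto_by_od <- function(ds, tagged, untagged, fluorophore = "F525",
                               sg_window = 11, sg_order = 3,
                               condition = NULL) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data
  if (!fluorophore %in% d$signal)
    stop("fluorescence channel '", fluorophore, "' not present")
  if (!untagged %in% d$strain)
    stop("untagged strain '", untagged, "' not present")
  conds <- if (is.null(condition)) {
    intersect(unique(d$condition[d$strain == tagged]),
              unique(d$condition[d$strain == untagged]))
  } else condition
  if (!length(conds))
    stop("no condition holds both tagged and untagged strains")
  out <- list(); reps <- list()
  for (exp in unique(d$experiment)) for (cond in conds) {
    sel <- d$experiment == exp & d$condition == cond
    uw <- unique(d$well[sel & d$strain == untagged])
    tw <- unique(d$well[sel & d$strain == tagged])
    if (length(uw) < 2)
      stop("need >= 2 replicate wells of the untagged strain in '", cond, "'")
    if (length(tw) < 2)
      stop("need >= 2 replicate wells of the tagged strain in '", cond, "'")
    dd <- d[sel, ]
    u_od <- .signal_matrix(dd, uw, "OD")
    u_fl <- .signal_matrix(dd, uw, fluorophore)
    pts <- data.frame(od = as.vector(u_od$m), fl = as.vector(u_fl$m))
    pts <- pts[order(pts$od), ]
    pts$smooth <- .sg_smooth(pts$fl, sg_window, sg_order)
    t_od <- .signal_matrix(dd, tw, "OD")
    t_fl <- .signal_matrix(dd, tw, fluorophore)
    outside <- t_od$m < min(pts$od) | t_od$m > max(pts$od)
    if (any(outside))
      warning(sum(outside), " tagged OD value(s) outside the untagged OD ",
              "range; using the nearest autofluorescence value")
    af <- if (diff(range(pts$od)) < 1e-12)
      matrix(mean(pts$smooth), nrow(t_od$m), ncol(t_od$m),
             dimnames = dimnames(t_od$m))
    else apply(t_od$m, 2, function(od)
      stats::approx(pts$od, pts$smooth, xout = od, rule = 2, ties = mean)$y)
    fcorr <- t_fl$m - af
    out[[length(out) + 1L]] <-
      .replicate_summary(exp, tagged, cond, t_od$times, fcorr, t_od$m)
    for (w in tw)
      reps[[length(reps) + 1L]] <- data.frame(
        experiment = exp, well = w, strain = tagged, condition = cond,
        time = t_od$times, fcorr = fcorr[, w],
        fcorr_per_od = fcorr[, w] / t_od$m[, w])
  }
  structure(list(summary = do.call(rbind, out),
                 replicates = do.call(rbind, reps),
                 method = "odmatch", fluorophore = fluorophore,
                 params = list(sg_window = sg_window, sg_order = sg_order)),
            class = "corrected_fluorescence")
}

#' @export
print.corrected_fluorescence <- function(x, ...) {
  s <- x$summary
  cat("corrected fluorescence (", x$method, "): ",
      length(unique(paste(s$experiment, s$condition))), " group(s), ",
      length(unique(s$time)), " timepoints, ", s$n[1], " replicates\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.corrected_fluorescence <- function(x, ...) x$summary

#' Consistency check on the untagged strain's corrected fluorescence
#'
#' Correcting the untagged strain by either method should leave a signal
#' fluctuating around zero; a systematic offset indicates a miscalibrated
#' spectral ratio or background. Flags when the time-averaged mean exceeds
#' twice its standard error.
#'
#' @param cf A \code{corrected_fluorescence} computed for the untagged strain
#'   (i.e. with \code{tagged} set to the untagged strain label).
#' @return A list: \code{mean} (time-averaged corrected fluorescence),
#'   \code{sd} (over time), \code{se} (of the time average), and
#'   logical \code{flag}.
#' @export
untagged_consistency <- function(cf) {
  stopifnot(inherits(cf, "corrected_fluorescence"))
  m <- cf$summary$mean
  avg <- mean(m)
  se <- stats::sd(m) / sqrt(length(m))
  list(mean = avg, sd = stats::sd(m), se = se, flag = abs(avg) > 2 * se)
}

#' Attach corrected fluorescence to a dataset as new signals
#'
#' Adds the per-replicate corrected fluorescence (and its per-OD version) to
#' the processed table, so the derivative machinery of [stats_on_signal()]
#' can run on them.
#'
#' @param ds A \code{plate_dataset}.
#' @param cf A \code{corrected_fluorescence}.
#' @param name Base name for the new signals; \code{<name>} and
#'   \code{<name>_per_od} are created.
#' @return The augmented dataset.
#' @export
attach_fluorescence <- function(ds, cf, name = "fcorr") {
  stopifnot(inherits(ds, "plate_dataset"),
            inherits(cf, "corrected_fluorescence"))
  r <- cf$replicates
  add <- rbind(
    data.frame(experiment = r$experiment, well = r$well, strain = r$strain,
               condition = r$condition, time = r$time, signal = name,
               value = r$fcorr),
    data.frame(experiment = r$experiment, well = r$well, strain = r$strain,
               condition = r$condition, time = r$time,
               signal = paste0(name, "_per_od"), value = r$fcorr_per_od))
  ds$data <- rbind(ds$data, add)
  ds$flags$auto_corrected <- TRUE
  .append_log(ds, "attach_fluorescence",
              list(method = cf$method, name = name))
}
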