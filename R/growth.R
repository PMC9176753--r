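# Growth-rate inference and summary statistics.
#
# The growth curve is the natural log of OD: a GP fitted to pooled ln(OD)
# from all replicate wells gives the specific growth rate mu(t) = d ln OD/dt
# as the derivative posterior, with measurement error propagated into error
# bands, and bootstrapped errors on the derived statistics.

#' Infer a time-resolved specific growth rate for one strain/condition group
#'
#' Pools ln(OD) observations from every replicate well of the group into a
#' single GP fit (Matern 5/2 by default), then evaluates the posterior of
#' ln OD, of mu(t) (first derivative, units 1/h) and of d mu/d t (second
#' derivative, 1/h^2) on an even time grid.
#'
#' @param ds A \code{plate_dataset} (ODs ideally media- and
#'   calibration-corrected first).
#' @param strain,condition Group selectors.
#' @param experiment Experiment label; required only when the dataset holds
#'   several experiments.
#' @param kernel Kernel family for [fit_gp()].
#' @param t_min Discard data before this time (hours); early OD readings can
#'   fluctuate while the plate equilibrates.
#' @param grid_n Length of the output time grid.
#' @param restarts,seed Hyperparameter-search controls for [fit_gp()].
#' @return An object of class \code{"growth_curve"}: a data frame
#'   \code{$curve} with columns \code{time}, \code{lnod}, \code{lnod_sd},
#'   \code{gr}, \code{gr_sd}, \code{dgr}, \code{dgr_sd}, plus the underlying
#'   \code{gpfit} and group metadata.
#' @export
infer_growth <- function(ds, strain, condition, experiment = NULL,
                         kernel = "matern52", t_min = 0, grid_n = 200,
                         restarts = 5, seed = 0) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data
  if (is.null(experiment)) {
    ee <- unique(d$experiment)
    if (length(ee) > 1)
      stop("dataset holds several experiments; pass `experiment`")
    experiment <- ee
  }
  sel <- d$experiment == experiment & d$strain == strain &
    d$condition == condition & d$signal == "OD" & d$time >= t_min
  sub <- d[sel, ]
  if (!nrow(sub)) stop("no OD data for ", strain, " in ", condition)
  pos <- sub$value > 0
  if (!any(pos)) stop("all ODs are non-positive for ", strain, " in ",
                      condition, "; cannot take logs")
  floored <- sum(!pos)
  if (floored) {
    floor_val <- min(sub$value[pos]) / 2
    sub$value[!pos] <- floor_val
    message(floored, " non-positive OD value(s) floored at ",
            format(floor_val, digits = 3), " before log transform")
  }
  if (length(unique(sub$time)) < 4)
    stop("fewer than 4 usable timepoints after filtering")
  lny <- log(sub$value)
  # With >= 3 replicate wells the spread of ln OD across replicates at each
  # timepoint estimates the (OD-dependent) measurement error; a smoothed
  # variance profile weights the GP noise so early low-OD points, whose log
  # error is largest, do not distort the fit.
  ns <- NULL
  if (length(unique(sub$well)) >= 3) {
    byt <- split(lny, sub$time)
    if (all(lengths(byt) >= 3)) {
      tt <- as.numeric(names(byt))
      v <- vapply(byt, stats::var, 0)[order(tt)]
      if (all(is.finite(v)) && any(v > 0)) {
        # smooth in the log domain: variances span orders of magnitude and
        # must stay positive
        lv <- log(pmax(v, max(v) * 1e-4))
        vs <- exp(.sg_smooth(lv, 11, 2))
        ns <- stats::approx(sort(tt), vs, xout = sub$time, rule = 2,
                            ties = mean)$y
        # the log of a noisy positive measurement is biased down by half its
        # relative variance (second-order Taylor); add it back so early
        # low-OD points do not steepen the apparent slope
        lny <- lny + ns / 2
      }
    }
  }
  fit <- fit_gp(sub$time, lny, kernel = kernel,
                restarts = restarts, seed = seed, noise_scale = ns,
                mean_fn = "linear")
  grid <- seq(min(sub$time), max(sub$time), length.out = grid_n)
  p0 <- gp_posterior(fit, grid)
  p1 <- gp_posterior_derivative(fit, grid, 1)
  p2 <- tryCatch(gp_posterior_derivative(fit, grid, 2),
                 error = function(e) list(mean = rep(NA_real_, grid_n),
                                          variance = rep(NA_real_, grid_n)))
  curve <- data.frame(time = grid,
                      lnod = p0$mean, lnod_sd = sqrt(p0$variance),
                      gr = p1$mean, gr_sd = sqrt(p1$variance),
                      dgr = p2$mean, dgr_sd = sqrt(p2$variance))
  structure(list(curve = curve, fit = fit,
                 experiment = experiment, strain = strain,
                 condition = condition, obs_well = sub$well,
                 n_wells = length(unique(sub$well)),
                 n_points = nrow(sub), floored = floored,
                 t_min = t_min),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat("growth curve:", x$strain, "in", x$condition,
      sprintf("(%s; %d wells, %d ln-OD points)\n",
              x$experiment, x$n_wells, x$n_points))
  cat("  max specific growth rate",
      format(max(x$curve$gr), digits = 4), "1/h at t =",
      format(x$curve$time[which.max(x$curve$gr)], digits = 4), "h\n")
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, ...) {
  cv <- x$curve
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(cv$time, cv$lnod, type = "l", xlab = "time (h)",
                 ylab = "ln OD", ...)
  graphics::lines(cv$time, cv$lnod + 2 * cv$lnod_sd, lty = 3)
  graphics::lines(cv$time, cv$lnod - 2 * cv$lnod_sd, lty = 3)
  graphics::plot(cv$time, cv$gr, type = "l", xlab = "time (h)",
                 ylab = "growth rate (1/h)", ...)
  graphics::lines(cv$time, cv$gr + 2 * cv$gr_sd, lty = 3)
  graphics::lines(cv$time, cv$gr - 2 * cv$gr_sd, lty = 3)
  invisible(x)
}

# Two bootstrap components for the statistic errors, combined in quadrature
# by the caller:
#   - posterior draws of (f, f') -- measurement noise propagated through the
#     GP;
#   - a case bootstrap over replicate wells (when >= 2 wells share one time
#     grid), re-deriving the curve under the fitted kernel for each resample
#     -- between-well variability the pointwise noise model misses.
.boot_stats <- function(gc, grid, n, seed, stat_fun) {
  fit <- gc$fit
  dgrid <- c(diff(grid), NA)
  draws <- gp_sample_posterior(fit, grid, n = n, seed = seed)
  post <- t(vapply(seq_len(n), function(i) {
    gr_i <- draws$df[i, ]
    stat_fun(draws$f[i, ], gr_i, c(diff(gr_i), NA) / dgrid)
  }, numeric(5)))

  wl <- if (!is.null(gc$obs_well)) split(seq_along(fit$x), gc$obs_well)
        else list()
  same_grid <- length(wl) >= 2 &&
    all(vapply(wl, function(ii)
      isTRUE(all.equal(fit$x[ii], fit$x[wl[[1]]])), TRUE))
  well <- NULL
  if (same_grid) {
    K00 <- .gp_cov(fit$kernel, grid, fit$x, 0, 0)
    K10 <- .gp_cov(fit$kernel, grid, fit$x, 1, 0)
    mline <- fit$beta[1] + fit$beta[2] * grid
    picks <- .with_seed(seed + 1L,
      matrix(sample(length(wl), n * length(wl), replace = TRUE), nrow = n))
    well <- t(vapply(seq_len(n), function(b) {
      yb <- numeric(length(fit$x))
      for (k in seq_along(wl))
        yb[wl[[k]]] <- fit$y[wl[[picks[b, k]]]]
      ycb <- yb - fit$beta[1] - fit$beta[2] * fit$x
      ab <- backsolve(fit$L, forwardsolve(t(fit$L), ycb))
      lnod <- as.numeric(K00 %*% ab) + mline
      gr <- as.numeric(K10 %*% ab) + fit$beta[2]
      stat_fun(lnod, gr, c(diff(gr), NA) / dgrid)
    }, numeric(5)))
  }
  list(post = post, well = well)
}

# largest interior local maximum of mu given its values and the sign of
# dmu/dt on the grid; first/last `edge` points excluded. NA when none.
.local_max <- function(gr, dgr, edge = 2) {
  n <- length(gr)
  if (n < 2 * edge + 2) return(NA_real_)
  cand <- which(dgr[-n] > 0 & dgr[-1] <= 0)  # + -> - crossing at i..i+1
  cand <- cand[cand > edge & cand < n - edge]
  if (!length(cand)) return(NA_real_)
  vals <- pmax(gr[cand], gr[cand + 1])
  max(vals)
}

#' Summary statistics of a growth curve, with bootstrapped errors
#'
#' Computes the maximal growth rate (grid maximum of the posterior mean of
#' mu), the local maximal growth rate (largest interior maximum, where
#' d mu/d t crosses zero away from the curve ends -- absent when mu only
#' peaks at a boundary), the lag time (t-axis intercept of the tangent to
#' ln OD at the time of maximal growth, relative to the initial ln-OD
#' level), and the maximal OD.
#'
#' Errors are bootstrap standard deviations. With two or more replicate
#' wells sharing a time grid, wells are resampled with replacement and the
#' curve re-derived under the fitted kernel for each resample -- capturing
#' between-well variability the pointwise noise model would miss. Otherwise
#' (single well, or ragged grids) seeded joint posterior draws of the curve
#' and its derivative are used.
#'
#' @param gc A \code{growth_curve}.
#' @param bootstrap_n Number of bootstrap resamples / posterior draws.
#' @param seed Integer seed for the draws.
#' @return One-row data frame with the statistics and their errors.
#' @export
summarise_growth <- function(gc, bootstrap_n = 100, seed = 0) {
  stopifnot(inherits(gc, "growth_curve"))
  cv <- gc$curve
  if (!all(is.finite(cv$gr))) stop("growth curve contains non-finite values")
  grid <- cv$time
  stat_fun <- function(lnod, gr, dgr) {
    imax <- which.max(gr)
    max_gr <- gr[imax]; t_max <- grid[imax]
    lag <- t_max - (lnod[imax] - lnod[1]) / max_gr
    c(max_gr = max_gr, t_max = t_max,
      local_max_gr = .local_max(gr, dgr),
      lag = max(lag, 0), max_od = max(exp(lnod)))
  }
  point <- stat_fun(cv$lnod, cv$gr, cv$dgr)
  boot <- .boot_stats(gc, grid, bootstrap_n, seed, stat_fun)
  err <- apply(boot$post, 2, stats::sd, na.rm = TRUE)
  if (!is.null(boot$well)) {
    ew <- apply(boot$well, 2, stats::sd, na.rm = TRUE)
    ew[is.na(ew)] <- 0
    err <- sqrt(err^2 + ew^2)
  }
  data.frame(experiment = gc$experiment, strain = gc$strain,
             condition = gc$condition,
             max_gr = point[["max_gr"]], max_gr_err = err[["max_gr"]],
             t_max = point[["t_max"]],
             local_max_gr = point[["local_max_gr"]],
             local_max_gr_err = if (is.na(point[["local_max_gr"]])) NA_real_
               else err[["local_max_gr"]],
             lag = point[["lag"]], lag_err = err[["lag"]],
             max_od = point[["max_od"]],
             n_wells = gc$n_wells,
             stringsAsFactors = FALSE)
}

#' Growth statistics for every strain/condition group of a dataset
#'
#' Runs [infer_growth()] and [summarise_growth()] for each group of each
#' experiment (media-only wells excluded) and attaches the resulting summary
#' table to the dataset.
#'
#' @inheritParams infer_growth
#' @inheritParams summarise_growth
#' @param ds A \code{plate_dataset}.
#' @return The dataset with \code{$summary} filled in; the fitted
#'   \code{growth_curve} objects are attached as
#'   \code{attr(ds$summary, "curves")}.
#' @export
get_growth_stats <- function(ds, kernel = "matern52", t_min = 0,
                             grid_n = 200, bootstrap_n = 100,
                             restarts = 5, seed = 0) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data[ds$data$strain != "null" & ds$data$signal == "OD", ]
  groups <- unique(d[c("experiment", "strain", "condition")])
  rows <- list(); curves <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    gc <- infer_growth(ds, g$strain, g$condition, g$experiment,
                       kernel = kernel, t_min = t_min, grid_n = grid_n,
                       restarts = restarts, seed = seed + i - 1)
    rows[[i]] <- summarise_growth(gc, bootstrap_n, seed = seed + i - 1)
    curves[[paste(g$experiment, g$strain, g$condition, sep = " | ")]] <- gc
  }
  ds$summary <- do.call(rbind, rows)
  attr(ds$summary, "curves") <- curves
  .append_log(ds, "get_growth_stats",
              list(kernel = kernel, t_min = t_min,
                   bootstrap_n = bootstrap_n, seed = seed))
}

#' Apply the derivative machinery to an arbitrary signal
#'
#' Fits the same GP used for growth rates to any signal of a group (for
#' example corrected fluorescence per OD) and returns its posterior together
#' with the first time derivative. No log transform is applied unless
#' requested.
#'
#' @inheritParams infer_growth
#' @param signal Signal name in the processed table.
#' @param log_transform Fit ln(signal) instead of the signal.
#' @return A \code{"growth_curve"} object (the \code{lnod} column holds the
#'   possibly untransformed signal posterior).
#' @export
stats_on_signal <- function(ds, signal, strain, condition, experiment = NULL,
                            kernel = "matern52", t_min = 0, grid_n = 200,
                            log_transform = FALSE, restarts = 5, seed = 0) {
  stopifnot(inherits(ds, "plate_dataset"))
  d <- ds$data
  if (!signal %in% d$signal) stop("unknown signal '", signal, "'")
  if (is.null(experiment)) {
    ee <- unique(d$experiment)
    if (length(ee) > 1)
      stop("dataset holds several experiments; pass `experiment`")
    experiment <- ee
  }
  sel <- d$experiment == experiment & d$strain == strain &
    d$condition == condition & d$signal == signal & d$time >= t_min
  sub <- d[sel, ]
  if (!nrow(sub)) stop("no ", signal, " data for ", strain, " in ", condition)
  if (length(unique(sub$time)) < 4)
    stop("fewer than 4 usable timepoints after filtering")
  y <- if (log_transform) {
    if (any(sub$value <= 0)) stop("signal must be positive for log transform")
    log(sub$value)
  } else sub$value
  fit <- fit_gp(sub$time, y, kernel = kernel, restarts = restarts, seed = seed)
  grid <- seq(min(sub$time), max(sub$time), length.out = grid_n)
  p0 <- gp_posterior(fit, grid)
  p1 <- gp_posterior_derivative(fit, grid, 1)
  p2 <- tryCatch(gp_posterior_derivative(fit, grid, 2),
                 error = function(e) list(mean = rep(NA_real_, grid_n),
                                          variance = rep(NA_real_, grid_n)))
  curve <- data.frame(time = grid,
                      lnod = p0$mean, lnod_sd = sqrt(p0$variance),
                      gr = p1$mean, gr_sd = sqrt(p1$variance),
                      dgr = p2$mean, dgr_sd = sqrt(p2$variance))
  structure(list(curve = curve, fit = fit, experiment = experiment,
                 strain = strain, condition = condition,
                 n_wells = length(unique(sub$well)),
                 n_points = nrow(sub), floored = 0L, t_min = t_min,
                 signal = signal, log_transform = log_transform),
            class = "growth_curve")
}
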