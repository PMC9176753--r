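# Monod kinetics and the OD-based glucose proxy.
#
# Monod's observation: the mid-log growth rate follows a hyperbola in the
# limiting-nutrient concentration S,
#     mu(S) = mu_max * S / (K_S + S),
# with mu_max the saturated rate and K_S the concentration at half-maximal
# growth. The glucose proxy assumes a fixed amount of glucose imported per
# cell division, so residual glucose falls linearly with OD:
#     g(t) = g0 * (OD_max - OD(t)) / (OD_max - OD_min).

#' Fit the Monod equation to growth rates versus nutrient concentration
#'
#' Least squares (weighted by 1/sd^2 when errors are given) in
#' log-parameter space, which enforces positivity of both parameters;
#' the K_S search is multi-started from 8 log-spaced values spanning the
#' concentration range. Confidence intervals come from residual resampling.
#'
#' @param S Nutrient concentrations (>= 3 distinct values).
#' @param mu Observed growth rates (1/h), one per element of \code{S}.
#' @param err Optional standard deviations of \code{mu} (weights 1/err^2).
#' @param bootstrap_n Number of residual-resampling bootstrap refits for the
#'   confidence intervals (0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class \code{"monod_fit"} with \code{coef}
#'   (\code{mu_max}, \code{K_S}), \code{rss}, bootstrap \code{ci} and
#'   \code{se}, and the data. Methods: \code{print}, \code{coef},
#'   \code{predict}, \code{summary}, \code{residuals}.
#' @export
fit_monod <- function(S, mu, err = NULL, bootstrap_n = 100, seed = 0) {
  S <- as.numeric(S); mu <- as.numeric(mu)
  if (length(S) != length(mu)) stop("S and mu lengths differ")
  if (!all(is.finite(S)) || !all(is.finite(mu))) stop("non-finite data")
  if (any(S < 0)) stop("concentrations must be non-negative")
  if (length(unique(S)) < 3)
    stop("Monod parameters are not identifiable from fewer than 3 ",
         "distinct concentrations")
  w <- if (is.null(err)) rep(1, length(mu)) else {
    if (any(err <= 0)) stop("errors must be positive")
    1 / err^2
  }
  # The model is linear in mu_max given K_S, so mu_max is profiled out
  # exactly and only log K_S is searched: a coarse grid bracket followed by
  # golden-section refinement. Log parameters keep both positive.
  Spos <- S[S > 0]
  lks_grid <- seq(log(min(Spos)) - 3, log(max(Spos)) + 3, length.out = 64)
  fit_one <- function(mu_obs) {
    prof <- function(lks) {
      phi <- S / (exp(lks) + S)
      m <- sum(w * phi * mu_obs) / sum(w * phi^2)
      sum(w * (mu_obs - m * phi)^2)
    }
    vals <- vapply(lks_grid, prof, 0)
    i <- which.min(vals)
    bracket <- lks_grid[c(max(1, i - 1), min(length(lks_grid), i + 1))]
    opt <- stats::optimize(prof, interval = bracket, tol = 1e-12)
    ks <- exp(opt$minimum)
    phi <- S / (ks + S)
    m <- sum(w * phi * mu_obs) / sum(w * phi^2)
    c(mu_max = m, K_S = ks, rss = opt$objective)
  }
  sol <- fit_one(mu)
  if (!all(is.finite(sol)) || sol["mu_max"] <= 0)
    stop("Monod fit did not converge")
  pars <- sol[c("mu_max", "K_S")]
  fitted <- pars[1] * S / (pars[2] + S)
  res <- mu - fitted

  boot <- NULL; se <- c(mu_max = NA_real_, K_S = NA_real_); ci <- NULL
  if (bootstrap_n > 0) {
    boot <- .with_seed(seed, t(vapply(seq_len(bootstrap_n), function(i)
      fit_one(fitted + sample(res, replace = TRUE))[1:2], numeric(2))))
    colnames(boot) <- c("mu_max", "K_S")
    se <- apply(boot, 2, stats::sd)
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
  }
  structure(list(coef = pars, rss = unname(sol["rss"]), se = se, ci = ci,
                 fitted = fitted, residuals = res, S = S, mu = mu,
                 weights = w, bootstrap_n = bootstrap_n, seed = seed),
            class = "monod_fit")
}

#' @export
coef.monod_fit <- function(object, ...) object$coef

#' @export
residuals.monod_fit <- function(object, ...) object$residuals

#' @export
predict.monod_fit <- function(object, newdata = object$S, ...) {
  S <- if (is.data.frame(newdata)) newdata$S else as.numeric(newdata)
  unname(object$coef[1] * S / (object$coef[2] + S))
}

#' @export
print.monod_fit <- function(x, ...) {
  cat("Monod fit: mu = mu_max * S / (K_S + S)\n")
  cat(sprintf("  mu_max = %.4g 1/h   K_S = %.4g\n",
              x$coef[1], x$coef[2]))
  cat(sprintf("  weighted RSS %.4g on %d points\n", x$rss, length(x$S)))
  invisible(x)
}

#' @export
summary.monod_fit <- function(object, ...) {
  cat("Monod fit on", length(object$S), "points\n")
  tab <- cbind(estimate = object$coef, se = object$se)
  if (!is.null(object$ci)) tab <- cbind(tab, t(object$ci))
  print(tab)
  invisible(tab)
}

#' @export
plot.monod_fit <- function(x, ...) {
  graphics::plot(x$S, x$mu, xlab = "concentration",
                 ylab = "growth rate (1/h)", ...)
  ss <- seq(0, max(x$S), length.out = 200)
  graphics::lines(ss, predict(x, ss), lty = 2)
  invisible(x)
}

#' Estimate residual glucose from the OD time course
#'
#' Applies the linear proxy \eqn{g(t) = g_0 (OD_{max} - OD(t)) /
#' (OD_{max} - OD_{min})}: residual glucose equals the initial concentration
#' \eqn{g_0} at the minimal OD (the start) and zero at the maximal OD (the
#' plateau, when the sugar is exhausted). To keep the endpoints from being
#' set by measurement noise, the extremes are taken from a Savitzky-Golay
#' smoothed copy of the series by default.
#'
#' @param od Numeric OD series (time-ordered).
#' @param g0 Initial glucose concentration (> 0), any concentration unit.
#' @param time Optional time vector (returned alongside).
#' @param smooth Use a smoothed series for the proxy (default TRUE).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return An object of class \code{"glucose_proxy"}: \code{g} (same units
#'   as \code{g0}), \code{od_min}, \code{od_max}, \code{time}.
#' @export
glucose_proxy <- function(od, g0, time = NULL, smooth = TRUE,
                          sg_window = 11, sg_order = 3) {
  od <- as.numeric(od)
  if (g0 <= 0) stop("g0 must be positive")
  ods <- if (smooth) .sg_smooth(od, sg_window, sg_order) else od
  od_min <- min(ods); od_max <- max(ods)
  if (od_max - od_min < 1e-12)
    stop("degenerate OD series: no growth, glucose proxy undefined")
  g <- g0 * (od_max - ods) / (od_max - od_min)
  structure(list(g = g, g0 = g0, od_min = od_min, od_max = od_max,
                 od = ods, time = time),
            class = "glucose_proxy")
}

#' @export
print.glucose_proxy <- function(x, ...) {
  cat("glucose proxy: g0 =", x$g0, " OD range [",
      format(x$od_min, digits = 4), ",", format(x$od_max, digits = 4), "]\n")
  invisible(x)
}

#' Convert between percent weight/volume and millimolar
#'
#' \code{1\% w/v = 10 g/L}; default molar mass is anhydrous raffinose
#' (504.4 g/mol), so 20 mM raffinose is 1.0\% w/v.
#'
#' @param mM,percent Concentration to convert.
#' @param mw Molar mass in g/mol.
#' @return The converted concentration.
#' @export
conc_mM_to_percent <- function(mM, mw = 504.4) mM * mw / 10000

#' @rdname conc_mM_to_percent
#' @export
conc_percent_to_mM <- function(percent, mw = 504.4) percent * 10000 / mw
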