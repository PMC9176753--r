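# Gaussian-process regression with analytic derivative posteriors.
#
# The engine behind both growth-rate inference and calibration smoothing.
# Kernels are implemented with their exact derivatives so that the posterior
# of f' (and f'') is obtained analytically, never by finite differences.

#' Construct a covariance kernel
#'
#' @param family Kernel family. \code{"matern52"} (default) gives sample paths
#'   that are exactly twice differentiable -- the weakest smoothness assumption
#'   under which a specific growth rate and its time derivative are defined.
#'   \code{"se"} is the infinitely smooth squared exponential;
#'   \code{"nnlike"} is the non-stationary neural-network (arcsine) kernel.
#' @param amplitude,lengthscale Initial hyperparameter values (positive).
#'   For \code{"nnlike"}, \code{lengthscale} holds \code{c(bias, weight)}
#'   standard deviations.
#' @return An object of class \code{"gp_kernel"}.
#' @export
gp_kernel <- function(family = c("matern52", "se", "nnlike"),
                      amplitude = 1, lengthscale = 1) {
  family <- match.arg(family)
  if (amplitude <= 0 || any(lengthscale <= 0))
    stop("kernel hyperparameters must be positive")
  if (family == "nnlike" && length(lengthscale) == 1L)
    lengthscale <- rep(lengthscale, 2L)
  structure(list(family = family, amplitude = amplitude,
                 lengthscale = lengthscale),
            class = "gp_kernel")
}

# Stationary kernels as g(d) = cov(f(x), f(x+d)) and its derivatives in d.
# order 0..4; cov(d^p f(x), d^q f(x')) = (-1)^q g^(p+q)(x - x').
.gp_g <- function(family, d, a2, l, order) {
  if (family == "matern52") {
    cc <- sqrt(5) / l
    u <- abs(d)
    e <- exp(-cc * u)
    switch(as.character(order),
      "0" = a2 * (1 + cc * u + cc^2 * u^2 / 3) * e,
      "1" = -(a2 * cc^2 / 3) * d * (1 + cc * u) * e,
      "2" = -(a2 * cc^2 / 3) * (1 + cc * u - cc^2 * u^2) * e,
      "3" = (a2 * cc^4 / 3) * d * (3 - cc * u) * e,
      "4" = (a2 * cc^4 / 3) * (3 - 5 * cc * u + cc^2 * u^2) * e,
      stop("unsupported derivative order"))
  } else if (family == "se") {
    e <- a2 * exp(-d^2 / (2 * l^2))
    switch(as.character(order),
      "0" = e,
      "1" = -(d / l^2) * e,
      "2" = (d^2 / l^4 - 1 / l^2) * e,
      "3" = (3 * d / l^4 - d^3 / l^6) * e,
      "4" = (3 / l^4 - 6 * d^2 / l^6 + d^4 / l^8) * e,
      stop("unsupported derivative order"))
  } else stop("not a stationary family")
}

# Neural-network (arcsine) kernel and its first cross-derivatives.
# k(x, x') = a2 * (2/pi) * asin(N / sqrt(D1 D2)),
# N = 2 (s0 + s1 x x'), D1 = 1 + 2 s0 + 2 s1 x^2  (s0, s1 are variances).
.gp_nn <- function(x1, x2, a2, s0, s1, p, q) {
  X1 <- matrix(x1, length(x1), length(x2))
  X2 <- matrix(x2, length(x1), length(x2), byrow = TRUE)
  N <- 2 * (s0 + s1 * X1 * X2)
  D1 <- 1 + 2 * s0 + 2 * s1 * X1^2
  D2 <- 1 + 2 * s0 + 2 * s1 * X2^2
  z <- N / sqrt(D1 * D2)
  z <- pmin(pmax(z, -1 + 1e-12), 1 - 1e-12)
  A <- a2 * 2 / pi
  if (p == 0 && q == 0) return(A * asin(z))
  w <- sqrt(1 - z^2)
  # partials of z
  Nx  <- 2 * s1 * X2          # dN/dx1
  Ny  <- 2 * s1 * X1          # dN/dx2
  Nxy <- 2 * s1
  D1x <- 4 * s1 * X1
  D2y <- 4 * s1 * X2
  r <- 1 / sqrt(D1 * D2)
  zx <- (Nx - N * D1x / (2 * D1)) * r
  zy <- (Ny - N * D2y / (2 * D2)) * r
  if (p == 1 && q == 0) return(A * zx / w)
  if (p == 0 && q == 1) return(A * zy / w)
  if (p == 1 && q == 1) {
    zxy <- (Nxy - Ny * D1x / (2 * D1) -
              (Nx - N * D1x / (2 * D1)) * D2y / (2 * D2)) * r
    return(A * (zxy / w + z * zx * zy / w^3))
  }
  stop("second and higher derivatives are not available for the ",
       "neural-network kernel; use the matern52 or se family", call. = FALSE)
}

# Cross-covariance matrix cov(d^p f(x1), d^q f(x2)).
.gp_cov <- function(kern, x1, x2, p = 0, q = 0) {
  a2 <- kern$amplitude^2
  if (kern$family == "nnlike")
    return(.gp_nn(x1, x2, a2, kern$lengthscale[1]^2, kern$lengthscale[2]^2,
                  p, q))
  D <- outer(x1, x2, "-")
  (-1)^q * .gp_g(kern$family, D, a2, kern$lengthscale, p + q)
}

# Cholesky with an escalating jitter ladder.
.gp_chol <- function(K) {
  jit <- c(0, 10^seq(-10, -6, by = 1)) * mean(diag(K))
  for (j in jit) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is not positive definite even after jitter",
       call. = FALSE)
}

.gp_hyp_pack <- function(kern, noise) {
  if (kern$family == "nnlike")
    log(c(kern$amplitude, kern$lengthscale, noise))
  else
    log(c(kern$amplitude, kern$lengthscale, noise))
}

.gp_hyp_unpack <- function(family, theta) {
  v <- exp(theta)
  if (family == "nnlike")
    list(kern = gp_kernel(family, v[1], v[2:3]), noise = v[4])
  else
    list(kern = gp_kernel(family, v[1], v[2]), noise = v[3])
}

# Negative log marginal likelihood of the centred targets.
.gp_nlml <- function(theta, family, x, y, gscale = NULL) {
  h <- tryCatch(.gp_hyp_unpack(family, theta), error = function(e) NULL)
  if (is.null(h)) return(1e10)
  if (is.null(gscale)) gscale <- rep(1, length(x))
  K <- .gp_cov(h$kern, x, x) + diag(h$noise^2 * gscale, length(x))
  L <- tryCatch(.gp_chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  val <- 0.5 * sum(y * alpha) + sum(log(diag(L))) +
    0.5 * length(x) * log(2 * pi)
  if (!is.finite(val)) 1e10 else val
}

#' Fit a Gaussian process by marginal-likelihood maximisation
#'
#' Hyperparameters (amplitude, length scale(s), observation-noise standard
#' deviation) are optimised jointly in log space over several random restarts.
#' Targets are centred on their mean internally; the posterior adds it back.
#'
#' @param x,y Numeric vectors of inputs and targets (at least 4 points).
#' @param kernel A \code{gp_kernel} or a family name string.
#' @param bounds Optional named list with elements \code{amplitude},
#'   \code{lengthscale}, \code{noise}, each a length-2 positive range.
#'   Defaults: amplitude in \code{[1e-4, 1e4] * sd(y)}, length scale in
#'   \code{[1e-4, 1e4] * span(x)}, noise sd in \code{[1e-3, 1] * sd(y)}.
#' @param restarts Number of random restarts (log-uniform over the bounds).
#' @param seed Integer seed making the restarts reproducible.
#' @param max_opt_points Marginal-likelihood optimisation cost grows cubically
#'   with n; above this many points the hyperparameter search runs on an even
#'   stride through the (input-sorted) data, and only the final posterior
#'   conditions on the full set.
#' @param noise_scale Optional positive vector, one value per observation,
#'   giving the relative noise \emph{variance} of each point (internally
#'   normalised to median 1). Lets measurements of known unequal precision --
#'   e.g. log-OD values, whose error grows as OD falls -- be weighted
#'   properly; the overall noise level is still fitted.
#' @param mean_fn Prior mean: \code{"constant"} (the data mean) or
#'   \code{"linear"} (least-squares line, subtracted before fitting and
#'   restored in the posterior and its derivative). A linear mean avoids the
#'   shrink-to-zero of the derivative posterior at the edges of the data
#'   window, which matters when the quantity of interest is a slope near a
#'   boundary -- as for growth curves.
#' @return An object of class \code{"gpfit"} with components \code{kernel},
#'   \code{noise}, \code{x}, \code{y}, \code{beta} (prior-mean coefficients)
#'   and \code{lml} (the log marginal likelihood).
#' @seealso [gp_posterior()], [gp_posterior_derivative()],
#'   [gp_sample_posterior()]
#' @export
fit_gp <- function(x, y, kernel = "matern52", bounds = NULL,
                   restarts = 5, seed = 0, max_opt_points = 250,
                   noise_scale = NULL, mean_fn = c("constant", "linear")) {
  mean_fn <- match.arg(mean_fn)
  if (is.character(kernel)) kernel <- gp_kernel(kernel)
  stopifnot(inherits(kernel, "gp_kernel"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (!all(is.finite(x))) stop("inputs must be finite")
  if (!all(is.finite(y))) stop("targets must be finite")
  if (length(x) < 4) stop("at least 4 points are required to fit a GP")

  span <- diff(range(x)); if (span <= 0) stop("inputs are all identical")
  sdy <- stats::sd(y); if (sdy == 0) sdy <- max(abs(y), 1)
  defaults <- list(amplitude = c(1e-4, 1e4) * sdy,
                   lengthscale = c(1e-4, 1e4) * span,
                   noise = c(1e-3, 1) * sdy)
  if (!is.null(bounds)) defaults[names(bounds)] <- bounds
  b <- defaults
  family <- kernel$family
  nls <- if (family == "nnlike") 2L else 1L
  lower <- log(c(b$amplitude[1], rep(b$lengthscale[1], nls), b$noise[1]))
  upper <- log(c(b$amplitude[2], rep(b$lengthscale[2], nls), b$noise[2]))

  g <- if (is.null(noise_scale)) rep(1, length(x)) else {
    if (length(noise_scale) != length(x) || any(noise_scale <= 0))
      stop("noise_scale must be positive, one value per observation")
    noise_scale / stats::median(noise_scale)
  }
  beta <- if (mean_fn == "linear") {
    w <- if (is.null(noise_scale)) NULL else 1 / g
    unname(stats::coef(stats::lm(y ~ x, weights = w)))
  } else c(mean(y), 0)
  yc <- y - beta[1] - beta[2] * x
  if (length(x) > max_opt_points) {
    ord <- order(x)
    keep <- ord[unique(round(seq(1, length(x), length.out = max_opt_points)))]
    xo <- x[keep]; yo <- yc[keep]; go <- g[keep]
  } else {
    xo <- x; yo <- yc; go <- g
  }
  rng <- .seeded_rng(seed)
  starts <- lapply(seq_len(max(1, restarts)), function(i) {
    if (i == 1) pmin(pmax(log(c(sdy, rep(span / 4, nls), 0.1 * sdy)),
                          lower), upper)
    else lower + rng(length(lower)) * (upper - lower)
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, .gp_nlml, family = family, x = xo, y = yo, gscale = go,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimisation failed on all restarts")

  h <- .gp_hyp_unpack(family, best$par)
  K <- .gp_cov(h$kern, x, x) + diag(h$noise^2 * g, length(x))
  L <- .gp_chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  lml <- -(0.5 * sum(yc * alpha) + sum(log(diag(L))) +
             0.5 * length(x) * log(2 * pi))
  structure(list(kernel = h$kern, noise = h$noise, noise_scale = g,
                 x = x, y = y,
                 beta = beta, mean_fn = mean_fn, L = L, alpha = alpha,
                 lml = lml, bounds = b, restarts = restarts,
                 seed = seed),
            class = "gpfit")
}

# uniform(0,1) generator isolated from the global RNG stream
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    u <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    u
  }
}

#' Posterior mean and variance of the latent function
#'
#' @param fit A \code{gpfit}.
#' @param x_star Numeric vector of evaluation points (may be empty).
#' @return A list with numeric vectors \code{mean} and \code{variance}.
#' @export
gp_posterior <- function(fit, x_star) {
  stopifnot(inherits(fit, "gpfit"))
  x_star <- as.numeric(x_star)
  if (length(x_star) == 0)
    return(list(mean = numeric(0), variance = numeric(0)))
  Ks <- .gp_cov(fit$kernel, x_star, fit$x, 0, 0)
  mu <- as.numeric(Ks %*% fit$alpha) + fit$beta[1] + fit$beta[2] * x_star
  V <- forwardsolve(t(fit$L), t(Ks))
  var <- pmax(diag(.gp_cov(fit$kernel, x_star, x_star, 0, 0)) -
                colSums(V^2), 0)
  list(mean = mu, variance = var)
}

#' Posterior of the first or second derivative of the latent function
#'
#' Uses exact kernel derivatives; available for the Matern 5/2 (up to the
#' second derivative -- the order its sample paths admit) and squared
#' exponential families, and for the first derivative of the neural-network
#' kernel.
#'
#' @inheritParams gp_posterior
#' @param order Derivative order, 1 or 2.
#' @return A list with \code{mean} and \code{variance} of the derivative.
#' @export
gp_posterior_derivative <- function(fit, x_star, order = 1) {
  stopifnot(inherits(fit, "gpfit"), order %in% c(1, 2))
  x_star <- as.numeric(x_star)
  if (length(x_star) == 0)
    return(list(mean = numeric(0), variance = numeric(0)))
  Kd <- .gp_cov(fit$kernel, x_star, fit$x, order, 0)
  mu <- as.numeric(Kd %*% fit$alpha) + if (order == 1) fit$beta[2] else 0
  V <- forwardsolve(t(fit$L), t(Kd))
  var <- pmax(diag(.gp_cov(fit$kernel, x_star, x_star, order, order)) -
                colSums(V^2), 0)
  list(mean = mu, variance = var)
}

#' Joint posterior draws of the function and its first derivative
#'
#' Draws are taken from the exact joint posterior of \code{(f, f')} on the
#' grid, so each sample is a coherent curve/derivative pair -- the basis for
#' bootstrapped errors on growth statistics.
#'
#' @inheritParams gp_posterior
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A list with matrices \code{f} and \code{df}, each \code{n} rows by
#'   \code{length(x_star)} columns.
#' @export
gp_sample_posterior <- function(fit, x_star, n, seed = 0) {
  stopifnot(inherits(fit, "gpfit"))
  if (n < 1) stop("at least one posterior draw is required")
  x_star <- as.numeric(x_star)
  m <- length(x_star)
  # prior joint covariance of (f*, f'*) and cross-covariance with data
  K00 <- .gp_cov(fit$kernel, x_star, x_star, 0, 0)
  K01 <- .gp_cov(fit$kernel, x_star, x_star, 0, 1)
  K11 <- .gp_cov(fit$kernel, x_star, x_star, 1, 1)
  P <- rbind(cbind(K00, K01), cbind(t(K01), K11))
  Cs <- rbind(.gp_cov(fit$kernel, x_star, fit$x, 0, 0),
              .gp_cov(fit$kernel, x_star, fit$x, 1, 0))
  mu <- as.numeric(Cs %*% fit$alpha) +
    c(fit$beta[1] + fit$beta[2] * x_star, rep(fit$beta[2], m))
  V <- forwardsolve(t(fit$L), t(Cs))
  S <- P - crossprod(V)
  S <- (S + t(S)) / 2
  Lp <- .gp_chol(S + diag(1e-12 * mean(diag(P)), 2 * m))
  rng <- .seeded_rng(seed)
  z <- matrix(stats::qnorm(rng(n * 2 * m)), n, 2 * m)
  draws <- sweep(z %*% Lp, 2, mu, "+")
  list(f = draws[, seq_len(m), drop = FALSE],
       df = draws[, m + seq_len(m), drop = FALSE])
}

#' @export
logLik.gpfit <- function(object, ...) {
  structure(object$lml, df = length(.gp_hyp_pack(object$kernel, object$noise)),
            class = "logLik")
}

#' @export
print.gpfit <- function(x, ...) {
  cat("Gaussian process fit (", x$kernel$family, " kernel)\n", sep = "")
  cat("  n =", length(x$x), "points\n")
  cat("  amplitude   ", format(x$kernel$amplitude, digits = 4), "\n")
  cat("  length scale", format(x$kernel$lengthscale, digits = 4), "\n")
  cat("  noise sd    ", format(x$noise, digits = 4), "\n")
  cat("  log marginal likelihood", format(x$lml, digits = 6), "\n")
  invisible(x)
}

#' @export
predict.gpfit <- function(object, newdata = object$x, deriv = 0, ...) {
  if (deriv == 0) gp_posterior(object, newdata)
  else gp_posterior_derivative(object, newdata, order = deriv)
}
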