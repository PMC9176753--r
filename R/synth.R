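# Synthetic-plate generator with known ground truth.
#
# Emits plate-reader data files, contents grids and dilution series in the
# documented dialects, so every stage of the pipeline can be exercised against
# latent quantities (true growth rate, true corrected fluorescence, true
# glucose) that real exports never reveal.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv())
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# logistic population and its specific growth rate, with an optional lag
.logistic_od <- function(t, r, K, N0, lag = 0) {
  tt <- pmax(t - lag, 0)
  K * N0 * exp(r * tt) / (K + N0 * (exp(r * tt) - 1))
}

.logistic_mu <- function(t, r, K, N0, lag = 0) {
  n <- .logistic_od(t, r, K, N0, lag)
  ifelse(t < lag, 0, r * (1 - n / K))
}

#' Specification for a synthetic 96-well plate
#'
#' The default plate emulates a Monod-style design: 10 carbon-source
#' concentrations in columns 1-10, seven replicate rows (A-G), and a
#' media-only row H, sampled every 10 minutes for 24 h. Per-well growth is
#' logistic with rate set by the Monod equation at that well's concentration.
#' The \code{"gfp"} preset instead grows a GFP-tagged strain (5 wells), an
#' untagged strain (7 wells) and media in one condition, with two emission
#' channels (F525, F585) carrying GFP plus OD-proportional autofluorescence.
#'
#' @param preset \code{"monod"} (OD only) or \code{"gfp"} (OD + F525/F585).
#' @param duration,interval Sampling window and spacing, hours.
#' @param concentrations Carbon-source concentrations (\% w/v) for the monod
#'   preset, one per plate column.
#' @param replicates Number of replicate rows (1-7).
#' @param mu_max,K_S Monod parameters generating the per-condition growth
#'   rates (h^-1 and \% w/v).
#' @param N0 Inoculum OD; \code{capacity} either a fixed carrying-capacity OD
#'   or \code{NULL} to scale it with concentration.
#' @param lag Lag before growth starts, hours.
#' @param media_od Media OD baseline added to every well.
#' @param instrument_response Monotone function distorting true OD into
#'   measured OD (the plate reader's non-linearity);
#'   default \code{2 * (1 - exp(-x / 2))}. Use \code{identity} for a linear
#'   instrument.
#' @param autofl_per_od Autofluorescence at 525 nm per unit OD;
#'   \code{r_a} the untagged emission ratio 585/525; \code{r_g} GFP's ratio;
#'   \code{gfp_level} GFP signal per unit OD (gfp preset).
#' @param noise Named list of Gaussian noise sds per signal.
#' @param seed Integer; the same spec and seed give byte-identical files.
#' @return An object of class \code{"synth_spec"}.
#' @export
synth_plate_spec <- function(preset = c("monod", "gfp"),
                             duration = 24, interval = 1 / 6,
                             concentrations = c(0.05, 0.1, 0.15, 0.25, 0.35,
                                                0.5, 0.75, 1, 1.5, 2),
                             replicates = 7,
                             mu_max = 0.82, K_S = 1.0,
                             N0 = 0.05, capacity = NULL, lag = 0,
                             media_od = 0.04,
                             instrument_response = function(x) 2 * (1 - exp(-x / 2)),
                             autofl_per_od = 80, r_a = 2.0, r_g = 0.1,
                             gfp_level = 60,
                             noise = list(OD = 0.01, F525 = 1, F585 = 0.5),
                             seed = 0) {
  preset <- match.arg(preset)
  if (duration <= 0 || interval <= 0) stop("duration and interval must be positive")
  if (replicates < 1 || replicates > 7) stop("replicates must be 1..7")
  if (mu_max <= 0 || K_S <= 0 || N0 <= 0) stop("rates and ODs must be positive")
  if (preset == "monod" && length(concentrations) > 10)
    stop("at most 10 concentrations (plate columns 1-10)")
  structure(list(preset = preset, duration = duration, interval = interval,
                 concentrations = concentrations, replicates = replicates,
                 mu_max = mu_max, K_S = K_S, N0 = N0, capacity = capacity,
                 lag = lag, media_od = media_od,
                 instrument_response = instrument_response,
                 autofl_per_od = autofl_per_od, r_a = r_a, r_g = r_g,
                 gfp_level = gfp_level, noise = noise, seed = seed),
            class = "synth_spec")
}

# plate layout for a spec: data frame (well, strain, condition, S, r, K)
.synth_layout <- function(spec) {
  rows <- LETTERS[seq_len(spec$replicates)]
  out <- list()
  if (spec$preset == "monod") {
    for (j in seq_along(spec$concentrations)) {
      S <- spec$concentrations[j]
      r <- spec$mu_max * S / (spec$K_S + S)
      K <- if (is.null(spec$capacity)) pmin(0.1 + 0.9 * S, 1.8) else spec$capacity
      cond <- paste0(S, "% raf")
      for (rw in rows)
        out[[length(out) + 1L]] <- data.frame(
          well = paste0(rw, j), strain = "wt", condition = cond,
          S = S, r = r, K = K, stringsAsFactors = FALSE)
    }
    # one media-only well per condition in row H, column matching the
    # condition's column
    for (j in seq_along(spec$concentrations))
      out[[length(out) + 1L]] <- data.frame(
        well = paste0("H", j), strain = "null",
        condition = paste0(spec$concentrations[j], "% raf"),
        S = spec$concentrations[j], r = 0, K = 0, stringsAsFactors = FALSE)
  } else {
    cond <- "2% glu"
    K <- if (is.null(spec$capacity)) 1.2 else spec$capacity
    r <- spec$mu_max
    for (j in 1:5)
      out[[length(out) + 1L]] <- data.frame(
        well = paste0("A", j), strain = "tag-GFP", condition = cond,
        S = 2, r = r, K = K, stringsAsFactors = FALSE)
    for (j in 1:7)
      out[[length(out) + 1L]] <- data.frame(
        well = paste0("B", j), strain = "wt", condition = cond,
        S = 2, r = r, K = K, stringsAsFactors = FALSE)
    for (j in 1:3)
      out[[length(out) + 1L]] <- data.frame(
        well = paste0("H", j), strain = "null", condition = cond,
        S = 2, r = 0, K = 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.synth_fmt <- function(x) sprintf("%.8g", x)

#' Generate a synthetic plate
#'
#' Writes a data file and a contents grid in the documented dialects and
#' returns them together with the ground truth of every latent quantity.
#'
#' @param spec A [synth_plate_spec()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return A list: \code{data_file}, \code{contents_file}, and \code{truth} --
#'   a list holding the layout (with per-well logistic parameters), the time
#'   grid, the latent OD/growth-rate functions \code{od(well, t)} and
#'   \code{mu(well, t)}, the true corrected fluorescence
#'   \code{fcorr(well, t)}, and the generating constants.
#' @export
generate_plate <- function(spec, dir = tempdir(), stem = "plate") {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- .synth_layout(spec)
  times <- seq(0, spec$duration, by = spec$interval)
  lut <- layout; rownames(lut) <- lut$well

  od_true <- function(well, t) {
    p <- lut[well, ]
    if (p$strain == "null") rep(0, length(t))
    else .logistic_od(t, p$r, p$K, spec$N0, spec$lag)
  }
  mu_true <- function(well, t) {
    p <- lut[well, ]
    if (p$strain == "null") rep(0, length(t))
    else .logistic_mu(t, p$r, p$K, spec$N0, spec$lag)
  }
  fcorr_true <- function(well, t) {
    p <- lut[well, ]
    if (p$strain == "tag-GFP") spec$gfp_level * od_true(well, t)
    else rep(0, length(t))
  }

  signals <- if (spec$preset == "gfp") c("OD", "F525", "F585") else "OD"
  blocks <- .with_seed(spec$seed, {
    lapply(signals, function(sig) {
      sd <- spec$noise[[sig]]; if (is.null(sd)) sd <- 0
      rows <- vapply(layout$well, function(w) {
        od <- od_true(w, t = times)
        clean <- switch(sig,
          OD = spec$instrument_response(od) + spec$media_od,
          F525 = spec$autofl_per_od * od + fcorr_true(w, times),
          F585 = spec$r_a * spec$autofl_per_od * od +
                 spec$r_g * fcorr_true(w, times))
        vals <- clean + stats::rnorm(length(times), 0, sd)
        paste(c(w, .synth_fmt(vals)), collapse = "\t")
      }, "")
      c(paste0(sig, "\t(ex 485 nm)"),
        paste(c("time_h", .synth_fmt(times)), collapse = "\t"),
        rows, "")
    })
  })
  data_file <- file.path(dir, paste0(stem, "_data.tsv"))
  writeLines(unlist(blocks), data_file)

  grid <- matrix("", 8, 12)
  for (i in seq_len(nrow(layout))) {
    w <- layout$well[i]
    r <- match(substr(w, 1, 1), LETTERS)
    cc <- as.integer(substring(w, 2))
    grid[r, cc] <- paste(layout$strain[i], "in", layout$condition[i])
  }
  contents_file <- file.path(dir, paste0(stem, "_contents.csv"))
  writeLines(apply(grid, 1, paste, collapse = ","), contents_file)

  list(data_file = data_file, contents_file = contents_file,
       truth = list(layout = layout, times = times, N0 = spec$N0,
                    lag = spec$lag, media_od = spec$media_od,
                    r_a = spec$r_a, r_g = spec$r_g,
                    autofl_per_od = spec$autofl_per_od,
                    gfp_level = spec$gfp_level,
                    mu_max = spec$mu_max, K_S = spec$K_S,
                    od = od_true, mu = mu_true, fcorr = fcorr_true))
}

#' Generate a synthetic dilution-series calibration file
#'
#' A dense reference culture of known (linear) OD \code{od_ref} is diluted by
#' the given factors; the instrument records
#' \code{saturation(od_ref * factor)} plus noise.
#'
#' @param saturation Monotone instrument-response function.
#' @param n_points Number of dilutions (log-spaced factors down from 1).
#' @param od_ref Reference-culture OD in linear units.
#' @param noise_sd Gaussian noise sd on the measured OD.
#' @param seed Integer seed.
#' @param path Optional output file; when given, a two-column text file
#'   (measured OD, dilution factor, '#' comments) is written.
#' @return Data frame with columns \code{measured} and \code{dilution}
#'   (invisibly if \code{path} is given).
#' @export
generate_dilution_series <- function(saturation = function(x) 2 * (1 - exp(-x / 2)),
                                     n_points = 8, od_ref = 2,
                                     noise_sd = 0, seed = 0, path = NULL) {
  factors <- 2^(-(seq_len(n_points) - 1) * 6 / (n_points - 1))
  expected <- od_ref * factors
  measured <- .with_seed(seed,
    saturation(expected) + stats::rnorm(n_points, 0, noise_sd))
  if (any(diff(measured[order(factors)]) < 0) && noise_sd == 0)
    stop("saturation function must be monotone")
  df <- data.frame(measured = measured, dilution = factors)
  if (!is.null(path)) {
    writeLines(c("# dilution series: measured OD, dilution factor",
                 paste(.synth_fmt(df$measured), .synth_fmt(df$dilution))),
               path)
    return(invisible(df))
  }
  df
}
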