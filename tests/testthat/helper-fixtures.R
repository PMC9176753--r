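# In-code fixtures shared across the suite. Everything is generated at test
# time with fixed seeds; no files are shipped.

# minimal long table for one signal over given wells
long_signal <- function(wells, times, values_fun, signal = "OD") {
  do.call(rbind, lapply(seq_along(wells), function(i)
    data.frame(well = wells[i], time = times, signal = signal,
               value = values_fun(i, times))))
}

# dataset with tagged + untagged + media wells carrying OD, F525, F585;
# signals built from an OD trajectory and spectral constants, plus iid noise
make_fluor_ds <- function(n_t = 25, n_tag = 3, n_untag = 3,
                          r_a = 2, r_g_true = 0.1,
                          autofl_per_od = 50, gfp_per_od = 50,
                          od_fun = function(t) 0.05 * exp(0.3 * t),
                          noise = 0, seed = 1) {
  times <- seq(0, 6, length.out = n_t)
  tag_wells <- paste0("A", seq_len(n_tag))
  untag_wells <- paste0("B", seq_len(n_untag))
  withr::with_seed(seed, {
    rows <- list()
    for (w in c(tag_wells, untag_wells)) {
      od <- od_fun(times)
      gfp <- if (w %in% tag_wells) gfp_per_od * od else 0
      f525 <- autofl_per_od * od + gfp + rnorm(n_t, 0, noise)
      f585 <- r_a * autofl_per_od * od + r_g_true * gfp +
        rnorm(n_t, 0, noise)
      strain <- if (w %in% tag_wells) "tag" else "wt"
      rows[[length(rows) + 1L]] <- rbind(
        data.frame(well = w, strain = strain, condition = "c1",
                   time = times, signal = "OD",
                   value = od + rnorm(n_t, 0, noise / 100)),
        data.frame(well = w, strain = strain, condition = "c1",
                   time = times, signal = "F525", value = f525),
        data.frame(well = w, strain = strain, condition = "c1",
                   time = times, signal = "F585", value = f585))
    }
    plate_dataset(do.call(rbind, rows))
  })
}

# small logistic plate on disk: one condition, n replicate wells + media row
logistic_plate <- function(r = 0.5, K = 1.2, N0 = 0.05, sigma = 0.01,
                           replicates = 7, interval = 0.5, duration = 24,
                           seed = 0, linear_instrument = TRUE,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  spec <- synth_plate_spec(
    preset = "monod", duration = duration, interval = interval,
    concentrations = 2, replicates = replicates,
    mu_max = r * (1 + 2) / 2, K_S = 1, N0 = N0, capacity = K,
    media_od = if (linear_instrument) 0 else 0.04,
    instrument_response = if (linear_instrument) identity
      else function(x) 2 * (1 - exp(-x / 2)),
    noise = list(OD = sigma), seed = seed)
  gen <- generate_plate(spec, dir = dir, stem = paste0("lp", seed))
  gen$r <- r; gen$K <- K; gen$N0 <- N0
  gen
}
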