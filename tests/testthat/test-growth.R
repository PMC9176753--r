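# Growth-rate inference and summary statistics.

test_that("noise-free exponential growth gives a flat growth rate", {
  times <- seq(0, 8, length.out = 40)
  df <- long_signal(c("A1", "A2"), times, function(i, t) 0.05 * exp(0.5 * t))
  df$strain <- "wt"; df$condition <- "c"
  gc <- infer_growth(plate_dataset(df), "wt", "c")
  interior <- gc$curve$time > 0.8 & gc$curve$time < 7.2
  expect_lt(max(abs(gc$curve$gr[interior] - 0.5) / 0.5), 0.02)
})

test_that("noisy logistic growth recovers the early maximal rate", {
  truth <- 0.6 * (1 - 0.05 / 1.2)        # logistic mu at t = 0
  rel <- vapply(21:28, function(seed) {
    gen <- logistic_plate(r = 0.6, K = 1.2, N0 = 0.05, sigma = 0.01,
                          seed = seed)
    ds <- load_plate(gen$data_file, gen$contents_file, "lp")
    gc <- infer_growth(ds, "wt", "2% raf")
    abs(max(gc$curve$gr) - truth) / truth
  }, 0)
  expect_lt(stats::median(rel), 0.05)
})

test_that("replicates tighten the posterior without moving it", {
  times <- seq(0, 8, length.out = 30)
  one <- long_signal("A1", times, function(i, t) 0.05 * exp(0.4 * t))
  two <- long_signal(c("A1", "A2"), times, function(i, t) 0.05 * exp(0.4 * t))
  one$strain <- two$strain <- "wt"; one$condition <- two$condition <- "c"
  g1 <- infer_growth(plate_dataset(one), "wt", "c")
  g2 <- infer_growth(plate_dataset(two), "wt", "c")
  expect_equal(g2$curve$gr, g1$curve$gr, tolerance = 0.02)
  expect_lt(mean(g2$curve$lnod_sd), mean(g1$curve$lnod_sd) + 1e-12)
})

test_that("scaling all ODs by a constant leaves the growth rate unchanged", {
  times <- seq(0, 8, length.out = 30)
  df <- long_signal(c("A1", "A2"), times,
                    function(i, t) 0.05 * exp(0.4 * t) * (1 + 0.01 * i))
  df$strain <- "wt"; df$condition <- "c"
  g1 <- infer_growth(plate_dataset(df), "wt", "c")
  df2 <- df; df2$value <- df2$value * 7.3
  g2 <- infer_growth(plate_dataset(df2), "wt", "c")
  expect_equal(g2$curve$gr, g1$curve$gr, tolerance = 1e-6)
})

test_that("summary statistics follow the curve geometry", {
  # flat ln OD until t = 2, then slope 0.5: the tangent construction puts
  # the lag at the breakpoint
  times <- seq(0, 10, length.out = 60)
  lnod <- ifelse(times < 2, log(0.05), log(0.05) + 0.5 * (times - 2))
  df <- long_signal(c("A1", "A2"), times, function(i, t) exp(lnod))
  df$strain <- "wt"; df$condition <- "c"
  gc <- infer_growth(plate_dataset(df), "wt", "c")
  s <- summarise_growth(gc, bootstrap_n = 60, seed = 2)
  expect_equal(s$lag, 2, tolerance = 0.25)
  # the GP rounds the kink, letting mu overshoot the plateau slope slightly
  expect_lt(abs(s$max_gr - 0.5), 0.07)
  expect_gt(s$lag_err, 0)
  expect_gt(s$max_gr_err, 0)
  expect_equal(s$max_od, exp(max(lnod)), tolerance = 0.05)
})

test_that("a monotone growth rate has no interior local maximum", {
  times <- seq(0, 8, length.out = 40)
  # mu(t) rises steadily: ln OD = t^2/16 so mu = t/8, max at the boundary
  df <- long_signal(c("A1", "A2"), times, function(i, t) exp(t^2 / 16))
  df$strain <- "wt"; df$condition <- "c"
  gc <- infer_growth(plate_dataset(df), "wt", "c")
  s <- summarise_growth(gc, bootstrap_n = 20, seed = 1)
  expect_true(is.na(s$local_max_gr))
  expect_equal(s$t_max, 8, tolerance = 0.2)
})

test_that("an interior peak is both the maximum and the local maximum", {
  gen <- logistic_plate(r = 0.5, K = 1.2, N0 = 0.1, sigma = 0.005,
                        seed = 31, duration = 16)
  # inject a lag so the growth-rate peak is interior
  spec <- synth_plate_spec(preset = "monod", duration = 16, interval = 0.5,
                           concentrations = 2, replicates = 7,
                           mu_max = 0.75, K_S = 1, N0 = 0.1, capacity = 1.2,
                           lag = 3, media_od = 0,
                           instrument_response = identity,
                           noise = list(OD = 0.005), seed = 31)
  gen <- generate_plate(spec, dir = withr::local_tempdir())
  ds <- load_plate(gen$data_file, gen$contents_file, "lagged")
  gc <- infer_growth(ds, "wt", "2% raf")
  s <- summarise_growth(gc, bootstrap_n = 40, seed = 3)
  expect_false(is.na(s$local_max_gr))
  expect_lte(s$local_max_gr, s$max_gr + 1e-9)
  expect_equal(s$local_max_gr, s$max_gr, tolerance = 0.05)
  expect_gt(s$t_max, 2); expect_lt(s$t_max, 14)
  expect_equal(s$lag, 3, tolerance = 1.0)
})

test_that("max growth rate is recovered across seeded logistic simulations", {
  # r in {0.2, 0.5, 0.8}, sigma_OD = 0.01, 7 replicate wells each;
  # one independent noise realisation per case
  cases <- expand.grid(r = c(0.2, 0.5, 0.8), rep = 1:6)
  cases$seed <- 97 * seq_len(nrow(cases)) + 13
  rel_err <- numeric(nrow(cases)); covered <- logical(nrow(cases))
  for (i in seq_len(nrow(cases))) {
    gen <- logistic_plate(r = cases$r[i], K = 1.2, N0 = 0.05, sigma = 0.01,
                          seed = cases$seed[i])
    ds <- load_plate(gen$data_file, gen$contents_file, paste0("s", i))
    gc <- infer_growth(ds, "wt", "2% raf", seed = i)
    s <- summarise_growth(gc, bootstrap_n = 60, seed = i)
    truth <- cases$r[i] * (1 - 0.05 / 1.2)
    rel_err[i] <- abs(s$max_gr - truth) / truth
    covered[i] <- abs(s$max_gr - truth) <= 2 * s$max_gr_err
  }
  expect_lt(stats::median(rel_err), 0.05)
  expect_gte(mean(covered), 0.8)
})

test_that("bootstrap errors shrink when the OD noise halves", {
  # the shrink is sub-linear because the refitted hyperparameters adapt --
  # noisier data gets smoothed harder -- but halving the noise must still
  # reduce the error materially on matched seeds
  ratio <- vapply(c(77, 177), function(seed) {
    errs <- vapply(c(0.02, 0.01), function(sg) {
      gen <- logistic_plate(r = 0.5, K = 1.2, sigma = sg, seed = seed)
      ds <- load_plate(gen$data_file, gen$contents_file, "n")
      s <- summarise_growth(infer_growth(ds, "wt", "2% raf"),
                            bootstrap_n = 80, seed = 4)
      s$max_gr_err
    }, 0)
    errs[2] / errs[1]
  }, 0)
  expect_lt(mean(ratio), 0.85)
  expect_gt(mean(ratio), 0.4)
})

test_that("degenerate inputs are refused and flooring is reported", {
  times <- seq(0, 2, length.out = 6)
  df <- long_signal("A1", times, function(i, t) -1 + 0 * t)
  df$strain <- "wt"; df$condition <- "c"
  expect_error(infer_growth(plate_dataset(df), "wt", "c"), "non-positive")
  df2 <- long_signal("A1", times, function(i, t) c(-0.01, 0.1, 0.12, 0.15,
                                                   0.2, 0.25))
  df2$strain <- "wt"; df2$condition <- "c"
  expect_message(gc <- infer_growth(plate_dataset(df2), "wt", "c"),
                 "floored")
  expect_equal(gc$floored, 1L)
  df3 <- df2[df2$time < 0.9, ]
  expect_error(suppressMessages(infer_growth(plate_dataset(df3), "wt", "c")),
               "4 usable")
})

test_that("the same machinery runs on other signals without log transform", {
  times <- seq(0, 6, length.out = 30)
  df <- rbind(
    cbind(long_signal(c("A1", "A2"), times,
                      function(i, t) 0.05 * exp(0.3 * t)), strain = "wt",
          condition = "c"),
    cbind(long_signal(c("A1", "A2"), times, function(i, t) t^2,
                      signal = "gfp_per_od"), strain = "wt",
          condition = "c"))
  ds <- plate_dataset(df)
  # quadratic signal: derivative is 2t within 2% on the interior
  gq <- stats_on_signal(ds, "gfp_per_od", "wt", "c")
  interior <- gq$curve$time > 1 & gq$curve$time < 5
  expect_lt(max(abs(gq$curve$gr[interior] - 2 * gq$curve$time[interior]) /
                  (2 * gq$curve$time[interior])), 0.02)
  # constant signal: zero derivative
  dfc <- cbind(long_signal(c("A1", "A2"), times, function(i, t) 5 + 0 * t,
                           signal = "flat"), strain = "wt", condition = "c")
  gc <- stats_on_signal(plate_dataset(dfc), "flat", "wt", "c")
  expect_lt(max(abs(gc$curve$gr)), 1e-4)
  # linear signal: constant derivative
  dfl <- cbind(long_signal(c("A1", "A2"), times, function(i, t) 1 + 3 * t,
                           signal = "lin"), strain = "wt", condition = "c")
  gl <- stats_on_signal(plate_dataset(dfl), "lin", "wt", "c")
  expect_equal(gl$curve$gr[interior], rep(3, sum(interior)), tolerance = 0.01)
})

test_that("get_growth_stats fills the summary for every group", {
  spec <- synth_plate_spec(duration = 12, interval = 0.75,
                           concentrations = c(0.2, 2), replicates = 3,
                           media_od = 0, instrument_response = identity,
                           noise = list(OD = 0.005), seed = 9)
  gen <- generate_plate(spec, dir = withr::local_tempdir())
  ds <- load_plate(gen$data_file, gen$contents_file, "two-cond")
  ds <- get_growth_stats(ds, bootstrap_n = 30, seed = 5)
  expect_equal(nrow(ds$summary), 2)
  expect_true(all(c("max_gr", "max_gr_err", "lag", "max_od") %in%
                    names(ds$summary)))
  # faster growth in the richer condition
  sm <- ds$summary[order(ds$summary$condition), ]
  expect_lt(sm$max_gr[sm$condition == "0.2% raf"],
            sm$max_gr[sm$condition == "2% raf"])
  expect_match(ds$log[length(ds$log)], "get_growth_stats")
})
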