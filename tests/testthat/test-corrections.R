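# Media-blank subtraction and autofluorescence corrections.

test_that("constant media background is subtracted exactly", {
  times <- seq(0, 2, length.out = 11)
  df <- rbind(
    data.frame(well = "A1", strain = "wt", condition = "c", time = times,
               signal = "OD", value = 0.38),
    data.frame(well = "H1", strain = "null", condition = "c", time = times,
               signal = "OD", value = 0.08))
  ds <- correct_media(plate_dataset(df))
  expect_equal(ds$data$value[ds$data$well == "A1"], rep(0.30, 11))
  expect_true(ds$flags$media_corrected)
  # the media well itself ends up at zero
  expect_equal(ds$data$value[ds$data$well == "H1"], rep(0, 11))
})

test_that("two media wells are averaged before subtraction", {
  times <- seq(0, 2, length.out = 11)
  df <- rbind(
    data.frame(well = "A1", strain = "wt", condition = "c", time = times,
               signal = "OD", value = 0.38),
    data.frame(well = "H1", strain = "null", condition = "c", time = times,
               signal = "OD", value = 0.07),
    data.frame(well = "H2", strain = "null", condition = "c", time = times,
               signal = "OD", value = 0.09))
  ds <- correct_media(plate_dataset(df))
  expect_equal(ds$data$value[ds$data$well == "A1"], rep(0.30, 11))
})

test_that("Savitzky-Golay smoothing reproduces a cubic media trace exactly", {
  times <- seq(0, 2, length.out = 31)
  cubic <- 0.06 + 0.01 * times - 0.004 * times^2 + 0.002 * times^3
  df <- rbind(
    data.frame(well = "A1", strain = "wt", condition = "c", time = times,
               signal = "OD", value = 0.3 + cubic),
    data.frame(well = "H1", strain = "null", condition = "c", time = times,
               signal = "OD", value = cubic))
  ds <- correct_media(plate_dataset(df), sg_window = 11, sg_order = 3)
  # an order-3 filter passes cubics untouched, so the subtraction is exact
  expect_equal(ds$data$value[ds$data$well == "A1"], rep(0.3, 31),
               tolerance = 1e-12)
})

test_that("a condition without media wells is refused by name", {
  times <- seq(0, 1, length.out = 6)
  df <- data.frame(well = "A1", strain = "wt", condition = "odd-cond",
                   time = times, signal = "OD", value = 0.3)
  expect_error(correct_media(plate_dataset(df)), "odd-cond")
})

test_that("linear unmixing matches direct arithmetic of the formula", {
  # constant spectra: r_a = 2 from the untagged wells, r_g = 0.1;
  # tagged emissions f525 = 10, f585 = 5 at every time
  times <- seq(0, 2, length.out = 13)
  mk <- function(well, strain, f525, f585) rbind(
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "OD", value = 0.2 + 0.05 * times),
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "F525", value = f525),
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "F585", value = f585))
  ds <- plate_dataset(rbind(
    mk("A1", "tag", 10, 5), mk("A2", "tag", 10, 5),
    mk("B1", "wt", 4, 8), mk("B2", "wt", 4, 8)))
  cf <- suppressWarnings(correct_gfp(ds, "tag", "wt", r_g = 0.1))
  expect_equal(cf$summary$mean, rep((2 * 10 - 5) / (2 - 0.1), 13),
               tolerance = 1e-9)
  expect_equal(cf$summary$var, rep(0, 13), tolerance = 1e-12)
  expect_equal(cf$summary$n, rep(2, 13))
  # per-OD values divide each replicate by its own OD before averaging
  expect_equal(cf$summary$mean_per_od,
               (2 * 10 - 5) / (2 - 0.1) / (0.2 + 0.05 * times),
               tolerance = 1e-9)

  # a pure autofluorescence spectrum is cancelled completely
  ds0 <- plate_dataset(rbind(
    mk("A1", "tag", 7, 14), mk("A2", "tag", 7, 14),
    mk("B1", "wt", 4, 8), mk("B2", "wt", 4, 8)))
  cf0 <- suppressWarnings(correct_gfp(ds0, "tag", "wt", r_g = 0.1))
  expect_equal(cf0$summary$mean, rep(0, 13), tolerance = 1e-9)

  # with r_g = 0 the formula reduces to f525 - f585 / r_a
  ds1 <- plate_dataset(rbind(
    mk("A1", "tag", 10, 4), mk("A2", "tag", 10, 4),
    mk("B1", "wt", 4, 8), mk("B2", "wt", 4, 8)))
  cf1 <- suppressWarnings(correct_gfp(ds1, "tag", "wt", r_g = 0))
  expect_equal(cf1$summary$mean, rep(10 - 4 / 2, 13), tolerance = 1e-9)
})

test_that("unmixing is homogeneous: scaling both channels scales the result", {
  ds <- make_fluor_ds(noise = 0.5, seed = 2)
  cf1 <- suppressWarnings(correct_gfp(ds, "tag", "wt", r_g = 0.1))
  ds2 <- ds
  fl <- ds2$data$signal %in% c("F525", "F585")
  ds2$data$value[fl] <- 3 * ds2$data$value[fl]
  cf2 <- suppressWarnings(correct_gfp(ds2, "tag", "wt", r_g = 0.1))
  expect_equal(cf2$summary$mean, 3 * cf1$summary$mean, tolerance = 1e-9)
})

test_that("unmixing recovers the injected GFP signal from noisy plates", {
  ds <- make_fluor_ds(n_tag = 5, n_untag = 7, noise = 0.5, seed = 3,
                      r_a = 2, r_g_true = 0.1, gfp_per_od = 50)
  cf <- suppressWarnings(correct_gfp(ds, "tag", "wt", r_g = 0.1))
  truth <- 50 * 0.05 * exp(0.3 * cf$summary$time)
  expect_lt(stats::median(abs(cf$summary$mean - truth) / truth), 0.05)
})

test_that("near-singular unmixing is refused", {
  ds <- make_fluor_ds(noise = 0, r_a = 2)
  expect_error(suppressWarnings(correct_gfp(ds, "tag", "wt", r_g = 1.98)),
               "singular")
})

test_that("OD-matched autofluorescence subtraction uses a linear oracle", {
  # untagged fluorescence = 5 * OD; tagged = 5 * OD + 100: corrected = 100
  times <- seq(0, 4, length.out = 21)
  od <- function(t) 0.05 * exp(0.5 * t)
  mk <- function(well, strain, extra) rbind(
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "OD", value = od(times)),
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "F525", value = 5 * od(times) + extra))
  ds <- plate_dataset(rbind(mk("A1", "tag", 100), mk("A2", "tag", 100),
                            mk("B1", "wt", 0), mk("B2", "wt", 0)))
  # exact up to the filter's discretisation of the uneven OD spacing
  cf <- correct_auto_by_od(ds, "tag", "wt")
  expect_equal(cf$summary$mean, rep(100, 21), tolerance = 1e-4)
  # subtracting the untagged strain from itself gives zero (up to the
  # filter's discretisation; the signal scale is 100)
  cf0 <- correct_auto_by_od(ds, "wt", "wt")
  expect_lt(max(abs(cf0$summary$mean)), 0.05)
})

test_that("tagged ODs outside the untagged range fall back to nearest value", {
  times <- seq(0, 4, length.out = 21)
  mk <- function(well, strain, odf, extra) rbind(
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "OD", value = odf(times)),
    data.frame(well = well, strain = strain, condition = "c", time = times,
               signal = "F525", value = 5 * odf(times) + extra))
  # tagged wells start below every untagged OD
  ds <- plate_dataset(rbind(
    mk("A1", "tag", function(t) 0.01 + 0.02 * t, 100),
    mk("A2", "tag", function(t) 0.01 + 0.02 * t, 100),
    mk("B1", "wt", function(t) 0.10 + 0.02 * t, 0),
    mk("B2", "wt", function(t) 0.10 + 0.02 * t, 0)))
  expect_warning(cf <- correct_auto_by_od(ds, "tag", "wt"), "outside")
  # at the lowest tagged ODs the nearest untagged value (5 * 0.10) is used
  first <- cf$summary$mean[1]
  expect_equal(first, 5 * 0.01 + 100 - 5 * 0.10, tolerance = 1e-4)
})

test_that("untagged consistency flags a systematic offset and passes noise", {
  # iid noise only: corrected untagged fluorescence fluctuates around zero
  ds <- make_fluor_ds(n_tag = 2, n_untag = 4, noise = 0.3, seed = 5,
                      gfp_per_od = 0)
  cf <- suppressWarnings(correct_gfp(ds, "wt", "wt", r_g = 0.1))
  chk <- untagged_consistency(cf)
  expect_false(chk$flag)
  expect_lt(abs(chk$mean), 2 * chk$se + 1e-9)
  # zero noise: corrected is identically zero
  ds0 <- make_fluor_ds(n_tag = 2, n_untag = 4, noise = 0, gfp_per_od = 0)
  cf0 <- suppressWarnings(correct_gfp(ds0, "wt", "wt", r_g = 0.1))
  expect_equal(cf0$summary$mean, rep(0, 25), tolerance = 1e-9)
  # a constant +50 offset on F525 propagates through the formula and flags
  dso <- make_fluor_ds(n_tag = 2, n_untag = 4, noise = 1, seed = 6,
                       gfp_per_od = 0)
  tagsel <- dso$data$strain == "tag" & dso$data$signal == "F525"
  dso$data$value[tagsel] <- dso$data$value[tagsel] + 50
  cfo <- suppressWarnings(correct_gfp(dso, "tag", "wt", r_g = 0.1))
  expect_true(untagged_consistency(cfo)$flag)
  expect_gt(untagged_consistency(cfo)$mean, 10)
})

test_that("replicate-variance errors shrink as 1/n on iid replicates", {
  vars <- vapply(c(2, 4, 8), function(n) {
    ds <- make_fluor_ds(n_t = 80, n_tag = n, n_untag = 8, noise = 1,
                        seed = 11, gfp_per_od = 40,
                        od_fun = function(t) 0.2 * exp(0.25 * t))
    cf <- suppressWarnings(correct_gfp(ds, "tag", "wt", r_g = 0.1))
    expect_true(all(cf$summary$var >= 0))
    # variance of the replicate mean
    mean(cf$summary$var / cf$summary$n)
  }, 0)
  # halving steps: each doubling of n roughly halves the error of the mean
  expect_lt(vars[2] / vars[1], 0.75)
  expect_lt(vars[3] / vars[2], 0.75)
})

test_that("negative corrected values are retained, not clipped", {
  ds <- make_fluor_ds(n_tag = 2, n_untag = 4, noise = 2, seed = 8,
                      gfp_per_od = 0)
  cf <- suppressWarnings(correct_gfp(ds, "wt", "wt", r_g = 0.1))
  expect_true(any(cf$summary$mean < 0))
})
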