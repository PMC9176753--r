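# Data model: dialect parsing, annotation, well exclusion, exports, run log.

make_small_plate <- function(dir, n_t = 5) {
  times <- seq(0, 2, length.out = n_t)
  data_file <- file.path(dir, "d.tsv")
  writeLines(c(
    "OD\t(ex 600 nm)",
    paste(c("time_h", times), collapse = "\t"),
    paste(c("A1", 0.1 * (1:n_t)), collapse = "\t"),
    paste(c("A2", 0.2 * (1:n_t)), collapse = "\t"),
    paste(c("H1", rep(0.08, n_t)), collapse = "\t")),
    data_file)
  contents_file <- file.path(dir, "c.csv")
  grid <- matrix("", 8, 12)
  grid[1, 1] <- "wt in 1% glu"; grid[1, 2] <- "wt in 1% glu"
  grid[8, 1] <- "null in 1% glu"
  writeLines(apply(grid, 1, paste, collapse = ","), contents_file)
  list(data = data_file, contents = contents_file, times = times)
}

test_that("loading ingests all mapped wells and annotates from the grid", {
  p <- make_small_plate(withr::local_tempdir())
  ds <- load_plate(p$data, p$contents, "e1")
  expect_s3_class(ds, "plate_dataset")
  expect_setequal(unique(ds$data$well), c("A1", "A2", "H1"))
  expect_equal(nrow(ds$data), 15)
  expect_equal(unique(ds$data$strain[ds$data$well == "H1"]), "null")
  # ingestion preserves the value multiset
  expect_equal(sum(ds$data$value), sum(0.1 * (1:5)) + sum(0.2 * (1:5)) +
                 5 * 0.08)
  expect_identical(ds$raw, ds$data)
  expect_match(ds$log[length(ds$log)], "load_plate")
})

test_that("a full 96-well synthetic plate loads with media row annotated", {
  spec <- synth_plate_spec(duration = 2, interval = 0.5, seed = 2)
  gen <- generate_plate(spec, dir = withr::local_tempdir())
  ds <- load_plate(gen$data_file, gen$contents_file, "full")
  # 7 replicate rows x 10 concentrations + 10 media wells
  expect_equal(length(unique(ds$data$well)), 80)
  h <- ds$data[grepl("^H", ds$data$well), ]
  expect_true(all(h$strain == "null"))
})

test_that("time units are converted to hours at load", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "d.tsv")
  writeLines(c("OD", paste(c("time_s", c(0, 1800, 3600)), collapse = "\t"),
               paste(c("A1", c(1, 2, 3)), collapse = "\t")), f)
  expect_equal(read_plate_data(f)$time, c(0, 0.5, 1))
  writeLines(c("OD", paste(c("time_min", c(0, 30, 60)), collapse = "\t"),
               paste(c("A1", c(1, 2, 3)), collapse = "\t")), f)
  expect_equal(read_plate_data(f)$time, c(0, 0.5, 1))
})

test_that("structural and key-uniqueness faults are rejected by name", {
  dir <- withr::local_tempdir()
  p <- make_small_plate(dir)
  # duplicated timepoint for A1
  bad <- file.path(dir, "dup.tsv")
  writeLines(c("OD", paste(c("time_h", c(0, 2, 2)), collapse = "\t"),
               paste(c("A1", c(1, 2, 3)), collapse = "\t")), bad)
  expect_error(load_plate(bad, p$contents), "A1")
  # malformed grid: 7 rows
  short <- file.path(dir, "short.csv")
  writeLines(rep("wt in x,,,,,,,,,,,", 7), short)
  expect_error(load_plate(p$data, short), "8 rows")
  # wells missing from the map are dropped with a warning
  grid <- matrix("", 8, 12); grid[1, 1] <- "wt in 1% glu"
  partial <- file.path(dir, "partial.csv")
  writeLines(apply(grid, 1, paste, collapse = ","), partial)
  expect_warning(ds <- load_plate(p$data, partial), "A2")
  expect_setequal(unique(ds$data$well), "A1")
})

test_that("ignore_wells removes whole wells, is idempotent, warns on absent", {
  p <- make_small_plate(withr::local_tempdir())
  ds <- load_plate(p$data, p$contents, "e1")
  n0 <- nrow(ds$data)
  ds1 <- ignore_wells(ds, "A2")
  expect_equal(n0 - nrow(ds1$data), 5)   # timepoints x signals for A2
  expect_identical(ignore_wells(ds, character(0))$data, ds$data)
  suppressWarnings(ds2 <- ignore_wells(ds1, "A2"))
  expect_identical(ds2$data, ds1$data)
  expect_warning(ignore_wells(ds1, "A2"), "not present")
  expect_error(ignore_wells(ds, "Z9"), "invalid well")
})

test_that("plate plot draws one panel per mapped well and skips ignored ones", {
  spec <- synth_plate_spec(duration = 2, interval = 0.5, seed = 2)
  gen <- generate_plate(spec, dir = withr::local_tempdir())
  ds <- load_plate(gen$data_file, gen$contents_file, "full")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  fig <- plot_plate(ds, "OD")
  expect_equal(sort(fig$wells), sort(unique(ds$data$well)))
  expect_true(all(grepl("^H", fig$media_wells)))
  ds2 <- ignore_wells(ds, "A1")
  expect_false("A1" %in% plot_plate(ds2, "OD")$wells)
  expect_error(plot_plate(ds, "F525"), "unknown signal")
})

test_that("export/import round trips are lossless for tsv and json", {
  p <- make_small_plate(withr::local_tempdir())
  ds <- load_plate(p$data, p$contents, "e1")
  ds$data$value <- ds$data$value * pi   # non-terminating decimals
  stem <- file.path(withr::local_tempdir(), "out")
  export_dataset(ds, stem, "tsv")
  back <- import_dataset(stem, "tsv")
  expect_identical(back$processed$value, ds$data$value)
  expect_identical(back$raw$value, ds$raw$value)
  export_dataset(ds, stem, "json")
  backj <- import_dataset(stem, "json")
  expect_equal(backj$processed$value, ds$data$value, tolerance = 1e-15)
  # csv workbook writes one sheet per table
  wb <- file.path(withr::local_tempdir(), "wb")
  export_dataset(ds, wb, "csv-workbook")
  expect_setequal(list.files(wb), c("raw.csv", "processed.csv"))
  # empty dataset refuses to export
  ds$data <- ds$data[0, ]
  expect_error(export_dataset(ds, stem, "tsv"), "empty")
})

test_that("the run log records each call and exports as text", {
  p <- make_small_plate(withr::local_tempdir())
  ds <- load_plate(p$data, p$contents, "e1")
  ds <- ignore_wells(ds, "A2")
  f <- file.path(withr::local_tempdir(), "log.txt")
  write_run_log(ds, f)
  lg <- readLines(f)
  expect_length(lg, 2)
  expect_match(lg[1], "load_plate")
  expect_match(lg[2], "ignore_wells.*A2")
})
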