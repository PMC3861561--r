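test_that("field annotations are constructed and validated against geometry", {
  geo <- field_geometry(100, 50)
  f <- field_annotation("c1", "f1",
                        data.frame(x = c(10, 20, 100), y = c(5, 5, 50),
                                   label = c("positive", "positive", "negative")),
                        geo)
  expect_s3_class(f, "field_annotation")
  expect_equal(nrow(f$markers), 3)
  # border marker (100, 50) is in-bounds: closed interval
  expect_error(
    field_annotation("c1", "f1",
                     data.frame(x = 100.01, y = 5, label = "positive"), geo),
    class = "ki67_validation_error")
  expect_error(
    field_annotation("c1", "f1",
                     data.frame(x = 10, y = 5, label = "pos"), geo),
    regexp = "pos", class = "ki67_validation_error")
})

test_that("validation partitions rows: accepted + rejected = input", {
  geo <- field_geometry(100, 50)
  set.seed(11)
  n <- 60
  df <- data.frame(x = runif(n, -20, 120), y = runif(n, -10, 60),
                   label = sample(c("positive", "negative", "bogus"), n,
                                  replace = TRUE, prob = c(.45, .45, .1)))
  res <- validate_marker_rows(df, geo)
  expect_equal(nrow(res$accepted) + nrow(res$rejected), n)
  # every rejected row really violates a rule; every accepted row violates none
  viol <- !(df$label %in% c("positive", "negative")) |
    df$x < 0 | df$x > 100 | df$y < 0 | df$y > 50
  expect_equal(sort(res$rejected$row), which(viol))
})

test_that("CSV and GeoJSON round-trips preserve counts, labels and coordinates", {
  geo <- ref_geometry()
  fields <- list(make_field(45, 128, "c1", "f1", geo),
                 make_field(3, 7, "c1", "f2", geo),
                 make_field(0, 12, "c2", "f1", geo))
  for (ext in c(".csv", ".geojson")) {
    path <- withr::local_tempfile(fileext = ext)
    write_field_annotations(fields, path, unit = "um")
    back <- read_field_annotations(path, calibration = geo)
    expect_named(back, c("c1/f1", "c1/f2", "c2/f1"))
    for (k in names(back)) {
      orig <- fields[[match(k, c("c1/f1", "c1/f2", "c2/f1"))]]
      expect_identical(back[[k]]$markers$label, orig$markers$label)
      expect_equal(back[[k]]$markers$x, orig$markers$x, tolerance = 1e-8)
      expect_equal(back[[k]]$markers$y, orig$markers$y, tolerance = 1e-8)
    }
  }
})

test_that("pixel-unit round trip converts through the calibration scale", {
  geo <- field_geometry(310.3, 232.72, um_per_px = 0.12121)
  f <- make_field(5, 5, geometry = geo)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_annotations(f, path, unit = "px")
  expect_match(readLines(path, n = 1), "# unit: px", fixed = TRUE)
  back <- read_field_annotations(path, calibration = geo)  # unit from header
  expect_equal(back[[1]]$markers$x, f$markers$x, tolerance = 1e-6)
  # px coordinates without a scale are an error
  f_noscale <- make_field(2, 2, geometry = field_geometry(310.3, 232.72))
  expect_error(write_field_annotations(f_noscale, path, unit = "px"),
               regexp = "um_per_px", class = "ki67_validation_error")
})

test_that("read errors name the missing piece", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case_id,x,y,label", "c1,1,2,positive"), path)
  expect_error(read_field_annotations(path, unit = "um"),
               regexp = "field_id", class = "ki67_validation_error")
  expect_error(read_field_annotations("no/such/file.csv"),
               class = "ki67_io_error")
})

test_that("empty collections write header-only files that read back empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_annotations(list(), path)
  expect_length(read_field_annotations(path, unit = "um"), 0)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_field_annotations(list(), gj)
  expect_length(read_field_annotations(gj, unit = "um"), 0)
})

test_that("calibration sidecars load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("width_um: 310.3", "height_um: 232.72", "um_per_px: 0.12121"), yml)
  geo <- read_calibration(yml)
  expect_equal(geo$width_um, 310.3)
  expect_equal(geo$um_per_px, 0.12121)
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"width_um": 1000, "height_um": 1000}', js)
  expect_equal(field_area_mm2(read_calibration(js)), 1)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("width_um: 310.3", bad)
  expect_error(read_calibration(bad), class = "ki67_validation_error")
})

test_that("near-duplicate flagging matches a brute-force pair scan", {
  geo <- field_geometry(100, 100)
  # collinear markers at x = 0, 3, 6 um with threshold 4: pairs (1,2), (2,3)
  f <- field_annotation("c", "f",
                        data.frame(x = c(0, 3, 6), y = 0,
                                   label = "negative"), geo)
  got <- flag_near_duplicates(f, 4)
  expect_equal(got$i, c(1L, 2L))
  expect_equal(got$j, c(2L, 3L))
  expect_equal(got$distance_um, c(3, 3))
  expect_equal(nrow(flag_near_duplicates(f, 0)), 0)

  set.seed(21)
  rf <- field_annotation("c", "f",
                         data.frame(x = runif(40, 0, 30), y = runif(40, 0, 30),
                                    label = "positive"), geo)
  thr <- 2.5
  brute <- list()
  for (i in 1:39) for (j in (i + 1):40) {
    d <- sqrt((rf$markers$x[i] - rf$markers$x[j])^2 +
                (rf$markers$y[i] - rf$markers$y[j])^2)
    if (d < thr) brute[[length(brute) + 1]] <- c(i, j)
  }
  got <- flag_near_duplicates(rf, thr)
  expect_equal(nrow(got), length(brute))
  expect_equal(Map(c, got$i, got$j), unname(brute), ignore_attr = TRUE)
  # input not mutated
  expect_equal(nrow(rf$markers), 40)
})
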