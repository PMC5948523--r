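# Channel filtering, interpolation, normalization and windowing

make_schema4 <- function() {
  channel_schema(c("a", "b", "q", "lab"),
                 c("body", "body", "quaternion", "label"))
}

test_that("read_sensor_table parses sentinels, degenerate and bad input", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("1 2 3 0", "4 NaN 6 1", "7 8 9 0"), path)
  fr <- read_sensor_table(path, make_schema4())
  expect_identical(dim(fr$values), c(3L, 3L))
  expect_identical(sum(is.na(fr$values)), 1L)
  expect_true(is.na(fr$values[2, 2]))
  expect_identical(fr$labels, c(0L, 1L, 0L))

  empty <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(0), empty)
  fr0 <- read_sensor_table(empty, make_schema4())
  expect_identical(nrow(fr0$values), 0L)

  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("1 2 3 0", "4 x 6 1"), bad)
  expect_error(read_sensor_table(bad, make_schema4()),
               "row 2", class = "gennas_parse_error")

  wide <- withr::local_tempfile(fileext = ".dat")
  writeLines("1 2 3", wide)
  expect_error(read_sensor_table(wide, make_schema4()),
               class = "gennas_schema_error")
})

test_that("numeric sentinels are converted to the missing mask", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("1 -999 3 0", "4 5 6 1"), path)
  fr <- read_sensor_table(path, make_schema4(), sentinel = -999)
  expect_true(is.na(fr$values[1, 2]))
  expect_identical(sum(is.na(fr$values)), 1L)
})

test_that("sensor tables round-trip through write/read", {
  cfg <- synth_config(n_classes = 3, n_body = 4, n_quaternion = 1,
                      n_object = 1, T = 200, missing_rate = 0.01, seed = 3)
  fr <- generate_frame(cfg)$frame
  path <- withr::local_tempfile(fileext = ".dat")
  write_sensor_table(fr, path)
  fr2 <- read_sensor_table(path, fr$schema)
  expect_equal(fr2$values, fr$values, tolerance = 1e-12)
  expect_identical(fr2$labels, fr$labels)
  expect_identical(is.na(fr2$values), is.na(fr$values))
})

test_that("filter_channels keeps body channels only", {
  fx <- opportunity_like_fixture(1)
  expect_identical(ncol(fx$values), 248L)          # 113 + 16 + 119
  filtered <- filter_channels(fx)
  expect_identical(ncol(filtered$values), 113L)
  expect_true(all(filtered$schema$role %in% c("body", "label")))

  all_body <- sensor_frame(matrix(1:6, 3), rep(0L, 3))
  expect_identical(filter_channels(all_body)$values, all_body$values)

  quat_only <- sensor_frame(matrix(1:6, 3), rep(0L, 3),
                            channel_schema(c("q1", "q2", "lab"),
                                           c("quaternion", "quaternion",
                                             "label")))
  expect_error(filter_channels(quat_only), class = "gennas_validation_error")
})

test_that("interpolation fills interior gaps linearly and zero-fills edges", {
  fr <- sensor_frame(cbind(c(1, NA, 3), c(NA, NA, 5)), rep(0L, 3))
  out <- interpolate_missing(fr)
  expect_equal(out$values[, 1], c(1, 2, 3))
  expect_equal(out$values[, 2], c(0, 0, 5))
  expect_false(anyNA(out$values))
})

test_that("interpolation agrees with brute-force per-gap two-point interpolation", {
  set.seed(17)
  for (rep in 1:20) {
    T <- 50
    v <- matrix(rnorm(T * 3), T, 3)
    mask <- matrix(runif(T * 3) < 0.3, T, 3)
    vm <- v; vm[mask] <- NA
    out <- interpolate_missing(sensor_frame(vm, rep(0L, T)))
    expect_false(anyNA(out$values))
    for (c in 1:3) {
      col <- vm[, c]
      ref <- col
      ok <- which(!is.na(col))
      for (t in which(is.na(col))) {
        lo <- suppressWarnings(max(ok[ok < t])); hi <- suppressWarnings(min(ok[ok > t]))
        ref[t] <- if (is.infinite(lo) || is.infinite(hi)) 0
        else col[lo] + (col[hi] - col[lo]) * (t - lo) / (hi - lo)
      }
      expect_equal(out$values[, c], ref, tolerance = 1e-12)
    }
  }
})

test_that("normalization maps endpoints, handles constants, clips foreign stats", {
  fr <- sensor_frame(cbind(c(0, 5, 10), c(2, 2, 2)), rep(0L, 3))
  out <- normalize_frame(fr)
  expect_equal(out$values[, 1], c(0, 0.5, 1))
  expect_equal(out$values[, 2], c(0, 0, 0))

  stats <- compute_norm_stats(sensor_frame(cbind(c(0, 10), c(0, 1)),
                                           rep(0L, 2)))
  ev <- normalize_frame(sensor_frame(cbind(c(-5, 20), c(0.5, 2)),
                                     rep(0L, 2)), stats)
  expect_true(all(ev$values >= 0 & ev$values <= 1))
  expect_equal(ev$values[1, 1], 0, ignore_attr = TRUE)   # clipped below
  expect_equal(ev$values[2, 1], 1, ignore_attr = TRUE)   # clipped above
})

test_that("normalization with own stats is idempotent", {
  set.seed(19)
  fr <- sensor_frame(matrix(rnorm(200), 50, 4), rep(0L, 50))
  n1 <- normalize_frame(fr)
  n2 <- normalize_frame(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)
})

test_that("compute_norm_stats matches a brute-force scan", {
  set.seed(23)
  fr <- sensor_frame(matrix(rnorm(300), 100, 3), rep(0L, 100))
  st <- compute_norm_stats(fr)
  for (c in 1:3) {
    expect_identical(st$min[[c]], min(fr$values[, c]))
    expect_identical(st$max[[c]], max(fr$values[, c]))
  }
  one <- compute_norm_stats(sensor_frame(matrix(c(3, 7), 1), 0L))
  expect_identical(one$min, one$max)
})

test_that("window counts follow floor((T - w)/wstep) + 1", {
  mkframe <- function(T) sensor_frame(matrix(runif(T * 2), T, 2),
                                      rep_len(0:1, T))
  set.seed(29)
  expect_identical(dim(slide_windows(mkframe(100), 32, 1)$tensor)[[1]], 69L)
  expect_identical(dim(slide_windows(mkframe(32), 32, 1)$tensor)[[1]], 1L)
  expect_identical(dim(slide_windows(mkframe(24), 24, 2)$tensor)[[1]], 1L)
  expect_identical(dim(slide_windows(mkframe(26), 24, 2)$tensor)[[1]], 2L)
  # brute-force enumeration of start indices across a grid
  for (T in c(10, 47, 100)) for (w in c(3, 10)) for (s in c(1, 2, 4)) {
    N <- dim(slide_windows(mkframe(T), w, s)$tensor)[[1]]
    expect_identical(N, length(seq(0, T - w, by = s)))
  }
  expect_warning(wd0 <- slide_windows(mkframe(5), 10, 1), "0 windows")
  expect_identical(dim(wd0$tensor)[[1]], 0L)
})

test_that("windows carry the right content, labels and tensor layout", {
  T <- 30
  vals <- cbind(seq_len(T), 100 + seq_len(T))
  fr <- sensor_frame(vals, c(rep(0L, 15), rep(1L, 15)))
  wd <- slide_windows(fr, 10, 5)
  expect_identical(dim(wd$tensor), c(5L, 1L, 10L, 2L))
  expect_identical(wd$starts, c(0L, 5L, 10L, 15L, 20L))
  # window k covers timesteps [start, start + w)
  for (k in 1:5)
    expect_equal(wd$tensor[k, 1, , 1], vals[(wd$starts[[k]] + 1):(wd$starts[[k]] + 10), 1])
  # default label = last timestep's label
  expect_identical(wd$labels, fr$labels[wd$starts + 10L])
  wmaj <- slide_windows(fr, 10, 5, label_rule = "majority")
  expect_identical(wmaj$labels[[1]], 0L)
  expect_identical(wmaj$labels[[5]], 1L)
})

test_that("non-overlapping windows reconstruct the original series", {
  set.seed(37)
  fr <- sensor_frame(matrix(runif(120 * 3), 120, 3), rep(0L, 120))
  w <- 16
  wd <- slide_windows(fr, w, w)
  N <- dim(wd$tensor)[[1]]
  rebuilt <- do.call(rbind, lapply(seq_len(N), function(k)
    matrix(wd$tensor[k, 1, , ], w)))
  expect_equal(rebuilt, unname(fr$values[seq_len(N * w), ]), tolerance = 1e-15)
})

test_that("the pipeline rejects missing values reaching normalize", {
  fr <- sensor_frame(cbind(c(1, NA, 3)), rep(0L, 3))
  expect_error(normalize_frame(fr), "interpolate")
  expect_error(compute_norm_stats(fr), "interpolate")
  wd <- preprocess_pipeline(generate_frame(synth_config(T = 200, seed = 4))$frame,
                            w = 16, wstep = 4)
  expect_true(all(wd$tensor >= 0 & wd$tensor <= 1))
})
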