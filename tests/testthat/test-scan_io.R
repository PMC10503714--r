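test_that("scan path enumeration reproduces the numbered-file convention", {
  d <- withr::local_tempdir()
  nums <- seq(1, 101, by = 10)
  for (n in nums) file.create(file.path(d, sprintf("%05d.ip2", n)))
  p <- enumerate_scan_paths(d, "IP2", 1, 101, 10)
  expect_length(p, 11)
  expect_identical(basename(p),
                   c("00001.ip2", "00011.ip2", "00021.ip2", "00031.ip2",
                     "00041.ip2", "00051.ip2", "00061.ip2", "00071.ip2",
                     "00081.ip2", "00091.ip2", "00101.ip2"))

  file.create(file.path(d, "00007.ip2"))
  expect_identical(basename(enumerate_scan_paths(d, "ip2", 7, 7, 5)),
                   "00007.ip2")

  expect_error(enumerate_scan_paths(d, "ip2", 2, 20, 3), class = "sv_io_error")
  expect_error(enumerate_scan_paths(d, "ip2", 5, 2, 1), class = "sv_value_error")
})

test_that("enumeration count follows the arithmetic-progression formula", {
  set.seed(101)
  for (i in 1:50) {
    first <- sample(1:50, 1)
    last <- first + sample(0:200, 1)
    interval <- sample(1:17, 1)
    p <- enumerate_scan_paths(tempdir(), "xx1", first, last, interval,
                              must_exist = FALSE)
    expect_length(p, (last - first) %/% interval + 1)
  }
})

test_that("scan files round-trip bit-exactly at the written precision", {
  d <- withr::local_tempdir()
  sc <- make_scan(radii = seq(5.95, 7.2, by = 0.01),
                  signal = sin(seq(5.95, 7.2, by = 0.01)) * 0.3 + 0.5,
                  time_s = 3600, rpm = 50000, temp = 20.1)
  p1 <- file.path(d, "00001.ra1")
  write_scan(sc, p1)
  back <- read_scan(p1)
  expect_equal(back$rpm, 50000)
  expect_equal(back$time_s, 3600)
  expect_equal(back$temperature, 20.1)
  expect_equal(length(back$radii), length(sc$radii))
  p2 <- file.path(d, "00002.ra1")
  write_scan(back, p2)
  expect_identical(readLines(p1)[-1], readLines(p2)[-1])  # same numeric body
})

test_that("malformed scan files are rejected with classed errors", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.ra1")
  writeLines(c("desc", "R 1 20.00 50000 600.00 1.6e+09 280.00 1",
               "6.0000\t0.1", "5.9000\t0.2"), p)
  expect_error(read_scan(p), class = "sv_data_error")
  writeLines(c("desc", "R 1", "6.0\t0.1", "6.1\t0.2"), p)
  expect_error(read_scan(p), class = "sv_format_error")
  writeLines(c("desc", "R 1 20.00 50000 600.00 1.6e+09 280.00 1",
               "6.0000\t0.1"), p)
  expect_error(read_scan(p), class = "sv_format_error")
})

test_that("spike filter removes exactly the isolated double-sided outliers", {
  r <- seq(6, 7, by = 0.01)
  smooth <- make_scan(r, 1 / (1 + exp(-(r - 6.5) * 30)))
  f <- filter_spikes(smooth, 0.4)
  expect_identical(f$removed, 0L)
  expect_identical(f$scan$signal, smooth$signal)

  sig <- rep(0, 21); sig[11] <- 0.5
  spiky <- make_scan(seq(6, 6.2, by = 0.01), sig)
  f <- filter_spikes(spiky, 0.4)
  expect_identical(f$removed, 1L)
  expect_length(f$scan$signal, 20)
  expect_false(6.10 %in% f$scan$radii)

  f2 <- filter_spikes(spiky, 0.6)   # deviation 0.5 does not exceed 0.6
  expect_identical(f2$removed, 0L)
})

test_that("spike filter is idempotent, including cascaded spikes", {
  # single sweep would unmask the second point; sweeps run to a fixpoint
  sc <- make_scan(seq(6, 6.03, by = 0.01), c(0, 0.9, 0.45, 0))
  f1 <- filter_spikes(sc, 0.4)
  f2 <- filter_spikes(f1$scan, 0.4)
  expect_identical(f2$removed, 0L)
  expect_identical(f1$scan$signal, f2$scan$signal)

  set.seed(7)
  for (i in 1:20) {
    n <- 60
    sig <- cumsum(rnorm(n, 0, 0.05))
    idx <- sample(3:(n - 2), 4)
    sig[idx] <- sig[idx] + 1
    sc <- make_scan(seq(6, by = 0.003, length.out = n), sig)
    f1 <- filter_spikes(sc, 0.4)
    f2 <- filter_spikes(f1$scan, 0.4)
    expect_identical(f2$removed, 0L)
  }
})

test_that("fit-range restriction keeps exactly the in-range points, idempotently", {
  r <- seq(5.9, 7.2, by = 0.01)
  ss <- scan_set(list(make_scan(r, r * 0, time_s = 600),
                      make_scan(r, r * 0 + 1, time_s = 1200)))
  out <- restrict_fit_range(ss, 6.0, 7.1)
  expect_true(all(vapply(out$scans,
                         function(s) all(s$radii >= 6.0 & s$radii <= 7.1),
                         logical(1))))
  expect_false(is.unsorted(out$scans[[1]]$radii))
  again <- restrict_fit_range(out, 6.0, 7.1)
  expect_identical(again$scans[[1]]$radii, out$scans[[1]]$radii)

  full <- restrict_fit_range(ss, 5.8, 7.3)
  expect_identical(full$scans[[1]]$radii, r)

  expect_error(restrict_fit_range(ss, 7.25, 7.3), class = "sv_data_error")
})

test_that("metadata aggregation summarizes the scan headers", {
  r <- seq(6, 7, by = 0.05)
  scans <- list(make_scan(r, r * 0, time_s = 600, temp = 20.0),
                make_scan(r, r * 0, time_s = 1200, temp = 20.1),
                make_scan(r, r * 0, time_s = 3600, temp = 19.9,
                          w2t = 1.2e11))
  md <- aggregate_metadata(scan_set(scans))
  expect_equal(md$TemperatureStart, 20.0)
  expect_equal(md$TemperatureEnd, 19.9)
  expect_equal(md$TemperatureAverage, 20.0)
  expect_equal(md$TemperatureDiffMaxMin, 0.2, tolerance = 1e-12)
  expect_equal(md$tLastScan, 3600)
  expect_equal(md$w2tLastScan, 1.2e11)
  expect_false(md$CheckTimeStamps)   # no source files on disk

  md1 <- aggregate_metadata(scan_set(scans[1]))
  expect_equal(md1$TemperatureStart, md1$TemperatureEnd)
  expect_equal(md1$TemperatureDiffMaxMin, 0)
})
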