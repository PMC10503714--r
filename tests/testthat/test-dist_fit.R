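test_that("s-grids are built as arithmetic or geometric progressions", {
  expect_equal(build_grid(1, 10, 10, FALSE)$values, 1:10)
  expect_equal(build_grid(1, 100, 3, TRUE)$values, c(1, 10, 100))
  expect_equal(build_grid(0.5, 25, 2, FALSE)$values, c(0.5, 25))
  expect_error(build_grid(10, 1, 5), class = "sv_value_error")
  expect_error(build_grid(1, 10, 1), class = "sv_value_error")
})

test_that("sdist grid files read, reject disorder, and round-trip", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sdist.ra1")
  writeLines(c("1", "2", "5"), p)
  expect_equal(grid_from_file(p)$values, c(1, 2, 5))

  writeLines(c("2", "1"), p)
  expect_error(grid_from_file(p), class = "sv_data_error")
  writeLines(c("1", "two"), p)
  expect_error(grid_from_file(p), class = "sv_format_error")

  g <- build_grid(0.7, 31.4, 40, TRUE)
  write_sdist(g, p)
  expect_equal(grid_from_file(p)$values, g$values, tolerance = 1e-10)
})

test_that("design matrices hold unit-loading kernels on the data grid", {
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  radii <- seq(6.05, 7.1, by = 0.02)
  times <- c(600, 1500, 2400)
  ss <- scan_set(lapply(times, function(t) make_scan(radii, radii * 0, time_s = t)))
  grid <- build_grid(2, 10, 9, FALSE)

  dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)
  expect_identical(dim(dm$columns), c(length(radii) * 3L, 9L))
  expect_identical(nrow(dm$row_index), nrow(dm$columns))

  # lsgofs columns equal the closed-form step/dilution formula at every row
  dl <- build_design_matrix(grid, "lsgofs", NA, cond, geom, 50000, ss)
  for (k in c(1, 5, 9)) {
    expected <- unlist(lapply(times, function(t)
      nondiffusing_profile(grid$values[k], geom, 50000, t, radii)))
    expect_equal(dl$columns[, k], expected, tolerance = 1e-12)
  }

  # at t = 0 every kernel equals the uniform unit loading
  ss0 <- scan_set(lapply(c(1e-6, 600), function(t)
    make_scan(radii, radii * 0, time_s = t)))
  dm0 <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss0)
  first_rows <- dm0$row_index$time < 1
  expect_lt(max(abs(dm0$columns[first_rows, ] - 1)), 1e-6)
})

test_that("noiseless single-species data are recovered exactly at their node", {
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  radii <- seq(6.05, 7.1, by = 0.01)
  times <- c(800, 1600, 2400, 3200)
  ss <- scan_set(lapply(times, function(t) make_scan(radii, radii * 0, time_s = t)))
  grid <- build_grid(1, 10, 19, FALSE)       # node exactly at 5 S
  dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)

  j <- which(grid$values == 5)
  loading <- 0.8
  y <- dm$columns[, j] * loading
  off <- 0L
  for (i in seq_along(ss$scans)) {
    n <- length(radii)
    ss$scans[[i]]$signal <- y[off + seq_len(n)]
    off <- off + n
  }
  fit <- fit_linear(ss, dm, reg = NULL, ti = FALSE, ri = FALSE)
  expect_lt(abs(sum(fit$amounts) - loading) / loading, 1e-3)
  expect_lt(abs(fit$amounts[j] - loading) / loading, 1e-3)
  expect_lt(max(fit$c[-j]) , 1e-3 * fit$c[j])
})

test_that("pure TI profiles separate into noise, leaving a zero distribution", {
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  radii <- seq(6.05, 7.1, by = 0.01)
  ss <- scan_set(lapply(c(700, 1400, 2100), function(t)
    make_scan(radii, 0.05 * sin(8 * radii) + 0.02, time_s = t)))
  grid <- build_grid(2, 8, 7, FALSE)
  dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)
  fit <- suppressWarnings(fit_linear(ss, dm, reg = NULL, ti = TRUE, ri = FALSE))
  expect_lt(sqrt(mean((fit$ti_noise$value -
                         (0.05 * sin(8 * radii) + 0.02))^2)), 1e-6)
  expect_true(all(fit$c == 0))
})

test_that("the active-set NNLS solver matches the exhaustive subset oracle", {
  set.seed(33)
  for (i in 1:25) {
    X <- matrix(rnorm(15), 5, 3)
    y <- rnorm(5)
    f <- nnls_fit(X, y)
    o <- nnls_oracle(X, y)
    expect_true(f$kkt_ok)
    expect_equal(f$x, o$x, tolerance = 1e-7)
    expect_equal(f$deviance, o$ssr, tolerance = 1e-8)
  }
  for (i in 1:5) {
    X <- matrix(rnorm(60), 10, 6)
    y <- rnorm(10)
    f <- nnls_fit(X, y)
    o <- nnls_oracle(X, y)
    expect_equal(f$deviance, o$ssr, tolerance = 1e-8)
  }
})

test_that("algebraic noise projection equals the joint explicit solve", {
  set.seed(91)
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  radii <- seq(6.1, 6.4, by = 0.03)
  for (rep in 1:8) {
    ss <- scan_set(lapply(c(500, 1500, 2500), function(t)
      make_scan(radii, rnorm(length(radii), 0.3, 0.1), time_s = t)))
    grid <- build_grid(2, 9, 3, FALSE)
    dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)
    fit <- fit_linear(ss, dm, reg = NULL, ti = TRUE, ri = TRUE)

    # oracle: exhaustive passive subsets of c with the noise columns free
    y <- unlist(lapply(ss$scans, `[[`, "signal"))
    w <- fit$weights
    Xe <- sweep(dm$columns, 2, w, "*")
    nd <- svengine:::sv_noise_design(dm$row_index, TRUE, TRUE, FALSE)
    k <- ncol(Xe)
    best <- NULL
    for (code in 0:(2^k - 1)) {
      S <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
      A <- cbind(Xe[, S, drop = FALSE], nd$N)
      beta <- qr.coef(qr(A), y)
      beta[is.na(beta)] <- 0
      cS <- beta[seq_along(S)]
      if (length(S) && any(cS < -1e-10)) next
      ssr <- sum((y - A %*% beta)^2)
      if (is.null(best) || ssr < best$ssr - 1e-12) {
        x <- numeric(k); x[S] <- pmax(cS, 0)
        best <- list(ssr = ssr, x = x)
      }
    }
    expect_equal(fit$ssr, best$ssr, tolerance = 1e-8)
    expect_equal(fit$c, best$x, tolerance = 1e-6)
  }
})

test_that("regularization trades SSR for breadth as the p-value grows", {
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  g <- small_dataset(withr::local_tempdir(), noise = 0.005, seed = 5)
  scans <- lapply(g$scan_paths, read_scan)
  ss <- restrict_fit_range(scan_set(scans, "ra1", g$scan_paths), 6.05, 7.1)
  grid <- build_grid(1, 10, 25, FALSE)
  dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)

  breadth <- function(p) {
    fit <- fit_linear(ss, dm, reg = regularization_spec("Tikhonov", p))
    pk <- integrate_distribution(fit, 1, 10)
    m2 <- sum(fit$amounts * (grid$values - pk$sw)^2) / sum(fit$amounts)
    c(ssr = fit$ssr, m2 = m2, lambda = fit$lambda)
  }
  b55 <- breadth(0.55); b95 <- breadth(0.95)
  expect_gte(b95[["ssr"]], b55[["ssr"]] - 1e-12)
  expect_gte(b95[["m2"]], b55[["m2"]] - 1e-12)
  expect_gte(b95[["lambda"]], b55[["lambda"]])
})

test_that("noise folding and bookkeeping reconstruct the stored fit exactly", {
  geom <- cell_geometry(6, 7.2); cond <- solution_conditions()
  g <- small_dataset(withr::local_tempdir(), noise = 0.004, seed = 6)
  scans <- lapply(g$scan_paths, read_scan)
  ss <- restrict_fit_range(scan_set(scans, "ra1", g$scan_paths), 6.05, 7.1)
  grid <- build_grid(1, 10, 20, FALSE)
  dm <- build_design_matrix(grid, "cofs", 1.3, cond, geom, 50000, ss)
  fit <- fit_linear(ss, dm, reg = NULL, ti = TRUE, ri = TRUE)

  folded <- fold_noise(fit, ss)
  expect_identical(nrow(folded$ri), length(ss$scans))
  expect_identical(nrow(folded$ti), length(unique(dm$row_index$radius)))

  # fit = X c + TI + RI + b reproduces the stored per-point values
  Xe <- sweep(dm$columns, 2, fit$weights, "*")
  recon <- drop(Xe %*% fit$c) + fit$baseline +
    folded$ti$value[match(dm$row_index$radius, folded$ti$radius)] +
    folded$ri$value[dm$row_index$scan]
  expect_lt(max(abs(recon - fit$fitted)), 1e-10)

  fit_no_ti <- fit_linear(ss, dm, reg = NULL, ti = FALSE, ri = TRUE)
  folded2 <- fold_noise(fit_no_ti, ss)
  expect_true(all(folded2$ti$value == 0))
})

test_that("distribution integration reproduces hand-computed windows", {
  grid <- list(values = seq(1, 12, by = 0.01))
  cc <- numeric(length(grid$values))
  tri <- function(center, half, area) {
    h <- area / half                 # triangle height so that area matches
    v <- pmax(0, 1 - abs(grid$values - center) / half) * h
    v
  }
  cc <- tri(6.5, 0.2, 0.3) + tri(9.5, 0.2, 0.1)
  res <- list(grid = grid, c = cc)
  w <- integrate_distribution(res, 5, 8)
  expect_equal(w$fraction, 75, tolerance = 1e-3)
  full <- integrate_distribution(res, 1, 12)
  expect_equal(full$fraction, 100, tolerance = 1e-12)
  expect_equal(full$sw, 7.25, tolerance = 1e-3)

  empty <- integrate_distribution(res, 2, 3)
  expect_equal(empty$fraction, 0)
  expect_false(empty$defined)
  expect_true(is.na(empty$sw))

  expect_error(integrate_distribution(res, 8, 5), class = "sv_value_error")
  expect_error(integrate_distribution(res, 13, 14), class = "sv_value_error")
})
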