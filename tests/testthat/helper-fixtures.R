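# In-code fixtures: scans and small synthetic experiments built at test time.

make_scan <- function(radii, signal, time_s = 600, rpm = 50000, temp = 20,
                      w2t = NULL, wavelength = 280, desc = "test scan") {
  if (is.null(w2t)) w2t <- (rpm * pi / 30)^2 * time_s
  structure(list(description = desc, data_type = "R", cell = 1L,
                 temperature = temp, rpm = rpm, time_s = time_s, w2t = w2t,
                 wavelength = wavelength, radii = radii, signal = signal),
            class = "sv_scan")
}

# write a tiny synthetic experiment and return its directory + truth
small_dataset <- function(dir,
                          species = data.frame(s = 5, ffr = 1.3, loading = 0.8),
                          noise = 0.005, seed = 42,
                          times = seq(600, 4200, by = 600),
                          geometry = cell_geometry(6, 7.2),
                          n_spikes = 0L, ti = 0.008, ri = 0.004) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- simulation_spec(species, geometry, 50000, times,
                          noise_sigma = noise, ti_amplitude = ti,
                          ri_amplitude = ri, n_spikes = n_spikes, seed = seed)
  generate_dataset(spec, dir)
}

# a complete small request for lsgofs Run-only sessions (fast: no PDE solves)
quick_request <- function(root, data_dir, n_scans, ...) {
  analysis_request(
    AllDoneFlagFile = file.path(root, "done.txt"),
    OutputResultsDirectory = file.path(root, "results"),
    DataDirectory = data_dir, Channel = "ra1",
    FirstScan = 1L, LastScan = as.integer(n_scans),
    Meniscus = 6.0, Bottom = 7.2,
    LeftFitLimit = 6.05, RightFitLimit = 7.1,
    Model = "lsgofs", Resolution = 25L, Smin = 1, Smax = 12,
    RegularizationType = "Tikhonov", AutoRun = TRUE,
    ...
  )
}

run_quick_session <- function(root, handshake = "hs", mode = "111", ...) {
  data_dir <- file.path(root, "data")
  small_dataset(data_dir)
  req <- quick_request(root, data_dir, 7, ...)
  xml <- file.path(root, "in.xml")
  write_request_xml(req, xml)
  run_session(parse_command_line(c(mode, handshake, xml)))
}

# exact integral of a piecewise-linear concentration profile times r
pl_mass <- function(r, c) {
  a <- r[-length(r)]; b <- r[-1]
  ca <- c[-length(c)]; cb <- c[-1]
  sum((b - a) / 6 * (ca * (2 * a + b) + cb * (a + 2 * b)))
}

# brute-force NNLS oracle: feasible least squares over all passive subsets
nnls_oracle <- function(X, y) {
  k <- ncol(X)
  best <- list(x = numeric(k), ssr = sum(y^2))
  for (code in seq_len(2^k) - 1L) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
    if (!length(S)) next
    beta <- tryCatch(qr.solve(X[, S, drop = FALSE], y),
                     error = function(e) NULL)
    if (is.null(beta) || any(beta < 0)) next
    x <- numeric(k); x[S] <- beta
    ssr <- sum((y - X %*% x)^2)
    if (ssr < best$ssr - 1e-12) best <- list(x = x, ssr = ssr)
  }
  best
}
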