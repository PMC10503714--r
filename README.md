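# svengine

Headless, automation-compatible sedimentation-velocity analytical
ultracentrifugation (SV-AUC) analysis.

SV-AUC measures particle size distributions from the evolution of
concentration profiles in a spinning sector-shaped cell, and is a workhorse
for characterizing protein therapeutics, vaccines, viral vectors and
nanoparticles. The analyses that dominate practice are sedimentation
coefficient distributions obtained by direct boundary fitting: the apparent
distribution ls-g\*(s) (non-diffusing step kernels) and the
diffusion-deconvoluted distribution c(s). Regulated (GMP-style) environments
additionally need the analysis to run as a spawned computational module with
controlled file-based input and output, so that a supervising program can
enforce access control, audit trails and meta-analyses.

`svengine` provides both pieces:

* **Protocol** — the engine is started with three command-line tokens
  (`<mode> <handshake> <input.xml>`), reads its ~40 analysis parameters from
  an XML file with root `cGMPSedfitCall`, writes all results to files in a
  freshly created output directory, and finally creates a flag file whose
  sole content is the handshake string. The flag file is written strictly
  last, so its existence certifies a complete result set. Mode `111` allows
  every option; mode `112` is a restricted profile for elementary
  size-distribution analyses.
* **Analysis** — direct boundary modelling of the loaded scans
  `a(r, t) = ∫ c(s) K(s; r, t) ds + TI(r) + RI(t) + b + ε`, where the kernel
  `K` is either the non-diffusing step/dilution profile (ls-g\*(s)) or a
  finite-element Lamm-equation solution (c(s)) with diffusion coefficients
  tied to s through a single frictional ratio f/f0:
  `D(s) = (√2/18π) kT s^(-1/2) (η f/f0)^(-3/2) ((1 − v̄ρ)/v̄)^(1/2)`.
  The inversion is a regularized non-negative least-squares problem (maximum
  entropy or Tikhonov, scaled by F-statistics at a configurable p-value),
  with systematic time-invariant TI(r) and radial-invariant RI(t) noise
  eliminated algebraically. Meniscus, bottom and f/f0 can be optimized by
  bounded Nelder–Mead or Levenberg–Marquardt regression.
* **Synthetic experiments** — a generator that simulates complete multi-species
  SV-AUC runs (boundaries + TI/RI baselines + Gaussian noise + isolated data
  spikes) and writes protocol-conformant scan files with a ground-truth
  sidecar, so the whole pipeline is testable without instrument data.

## Worked example

Simulate a four-species analog of a partially degraded antibody sample
(trace fragment near 4.2 S, monomer 6.5 S, dimer 9.5 S, aggregates near
17 S; 50,000 rpm, noise 0.005 signal units), then run one fully automated
c(s) session through the protocol:

```r
library(svengine)
root <- tempfile("demo"); dir.create(root)
data_dir <- file.path(root, "data"); dir.create(data_dir)
generate_dataset(nistmab_like_preset(seed = 1234), data_dir)

req <- analysis_request(
  AllDoneFlagFile = file.path(root, "finished.txt"),
  OutputResultsDirectory = file.path(root, "results1"),
  DataDirectory = data_dir, Channel = "ra1",
  FirstScan = 1L, LastScan = 13L,
  Meniscus = 6.0, MeniscusLowerLimit = 5.95, MeniscusUpperLimit = 6.045,
  Bottom = 7.2, LeftFitLimit = 6.05, RightFitLimit = 7.10,
  Model = "cofs", Resolution = 60L, Smin = 1, Smax = 30,
  UseLogSpaceSgrid = TRUE, RegularizationType = "maxent",
  SuppressBaselineCorrelation = TRUE,
  AutoRun = TRUE, AutoFit = TRUE, MeniscusFitted = TRUE,
  FrictionalRatioFitted = TRUE, StartingFrictionalRatio = 1.25,
  FittingAlgorithm = "Levenberg-Marquardt")
xml <- file.path(root, "input.xml")
write_request_xml(req, xml)

res <- run_session(parse_command_line(c("111", "demo-handshake", xml)),
                   n_radial = 150)
readLines(file.path(root, "finished.txt"))   # "demo-handshake"
```

The session creates `results1/` with `screenshot.bmp`, `distribution.dat`,
`TInoise.dat`, `RInoise.dat`, `ScanRMSD.dat`, `dfr.dat`,
`session_log.json` and `ResultParameters.xml`, plus an `sdist.ra1` grid
file next to the scan data. Integrating the fitted distribution:

```r
cat(sprintf("best-fit meniscus %.4f cm, f/f0 %.3f, rmsd %.6f (%d points)\n",
            res$par["Meniscus"], res$par["FrictionalRatio"],
            res$stats$RMSD, res$stats$RMSD_points))
for (w in list(c(3, 5.4), c(5.4, 8), c(8, 12.5), c(12.5, 30))) {
  pk <- integrate_distribution(res$dist, w[1], w[2])
  cat(sprintf("window [%4.1f, %4.1f] S: sw = %6.3f S, %5.2f%% of signal\n",
              w[1], w[2], pk$sw, pk$fraction))
}
```

prints

```
best-fit meniscus 5.9995 cm, f/f0 1.383, rmsd 0.007801 (4547 points)
window [ 3.0,  5.4] S: sw =  4.273 S,  0.71% of signal
window [ 5.4,  8.0] S: sw =  6.465 S, 29.61% of signal
window [ 8.0, 12.5] S: sw =  9.370 S, 13.18% of signal
window [12.5, 30.0] S: sw = 16.856 S, 54.64% of signal
```

i.e. the trace fragment, monomer, dimer and aggregate populations are
recovered at their simulated positions (true meniscus 6.0 cm, true f/f0
1.37), with the fitted rmsd close to the injected noise level.

## Command-line use

The installed `exec/svengine` script exposes the protocol directly:

```sh
svengine 111 handshakestring /path/to/TestInput.xml
```

The exit status is 0 only when the completion flag file was written.

See the methods vignette (`vignettes/cs-distribution-methods.Rmd`) for the
model, the numerical choices and the known limitations.
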