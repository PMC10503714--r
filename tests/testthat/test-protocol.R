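test_that("the three-token command line parses and rejects per contract", {
  cmd <- parse_command_line(c("111", "handshakestring",
                              "c:\\datafolder\\TestInput.xml"),
                            check_input = FALSE)
  expect_equal(cmd$mode, 111L)
  expect_equal(cmd$handshake, "handshakestring")
  expect_equal(cmd$input_path, "c:\\datafolder\\TestInput.xml")
  expect_false(cmd$restricted)

  cmd2 <- parse_command_line(c("112", "x", "in.xml"), check_input = FALSE)
  expect_true(cmd2$restricted)

  expect_error(parse_command_line(c("111", "x")), class = "sv_usage_error")
  expect_error(parse_command_line(c("111", "x", "a", "b")),
               class = "sv_usage_error")
  expect_error(parse_command_line(c("113", "x", "in.xml")),
               class = "sv_mode_error")
  expect_error(parse_command_line(c("111", "  ", "in.xml")),
               class = "sv_usage_error")
  expect_error(parse_command_line(c("111", "x", tempfile("nope"))),
               class = "sv_io_error")
})

test_that("XML requests parse case-sensitively with documented defaults", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall>",
               "  <Model>cofs</Model>",
               "  <Smax>15</Smax>",
               "</cGMPSedfitCall>"), p)
  req <- read_request(p)
  expect_identical(req$Model, "cofs")
  expect_equal(req$Smax, 15)
  # spike filtering defaults when both parameters are absent
  expect_true(req$FilterDataSpikes)
  expect_equal(req$DataSpikeThreshold, 0.4)
  expect_equal(req$NumberComputationThreads, 2L)
  expect_true(req$TINoiseFitted)
  expect_false(req$AutoFit)

  # names are case-sensitive: lower-case element is ignored with a warning
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall><model>lsgofs</model></cGMPSedfitCall>"), p)
  expect_warning(req2 <- read_request(p), "unknown")
  expect_identical(req2$Model, "cofs")

  # malformed document and wrong root
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall><Model>cofs</Model>"), p)
  expect_error(read_request(p), class = "sv_format_error")
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<OtherRoot><Model>cofs</Model></OtherRoot>"), p)
  expect_error(read_request(p), class = "sv_format_error")

  # value errors name the offending parameter
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall><Resolution>abc</Resolution></cGMPSedfitCall>"),
             p)
  expect_error(read_request(p), "Resolution", class = "sv_value_error")
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall><AutoRun>yes</AutoRun></cGMPSedfitCall>"), p)
  expect_error(read_request(p), "AutoRun", class = "sv_value_error")
})

test_that("PassThrough is preserved verbatim, including nested markup", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               "<cGMPSedfitCall>",
               "  <PassThrough><Sample>lot 7</Sample><Note>ok</Note></PassThrough>",
               "</cGMPSedfitCall>"), p)
  req <- read_request(p)
  expect_identical(req$PassThrough,
                   "<Sample>lot 7</Sample><Note>ok</Note>")

  # plain text with commas survives the round trip too
  req2 <- analysis_request(PassThrough = "sample A, lot 7")
  out <- withr::local_tempfile(fileext = ".xml")
  write_request_xml(req2, out)
  expect_identical(read_request(out)$PassThrough, "sample A, lot 7")
})

test_that("request XML writing and reading round-trips every parameter", {
  root <- withr::local_tempdir()
  req <- analysis_request(
    AllDoneFlagFile = file.path(root, "f.txt"),
    OutputResultsDirectory = file.path(root, "res"),
    DataDirectory = root, Channel = "IP2",
    FirstScan = 3L, LastScan = 99L, ScanInterval = 4L,
    Meniscus = 6.1234567891, MeniscusLowerLimit = 6.09,
    MeniscusUpperLimit = 6.2, Bottom = 7.19998, LeftFitLimit = 6.25,
    RightFitLimit = 7.05, Model = "lsgofs", Resolution = 73L,
    Smin = 0.4, Smax = 54.3, UseLogSpaceSgrid = TRUE,
    RegularizationType = "Tikhonov", RegularizationPvalue = 0.9,
    FittingAlgorithm = "Levenberg-Marquardt",
    StartingFrictionalRatio = 1.543210987,
    Vbar = 0.7312, BufferDensity = 1.00123, BufferViscosity = 0.010314,
    PassThrough = "round trip")
  p <- file.path(root, "req.xml")
  write_request_xml(req, p)
  back <- read_request(p)
  for (nm in names(unclass(req)))
    expect_equal(back[[nm]], req[[nm]], tolerance = 1e-14, label = nm)
})

test_that("request validation reports each broken rule as data", {
  root <- withr::local_tempdir()
  ok <- analysis_request(
    AllDoneFlagFile = file.path(root, "flag.txt"),
    OutputResultsDirectory = file.path(root, "out"),
    DataDirectory = root, Channel = "ra1", FirstScan = 1L, LastScan = 5L,
    Meniscus = 6.0, Bottom = 7.2, LeftFitLimit = 6.05, RightFitLimit = 7.1)
  expect_identical(nrow(validate_request(ok)), 0L)

  v <- validate_request(modifyList(ok, list(RegularizationPvalue = 0.3)),
                        check_fs = FALSE)
  expect_true(any(v$parameter == "RegularizationPvalue" &
                  grepl("0.5", v$rule)))

  v <- validate_request(modifyList(ok, list(Meniscus = 6.0,
                                            MeniscusUpperLimit = 5.9)),
                        check_fs = FALSE)
  expect_true(any(v$parameter == "MeniscusUpperLimit"))

  v <- validate_request(modifyList(ok, list(Smin = 10, Smax = 1)),
                        check_fs = FALSE)
  expect_true(any(v$parameter == "Smin"))

  # filesystem preconditions
  file.create(file.path(root, "flag.txt"))
  v <- validate_request(ok)
  expect_true(any(v$parameter == "AllDoneFlagFile"))
  unlink(file.path(root, "flag.txt"))
  dir.create(file.path(root, "out"))
  v <- validate_request(ok)
  expect_true(any(v$parameter == "OutputResultsDirectory"))

  # restricted-mode (112) profile
  v <- validate_request(modifyList(ok, list(GridfromFile = TRUE)),
                        check_fs = FALSE, restricted = TRUE)
  expect_true(any(v$parameter == "GridfromFile"))
})

test_that("a session writes all artifacts and the flag file last", {
  root <- withr::local_tempdir()
  res <- run_quick_session(root, handshake = "hs-abc123")

  flag <- file.path(root, "done.txt")
  expect_true(file.exists(flag))
  expect_identical(readLines(flag), "hs-abc123")

  outd <- file.path(root, "results")
  expect_setequal(list.files(outd),
                  c("screenshot.bmp", "RInoise.dat", "TInoise.dat",
                    "ScanRMSD.dat", "distribution.dat", "dfr.dat",
                    "session_log.json", "ResultParameters.xml"))
  # the sdist grid file appears next to the scan data
  expect_true(file.exists(file.path(root, "data", "sdist.ra1")))

  # a pre-existing flag file makes a fresh session refuse to run
  root2 <- withr::local_tempdir()
  small_dataset(file.path(root2, "data"))
  req <- quick_request(root2, file.path(root2, "data"), 7)
  file.create(file.path(root2, "done.txt"))
  xml <- file.path(root2, "in.xml")
  write_request_xml(req, xml)
  expect_error(run_session(parse_command_line(c("111", "h", xml))),
               class = "sv_refuse_error")
  expect_false(dir.exists(file.path(root2, "results")))
})

test_that("mode 112 rejects non-standard options", {
  root <- withr::local_tempdir()
  expect_error(
    run_quick_session(root, mode = "112", UseLogSpaceSgrid = TRUE),
    "restricted mode", class = "sv_value_error")
  expect_false(file.exists(file.path(root, "done.txt")))

  root2 <- withr::local_tempdir()
  res <- run_quick_session(root2, mode = "112")
  expect_true(file.exists(file.path(root2, "done.txt")))
})

test_that("a fault before any writer leaves no flag file behind", {
  stages <- c("sdist", "screenshot.bmp", "RInoise.dat", "TInoise.dat",
              "ScanRMSD.dat", "distribution.dat", "dfr.dat",
              "session_log.json", "ResultParameters.xml", "AllDoneFlagFile")
  for (stage in stages) {
    root <- withr::local_tempdir()
    withr::local_options(svengine.abort_stage = stage)
    expect_error(run_quick_session(root), class = "sv_injected_fault")
    expect_false(file.exists(file.path(root, "done.txt")))
  }
  # and the final stage confirms everything else was already on disk
  root <- withr::local_tempdir()
  withr::local_options(svengine.abort_stage = "AllDoneFlagFile")
  expect_error(run_quick_session(root), class = "sv_injected_fault")
  expect_true(file.exists(file.path(root, "results", "ResultParameters.xml")))
  expect_true(file.exists(file.path(root, "results", "screenshot.bmp")))
})

test_that("the CLI wrapper maps outcomes to exit statuses", {
  expect_identical(suppressMessages(svengine_main(c("111", "x"))), 1L)
  expect_identical(suppressMessages(svengine_main(c("113", "x", "y"))), 1L)
  root <- withr::local_tempdir()
  small_dataset(file.path(root, "data"))
  xml <- file.path(root, "in.xml")
  write_request_xml(quick_request(root, file.path(root, "data"), 7), xml)
  expect_identical(svengine_main(c("111", "cli-hs", xml)), 0L)
  expect_identical(readLines(file.path(root, "done.txt")), "cli-hs")
})

test_that("results are invariant to the computation-thread setting", {
  run_with_threads <- function(n) {
    root <- withr::local_tempdir(.local_envir = parent.frame())
    run_quick_session(root, NumberComputationThreads = n)
    readLines(file.path(root, "results", "distribution.dat"))
  }
  expect_identical(run_with_threads(1L), run_with_threads(4L))
})

test_that("concurrent sessions reproduce serial sessions byte for byte", {
  make_root <- function() {
    root <- tempfile("conc")
    dir.create(root)
    small_dataset(file.path(root, "data"))
    xml <- file.path(root, "in.xml")
    write_request_xml(quick_request(root, file.path(root, "data"), 7), xml)
    root
  }
  roots <- list(make_root(), make_root())
  runs <- function() lapply(roots, function(root)
    run_session(parse_command_line(c("111", "shared-handshake",
                                     file.path(root, "in.xml")))))
  snapshot <- function(root) {
    files <- sort(list.files(file.path(root, "results"), full.names = TRUE))
    lapply(files, function(f) readBin(f, "raw", file.size(f)))
  }
  runs()
  serial <- lapply(roots, snapshot)
  for (root in roots) {
    unlink(file.path(root, "results"), recursive = TRUE)
    unlink(file.path(root, "done.txt"))
    unlink(file.path(root, "data", "sdist.ra1"))
  }
  parallel::mclapply(roots, function(root)
    run_session(parse_command_line(c("111", "shared-handshake",
                                     file.path(root, "in.xml")))),
    mc.cores = 2)
  concurrent <- lapply(roots, snapshot)
  expect_identical(serial, concurrent)
  for (root in roots) unlink(root, recursive = TRUE)
})
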