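# Vendor readers, fixture writers and SpectrumSet assembly.

test_that("Bruker fixture round trip is the identity for every word type and byte order", {
  ax <- smallAxis(512)
  plan <- simulationPlan(1, list(peakSpec(2, 1, 6), peakSpec(7, 3, 9)),
                         seed = 4)
  fid <- simulateFid(plan, ax)
  big <- fid
  big@signal <- fid@signal * 1e6        # int32 headroom
  for (dtypa in c(0L, 2L)) for (bo in c(0L, 1L)) {
    d <- withr::local_tempdir()
    writeBrukerFixture(big, d, dtypa = dtypa, bytorda = bo)
    rt <- readBrukerFid(d)
    tol <- if (dtypa == 0L) 0.51 else 1e-12
    expect_lt(max(Mod(rt@signal - big@signal)), tol)
    expect_equal(rt@swPpm, big@swPpm)
    expect_equal(rt@sfoMHz, big@sfoMHz)
    expect_equal(rt@o1Hz, big@o1Hz)
  }
})

test_that("corrupt or inconsistent Bruker inputs raise format errors naming the file", {
  d <- withr::local_tempdir()
  ax <- smallAxis(256)
  fid <- simulateFid(simulationPlan(1, list(peakSpec(4, 1, 6)), seed = 1), ax)
  writeBrukerFixture(fid, d, dtypa = 2L)
  # truncate fid
  raw <- readBin(file.path(d, "fid"), "raw", n = 999999)
  writeBin(raw[1:100], file.path(d, "fid"))
  expect_error(readBrukerFid(d), "fid")
  # unknown word type
  d2 <- withr::local_tempdir()
  writeBrukerFixture(fid, d2, dtypa = 2L)
  acq <- readLines(file.path(d2, "acqus"))
  writeLines(sub("DTYPA= 2", "DTYPA= 7", acq), file.path(d2, "acqus"))
  expect_error(readBrukerFid(d2), "DTYPA")
  expect_error(readBrukerFid(withr::local_tempdir()), "missing file")
})

test_that("group delay falls back from GRPDLY to the DECIM/DSPFVS table", {
  d <- withr::local_tempdir()
  ax <- smallAxis(256)
  fid <- simulateFid(simulationPlan(1, list(peakSpec(4, 1, 6)), seed = 1), ax)
  fid@groupDelay <- 67.5
  writeBrukerFixture(fid, d, dtypa = 2L)
  expect_equal(readBrukerFid(d)@groupDelay, 67.5)
  acq <- readLines(file.path(d, "acqus"))
  acq <- acq[!grepl("GRPDLY", acq)]
  writeLines(c(acq, "##$DECIM= 16", "##$DSPFVS= 12"), file.path(d, "acqus"))
  expect_equal(readBrukerFid(d)@groupDelay, 71.6)
})

test_that("Bruker 1r reading honours NC_proc scaling and the derived axis", {
  ppm <- seq(9.5, -0.5, length.out = 1024)
  y <- round(lorentzianProfile(list(peakSpec(5, 1, 8)), ppm, 500) * 1e5)
  for (nc in c(0L, 2L)) {
    d <- withr::local_tempdir()
    writeBruker1rFixture(y * 2^nc, ppm, 500, d, ncProc = nc)
    got <- readBruker1r(d)
    expect_equal(got$spectrum, y * 2^nc)
    # axis recomputed by hand from the procs parameters
    p <- nmrflow:::parseJcamp(file.path(d, "procs"))
    expect_equal(got$ppm[1], p$OFFSET)
    expect_equal(got$ppm[1024],
                 p$OFFSET - (p$SW_p / p$SF), tolerance = 1e-9)
    expect_equal(got$ppm, ppm, tolerance = 1e-9)
  }
  d <- withr::local_tempdir()
  writeBruker1rFixture(y, ppm, 500, d)
  writeBin(as.integer(1:10), file.path(d, "1r"), size = 4L)
  expect_error(readBruker1r(d), "SI")
})

test_that("Varian round trip works and matches the Bruker rendering of the same signal", {
  ax <- smallAxis(512)
  fid <- simulateFid(simulationPlan(1, list(peakSpec(3, 1, 6)), seed = 9), ax)
  d <- withr::local_tempdir()
  writeVarianFixture(fid, d)
  rt <- readVarianFid(d)
  relErr <- max(Mod(rt@signal - fid@signal)) / max(Mod(fid@signal))
  expect_lt(relErr, 1e-6)               # float32 quantization
  expect_equal(rt@swPpm, fid@swPpm, tolerance = 1e-9)
  # same signal through the Bruker path
  d2 <- withr::local_tempdir()
  writeBrukerFixture(fid, d2, dtypa = 2L)
  rb <- readBrukerFid(d2)
  expect_lt(max(Mod(rt@signal - rb@signal)) / max(Mod(rb@signal)), 1e-6)
  # missing np key
  pp <- readLines(file.path(d, "procpar"))
  writeLines(pp[-(1:3)], file.path(d, "procpar"))
  expect_error(readVarianFid(d), "np")
})

test_that("nmrML round trips plainly and zlib-compressed; 2D files are refused", {
  ax <- smallAxis(256)
  fid <- simulateFid(simulationPlan(1, list(peakSpec(4, 2, 7)), seed = 6), ax)
  f1 <- withr::local_tempfile(fileext = ".nmrML")
  f2 <- withr::local_tempfile(fileext = ".nmrML")
  writeNmrML(fid, f1, compressed = FALSE)
  writeNmrML(fid, f2, compressed = TRUE)
  r1 <- readNmrML(f1); r2 <- readNmrML(f2)
  expect_identical(r1@signal, fid@signal)
  expect_identical(r2@signal, fid@signal)
  expect_equal(r1@swPpm, fid@swPpm)
  # a 2D document is refused with a dimensionality error
  doc <- xml2::read_xml(f1)
  xml2::xml_add_child(xml2::xml_find_first(doc, ".//acquisition"),
                      "acquisition2D")
  f3 <- withr::local_tempfile(fileext = ".nmrML")
  xml2::write_xml(doc, f3)
  expect_error(readNmrML(f3), "dimensionality")
})

test_that("assembly enforces shared axes and follows sample-table order", {
  ppm <- seq(9.5, -0.5, length.out = 256)
  mk <- function(h) list(spectrum = lorentzianProfile(
    list(peakSpec(5, h, 8)), ppm, 500), ppm = ppm)
  spectra <- list(a = mk(1), b = mk(2), c = mk(3))
  tab <- data.frame(sample_id = c("c", "a", "b"), group = c("x", "y", "x"))
  set <- assembleSpectrumSet(spectra, tab)
  expect_equal(sampleNames(set), c("c", "a", "b"))
  expect_equal(unname(intensities(set)[1, ]), spectra$c$spectrum)
  # permutation equivariance
  set2 <- assembleSpectrumSet(spectra[c(2, 3, 1)], tab)
  expect_identical(intensities(set), intensities(set2))
  # point-count mismatch names the offender
  spectra$b <- list(spectrum = spectra$b$spectrum[-1], ppm = ppm[-1])
  expect_error(assembleSpectrumSet(spectra, tab), "b")
  expect_error(assembleSpectrumSet(list(a = mk(1)),
                                   data.frame(sample_id = "zz", group = "x")),
               "missing from the sample table")
  expect_error(assembleSpectrumSet(list(a = mk(1), b = mk(2)),
                                   data.frame(sample_id = c("a", "a", "b"),
                                              group = "x")),
               "duplicate")
})

test_that("factor subsetting is order-preserving and validates its inputs", {
  set <- matrixSet(matrix(1, 6, 32), seq(9.5, -0.5, length.out = 32),
                   groups = c("A", "B", "A", "B", "A", "B"))
  expect_equal(subsetByFactor(set, "group", "A"), c(1, 3, 5))
  expect_equal(subsetByFactor(set, "group", "B"), c(2, 4, 6))
  expect_error(subsetByFactor(set, "group", "C"), "not present")
  expect_error(subsetByFactor(set, "batch", "A"), "unknown factor")
  one <- matrixSet(matrix(1, 3, 32), seq(9.5, -0.5, length.out = 32))
  expect_equal(subsetByFactor(one, "group", "A"), 1:3)
})

test_that("sample tables read back with factor columns intact", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("S01", "S02"), genotype = c("wt", "mut"),
                   day = c("1", "2"), stringsAsFactors = FALSE)
  writeSampleTable(df, f)
  expect_equal(readSampleTable(f), df)
})
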