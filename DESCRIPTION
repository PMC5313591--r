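Package: nmrflow
Title: Processing Engine for 1D NMR Spectra Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless processing engine for sets of 1D (1H/13C) NMR
    spectra in metabolomics: reading Bruker and Varian/Agilent free
    induction decays and Bruker processed spectra, Fourier processing with
    automatic phasing, global and local baseline correction, chemical-shift
    calibration, zone-wise spectral alignment by least-squares shifting or
    parametric time warping (optionally per experimental-factor subset),
    bucketing by uniform binning, adaptive intelligent binning or explicit
    ppm ranges, signal-to-noise filtering, and export of statistics-ready
    data matrices and a five-table quantitative 1H NMR workbook. Every
    processing step is recorded as a macro command so a workflow tuned on
    one spectra set can be replayed in batch on comparable sets, including
    from a command line. A synthetic-spectra module generates controlled
    fixtures (peaks, multiplets, shifts, baselines, noise, factor groups)
    and on-disk vendor-format directories for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
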