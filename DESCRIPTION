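Package: bloomfill
Title: Monte-Carlo Multiple Imputation of Gappy Ocean-Color Fields and
    Bloom Phenology with Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step gap-filling of gridded satellite chlorophyll-a time
    series: sequential optimal linear interpolation along longitude,
    latitude and time restricted to immediate neighbours, followed by
    Monte-Carlo multiple imputation in which every remaining missing pixel
    is filled with pseudo-random draws from a per-grid-cell best-fit
    probability distribution (normal, lognormal or gamma selected by
    Kolmogorov-Smirnov p-value, with a cross-validated Gaussian kernel
    density estimate as fallback). The resulting ensemble of gap-free
    fields propagates the imputation uncertainty into phytoplankton bloom
    phenology indicators (initiation and peak dates by the threshold
    method), reported as min/mean/max date ranges. Includes a seeded
    synthetic chlorophyll simulator with known phenology and realistic
    seasonal cloud-gap masks, 8-day temporal compositing, conservative
    regridding, and CF-style netCDF input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    MASS,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
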