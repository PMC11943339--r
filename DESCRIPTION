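Package: voltigrid
Title: Degree-Day Voltinism Projections on Gridded Climate Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for projecting insect voltinism from gridded daily
    temperature under climate-change scenarios. Implements cumulative
    growing degree-day (CGDD) accumulation above a developmental zero,
    the voltinism ratio CGDD/K for a multivoltine defoliator
    (parameterised for the pine caterpillar, Dendrolimus spectabilis),
    Taylor-statistic evaluation and averaging of multi-model climate
    ensembles, bilinear regridding, elevation and latitude gradient
    stratification, decadal trend estimation, and voltinism-versus-warming
    regressions. Ships a seeded synthetic generator for baseline and
    pseudo-GCM scenario temperature grids so the full pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ncdf4,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
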