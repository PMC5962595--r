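Package: borealgdd
Title: Agro-Climatic Feasibility of the Boreal Zone from Gridded Monthly Climate
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for assessing the northward shift of the agricultural
    climate zone from multi-model gridded monthly climate series: pentad
    (five-year) climatologies, annual growing degree days above 5 degrees C
    (GDD5) via days-per-month multipliers, GDD5 >= 1200 crop-feasibility
    masks, Thornthwaite potential evapotranspiration with day-length
    correction at discrete 5-degree latitude bands, growing-season climatic
    water balance and p/PET aridity classification, equal-weight ensemble
    statistics, spherical zonal area accounting, latitude-band summaries and
    per-longitude leading-edge shift distances. Includes a seeded synthetic
    pseudo-GCM climate generator and rasterized region masks for fully
    reproducible, self-contained experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
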