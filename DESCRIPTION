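Package: droughtnpp
Title: Drought Indices and CASA Net Primary Productivity Analysis for Gridded Monthly Climate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gridded pipeline for analysing drought and its impact on
    vegetation net primary productivity (NPP) from monthly raster stacks of
    precipitation, temperature, solar radiation, soil moisture and NDVI.
    Implements the Carnegie-Ames-Stanford Approach (CASA) light-use-efficiency
    NPP model, multi-scale Standardized Precipitation Evapotranspiration Index
    (SPEI, log-logistic L-moment fit) and Standardized Soil Moisture Index
    (SSMI), drought severity classification and frequency mapping, per-pixel
    Theil-Sen slope and Mann-Kendall trend fields, Pearson and partial
    correlation of NPP with climate drivers, drought-severity NPP anomaly
    tables, and categorical skill validation (POD/FAR/CSI) against a
    drought-event catalog. A synthetic-data generator produces monthly cubes
    with known seasonal cycles, trends, drought episodes and
    NDVI-precipitation coupling so every stage has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
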