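Package: glspipe
Title: Light-Level Geolocator Track Processing for Trans-Equatorial Seabird Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes light-level geolocator (GLS) observations into cleaned
    daily tracks and migration summaries for long-distance migratory seabirds.
    Implements threshold geolocation (longitude from the sunrise/sunset
    midpoint, latitude from day length), sea-surface-temperature correlation
    to rescue latitudes around the equinoxes, a sustained-speed track filter,
    1:2:1 weighted track smoothing, stopover/travel segmentation with burst
    adjustment, kernel-density occupancy contours in an equal-area projection,
    and great-circle migration metrics with the accompanying comparison
    statistics. Includes a synthetic-bird generator producing twilight,
    tag-SST and satellite-grid observations with known ground truth, so every
    pipeline stage can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
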