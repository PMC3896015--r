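Package: bycatchr
Title: Predicting Sea Turtle Bycatch Hotspots from Telemetry and Longline Effort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting where and when pelagic longline fisheries are
    most likely to interact with satellite-tracked sea turtles. Daily telemetry
    positions are weighted by the inverse of the number of individuals still
    tracked on the same relative track day (with an 85th-percentile threshold
    day and cross-population sample-size inflation), summed onto a 5-degree by
    5-degree quarterly grid, and combined with gear-adjusted longline effort
    (hooks scaled by a billfish/tuna catchability index and the local billfish
    catch fraction) into a normalized interaction index whose cell-quarter
    values sum to one. Includes seeded generators for synthetic tracks, effort
    and catch fields with planted ground-truth hotspots for end-to-end testing,
    plus hotspot ranking and delimited-text/GeoJSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
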