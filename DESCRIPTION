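Package: peripeak
Title: Peri-Peak Speed Dynamics from 10 Hz Athlete Tracking Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing match peak running speeds from 10 Hz
    GNSS speed traces of team-sport athletes. Reads and validates raw
    speed/time series, filters implausible speed spikes, identifies each
    player-match peak speed under a corroborating-effort validity rule,
    extracts the 20-second peri-peak window at 0.1 s resolution, and
    summarises per-second speed dynamics with paired mean differences,
    Cohen's d effect sizes with magnitude bands, and between-position
    comparisons. Includes a seeded synthetic match-trace simulator with
    ground truth for end-to-end testing without proprietary club data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
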