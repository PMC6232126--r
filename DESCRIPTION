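Package: kdspacetime
Title: Spatiotemporal Cluster and Climate Analysis for Kawasaki Disease Surveillance
Version: 0.1.0
Authors@R:
    person("San Diego", "Surveillance Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the spatiotemporal epidemiology of Kawasaki disease
    (KD) case series: two-stage temporal cluster construction (7-day moving
    window, minimum case count) with a seasonal Monte Carlo null; an excess
    Knox space-time interaction statistic over a threshold grid with a
    location-versus-date permutation null; day-of-year climatologies, daily
    anomalies and event-lagged composite maps with per-cell t-statistic
    significance masks; forward-window conditional-median autocorrelation of
    clinical traits and a spatial label-permutation test for binary traits;
    and a synthetic-data generator (seasonal inhomogeneous Poisson case
    process with injected bursts, plus AR(1) gridded climate fields with
    event-coupled anomalies) so that every stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
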