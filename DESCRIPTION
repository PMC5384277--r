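Package: pharynxflow
Title: Pharyngeal Airflow Simulation for Incisor-Retraction Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational model of upper-airway aerodynamics
    after orthodontic incisor retraction. Generates parametric axisymmetric
    pharyngeal phantoms (nasopharynx, oropharynx, hypopharynx) with
    prescribed region volumes and minimum cross-sectional area, voxelizes
    and segments them with CT Hounsfield-unit thresholds, meshes them with
    structured body-fitted axisymmetric grids, and solves steady laminar
    incompressible flow with a finite-volume SIMPLE pressure-velocity
    coupling scheme. Extracts the standard pharyngeal outcome metrics
    (per-millimetre slice sweep, minimum area, regional pressure drops,
    resistance) and provides the accompanying statistics layer: paired t
    tests with Holm step-down correction, Pearson correlation, Dahlberg
    method error, and intraclass correlation reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
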