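Package: glucoroute
Title: Route-Dependent Glucose Kinetics, Insulin Secretion and Sensitivity Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired oral versus isoglycaemic intravenous
    glucose studies with dual stable-isotope tracers. Reconstructs total and
    oral glucose rate of appearance, disappearance and endogenous glucose
    production from tracer-to-tracee ratios via the non-steady-state Steele
    equation; deconvolves the insulin secretion rate from C-peptide using
    population two-compartment kinetics; fits a three-load oral minimal model
    of beta cell glucose sensitivity; and computes insulin sensitivity,
    clearance, disposition and adipose-tissue resistance indices together with
    insulin-driven metabolite decay statistics. A forward simulator generates
    paired sessions from known ground-truth physiology so every stage can be
    validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
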