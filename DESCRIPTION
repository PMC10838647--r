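Package: hpaxis
Title: Dynamic Modelling of HPA-Axis Glucocorticoid Responses and
    Receptor-Mediated Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the hypothalamic-pituitary-adrenal (HPA) axis as a
    system of ordinary differential equations: a stressor-driven stimulus
    activates the CRH -> ACTH -> glucocorticoid (GC) cascade, and
    glucocorticoids bind glucocorticoid (GR) and mineralocorticoid (MR)
    receptors by mass-action kinetics, closing the negative feedback loop
    that restores baseline hormone levels. Supports timed hormone-challenge
    events (ACTH and dexamethasone boluses), maximum-likelihood fitting of
    model parameters to multi-timepoint plasma GC profiles via Nelder-Mead
    simplex search, receptor-abundance and stressor-intensity sweeps, and
    single-timepoint association analyses between plasma GC and the
    GC-GR-complex readout of physiological response. Includes a seeded
    synthetic-population generator emulating field-endocrinology sampling
    designs (baseline, stress-induced, post-dexamethasone and post-ACTH
    samples) for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
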