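Package: semacd
Title: Scoring and Multi-Reader Validation of the Simplified Endoscopic
    Mucosal Assessment for Crohn's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Simplified Endoscopic Mucosal Assessment for
    Crohn's Disease (SEMA-CD, range 0-20) and its comparator, the Simple
    Endoscopic Score for Crohn's Disease (SES-CD), from segment-level
    endoscopic findings, and implements the complete multi-reader central
    reading workflow used to validate such indices: blinded double reads,
    score adjudication when primary readers disagree by more than a fixed
    margin, median-of-reads final scores, and a re-read subsample for
    intra-rater analysis. Reliability statistics include Spearman rank
    correlations with Bonett-Wright confidence intervals, one-way
    random-effects intraclass correlation coefficients, linearly or
    quadratically weighted Cohen kappa with large-sample intervals, and
    inverse-variance pooling of stratum-level mean differences and
    pairwise kappas. A seeded synthetic-study generator emulates a
    two-cohort ileocolonoscopy trial (latent severity, ordinal segment
    pathology, noisy ordinal reader ratings) so the whole pipeline runs
    end-to-end without access to trial videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
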