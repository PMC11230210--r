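Package: strideadapt
Title: State-Space Models of Stride-by-Stride Motor Adaptation to Robotic
    Gait Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the stride-by-stride evolution of propulsion
    mechanics (hip extension angle, normalized propulsive impulse) during and
    after robot-assisted gait training with pulsed torque assistance. Implements
    five discrete-time state-space motor-adaptation models -- single-state
    error-based, use-dependent learning (UDL), two-state fast/slow, general
    two-state, and a modified UDL model with a dynamic reference state that can
    express persistent after-effects -- together with stride-series
    preprocessing (interpolation, session-local smoothing, baseline referencing,
    SD normalization), constrained multi-start least-squares fitting scored by
    R-squared and AIC, group-level model comparison (Shapiro-Wilk gate,
    repeated-measures ANOVA or Friedman omnibus, paired t or Wilcoxon
    signed-rank post hoc with Bonferroni correction), and a synthetic-cohort
    generator emulating the 100/200/100-stride torque-pulse protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
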