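Package: numbias
Title: Simulation and Analysis of Connectedness-Induced Numerosity Biases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse two-alternative forced-choice (2AFC)
    numerosity discrimination experiments in which connecting pairs of dots with
    thin lines reduces apparent numerosity. Provides constrained generation of
    isolated and connected random-dot stimuli, a discretized-posterior QUEST
    adaptive procedure for probe placement, a generative observer model whose
    grouping-induced underestimation varies with autism-spectrum-quotient (AQ)
    scores, maximum-likelihood cumulative-Gaussian psychometric fitting
    (PSE, JND, Weber fraction), and the group-level statistics used in this
    literature: median splits, pooled-variance t tests, repeated-measures
    ANOVA, the Jarque-Bera normality test, and default Bayes factors for t
    statistics (JZS Cauchy prior) and Pearson correlations (Zellner-Siow and
    stretched-beta priors) computed by numerical integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    e1071,
    withr
Config/testthat/edition: 3
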