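Package: dcemix
Title: Discrete Choice Experiment Design and Panel Mixed Logit Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for stated-preference discrete choice experiments with
    paired alternatives: D-efficient, level-balanced choice-set design with
    blocking and embedded validity tasks (repeated and dominated choice
    sets); simulation of panels of respondents with heterogeneous
    preferences; estimation of panel mixed multinomial logit models by
    maximum simulated likelihood with Halton quasi-random draws, including
    sign-constrained triangular mixing for cost coefficients and
    attribute-by-covariate interactions; response-validity statistics
    (monotonicity pass rate, repeat consistency, Cohen's kappa); and
    post-estimation analytics (fit statistics, predictive hit rate,
    attribute relative importance at the population and individual level,
    harm-versus-benefit classification, marginal rates of substitution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
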