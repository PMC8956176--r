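#' waterfowlSSM: dual-protocol count integration with conditional detection
#'
#' State-space models for long-term waterfowl monitoring where two
#' independent count protocols (aerial and ground) cover the same sites. The
#' latent site abundance follows stochastic exponential growth with a
#' random-walk growth rate; observations carry heavy-tailed log-Student
#' error with a hierarchical seasonal pattern; detection enters as a
#' baseline-anchored logit-linear index over aerial observer periods and
#' ground protected areas. See the package vignette for the model, its
#' assumptions and the design choices.
#'
#' @importFrom stats dnorm dt plogis qlogis quantile rnorm rt runif var sd
#'   median cor setNames qnorm update
#' @importFrom utils read.csv write.csv head
#' @name waterfowlSSM-package
#' @aliases waterfowlSSM
"_PACKAGE"
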