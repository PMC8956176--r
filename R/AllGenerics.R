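#' @include AllClasses.R
NULL

#' Number of sites, years and survey months
#'
#' Dimension accessors shared by \code{StudyStructure}, \code{SurveyDataset},
#' \code{DetectionDesign} and \code{PosteriorSamples}.
#'
#' @param object an object carrying a study structure.
#' @return an integer count.
#' @export
setGeneric("nSites", function(object) standardGeneric("nSites"))

#' @rdname nSites
#' @export
setGeneric("nYears", function(object) standardGeneric("nYears"))

#' @rdname nSites
#' @export
setGeneric("nMonths", function(object) standardGeneric("nMonths"))

#' Protected-area membership of each site
#' @param object an object carrying a study structure.
#' @return character vector of area labels, one per site.
#' @export
setGeneric("areaOfSite", function(object) standardGeneric("areaOfSite"))

#' Extract the study structure
#' @param object an object built on a \code{StudyStructure}.
#' @return the \code{\linkS4class{StudyStructure}}.
#' @export
setGeneric("studyStructure", function(object) standardGeneric("studyStructure"))

#' Split-chain potential scale reduction factor
#'
#' @param object a \code{\linkS4class{PosteriorSamples}} object.
#' @param ... passed to methods.
#' @return named numeric vector of split-R-hat values; \code{NA} where the
#'   within-chain variance is zero (constant chains), for which the diagnostic
#'   is undefined.
#' @export
setGeneric("rhat", function(object, ...) standardGeneric("rhat"))

#' Effective sample size of retained draws
#' @inheritParams rhat
#' @return named numeric vector of effective sample sizes.
#' @export
setGeneric("effectiveSamples", function(object, ...) standardGeneric("effectiveSamples"))

#' Pooled-chain draws of one or more parameters
#'
#' @param object a \code{\linkS4class{PosteriorSamples}} object.
#' @param parameters character vector of parameter names (see
#'   \code{\link{parameterNames}}).
#' @return a draws x parameters numeric matrix (chains concatenated).
#' @export
setGeneric("drawsOf", function(object, parameters) standardGeneric("drawsOf"))

#' Names of stored parameters
#' @param object a \code{\linkS4class{PosteriorSamples}} object.
#' @param which "all", "top" (top-level parameters) or "cells" (detection
#'   cells present in the fitted design).
#' @export
setGeneric("parameterNames", function(object, which = "all")
  standardGeneric("parameterNames"))
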