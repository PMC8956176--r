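#' @include AllClasses.R structure.R
NULL

#' Build the detection design from a study structure
#'
#' Maps every (method, site, year) to one of the eight detection cells: the
#' aerial method follows the observer periods (cell depends only on the year);
#' the ground method follows the site's protected area, with the
#' protocol-change area (Tour du Valat) switching from its "old" to its "new"
#' cell at the configured change year, and the Marais du Vigueirat fixed at
#' the ground baseline (linear predictor exactly \code{beta2}).
#'
#' @param structure a \code{\linkS4class{StudyStructure}}.
#' @return a \code{\linkS4class{DetectionDesign}}.
#' @examples
#' d <- buildDetectionDesign(studyStructureOf("full"))
#' designCell(d, "aerial", site = 1, year = 30)   # "aerial_obs2"
#' @export
buildDetectionDesign <- function(structure) {
  stopifnot(is(structure, "StudyStructure"))
  S <- structure@nSites; T <- structure@nYears
  cells <- array(NA_character_, dim = c(2L, S, T),
                 dimnames = list(method = kMethods, site = NULL, year = NULL))
  aerialCell <- c("aerial_obs1", "aerial_obs2", "aerial_obs3")[
    structure@observerPeriodOfYear]
  groundCellOfArea <- c(Palissade = "ground_palissade",
                        RNNCamargue = "ground_rnn",
                        TourDuValat = "ground_tdv_old",
                        Vigueirat = "ground_vigueirat")
  for (s in seq_len(S)) {
    area <- structure@areaOfSite[s]
    if (is.na(groundCellOfArea[area])) stop("site ", s, " has no known area")
    cells["aerial", s, ] <- aerialCell
    g <- rep(groundCellOfArea[[area]], T)
    if (length(structure@changeArea) && area == structure@changeArea)
      g[seq_len(T) >= structure@changeYear] <- "ground_tdv_new"
    cells["ground", s, ] <- g
  }
  new("DetectionDesign", cells = cells, structure = structure)
}

#' Look up the detection cell of one (method, site, year)
#'
#' @param design a \code{\linkS4class{DetectionDesign}}.
#' @param method \code{"aerial"} or \code{"ground"}.
#' @param site,year indices within the design's structure.
#' @return a cell label from \code{kDetectionCells}.
#' @export
designCell <- function(design, method, site, year) {
  st <- design@structure
  if (!method %in% kMethods) stop("unknown method: ", method)
  if (any(site < 1L | site > st@nSites)) stop("site index out of range")
  if (any(year < 1L | year > st@nYears)) stop("year index out of range")
  unname(design@cells[method, site, year])
}

#' Linear predictors and detection indices of the design cells
#'
#' \code{cellLinearPredictors} returns the logit-scale linear predictor of
#' each cell given the model parameters; \code{ground_vigueirat} is exactly
#' \code{beta2}. \code{cellDetection} applies the inverse logit.
#'
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @return named numeric vector over \code{kDetectionCells}.
#' @export
cellLinearPredictors <- function(params) {
  c(aerial_obs1 = params@beta1,
    aerial_obs2 = params@beta1 + unname(params@gammaAerial["obs2"]),
    aerial_obs3 = params@beta1 + unname(params@gammaAerial["obs3"]),
    ground_palissade = params@beta2 + unname(params@gammaGround["palissade"]),
    ground_rnn = params@beta2 + unname(params@gammaGround["rnn"]),
    ground_tdv_old = params@beta2 + unname(params@gammaGround["tdv_old"]),
    ground_tdv_new = params@beta2 + unname(params@gammaGround["tdv_new"]),
    ground_vigueirat = params@beta2)
}

#' @rdname cellLinearPredictors
#' @export
cellDetection <- function(params) {
  eta <- cellLinearPredictors(params)
  stats::setNames(detectionProbability(eta, 0), names(eta))
}

#' Per-(method, site, year) detection index array
#'
#' @param design a \code{\linkS4class{DetectionDesign}}.
#' @param params a \code{\linkS4class{ModelParameters}}.
#' @return numeric array 2 x sites x years of detection indices in (0, 1).
#' @export
detectionArray <- function(design, params) {
  p <- cellDetection(params)
  out <- array(p[design@cells], dim = dim(design@cells),
               dimnames = dimnames(design@cells))
  out
}

#' Detection cells actually occurring in a design
#' @param design a \code{\linkS4class{DetectionDesign}}.
#' @return character vector, subset of \code{kDetectionCells} in canonical order.
#' @export
cellsPresent <- function(design) {
  kDetectionCells[kDetectionCells %in% unique(as.vector(design@cells))]
}

setMethod("show", "DetectionDesign", function(object) {
  cat("DetectionDesign over", object@structure@nSites, "sites x",
      object@structure@nYears, "years\n")
  cat("  cells present:", paste(cellsPresent(object), collapse = ", "), "\n")
})
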