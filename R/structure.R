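#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a StudyStructure
#'
#' @param nSites,nYears,nMonths survey dimensions; month 1 is September.
#' @param areaOfSite character vector of area labels (one of \code{kAreas})
#'   per site.
#' @param observerPeriodOfYear integer vector mapping each year to its aerial
#'   observer period (1, 2 or 3), in contiguous blocks starting at 1.
#' @param groundMethodChange \code{NULL}, or \code{list(area =, year =)}
#'   giving the area whose ground protocol changed and the first year under
#'   the new protocol.
#' @param aerialIntroYear first year of aerial coverage per site (default:
#'   all covered from year 1).
#' @param missingnessRate methods x areas matrix of missing-cell fractions;
#'   defaults to zero.
#' @return a validated \code{\linkS4class{StudyStructure}}.
#' @examples
#' st <- studyStructureOf("tiny")
#' nSites(st); nYears(st)
#' @export
newStudyStructure <- function(nSites, nYears, nMonths, areaOfSite,
                              observerPeriodOfYear,
                              groundMethodChange = NULL,
                              aerialIntroYear = rep(1L, nSites),
                              missingnessRate = NULL) {
  areas <- unique(areaOfSite)
  if (is.null(missingnessRate)) {
    missingnessRate <- matrix(0, 2, length(areas),
                              dimnames = list(kMethods, areas))
  }
  new("StudyStructure",
      nSites = as.integer(nSites), nYears = as.integer(nYears),
      nMonths = as.integer(nMonths),
      areaOfSite = as.character(areaOfSite),
      observerPeriodOfYear = as.integer(observerPeriodOfYear),
      changeArea = if (is.null(groundMethodChange)) character(0) else
        as.character(groundMethodChange$area),
      changeYear = if (is.null(groundMethodChange)) integer(0) else
        as.integer(groundMethodChange$year),
      aerialIntroYear = as.integer(aerialIntroYear),
      missingnessRate = missingnessRate)
}

#' Named study structures
#'
#' \code{"full"} mirrors the Camargue study design: 40 sites split 7 / 21 /
#' 10 / 2 across the Marais de la Palissade, the Reserve Naturelle Nationale
#' de Camargue, the Tour du Valat and the Marais du Vigueirat; 44 years; 7
#' survey months (September to March); aerial observer periods of length
#' 27 / 10 / 7; a Tour du Valat ground-protocol change first effective in
#' year 32; area-level ground missingness of 0.58 / 0.41 / 0.40 / 0.46 and
#' near-complete aerial coverage; 8 sites enter the aerial survey late.
#' \code{"tiny"} (6 sites, 10 years) and \code{"small"} (12 sites, 20 years)
#' keep every design feature (all four areas, three observer periods, the
#' protocol change, late aerial introduction) at a scale suited to test
#' suites.
#'
#' @param scale one of \code{"tiny"}, \code{"small"}, \code{"full"}.
#' @return a \code{\linkS4class{StudyStructure}}.
#' @export
studyStructureOf <- function(scale = c("tiny", "small", "full")) {
  if (!is.character(scale) || length(scale) != 1L ||
      !scale %in% c("tiny", "small", "full"))
    stop("unknown fixture scale: ", paste(scale, collapse = ", "))
  switch(scale,
    full = {
      areas <- rep(kAreas, times = c(7L, 21L, 10L, 2L))
      mr <- matrix(0, 2, 4, dimnames = list(kMethods, kAreas))
      mr["ground", ] <- c(0.58, 0.41, 0.40, 0.46)
      mr["aerial", ] <- 0.003
      intro <- rep(1L, 40L)
      intro[33:39] <- 28L   # added with the second aerial observer
      intro[40] <- 38L      # added with the third
      newStudyStructure(40L, 44L, 7L, areas,
                        rep(1:3, times = c(27L, 10L, 7L)),
                        groundMethodChange = list(area = "TourDuValat", year = 32L),
                        aerialIntroYear = intro,
                        missingnessRate = mr)
    },
    small = {
      areas <- rep(kAreas, times = c(2L, 5L, 3L, 2L))
      mr <- matrix(0, 2, 4, dimnames = list(kMethods, kAreas))
      mr["ground", ] <- c(0.58, 0.41, 0.40, 0.46)
      mr["aerial", ] <- 0.003
      intro <- rep(1L, 12L)
      intro[10] <- 13L
      newStudyStructure(12L, 20L, 7L, areas,
                        rep(1:3, times = c(12L, 5L, 3L)),
                        groundMethodChange = list(area = "TourDuValat", year = 15L),
                        aerialIntroYear = intro,
                        missingnessRate = mr)
    },
    tiny = {
      areas <- rep(kAreas, times = c(1L, 2L, 2L, 1L))
      mr <- matrix(0, 2, 4, dimnames = list(kMethods, kAreas))
      mr["ground", ] <- 0.30
      mr["aerial", ] <- 0.02
      intro <- rep(1L, 6L)
      intro[5] <- 4L
      newStudyStructure(6L, 10L, 7L, areas,
                        rep(1:3, times = c(5L, 3L, 2L)),
                        groundMethodChange = list(area = "TourDuValat", year = 7L),
                        aerialIntroYear = intro,
                        missingnessRate = mr)
    })
}

#' @rdname nSites
#' @export
setMethod("nSites", "StudyStructure", function(object) object@nSites)
#' @rdname nSites
#' @export
setMethod("nYears", "StudyStructure", function(object) object@nYears)
#' @rdname nSites
#' @export
setMethod("nMonths", "StudyStructure", function(object) object@nMonths)
#' @rdname areaOfSite
#' @export
setMethod("areaOfSite", "StudyStructure", function(object) object@areaOfSite)

setMethod("show", "StudyStructure", function(object) {
  cat(sprintf("StudyStructure: %d sites, %d years, %d months (1 = September)\n",
              object@nSites, object@nYears, object@nMonths))
  tab <- table(object@areaOfSite)
  cat("  sites per area:",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  cat("  aerial observer periods:",
      paste(rle(object@observerPeriodOfYear)$lengths, collapse = " / "),
      "years\n")
  if (length(object@changeArea))
    cat(sprintf("  ground protocol change: %s from year %d\n",
                object@changeArea, object@changeYear))
})

# years (as a 0/1 missing template) each site is aerially covered
aerialCovered <- function(structure, site, year) {
  year >= structure@aerialIntroYear[site]
}
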