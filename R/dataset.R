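#' @include AllClasses.R structure.R
NULL

#' Construct a SurveyDataset from a count array
#'
#' @param counts integer array 2 x months x sites x years (methods first,
#'   ordered aerial, ground); \code{NA} marks missing occasions.
#' @param structure the matching \code{\linkS4class{StudyStructure}}.
#' @param species species label.
#' @param logCounts optional log-scale observations; defaults to
#'   \code{log(counts + 1)}. The generator passes the exact continuous draws
#'   here when asked to.
#' @return a validated \code{\linkS4class{SurveyDataset}}.
#' @export
surveyDataset <- function(counts, structure, species = "synthetic",
                          logCounts = NULL) {
  dimnames(counts) <- list(method = kMethods, month = NULL, site = NULL,
                           year = NULL)
  if (is.null(logCounts)) logCounts <- log1p(counts)
  dimnames(logCounts) <- dimnames(counts)
  new("SurveyDataset", species = species, counts = counts,
      logCounts = logCounts, structure = structure)
}

#' @rdname nSites
#' @export
setMethod("nSites", "SurveyDataset", function(object) object@structure@nSites)
#' @rdname nSites
#' @export
setMethod("nYears", "SurveyDataset", function(object) object@structure@nYears)
#' @rdname nSites
#' @export
setMethod("nMonths", "SurveyDataset", function(object) object@structure@nMonths)
#' @rdname studyStructure
#' @export
setMethod("studyStructure", "SurveyDataset", function(object) object@structure)

#' Observed (non-missing) cell count per method
#' @param dataset a \code{\linkS4class{SurveyDataset}}.
#' @return named integer vector (aerial, ground).
#' @export
nObserved <- function(dataset) {
  stats::setNames(
    c(sum(!is.na(dataset@counts[1, , , ])), sum(!is.na(dataset@counts[2, , , ]))),
    kMethods)
}

#' Fraction of missing cells per (method, area)
#' @param dataset a \code{\linkS4class{SurveyDataset}}.
#' @return methods x areas matrix of empirical missing fractions.
#' @export
missingFraction <- function(dataset) {
  st <- dataset@structure
  areas <- sort(unique(st@areaOfSite))
  out <- matrix(NA_real_, 2, length(areas), dimnames = list(kMethods, areas))
  for (a in areas) {
    sites <- which(st@areaOfSite == a)
    for (i in 1:2)
      out[i, a] <- mean(is.na(dataset@counts[i, , sites, ]))
  }
  out
}

setMethod("show", "SurveyDataset", function(object) {
  st <- object@structure
  no <- nObserved(object)
  cat(sprintf("SurveyDataset '%s': %d sites x %d years x %d months x 2 methods\n",
              object@species, st@nSites, st@nYears, st@nMonths))
  cat(sprintf("  observed cells: %d aerial, %d ground (%.0f%% missing overall)\n",
              no[1], no[2], 100 * mean(is.na(object@counts))))
})

#' Write a survey dataset to long-format CSV
#'
#' One row per (site, year, month, method) with columns \code{species, site,
#' area, year, month, method, observer_period, count}; missing occasions have
#' an empty count field.
#'
#' @param dataset a \code{\linkS4class{SurveyDataset}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(dataset, path) {
  st <- dataset@structure
  grid <- expand.grid(method = kMethods, month = seq_len(st@nMonths),
                      site = seq_len(st@nSites), year = seq_len(st@nYears),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- data.frame(
    species = dataset@species,
    site = grid$site,
    area = st@areaOfSite[grid$site],
    year = grid$year,
    month = grid$month,
    method = grid$method,
    observer_period = st@observerPeriodOfYear[grid$year],
    count = dataset@counts[cbind(match(grid$method, kMethods), grid$month,
                                 grid$site, grid$year)])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format count CSV into a SurveyDataset
#'
#' Expects the schema written by \code{\link{writeCounts}}. Blank counts
#' become missing; duplicate (species, method, site, year, month) rows and
#' negative counts are rejected with their row numbers. The study structure
#' is reconstructed from the file (areas from the site-area mapping, observer
#' periods from the year column, aerial introduction years from the first
#' non-missing aerial record per site, empirical missingness rates) unless an
#' explicit \code{structure} is supplied.
#'
#' @param path CSV file.
#' @param species which species to load (default: the only one present).
#' @param structure optional known \code{\linkS4class{StudyStructure}}.
#' @param groundMethodChange optional \code{list(area =, year =)} protocol
#'   change to record when inferring the structure; defaults to the Tour du
#'   Valat change at year 32 when that area is present and the series is long
#'   enough, else none.
#' @return a \code{\linkS4class{SurveyDataset}}.
#' @examples
#' path <- system.file("extdata", "tiny_synthetic_counts.csv",
#'                     package = "waterfowlSSM")
#' ds <- readCounts(path, groundMethodChange = list(area = "TourDuValat",
#'                                                  year = 7L))
#' ds
#' @export
readCounts <- function(path, species = NULL, structure = NULL,
                       groundMethodChange = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "site", "area", "year", "month", "method", "count")
  if (!all(need %in% names(df)))
    stop("count file lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(species)) {
    species <- unique(df$species)
    if (length(species) != 1L)
      stop("file holds several species; pick one of: ",
           paste(species, collapse = ", "))
  }
  df <- df[df$species == species, ]
  if (!nrow(df)) stop("no rows for species ", species)
  bad <- which(!df$method %in% kMethods)
  if (length(bad)) stop("unknown method at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$area %in% kAreas)
  if (length(bad))
    stop("unknown area label at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  conflict <- tapply(df$area, df$site, function(a) length(unique(a)) > 1L)
  if (any(conflict))
    stop("conflicting area mapping for site(s): ",
         paste(utils::head(names(conflict)[conflict], 5), collapse = ", "))
  bad <- which(!is.na(df$count) & (df$count < 0 | df$count != round(df$count)))
  if (length(bad))
    stop("negative or non-integer count at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(df$species, df$method, df$site, df$year, df$month)
  if (anyDuplicated(key))
    stop("duplicate records at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))

  if (is.null(structure)) {
    S <- max(df$site); T <- max(df$year); M <- max(df$month)
    areaOf <- rep(NA_character_, S)
    areaOf[df$site] <- df$area
    if (anyNA(areaOf)) stop("site without an area mapping")
    if (!all(areaOf %in% kAreas))
      stop("unknown area label(s): ",
           paste(setdiff(areaOf, kAreas), collapse = ", "))
    per <- rep(NA_integer_, T)
    if ("observer_period" %in% names(df)) {
      per[df$year] <- as.integer(df$observer_period)
    } else per[] <- 1L
    if (anyNA(per)) stop("year without an observer period")
    aer <- df[df$method == "aerial" & !is.na(df$count), ]
    intro <- rep(1L, S)
    if (nrow(aer)) {
      first <- tapply(aer$year, aer$site, min)
      intro[as.integer(names(first))] <- as.integer(first)
      intro[intro > 1L & intro <= 2L] <- 1L   # tolerate a missing first year
    }
    if (is.null(groundMethodChange) && "TourDuValat" %in% areaOf && T >= 32L)
      groundMethodChange <- list(area = "TourDuValat", year = 32L)
    structure <- newStudyStructure(S, T, M, areaOf, per,
                                   groundMethodChange = groundMethodChange,
                                   aerialIntroYear = intro)
  }
  st <- structure
  if (max(df$site) > st@nSites || max(df$year) > st@nYears ||
      max(df$month) > st@nMonths)
    stop("record indices exceed the study structure")
  counts <- array(NA_real_, c(2L, st@nMonths, st@nSites, st@nYears))
  counts[cbind(match(df$method, kMethods), df$month, df$site, df$year)] <-
    as.numeric(df$count)
  ds <- surveyDataset(counts, st, species = species)
  # record the empirical missingness in the inferred structure
  ds@structure@missingnessRate <- missingFraction(ds)
  ds
}
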