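#' InfiltrationSummary: percent TIL infiltration of one slide
#'
#' Counts of tumor cells and co-positive (tumor-and-lymphocyte) cells on
#' the common lattice, and the derived percent infiltration
#' `100 * n_co_positive / n_tumor`.  The TIL class is a cohort-level label
#' assigned later by [assignTilClass()].
#'
#' @slot nTumorCells number of tumor-positive lattice cells.
#' @slot nCoPositiveCells number of cells positive for both tumor and
#'   lymphocyte.
#' @slot percentInfiltration percent in \[0, 100\].
#' @slot tilClass "High", "Low", or `NA` when unassigned.
#' @slot slideId slide identifier.
#' @exportClass InfiltrationSummary
setClass("InfiltrationSummary",
  representation(
    nTumorCells = "integer",
    nCoPositiveCells = "integer",
    percentInfiltration = "numeric",
    tilClass = "character",
    slideId = "character"
  ),
  prototype(tilClass = NA_character_)
)

setValidity("InfiltrationSummary", function(object) {
  if (object@nCoPositiveCells < 0L ||
      object@nCoPositiveCells > object@nTumorCells) {
    return("need 0 <= nCoPositiveCells <= nTumorCells")
  }
  if (object@nTumorCells > 0L) {
    expect <- 100 * object@nCoPositiveCells / object@nTumorCells
    if (!isTRUE(all.equal(expect, object@percentInfiltration))) {
      return("percentInfiltration must equal 100 * nCoPositive / nTumor")
    }
  }
  TRUE
})

setMethod("show", "InfiltrationSummary", function(object) {
  cat(sprintf(
    "InfiltrationSummary '%s': %d / %d tumor cells co-positive = %.2f%%%s\n",
    object@slideId, object@nCoPositiveCells, object@nTumorCells,
    object@percentInfiltration,
    if (is.na(object@tilClass)) "" else paste0(" (TIL ", object@tilClass, ")")
  ))
})

#' Compose aligned grids into a Tumor-TIL map
#'
#' Copies the per-cell tumor and lymphocyte flags of a resampled
#' [LatticePair-class] into a [CompositeMap-class].  Each cell then belongs
#' to exactly one of four categories: background, tumor-only,
#' lymphocyte-only, or co-positive.
#'
#' @param pair a [LatticePair-class] from [resampleToCommonLattice()].
#' @return a [CompositeMap-class].
#' @aliases composeMap
#' @export
#' @examples
#' tum <- BinaryGrid(matrix(TRUE, 4, 4), 87.5, "s1")
#' lym <- BinaryGrid(matrix(TRUE, 7, 7), 50, "s1")
#' composeMap(resampleToCommonLattice(tum, lym))
setMethod("composeMap", "LatticePair", function(pair) {
  if (!identical(dim(pair@tumor@values), dim(pair@lymph@values))) {
    tlsStop("tilscape_alignment_error", "lattice shapes differ")
  }
  CompositeMap(pair@tumor@values, pair@lymph@values, pair@cellSizeUm,
               pair@tumor@slideId)
})

#' Per-cell categories of a Tumor-TIL map
#'
#' @param map a [CompositeMap-class].
#' @return a character matrix over
#'   `{"background", "tumor", "lymph", "tumor+lymph"}`.
#' @export
cellCategories <- function(map) {
  stopifnot(is(map, "CompositeMap"))
  out <- matrix("background", nrow(map@tumor), ncol(map@tumor))
  out[map@tumor & !map@lymph] <- "tumor"
  out[!map@tumor & map@lymph] <- "lymph"
  out[map@tumor & map@lymph] <- "tumor+lymph"
  out
}

#' Percent TIL infiltration of a Tumor-TIL map
#'
#' The number of lattice cells positive for both tumor and lymphocyte
#' divided by the total number of tumor-positive cells, times 100.  A map
#' with no tumor cells has undefined infiltration and raises a classed
#' error (`tilscape_undefined_error`) so the slide can be flagged rather
#' than silently scored 0.
#'
#' @param map a [CompositeMap-class].
#' @return an [InfiltrationSummary-class].
#' @aliases percentInfiltration
#' @export
#' @examples
#' tum <- matrix(TRUE, 10, 10)
#' lym <- matrix(FALSE, 10, 10); lym[1:5, 1:5] <- TRUE
#' percentInfiltration(CompositeMap(tum, lym))   # 25%
setMethod("percentInfiltration", "CompositeMap", function(map) {
  nTumor <- sum(map@tumor)
  if (nTumor == 0L) {
    tlsStop("tilscape_undefined_error",
            "slide '%s' has no tumor-positive cells; infiltration undefined",
            map@slideId)
  }
  nCo <- sum(map@tumor & map@lymph)
  new("InfiltrationSummary", nTumorCells = nTumor, nCoPositiveCells = nCo,
      percentInfiltration = 100 * nCo / nTumor, slideId = map@slideId)
})

#' Assign TIL classes around a cohort center
#'
#' Slides whose percent infiltration exceeds the cohort center statistic
#' (mean by default; median also supported) are labeled "High", all others
#' "Low".  Ties with the center go to "Low".
#'
#' @param values numeric vector of percent infiltration, one per slide
#'   (at least 2 finite values).
#' @param center "mean" or "median".
#' @return character vector of "High"/"Low", same length as `values`.
#' @export
#' @examples
#' assignTilClass(c(1, 2, 3, 4))          # Low Low High High (mean 2.5)
assignTilClass <- function(values, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values) == 0L) {
    tlsStop("tilscape_parameter_error", "no infiltration values supplied")
  }
  finite <- values[is.finite(values)]
  if (length(finite) < 2L) {
    tlsStop("tilscape_parameter_error",
            "need at least 2 finite infiltration values")
  }
  ctr <- if (center == "mean") mean(finite) else stats::median(finite)
  ifelse(values > ctr, "High", "Low")
}
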