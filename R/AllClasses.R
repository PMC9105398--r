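#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' HeatmapGrid: a patch-level probability grid
#'
#' Raw output of a patch classifier for one slide: a rectangular grid of
#' probabilities in \[0, 1\], one cell per tiled image patch, together with
#' the physical edge length of a patch in micrometres.  An optional logical
#' `tissueMask` marks patches that contain analyzable tissue; probabilities
#' outside the mask are ignored downstream.
#'
#' @slot values numeric matrix of probabilities in \[0, 1\].
#' @slot patchSizeUm physical edge length of one patch (micrometres, > 0).
#' @slot slideId slide identifier.
#' @slot tissueMask logical matrix of the same shape, or `NULL` meaning
#'   every patch is analyzable.
#'
#' @seealso [readHeatmap()], [binarize()]
#' @exportClass HeatmapGrid
setClass("HeatmapGrid",
  representation(
    values = "matrix",
    patchSizeUm = "numeric",
    slideId = "character",
    tissueMask = "matrixOrNULL"
  ),
  prototype(tissueMask = NULL)
)

setValidity("HeatmapGrid", function(object) {
  v <- object@values
  msk <- object@tissueMask
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (length(object@patchSizeUm) != 1L || !is.finite(object@patchSizeUm) ||
      object@patchSizeUm <= 0) {
    return("'patchSizeUm' must be a single positive number")
  }
  if (length(object@slideId) != 1L) return("'slideId' must be a single string")
  if (!is.null(msk)) {
    if (!is.logical(msk)) return("'tissueMask' must be a logical matrix")
    if (!identical(dim(msk), dim(v))) {
      return("'tissueMask' must have the same shape as 'values'")
    }
  }
  inside <- if (is.null(msk)) rep(TRUE, length(v)) else as.vector(msk)
  vv <- as.vector(v)[inside]
  if (anyNA(vv)) return("NA probabilities are only allowed outside the tissue mask")
  if (any(vv < 0 | vv > 1)) return("probabilities must lie in [0, 1]")
  TRUE
})

#' BinaryGrid: a thresholded patch grid
#'
#' A rectangular logical grid obtained by binarizing a [HeatmapGrid-class]
#' (or planted directly by the synthetic generator), with its patch size.
#'
#' @slot values logical matrix.
#' @slot patchSizeUm physical edge length of one patch (micrometres, > 0).
#' @slot slideId slide identifier.
#'
#' @exportClass BinaryGrid
setClass("BinaryGrid",
  representation(
    values = "matrix",
    patchSizeUm = "numeric",
    slideId = "character"
  )
)

setValidity("BinaryGrid", function(object) {
  if (!is.logical(object@values)) return("'values' must be a logical matrix")
  if (anyNA(object@values)) return("'values' must not contain NA")
  if (length(object@patchSizeUm) != 1L || !is.finite(object@patchSizeUm) ||
      object@patchSizeUm <= 0) {
    return("'patchSizeUm' must be a single positive number")
  }
  TRUE
})

#' LatticePair: tumor and lymphocyte grids on a shared fine lattice
#'
#' The two binarized model outputs resampled onto a common lattice whose
#' pitch is the greatest common divisor of the two patch sizes (12.5 um for
#' the default 87.5 um tumor / 50 um lymphocyte patches), so that the maps
#' can be overlaid cell by cell.
#'
#' @slot tumor [BinaryGrid-class] on the common lattice.
#' @slot lymph [BinaryGrid-class] on the common lattice, same shape.
#' @slot cellSizeUm common lattice pitch (micrometres).
#'
#' @seealso [resampleToCommonLattice()], [composeMap()]
#' @exportClass LatticePair
setClass("LatticePair",
  representation(
    tumor = "BinaryGrid",
    lymph = "BinaryGrid",
    cellSizeUm = "numeric"
  )
)

setValidity("LatticePair", function(object) {
  if (!identical(dim(object@tumor@values), dim(object@lymph@values))) {
    return("tumor and lymph grids must have identical shape")
  }
  if (!isTRUE(all.equal(object@tumor@patchSizeUm, object@cellSizeUm)) ||
      !isTRUE(all.equal(object@lymph@patchSizeUm, object@cellSizeUm))) {
    return("both grids must carry the common cell size")
  }
  TRUE
})

#' CompositeMap: the Tumor-TIL map
#'
#' Per-cell tumor and lymphocyte flags on the common lattice.  Each cell
#' falls in exactly one of four categories: background, tumor-only,
#' lymphocyte-only, or co-positive (tumor and lymphocyte) -- the last is
#' what counts as TIL infiltration.
#'
#' @slot tumor logical matrix of tumor flags.
#' @slot lymph logical matrix of lymphocyte flags, same shape.
#' @slot cellSizeUm lattice pitch (micrometres).
#' @slot slideId slide identifier.
#'
#' @seealso [composeMap()], [percentInfiltration()], [scoreAll()]
#' @exportClass CompositeMap
setClass("CompositeMap",
  representation(
    tumor = "matrix",
    lymph = "matrix",
    cellSizeUm = "numeric",
    slideId = "character"
  )
)

setValidity("CompositeMap", function(object) {
  if (!is.logical(object@tumor) || !is.logical(object@lymph)) {
    return("'tumor' and 'lymph' must be logical matrices")
  }
  if (!identical(dim(object@tumor), dim(object@lymph))) {
    return("'tumor' and 'lymph' must have identical shape")
  }
  if (length(object@cellSizeUm) != 1L || object@cellSizeUm <= 0) {
    return("'cellSizeUm' must be a single positive number")
  }
  TRUE
})

#' MorphologyConfig: tunable parameters of the spatial feature scorers
#'
#' All knobs of the morphological scoring rules.  Area thresholds are
#' fractions of the tumor mask area; the strength cutoffs grade the
#' infiltration fraction into the ordinal 0-3 ladder.  Construct with
#' [morphologyConfig()] which documents the defaults.
#'
#' @slot connectivity 4 or 8; neighborhood used for connected components.
#' @slot desertMinComponentFrac smallest TIL-free component (fraction of
#'   tumor area) that counts towards the desert total.
#' @slot desertAreaFracThreshold qualifying TIL-free area (fraction of
#'   tumor area) at or above which deserts score 1.
#' @slot forestMinComponentFrac smallest confluent TIL component (fraction
#'   of tumor area) that counts towards the forest total.
#' @slot forestAreaFracThreshold qualifying confluent TIL area at or above
#'   which forests score 1.
#' @slot bandWidthCells peritumoral band width in lattice cells.
#' @slot strengthCutoffs two ascending fractions (c1, c2) splitting the
#'   nonzero infiltration range into grades 1, 2, 3.
#' @slot aggregateMinCells smallest distal lymphoid cluster (cells) that
#'   qualifies as an aggregate.
#' @slot aggregateMultifocalMin number of qualifying clusters required for
#'   a positive "multifocal aggregates" call.
#'
#' @exportClass MorphologyConfig
setClass("MorphologyConfig",
  representation(
    connectivity = "integer",
    desertMinComponentFrac = "numeric",
    desertAreaFracThreshold = "numeric",
    forestMinComponentFrac = "numeric",
    forestAreaFracThreshold = "numeric",
    bandWidthCells = "integer",
    strengthCutoffs = "numeric",
    aggregateMinCells = "integer",
    aggregateMultifocalMin = "integer"
  )
)

setValidity("MorphologyConfig", function(object) {
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  fr <- c(object@desertMinComponentFrac, object@desertAreaFracThreshold,
          object@forestMinComponentFrac, object@forestAreaFracThreshold)
  if (any(fr <= 0 | fr >= 1)) return("area fractions must lie in (0, 1)")
  if (length(object@strengthCutoffs) != 2L ||
      diff(object@strengthCutoffs) <= 0 ||
      any(object@strengthCutoffs <= 0 | object@strengthCutoffs >= 1)) {
    return("strengthCutoffs must be two strictly ascending fractions in (0, 1)")
  }
  if (object@bandWidthCells < 1L) return("bandWidthCells must be >= 1")
  if (object@aggregateMinCells < 1L) return("aggregateMinCells must be >= 1")
  if (object@aggregateMultifocalMin < 1L) {
    return("aggregateMultifocalMin must be >= 1")
  }
  TRUE
})

#' FeatureScores: the five graded spatial features of one Tumor-TIL map
#'
#' Intratumoral strength and peritumoral strength are ordinal 0-3;
#' deserts, forests and aggregates are binary.  A map on which the rules
#' are undefined (e.g. no tumor region) carries `excluded = TRUE` and a
#' reason, with all scores `NA`.
#'
#' @slot intratumoralStrength integer 0-3 (NA when excluded).
#' @slot deserts integer 0/1.
#' @slot forests integer 0/1.
#' @slot peritumoralStrength integer 0-3.
#' @slot aggregates integer 0/1.
#' @slot excluded logical flag for maps the rules cannot score.
#' @slot reason reason for exclusion ("" when not excluded).
#'
#' @seealso [scoreAll()], [highRiskProfile()]
#' @exportClass FeatureScores
setClass("FeatureScores",
  representation(
    intratumoralStrength = "integer",
    deserts = "integer",
    forests = "integer",
    peritumoralStrength = "integer",
    aggregates = "integer",
    excluded = "logical",
    reason = "character"
  ),
  prototype(excluded = FALSE, reason = "")
)

setValidity("FeatureScores", function(object) {
  chk <- function(x, hi, nm) {
    if (length(x) != 1L) return(sprintf("'%s' must be length 1", nm))
    if (!is.na(x) && (x < 0L || x > hi)) {
      return(sprintf("'%s' must lie in 0..%d", nm, hi))
    }
    NULL
  }
  for (m in list(chk(object@intratumoralStrength, 3L, "intratumoralStrength"),
                 chk(object@deserts, 1L, "deserts"),
                 chk(object@forests, 1L, "forests"),
                 chk(object@peritumoralStrength, 3L, "peritumoralStrength"),
                 chk(object@aggregates, 1L, "aggregates"))) {
    if (!is.null(m)) return(m)
  }
  if (isTRUE(object@excluded)) {
    sc <- c(object@intratumoralStrength, object@deserts, object@forests,
            object@peritumoralStrength, object@aggregates)
    if (!all(is.na(sc))) return("excluded scores must be NA")
  }
  TRUE
})

#' HighRiskProfile: binary high-risk indicators and the resulting group
#'
#' Graded feature scores mapped to the binary high-risk indicators (low
#' intratumoral strength 0-1, deserts present, forests absent, low
#' peritumoral strength 0-1, and optionally aggregates absent) and the
#' two-or-more rule that assigns the high-risk group.
#'
#' @slot indicators character vector of the indicators that fired, among
#'   the active feature set.
#' @slot count number of active indicators that fired.
#' @slot group "high-risk" if `count >= 2`, else "low-risk".
#'
#' @seealso [highRiskProfile()]
#' @exportClass HighRiskProfile
setClass("HighRiskProfile",
  representation(
    indicators = "character",
    count = "integer",
    group = "character"
  )
)

setValidity("HighRiskProfile", function(object) {
  if (object@count != length(object@indicators)) {
    return("'count' must equal the number of indicators")
  }
  if (!object@group %in% c("high-risk", "low-risk")) {
    return("'group' must be 'high-risk' or 'low-risk'")
  }
  if ((object@count >= 2L) != (object@group == "high-risk")) {
    return("'group' must be high-risk exactly when count >= 2")
  }
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "HeatmapGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("HeatmapGrid '%s': %d x %d patches @ %g um\n",
              object@slideId, d[1], d[2], object@patchSizeUm))
  cat(sprintf("  probability range: [%.3g, %.3g]%s\n",
              min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE),
              if (is.null(object@tissueMask)) "" else
                sprintf("; %d/%d patches in tissue",
                        sum(object@tissueMask), length(object@tissueMask))))
})

setMethod("show", "BinaryGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryGrid '%s': %d x %d patches @ %g um, %d positive\n",
              object@slideId, d[1], d[2], object@patchSizeUm,
              sum(object@values)))
})

setMethod("show", "LatticePair", function(object) {
  d <- dim(object@tumor@values)
  cat(sprintf("LatticePair '%s': %d x %d cells @ %g um (tumor+ %d, lymph+ %d)\n",
              object@tumor@slideId, d[1], d[2], object@cellSizeUm,
              sum(object@tumor@values), sum(object@lymph@values)))
})

setMethod("show", "CompositeMap", function(object) {
  d <- dim(object@tumor)
  co <- sum(object@tumor & object@lymph)
  cat(sprintf("CompositeMap '%s': %d x %d cells @ %g um\n",
              object@slideId, d[1], d[2], object@cellSizeUm))
  cat(sprintf("  tumor %d | lymph %d | co-positive %d | background %d\n",
              sum(object@tumor & !object@lymph),
              sum(!object@tumor & object@lymph), co,
              sum(!object@tumor & !object@lymph)))
})

setMethod("show", "FeatureScores", function(object) {
  if (object@excluded) {
    cat(sprintf("FeatureScores: excluded (%s)\n", object@reason))
  } else {
    cat(sprintf(paste0("FeatureScores: intratumoral %d | deserts %d | ",
                       "forests %d | peritumoral %d | aggregates %d\n"),
                object@intratumoralStrength, object@deserts, object@forests,
                object@peritumoralStrength, object@aggregates))
  }
})

setMethod("show", "HighRiskProfile", function(object) {
  cat(sprintf("HighRiskProfile: %s (%d indicator%s%s)\n", object@group,
              object@count, if (object@count == 1L) "" else "s",
              if (object@count) paste0(": ",
                paste(object@indicators, collapse = ", ")) else ""))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for grid and map objects
#'
#' `gridValues()` returns the numeric or logical value matrix,
#' `patchSize()` the physical patch/cell size in micrometres, `slideId()`
#' the slide identifier, `tumorMask()`/`lymphMask()` the per-cell flags of
#' a [CompositeMap-class].
#'
#' @param x a tilscape grid or map object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases gridValues patchSize slideId tumorMask lymphMask
#'
#' @examples
#' g <- HeatmapGrid(matrix(runif(12), 3), patchSizeUm = 50)
#' dim(gridValues(g))
#' patchSize(g)
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("patchSize", function(x) standardGeneric("patchSize"))
#' @rdname accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("lymphMask", function(x) standardGeneric("lymphMask"))

#' @rdname accessors
setMethod("gridValues", "HeatmapGrid", function(x) x@values)
#' @rdname accessors
setMethod("gridValues", "BinaryGrid", function(x) x@values)
#' @rdname accessors
setMethod("patchSize", "HeatmapGrid", function(x) x@patchSizeUm)
#' @rdname accessors
setMethod("patchSize", "BinaryGrid", function(x) x@patchSizeUm)
#' @rdname accessors
setMethod("patchSize", "CompositeMap", function(x) x@cellSizeUm)
#' @rdname accessors
setMethod("patchSize", "LatticePair", function(x) x@cellSizeUm)
#' @rdname accessors
setMethod("slideId", "HeatmapGrid", function(x) x@slideId)
#' @rdname accessors
setMethod("slideId", "BinaryGrid", function(x) x@slideId)
#' @rdname accessors
setMethod("slideId", "CompositeMap", function(x) x@slideId)
#' @rdname accessors
setMethod("tumorMask", "CompositeMap", function(x) x@tumor)
#' @rdname accessors
setMethod("tumorMask", "LatticePair", function(x) x@tumor)
#' @rdname accessors
setMethod("lymphMask", "CompositeMap", function(x) x@lymph)
#' @rdname accessors
setMethod("lymphMask", "LatticePair", function(x) x@lymph)

## ---- constructors -------------------------------------------------------

#' Construct a HeatmapGrid
#'
#' @param values numeric matrix of probabilities in \[0, 1\].
#' @param patchSizeUm physical patch edge length (micrometres).
#' @param slideId slide identifier.
#' @param tissueMask optional logical matrix marking analyzable patches.
#' @return a [HeatmapGrid-class].
#' @export
#' @examples
#' HeatmapGrid(matrix(c(0.2, 0.8, 1, 0), 2, byrow = TRUE), 87.5, "s1")
HeatmapGrid <- function(values, patchSizeUm, slideId = "slide",
                        tissueMask = NULL) {
  new("HeatmapGrid", values = values, patchSizeUm = as.numeric(patchSizeUm),
      slideId = as.character(slideId), tissueMask = tissueMask)
}

#' Construct a BinaryGrid
#'
#' @param values logical matrix.
#' @param patchSizeUm physical patch edge length (micrometres).
#' @param slideId slide identifier.
#' @return a [BinaryGrid-class].
#' @export
BinaryGrid <- function(values, patchSizeUm, slideId = "slide") {
  new("BinaryGrid", values = values, patchSizeUm = as.numeric(patchSizeUm),
      slideId = as.character(slideId))
}

#' Construct a CompositeMap directly from two logical matrices
#'
#' Mostly useful in tests and simulations; the pipeline route is
#' [composeMap()] on a [LatticePair-class].
#'
#' @param tumor,lymph logical matrices of identical shape.
#' @param cellSizeUm lattice pitch (micrometres).
#' @param slideId slide identifier.
#' @return a [CompositeMap-class].
#' @export
CompositeMap <- function(tumor, lymph, cellSizeUm = 12.5, slideId = "slide") {
  new("CompositeMap", tumor = tumor, lymph = lymph,
      cellSizeUm = as.numeric(cellSizeUm), slideId = as.character(slideId))
}

#' Construct a FeatureScores object
#'
#' @param intratumoralStrength,peritumoralStrength ordinal scores 0-3.
#' @param deserts,forests,aggregates binary scores 0/1.
#' @param excluded logical; `TRUE` marks an unscorable map.
#' @param reason reason for exclusion.
#' @return a [FeatureScores-class].
#' @export
FeatureScores <- function(intratumoralStrength = NA_integer_,
                          deserts = NA_integer_, forests = NA_integer_,
                          peritumoralStrength = NA_integer_,
                          aggregates = NA_integer_,
                          excluded = FALSE, reason = "") {
  new("FeatureScores",
      intratumoralStrength = as.integer(intratumoralStrength),
      deserts = as.integer(deserts), forests = as.integer(forests),
      peritumoralStrength = as.integer(peritumoralStrength),
      aggregates = as.integer(aggregates),
      excluded = excluded, reason = reason)
}

#' Convert FeatureScores to a one-row data.frame
#'
#' @param x a [FeatureScores-class].
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @return one-row `data.frame` with the five scores, `excluded`, `reason`.
#' @export
as.data.frame.FeatureScores <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    intratumoral_strength = x@intratumoralStrength,
    deserts = x@deserts, forests = x@forests,
    peritumoral_strength = x@peritumoralStrength,
    aggregates = x@aggregates,
    excluded = x@excluded, reason = x@reason,
    stringsAsFactors = FALSE, row.names = row.names
  )
}
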