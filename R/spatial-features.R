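checkTumor <- function(map) {
  if (!any(map@tumor)) {
    tlsStop("tilscape_undefined_error",
            "slide '%s' has no tumor cells; spatial features undefined",
            map@slideId)
  }
}

## qualifying area of a mask: sum of the components (within `mask`) whose
## size reaches minFrac * tumorArea
qualifyingArea <- function(mask, tumorArea, minFrac, connectivity) {
  cc <- connectedComponents(mask, connectivity)
  keep <- cc$sizes >= minFrac * tumorArea
  sum(cc$sizes[keep])
}

#' Score intratumoral TIL deserts
#'
#' A desert is a confluent intratumoral region completely clear of TIL
#' infiltrate.  Connected components of TIL-free tumor cells at least
#' `desertMinComponentFrac` of the tumor area qualify; the score is 1 when
#' their summed area reaches `desertAreaFracThreshold` (default 25%) of
#' the tumor area, else 0.
#'
#' @param map a [CompositeMap-class] with at least one tumor cell.
#' @param cfg a [MorphologyConfig-class].
#' @return integer 0 or 1.
#' @export
#' @examples
#' tum <- matrix(TRUE, 20, 20)
#' lym <- matrix(TRUE, 20, 20); lym[1:10, 1:10] <- FALSE  # 25% TIL-free
#' scoreDeserts(CompositeMap(tum, lym))  # 1
scoreDeserts <- function(map, cfg = morphologyConfig()) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  checkTumor(map)
  tumorArea <- sum(map@tumor)
  tilFree <- map@tumor & !map@lymph
  qual <- qualifyingArea(tilFree, tumorArea, cfg@desertMinComponentFrac,
                         cfg@connectivity)
  as.integer(qual >= cfg@desertAreaFracThreshold * tumorArea)
}

#' Score intratumoral TIL forests
#'
#' A forest is a confluent group of TIL-positive patches inside the tumor.
#' Components of co-positive cells at least `forestMinComponentFrac` of the
#' tumor area qualify; the score is 1 when their summed area reaches
#' `forestAreaFracThreshold` (default 10%) of the tumor area, else 0.
#'
#' @inheritParams scoreDeserts
#' @return integer 0 or 1.
#' @export
scoreForests <- function(map, cfg = morphologyConfig()) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  checkTumor(map)
  tumorArea <- sum(map@tumor)
  coPos <- map@tumor & map@lymph
  qual <- qualifyingArea(coPos, tumorArea, cfg@forestMinComponentFrac,
                         cfg@connectivity)
  as.integer(qual >= cfg@forestAreaFracThreshold * tumorArea)
}

## grade a fraction on the 0-3 ladder: exactly zero -> 0, then cutoffs
gradeStrength <- function(frac, cutoffs) {
  if (frac == 0) return(0L)
  if (frac <= cutoffs[1]) return(1L)
  if (frac <= cutoffs[2]) return(2L)
  3L
}

#' Grade intratumoral TIL strength (0-3)
#'
#' Score 0 when no tumor cell is TIL-positive; otherwise the infiltration
#' fraction (co-positive cells / tumor cells) is graded by the configured
#' cutoffs: weak (1) up to c1, moderate (2) up to c2, strong (3) above
#' (defaults c1 = 5%, c2 = 15%).
#'
#' @inheritParams scoreDeserts
#' @return integer 0-3.
#' @export
scoreIntratumoralStrength <- function(map, cfg = morphologyConfig()) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  checkTumor(map)
  frac <- sum(map@tumor & map@lymph) / sum(map@tumor)
  gradeStrength(frac, cfg@strengthCutoffs)
}

#' Grade peritumoral TIL strength (0-3)
#'
#' The fraction of peritumoral-band cells that are lymphocyte-positive,
#' graded on the same 0-3 ladder as intratumoral strength; 0 means no
#' TIL-positive patch at the invasive boundary, 3 a nearly confluent
#' accumulation around the tumor.  An empty band (tumor filling the whole
#' lattice) is an undefined-feature error.
#'
#' @inheritParams scoreDeserts
#' @return integer 0-3.
#' @export
scorePeritumoralStrength <- function(map, cfg = morphologyConfig()) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  checkTumor(map)
  band <- peritumoralBand(map, cfg)
  nBand <- sum(band)
  if (nBand == 0L) {
    tlsStop("tilscape_undefined_error",
            "slide '%s': peritumoral band is empty", map@slideId)
  }
  frac <- sum(band & map@lymph) / nBand
  gradeStrength(frac, cfg@strengthCutoffs)
}

#' Score tertiary lymphoid aggregates beyond the peritumoral region
#'
#' Lymphocyte-positive components lying entirely outside the tumor and its
#' peritumoral band, with at least `aggregateMinCells` cells, qualify as
#' lymphoid aggregates; the score is 1 when at least
#' `aggregateMultifocalMin` (default 2, i.e. multifocal) such components
#' exist, else 0.
#'
#' @inheritParams scoreDeserts
#' @return integer 0 or 1.
#' @export
scoreAggregates <- function(map, cfg = morphologyConfig()) {
  stopifnot(is(map, "CompositeMap"), is(cfg, "MorphologyConfig"))
  checkTumor(map)
  inner <- map@tumor | peritumoralBand(map, cfg)   # tumor + band
  cc <- connectedComponents(map@lymph & !map@tumor, cfg@connectivity)
  if (!length(cc$sizes)) return(0L)
  ## a component qualifies only if none of its cells touches tumor or band;
  ## components of lymph outside tumor may still enter the band region
  k <- length(cc$sizes)
  touches <- logical(k)
  lab <- cc$labels
  hit <- lab[inner & lab > 0L]
  if (length(hit)) touches[unique(hit)] <- TRUE
  qual <- !touches & cc$sizes >= cfg@aggregateMinCells
  as.integer(sum(qual) >= cfg@aggregateMultifocalMin)
}

#' Score all five spatial features of a Tumor-TIL map
#'
#' Runs the five scorers (intratumoral strength, deserts, forests,
#' peritumoral strength, aggregates) and returns them as a
#' [FeatureScores-class].  Maps on which the rules are undefined (no tumor
#' region, or an empty peritumoral band) come back with `excluded = TRUE`
#' and the reason, rather than an error.
#'
#' @param map a [CompositeMap-class].
#' @param cfg a [MorphologyConfig-class].
#' @return a [FeatureScores-class].
#' @aliases scoreAll
#' @export
#' @examples
#' tum <- matrix(TRUE, 20, 20)
#' scoreAll(CompositeMap(tum, matrix(FALSE, 20, 20)))  # all-desert map
setMethod("scoreAll", "CompositeMap", function(map, cfg = morphologyConfig()) {
  res <- tryCatch(
    FeatureScores(
      intratumoralStrength = scoreIntratumoralStrength(map, cfg),
      deserts = scoreDeserts(map, cfg),
      forests = scoreForests(map, cfg),
      peritumoralStrength = scorePeritumoralStrength(map, cfg),
      aggregates = scoreAggregates(map, cfg)
    ),
    tilscape_undefined_error = function(e) {
      FeatureScores(excluded = TRUE, reason = conditionMessage(e))
    }
  )
  res
})

#' High-risk feature names
#'
#' The default active set excludes `aggregates_absent`, which was screened
#' out of high-risk scoring for low interrater agreement; it can be
#' re-activated explicitly or via [screenFeatures()].
#'
#' @return character vector of indicator names.
#' @export
highRiskFeatureNames <- function() {
  c("low_intratumoral", "deserts_present", "forests_absent",
    "low_peritumoral", "aggregates_absent")
}

#' Map feature scores to high-risk indicators and risk group
#'
#' High-risk indicators fire for low intratumoral strength (score 0 or 1),
#' presence of deserts (1), absence of forests (0), low peritumoral
#' strength (0 or 1), and -- when active -- absence of aggregates (0).
#' The patient is high-risk when two or more active indicators fire.
#'
#' @param scores a non-excluded [FeatureScores-class].
#' @param active character vector of active indicators (subset of
#'   [highRiskFeatureNames()]); the default omits `aggregates_absent`.
#' @return a [HighRiskProfile-class].
#' @export
#' @examples
#' s <- FeatureScores(1, 1, 0, 1, 1)
#' highRiskProfile(s)   # 4 indicators, high-risk
highRiskProfile <- function(scores,
                            active = setdiff(highRiskFeatureNames(),
                                             "aggregates_absent")) {
  stopifnot(is(scores, "FeatureScores"))
  if (isTRUE(scores@excluded)) {
    tlsStop("tilscape_undefined_error",
            "cannot derive a risk profile from excluded scores (%s)",
            scores@reason)
  }
  bad <- setdiff(active, highRiskFeatureNames())
  if (length(bad)) {
    tlsStop("tilscape_parameter_error",
            "unknown high-risk features: %s", paste(bad, collapse = ", "))
  }
  fired <- c(
    low_intratumoral = scores@intratumoralStrength <= 1L,
    deserts_present = scores@deserts == 1L,
    forests_absent = scores@forests == 0L,
    low_peritumoral = scores@peritumoralStrength <= 1L,
    aggregates_absent = scores@aggregates == 0L
  )
  ind <- intersect(names(fired)[fired], active)
  new("HighRiskProfile", indicators = ind, count = length(ind),
      group = if (length(ind) >= 2L) "high-risk" else "low-risk")
}

#' Score a batch of composite maps into a data.frame
#'
#' @param maps list of [CompositeMap-class] objects.
#' @param cfg a [MorphologyConfig-class].
#' @return data.frame with one row per map: slide_id, the five scores,
#'   `excluded` and `reason`.
#' @export
scoreSlides <- function(maps, cfg = morphologyConfig()) {
  rows <- lapply(maps, function(m) {
    df <- as.data.frame(scoreAll(m, cfg))
    cbind(slide_id = m@slideId, df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
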