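## run expr under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' PhenotypeSpec: recipe for a synthetic slide with a planted phenotype
#'
#' Describes one synthetic slide: the physical extent, the two model patch
#' sizes, the tumor geometry (a seeded union of discs), the spatial
#' phenotype to plant in the lymphocyte channel, and the probability noise
#' around the planted boolean pattern.  A spec is a pure description:
#' identical specs always generate identical output.
#'
#' @slot phenotype one of "cold", "diffuse", "forest", "desert",
#'   "peritumoral_ring", "distal_aggregates", "mixed".
#' @slot extentUm physical slide extent (square, micrometres).
#' @slot tumorPatchUm,lymphPatchUm model patch sizes (defaults 87.5 / 50).
#' @slot blobCount number of discs forming the tumor blob (>= 1).
#' @slot radiusRangeUm optional explicit main-disc radius range; when NA
#'   the radius is derived from `targetTumorFrac`.
#' @slot targetTumorFrac target tumor area as a fraction of the slide.
#' @slot diffuseFrac per-patch probability of planting a TIL patch inside
#'   the tumor for the diffuse component.
#' @slot desertFrac planted TIL-free disc area as a fraction of tumor area.
#' @slot forestFrac planted confluent TIL disc area as a fraction of
#'   tumor area.
#' @slot bandTilFrac per-patch TIL probability inside the peritumoral ring.
#' @slot ringWidthUm depth of the planted peritumoral ring.
#' @slot nAggregates number of planted distal lymphoid aggregates.
#' @slot aggregateRadiusUm radius of each planted aggregate.
#' @slot aggregateMarginUm minimum clearance between an aggregate and the
#'   tumor boundary.
#' @slot jitter probability-noise width; planted cells get beta-distributed
#'   probabilities concentrated near 0.9 (positives) / 0.1 (negatives),
#'   wider for larger jitter.
#' @slot seed integer seed fixing all randomness.
#' @exportClass PhenotypeSpec
setClass("PhenotypeSpec",
  representation(
    phenotype = "character",
    extentUm = "numeric",
    tumorPatchUm = "numeric",
    lymphPatchUm = "numeric",
    blobCount = "integer",
    radiusRangeUm = "numeric",
    targetTumorFrac = "numeric",
    diffuseFrac = "numeric",
    desertFrac = "numeric",
    forestFrac = "numeric",
    bandTilFrac = "numeric",
    ringWidthUm = "numeric",
    nAggregates = "integer",
    aggregateRadiusUm = "numeric",
    aggregateMarginUm = "numeric",
    jitter = "numeric",
    seed = "integer"
  )
)

setValidity("PhenotypeSpec", function(object) {
  phenos <- c("cold", "diffuse", "forest", "desert", "peritumoral_ring",
              "distal_aggregates", "mixed")
  if (!object@phenotype %in% phenos) {
    return(paste("phenotype must be one of:", paste(phenos, collapse = ", ")))
  }
  fr <- c(object@targetTumorFrac, object@diffuseFrac, object@desertFrac,
          object@forestFrac, object@bandTilFrac)
  if (any(fr < 0 | fr > 1)) return("area fractions must lie in [0, 1]")
  if (object@blobCount < 1L) return("blobCount must be >= 1")
  if (object@jitter <= 0 || object@jitter > 1) {
    return("jitter must lie in (0, 1]")
  }
  TRUE
})

#' Construct a PhenotypeSpec
#'
#' See [PhenotypeSpec-class] for the meaning of each field.  Defaults give
#' a 2100 um square slide (24 x 24 tumor patches at 87.5 um, 42 x 42
#' lymphocyte patches at 50 um, a 168 x 168 common lattice at 12.5 um),
#' a connected tumor blob covering about a third of the slide, and planted
#' fractions safely past the scoring thresholds: desert disc 30% of tumor
#' area (threshold 25%), forest disc 15% (threshold 10%).
#'
#' @param phenotype,extentUm,tumorPatchUm,lymphPatchUm,blobCount see
#'   [PhenotypeSpec-class].
#' @param radiusRangeUm,targetTumorFrac,diffuseFrac,desertFrac,forestFrac
#'   see [PhenotypeSpec-class].
#' @param bandTilFrac,ringWidthUm,nAggregates,aggregateRadiusUm see
#'   [PhenotypeSpec-class].
#' @param aggregateMarginUm,jitter,seed see [PhenotypeSpec-class].
#' @return a validated [PhenotypeSpec-class].
#' @export
#' @examples
#' phenotypeSpec("desert", seed = 7)
phenotypeSpec <- function(phenotype = "diffuse", extentUm = 2100,
                          tumorPatchUm = 87.5, lymphPatchUm = 50,
                          blobCount = 3, radiusRangeUm = NA_real_,
                          targetTumorFrac = 0.35, diffuseFrac = 0.25,
                          desertFrac = 0.30, forestFrac = 0.15,
                          bandTilFrac = 0.9, ringWidthUm = 100,
                          nAggregates = 3, aggregateRadiusUm = 75,
                          aggregateMarginUm = 150, jitter = 0.1, seed = 1) {
  new("PhenotypeSpec", phenotype = phenotype, extentUm = extentUm,
      tumorPatchUm = tumorPatchUm, lymphPatchUm = lymphPatchUm,
      blobCount = as.integer(blobCount),
      radiusRangeUm = as.numeric(radiusRangeUm),
      targetTumorFrac = targetTumorFrac, diffuseFrac = diffuseFrac,
      desertFrac = desertFrac, forestFrac = forestFrac,
      bandTilFrac = bandTilFrac, ringWidthUm = ringWidthUm,
      nAggregates = as.integer(nAggregates),
      aggregateRadiusUm = aggregateRadiusUm,
      aggregateMarginUm = aggregateMarginUm,
      jitter = jitter, seed = as.integer(seed))
}

## ---- disc geometry ------------------------------------------------------

## centers of an n-patch row at pitch s: (i - 0.5) * s
patchCenters <- function(extent, patch) {
  ((seq_len(floor(extent / patch + 1e-9))) - 0.5) * patch
}

## discs: data.frame(cx, cy, r).  membership of points (x, y)
inDiscs <- function(x, y, discs) {
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(discs))) {
    hit <- hit | ((x - discs$cx[i])^2 + (y - discs$cy[i])^2 <=
                    discs$r[i]^2)
  }
  hit
}

## signed-ish distance to a disc union (negative inside)
distToDiscs <- function(x, y, discs) {
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(discs))) {
    d <- pmin(d, sqrt((x - discs$cx[i])^2 + (y - discs$cy[i])^2) - discs$r[i])
  }
  d
}

## sample the tumor disc union for a spec; expects RNG already seeded
sampleTumorDiscs <- function(spec) {
  E <- spec@extentUm
  k <- spec@blobCount
  if (all(is.finite(spec@radiusRangeUm)) && length(spec@radiusRangeUm) == 2L) {
    rMain <- stats::runif(1, spec@radiusRangeUm[1], spec@radiusRangeUm[2])
  } else {
    ## one main disc plus (k - 1) half-exposed lobes of radius r/3;
    ## inflate target area accordingly so the union lands near target
    rMain <- sqrt(spec@targetTumorFrac * E^2 /
                    (pi * (1 + 0.5 * (k - 1) / 9)))
  }
  cx <- E / 2 + stats::runif(1, -0.04, 0.04) * E
  cy <- E / 2 + stats::runif(1, -0.04, 0.04) * E
  discs <- data.frame(cx = cx, cy = cy, r = rMain)
  for (i in seq_len(k - 1L)) {
    ang <- stats::runif(1, 0, 2 * pi)
    discs <- rbind(discs, data.frame(
      cx = cx + cos(ang) * rMain, cy = cy + sin(ang) * rMain, r = rMain / 3))
  }
  discs
}

## boolean grid at pitch `patch` from a disc union (by patch-center test)
discsToGrid <- function(discs, extent, patch, negate = FALSE) {
  cs <- patchCenters(extent, patch)
  X <- matrix(rep(cs, each = length(cs)), length(cs))         # column coords
  Y <- matrix(rep(cs, times = length(cs)), length(cs))        # row coords
  m <- matrix(inDiscs(as.vector(Y), as.vector(X), discs),
              length(cs), length(cs))
  ## row index i follows y (vertical), column j follows x
  m
}

#' Generate a synthetic tumor mask
#'
#' A connected tumor blob built as a seeded union of discs: one main disc
#' (radius derived from the target area fraction, or drawn from
#' `radiusRangeUm`) plus `blobCount - 1` boundary lobes.  A patch is tumor
#' when its center lies inside the union.
#'
#' @param spec a [PhenotypeSpec-class].
#' @return a [BinaryGrid-class] at `tumorPatchUm` pitch.
#' @export
#' @examples
#' g <- generateTumorMask(phenotypeSpec(seed = 3))
#' mean(gridValues(g))   # about the target tumor fraction
generateTumorMask <- function(spec) {
  stopifnot(is(spec, "PhenotypeSpec"))
  withSeed(spec@seed, {
    discs <- sampleTumorDiscs(spec)
    m <- discsToGrid(discs, spec@extentUm, spec@tumorPatchUm)
    if (!any(m)) {
      tlsStop("tilscape_validation_error",
              "tumor geometry produced an empty mask")
    }
    BinaryGrid(m, spec@tumorPatchUm, sprintf("synthetic-%d", spec@seed))
  })
}

## beta-noise probabilities around a boolean pattern; concentration
## shrinks as jitter grows, so larger jitter means more threshold flips
noisyProbs <- function(pattern, jitter) {
  conc <- 3 / jitter
  n <- length(pattern)
  p <- numeric(n)
  neg <- !pattern
  p[neg] <- stats::rbeta(sum(neg), 0.1 * conc, 0.9 * conc)
  p[!neg] <- stats::rbeta(sum(!neg), 0.9 * conc, 0.1 * conc)
  dim(p) <- dim(pattern)
  p
}

## plant the lymphocyte pattern for a phenotype; RNG already seeded.
## lymph patch (i, j) is tested at its center against disc geometry.
plantLymphPattern <- function(spec, tumorDiscs) {
  E <- spec@extentUm
  cs <- patchCenters(E, spec@lymphPatchUm)
  n <- length(cs)
  X <- as.vector(matrix(rep(cs, each = n), n))   # column (x) coord per cell
  Y <- as.vector(matrix(rep(cs, times = n), n))  # row (y) coord per cell
  inTum <- inDiscs(Y, X, tumorDiscs)
  dTum <- distToDiscs(Y, X, tumorDiscs)
  areaUm2 <- sum(inTum) * spec@lymphPatchUm^2
  pos <- rep(FALSE, n * n)

  addDiffuse <- function(pos, frac) {
    pos | (inTum & stats::runif(n * n) < frac)
  }
  addRing <- function(pos) {
    ring <- !inTum & dTum <= spec@ringWidthUm
    pos | (ring & stats::runif(n * n) < spec@bandTilFrac)
  }
  addAggregates <- function(pos) {
    placed <- 0L
    tries <- 0L
    aggDiscs <- NULL
    while (placed < spec@nAggregates && tries < 2000L) {
      tries <- tries + 1L
      px <- stats::runif(1, spec@aggregateRadiusUm,
                         E - spec@aggregateRadiusUm)
      py <- stats::runif(1, spec@aggregateRadiusUm,
                         E - spec@aggregateRadiusUm)
      if (distToDiscs(py, px, tumorDiscs) <
            spec@aggregateMarginUm + spec@aggregateRadiusUm) next
      if (!is.null(aggDiscs) &&
          any(sqrt((aggDiscs$cx - px)^2 + (aggDiscs$cy - py)^2) <
                2.5 * spec@aggregateRadiusUm)) next
      aggDiscs <- rbind(aggDiscs, data.frame(cx = px, cy = py,
                                             r = spec@aggregateRadiusUm))
      placed <- placed + 1L
    }
    if (placed < spec@nAggregates) {
      tlsStop("tilscape_parameter_error",
              "could not place %d aggregates clear of the tumor; %s",
              spec@nAggregates, "reduce nAggregates or the tumor fraction")
    }
    pos | (inDiscs(Y, X, aggDiscs) & !inTum)
  }

  switch(spec@phenotype,
    cold = NULL,
    diffuse = pos <- addDiffuse(pos, spec@diffuseFrac),
    forest = {
      rF <- sqrt(spec@forestFrac * areaUm2 / pi)
      ctr <- tumorDiscs[1L, ]
      off <- max(0, (ctr$r - rF)) * 0.5
      ang <- stats::runif(1, 0, 2 * pi)
      fd <- data.frame(cx = ctr$cx + cos(ang) * off,
                       cy = ctr$cy + sin(ang) * off, r = rF)
      pos <- pos | (inTum & inDiscs(Y, X, fd))
    },
    desert = {
      if (spec@desertFrac > 1) {
        tlsStop("tilscape_parameter_error", "desertFrac exceeds tumor area")
      }
      rD <- sqrt(spec@desertFrac * areaUm2 / pi)
      ctr <- tumorDiscs[1L, ]
      off <- max(0, (ctr$r - rD)) * 0.4
      ang <- stats::runif(1, 0, 2 * pi)
      dd <- data.frame(cx = ctr$cx + cos(ang) * off,
                       cy = ctr$cy + sin(ang) * off, r = rD)
      ## an immune-cold disc inside an otherwise diffusely infiltrated
      ## tumor (deserts accompany modest, not saturated, infiltration)
      pos <- inTum & !inDiscs(Y, X, dd) &
        stats::runif(n * n) < spec@diffuseFrac
    },
    peritumoral_ring = pos <- addRing(pos),
    distal_aggregates = pos <- addAggregates(pos),
    mixed = {
      pos <- addDiffuse(pos, spec@diffuseFrac)
      pos <- addRing(pos)
      pos <- addAggregates(pos)
    }
  )
  matrix(pos, n, n)
}

#' Plant a spatial phenotype in a pair of synthetic heatmaps
#'
#' Generates a tumor-model heatmap and a lymphocyte-model heatmap whose
#' binarization at 0.5 reproduces a planted boolean pattern carrying the
#' requested spatial phenotype, plus the ground-truth feature scores of
#' that planted pattern.  Probabilities are beta-distributed around 0.9
#' (planted positives) and 0.1 (negatives); at the default jitter the
#' chance of a threshold flip is negligible, and it grows as `jitter`
#' grows.  Ground truth is computed by scoring the noiseless planted
#' pattern with the configured rules, so truth for the graded strengths is
#' defined relative to the same grading ladder the scorer uses.
#'
#' @param spec a [PhenotypeSpec-class].
#' @param cfg [MorphologyConfig-class] used to compute the ground truth.
#' @return list with `tumor` and `lymph` ([HeatmapGrid-class] at the two
#'   model pitches), `tumorMask`/`lymphMask` (the planted
#'   [BinaryGrid-class] patterns), `truth` (a [FeatureScores-class]), and
#'   `truthInfiltration` (percent infiltration of the planted pattern).
#' @export
#' @examples
#' out <- plantPhenotype(phenotypeSpec("forest", seed = 11))
#' out$truth
plantPhenotype <- function(spec, cfg = morphologyConfig()) {
  stopifnot(is(spec, "PhenotypeSpec"))
  withSeed(spec@seed, {
    discs <- sampleTumorDiscs(spec)
    tumorPat <- discsToGrid(discs, spec@extentUm, spec@tumorPatchUm)
    if (!any(tumorPat)) {
      tlsStop("tilscape_validation_error",
              "tumor geometry produced an empty mask")
    }
    lymphPat <- plantLymphPattern(spec, discs)
    id <- sprintf("synthetic-%d", spec@seed)
    tumorMask <- BinaryGrid(tumorPat, spec@tumorPatchUm, id)
    lymphMask <- BinaryGrid(lymphPat, spec@lymphPatchUm, id)
    pair <- resampleToCommonLattice(tumorMask, lymphMask)
    cmap <- composeMap(pair)
    truth <- scoreAll(cmap, cfg)
    truthInf <- percentInfiltration(cmap)@percentInfiltration
    tumorHm <- HeatmapGrid(noisyProbs(tumorPat, spec@jitter),
                           spec@tumorPatchUm, id)
    lymphHm <- HeatmapGrid(noisyProbs(lymphPat, spec@jitter),
                           spec@lymphPatchUm, id)
    list(tumor = tumorHm, lymph = lymphHm,
         tumorMask = tumorMask, lymphMask = lymphMask,
         truth = truth, truthInfiltration = truthInf)
  })
}

## score range per feature (for adjacent-category rater errors)
featureMaxScore <- c(intratumoral_strength = 3L, deserts = 1L, forests = 1L,
                     peritumoral_strength = 3L, aggregates = 1L)

#' Simulate a panel of imperfect raters
#'
#' Each rater reports the true score with probability `1 - epsilon` and
#' otherwise a uniformly drawn adjacent category (for binary features, the
#' other category; for ordinal features, one step up or down within
#' range).  Deterministic per seed.
#'
#' @param truth a [FeatureScores-class], or a data.frame with `slide_id`
#'   and the five feature columns.
#' @param errorRates named per-feature error probabilities; unnamed single
#'   value applies to all features.
#' @param nRaters number of raters (the study used 3).
#' @param seed integer seed.
#' @return long data.frame `{slide_id, rater_id, feature, score}` suitable
#'   for [consensusMedian()] and [kappaReport()].
#' @export
#' @examples
#' truth <- data.frame(slide_id = "s1", intratumoral_strength = 2,
#'                     deserts = 0, forests = 1, peritumoral_strength = 3,
#'                     aggregates = 1)
#' simulateRaters(truth, errorRates = 0, seed = 1)   # all raters = truth
simulateRaters <- function(truth, errorRates = 0.1, nRaters = 3, seed = 1) {
  if (is(truth, "FeatureScores")) {
    truth <- cbind(slide_id = "slide", as.data.frame(truth))
  }
  feats <- spatialFeatureNames()
  stopifnot(all(c("slide_id", feats) %in% names(truth)))
  if (is.null(names(errorRates))) {
    errorRates <- stats::setNames(rep(errorRates[1L], length(feats)), feats)
  } else {
    ## named rates: unnamed features default to error-free raters
    full <- stats::setNames(rep(0, length(feats)), feats)
    full[intersect(names(errorRates), feats)] <-
      errorRates[intersect(names(errorRates), feats)]
    errorRates <- full
  }
  if (any(errorRates < 0 | errorRates > 1)) {
    tlsStop("tilscape_parameter_error", "error rates must lie in [0, 1]")
  }
  withSeed(seed, {
    rows <- vector("list", nrow(truth) * nRaters * length(feats))
    k <- 0L
    for (i in seq_len(nrow(truth))) {
      for (f in feats) {
        tv <- truth[[f]][i]
        hi <- featureMaxScore[[f]]
        for (r in seq_len(nRaters)) {
          sc <- tv
          if (!is.na(tv) && stats::runif(1) < errorRates[[f]]) {
            adj <- intersect(c(tv - 1L, tv + 1L), 0:hi)
            sc <- if (length(adj) == 1L) adj else sample(adj, 1L)
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            slide_id = truth$slide_id[i], rater_id = sprintf("rater%d", r),
            feature = f, score = as.integer(sc), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows[seq_len(k)])
  })
}

#' CohortSpec: recipe for a synthetic patient cohort
#'
#' Parameters of a cohort with exponential progression-free-interval event
#' times under a proportional-hazards structure: a baseline daily rate,
#' log-hazard coefficients for the planted covariates, and uniform
#' censoring over a follow-up window.  Categorical covariates are drawn
#' from the supplied probabilities.
#'
#' @slot n number of patients (>= 2).
#' @slot pam50Probs,erProbs,stageProbs named category probabilities
#'   (each summing to 1).
#' @slot baselineRate baseline exponential event rate per day (> 0).
#' @slot coefs named log-hazard coefficients; recognized names are
#'   `high_risk` (indicator of the high-risk group) and `til_per_sd`
#'   (percent infiltration scaled by its cohort SD).
#' @slot censorDays censoring window: censoring times are uniform on
#'   (0, censorDays\].
#' @slot seed integer seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    n = "integer",
    pam50Probs = "numeric",
    erProbs = "numeric",
    stageProbs = "numeric",
    baselineRate = "numeric",
    coefs = "numeric",
    censorDays = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  if (object@n < 2L) return("n must be >= 2")
  for (p in list(object@pam50Probs, object@erProbs, object@stageProbs)) {
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      return("category probabilities must be named, non-negative, sum to 1")
    }
  }
  if (object@baselineRate <= 0) return("baselineRate must be > 0")
  if (object@censorDays <= 0) return("censorDays must be > 0")
  bad <- setdiff(names(object@coefs), c("high_risk", "til_per_sd"))
  if (length(bad)) {
    return(paste("unknown coefficient name(s):", paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a CohortSpec
#'
#' Default category probabilities follow the composition of a large
#' breast-cancer cohort (PAM50 roughly 18% Basal / 8% Her2 / 52% LumA /
#' 22% LumB; 22% ER-negative; stages 27/53/17/3%).  The default baseline
#' rate (1/2500 per day) with a 2000-day censoring window yields roughly
#' 40% observed events, matching a progression-free-interval study at
#' desk scale.
#'
#' @param n,baselineRate,coefs,censorDays,seed see [CohortSpec-class].
#' @param pam50Probs,erProbs,stageProbs named probabilities per factor.
#' @return a validated [CohortSpec-class].
#' @export
cohortSpec <- function(n = 400,
                       pam50Probs = c(Basal = 0.18, Her2 = 0.08,
                                      LumA = 0.52, LumB = 0.22),
                       erProbs = c(Negative = 0.22, Positive = 0.78),
                       stageProbs = c(I = 0.27, II = 0.53, III = 0.17,
                                      IV = 0.03),
                       baselineRate = 1 / 2500,
                       coefs = c(high_risk = log(2)),
                       censorDays = 2000, seed = 1) {
  new("CohortSpec", n = as.integer(n), pam50Probs = pam50Probs,
      erProbs = erProbs, stageProbs = stageProbs,
      baselineRate = baselineRate, coefs = coefs,
      censorDays = censorDays, seed = as.integer(seed))
}

#' Simulate a patient cohort with planted hazards
#'
#' Draws molecular subtype, ER status and stage from the spec's category
#' probabilities, attaches (or generates) per-patient risk covariates, and
#' simulates day-resolution progression-free-interval outcomes: event
#' times are exponential with rate `baselineRate * exp(linear predictor)`,
#' censoring is uniform on the follow-up window, and `event = 0` when
#' censoring precedes the event.
#'
#' When `covariates` does not supply `percent_infiltration`, it is drawn
#' from a zero-inflated lognormal resembling computed TIL infiltration
#' (median near 3.5%, long right tail); when it does not supply
#' `risk_group`, patients are split "high-risk"/"low-risk" with
#' probability `highRiskProb`.
#'
#' @param spec a [CohortSpec-class].
#' @param covariates optional data.frame with `risk_group` and/or
#'   `percent_infiltration` per patient (recycled checks apply).
#' @param highRiskProb probability of the high-risk group when generated.
#' @return data.frame of patient records: `patient_id`, `pfi_days`,
#'   `event`, `pam50`, `er_status`, `stage`, `percent_infiltration`,
#'   `risk_group`.
#' @export
#' @examples
#' head(simulateCohort(cohortSpec(n = 10, seed = 2)))
simulateCohort <- function(spec, covariates = NULL, highRiskProb = 0.4) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@n
  if (!is.null(covariates) && nrow(covariates) != n) {
    tlsStop("tilscape_parameter_error",
            "covariates must have one row per patient (%d)", n)
  }
  withSeed(spec@seed, {
    d <- data.frame(
      patient_id = sprintf("pt%04d", seq_len(n)),
      pam50 = sample(names(spec@pam50Probs), n, TRUE, spec@pam50Probs),
      er_status = sample(names(spec@erProbs), n, TRUE, spec@erProbs),
      stage = sample(names(spec@stageProbs), n, TRUE, spec@stageProbs),
      stringsAsFactors = FALSE
    )
    d$percent_infiltration <- if (!is.null(covariates) &&
                                  "percent_infiltration" %in% names(covariates)) {
      covariates$percent_infiltration
    } else {
      pmin(ifelse(stats::runif(n) < 0.1, 0,
                  stats::rlnorm(n, meanlog = log(3.5), sdlog = 1.1)), 90)
    }
    d$risk_group <- if (!is.null(covariates) &&
                        "risk_group" %in% names(covariates)) {
      covariates$risk_group
    } else {
      ifelse(stats::runif(n) < highRiskProb, "high-risk", "low-risk")
    }
    lp <- rep(0, n)
    if ("high_risk" %in% names(spec@coefs)) {
      lp <- lp + spec@coefs[["high_risk"]] * (d$risk_group == "high-risk")
    }
    if ("til_per_sd" %in% names(spec@coefs)) {
      sdI <- stats::sd(d$percent_infiltration)
      if (isTRUE(sdI > 0)) {
        lp <- lp + spec@coefs[["til_per_sd"]] * d$percent_infiltration / sdI
      }
    }
    tEvent <- stats::rexp(n, rate = spec@baselineRate * exp(lp))
    tCens <- stats::runif(n, 0, spec@censorDays)
    d$event <- as.integer(tEvent <= tCens)
    d$pfi_days <- pmax(1, ceiling(pmin(tEvent, tCens)))   # day resolution
    if (sum(d$event) == 0L) {
      warning("simulated cohort contains no events")
    }
    d[c("patient_id", "pfi_days", "event", "pam50", "er_status", "stage",
        "percent_infiltration", "risk_group")]
  })
}
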