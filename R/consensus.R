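#' Spatial feature names scored by raters
#' @return character vector of the five feature column names.
#' @export
spatialFeatureNames <- function() {
  c("intratumoral_strength", "deserts", "forests",
    "peritumoral_strength", "aggregates")
}

## ordinal median: for an even number of raters take the lower middle
## value, so the consensus stays inside the ordinal score domain
ordinalMedian <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1L) / 2L)]
}

#' Median consensus of a multi-rater score panel
#'
#' For every slide and feature, the consensus score is the median of the
#' individual raters' scores (with an even rater count, the lower middle
#' value, keeping the result ordinal).  Slides rated by fewer than two
#' raters are excluded with a reason.
#'
#' @param panel long data.frame with columns `slide_id`, `rater_id`,
#'   `feature`, `score`; each (slide, rater, feature) at most once.
#' @return wide data.frame of consensus scores, one row per retained
#'   slide, columns `slide_id` + feature names; excluded slides are in
#'   `attr(, "excluded")` as a data.frame `{slide_id, reason}`.
#' @export
#' @examples
#' panel <- expand.grid(slide_id = "s1", rater_id = c("r1", "r2", "r3"),
#'                      feature = "deserts", stringsAsFactors = FALSE)
#' panel$score <- c(0, 0, 1)
#' consensusMedian(panel)   # deserts consensus 0
consensusMedian <- function(panel) {
  need <- c("slide_id", "rater_id", "feature", "score")
  if (!all(need %in% names(panel))) {
    tlsStop("tilscape_validation_error",
            "panel must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(panel[c("slide_id", "rater_id", "feature")])) {
    tlsStop("tilscape_validation_error",
            "duplicate (slide, rater, feature) rows in panel")
  }
  slides <- unique(panel$slide_id)
  nRaters <- vapply(slides, function(s) {
    length(unique(panel$rater_id[panel$slide_id == s]))
  }, integer(1))
  drop <- slides[nRaters < 2L]
  keep <- setdiff(slides, drop)
  feats <- unique(as.character(panel$feature))
  out <- data.frame(slide_id = keep, stringsAsFactors = FALSE)
  for (f in feats) {
    out[[f]] <- vapply(keep, function(s) {
      sc <- panel$score[panel$slide_id == s & panel$feature == f]
      if (!length(sc)) NA_integer_ else as.integer(ordinalMedian(sc))
    }, integer(1))
  }
  attr(out, "excluded") <- data.frame(
    slide_id = drop,
    reason = rep("fewer than 2 raters", length(drop)),
    stringsAsFactors = FALSE
  )
  out
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for n raters assigning one of k categories to
#' each of N subjects: `kappa = (Pbar - Pe) / (1 - Pe)`, where `Pbar` is
#' the mean per-subject pairwise agreement and `Pe` the expected agreement
#' from the marginal category frequencies.  When every rating falls in a
#' single category `Pe = 1` and the statistic is degenerate; kappa is then
#' reported as 1 with attribute `degenerate = TRUE`.
#'
#' @param counts N x k matrix of category counts; every row must sum to
#'   the same number of raters n >= 2.
#' @return kappa (<= 1), with attribute `degenerate`.
#' @export
#' @examples
#' m <- matrix(c(3, 0, 0, 3, 3, 0), ncol = 2, byrow = TRUE)
#' fleissKappa(m)   # perfect agreement: 1
fleissKappa <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) {
    tlsStop("tilscape_validation_error", "counts must be non-negative")
  }
  n <- sum(counts[1L, ])
  if (n < 2L || any(abs(rowSums(counts) - n) > 1e-9)) {
    tlsStop("tilscape_validation_error",
            "every subject must be rated by the same number (>= 2) of raters")
  }
  N <- nrow(counts)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  if (1 - Pe < 1e-12) {
    return(structure(1, degenerate = TRUE))
  }
  structure((Pbar - Pe) / (1 - Pe), degenerate = FALSE)
}

## long rating panel -> slide x category count matrix for one feature,
## keeping only slides rated by exactly the modal rater count
ratingsToCounts <- function(panel, feature, categories = NULL) {
  sub <- panel[panel$feature == feature & !is.na(panel$score), , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  if (is.null(categories)) categories <- sort(unique(sub$score))
  tab <- table(factor(sub$slide_id),
               factor(sub$score, levels = categories))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  nR <- rowSums(m)
  nMode <- as.integer(names(sort(table(nR), decreasing = TRUE))[1L])
  m[nR == nMode, , drop = FALSE]
}

#' Interrater agreement report for a rating panel
#'
#' Computes Fleiss' kappa per feature from a long multi-rater panel.
#' Unscored slides (missing scores) are dropped per feature, not imputed;
#' slides whose rater count differs from the panel's modal count are
#' likewise dropped so rows stay balanced.
#'
#' @param panel long data.frame `{slide_id, rater_id, feature, score}`.
#' @param features features to assess (default: all present).
#' @param cutoff kappa below which a feature is flagged as not included.
#' @return data.frame `{feature, kappa, n_slides, n_raters, included}`.
#' @export
kappaReport <- function(panel, features = unique(as.character(panel$feature)),
                        cutoff = 0.5) {
  rows <- lapply(features, function(f) {
    m <- ratingsToCounts(panel, f)
    if (is.null(m) || nrow(m) < 2L) {
      return(data.frame(feature = f, kappa = NA_real_, n_slides = 0L,
                        n_raters = NA_integer_, included = FALSE))
    }
    k <- fleissKappa(m)
    data.frame(feature = f, kappa = as.numeric(k), n_slides = nrow(m),
               n_raters = as.integer(sum(m[1L, ])),
               included = as.numeric(k) >= cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen features by interrater agreement
#'
#' Features whose kappa falls below the cutoff (default 0.5, below which
#' agreement is unacceptable for downstream analysis) are removed from the
#' active feature set used for high-risk scoring; a feature exactly at the
#' cutoff is retained.
#'
#' @param kappas data.frame from [kappaReport()] (columns `feature`,
#'   `kappa`), or a named numeric vector of kappas.
#' @param cutoff exclusion cutoff.
#' @return character vector of retained feature names.
#' @export
#' @examples
#' screenFeatures(c(deserts = 0.61, aggregates = 0.37))   # drops aggregates
screenFeatures <- function(kappas, cutoff = 0.5) {
  if (is.data.frame(kappas)) {
    k <- stats::setNames(kappas$kappa, kappas$feature)
  } else {
    k <- kappas
  }
  names(k)[!is.na(k) & k >= cutoff]
}

#' Translate feature names to high-risk indicator names
#'
#' Used to turn the output of [screenFeatures()] into the `active` set of
#' [highRiskProfile()].
#'
#' @param features character vector of feature names
#'   (see [spatialFeatureNames()]).
#' @return character vector of indicator names.
#' @export
indicatorsForFeatures <- function(features) {
  map <- c(intratumoral_strength = "low_intratumoral",
           deserts = "deserts_present",
           forests = "forests_absent",
           peritumoral_strength = "low_peritumoral",
           aggregates = "aggregates_absent")
  unname(map[intersect(features, names(map))])
}
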