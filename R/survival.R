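#' Select the TIL-sensitive validation subset of a cohort
#'
#' Keeps patients with negative estrogen receptor status by IHC and/or a
#' PAM50 molecular subtype of LumB or Her2.  Records missing both fields
#' cannot be classified and are dropped; their count is reported in a
#' message and in `attr(, "n_dropped_missing")`.
#'
#' @param records data.frame with columns `er_status`
#'   ("Negative"/"Positive"/NA) and `pam50`
#'   ("Basal"/"Her2"/"LumA"/"LumB"/NA).
#' @return the TIL-sensitive subset of `records`.
#' @export
#' @examples
#' df <- data.frame(er_status = c("Negative", "Positive", "Positive"),
#'                  pam50 = c("LumA", "LumB", "Basal"))
#' selectTilSensitive(df)   # rows 1 and 2
selectTilSensitive <- function(records) {
  stopifnot(all(c("er_status", "pam50") %in% names(records)))
  erNeg <- !is.na(records$er_status) & records$er_status == "Negative"
  subHit <- !is.na(records$pam50) & records$pam50 %in% c("LumB", "Her2")
  missingBoth <- is.na(records$er_status) & is.na(records$pam50)
  if (any(missingBoth)) {
    message(sum(missingBoth),
            " record(s) missing both ER status and PAM50 subtype dropped")
  }
  out <- records[(erNeg | subHit) & !missingBoth, , drop = FALSE]
  attr(out, "n_dropped_missing") <- sum(missingBoth)
  out
}

#' Stratify patients into high-/low-risk groups from feature scores
#'
#' Applies [highRiskProfile()] row-wise to a table of consensus feature
#' scores: patients with two or more active high-risk indicators are
#' "high-risk", the rest "low-risk".  Rows with excluded/missing scores
#' are dropped with a reason.
#'
#' @param scores data.frame with the five feature columns
#'   (see [spatialFeatureNames()]) and optionally `excluded`.
#' @param active active high-risk indicator set (default omits
#'   `aggregates_absent`).
#' @return `scores` for retained rows, with added columns
#'   `n_high_risk_features` and `risk_group`; dropped rows are recorded in
#'   `attr(, "dropped")`.
#' @export
stratifyRisk <- function(scores,
                         active = setdiff(highRiskFeatureNames(),
                                          "aggregates_absent")) {
  feats <- spatialFeatureNames()
  stopifnot(all(feats %in% names(scores)))
  excl <- if ("excluded" %in% names(scores)) {
    scores$excluded %in% TRUE
  } else {
    rep(FALSE, nrow(scores))
  }
  excl <- excl | Reduce(`|`, lapply(scores[feats], is.na))
  kept <- scores[!excl, , drop = FALSE]
  profs <- lapply(seq_len(nrow(kept)), function(i) {
    highRiskProfile(FeatureScores(
      intratumoralStrength = kept$intratumoral_strength[i],
      deserts = kept$deserts[i], forests = kept$forests[i],
      peritumoralStrength = kept$peritumoral_strength[i],
      aggregates = kept$aggregates[i]), active = active)
  })
  kept$n_high_risk_features <- vapply(profs, function(p) p@count, integer(1))
  kept$risk_group <- vapply(profs, function(p) p@group, character(1))
  attr(kept, "dropped") <- scores[excl, , drop = FALSE]
  kept
}

#' Kaplan-Meier estimate of progression-free interval per group
#'
#' Product-limit estimator with right censoring (`event = 0` censors at
#' `pfi_days`), one curve per level of `grouping`.
#'
#' @param records data.frame with `pfi_days` and `event` columns.
#' @param grouping vector of group labels, one per record (a single label
#'   gives one pooled curve).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (estimates start at 1 and are non-increasing).
#' @export
kmEstimate <- function(records, grouping = rep("all", nrow(records))) {
  stopifnot(all(c("pfi_days", "event") %in% names(records)))
  grouping <- as.character(grouping)
  empty <- setdiff(unique(grouping), grouping[!is.na(records$pfi_days)])
  if (length(empty)) warning("dropping empty group(s): ",
                             paste(empty, collapse = ", "))
  rows <- lapply(unique(grouping), function(g) {
    sub <- records[grouping == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    fit <- survival::survfit(
      survival::Surv(pfi_days, event) ~ 1, data = sub)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               surv = fit$surv, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Log-rank test across groups
#'
#' @param records data.frame with `pfi_days` and `event` columns.
#' @param grouping vector of group labels (at least two distinct groups
#'   with at least one event overall).
#' @return list with `statistic` (chi-square), `df`, and `p_value`.
#' @export
logrankTest <- function(records, grouping) {
  stopifnot(all(c("pfi_days", "event") %in% names(records)))
  grouping <- as.character(grouping)
  if (length(unique(grouping)) < 2L) {
    tlsStop("tilscape_parameter_error",
            "log-rank test needs at least two groups")
  }
  if (sum(records$event) < 1L) {
    tlsStop("tilscape_parameter_error",
            "log-rank test needs at least one event")
  }
  sd <- survival::survdiff(
    survival::Surv(pfi_days, event) ~ grp,
    data = cbind(records, grp = grouping))
  df <- length(sd$n) - 1L
  list(statistic = as.numeric(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' CoxFit: summary of a fitted proportional-hazards model
#'
#' @slot coefTable data.frame with one row per coefficient: `term`,
#'   `coef`, `hr`, `ci_lower`, `ci_upper`, `p_value`.
#' @slot concordance model concordance index in \[0, 1\].
#' @slot logLik maximized log partial likelihood.
#' @slot n,nEvents fitted sample size and event count.
#' @slot sdInfiltration cohort SD used to scale percent infiltration
#'   (NA when scaling was off or infiltration was not a covariate).
#' @slot fit the underlying [survival::coxph] fit.
#' @exportClass CoxFit
setClass("CoxFit",
  representation(
    coefTable = "data.frame",
    concordance = "numeric",
    logLik = "numeric",
    n = "integer",
    nEvents = "integer",
    sdInfiltration = "numeric",
    fit = "ANY"
  )
)

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit: n = %d, events = %d, concordance = %.3f\n",
              object@n, object@nEvents, object@concordance))
  tab <- object@coefTable
  tab$hr <- sprintf("%.3f [%.3f, %.3f]", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[c("term", "coef", "hr", "p_value")], row.names = FALSE)
})

#' Cox proportional-hazards fit of progression-free interval
#'
#' Maximizes the Cox partial likelihood over the requested covariates with
#' Efron tie handling by default (Breslow available for cross-checks).
#' Categorical covariates are expanded against declared reference levels
#' (PAM50 reference LumA, stage reference I).  When `scaleInfiltration`
#' is on and `percent_infiltration` is a covariate, it is divided by its
#' cohort standard deviation before fitting, so its hazard ratio is per
#' one SD of infiltration.  Rows with missing covariates are removed
#' listwise and their count messaged.  Confidence intervals are Wald on
#' the coefficient scale, exponentiated.
#'
#' @param records data.frame with `pfi_days`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties "efron" or "breslow".
#' @param scaleInfiltration divide `percent_infiltration` by its SD first.
#' @return a [CoxFit-class].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(pfi_days = rexp(80, 1 / 500), event = 1,
#'                 x = rbinom(80, 1, 0.5))
#' coxFit(d, "x")
coxFit <- function(records, covariates, ties = c("efron", "breslow"),
                   scaleInfiltration = TRUE) {
  ties <- match.arg(ties)
  stopifnot(all(c("pfi_days", "event") %in% names(records)),
            all(covariates %in% names(records)))
  d <- records[c("pfi_days", "event", covariates)]
  complete <- stats::complete.cases(d)
  if (any(!complete)) {
    message(sum(!complete), " record(s) with missing covariates dropped")
  }
  d <- d[complete, , drop = FALSE]
  if (sum(d$event) < 1L) {
    tlsStop("tilscape_parameter_error", "no events among complete records")
  }
  sdInf <- NA_real_
  if ("percent_infiltration" %in% covariates && scaleInfiltration) {
    sdInf <- stats::sd(d$percent_infiltration)
    if (!isTRUE(sdInf > 0)) {
      tlsStop("tilscape_parameter_error",
              "percent_infiltration has zero variance; cannot scale")
    }
    d$percent_infiltration <- d$percent_infiltration / sdInf
  }
  if ("pam50" %in% covariates) {
    d$pam50 <- stats::relevel(factor(d$pam50), ref = "LumA")
  }
  if ("stage" %in% covariates) {
    d$stage <- stats::relevel(factor(d$stage), ref = "I")
  }
  if ("risk_group" %in% covariates) {
    d$risk_group <- stats::relevel(factor(d$risk_group), ref = "low-risk")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(pfi_days, event) ~", paste(covariates, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep) warning("possible complete separation: a coefficient may be ",
                   "infinite; estimates reported as-is")
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    ci_lower = sm$conf.int[, "lower .95"],
    ci_upper = sm$conf.int[, "upper .95"],
    p_value = co[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  new("CoxFit", coefTable = tab,
      concordance = unname(sm$concordance["C"]),
      logLik = unname(fit$loglik[length(fit$loglik)]),
      n = as.integer(fit$n), nEvents = as.integer(fit$nevent),
      sdInfiltration = sdInf, fit = fit)
}

#' Concordance index of a risk score
#'
#' Fraction of comparable patient pairs in which the patient with the
#' higher risk score fails first; pairs tied on risk contribute 0.5.
#' A value of 1 means the score captures the full risk ordering; 0.5 is
#' random.  Computed with [survival::concordance] (risk direction:
#' larger score, earlier failure).
#'
#' @param records data.frame with `pfi_days` and `event`.
#' @param riskScores numeric vector, one score per record.
#' @return concordance in \[0, 1\].
#' @export
concordanceIndex <- function(records, riskScores) {
  stopifnot(all(c("pfi_days", "event") %in% names(records)),
            length(riskScores) == nrow(records))
  d <- data.frame(t = records$pfi_days, e = records$event, r = riskScores)
  cf <- survival::concordance(survival::Surv(t, e) ~ r, data = d,
                              reverse = TRUE)
  counts <- cf$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (comparable < 1) {
    tlsStop("tilscape_undefined_error",
            "no comparable pairs; concordance undefined")
  }
  unname(cf$concordance)
}

#' Significance markers for p-values
#'
#' `ordering = "published"` reproduces the study's printed legend
#' (*** = p < 0.001, ** = p < 0.05, * = p < 0.01) exactly as printed,
#' including its unusual ordering of the last two symbols;
#' `ordering = "corrected"` uses the conventional ladder
#' (*** < 0.001, ** < 0.01, * < 0.05).
#'
#' @param p numeric vector of p-values.
#' @param ordering "published" or "corrected".
#' @return character vector of markers ("" when not significant).
#' @export
pvalueMarkers <- function(p, ordering = c("published", "corrected")) {
  ordering <- match.arg(ordering)
  marker1 <- function(x) {
    if (is.na(x)) return("")
    if (x < 0.001) return("***")
    if (ordering == "published") {
      if (x < 0.01) return("*")
      if (x < 0.05) return("**")
    } else {
      if (x < 0.01) return("**")
      if (x < 0.05) return("*")
    }
    ""
  }
  vapply(p, marker1, character(1))
}
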