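test_that("TIL-sensitive selection keeps ER-negative and LumB/Her2", {
  df <- data.frame(
    er_status = c("Negative", "Positive", "Positive", "Positive", NA, NA),
    pam50 = c("LumA", "LumB", "Basal", "Her2", "LumB", NA))
  out <- suppressMessages(selectTilSensitive(df))
  expect_equal(rownames(out), c("1", "2", "4", "5"))
  expect_equal(attr(out, "n_dropped_missing"), 1L)
})

test_that("risk stratification applies the two-or-more rule row-wise", {
  scores <- data.frame(
    slide_id = c("a", "b", "c", "d"),
    intratumoral_strength = c(3L, 1L, 0L, NA),
    deserts = c(0L, 1L, 0L, 0L),
    forests = c(1L, 0L, 1L, 1L),
    peritumoral_strength = c(3L, 1L, 2L, 2L),
    aggregates = c(1L, 0L, 1L, 1L))
  out <- stratifyRisk(scores)
  expect_equal(out$risk_group, c("low-risk", "high-risk", "low-risk"))
  expect_equal(out$n_high_risk_features, c(0L, 4L, 1L))
  expect_equal(attr(out, "dropped")$slide_id, "d")

  # count boundaries: exactly 2 is high-risk
  s2 <- data.frame(slide_id = "x", intratumoral_strength = 1L, deserts = 1L,
                   forests = 1L, peritumoral_strength = 2L, aggregates = 1L)
  expect_equal(stratifyRisk(s2)$risk_group, "high-risk")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # no censoring: KM is the empirical survival fraction
  rec <- data.frame(pfi_days = c(10, 20, 30, 40, 50), event = 1)
  km <- kmEstimate(rec)
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_true(all(diff(km$surv) <= 0))

  # all censored: flat at 1
  recC <- data.frame(pfi_days = c(5, 10, 15), event = 0)
  expect_true(all(kmEstimate(recC)$surv == 1))

  # 10-record toy with mixed censoring vs the hand oracle
  toy <- data.frame(
    pfi_days = c(3, 5, 5, 8, 10, 12, 15, 18, 20, 25),
    event    = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0))
  km10 <- kmEstimate(toy)
  ref <- kmByHand(toy$pfi_days, toy$event)
  at <- km10$n_event > 0
  expect_equal(km10$surv[at], ref$surv[match(km10$time[at], ref$time)])
  # spot-check one step by explicit product: after t=8,
  # S = (9/10)(8/9)(6/7)
  expect_equal(ref$surv[ref$time == 8], (9 / 10) * (8 / 9) * (6 / 7))
})

test_that("log-rank statistic vanishes on identical groups and matches a
          2-sample hand computation", {
  base <- data.frame(pfi_days = c(5, 10, 15, 20), event = c(1, 1, 0, 1))
  dup <- rbind(base, base)
  lr <- logrankTest(dup, rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$df, 1L)

  # hand computation of observed - expected over event times
  d <- data.frame(pfi_days = c(2, 4, 6, 8, 10, 12), event = 1,
                  g = rep(c("a", "b"), 3))
  lr2 <- logrankTest(d, d$g)
  tev <- sort(d$pfi_days)
  O <- 0; E <- 0; V <- 0
  for (t in tev) {
    n <- sum(d$pfi_days >= t); n1 <- sum(d$pfi_days >= t & d$g == "a")
    dth <- sum(d$pfi_days == t)
    o1 <- sum(d$pfi_days == t & d$g == "a")
    O <- O + o1; E <- E + dth * n1 / n
    if (n > 1) V <- V + dth * (n1 / n) * (1 - n1 / n) * (n - dth) / (n - 1)
  }
  expect_equal(lr2$statistic, (O - E)^2 / V, tolerance = 1e-9)

  expect_error(logrankTest(base, rep("a", 4)),
               class = "tilscape_parameter_error")
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(202)
  rej <- 0L
  nRep <- 400
  for (r in seq_len(nRep)) {
    d <- data.frame(pfi_days = ceiling(rexp(100, 1 / 500)),
                    event = rbinom(100, 1, 0.7))
    p <- logrankTest(d, rep(c("a", "b"), 50))$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / nRep, 0.02)
  expect_lt(rej / nRep, 0.08)
})

test_that("Cox coefficient matches a brute-force partial-likelihood grid
          search on a no-ties toy", {
  toy <- data.frame(
    pfi_days = c(12, 25, 37, 49, 58, 66, 77, 89),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    x = c(1, 0, 1, 1, 0, 0, 1, 0))
  fit <- coxFit(toy, "x")
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, coxLogPartialLik, numeric(1),
               time = toy$pfi_days, event = toy$event, x = toy$x)
  expect_equal(fit@coefTable$coef, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit@coefTable$hr, exp(fit@coefTable$coef))
  # Wald CI brackets the estimate
  expect_lt(fit@coefTable$ci_lower, fit@coefTable$hr)
  expect_gt(fit@coefTable$ci_upper, fit@coefTable$hr)
})

test_that("SD scaling multiplies the infiltration coefficient without
          touching its p-value", {
  set.seed(13)
  d <- data.frame(pfi_days = ceiling(rexp(120, 1 / 400)),
                  event = rbinom(120, 1, 0.6),
                  percent_infiltration = pmin(rlnorm(120, 1.3, 1), 80))
  fScaled <- coxFit(d, "percent_infiltration", scaleInfiltration = TRUE)
  fRaw <- coxFit(d, "percent_infiltration", scaleInfiltration = FALSE)
  sdI <- sd(d$percent_infiltration)
  expect_equal(fScaled@sdInfiltration, sdI)
  expect_equal(fScaled@coefTable$coef, fRaw@coefTable$coef * sdI,
               tolerance = 1e-8)
  expect_equal(fScaled@coefTable$p_value, fRaw@coefTable$p_value,
               tolerance = 1e-8)
  expect_equal(fScaled@concordance, fRaw@concordance, tolerance = 1e-12)
})

test_that("multivariate fits expand factors against LumA / stage I
          references and drop incomplete rows", {
  d <- simulateCohort(cohortSpec(n = 300, seed = 8,
                                 coefs = c(til_per_sd = -0.3)))
  d$stage[1:5] <- NA
  expect_message(f <- coxFit(d, c("percent_infiltration", "pam50", "stage")),
                 "5 record")
  terms <- f@coefTable$term
  expect_false(any(grepl("LumA", terms)))
  expect_false(any(grepl("stageI$", terms)))
  expect_true(all(c("pam50Basal", "pam50Her2", "pam50LumB") %in% terms))
  expect_equal(f@n, 295L)
  expect_true(f@concordance >= 0 && f@concordance <= 1)
})

test_that("concordance matches exhaustive pair enumeration", {
  # risk identical to event order, no censoring -> 1
  d1 <- data.frame(pfi_days = c(10, 20, 30, 40), event = 1)
  expect_equal(concordanceIndex(d1, c(4, 3, 2, 1)), 1)

  # random scores at large n -> about 0.5
  set.seed(3)
  dn <- data.frame(pfi_days = ceiling(rexp(600, 1 / 300)), event = 1)
  expect_lt(abs(concordanceIndex(dn, runif(600)) - 0.5), 0.05)

  # 6-record toy with one censored record and a risk tie
  toy <- data.frame(pfi_days = c(5, 8, 8, 12, 20, 22),
                    event = c(1, 1, 0, 1, 0, 1))
  risk <- c(3.0, 2.5, 2.5, 1.0, 0.5, 0.2)
  expect_equal(concordanceIndex(toy, risk),
               concordanceByPairs(toy$pfi_days, toy$event, risk))

  # several random toys against the oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    tt <- sample(1:40, n)
    ev <- rbinom(n, 1, 0.7)
    rk <- round(runif(n), 1)            # coarse scores force ties
    if (sum(ev) == 0) next
    expect_equal(concordanceIndex(data.frame(pfi_days = tt, event = ev), rk),
                 concordanceByPairs(tt, ev, rk))
  }
})

test_that("pipeline results are invariant to patient ordering", {
  d <- simulateCohort(cohortSpec(n = 200, seed = 21))
  f1 <- coxFit(d, "risk_group")
  set.seed(99)
  d2 <- d[sample(nrow(d)), ]
  f2 <- coxFit(d2, "risk_group")
  expect_equal(f1@coefTable$coef, f2@coefTable$coef, tolerance = 1e-10)
  expect_equal(f1@concordance, f2@concordance, tolerance = 1e-10)
})

test_that("p-value markers reproduce the published legend and the
          corrected ladder", {
  p <- c(0.0005, 0.005, 0.03, 0.2, NA)
  expect_equal(pvalueMarkers(p, "published"), c("***", "*", "**", "", ""))
  expect_equal(pvalueMarkers(p, "corrected"), c("***", "**", "*", "", ""))
})
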