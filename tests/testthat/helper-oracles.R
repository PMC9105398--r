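# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no igraph, no survival::coxph) so agreement is evidence, not
# tautology.

# breadth-first flood fill over a logical matrix
floodFillComponents <- function(grid, connectivity = 4) {
  m <- nrow(grid); n <- ncol(grid)
  labels <- matrix(0L, m, n)
  nb <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
         c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  }
  lab <- 0L
  for (j in seq_len(n)) for (i in seq_len(m)) {
    if (!grid[i, j] || labels[i, j] > 0L) next
    lab <- lab + 1L
    queue <- list(c(i, j))
    labels[i, j] <- lab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in nb) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= m && c >= 1 && c <= n &&
            grid[r, c] && labels[r, c] == 0L) {
          labels[r, c] <- lab
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  list(labels = labels, sizes = as.integer(tabulate(labels)))
}

# note: floodFill assigns labels column by column; package labels go in
# first-linear-index order.  compare as partitions, not label values.
samePartition <- function(lab1, lab2) {
  if (!identical(dim(lab1), dim(lab2))) return(FALSE)
  if (!identical(lab1 > 0, lab2 > 0)) return(FALSE)
  on1 <- lab1[lab1 > 0]; on2 <- lab2[lab2 > 0]
  all(tapply(on2, on1, function(x) length(unique(x))) == 1L) &&
    all(tapply(on1, on2, function(x) length(unique(x))) == 1L)
}

# Fleiss' kappa evaluated element by element from the definition
fleissKappaByHand <- function(counts) {
  N <- nrow(counts); k <- ncol(counts); n <- sum(counts[1, ])
  P <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(k)) s <- s + counts[i, j] * (counts[i, j] - 1)
    P[i] <- s / (n * (n - 1))
  }
  pj <- numeric(k)
  for (j in seq_len(k)) pj[j] <- sum(counts[, j]) / (N * n)
  Pe <- sum(pj * pj)
  (mean(P) - Pe) / (1 - Pe)
}

# Cox log partial likelihood for a single covariate, no ties (Breslow and
# Efron coincide when event times are distinct)
coxLogPartialLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    atrisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atrisk])))
  }
  ll
}

# concordance by exhaustive pair enumeration: pair (i, j) is comparable
# when the earlier time is an event; ties in risk count 0.5
concordanceByPairs <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ti <- time[i]; tj <- time[j]
    if (ti == tj && event[i] && event[j]) next  # tied failure times unusable
    first <- if (ti < tj) i else if (tj < ti) j else NA
    if (is.na(first)) {
      # tied times, one censored: the event precedes the censoring
      first <- if (event[i]) i else if (event[j]) j else NA
    }
    if (is.na(first) || !event[first]) next
    other <- if (first == i) j else i
    den <- den + 1
    if (risk[first] > risk[other]) num <- num + 1
    else if (risk[first] == risk[other]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# product-limit estimate by hand at each distinct event time
kmByHand <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  tev <- sort(unique(time[event == 1]))
  surv <- numeric(length(tev))
  s <- 1
  for (k in seq_along(tev)) {
    at <- sum(time >= tev[k])
    d <- sum(time == tev[k] & event == 1)
    s <- s * (1 - d / at)
    surv[k] <- s
  }
  data.frame(time = tev, surv = surv)
}

# chebyshev-distance peritumoral band by direct per-cell minimization
bandByDistance <- function(tumor, width) {
  m <- nrow(tumor); n <- ncol(tumor)
  tr <- which(tumor, arr.ind = TRUE)
  out <- matrix(FALSE, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (tumor[i, j]) next
    d <- min(pmax(abs(tr[, 1] - i), abs(tr[, 2] - j)))
    out[i, j] <- d <= width
  }
  out
}

# nearest-source resampling by looping over fine cells and source
# rectangles (patch (i,j) covers the half-open square [(i-1)s, is))
resampleByRectangles <- function(values, patchUm, cellUm, nFine) {
  out <- matrix(NA, nFine[1], nFine[2])
  for (i in seq_len(nFine[1])) for (j in seq_len(nFine[2])) {
    cy <- (i - 0.5) * cellUm; cx <- (j - 0.5) * cellUm
    si <- NA; sj <- NA
    for (r in seq_len(nrow(values))) {
      if (cy >= (r - 1) * patchUm && cy < r * patchUm) si <- r
    }
    for (c in seq_len(ncol(values))) {
      if (cx >= (c - 1) * patchUm && cx < c * patchUm) sj <- c
    }
    out[i, j] <- if (is.na(si) || is.na(sj)) FALSE else values[si, sj]
  }
  out
}

# random logical matrix under a local seed
randomGrid <- function(nr, nc, p, seed) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

# all-tumor composite with a given lymph pattern
allTumorMap <- function(lymph, cellSizeUm = 12.5) {
  CompositeMap(matrix(TRUE, nrow(lymph), ncol(lymph)), lymph,
               cellSizeUm = cellSizeUm)
}
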