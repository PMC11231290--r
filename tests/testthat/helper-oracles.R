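# Independent oracles and fixture builders used across the suite.

# canonical key for a tricluster as index triple
tricKey <- function(I, J, K) {
  paste(paste(sort(I), collapse = ","), paste(sort(J), collapse = ","),
        paste(sort(K), collapse = ","), sep = "|")
}

solutionKeys <- function(sol, ds) {
  v <- values(ds)
  sort(vapply(triclusters(sol), function(t) tricKey(
    match(t@subjects, dimnames(v)[[1]]),
    match(t@features, dimnames(v)[[2]]),
    t@contexts), character(1)))
}

bruteKeys <- function(bf) {
  sort(vapply(bf, function(b) tricKey(b$I, b$J, b$K), character(1)))
}

randomCube <- function(dims, lo = 1, hi = 10) {
  threeWayDataset(array(stats::runif(prod(dims), lo, hi), dim = dims))
}

# double-loop ratio-coherence check, independent of the mining code path
coherentBlockOracle <- function(w, I, J, K, epsilon) {
  for (k in K) {
    for (a in seq_along(J)) {
      for (b in seq_along(J)) {
        if (b <= a) next
        r <- numeric(length(I))
        for (ii in seq_along(I)) r[ii] <- w[I[ii], J[b], k] / w[I[ii], J[a], k]
        if (max(r) > (1 + epsilon) * min(r)) return(FALSE)
      }
    }
  }
  TRUE
}

# textbook double-loop silhouette; singleton clusters contribute 0
silhouetteOracle <- function(m, labels) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

calinskiHarabaszOracle <- function(m, labels) {
  n <- nrow(m); k <- length(unique(labels))
  grand <- colMeans(m)
  bgss <- 0; wgss <- 0
  for (cl in unique(labels)) {
    rows <- m[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    bgss <- bgss + nrow(rows) * sum((cen - grand)^2)
    for (i in seq_len(nrow(rows))) wgss <- wgss + sum((rows[i, ] - cen)^2)
  }
  (bgss / (k - 1)) / (wgss / (n - k))
}

daviesBouldinOracle <- function(m, labels) {
  cls <- sort(unique(labels))
  k <- length(cls)
  cen <- lapply(cls, function(cl) colMeans(m[labels == cl, , drop = FALSE]))
  s <- vapply(seq_len(k), function(ci) {
    rows <- m[labels == cls[ci], , drop = FALSE]
    mean(vapply(seq_len(nrow(rows)), function(i)
      sqrt(sum((rows[i, ] - cen[[ci]])^2)), numeric(1)))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i)
    max(vapply(seq_len(k), function(j) {
      if (i == j) return(-Inf)
      (s[i] + s[j]) / sqrt(sum((cen[[i]] - cen[[j]])^2))
    }, numeric(1))), numeric(1)))
}

# hand product-limit estimator
kmOracle <- function(times, events, at) {
  ut <- sort(unique(times[events == 1]))
  surv <- 1
  for (t in ut[ut <= at]) {
    nrisk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    surv <- surv * (1 - d / nrisk)
  }
  surv
}

# long-format record list builder: one test with given items per visit
makeRecords <- function(pid, dates, itemsPerVisit, test = "ALSFRS-R") {
  lapply(seq_along(dates), function(v) {
    payload <- itemsPerVisit[[v]]
    names(payload) <- paste0("item", seq_along(payload))
    list(patient_id = pid, date = dates[v], test_name = test,
         payload = payload)
  })
}

smallCohortDataset <- function(n = 60, seed = 7) {
  coh <- generateCohort(n, seed = seed)
  snaps <- buildSnapshots(cohortToRecords(coh))
  list(cohort = coh,
       dataset = assembleThreeWay(featureTable(snaps),
                                  staticData = cohortStaticData(coh)))
}
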