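## Seeded generator of synthetic longitudinal cohorts with planted
## progression groups, irregular visit schedules (gamma-distributed gaps,
## mean ~3 months), item-level ALSFRS-R decline with noise, plateaus and
## occasional mild improvements, and per-group survival outcomes.

.domainOrder <- c("bulbar", "upper_limb", "lower_limb", "trunk", "respiratory")
.domainItems <- list(bulbar = 1:3, upper_limb = 4:5, lower_limb = 8:9,
                     trunk = 6:7, respiratory = 10:12)
.domainMax <- c(bulbar = 12, upper_limb = 8, lower_limb = 8, trunk = 8,
                respiratory = 12)

#' Default planted progression-group profiles
#'
#' Four profiles — SP (slow), MPb (moderate, mainly bulbar), MPs
#' (moderate, mainly spinal) and FP (fast) — ordered slow to fast in
#' total monthly decline, with MPb declining fastest in the bulbar domain
#' and MPs fastest in limbs/trunk among the moderates. Loaded from the
#' versioned YAML shipped with the package so tests pin one set of
#' numbers.
#'
#' @param path YAML file (default: the packaged \code{profiles.yaml}).
#' @return list with \code{profiles} (named list of group profiles) and
#'   generator-level settings (visit gap distribution, horizon).
#' @export
defaultProfiles <- function(path = system.file("extdata", "profiles.yaml",
                                               package = "clustric")) {
  cfg <- yaml::read_yaml(path)
  fr <- vapply(cfg$profiles, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("profile fractions must sum to 1")
  cfg
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## integer item scores for one domain from a continuous domain subscore
.allocateItems <- function(score, nItems) {
  total <- round(.clip(score, 0, 4 * nItems))
  q <- total %/% nItems
  r <- total %% nItems
  out <- rep(q, nItems)
  if (r > 0) out[seq_len(r)] <- out[seq_len(r)] + 1L
  out
}

.patientSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483587)
}

#' Generate a synthetic cohort with planted progression groups
#'
#' Each patient is assigned a group, a baseline per-domain score, and an
#' irregular visit schedule (gamma-distributed gaps with mean ~90 days).
#' Between visits each functional domain declines at the group's
#' points/month rate, with per-interval plateaus (no decline) and
#' occasional mild improvements, plus observation noise; domain scores
#' are allocated to the 12 ALSFRS-R items and clipped to 0-4. Survival
#' times are drawn from the group's exponential model, measured from the
#' first visit. A single master seed drives per-patient substreams, so
#' enlarging the cohort does not perturb existing patients.
#'
#' @param nPatients cohort size.
#' @param profiles profile configuration
#'   (see \code{\link{defaultProfiles}}).
#' @param nVisitsRange inclusive range of per-patient visit counts
#'   (default 3 to 7).
#' @param seed integer master seed.
#' @return object of class \code{"SyntheticCohort"}: a list with
#'   \code{records} (long data.frame: patient_id, date, test, item,
#'   value), \code{truth} (patient_id, group, survival_months, event),
#'   \code{parameters} and \code{seed}.
#' @export
generateCohort <- function(nPatients, profiles = defaultProfiles(),
                           nVisitsRange = c(3L, 7L), seed) {
  stopifnot(nPatients >= 1, length(nVisitsRange) == 2L,
            nVisitsRange[1L] >= 1L, nVisitsRange[1L] <= nVisitsRange[2L])
  if (missing(seed)) stop("a seed is required")
  pr <- profiles$profiles
  groups <- names(pr)
  fractions <- vapply(pr, `[[`, numeric(1), "fraction")
  gapShape <- profiles$visit_gap_gamma_shape %||% 4
  gapMean <- profiles$visit_gap_days_mean %||% 90
  horizon <- profiles$horizon_months %||% 96
  set.seed(seed)
  assigned <- sample(groups, nPatients, replace = TRUE, prob = fractions)
  recs <- vector("list", nPatients)
  truth <- vector("list", nPatients)
  ids <- sprintf("P%04d", seq_len(nPatients))
  for (i in seq_len(nPatients)) {
    set.seed(.patientSeed(seed, i))
    p <- pr[[assigned[i]]]
    nv <- sample(seq(nVisitsRange[1L], nVisitsRange[2L]), 1L)
    gaps <- pmax(1, round(stats::rgamma(max(nv - 1L, 0L), shape = gapShape,
                                        scale = gapMean / gapShape)))
    dates <- cumsum(c(0, gaps))
    latent <- .clip(stats::rnorm(5L,
                                 unlist(p$baseline_mean[.domainOrder]),
                                 unlist(p$baseline_sd[.domainOrder])),
                    0, .domainMax)
    names(latent) <- .domainOrder
    rates <- unlist(p$rates[.domainOrder])
    visitRows <- vector("list", nv)
    for (v in seq_len(nv)) {
      if (v > 1L) {
        gapMonths <- gaps[v - 1L] / 30.44
        for (d in .domainOrder) {
          u <- stats::runif(1)
          step <- if (u < p$plateau_prob) 0
                  else if (u < p$plateau_prob + p$improve_prob) -0.5
                  else rates[[d]] * gapMonths
          latent[d] <- .clip(latent[d] - step, 0, .domainMax[[d]])
        }
      }
      observed <- .clip(latent + stats::rnorm(5L, 0, p$noise_sd),
                        0, .domainMax)
      items <- numeric(12L)
      for (d in .domainOrder)
        items[.domainItems[[d]]] <-
          .allocateItems(observed[[d]], length(.domainItems[[d]]))
      visitRows[[v]] <- data.frame(
        patient_id = ids[i], date = dates[v], test = "ALSFRS-R",
        item = paste0("item", 1:12), value = items,
        stringsAsFactors = FALSE)
    }
    recs[[i]] <- do.call(rbind, visitRows)
    medianM <- p$survival$median_months
    tDeath <- stats::rexp(1L, rate = log(2) / medianM)
    censored <- stats::runif(1) < p$survival$censor_frac
    if (censored) {
      time <- stats::runif(1, 0, tDeath); event <- 0L
    } else if (tDeath > horizon) {
      time <- horizon; event <- 0L
    } else {
      time <- tDeath; event <- 1L
    }
    truth[[i]] <- data.frame(patient_id = ids[i], group = assigned[i],
                             survival_months = time, event = event,
                             stringsAsFactors = FALSE)
  }
  out <- list(records = do.call(rbind, recs),
              truth = do.call(rbind, truth),
              parameters = list(nPatients = nPatients,
                                nVisitsRange = as.integer(nVisitsRange),
                                profiles = profiles),
              seed = seed)
  class(out) <- "SyntheticCohort"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", x$parameters$nPatients, "patients,",
      nrow(x$records), "item rows, seed", x$seed, "\n")
  print(table(group = x$truth$group))
  invisible(x)
}

#' Convert a synthetic cohort to assessment records
#'
#' Emits the same record structure \code{\link{readLongRecords}} produces
#' from a long CSV, so a generated cohort round-trips through the full
#' pipeline.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @return list of assessment records.
#' @export
cohortToRecords <- function(cohort) {
  df <- cohort$records
  key <- paste(df$patient_id, df$date, df$test, sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- lapply(groups, function(ix) {
    payload <- df$value[ix]
    names(payload) <- df$item[ix]
    list(patient_id = df$patient_id[ix[1L]], date = as.numeric(df$date[ix[1L]]),
         test_name = df$test[ix[1L]], payload = payload)
  })
  names(out) <- NULL
  out
}

#' Static per-subject table of a synthetic cohort
#'
#' @param cohort a \code{SyntheticCohort}.
#' @return data.frame (row names = patient ids) with planted group,
#'   survival time (months from first visit) and event flag.
#' @export
cohortStaticData <- function(cohort) {
  df <- cohort$truth
  data.frame(group = df$group, survival_months = df$survival_months,
             event = df$event, row.names = df$patient_id,
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort's records and truth to CSV
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param recordsPath,truthPath output CSV paths.
#' @return \code{recordsPath}, invisibly.
#' @export
writeCohort <- function(cohort, recordsPath, truthPath = NULL) {
  utils::write.csv(cohort$records, recordsPath, row.names = FALSE)
  if (!is.null(truthPath))
    utils::write.csv(cohort$truth, truthPath, row.names = FALSE)
  invisible(recordsPath)
}
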