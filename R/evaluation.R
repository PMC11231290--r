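## Characterisation of discovered groups: per-group mean trajectories
## with 95% confidence bands and inter-appointment slopes, and survival
## validation (Kaplan-Meier curves, 2-year survival rates with Greenwood
## confidence intervals, log-rank tests).

#' Per-group trajectory summary
#'
#' For each (group, feature, appointment): the number of contributing
#' patients, the mean, and a normal-approximation 95% confidence
#' half-width (1.96 sd / sqrt(n)). For each consecutive appointment pair:
#' the average slope, in points per month when anchor dates are
#' available (mean inter-appointment gap), else points per appointment.
#' With \code{anchor = TRUE} an appointment-0 row holding each feature's
#' maximum score (stage 0 for MiToS) is prepended, standing in for the
#' intact score at symptom onset.
#'
#' @param features feature table (\code{\link{featureTable}}) or a
#'   \code{ThreeWayDataset}.
#' @param labels named vector of group labels (names = patient ids).
#' @param nAppointments appointments to summarise (default 5; cells with
#'   no patients are dropped, not an error).
#' @param anchor prepend the onset-anchor row (default FALSE).
#' @return list with data.frames \code{points} (group, feature,
#'   appointment, n, mean, ci_halfwidth) and \code{slopes} (group,
#'   feature, from, to, slope, unit).
#' @export
trajectorySummary <- function(features, labels, nAppointments = 5L,
                              anchor = FALSE) {
  if (is(features, "ThreeWayDataset")) {
    v <- values(features)
    ad <- anchorDates(features)
    long <- expand.grid(patient_id = dimnames(v)[[1L]],
                        feature = dimnames(v)[[2L]],
                        appointment = seq_len(dim(v)[3L]),
                        stringsAsFactors = FALSE)
    long$value <- as.vector(v)
    long$anchor_date <- if (!is.null(ad))
      ad[cbind(long$patient_id, long$appointment)] else NA_real_
    features <- long
  } else if (all(c("feature", "value") %in% names(features))) {
    # already long (patient_id, appointment, feature, value[, anchor_date])
    if (!"anchor_date" %in% names(features))
      features$anchor_date <- NA_real_
  } else {
    fn <- intersect(clustricFeatures(), names(features))
    long <- stats::reshape(
      features[, c("patient_id", "appointment", "anchor_date", fn)],
      direction = "long", varying = fn, v.names = "value",
      times = fn, timevar = "feature", idvar = c("patient_id", "appointment"))
    rownames(long) <- NULL
    features <- long
  }
  features <- features[features$appointment <= nAppointments &
                         features$patient_id %in% names(labels), ]
  features$group <- labels[features$patient_id]
  features <- features[!is.na(features$value), ]
  agg <- stats::aggregate(value ~ group + feature + appointment, features,
                          function(x) c(n = length(x), mean = mean(x),
                                        sd = stats::sd(x)))
  points <- data.frame(group = agg$group, feature = agg$feature,
                       appointment = agg$appointment,
                       n = agg$value[, "n"], mean = agg$value[, "mean"],
                       ci_halfwidth = 1.96 * ifelse(agg$value[, "n"] > 1,
                                                    agg$value[, "sd"], 0) /
                         sqrt(agg$value[, "n"]))
  points <- points[order(points$group, points$feature, points$appointment), ]
  rownames(points) <- NULL
  ## mean inter-appointment gaps in months, per group
  haveDates <- "anchor_date" %in% names(features) &&
    any(!is.na(features$anchor_date))
  gapMonths <- NULL
  if (haveDates) {
    pd <- unique(features[, c("patient_id", "appointment", "anchor_date",
                              "group")])
    pd <- pd[order(pd$patient_id, pd$appointment), ]
    gaps <- do.call(rbind, lapply(split(pd, pd$patient_id), function(d) {
      if (nrow(d) < 2L) return(NULL)
      data.frame(group = d$group[-1L], from = d$appointment[-nrow(d)],
                 gap = diff(d$anchor_date) / 30.44)
    }))
    if (!is.null(gaps))
      gapMonths <- stats::aggregate(gap ~ group + from, gaps, mean)
  }
  slopes <- list()
  for (g in unique(points$group)) for (f in unique(points$feature)) {
    sub <- points[points$group == g & points$feature == f, ]
    if (nrow(sub) < 2L) next
    for (r in seq_len(nrow(sub) - 1L)) {
      a <- sub$appointment[r]; b <- sub$appointment[r + 1L]
      if (b != a + 1L) next
      dmean <- sub$mean[r + 1L] - sub$mean[r]
      gm <- NA_real_
      if (!is.null(gapMonths)) {
        hit <- gapMonths$gap[gapMonths$group == g & gapMonths$from == a]
        if (length(hit)) gm <- hit[1L]
      }
      slopes[[length(slopes) + 1L]] <- data.frame(
        group = g, feature = f, from = a, to = b,
        slope = if (!is.na(gm) && gm > 0) dmean / gm else dmean,
        unit = if (!is.na(gm) && gm > 0) "points/month" else
          "points/appointment",
        stringsAsFactors = FALSE)
    }
  }
  slopes <- if (length(slopes)) do.call(rbind, slopes) else
    data.frame(group = character(), feature = character(), from = integer(),
               to = integer(), slope = numeric(), unit = character())
  if (anchor) {
    mx <- clustricFeatureMaxima()
    mx["MITOS"] <- 0 # intact staging at onset
    groupSizes <- table(labels)
    anchorRows <- do.call(rbind, lapply(names(groupSizes), function(g)
      data.frame(group = g, feature = names(mx), appointment = 0L,
                 n = as.integer(groupSizes[[g]]), mean = as.numeric(mx),
                 ci_halfwidth = 0, stringsAsFactors = FALSE)))
    keep <- anchorRows$feature %in% unique(points$feature)
    points <- rbind(anchorRows[keep, ], points)
    rownames(points) <- NULL
  }
  list(points = points, slopes = slopes)
}

#' Kaplan-Meier survival estimate with a 2-year rate
#'
#' Product-limit estimator with plain Greenwood 95% confidence limits
#' (clipped to [0, 1]); the 2-year survival rate is the step function
#' read at 24 months. Follow-up is administratively censored at
#' \code{horizonMonths}.
#'
#' @param times survival times in months (from first visit).
#' @param events event flags (1 = death observed, 0 = censored).
#' @param horizonMonths follow-up truncation (default 96 = 8 years).
#' @param rateAtMonths time at which the survival rate is read
#'   (default 24).
#' @return list with \code{curve} (data.frame: time, n_risk, n_event,
#'   n_censor, surv, lower, upper), \code{median_survival},
#'   \code{rate} (survival at \code{rateAtMonths}), \code{rate_ci}
#'   (Greenwood 95% CI) and \code{n}.
#' @export
kaplanMeier <- function(times, events, horizonMonths = 96,
                        rateAtMonths = 24) {
  if (length(times) == 0L) stop("no subjects")
  if (any(times < 0)) stop("negative survival time")
  over <- times > horizonMonths
  events <- ifelse(over, 0L, as.integer(events))
  times <- pmin(times, horizonMonths)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "plain")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv,
                      lower = pmax(fit$lower, 0), upper = pmin(fit$upper, 1))
  sm <- summary(fit, times = rateAtMonths, extend = TRUE)
  med <- unname(summary(fit)$table["median"])
  list(curve = curve, median_survival = med,
       rate = sm$surv,
       rate_ci = c(pmax(sm$lower, 0), pmin(sm$upper, 1)),
       n = length(times))
}

#' Log-rank test across survival groups
#'
#' Standard log-rank over pooled event times, plus the pairwise
#' comparison table (optionally Bonferroni-adjusted).
#'
#' @param times survival times in months.
#' @param events event flags.
#' @param groups group label per subject (>= 2 nonempty groups).
#' @param bonferroni adjust pairwise p-values (default TRUE).
#' @return list with \code{chisq}, \code{df}, \code{p} and
#'   \code{pairwise} (data.frame: group1, group2, chisq, p, p_adj).
#' @export
logRank <- function(times, events, groups, bonferroni = TRUE) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  sd1 <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  df <- length(sd1$n) - 1L
  p <- stats::pchisq(sd1$chisq, df, lower.tail = FALSE)
  gl <- sort(unique(groups))
  pairs <- utils::combn(gl, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- groups %in% pr
    sd2 <- survival::survdiff(
      survival::Surv(times[sel], as.integer(events)[sel]) ~ groups[sel])
    data.frame(group1 = pr[1L], group2 = pr[2L], chisq = sd2$chisq,
               p = stats::pchisq(sd2$chisq, 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- if (bonferroni) pmin(pw$p * nrow(pw), 1) else pw$p
  list(chisq = unname(sd1$chisq), df = df, p = unname(p), pairwise = pw)
}

#' Survival comparison of progression groups
#'
#' Runs \code{\link{kaplanMeier}} per group and the \code{\link{logRank}}
#' panel across groups.
#'
#' @param staticData data.frame with \code{survival_months} and
#'   \code{event} columns, row names = patient ids.
#' @param labels named group labels (cluster ids or aliases).
#' @param horizonMonths follow-up truncation (default 96).
#' @return list with \code{perGroup} (named list of Kaplan-Meier
#'   results), \code{logrank}, and \code{table} (data.frame: group, n,
#'   events, median_survival, two_year_rate with CI).
#' @export
survivalByGroup <- function(staticData, labels, horizonMonths = 96) {
  ids <- intersect(names(labels), rownames(staticData))
  if (!length(ids)) stop("labels and staticData share no patients")
  sd <- staticData[ids, , drop = FALSE]
  lab <- as.character(labels[ids])
  perGroup <- lapply(split(seq_along(ids), lab), function(ix)
    kaplanMeier(sd$survival_months[ix], sd$event[ix], horizonMonths))
  lr <- logRank(sd$survival_months, sd$event, lab)
  tab <- do.call(rbind, lapply(names(perGroup), function(g) {
    km <- perGroup[[g]]
    data.frame(group = g, n = km$n,
               events = sum(km$curve$n_event),
               median_survival = km$median_survival,
               two_year_rate = km$rate,
               two_year_lower = km$rate_ci[1L],
               two_year_upper = km$rate_ci[2L],
               stringsAsFactors = FALSE)
  }))
  list(perGroup = perGroup, logrank = lr, table = tab)
}
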