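## Reading long-format clinical records, aligning them into appointment
## snapshots, deriving the seven temporal features, and assembling the
## three-way (patient x feature x appointment) dataset.

#' The seven temporal feature names
#'
#' Feature order used throughout the package: ALSFRS-R total, bulbar,
#' upper-limb, lower-limb, trunk and respiratory subscores, and the MiToS
#' stage.
#'
#' @return character vector of length 7.
#' @export
clustricFeatures <- function() {
  c("ALSFRSR", "ALSFRSb", "ALSFRSsUL", "ALSFRSsLL", "ALSFRSsT",
    "ALSFRSr", "MITOS")
}

#' Feature types for the seven temporal features
#'
#' MiToS stage is categorical (its representative value in a virtual
#' pattern is a mode); the six functional scores are numeric.
#'
#' @return named character vector.
#' @export
clustricFeatureTypes <- function() {
  ft <- c(rep("numeric", 6L), "categorical")
  names(ft) <- clustricFeatures()
  ft
}

#' Upper bounds of the seven features (lower bounds are all 0)
#' @return named numeric vector.
#' @export
clustricFeatureMaxima <- function() {
  mx <- c(48, 12, 8, 8, 8, 12, 4)
  names(mx) <- clustricFeatures()
  mx
}

## ALSFRS-R item partition into functional domains
.itemPartition <- list(
  ALSFRSb   = 1:3,
  ALSFRSsUL = 4:5,
  ALSFRSsT  = 6:7,
  ALSFRSsLL = 8:9,
  ALSFRSr   = 10:12
)

.parseDays <- function(x) {
  # ISO-8601 dates or integer day offsets; all arithmetic in days
  num <- suppressWarnings(as.numeric(x))
  iso <- which(is.na(num) & !is.na(x) & nzchar(x))
  if (length(iso)) {
    d <- suppressWarnings(as.Date(as.character(x[iso]), format = "%Y-%m-%d"))
    num[iso] <- as.numeric(d)
  }
  num
}

#' Read long-format assessment records from a delimited text file
#'
#' Expects one row per measured item with columns for the patient id, the
#' assessment date (ISO-8601 or integer day offset), the test name, the
#' item name and the value; rows sharing (patient, date, test) are grouped
#' into one assessment record whose payload maps item names to values.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema named list mapping the roles \code{patient}, \code{date},
#'   \code{test}, \code{value} (and optionally \code{item}) to column
#'   names. When \code{item} is absent the payload holds a single value
#'   named after the test.
#' @param sep field separator (default \code{","}).
#' @return list of assessment records, each a list with
#'   \code{patient_id}, \code{date} (days, numeric), \code{test_name} and
#'   \code{payload} (named numeric). Rows that fail to parse are collected
#'   in the \code{"parseErrors"} attribute (a data.frame with row numbers)
#'   and reported as a warning, never silently dropped.
#' @export
readLongRecords <- function(path, schema = defaultSchema(), sep = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("patient", "date", "test", "value")
  miss <- needed[!vapply(needed, function(r) !is.null(schema[[r]]), logical(1))]
  if (length(miss))
    stop("schema is missing mandatory roles: ", paste(miss, collapse = ", "))
  cols <- unlist(schema[!vapply(schema, is.null, logical(1))])
  absent <- setdiff(cols, names(df))
  if (length(absent))
    stop("input lacks mapped columns: ", paste(absent, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- list()
    attr(out, "parseErrors") <- data.frame(row = integer(), message = character())
    return(out)
  }
  days <- .parseDays(df[[schema$date]])
  vals <- suppressWarnings(as.numeric(df[[schema$value]]))
  bad <- which(is.na(days) | is.na(vals))
  errors <- data.frame(
    row = bad,
    message = ifelse(is.na(days[bad]),
                     paste0("unparseable date: ", df[[schema$date]][bad]),
                     paste0("unparseable value: ", df[[schema$value]][bad])),
    stringsAsFactors = FALSE
  )
  keep <- setdiff(seq_len(nrow(df)), bad)
  df <- df[keep, , drop = FALSE]
  days <- days[keep]
  vals <- vals[keep]
  item <- if (!is.null(schema$item)) as.character(df[[schema$item]])
          else as.character(df[[schema$test]])
  key <- paste(df[[schema$patient]], days, df[[schema$test]], sep = "\r")
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  out <- lapply(groups, function(ix) {
    payload <- vals[ix]
    names(payload) <- item[ix]
    list(patient_id = as.character(df[[schema$patient]][ix[1L]]),
         date = days[ix[1L]],
         test_name = as.character(df[[schema$test]][ix[1L]]),
         payload = payload)
  })
  names(out) <- NULL
  attr(out, "parseErrors") <- errors
  if (nrow(errors))
    warning(nrow(errors), " row(s) failed to parse; see attr(, 'parseErrors')")
  out
}

#' Default column mapping for long-format records
#' @return named list of column roles.
#' @export
defaultSchema <- function() {
  list(patient = "patient_id", date = "date", test = "test",
       item = "item", value = "value")
}

#' Group a patient's records into appointment snapshots
#'
#' Constrained agglomerative (single-linkage on day distance) grouping:
#' nearest record groups are merged greedily, refusing any merge that
#' would stretch a snapshot past \code{windowDays} or place two records
#' of the same test in one snapshot (clinicians do not prescribe the same
#' test twice in one appointment). Snapshots are indexed chronologically
#' per patient starting at 1.
#'
#' @param records list of assessment records
#'   (see \code{\link{readLongRecords}}).
#' @param windowDays maximum day span of a snapshot (default 100).
#' @return list of snapshots, each a list with \code{patient_id},
#'   \code{index}, \code{records} (list) and \code{anchor_date} (earliest
#'   record date, days).
#' @export
buildSnapshots <- function(records, windowDays = 100) {
  stopifnot(windowDays > 0)
  if (length(records) == 0L) return(list())
  pid <- vapply(records, `[[`, character(1), "patient_id")
  out <- list()
  for (p in unique(pid)) {
    recs <- records[pid == p]
    groups <- lapply(seq_along(recs), function(i) i)
    repeat {
      best <- NULL
      bestDist <- Inf
      bestAnchor <- Inf
      for (a in seq_along(groups)) {
        for (b in seq_along(groups)) {
          if (b <= a) next
          ga <- groups[[a]]; gb <- groups[[b]]
          da <- vapply(recs[ga], `[[`, numeric(1), "date")
          db <- vapply(recs[gb], `[[`, numeric(1), "date")
          dlink <- min(abs(outer(da, db, "-")))
          span <- max(da, db) - min(da, db)
          tests <- vapply(recs[c(ga, gb)], `[[`, character(1), "test_name")
          if (span > windowDays || anyDuplicated(tests)) next
          anchor <- min(da, db)
          if (dlink < bestDist ||
              (dlink == bestDist && anchor < bestAnchor)) {
            best <- c(a, b); bestDist <- dlink; bestAnchor <- anchor
          }
        }
      }
      if (is.null(best)) break
      groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
      groups[[best[2L]]] <- NULL
    }
    anchors <- vapply(groups, function(g)
      min(vapply(recs[g], `[[`, numeric(1), "date")), numeric(1))
    ord <- order(anchors)
    snaps <- lapply(seq_along(ord), function(i) {
      g <- groups[[ord[i]]]
      list(patient_id = p, index = i, records = recs[g],
           anchor_date = anchors[ord[i]])
    })
    out <- c(out, snaps)
  }
  out
}

#' Default MiToS domain-loss rules
#'
#' A functional domain counts as lost when its ALSFRS-R item condition
#' holds; the MiToS stage is the number of lost domains (0-4). The table
#' is configurable so the staging map can be adjusted without code change.
#'
#' @return named list of rules; each rule has \code{op} ("any"/"all"),
#'   \code{items} (ALSFRS-R item numbers) and \code{thresholds}
#'   (domain lost when item value <= threshold).
#' @export
defaultMitosRules <- function() {
  list(
    movement      = list(op = "any", items = c(6L, 8L),  thresholds = c(1, 1)),
    swallowing    = list(op = "any", items = 3L,         thresholds = 1),
    communicating = list(op = "all", items = c(1L, 4L),  thresholds = c(1, 1)),
    breathing     = list(op = "any", items = c(10L, 12L), thresholds = c(1, 2))
  )
}

#' MiToS stage from the 12 ALSFRS-R items
#'
#' @param items numeric vector of the 12 item scores in item order.
#' @param rules domain-loss rules (see \code{\link{defaultMitosRules}}).
#' @return integer stage in 0..4.
#' @export
mitosStage <- function(items, rules = defaultMitosRules()) {
  stopifnot(length(items) == 12L)
  lost <- vapply(rules, function(r) {
    hit <- items[r$items] <= r$thresholds
    if (r$op == "any") any(hit) else all(hit)
  }, logical(1))
  sum(lost)
}

.extractItems <- function(payload) {
  # canonicalise payload names like "item7"/"7"/"Q7" to item numbers
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", names(payload))))
  if (any(is.na(n))) return(NULL)
  if (!setequal(n, 1:12)) return(NULL)
  items <- numeric(12L)
  items[n] <- as.numeric(payload)
  items
}

#' Derive the seven temporal features from one snapshot
#'
#' Requires an ALSFRS-R record with all 12 item scores; subscores follow
#' the standard item partition (bulbar 1-3, upper limb 4-5, trunk 6-7,
#' lower limb 8-9, respiratory 10-12), the total is the sum of all 12
#' items, and the MiToS stage counts lost functional domains.
#'
#' @param snapshot one snapshot from \code{\link{buildSnapshots}}.
#' @param testName name of the ALSFRS-R test in the records.
#' @param mitosRules MiToS domain-loss rules.
#' @return named numeric vector over \code{\link{clustricFeatures}()}, or
#'   all-\code{NA} when the snapshot has no complete ALSFRS-R record.
#' @export
deriveFeatures <- function(snapshot, testName = "ALSFRS-R",
                           mitosRules = defaultMitosRules()) {
  out <- rep(NA_real_, 7L)
  names(out) <- clustricFeatures()
  tests <- vapply(snapshot$records, `[[`, character(1), "test_name")
  hit <- which(tests == testName)
  if (length(hit) == 0L) return(out)
  items <- .extractItems(snapshot$records[[hit[1L]]]$payload)
  if (is.null(items) || anyNA(items)) return(out)
  if (any(items < 0 | items > 4))
    stop("ALSFRS-R item score outside 0-4 for patient ",
         snapshot$patient_id)
  out["ALSFRSR"] <- sum(items)
  for (sub in names(.itemPartition))
    out[sub] <- sum(items[.itemPartition[[sub]]])
  out["MITOS"] <- mitosStage(items, mitosRules)
  out
}

#' Feature table: one row per (patient, appointment)
#'
#' @param snapshots list of snapshots.
#' @param ... passed to \code{\link{deriveFeatures}}.
#' @return data.frame with \code{patient_id}, \code{appointment},
#'   \code{anchor_date} and the seven feature columns (NA when the
#'   snapshot lacks a complete ALSFRS-R record).
#' @export
featureTable <- function(snapshots, ...) {
  if (length(snapshots) == 0L) {
    out <- data.frame(patient_id = character(), appointment = integer(),
                      anchor_date = numeric())
    for (f in clustricFeatures()) out[[f]] <- numeric()
    return(out)
  }
  rows <- lapply(snapshots, function(s) {
    fv <- deriveFeatures(s, ...)
    c(list(patient_id = s$patient_id, appointment = s$index,
           anchor_date = s$anchor_date), as.list(fv))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Assemble the three-way dataset from derived features
#'
#' Takes each patient's first \code{nContexts} feature-complete
#' appointments; patients with fewer feature-complete appointments are
#' excluded and logged. Incomplete appointments (e.g. a missing ALSFRS-R
#' item) are skipped, not imputed.
#'
#' @param features feature table from \code{\link{featureTable}} (or a
#'   snapshot list, which is converted).
#' @param nContexts number of appointments retained per patient
#'   (default 3).
#' @param staticData optional per-subject data.frame (row names = patient
#'   ids), e.g. survival time and event flag; carried as metadata only.
#' @return a \code{\link{ThreeWayDataset-class}} object; the exclusion log
#'   is available via \code{exclusions()}.
#' @export
assembleThreeWay <- function(features, nContexts = 3, staticData = NULL) {
  if (nContexts < 1) stop("nContexts must be >= 1")
  if (is.list(features) && !is.data.frame(features))
    features <- featureTable(features)
  fn <- clustricFeatures()
  complete <- stats::complete.cases(features[, fn, drop = FALSE])
  excl <- list()
  keepRows <- list()
  for (p in unique(features$patient_id)) {
    ix <- which(features$patient_id == p & complete)
    ix <- ix[order(features$appointment[ix])]
    if (length(ix) < nContexts) {
      excl[[p]] <- sprintf("only %d feature-complete appointment(s), need %d",
                           length(ix), nContexts)
    } else {
      keepRows[[p]] <- ix[seq_len(nContexts)]
    }
  }
  pats <- names(keepRows) %||% character(0)
  vals <- array(NA_real_, dim = c(length(pats), length(fn), nContexts),
                dimnames = list(pats, fn, paste0("t", seq_len(nContexts))))
  dates <- matrix(NA_real_, length(pats), nContexts,
                  dimnames = list(pats, NULL))
  for (i in seq_along(pats)) {
    rows <- features[keepRows[[pats[i]]], , drop = FALSE]
    vals[i, , ] <- t(as.matrix(rows[, fn, drop = FALSE]))
    dates[i, ] <- rows$anchor_date
  }
  mask <- array(TRUE, dim = dim(vals), dimnames = dimnames(vals))
  static <- if (is.null(staticData)) {
    data.frame(row.names = pats)
  } else {
    staticData[intersect(rownames(staticData), pats), , drop = FALSE]
  }
  exclLog <- data.frame(patient_id = names(excl),
                        reason = unlist(excl, use.names = FALSE),
                        stringsAsFactors = FALSE)
  if (nrow(exclLog) == 0L)
    exclLog <- data.frame(patient_id = character(), reason = character())
  ds <- new("ThreeWayDataset", values = vals, mask = mask,
            featureType = clustricFeatureTypes(), staticData = static,
            exclusions = exclLog)
  attr(ds@values, "anchor_dates") <- dates
  ds
}

#' Appointment anchor dates of an assembled dataset
#' @param dataset a \code{ThreeWayDataset} from
#'   \code{\link{assembleThreeWay}}.
#' @return numeric matrix subjects x contexts of anchor dates (days), or
#'   NULL when the dataset was built directly from a cube.
#' @export
anchorDates <- function(dataset) attr(dataset@values, "anchor_dates")

#' Build a ThreeWayDataset directly from a value cube
#'
#' @param values numeric 3D array (subjects x features x contexts) with
#'   dimnames.
#' @param featureType named character vector; defaults to the package's
#'   seven-feature typing when names match, else all numeric.
#' @param staticData optional per-subject data.frame.
#' @return a \code{ThreeWayDataset}.
#' @export
threeWayDataset <- function(values, featureType = NULL, staticData = NULL) {
  if (is.null(dimnames(values)) ||
      any(vapply(dimnames(values), is.null, logical(1)))) {
    dimnames(values) <- list(
      paste0("P", seq_len(dim(values)[1L])),
      paste0("F", seq_len(dim(values)[2L])),
      paste0("t", seq_len(dim(values)[3L]))
    )
  }
  if (is.null(featureType)) {
    fn <- dimnames(values)[[2L]]
    featureType <- if (setequal(fn, clustricFeatures()))
      clustricFeatureTypes()[fn]
    else stats::setNames(rep("numeric", length(fn)), fn)
  }
  if (is.null(staticData))
    staticData <- data.frame(row.names = dimnames(values)[[1L]])
  mask <- array(!is.na(values), dim = dim(values), dimnames = dimnames(values))
  new("ThreeWayDataset", values = values, mask = mask,
      featureType = featureType, staticData = staticData,
      exclusions = data.frame(patient_id = character(), reason = character()))
}

#' Write / read a ThreeWayDataset as tidy CSV plus JSON sidecar
#'
#' @param dataset a \code{ThreeWayDataset}.
#' @param path CSV path; the sidecar is written next to it with extension
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
writeThreeWay <- function(dataset, path) {
  v <- values(dataset)
  d <- dim(v)
  long <- expand.grid(patient = dimnames(v)[[1L]], feature = dimnames(v)[[2L]],
                      appointment = seq_len(d[3L]), stringsAsFactors = FALSE)
  long$value <- as.vector(v)
  utils::write.csv(long, path, row.names = FALSE)
  sidecar <- list(subjects = dimnames(v)[[1L]], features = dimnames(v)[[2L]],
                  contexts = d[3L], featureType = as.list(featureType(dataset)))
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeThreeWay
#' @export
readThreeWay <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  v <- array(NA_real_,
             dim = c(length(meta$subjects), length(meta$features),
                     meta$contexts),
             dimnames = list(meta$subjects, meta$features,
                             paste0("t", seq_len(meta$contexts))))
  ix <- cbind(match(long$patient, meta$subjects),
              match(long$feature, meta$features),
              long$appointment)
  v[ix] <- long$value
  threeWayDataset(v, featureType = unlist(meta$featureType))
}
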