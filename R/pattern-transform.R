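## Virtual patterns (per-context representative vectors of a tricluster)
## and the patient-by-pattern Euclidean distance embedding.

.modeSmallest <- function(x) {
  # mode; ties resolved toward the smallest value
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1L])
}

#' Compute the 3D virtual pattern of a tricluster
#'
#' For each context k in the tricluster's K, the representative vector
#' rho_k holds, per feature, the mean of the tricluster's subjects'
#' values (numeric features) or the mode with ties to the smallest value
#' (categorical features).
#'
#' @param tricluster a \code{Tricluster}.
#' @param dataset the \code{ThreeWayDataset} it was mined from.
#' @param triclusterId integer id recorded in the pattern (default 1).
#' @return a \code{\link{VirtualPattern-class}}.
#' @export
virtualPattern <- function(tricluster, dataset, triclusterId = 1L) {
  v <- values(dataset)
  I <- match(tricluster@subjects, dimnames(v)[[1L]])
  J <- match(tricluster@features, dimnames(v)[[2L]])
  if (anyNA(I) || anyNA(J))
    stop("tricluster indices do not match the dataset")
  if (length(I) == 0L) stop("tricluster has no subjects")
  ft <- featureType(dataset)[tricluster@features]
  K <- tricluster@contexts
  rho <- matrix(NA_real_, length(K), length(J),
                dimnames = list(paste0("t", K), tricluster@features))
  for (ki in seq_along(K)) {
    for (ji in seq_along(J)) {
      col <- v[I, J[ji], K[ki]]
      rho[ki, ji] <- if (ft[ji] == "categorical") .modeSmallest(col)
                     else mean(col)
    }
  }
  new("VirtualPattern", triclusterId = as.integer(triclusterId),
      contexts = as.integer(K), features = tricluster@features, rho = rho)
}

#' Virtual patterns for every tricluster of a solution
#'
#' @param solution a \code{TriclusteringSolution}.
#' @param dataset the mined dataset.
#' @return list of \code{VirtualPattern}, in solution order.
#' @export
virtualPatterns <- function(solution, dataset) {
  tcs <- triclusters(solution)
  if (!length(tcs)) stop("solution has no triclusters")
  lapply(seq_along(tcs), function(l)
    virtualPattern(tcs[[l]], dataset, triclusterId = l))
}

#' Euclidean distance between a subject's feature values and a pattern row
#'
#' The scalar distance underlying every entry of the pattern-distance
#' matrix: sqrt of the summed squared differences between the subject's
#' values on the pattern's features at one context and the pattern's
#' representative vector rho_k.
#'
#' @param pattern a \code{VirtualPattern}.
#' @param subjectValues numeric vector of the subject's values on the
#'   pattern's features (same order) at context k.
#' @param k context index (must be one of the pattern's contexts).
#' @return nonnegative scalar distance.
#' @export
patternDistance <- function(pattern, subjectValues, k) {
  ki <- match(k, pattern@contexts)
  if (is.na(ki)) stop("context ", k, " not in the pattern")
  if (length(subjectValues) != length(pattern@features))
    stop("subject values do not match the pattern's features")
  sqrt(sum((subjectValues - pattern@rho[ki, ])^2))
}

#' Transform a cohort into the patient-by-pattern distance matrix
#'
#' Every subject (whether or not it belongs to any tricluster) receives
#' one column per (tricluster l, context k in K_l): the Euclidean
#' distance between its values on the tricluster's features at k and the
#' pattern's representative vector. Columns are ordered by tricluster in
#' solution order, contexts ascending within each; with the default
#' minTimes = |Z| the shape is |X| x (|Z| * L).
#'
#' @param dataset a complete \code{ThreeWayDataset}.
#' @param patterns list of \code{VirtualPattern}
#'   (see \code{\link{virtualPatterns}}).
#' @param standardize z-score each feature (per context) before computing
#'   distances; off by default since the method operates in raw score
#'   units.
#' @return a \code{\link{PatternDistanceMatrix-class}}.
#' @export
transformDataset <- function(dataset, patterns, standardize = FALSE) {
  if (length(patterns) == 0L) stop("no patterns supplied")
  v <- values(dataset)
  if (anyNA(v)) stop("dataset has masked cells")
  if (standardize) {
    for (j in seq_len(dim(v)[2L])) for (k in seq_len(dim(v)[3L])) {
      mu <- mean(v[, j, k]); sdv <- stats::sd(v[, j, k])
      v[, j, k] <- if (sdv > 0) (v[, j, k] - mu) / sdv else 0
    }
  }
  nX <- dim(v)[1L]
  nCols <- sum(vapply(patterns, function(p) length(p@contexts), integer(1)))
  mat <- matrix(NA_real_, nX, nCols,
                dimnames = list(dimnames(v)[[1L]], NULL))
  info <- data.frame(tricluster = integer(nCols), context = integer(nCols),
                     label = character(nCols), stringsAsFactors = FALSE)
  col <- 0L
  for (p in patterns) {
    J <- match(p@features, dimnames(v)[[2L]])
    for (ki in seq_along(p@contexts)) {
      k <- p@contexts[ki]
      col <- col + 1L
      diff <- v[, J, k, drop = FALSE]
      dim(diff) <- c(nX, length(J))
      diff <- sweep(diff, 2L, p@rho[ki, ])
      mat[, col] <- sqrt(rowSums(diff^2))
      info$tricluster[col] <- p@triclusterId
      info$context[col] <- k
      info$label[col] <- paste0("T", p@triclusterId, ".t", k)
    }
  }
  colnames(mat) <- info$label
  new("PatternDistanceMatrix", matrix = mat, columnInfo = info)
}

#' Append static covariate columns to a pattern-distance matrix
#'
#' Optional hook, disabled by default in the pipeline: numeric static
#' covariates are appended as extra columns after the pattern columns.
#'
#' @param pdm a \code{PatternDistanceMatrix}.
#' @param staticData data.frame with subject row names; only numeric
#'   columns are used.
#' @return a new \code{PatternDistanceMatrix}.
#' @export
appendStaticColumns <- function(pdm, staticData) {
  num <- staticData[, vapply(staticData, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) == 0L) return(pdm)
  m <- distanceMatrix(pdm)
  add <- as.matrix(num[rownames(m), , drop = FALSE])
  info <- rbind(columnInfo(pdm),
                data.frame(tricluster = NA_integer_, context = NA_integer_,
                           label = colnames(add), stringsAsFactors = FALSE))
  new("PatternDistanceMatrix", matrix = cbind(m, add), columnInfo = info)
}

#' Write a pattern-distance matrix as CSV with a JSON sidecar
#'
#' @param pdm a \code{PatternDistanceMatrix}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(pdm, path) {
  df <- data.frame(patient_id = rownames(distanceMatrix(pdm)),
                   distanceMatrix(pdm), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(columnInfo(pdm), sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$patient_id
  info <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  new("PatternDistanceMatrix", matrix = m, columnInfo = as.data.frame(info))
}
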