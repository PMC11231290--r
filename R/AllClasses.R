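#' @useDynLib clustric, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' ThreeWayDataset: an aligned patients x features x appointments cube
#'
#' Holds the value cube produced by snapshot alignment, together with a
#' presence mask, per-feature type tags (numeric vs categorical) and an
#' optional per-subject static table (covariates, survival time, event
#' flag). After completeness filtering every retained subject has all
#' features observed at all contexts, so the mask is all-\code{TRUE}.
#'
#' @slot values numeric 3D array, \code{subjects x features x contexts},
#'   with dimnames.
#' @slot mask logical array of the same dimensions; \code{TRUE} = observed.
#' @slot featureType named character vector, one of \code{"numeric"} or
#'   \code{"categorical"} per feature.
#' @slot staticData data.frame of per-subject covariates (row names are
#'   subject ids); zero rows when absent.
#' @slot exclusions data.frame logging subjects dropped during assembly
#'   (columns \code{patient_id}, \code{reason}).
#'
#' @exportClass ThreeWayDataset
setClass("ThreeWayDataset",
  representation(
    values = "array",
    mask = "array",
    featureType = "character",
    staticData = "data.frame",
    exclusions = "data.frame"
  )
)

setValidity("ThreeWayDataset", function(object) {
  v <- object@values
  m <- object@mask
  msgs <- character()
  if (length(dim(v)) != 3L) msgs <- c(msgs, "values must be a 3D array")
  if (!identical(dim(v), dim(m))) msgs <- c(msgs, "mask dimensions differ from values")
  noNames <- if (is.null(dimnames(v))) dim(v) > 0 else
    vapply(seq_along(dim(v)), function(i)
      is.null(dimnames(v)[[i]]) && dim(v)[i] > 0, logical(1))
  if (any(noNames))
    msgs <- c(msgs, "values must carry subject/feature/context dimnames")
  ft <- object@featureType
  if (length(ft) != dim(v)[2L] ||
      !all(ft %in% c("numeric", "categorical")))
    msgs <- c(msgs, "featureType must tag every feature as numeric or categorical")
  if (nrow(object@staticData) > 0 &&
      !all(rownames(object@staticData) %in% dimnames(v)[[1L]]))
    msgs <- c(msgs, "staticData row names must be subject ids")
  if (length(msgs)) msgs else TRUE
})

#' Tricluster: a coherent, temporally contiguous subspace of the cube
#'
#' Index triple (I subjects, J features, K contexts) where K is a
#' consecutive run of appointment indices and, at every context in K,
#' every feature pair restricted to I has a cross-feature value-ratio
#' spread bounded by 1 + epsilon (the coherence certificate is
#' re-checkable via \code{\link{checkCoherence}}).
#'
#' @slot subjects character vector of subject ids (I).
#' @slot features character vector of feature names (J).
#' @slot contexts integer vector of 1-based context indices (K),
#'   consecutive and increasing.
#'
#' @exportClass Tricluster
setClass("Tricluster",
  representation(
    subjects = "character",
    features = "character",
    contexts = "integer"
  )
)

setValidity("Tricluster", function(object) {
  k <- object@contexts
  msgs <- character()
  if (length(k) == 0L || any(diff(k) != 1L))
    msgs <- c(msgs, "contexts must be a non-empty consecutive run")
  if (length(object@subjects) == 0L) msgs <- c(msgs, "empty subject set")
  if (length(object@features) == 0L) msgs <- c(msgs, "empty feature set")
  if (anyDuplicated(object@subjects)) msgs <- c(msgs, "duplicate subjects")
  if (anyDuplicated(object@features)) msgs <- c(msgs, "duplicate features")
  if (length(msgs)) msgs else TRUE
})

#' TriclusteringSolution: a set of triclusters plus the mining parameters
#'
#' @slot triclusters list of \code{Tricluster}.
#' @slot parameters named list: \code{epsilon}, \code{shift},
#'   \code{minSubjects}, \code{minFeatures}, \code{minTimes}, \code{delta},
#'   \code{patternFamily}.
#'
#' @exportClass TriclusteringSolution
setClass("TriclusteringSolution",
  representation(
    triclusters = "list",
    parameters = "list"
  )
)

setValidity("TriclusteringSolution", function(object) {
  ok <- vapply(object@triclusters, is, logical(1), class2 = "Tricluster")
  if (!all(ok)) "triclusters must all be Tricluster objects" else TRUE
})

#' VirtualPattern: the per-context representative vectors of a tricluster
#'
#' For each context k of the tricluster, a vector of |J| representative
#' values: the mean across the tricluster's subjects for numeric features,
#' the mode (ties to the smallest value) for categorical ones.
#'
#' @slot triclusterId integer index of the tricluster within its solution.
#' @slot contexts integer context indices (K).
#' @slot features character feature names (J).
#' @slot rho numeric matrix |K| x |J| of representative values.
#'
#' @exportClass VirtualPattern
setClass("VirtualPattern",
  representation(
    triclusterId = "integer",
    contexts = "integer",
    features = "character",
    rho = "matrix"
  )
)

setValidity("VirtualPattern", function(object) {
  if (!identical(dim(object@rho),
                 c(length(object@contexts), length(object@features))))
    "rho must be |K| x |J|" else TRUE
})

#' PatternDistanceMatrix: patients embedded as distances to patterns
#'
#' Rows are subjects, columns are (tricluster, context) pairs; each entry
#' is the Euclidean distance between the subject's values on the
#' tricluster's features at that context and the pattern's representative
#' vector. When every tricluster spans all |Z| contexts the shape is
#' |X| x (|Z| * L).
#'
#' @slot matrix numeric matrix with subject row names.
#' @slot columnInfo data.frame with one row per column: \code{tricluster}
#'   (index), \code{context} (index), \code{label}.
#'
#' @exportClass PatternDistanceMatrix
setClass("PatternDistanceMatrix",
  representation(
    matrix = "matrix",
    columnInfo = "data.frame"
  )
)

setValidity("PatternDistanceMatrix", function(object) {
  msgs <- character()
  if (ncol(object@matrix) != nrow(object@columnInfo))
    msgs <- c(msgs, "columnInfo must describe every column")
  if (any(object@matrix < 0)) msgs <- c(msgs, "distances must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' ProgressionClustering: linkage tree, chosen k, labels, validity panel
#'
#' @slot tree the \code{hclust} object (Ward.D2 on Euclidean row distances).
#' @slot k integer, the cluster count the labels correspond to.
#' @slot labels named integer vector of cluster ids in 1..k, named by
#'   subject; clusters numbered by decreasing size (ties by smallest
#'   member index).
#' @slot validity data.frame with one row per candidate k: \code{k},
#'   \code{silhouette}, \code{calinski_harabasz}, \code{davies_bouldin}.
#' @slot groupNames optional character vector of clinician-style aliases
#'   (e.g. SP/MPb/MPs/FP), named by cluster id; length 0 when unset.
#'
#' @exportClass ProgressionClustering
setClass("ProgressionClustering",
  representation(
    tree = "ANY",
    k = "integer",
    labels = "integer",
    validity = "data.frame",
    groupNames = "character"
  )
)

setValidity("ProgressionClustering", function(object) {
  msgs <- character()
  if (!inherits(object@tree, "hclust")) msgs <- c(msgs, "tree must be an hclust")
  if (length(object@k) == 1L && !is.na(object@k)) {
    if (length(unique(object@labels)) != object@k)
      msgs <- c(msgs, "labels must use exactly k distinct ids")
  }
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by subject")
  if (length(msgs)) msgs else TRUE
})
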