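#' @rdname ThreeWayDataset-class
#' @param object,x a package object
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("contexts", function(x) standardGeneric("contexts"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("staticData", function(x) standardGeneric("staticData"))

#' @rdname ThreeWayDataset-class
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname TriclusteringSolution-class
#' @export
setGeneric("triclusters", function(x) standardGeneric("triclusters"))

#' @rdname TriclusteringSolution-class
#' @export
setGeneric("miningParameters", function(x) standardGeneric("miningParameters"))

#' @rdname ProgressionClustering-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ProgressionClustering-class
#' @export
setGeneric("validityTable", function(x) standardGeneric("validityTable"))

#' @rdname PatternDistanceMatrix-class
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname PatternDistanceMatrix-class
#' @export
setGeneric("columnInfo", function(x) standardGeneric("columnInfo"))

## ---- ThreeWayDataset accessors -------------------------------------------

#' @rdname ThreeWayDataset-class
#' @export
setMethod("subjects", "ThreeWayDataset", function(x) dimnames(x@values)[[1L]])

#' @rdname ThreeWayDataset-class
#' @export
setMethod("featureNames", "ThreeWayDataset", function(x) dimnames(x@values)[[2L]])

#' @rdname ThreeWayDataset-class
#' @export
setMethod("contexts", "ThreeWayDataset", function(x) seq_len(dim(x@values)[3L]))

#' @rdname ThreeWayDataset-class
#' @export
setMethod("values", "ThreeWayDataset", function(x) x@values)

#' @rdname ThreeWayDataset-class
#' @export
setMethod("featureType", "ThreeWayDataset", function(x) x@featureType)

#' @rdname ThreeWayDataset-class
#' @export
setMethod("staticData", "ThreeWayDataset", function(x) x@staticData)

#' @rdname ThreeWayDataset-class
#' @export
setMethod("exclusions", "ThreeWayDataset", function(x) x@exclusions)

#' @rdname ThreeWayDataset-class
#' @export
setMethod("dim", "ThreeWayDataset", function(x) dim(x@values))

#' @rdname ThreeWayDataset-class
setMethod("show", "ThreeWayDataset", function(object) {
  d <- dim(object@values)
  cat("ThreeWayDataset:", d[1L], "subjects x", d[2L], "features x",
      d[3L], "contexts\n")
  cat(" features:", paste(dimnames(object@values)[[2L]], collapse = ", "), "\n")
  cat(" complete cells:", sum(object@mask), "/", length(object@mask), "\n")
  if (nrow(object@staticData))
    cat(" static table:", ncol(object@staticData), "covariates\n")
  if (nrow(object@exclusions))
    cat(" excluded subjects:", nrow(object@exclusions), "\n")
  invisible(NULL)
})

## ---- Tricluster / solution accessors -------------------------------------

#' @rdname Tricluster-class
#' @param x a \code{Tricluster}
#' @export
setMethod("subjects", "Tricluster", function(x) x@subjects)

#' @rdname Tricluster-class
#' @export
setMethod("featureNames", "Tricluster", function(x) x@features)

#' @rdname Tricluster-class
#' @export
setMethod("contexts", "Tricluster", function(x) x@contexts)

#' @rdname Tricluster-class
setMethod("show", "Tricluster", function(object) {
  cat(sprintf("Tricluster: %d subjects x %d features x contexts [%d..%d]\n",
              length(object@subjects), length(object@features),
              min(object@contexts), max(object@contexts)))
  cat(" features:", paste(object@features, collapse = ", "), "\n")
  invisible(NULL)
})

#' @rdname TriclusteringSolution-class
#' @export
setMethod("triclusters", "TriclusteringSolution", function(x) x@triclusters)

#' @rdname TriclusteringSolution-class
#' @export
setMethod("miningParameters", "TriclusteringSolution", function(x) x@parameters)

#' @rdname TriclusteringSolution-class
#' @export
setMethod("length", "TriclusteringSolution", function(x) length(x@triclusters))

#' @rdname TriclusteringSolution-class
setMethod("show", "TriclusteringSolution", function(object) {
  p <- object@parameters
  cat("TriclusteringSolution:", length(object@triclusters), "triclusters\n")
  cat(sprintf(" epsilon=%g shift=%g minSubjects=%d minFeatures=%d minTimes=%d delta=%g\n",
              p$epsilon, p$shift, p$minSubjects, p$minFeatures, p$minTimes,
              p$delta))
  invisible(NULL)
})

## ---- PatternDistanceMatrix accessors -------------------------------------

#' @rdname PatternDistanceMatrix-class
#' @export
setMethod("distanceMatrix", "PatternDistanceMatrix", function(x) x@matrix)

#' @rdname PatternDistanceMatrix-class
#' @export
setMethod("columnInfo", "PatternDistanceMatrix", function(x) x@columnInfo)

#' @rdname PatternDistanceMatrix-class
#' @export
setMethod("dim", "PatternDistanceMatrix", function(x) dim(x@matrix))

#' @rdname PatternDistanceMatrix-class
setMethod("show", "PatternDistanceMatrix", function(object) {
  cat("PatternDistanceMatrix:", nrow(object@matrix), "subjects x",
      ncol(object@matrix), "(tricluster, context) columns\n")
  invisible(NULL)
})

## ---- ProgressionClustering accessors -------------------------------------

#' @rdname ProgressionClustering-class
#' @export
setMethod("clusterLabels", "ProgressionClustering", function(x) x@labels)

#' @rdname ProgressionClustering-class
#' @export
setMethod("validityTable", "ProgressionClustering", function(x) x@validity)

#' @rdname ProgressionClustering-class
setMethod("show", "ProgressionClustering", function(object) {
  cat("ProgressionClustering: k =", object@k, "\n")
  print(table(cluster = object@labels))
  if (nrow(object@validity)) {
    cat(" validity panel:\n")
    print(object@validity, row.names = FALSE)
  }
  invisible(NULL)
})
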