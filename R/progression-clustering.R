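## Grouping patients by Ward-linkage hierarchical clustering of the
## pattern-distance embedding, with validity indices (silhouette,
## Calinski-Harabasz, Davies-Bouldin) for choosing the cluster count.

.asMatrixRows <- function(x) {
  if (is(x, "PatternDistanceMatrix")) distanceMatrix(x)
  else as.matrix(x)
}

#' Ward-linkage tree over subjects
#'
#' Agglomerates subjects by Ward's minimum-variance criterion (the
#' \code{ward.D2} variant: squared-Euclidean objective with heights on
#' the Euclidean scale) on the Euclidean distances between rows of the
#' pattern-distance matrix.
#'
#' @param x a \code{PatternDistanceMatrix} or a numeric matrix whose rows
#'   are subjects.
#' @return an \code{hclust} tree.
#' @export
wardLinkage <- function(x) {
  m <- .asMatrixRows(x)
  if (nrow(m) < 2L) stop("need at least two subjects")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Cut a linkage tree into k clusters
#'
#' Labels are renumbered by decreasing cluster size; ties broken by the
#' cluster containing the smallest row index. Cluster ids are 1..k.
#'
#' @param tree an \code{hclust} tree.
#' @param k number of clusters, between 1 and the number of subjects.
#' @return named integer vector of cluster labels.
#' @export
cutTreeK <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  firstMember <- vapply(names(sizes), function(cl)
    min(which(raw == as.integer(cl))), numeric(1))
  ord <- order(-as.numeric(sizes), firstMember)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- relabel[raw]
  names(out) <- names(raw)
  out
}

#' Cluster validity indices
#'
#' Silhouette (mean, singleton clusters contribute 0), Calinski-Harabasz
#' and Davies-Bouldin, all on Euclidean distances between matrix rows.
#' Higher is better for silhouette and CH, lower for DB.
#'
#' @param x matrix or \code{PatternDistanceMatrix}; rows are subjects.
#' @param labels integer cluster labels, one per row, at least 2 distinct.
#' @return named numeric vector \code{silhouette},
#'   \code{calinski_harabasz}, \code{davies_bouldin}.
#' @export
validityScores <- function(x, labels) {
  m <- .asMatrixRows(x)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  n <- nrow(m)
  if (k < 2L) stop("need at least two clusters")
  if (k > n - 1L && k == n) {
    # all singletons: silhouette 0 by convention; CH/DB degenerate
  }
  sil <- cluster::silhouette(labels, stats::dist(m))
  silMean <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  centroids <- rowsum(m, labels) / as.vector(table(labels))
  grand <- colMeans(m)
  sizes <- as.vector(table(labels))
  bgss <- sum(sizes * rowSums(sweep(centroids, 2L, grand)^2))
  wgss <- sum((m - centroids[labels, , drop = FALSE])^2)
  ch <- if (wgss > 0) (bgss / (k - 1)) / (wgss / (n - k)) else Inf
  # Davies-Bouldin: mean over clusters of the worst similarity ratio
  s <- vapply(seq_len(k), function(c)
    mean(sqrt(rowSums((m[labels == c, , drop = FALSE] -
                         matrix(centroids[c, ], sum(labels == c),
                                ncol(m), byrow = TRUE))^2))), numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(k), function(i)
    max(vapply(seq_len(k), function(j)
      if (i == j) -Inf else (s[i] + s[j]) / cd[i, j], numeric(1))),
    numeric(1)))
  c(silhouette = silMean, calinski_harabasz = ch, davies_bouldin = db)
}

#' Validity panel over candidate cluster counts, with a recommendation
#'
#' Emits the full score table for each candidate k (the primary output,
#' meant for inspection alongside the dendrogram) plus a recommended k by
#' majority vote of the three indices (silhouette max, CH max, DB min);
#' ties resolve toward the smaller k.
#'
#' @param x matrix or \code{PatternDistanceMatrix}.
#' @param tree the Ward tree from \code{\link{wardLinkage}} (computed if
#'   missing).
#' @param candidates candidate cluster counts (default 3:5).
#' @return list with \code{table} (data.frame k x indices) and
#'   \code{recommended} (integer k).
#' @export
selectK <- function(x, tree = NULL, candidates = 3:5) {
  if (length(candidates) == 0L) stop("no candidate cluster counts")
  m <- .asMatrixRows(x)
  if (any(candidates < 2L | candidates > nrow(m) - 1L))
    stop("candidates must lie in [2, nSubjects - 1]")
  if (is.null(tree)) tree <- wardLinkage(m)
  rows <- lapply(candidates, function(k) {
    sc <- validityScores(m, cutTreeK(tree, k))
    data.frame(k = k, silhouette = sc[["silhouette"]],
               calinski_harabasz = sc[["calinski_harabasz"]],
               davies_bouldin = sc[["davies_bouldin"]])
  })
  tab <- do.call(rbind, rows)
  votes <- c(tab$k[which.max(tab$silhouette)],
             tab$k[which.max(tab$calinski_harabasz)],
             tab$k[which.min(tab$davies_bouldin)])
  cnt <- table(votes)
  winners <- as.integer(names(cnt)[cnt == max(cnt)])
  list(table = tab, recommended = min(winners))
}

#' Cluster patients into progression groups
#'
#' Runs Ward linkage on the pattern-distance matrix, evaluates the
#' validity panel over the candidate ks, and cuts the tree at \code{k}
#' (or the panel's recommendation when \code{k} is NULL).
#'
#' @param x a \code{PatternDistanceMatrix} or numeric matrix.
#' @param k cluster count; NULL picks the panel recommendation.
#' @param candidates candidate ks for the validity panel (default 3:5).
#' @param groupNames optional aliases per cluster id (e.g.
#'   \code{c("SP", "MPb", "MPs", "FP")}).
#' @return a \code{\link{ProgressionClustering-class}}.
#' @export
progressionClusters <- function(x, k = NULL, candidates = 3:5,
                                groupNames = character()) {
  m <- .asMatrixRows(x)
  tree <- wardLinkage(m)
  sel <- selectK(m, tree, candidates)
  if (is.null(k)) k <- sel$recommended
  labels <- cutTreeK(tree, k)
  if (is.null(names(labels))) names(labels) <- rownames(m)
  new("ProgressionClustering", tree = tree, k = as.integer(k),
      labels = labels, validity = sel$table,
      groupNames = as.character(groupNames))
}

#' Serialise a linkage tree's merge list as JSON
#'
#' @param tree an \code{hclust}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLinkageTree <- function(tree, path) {
  obj <- list(merge = apply(tree$merge, 1L, function(r) list(a = r[1L], b = r[2L])),
              height = tree$height, order = tree$order,
              labels = tree$labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write cluster labels as CSV
#'
#' @param clustering a \code{ProgressionClustering}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeClusterLabels <- function(clustering, path) {
  lab <- clusterLabels(clustering)
  alias <- clustering@groupNames
  df <- data.frame(patient_id = names(lab), cluster = as.integer(lab),
                   group = if (length(alias)) alias[lab] else NA_character_,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' subjects; 1 means identical partitions, 0 the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxIndex <- (sumi + sumj) / 2
  if (maxIndex == expected) return(1)
  (sumij - expected) / (maxIndex - expected)
}
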