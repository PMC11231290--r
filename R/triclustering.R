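## Mining temporally contiguous, ratio-coherent triclusters.
##
## Coherence criterion: within a block (I, J) on one time slice, for every
## feature pair (a, b) the cross-feature ratios r_i = v[i,b] / v[i,a]
## (computed on positively shifted values) must satisfy
## max(r) / min(r) <= 1 + epsilon. This captures constant and scaling
## patterns; an exponential pre-transform extends it to shifting patterns.

.transformValues <- function(v, shift = NULL,
                             patternFamily = c("scaling", "shifting")) {
  patternFamily <- match.arg(patternFamily)
  if (patternFamily == "shifting") {
    # additive coherence reduces to multiplicative coherence under exp;
    # centre on the maximum to avoid overflow
    return(list(values = exp(v - max(v)), shift = 0))
  }
  if (is.null(shift)) shift <- 1 - min(v)
  w <- v + shift
  if (any(w <= 0)) {
    bad <- which(w <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive shifted value at cell (%d, %d, %d); increase shift",
                 bad[1L], bad[2L], if (length(bad) > 2) bad[3L] else 1L))
  }
  list(values = w, shift = shift)
}

#' Ratio-range multigraph of one time slice
#'
#' For every unordered feature pair, the maximal subject ranges whose
#' cross-feature value ratios span at most a factor 1 + epsilon, found by
#' sorting subjects by ratio and sweeping. These ranges are the edges of
#' the multigraph from which maximal biclusters are grown.
#'
#' @param slice numeric matrix, subjects x features.
#' @param epsilon nonnegative coherence threshold.
#' @param shift added to all values before forming ratios; must make every
#'   value strictly positive. Default shifts the slice minimum to 1.
#' @param minSubjects smallest range worth keeping (default 2).
#' @return list with one element per feature pair \code{"a|b"}; each a
#'   list of ranges, each range a list with \code{subjects} (integer
#'   indices) and \code{ratio_bounds}.
#' @export
buildMultigraph <- function(slice, epsilon, shift = NULL, minSubjects = 2L) {
  stopifnot(is.matrix(slice), epsilon >= 0)
  if (is.null(shift)) shift <- 1 - min(slice)
  w <- slice + shift
  if (any(w <= 0)) {
    bad <- which(w <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive shifted value at cell (%d, %d)", bad[1L], bad[2L]))
  }
  nY <- ncol(w)
  out <- list()
  for (a in seq_len(nY - 1L)) {
    for (b in seq((a + 1L), nY)) {
      ratio <- w[, b] / w[, a]
      ranges <- .cppPairRanges(ratio, epsilon, as.integer(minSubjects))
      out[[paste(a, b, sep = "|")]] <- lapply(ranges, function(I) {
        list(subjects = I, ratio_bounds = range(ratio[I]))
      })
    }
  }
  out
}

#' Maximal coherent biclusters of one time slice
#'
#' Depth-first growth of feature sets over the ratio-range multigraph,
#' intersecting subject ranges pairwise; returns exactly the maximal
#' coherent biclusters meeting the size thresholds.
#'
#' @inheritParams buildMultigraph
#' @param minFeatures minimum feature-set size (default 2; 1 admits
#'   single-feature blocks spanning all subjects).
#' @return list of biclusters, each a list with integer index vectors
#'   \code{I} and \code{J}.
#' @export
mineBiclusters <- function(slice, epsilon, shift = NULL,
                           minSubjects = 2L, minFeatures = 2L) {
  stopifnot(is.matrix(slice), epsilon >= 0)
  if (minFeatures > ncol(slice)) {
    warning("minFeatures exceeds the number of features; empty result")
    return(list())
  }
  if (is.null(shift)) shift <- 1 - min(slice)
  w <- slice + shift
  if (any(w <= 0)) stop("nonpositive shifted value; increase shift")
  .cppMineSlice(w, epsilon, as.integer(minSubjects), as.integer(minFeatures))
}

.blockKey <- function(I, J, K) {
  paste(paste(sort(I), collapse = ","), paste(sort(J), collapse = ","),
        paste(sort(K), collapse = ","), sep = "|")
}

#' Combine per-slice biclusters into contiguous triclusters
#'
#' Extends time windows by pairwise intersection of adjacent slices'
#' maximal biclusters (the intersection of two coherent blocks stays
#' coherent, so maximal cross-window blocks are exactly the maximal
#' pairwise intersections), then filters global maximality across
#' windows.
#'
#' @param perSlice list (one element per context) of bicluster lists as
#'   returned by \code{\link{mineBiclusters}}.
#' @param minTimes minimum window length.
#' @param nSubjects,nFeatures dimensions of the underlying slices.
#' @param minSubjects,minFeatures size thresholds.
#' @param contiguous when TRUE (default) context sets are consecutive
#'   windows; when FALSE arbitrary context subsets are admitted.
#' @return list of triclusters, each a list with \code{I}, \code{J}
#'   (integer indices) and \code{K} (context indices).
#' @export
combineOverTime <- function(perSlice, minTimes, nSubjects, nFeatures,
                            minSubjects = 2L, minFeatures = 2L,
                            contiguous = TRUE) {
  nZ <- length(perSlice)
  if (minTimes > nZ) {
    warning("minTimes exceeds the number of contexts; empty result")
    return(list())
  }
  if (!contiguous) {
    return(.combineSubsets(perSlice, minTimes, nSubjects,
                           minSubjects, minFeatures))
  }
  ## W[[len]][[k]]: maximal blocks coherent on window [k, k+len-1]
  W <- vector("list", nZ)
  W[[1L]] <- perSlice
  if (nZ > 1L) {
    for (len in 2:nZ) {
      W[[len]] <- vector("list", nZ - len + 1L)
      for (k in seq_len(nZ - len + 1L)) {
        prev <- W[[len - 1L]][[k]]
        nxt <- perSlice[[k + len - 1L]]
        W[[len]][[k]] <- if (length(prev) && length(nxt)) {
          .cppIntersectBlocks(prev, nxt, as.integer(nSubjects),
                              as.integer(nFeatures),
                              as.integer(minSubjects),
                              as.integer(minFeatures))
        } else list()
      }
    }
  }
  blocks <- list(); kstart <- integer(); kend <- integer()
  for (len in seq(max(minTimes, 1L), nZ)) {
    for (k in seq_len(nZ - len + 1L)) {
      bl <- W[[len]][[k]]
      if (length(bl)) {
        blocks <- c(blocks, bl)
        kstart <- c(kstart, rep(k, length(bl)))
        kend <- c(kend, rep(k + len - 1L, length(bl)))
      }
    }
  }
  if (!length(blocks)) return(list())
  sizeOK <- vapply(blocks, function(b)
    length(b$I) >= minSubjects && length(b$J) >= minFeatures, logical(1))
  blocks <- blocks[sizeOK]; kstart <- kstart[sizeOK]; kend <- kend[sizeOK]
  if (!length(blocks)) return(list())
  keep <- .cppMaximalTriclusters(blocks, kstart, kend, as.integer(nSubjects))
  out <- mapply(function(b, ks, ke) list(I = b$I, J = b$J, K = ks:ke),
                blocks[keep], kstart[keep], kend[keep], SIMPLIFY = FALSE)
  names(out) <- NULL
  out
}

## arbitrary context subsets (non-contiguous); pure R, small |Z| only
.combineSubsets <- function(perSlice, minTimes, nSubjects,
                            minSubjects, minFeatures) {
  nZ <- length(perSlice)
  if (nZ > 12L) stop("non-contiguous combination supports at most 12 contexts")
  store <- new.env(parent = emptyenv())
  intersectLists <- function(A, B) {
    out <- list()
    for (a in A) for (b in B) {
      I <- intersect(a$I, b$I); J <- intersect(a$J, b$J)
      if (length(I) >= minSubjects && length(J) >= minFeatures)
        out[[length(out) + 1L]] <- list(I = I, J = J)
    }
    .maximalBlocksR(out)
  }
  results <- list()
  subsetsBySize <- lapply(seq_len(nZ), function(sz)
    utils::combn(nZ, sz, simplify = FALSE))
  for (sz in seq_len(nZ)) {
    for (S in subsetsBySize[[sz]]) {
      key <- paste(S, collapse = ",")
      bl <- if (sz == 1L) {
        .maximalBlocksR(Filter(function(b)
          length(b$I) >= minSubjects && length(b$J) >= minFeatures,
          perSlice[[S]]))
      } else {
        prevKey <- paste(S[-sz], collapse = ",")
        intersectLists(get(prevKey, store), perSlice[[S[sz]]])
      }
      assign(key, bl, store)
      if (sz >= minTimes)
        results <- c(results, lapply(bl, function(b)
          list(I = b$I, J = b$J, K = S)))
    }
  }
  ## global maximality across subsets
  if (!length(results)) return(list())
  keep <- rep(TRUE, length(results))
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      if (i == j) next
      a <- results[[i]]; b <- results[[j]]
      if (all(a$I %in% b$I) && all(a$J %in% b$J) && all(a$K %in% b$K)) {
        ident <- length(a$I) == length(b$I) && length(a$J) == length(b$J) &&
          length(a$K) == length(b$K)
        if (!ident || j < i) { keep[i] <- FALSE; break }
      }
    }
  }
  results[keep]
}

.maximalBlocksR <- function(blocks) {
  if (length(blocks) < 2L) return(blocks)
  keep <- rep(TRUE, length(blocks))
  for (i in seq_along(blocks)) {
    for (j in seq_along(blocks)) {
      if (i == j) next
      a <- blocks[[i]]; b <- blocks[[j]]
      if (all(a$I %in% b$I) && all(a$J %in% b$J)) {
        ident <- length(a$I) == length(b$I) && length(a$J) == length(b$J)
        if (!ident || j < i) { keep[i] <- FALSE; break }
      }
    }
  }
  blocks[keep]
}

#' Greedy overlap pruning of a triclustering solution
#'
#' Keeps triclusters in decreasing cell-count order (ties broken
#' lexicographically by smallest subject, feature, then context) and
#' drops any whose shared cells with an already-kept tricluster exceed
#' \code{delta} of its own cells. \code{delta = 1} disables pruning.
#'
#' @param solution a \code{TriclusteringSolution}.
#' @param delta overlap tolerance in [0, 1].
#' @return a pruned \code{TriclusteringSolution}.
#' @export
pruneOverlaps <- function(solution, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  tcs <- triclusters(solution)
  if (length(tcs) < 2L) return(solution)
  cells <- vapply(tcs, function(t)
    length(t@subjects) * length(t@features) * length(t@contexts), numeric(1))
  keys <- vapply(tcs, function(t)
    paste(min(t@subjects), min(t@features), min(t@contexts)), character(1))
  ord <- order(-cells, keys)
  kept <- list()
  for (ix in ord) {
    t <- tcs[[ix]]
    own <- length(t@subjects) * length(t@features) * length(t@contexts)
    drop <- FALSE
    for (k in kept) {
      shared <- length(intersect(t@subjects, k@subjects)) *
        length(intersect(t@features, k@features)) *
        length(intersect(t@contexts, k@contexts))
      smaller <- min(own,
                     length(k@subjects) * length(k@features) * length(k@contexts))
      if (shared / smaller > delta) { drop <- TRUE; break }
    }
    if (!drop) kept[[length(kept) + 1L]] <- t
  }
  params <- solution@parameters
  params$delta <- delta
  new("TriclusteringSolution", triclusters = .orderTriclusters(kept),
      parameters = params)
}

.orderTriclusters <- function(tcs) {
  if (length(tcs) < 2L) return(tcs)
  cells <- vapply(tcs, function(t)
    length(t@subjects) * length(t@features) * length(t@contexts), numeric(1))
  keys <- vapply(tcs, function(t)
    paste(paste(sort(t@subjects), collapse = ","),
          paste(sort(t@features), collapse = ","),
          min(t@contexts)), character(1))
  tcs[order(-cells, keys)]
}

#' Mine temporally contiguous coherent triclusters from a three-way dataset
#'
#' The full mining pipeline: values are shifted to be strictly positive
#' (or exponentiated for the shifting pattern family), maximal
#' ratio-coherent biclusters are mined per time slice from the
#' ratio-range multigraph, combined across adjacent slices into maximal
#' contiguous triclusters, and optionally pruned for overlap.
#'
#' @param dataset a complete \code{\link{ThreeWayDataset-class}}.
#' @param epsilon coherence threshold (default 0.05): within a block every
#'   feature-pair ratio spread is at most 1 + epsilon.
#' @param minSubjects minimum subjects per tricluster; default
#'   \code{max(5, ceiling(0.02 * nSubjects))}.
#' @param minFeatures minimum features per tricluster (default 2).
#' @param minTimes minimum contiguous contexts; default all contexts, so
#'   every pattern spans the whole follow-up and the pattern-distance
#'   matrix has the regular |X| x (|Z| * L) shape.
#' @param delta overlap tolerance for \code{\link{pruneOverlaps}}
#'   (default 1 = keep all maximal triclusters).
#' @param patternFamily \code{"scaling"} (ratio coherence on shifted
#'   values; also captures constant patterns) or \code{"shifting"}
#'   (additive coherence via an exponential pre-transform).
#' @param shift value shift; default makes the cube minimum equal 1.
#' @param contiguous require context sets to be consecutive (default).
#' @return a \code{\link{TriclusteringSolution-class}}.
#' @export
mineTriclusters <- function(dataset, epsilon = 0.05, minSubjects = NULL,
                            minFeatures = 2L, minTimes = NULL, delta = 1,
                            patternFamily = c("scaling", "shifting"),
                            shift = NULL, contiguous = TRUE) {
  patternFamily <- match.arg(patternFamily)
  stopifnot(epsilon >= 0)
  v <- values(dataset)
  if (anyNA(v)) stop("dataset has masked cells; complete it first")
  d <- dim(v)
  if (is.null(minSubjects)) minSubjects <- max(5L, ceiling(0.02 * d[1L]))
  if (is.null(minTimes)) minTimes <- d[3L]
  tr <- .transformValues(v, shift, patternFamily)
  w <- tr$values
  perSlice <- lapply(seq_len(d[3L]), function(k)
    .cppMineSlice(w[, , k, drop = TRUE], epsilon,
                  as.integer(minSubjects), as.integer(minFeatures)))
  raw <- combineOverTime(perSlice, minTimes, d[1L], d[2L],
                         minSubjects, minFeatures, contiguous)
  subj <- dimnames(v)[[1L]]; feat <- dimnames(v)[[2L]]
  tcs <- lapply(raw, function(b)
    new("Tricluster", subjects = subj[sort(b$I)],
        features = feat[sort(b$J)], contexts = as.integer(sort(b$K))))
  sol <- new("TriclusteringSolution",
             triclusters = .orderTriclusters(tcs),
             parameters = list(epsilon = epsilon, shift = tr$shift,
                               minSubjects = as.integer(minSubjects),
                               minFeatures = as.integer(minFeatures),
                               minTimes = as.integer(minTimes),
                               delta = delta,
                               patternFamily = patternFamily))
  if (delta < 1) sol <- pruneOverlaps(sol, delta) else sol
}

#' Re-check a tricluster's coherence certificate
#'
#' Recomputes, for every feature pair at every context of the tricluster,
#' the spread of cross-feature ratios across its subjects, and compares
#' against 1 + epsilon.
#'
#' @param tricluster a \code{Tricluster}.
#' @param dataset the dataset it was mined from.
#' @param epsilon,shift,patternFamily mining parameters (take them from
#'   the solution's \code{miningParameters}).
#' @return TRUE when every pair at every context satisfies the bound.
#' @export
checkCoherence <- function(tricluster, dataset, epsilon, shift = NULL,
                           patternFamily = "scaling") {
  v <- values(dataset)
  w <- .transformValues(v, shift, patternFamily)$values
  I <- match(tricluster@subjects, dimnames(v)[[1L]])
  J <- match(tricluster@features, dimnames(v)[[2L]])
  for (k in tricluster@contexts) {
    for (a in seq_along(J)[-length(J)]) {
      for (b in seq((a + 1L), length(J))) {
        r <- w[I, J[b], k] / w[I, J[a], k]
        if (max(r) > (1 + epsilon) * min(r)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Exhaustive reference enumeration of maximal coherent triclusters
#'
#' Brute-force oracle for small cubes: enumerates every (I, J, K) triple
#' with K contiguous, tests ratio coherence directly, and keeps the
#' blocks that cannot be extended by any single subject, feature or
#' adjacent context. Intended for testing the mining pipeline; refuses
#' cubes beyond \code{cap}.
#'
#' @inheritParams mineTriclusters
#' @param cap maximum dimensions (subjects, features, contexts); default
#'   \code{c(6, 4, 3)}.
#' @return list of triclusters, each a list with integer \code{I},
#'   \code{J}, \code{K}.
#' @export
bruteForceTriclusters <- function(dataset, epsilon = 0.05,
                                  minSubjects = 2L, minFeatures = 2L,
                                  minTimes = NULL, shift = NULL,
                                  patternFamily = "scaling",
                                  contiguous = TRUE, cap = c(6L, 4L, 3L)) {
  v <- values(dataset)
  d <- dim(v)
  if (any(d > cap))
    stop("cube exceeds the brute-force cap (", paste(cap, collapse = "x"), ")")
  if (is.null(minTimes)) minTimes <- d[3L]
  w <- .transformValues(v, shift, patternFamily)$values
  subsetsOf <- function(n) {
    out <- list()
    for (m in seq_len(2^n - 1L))
      out[[m]] <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0L)
    out
  }
  Is <- subsetsOf(d[1L]); Js <- subsetsOf(d[2L])
  Ks <- if (contiguous) {
    out <- list()
    for (k1 in seq_len(d[3L])) for (k2 in k1:d[3L])
      out[[length(out) + 1L]] <- k1:k2
    out
  } else subsetsOf(d[3L])
  coherent <- function(I, J, K) {
    if (length(J) >= 2L) {
      for (k in K) {
        sl <- w[, , k, drop = TRUE]
        for (a in seq_along(J)[-length(J)]) for (b in (a + 1L):length(J)) {
          r <- sl[I, J[b]] / sl[I, J[a]]
          if (max(r) > (1 + epsilon) * min(r)) return(FALSE)
        }
      }
    }
    TRUE
  }
  cohSet <- new.env(parent = emptyenv())
  all <- list()
  for (I in Is) for (J in Js) for (K in Ks) {
    if (coherent(I, J, K)) {
      key <- .blockKey(I, J, K)
      assign(key, TRUE, cohSet)
      all[[length(all) + 1L]] <- list(I = I, J = J, K = K)
    }
  }
  isCoh <- function(I, J, K) exists(.blockKey(I, J, K), cohSet)
  out <- list()
  for (b in all) {
    I <- b$I; J <- b$J; K <- b$K
    if (length(I) < minSubjects || length(J) < minFeatures ||
        length(K) < minTimes) next
    maximal <- TRUE
    for (i in setdiff(seq_len(d[1L]), I))
      if (isCoh(sort(c(I, i)), J, K)) { maximal <- FALSE; break }
    if (maximal) for (j in setdiff(seq_len(d[2L]), J))
      if (isCoh(I, sort(c(J, j)), K)) { maximal <- FALSE; break }
    if (maximal) {
      ext <- if (contiguous) {
        Filter(function(k) k >= 1L && k <= d[3L], c(min(K) - 1L, max(K) + 1L))
      } else setdiff(seq_len(d[3L]), K)
      for (k in ext)
        if (isCoh(I, J, sort(c(K, k)))) { maximal <- FALSE; break }
    }
    if (maximal) out[[length(out) + 1L]] <- b
  }
  out
}

#' Serialise / read a triclustering solution as JSON
#'
#' @param solution a \code{TriclusteringSolution}.
#' @param path output path.
#' @return \code{path} invisibly; \code{readTriclusters} returns the
#'   solution.
#' @export
writeTriclusters <- function(solution, path) {
  obj <- list(
    parameters = solution@parameters,
    triclusters = lapply(triclusters(solution), function(t)
      list(subjects = t@subjects, features = t@features,
           contexts = t@contexts))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTriclusters
#' @export
readTriclusters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  tcs <- lapply(obj$triclusters, function(t)
    new("Tricluster",
        subjects = vapply(t$subjects, as.character, character(1)),
        features = vapply(t$features, as.character, character(1)),
        contexts = vapply(t$contexts, as.integer, integer(1))))
  p <- obj$parameters
  p$minSubjects <- as.integer(p$minSubjects)
  p$minFeatures <- as.integer(p$minFeatures)
  p$minTimes <- as.integer(p$minTimes)
  new("TriclusteringSolution", triclusters = tcs, parameters = p)
}
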