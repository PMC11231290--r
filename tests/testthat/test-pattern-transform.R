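test_that("virtual patterns are per-context means (numeric) and modes (categorical)", {
  # constant tricluster: rho is the constant
  v <- array(7, dim = c(3, 2, 2))
  ds <- threeWayDataset(v)
  tc <- new("Tricluster", subjects = subjects(ds), features = featureNames(ds),
            contexts = 1:2)
  vp <- virtualPattern(tc, ds)
  expect_true(all(vp@rho == 7))
  expect_equal(dim(vp@rho), c(2L, 2L))

  # forced arithmetic mean: 40 and 44 -> 42
  v <- array(0, dim = c(2, 2, 1))
  v[, 1, 1] <- c(40, 44); v[, 2, 1] <- c(10, 12)
  ds <- threeWayDataset(v)
  tc <- new("Tricluster", subjects = subjects(ds), features = featureNames(ds),
            contexts = 1L)
  expect_equal(unname(virtualPattern(tc, ds)@rho[1, ]), c(42, 11))

  # categorical feature takes the mode, ties toward the smallest value
  v <- array(0, dim = c(3, 2, 1),
             dimnames = list(paste0("P", 1:3), c("score", "stage"), "t1"))
  v[, "score", 1] <- c(10, 10, 10)
  v[, "stage", 1] <- c(2, 2, 3)
  ds <- threeWayDataset(v, featureType = c(score = "numeric",
                                           stage = "categorical"))
  tc <- new("Tricluster", subjects = paste0("P", 1:3),
            features = c("score", "stage"), contexts = 1L)
  expect_equal(unname(virtualPattern(tc, ds)@rho[1, "stage"]), 2)
  # tie case {1,1,3,3} resolves toward the smaller stage
  v2 <- array(0, dim = c(4, 2, 1),
              dimnames = list(paste0("P", 1:4), c("score", "stage"), "t1"))
  v2[, "score", 1] <- 10
  v2[, "stage", 1] <- c(1, 1, 3, 3)
  ds2 <- threeWayDataset(v2, featureType = c(score = "numeric",
                                             stage = "categorical"))
  tc2 <- new("Tricluster", subjects = paste0("P", 1:4),
             features = c("score", "stage"), contexts = 1L)
  expect_equal(unname(virtualPattern(tc2, ds2)@rho[1, "stage"]), 1)

  # rho bounded by the subject min/max per cell
  set.seed(9)
  ds3 <- randomCube(c(6, 4, 3))
  tc3 <- new("Tricluster", subjects = subjects(ds3)[2:5],
             features = featureNames(ds3)[1:3], contexts = 1:3)
  vp3 <- virtualPattern(tc3, ds3)
  vv <- values(ds3)
  for (ki in 1:3) for (ji in 1:3) {
    col <- vv[2:5, ji, ki]
    expect_gte(vp3@rho[ki, ji], min(col))
    expect_lte(vp3@rho[ki, ji], max(col))
  }

  expect_error(virtualPattern(new("Tricluster", subjects = "nope",
                                  features = featureNames(ds3)[1:2],
                                  contexts = 1:3), ds3), "do not match")
})

test_that("the scalar pattern distance is a plain Euclidean distance", {
  vp <- new("VirtualPattern", triclusterId = 1L, contexts = 1:2,
            features = c("a", "b"),
            rho = matrix(c(3, 1, 4, 1), 2, 2))
  # identity
  expect_equal(patternDistance(vp, c(3, 4), 1), 0)
  # 3-4-5 right triangle
  expect_equal(patternDistance(vp, c(0, 0), 1), 5)
  # symmetric under consistent feature reordering
  vpR <- new("VirtualPattern", triclusterId = 1L, contexts = 1:2,
             features = c("b", "a"),
             rho = matrix(c(4, 1, 3, 1), 2, 2))
  expect_equal(patternDistance(vp, c(1, 7), 1), patternDistance(vpR, c(7, 1), 1))
  expect_error(patternDistance(vp, c(1, 2, 3), 1), "features")
  expect_error(patternDistance(vp, c(1, 2), 5), "not in the pattern")
})

test_that("the distance matrix has shape |X| x (|Z| L) and matches the scalar oracle", {
  set.seed(17)
  ds <- randomCube(c(10, 5, 3))
  sol <- mineTriclusters(ds, epsilon = 0.4, minSubjects = 2L, minTimes = 3L)
  pats <- virtualPatterns(sol, ds)
  pdm <- transformDataset(ds, pats)
  L <- length(pats)
  expect_gt(L, 0)
  expect_equal(dim(pdm), c(10L, 3L * L))
  m <- distanceMatrix(pdm)
  info <- columnInfo(pdm)
  v <- values(ds)
  # every entry equals the scalar Eq-style distance within 1e-9
  for (col in seq_len(ncol(m))) {
    p <- pats[[info$tricluster[col]]]
    J <- match(p@features, dimnames(v)[[2]])
    for (i in seq_len(nrow(m))) {
      expect_equal(m[i, col],
                   patternDistance(p, v[i, J, info$context[col]],
                                   info$context[col]),
                   tolerance = 1e-9)
    }
  }
  # column order: triclusters in solution order, contexts ascending
  expect_equal(info$tricluster, rep(seq_len(L), each = 3))
  expect_equal(info$context, rep(1:3, L))
  expect_true(all(m >= 0))
})

test_that("members of a constant tricluster sit at distance zero from its pattern", {
  v <- array(runif(6 * 3 * 2, 10, 20), dim = c(6, 3, 2))
  v[1:3, 1:2, ] <- 5 # constant block over both contexts
  ds <- threeWayDataset(v)
  tc <- new("Tricluster", subjects = subjects(ds)[1:3],
            features = featureNames(ds)[1:2], contexts = 1:2)
  pdm <- transformDataset(ds, list(virtualPattern(tc, ds)))
  m <- distanceMatrix(pdm)
  expect_equal(unname(m[1:3, ]), matrix(0, 3, 2))
  expect_true(all(m[4:6, ] > 0))
})

test_that("duplicating a subject duplicates its distance row exactly", {
  set.seed(23)
  v <- array(runif(5 * 3 * 2), dim = c(5, 3, 2))
  v[5, , ] <- v[1, , ] # subject 5 is a copy of subject 1
  ds <- threeWayDataset(v)
  sol <- mineTriclusters(ds, epsilon = 0.5, minSubjects = 2L, minTimes = 2L)
  pdm <- transformDataset(ds, virtualPatterns(sol, ds))
  m <- distanceMatrix(pdm)
  expect_equal(unname(m[5, ]), unname(m[1, ]))
  expect_error(transformDataset(ds, list()), "no patterns")
})

test_that("distance matrices round-trip through CSV and static columns append", {
  ds <- smallCohortDataset(15, seed = 2)$dataset
  sol <- mineTriclusters(ds, minSubjects = 3L)
  pdm <- transformDataset(ds, virtualPatterns(sol, ds))
  path <- tempfile(fileext = ".csv")
  writeDistanceMatrix(pdm, path)
  back <- readDistanceMatrix(path)
  expect_equal(distanceMatrix(back), distanceMatrix(pdm), tolerance = 1e-12)
  aug <- appendStaticColumns(pdm, staticData(ds))
  expect_gt(ncol(distanceMatrix(aug)), ncol(distanceMatrix(pdm)))
  expect_equal(distanceMatrix(aug)[, seq_len(ncol(distanceMatrix(pdm)))],
               distanceMatrix(pdm))
})
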