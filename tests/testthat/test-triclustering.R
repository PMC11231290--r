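test_that("the ratio-range multigraph finds maximal coherent subject ranges", {
  # feature 2 = 2 x feature 1: one full-cover edge with constant ratio 2
  slice <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  mg <- buildMultigraph(slice, epsilon = 0, shift = 0)
  expect_length(mg[["1|2"]], 1L)
  expect_equal(sort(mg[["1|2"]][[1]]$subjects), 1:4)
  expect_equal(mg[["1|2"]][[1]]$ratio_bounds, c(2, 2))

  # ratios (1.00, 1.005, 1.5, 1.505) at eps = 0.01: two maximal 2-ranges
  slice <- cbind(a = rep(1000, 4), b = c(1000, 1005, 1500, 1505))
  mg <- buildMultigraph(slice, epsilon = 0.01, shift = 0)
  ranges <- lapply(mg[["1|2"]], `[[`, "subjects")
  expect_length(ranges, 2L)
  expect_equal(lapply(ranges, sort), list(c(1L, 2L), c(3L, 4L)))

  # eps = 0 on distinct random ratios: no 2-subject range survives
  set.seed(5)
  slice <- cbind(a = runif(6, 1, 2), b = runif(6, 1, 2))
  mg <- buildMultigraph(slice, epsilon = 0, shift = 0, minSubjects = 2L)
  expect_length(mg[["1|2"]], 0L)

  # nonpositive shifted value is a domain error
  expect_error(buildMultigraph(cbind(a = c(-2, 1), b = c(1, 1)),
                               epsilon = 0.1, shift = 0), "nonpositive")
})

test_that("slice bicluster mining recovers planted blocks and degenerate cases", {
  set.seed(8)
  # planted 3x2 scaling block in a 4x3 slice, noise elsewhere
  slice <- matrix(runif(12, 5, 9), 4, 3)
  slice[1:3, 1] <- c(1, 2, 3)
  slice[1:3, 2] <- 2 * slice[1:3, 1]
  bcs <- mineBiclusters(slice, epsilon = 0.01, shift = 0,
                        minSubjects = 2L, minFeatures = 2L)
  keys <- vapply(bcs, function(b) paste(paste(sort(b$I), collapse = ","),
                                        paste(sort(b$J), collapse = ","),
                                        sep = "|"), character(1))
  expect_true("1,2,3|1,2" %in% keys)
  # every returned block is coherent and maximal per the double-loop oracle
  w <- array(slice, dim = c(4, 3, 1))
  for (b in bcs) {
    expect_true(coherentBlockOracle(w, b$I, b$J, 1L, 0.01))
    for (i in setdiff(1:4, b$I))
      expect_false(coherentBlockOracle(w, c(b$I, i), b$J, 1L, 0.01))
  }

  # all-constant slice: the entire slice is the single maximal bicluster
  bcs <- mineBiclusters(matrix(3, 5, 4), epsilon = 0, shift = 0,
                        minSubjects = 2L, minFeatures = 2L)
  expect_length(bcs, 1L)
  expect_equal(sort(bcs[[1]]$I), 1:5)
  expect_equal(sort(bcs[[1]]$J), 1:4)

  # unsatisfiable thresholds
  expect_length(mineBiclusters(matrix(3, 4, 3), 0.1, 0, minSubjects = 5L), 0L)
  expect_warning(res <- mineBiclusters(matrix(3, 4, 3), 0.1, 0,
                                       minFeatures = 4L), "minFeatures")
  expect_length(res, 0L)
})

test_that("cross-time combination enforces contiguity and emits maximal windows", {
  # identical planted structure coherent at every context
  v <- array(runif(4 * 3 * 3, 5, 9), dim = c(4, 3, 3))
  for (k in 1:3) { v[1:3, 1, k] <- c(1, 2, 3); v[1:3, 2, k] <- 2 * v[1:3, 1, k] }
  perSlice <- lapply(1:3, function(k)
    mineBiclusters(v[, , k], 0.01, 0, 2L, 2L))
  tcs <- combineOverTime(perSlice, minTimes = 3L, nSubjects = 4L,
                         nFeatures = 3L, minSubjects = 2L, minFeatures = 2L)
  keys <- vapply(tcs, function(t) tricKey(t$I, t$J, t$K), character(1))
  expect_true("1,2,3|1,2|1,2,3" %in% keys)

  # block coherent only at contexts 1 and 3: contiguity forbids spanning both
  v2 <- array(runif(4 * 3 * 3, 5, 9), dim = c(4, 3, 3))
  for (k in c(1, 3)) { v2[1:3, 1, k] <- c(1, 2, 3); v2[1:3, 2, k] <- 2 * v2[1:3, 1, k] }
  perSlice2 <- lapply(1:3, function(k) mineBiclusters(v2[, , k], 0.01, 0, 2L, 2L))
  tcs2 <- combineOverTime(perSlice2, minTimes = 2L, nSubjects = 4L,
                          nFeatures = 3L, minSubjects = 2L, minFeatures = 2L)
  for (t in tcs2)
    expect_false(all(c(1, 3) %in% t$K) && length(t$K) == 2)

  # non-contiguous mode does admit the split window
  tcs3 <- combineOverTime(perSlice2, minTimes = 2L, nSubjects = 4L,
                          nFeatures = 3L, minSubjects = 2L, minFeatures = 2L,
                          contiguous = FALSE)
  keys3 <- vapply(tcs3, function(t) tricKey(t$I, t$J, t$K), character(1))
  expect_true(any(grepl("\\|1,3$", keys3)))

  expect_warning(res <- combineOverTime(perSlice, minTimes = 4L,
                                        nSubjects = 4L, nFeatures = 3L),
                 "minTimes")
  expect_length(res, 0L)
})

test_that("staircase structure yields both maximal triclusters", {
  # (I1 = rows 1:4, J = {1,2}) coherent at contexts 1:2;
  # (I2 = rows 1:2, J) additionally coherent at context 3
  v <- array(0, dim = c(6, 3, 3))
  set.seed(13)
  v[, , ] <- runif(54, 40, 90)
  for (k in 1:2) { v[1:4, 1, k] <- 1:4; v[1:4, 2, k] <- 3 * (1:4) }
  v[1:2, 1, 3] <- c(1, 2); v[1:2, 2, 3] <- c(3, 6)
  ds <- threeWayDataset(v)
  sol <- mineTriclusters(ds, epsilon = 0.01, minSubjects = 2L,
                         minFeatures = 2L, minTimes = 2L, shift = 0)
  keys <- solutionKeys(sol, ds)
  expect_true(tricKey(1:4, 1:2, 1:2) %in% keys)
  expect_true(tricKey(1:2, 1:2, 1:3) %in% keys)
  bf <- bruteForceTriclusters(ds, epsilon = 0.01, minSubjects = 2L,
                              minFeatures = 2L, minTimes = 2L, shift = 0)
  expect_equal(keys, bruteKeys(bf))
})

test_that("mining equals exhaustive enumeration on random cubes", {
  set.seed(21)
  for (rep in 1:40) {
    dims <- c(sample(4:6, 1), sample(3:4, 1), 3)
    ds <- randomCube(dims)
    eps <- sample(c(0, 0.05, 0.2, 0.5, 1), 1)
    mi <- sample(2:3, 1); mj <- sample(1:2, 1); mt <- sample(1:3, 1)
    sol <- mineTriclusters(ds, epsilon = eps, minSubjects = mi,
                           minFeatures = mj, minTimes = mt)
    bf <- bruteForceTriclusters(ds, epsilon = eps, minSubjects = mi,
                                minFeatures = mj, minTimes = mt)
    expect_equal(solutionKeys(sol, ds), bruteKeys(bf),
                 info = sprintf("dims=%s eps=%g mi=%d mj=%d mt=%d",
                                paste(dims, collapse = "x"), eps, mi, mj, mt))
  }
})

test_that("emitted triclusters always carry a valid coherence certificate", {
  set.seed(31)
  for (rep in 1:5) {
    ds <- randomCube(c(8, 5, 3))
    eps <- sample(c(0.1, 0.3, 0.8), 1)
    sol <- mineTriclusters(ds, epsilon = eps, minSubjects = 2L)
    v <- values(ds)
    shift <- miningParameters(sol)$shift
    w <- v + shift
    for (t in triclusters(sol)) {
      I <- match(t@subjects, dimnames(v)[[1]])
      J <- match(t@features, dimnames(v)[[2]])
      expect_true(coherentBlockOracle(w, I, J, t@contexts, eps))
      expect_true(checkCoherence(t, ds, eps, shift))
    }
  }
})

test_that("coherent blocks persist as epsilon grows and mining is order-invariant", {
  set.seed(41)
  ds <- randomCube(c(6, 4, 3))
  v <- values(ds)
  sol1 <- mineTriclusters(ds, epsilon = 0.1, minSubjects = 2L)
  shift <- miningParameters(sol1)$shift
  # every block coherent at eps1 stays coherent at eps2 >= eps1
  for (t in triclusters(sol1)) {
    I <- match(t@subjects, dimnames(v)[[1]])
    J <- match(t@features, dimnames(v)[[2]])
    expect_true(coherentBlockOracle(v + shift, I, J, t@contexts, 0.4))
  }
  # and each is contained in some block of the coarser solution
  sol2 <- mineTriclusters(ds, epsilon = 0.4, minSubjects = 2L)
  for (t in triclusters(sol1)) {
    contained <- any(vapply(triclusters(sol2), function(u)
      all(t@subjects %in% u@subjects) && all(t@features %in% u@features) &&
        all(t@contexts %in% u@contexts), logical(1)))
    expect_true(contained)
  }

  # permuting subject order leaves the named solution unchanged
  perm <- sample(dim(v)[1])
  vp <- v[perm, , ]
  dsp <- threeWayDataset(vp)
  solp <- mineTriclusters(dsp, epsilon = 0.1, minSubjects = 2L)
  keys <- function(s) sort(vapply(triclusters(s), function(t)
    paste(paste(sort(t@subjects), collapse = ","),
          paste(sort(t@features), collapse = ","),
          paste(t@contexts, collapse = ","), sep = "|"), character(1)))
  expect_equal(keys(solp), keys(sol1))

  # identical rerun gives the identical solution object
  expect_equal(mineTriclusters(ds, epsilon = 0.1, minSubjects = 2L), sol1)
})

test_that("overlap pruning keeps large triclusters and drops redundant ones", {
  tc <- function(I, J, K) new("Tricluster", subjects = paste0("P", I),
                              features = paste0("F", J),
                              contexts = as.integer(K))
  mkSol <- function(tcs) new("TriclusteringSolution", triclusters = tcs,
                             parameters = list(epsilon = 0.1, shift = 0,
                                               minSubjects = 2L,
                                               minFeatures = 2L, minTimes = 1L,
                                               delta = 1,
                                               patternFamily = "scaling"))
  # identical duplicates collapse
  sol <- pruneOverlaps(mkSol(list(tc(1:3, 1:2, 1:2), tc(1:3, 1:2, 1:2))), 0.5)
  expect_length(triclusters(sol), 1L)
  # disjoint survive delta = 0
  sol <- pruneOverlaps(mkSol(list(tc(1:3, 1:2, 1:2), tc(4:6, 3:4, 1:2))), 0)
  expect_length(triclusters(sol), 2L)
  # nested smaller block sharing all its cells is dropped at delta = 0.9
  sol <- pruneOverlaps(mkSol(list(tc(1:4, 1:3, 1:3), tc(1:2, 1:2, 1:2))), 0.9)
  expect_length(triclusters(sol), 1L)
  expect_length(subjects(triclusters(sol)[[1]]), 4L)
  # delta = 1 disables pruning even for duplicates' nested companions
  sol <- pruneOverlaps(mkSol(list(tc(1:4, 1:3, 1:3), tc(1:2, 1:2, 1:2))), 1)
  expect_length(triclusters(sol), 2L)
  expect_error(pruneOverlaps(mkSol(list(tc(1:3, 1:2, 1:2))), 1.2), "delta")
})

test_that("the brute-force oracle refuses oversized cubes and handles edges", {
  expect_error(bruteForceTriclusters(randomCube(c(8, 4, 3))), "cap")
  # all-constant cube: single tricluster covering everything
  ds <- threeWayDataset(array(5, dim = c(4, 3, 3)))
  bf <- bruteForceTriclusters(ds, epsilon = 0, minSubjects = 2L,
                              minFeatures = 2L)
  expect_length(bf, 1L)
  expect_equal(bruteKeys(bf), tricKey(1:4, 1:3, 1:3))
})

test_that("a triclustering solution round-trips through JSON", {
  ds <- randomCube(c(6, 4, 3))
  sol <- mineTriclusters(ds, epsilon = 0.3, minSubjects = 2L)
  path <- tempfile(fileext = ".json")
  writeTriclusters(sol, path)
  back <- readTriclusters(path)
  expect_equal(length(back), length(sol))
  expect_equal(miningParameters(back)$epsilon, miningParameters(sol)$epsilon)
  for (i in seq_along(triclusters(sol))) {
    expect_equal(triclusters(back)[[i]]@subjects, triclusters(sol)[[i]]@subjects)
    expect_equal(triclusters(back)[[i]]@contexts, triclusters(sol)[[i]]@contexts)
  }
})
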