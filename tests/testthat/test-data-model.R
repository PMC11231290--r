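test_that("long-format records parse, group by assessment, and report bad rows", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,date,test,item,value",
               "P1,2020-01-05,ALSFRS-R,item1,4",
               "P1,2020-01-05,ALSFRS-R,item2,3",
               "P1,2020-01-05,ALSFRS-R,item3,2"), csv)
  recs <- readLongRecords(csv)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$patient_id, "P1")
  expect_equal(unname(recs[[1]]$payload), c(4, 3, 2))
  expect_equal(names(recs[[1]]$payload), c("item1", "item2", "item3"))

  # empty file with header
  writeLines("patient_id,date,test,item,value", csv)
  expect_length(readLongRecords(csv), 0L)

  # unparseable date is reported with its row number, not dropped silently
  writeLines(c("patient_id,date,test,item,value",
               "P1,not-a-date,ALSFRS-R,item1,4",
               "P1,100,ALSFRS-R,item1,4"), csv)
  expect_warning(recs <- readLongRecords(csv), "failed to parse")
  errs <- attr(recs, "parseErrors")
  expect_equal(errs$row, 1L)
  expect_match(errs$message, "not-a-date")
  expect_length(recs, 1L)

  # missing mandatory schema role
  expect_error(readLongRecords(csv, schema = list(patient = "patient_id",
                                                  date = "date")),
               "mandatory")
  # mapped column absent from the file
  expect_error(readLongRecords(csv, schema = list(patient = "pid",
                                                  date = "date", test = "test",
                                                  value = "value")),
               "lacks")
})

test_that("snapshots respect the window and the duplicate-test constraint", {
  rec <- function(pid, day, test) list(patient_id = pid, date = day,
                                       test_name = test,
                                       payload = c(x = 1))
  # 190-day gap exceeds the 100-day window
  snaps <- buildSnapshots(list(rec("P1", 0, "A"), rec("P1", 10, "B"),
                               rec("P1", 200, "A")), windowDays = 100)
  expect_length(snaps, 2L)
  expect_setequal(vapply(snaps[[1]]$records, `[[`, character(1), "test_name"),
                  c("A", "B"))
  expect_equal(snaps[[2]]$anchor_date, 200)

  # same test twice within the window must still split
  snaps <- buildSnapshots(list(rec("P1", 0, "A"), rec("P1", 50, "A")),
                          windowDays = 100)
  expect_length(snaps, 2L)

  # single record: one snapshot, first index
  snaps <- buildSnapshots(list(rec("P1", 5, "A")))
  expect_length(snaps, 1L)
  expect_equal(snaps[[1]]$index, 1L)
  expect_length(buildSnapshots(list()), 0L)
})

test_that("snapshot grouping partitions records and bounds spans on random inputs", {
  set.seed(11)
  tests <- c("A", "B", "C")
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    recs <- lapply(seq_len(n), function(i)
      list(patient_id = sample(c("P1", "P2"), 1),
           date = sample(0:400, 1),
           test_name = sample(tests, 1), payload = c(x = 1)))
    snaps <- buildSnapshots(recs, windowDays = 100)
    # partition: every record in exactly one snapshot of its patient
    expect_equal(sum(vapply(snaps, function(s) length(s$records), integer(1))),
                 n)
    for (s in snaps) {
      days <- vapply(s$records, `[[`, numeric(1), "date")
      expect_lte(max(days) - min(days), 100)
      expect_equal(min(days), s$anchor_date)
      tn <- vapply(s$records, `[[`, character(1), "test_name")
      expect_equal(anyDuplicated(tn), 0L)
      expect_equal(unique(vapply(s$records, `[[`, character(1), "patient_id")),
                   s$patient_id)
    }
    # indices strictly increasing by anchor date within patient
    for (p in unique(vapply(snaps, `[[`, character(1), "patient_id"))) {
      ps <- Filter(function(s) s$patient_id == p, snaps)
      anchors <- vapply(ps, `[[`, numeric(1), "anchor_date")
      idx <- vapply(ps, `[[`, integer(1), "index")
      expect_equal(idx, seq_along(ps))
      expect_true(all(diff(anchors[order(idx)]) >= 0))
    }
  }
})

test_that("feature derivation matches the ALSFRS-R item partition and MiToS staging", {
  fv <- deriveFeatures(list(patient_id = "P1", index = 1L,
                            records = makeRecords("P1", 0, list(rep(4, 12))),
                            anchor_date = 0))
  expect_equal(unname(fv), c(48, 12, 8, 8, 8, 12, 0))

  fv0 <- deriveFeatures(list(patient_id = "P1", index = 1L,
                             records = makeRecords("P1", 0, list(rep(0, 12))),
                             anchor_date = 0))
  expect_equal(unname(fv0), c(0, 0, 0, 0, 0, 0, 4))

  # lower-limb loss: items 8 and 9 at 1 -> LL = 2, movement domain lost
  items <- c(4, 4, 4, 4, 4, 4, 4, 1, 1, 4, 4, 4)
  fv1 <- deriveFeatures(list(patient_id = "P1", index = 1L,
                             records = makeRecords("P1", 0, list(items)),
                             anchor_date = 0))
  expect_equal(fv1[["ALSFRSR"]], 42)
  expect_equal(fv1[["ALSFRSsLL"]], 2)
  expect_equal(fv1[["MITOS"]], 1)

  # out-of-range item is a validation error
  bad <- c(5, rep(4, 11))
  expect_error(deriveFeatures(list(patient_id = "P1", index = 1L,
                                   records = makeRecords("P1", 0, list(bad)),
                                   anchor_date = 0)),
               "outside 0-4")

  # missing ALSFRS-R record -> all NA, not an error
  fvNA <- deriveFeatures(list(patient_id = "P1", index = 1L,
                              records = list(list(patient_id = "P1", date = 0,
                                                  test_name = "FVC",
                                                  payload = c(fvc = 90))),
                              anchor_date = 0))
  expect_true(all(is.na(fvNA)))
})

test_that("subscore conservation holds across random item vectors", {
  set.seed(3)
  for (rep in 1:50) {
    items <- sample(0:4, 12, replace = TRUE)
    fv <- deriveFeatures(list(patient_id = "P", index = 1L,
                              records = makeRecords("P", 0, list(items)),
                              anchor_date = 0))
    expect_equal(fv[["ALSFRSR"]],
                 sum(fv[c("ALSFRSb", "ALSFRSsUL", "ALSFRSsLL",
                          "ALSFRSsT", "ALSFRSr")]))
    expect_true(fv[["MITOS"]] %in% 0:4)
  }
})

test_that("three-way assembly keeps the first complete appointments and logs exclusions", {
  mk <- function(pid, nvisits) makeRecords(pid, seq(0, by = 120,
                                                    length.out = nvisits),
                                           replicate(nvisits, rep(3, 12),
                                                     simplify = FALSE))
  recs <- c(mk("A", 4), mk("B", 3), mk("C", 5), mk("D", 2), mk("E", 1))
  snaps <- buildSnapshots(recs)
  ds <- assembleThreeWay(featureTable(snaps), nContexts = 3)
  expect_equal(dim(ds), c(3L, 7L, 3L))
  expect_setequal(subjects(ds), c("A", "B", "C"))
  expect_setequal(exclusions(ds)$patient_id, c("D", "E"))
  expect_false(anyNA(values(ds)))

  # prefix selection: a patient's first three appointments are used
  dates <- anchorDates(ds)
  expect_equal(unname(dates["C", ]), c(0, 120, 240))

  # all patients incomplete -> empty dataset plus full exclusion log
  ds2 <- assembleThreeWay(featureTable(buildSnapshots(mk("D", 2))),
                          nContexts = 3)
  expect_equal(dim(ds2)[1], 0L)
  expect_equal(nrow(exclusions(ds2)), 1L)

  expect_error(assembleThreeWay(featureTable(snaps), nContexts = 0),
               "nContexts")
})

test_that("a three-way dataset round-trips through tidy CSV + sidecar", {
  ds <- smallCohortDataset(20, seed = 4)$dataset
  path <- tempfile(fileext = ".csv")
  writeThreeWay(ds, path)
  back <- readThreeWay(path)
  expect_equal(values(back), values(ds), ignore_attr = TRUE)
  expect_equal(subjects(back), subjects(ds))
  expect_equal(featureType(back), featureType(ds))
})
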