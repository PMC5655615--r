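test_that("CSV reading splits id, descriptor and activity columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,d1,d2,act", "a,1,2,0.5", "b,3,4,0.7", "c,5,6,0.9"), f)
  t <- readDescriptorCsv(f, idColumn = "id", activityColumns = "act")
  expect_equal(nCompounds(t), 3)
  expect_equal(descriptorNames(t), c("d1", "d2"))
  expect_equal(activityNames(t), "act")
  expect_equal(activityMatrix(t)[, "act"], c(0.5, 0.7, 0.9))

  ## ids synthesized when no id column is named
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("d1,act", "1,0.5", "3,0.7"), g)
  t2 <- readDescriptorCsv(g, activityColumns = "act")
  expect_equal(recordIds(t2), c("rec1", "rec2"))
  expect_equal(descriptorNames(t2), "d1")
})

test_that("CSV contract errors name the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,d1,d1,act", "a,1,2,0.5"), f)
  expect_error(readDescriptorCsv(f, "id", "act"), "duplicate")

  writeLines(c("id,d1,act", "a,1,0.5"), f)
  expect_error(readDescriptorCsv(f, "id", "missing"), "missing")

  writeLines(c("id,d1,act", "a,oops,0.5", "b,2,0.6"), f)
  expect_error(readDescriptorCsv(f, "id", "act"), "'oops'.*'d1'.*row 1")
})

test_that("CSV write uses '.' decimals, LF endings and round-trips exactly", {
  t <- makeRegressionFixture(n = 21, p = 10, signal = 1:2, beta = c(1, -2),
                             seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorCsv(t, f)
  raw <- readChar(f, file.size(f), useBytes = TRUE)
  expect_false(grepl("\r", raw))
  t2 <- readDescriptorCsv(f, idColumn = "id", activityColumns = "ACT")
  expect_identical(descriptorMatrix(t2), descriptorMatrix(t))
  expect_identical(activityMatrix(t2), activityMatrix(t))
  expect_identical(recordIds(t2), recordIds(t))

  ## 1x1 table is header + one row; 0.5 is written with a dot
  t1 <- DescriptorTable("a", cbind(d1 = 0.5), cbind(act = 1))
  writeDescriptorCsv(t1, f)
  expect_equal(readLines(f), c("id,d1,act", "a,0.5,1"))
})

test_that("shortest float formatting round-trips arbitrary doubles", {
  set.seed(42)
  x <- c(0.5, 1/3, pi, exp(-20), 1e300, -1.25, 0, 123456789.123,
         rnorm(200), runif(200) * 10^sample(-10:10, 200, TRUE))
  expect_identical(as.numeric(formatShortest(x)), x)
})

test_that("SDF reading builds the table and ids from titles", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeChar(makeToySdf(2, c("LOGK", "D1"), seed = 1), f, eos = NULL)
  t <- readDescriptorSdf(f, activityFields = "LOGK")
  expect_equal(nCompounds(t), 2)
  expect_equal(descriptorNames(t), "D1")
  expect_equal(activityNames(t), "LOGK")
  expect_equal(recordIds(t), c("MOL001", "MOL002"))
  expect_true(hasPayloads(t))
})

test_that("records missing a requested field error or are skipped", {
  txt <- makeToySdf(3, c("LOGK", "D1"), seed = 2)
  ## strip the LOGK item from record 2 only
  recs <- strsplit(txt, "(?<=\\$\\$\\$\\$\n)", perl = TRUE)[[1]]
  recs[2] <- gsub(">  <LOGK>\n[^\n]*\n\n", "", recs[2])
  f <- withr::local_tempfile(fileext = ".sdf")
  writeChar(paste0(recs, collapse = ""), f, eos = NULL)
  expect_error(readDescriptorSdf(f, "LOGK"), "record 2")
  expect_warning(t <- readDescriptorSdf(f, "LOGK", skipMissing = TRUE),
                 "dropping record 2")
  expect_equal(nCompounds(t), 2)
})

test_that("SDF round-trip is byte-identical for LF and CRLF dialects", {
  for (eol in c("\n", "\r\n")) {
    f <- withr::local_tempfile(fileext = ".sdf")
    writeChar(makeToySdf(4, c("LOGK", "D1", "D2"), seed = 3, eol = eol), f,
              eos = NULL)
    t <- readDescriptorSdf(f, "LOGK")
    g <- withr::local_tempfile(fileext = ".sdf")
    writeDescriptorSdf(t, g)
    expect_identical(readBin(g, "raw", file.size(g)),
                     readBin(f, "raw", file.size(f)))
  }
})

test_that("scrambling an SDF field rewrites only that field's value lines", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeChar(makeToySdf(6, c("LOGK", "D1"), seed = 4), f, eos = NULL)
  t <- readDescriptorSdf(f, "LOGK")
  set <- generateSets(t, RandomizationPlan("y_scramble", "LOGK",
                                           nSets = 1, masterSeed = 9))[[1]]
  g <- withr::local_tempfile(fileext = ".sdf")
  writeDescriptorSdf(set, g)
  a <- readLines(f); b <- readLines(g)
  expect_equal(length(a), length(b))
  changed <- which(a != b)
  ## every changed line must sit directly under a LOGK header
  expect_true(all(grepl("<LOGK>", a[changed - 1])))
  ## and the new file holds a permutation of the same activity values
  t2 <- readDescriptorSdf(g, "LOGK")
  expect_equal(sort(activityMatrix(t2)[, 1]), sort(activityMatrix(t)[, 1]))
  expect_identical(descriptorMatrix(t2), descriptorMatrix(t))
})

test_that("SDF output demands SDF input; row order is never permuted", {
  t <- makeRegressionFixture(n = 5, p = 2, seed = 5)
  expect_error(writeDescriptorSdf(t, tempfile()), "SDF output requires")

  f <- withr::local_tempfile(fileext = ".csv")
  writeDescriptorCsv(t, f)
  t2 <- readDescriptorCsv(f, "id", "ACT")
  expect_identical(recordIds(t2), recordIds(t))
})

test_that("blank molblock titles get synthesized stable ids", {
  txt <- makeToySdf(2, "LOGK", seed = 6)
  txt <- sub("^MOL001", "", txt)
  f <- withr::local_tempfile(fileext = ".sdf")
  writeChar(txt, f, eos = NULL)
  t <- readDescriptorSdf(f, "LOGK")
  expect_equal(recordIds(t), c("rec1", "MOL002"))
})
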