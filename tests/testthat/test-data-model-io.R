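test_that("feature tables parse identifiers, grouping and coordinates", {
  paths <- writeTinyTables()
  tab <- readFeatureTable(paths$features)
  expect_s4_class(tab, "IdrFeatureTable")
  expect_identical(dim(tab), c(3L, 2L))
  expect_identical(idrCounts(tab), c(A = 2L, B = 1L))
  expect_identical(featureNames(tab), c("f1", "f2"))
  expect_identical(idrIds(tab), c("A|1-45", "A|50-90", "B|10-30"))
  co <- idrCoordinates(tab)
  expect_identical(co$start, c(1L, 50L, 10L))
  expect_identical(co$end, c(45L, 90L, 30L))
  # ordinal dialect, comma-separated, is also accepted
  p2 <- file.path(withr::local_tempdir(), "ord.csv")
  writeLines(c("idr_id,f1", "P1|1,0.5", "P1|2,1.5", "Q9|1,-2"), p2)
  tab2 <- readFeatureTable(p2)
  expect_identical(idrCounts(tab2), c(P1 = 2L, Q9 = 1L))
  expect_true(all(is.na(idrCoordinates(tab2)$start)))
})

test_that("malformed feature tables raise located errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("idr_id\tf1\tf2", "A|1-45\t0.5\tx", "B|1-10\t1\t2"), bad)
  expect_error(readFeatureTable(bad), "row 1.*f2")
  writeLines(c("idr_id\tf1\tf2", "A|1-45\t0.5\t", "B|1-10\t1\t2"), bad)
  expect_error(readFeatureTable(bad), "row 1")
  writeLines(c("idr_id\tf1", "A|1-45\t1", "A|1-45\t2"), bad)
  expect_error(readFeatureTable(bad), "duplicate")
  writeLines(c("idr_id\tf1", "no_separator\t1"), bad)
  expect_error(readFeatureTable(bad), "\\|")
})

test_that("feature table round trip preserves values and row order", {
  set.seed(41)
  z <- matrix(rnorm(60) * 10^sample(-6:6, 60, TRUE), 10, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  tab <- IdrFeatureTable(z, proteinId = rep(sprintf("P%d", 1:5), each = 2))
  path <- file.path(withr::local_tempdir(), "rt.tsv")
  writeFeatureTable(tab, path)
  back <- readFeatureTable(path)
  expect_identical(idrIds(back), idrIds(tab))
  rel <- abs(featureMatrix(back) - featureMatrix(tab)) /
    pmax(abs(featureMatrix(tab)), 1e-300)
  expect_lt(max(rel), 1e-12)
})

test_that("annotation tables enforce binary cells and align by protein id", {
  paths <- writeTinyTables()
  ann <- readAnnotationTable(paths$annotations)
  expect_identical(functionNames(ann), c("fun1", "fun2"))
  expect_identical(annotationMatrix(ann)["A", "fun1"], 1L)
  bad <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines(c("protein_id\tfun1", "A\t2"), bad)
  expect_error(readAnnotationTable(bad), "0 or 1.*'2'")
  # all-zero table is valid
  writeLines(c("protein_id\tfun1\tfun2", "A\t0\t0", "B\t0\t0"), bad)
  expect_identical(sum(annotationMatrix(readAnnotationTable(bad))), 0L)
  # alignment is by protein id, not by row position
  tab <- makeCoordTable()
  y1 <- faidr:::.resolveLabels(tab, ann, "fun1")
  perm <- AnnotationTable(annotationMatrix(ann)[c("B", "A"), ])
  y2 <- faidr:::.resolveLabels(tab, perm, "fun1")
  expect_identical(y1, y2)
})

test_that("sites map onto IDR intervals with strict containment", {
  tab <- makeCoordTable()
  lab <- mapSitesToIdrs(data.frame(protein_id = "A", position = 10), tab)
  expect_identical(unname(lab), c(1L, 0L, 0L))
  # boundary: position 46 is outside 1-45, position 45 inside
  expect_identical(
    unname(mapSitesToIdrs(data.frame(protein_id = "A", position = 46), tab)),
    c(0L, 0L, 0L))
  expect_identical(
    unname(mapSitesToIdrs(data.frame(protein_id = "A", position = 45), tab)),
    c(1L, 0L, 0L))
  # two sites in one IDR still give a single 1 (binary, not a count)
  two <- mapSitesToIdrs(data.frame(protein_id = c("A", "A"),
                                   position = c(5, 20)), tab)
  expect_identical(unname(two), c(1L, 0L, 0L))
  # unknown protein: skipped with a warning naming the count
  expect_warning(
    mapSitesToIdrs(data.frame(protein_id = "ZZZ", position = 1), tab),
    "1 site")
})

test_that("site mapping is idempotent and monotone in the site list", {
  tab <- makeCoordTable()
  sites <- data.frame(protein_id = c("A", "B"), position = c(60, 15))
  l1 <- mapSitesToIdrs(sites, tab)
  l2 <- mapSitesToIdrs(rbind(sites, sites), tab)
  expect_identical(l1, l2)
  more <- rbind(sites, data.frame(protein_id = "A", position = 3))
  l3 <- mapSitesToIdrs(more, tab)
  expect_true(all(l3 >= l1))  # adding sites never clears a label
})

test_that("fit serialization round-trips at full precision", {
  sim <- generateSynthetic(nProteins = 40, mFeatures = 4, supportSize = 2,
                           effectSize = 3, seed = 2)
  fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                  faidrControl(lambda = 0.05))
  path <- file.path(withr::local_tempdir(), "fit.json")
  writeFit(fit, path)
  back <- readFit(path)
  expect_identical(back@coefficients, fit@coefficients)
  expect_identical(back@intercept, fit@intercept)
  expect_identical(back@responsibilities, fit@responsibilities)
  expect_identical(back@objectiveTrace, fit@objectiveTrace)
  expect_identical(back@nEmIterations, fit@nEmIterations)
  expect_identical(back@lambda, fit@lambda)

  # all-zero coefficient vectors survive too
  fit0 <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                   faidrControl(lambda = 50))
  expect_true(all(coef(fit0) == 0))
  writeFit(fit0, path)
  expect_identical(readFit(path)@coefficients, fit0@coefficients)
})

test_that("corrupt or mismatched fit files are rejected", {
  sim <- generateSynthetic(nProteins = 40, mFeatures = 3, supportSize = 1,
                           effectSize = 3, seed = 3)
  fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fit.json")
  writeFit(fit, path)
  txt <- readLines(path)
  writeLines(head(txt, length(txt) %/% 2), path)      # truncate
  expect_error(readFit(path), "truncated|parse")
  jsonlite::write_json(list(format = "faidr-fit/999"), path,
                       auto_unbox = TRUE)
  expect_error(readFit(path), "version mismatch")
  jsonlite::write_json(list(intercept = 1), path, auto_unbox = TRUE)
  expect_error(readFit(path), "version mismatch")
})

test_that("IDR label files round trip", {
  lab <- c("A|1-45" = 1L, "A|50-90" = 0L, "B|10-30" = 1L)
  path <- file.path(withr::local_tempdir(), "labels.tsv")
  writeIdrLabels(lab, path)
  expect_identical(readIdrLabels(path), lab)
})

test_that("class validity catches malformed objects", {
  z <- matrix(1:4 / 2, 2, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_error(IdrFeatureTable(rbind(z, c(NA, 1)), proteinId = c("A", "A", "B")),
               "finite")
  expect_error(IdrFeatureTable(z, proteinId = c("A", "A"),
                               start = c(5L, 2L), end = c(3L, 4L)),
               "start <= end")
  expect_error(AnnotationTable(matrix(2L, 1, 1, dimnames = list("A", "f"))),
               "0/1")
  expect_error(new("FaidrFit", functionName = "f",
                   coefficients = c(f1 = 0), intercept = 0,
                   responsibilities = c(0.4, 0.4), proteinId = c("A", "A"),
                   lambda = 0.2, alpha = 0.99, nEmIterations = 1L,
                   converged = TRUE, objectiveTrace = 0, control = list()),
               "sum to 1")
})
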