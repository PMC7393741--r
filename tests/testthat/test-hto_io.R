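test_that("MTX reader transposes CellRanger orientation and round-trips", {
  set.seed(101)
  counts <- matrix(rpois(20, 3), 5, 4,
                   dimnames = list(paste0("BC", 1:5), paste0("HTO", 1:4)))
  counts[sample(20, 6)] <- 0L
  dir <- withr::local_tempdir()
  write_hto_mtx(counts, dir) # writes features x barcodes, as CellRanger
  back <- read_hto_mtx(file.path(dir, "matrix.mtx"),
                       file.path(dir, "barcodes.tsv"),
                       file.path(dir, "features.tsv"))
  expect_identical(dim(back), c(5L, 4L))
  expect_equal(unname(back), unname(as_hto_matrix(counts)),
               ignore_attr = TRUE)
  expect_identical(rownames(back), paste0("BC", 1:5))
  expect_identical(colnames(back), paste0("HTO", 1:4))

  # a 3-feature x 5-barcode triplet yields n = 5 GEMs, M = 3 samples
  small <- matrix(1:15, 5, 3,
                  dimnames = list(paste0("G", 1:5), paste0("S", 1:3)))
  dir2 <- withr::local_tempdir()
  write_hto_mtx(small, dir2)
  got <- read_hto_mtx(file.path(dir2, "matrix.mtx"),
                      file.path(dir2, "barcodes.tsv"),
                      file.path(dir2, "features.tsv"))
  expect_identical(dim(got), c(5L, 3L))
})

test_that("MTX reader accepts gzip sidecars and feature selection", {
  counts <- matrix(c(10L, 0L, 3L, 25L, 7L, 1L), 3, 2,
                   dimnames = list(c("A", "B", "C"), c("HTO1", "HTO2")))
  dir <- withr::local_tempdir()
  paths <- write_hto_mtx(counts, dir)
  for (p in paths[c("barcodes", "features")]) {
    con <- gzfile(paste0(p, ".gz"), "w")
    writeLines(readLines(p), con)
    close(con)
    unlink(p)
  }
  back <- read_hto_mtx(paths[["matrix"]],
                       paste0(paths[["barcodes"]], ".gz"),
                       paste0(paths[["features"]], ".gz"))
  expect_equal(unname(back), unname(counts), ignore_attr = TRUE)

  sub <- read_hto_mtx(paths[["matrix"]],
                      paste0(paths[["barcodes"]], ".gz"),
                      paste0(paths[["features"]], ".gz"),
                      features = "HTO2")
  expect_identical(colnames(sub), "HTO2")
  expect_error(
    read_hto_mtx(paths[["matrix"]], paste0(paths[["barcodes"]], ".gz"),
                 paste0(paths[["features"]], ".gz"), features = "HTO9"),
    "not present")
})

test_that("MTX reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.mtx")
  file.create(empty)
  writeLines(c("A", "B"), file.path(dir, "barcodes.tsv"))
  writeLines("HTO1", file.path(dir, "features.tsv"))
  expect_error(read_hto_mtx(empty, file.path(dir, "barcodes.tsv"),
                            file.path(dir, "features.tsv")))

  counts <- matrix(1:6, 3, 2,
                   dimnames = list(c("A", "B", "C"), c("H1", "H2")))
  paths <- write_hto_mtx(counts, dir)
  writeLines(c("A", "B"), paths[["barcodes"]]) # wrong length
  expect_error(read_hto_mtx(paths[["matrix"]], paths[["barcodes"]],
                            paths[["features"]]), "do not match")
})

test_that("CSV reader parses the standard table layout and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,HTO 1,HTO 2,HTO 3",
               "ACTAGGACCA,204,57,23",
               "TCGGACTCGG,56,123,15",
               "GCAGTAGGCA,742,593,14",
               "CCAGACATGA,31,74,739",
               "CCTAGACTTA,2,115,33"), path)
  m <- read_hto_csv(path)
  expect_identical(dim(m), c(5L, 3L))
  expect_identical(rownames(m)[1], "ACTAGGACCA")
  expect_identical(m["GCAGTAGGCA", "HTO 2"], 593L)

  one <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,HTO1", "AAA,7"), one)
  expect_identical(dim(read_hto_csv(one)), c(1L, 1L))

  set.seed(7)
  counts <- matrix(rpois(40, 20), 10, 4,
                   dimnames = list(paste0("BC", 1:10), paste0("S", 1:4)))
  rt <- withr::local_tempfile(fileext = ".csv")
  write_hto_csv(counts, rt)
  expect_equal(unname(read_hto_csv(rt)), unname(counts),
               ignore_attr = TRUE)
})

test_that("CSV reader rejects duplicates and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,H1", "AAA,1", "AAA,2"), path)
  expect_error(read_hto_csv(path), "duplicate")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,H1", "AAA,x"), path2)
  expect_error(read_hto_csv(path2))
})

test_that("MTX and CSV readers agree on the same logical content", {
  set.seed(21)
  counts <- matrix(rpois(30, 8), 6, 5,
                   dimnames = list(paste0("BC", 1:6), paste0("H", 1:5)))
  dir <- withr::local_tempdir()
  paths <- write_hto_mtx(counts, dir)
  csv <- file.path(dir, "m.csv")
  write_hto_csv(counts, csv)
  expect_identical(read_hto_mtx(paths[["matrix"]], paths[["barcodes"]],
                                paths[["features"]]),
                   read_hto_csv(csv))
})

test_that("HTO matrix validation enforces the count invariants", {
  expect_error(as_hto_matrix(matrix(-1, 1, 1)), "non-negative")
  expect_error(as_hto_matrix(matrix(1.5, 1, 1)), "integral")
  expect_error(as_hto_matrix(matrix(1, 2, 1,
                                    dimnames = list(c("A", "A"), "H"))),
               "duplicate")
  expect_error(as_hto_matrix(matrix(1L, 1, 1,
                                    dimnames = list("A", "H+1"))), "'\\+'")
})

test_that("demux output files carry all 2^M + 1 labels and round-trip", {
  sim <- sim_hashing(sim_config(n_droplets = 1200, msm_fraction = 0.3,
                                seed = 5))
  fit <- demux(sim$counts, total_cells = 1500, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_demux_outputs(fit, dir)
  cls <- read.csv(paths[["classification"]], check.names = FALSE)
  expect_identical(nrow(cls), nrow(sim$counts))
  # with M = 4 at most 2^4 + 1 = 17 distinct labels can occur
  expect_lte(length(unique(cls$class)), 17L)
  expect_true(all(cls$confidence >= 0 & cls$confidence <= 1))

  summ <- read.csv(paths[["summary"]])
  expect_equal(summ$value[summ$key == "X"], fit$params$X,
               tolerance = 1e-8)
  expect_equal(summ$value[summ$key == "r_cap"], fit$params$r_cap,
               tolerance = 1e-8)
  rates <- read.csv(paths[["sample_rates"]])
  expect_identical(rates$sample, names(fit$observed$z))
  expect_equal(rates$rssm_pct, 100 * fit$rates$rssm_sample,
               tolerance = 1e-8, ignore_attr = TRUE)

  fit$classification <- fit$classification[0, ]
  expect_error(write_demux_outputs(fit, dir), "empty")
})
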