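test_that("the default intact scheme matches the printed design", {
  sch <- intact_scheme()
  expect_equal(nrow(sch), 5)
  expect_equal(sch$width, c(1.25, 2.2, 3.5, 8, 35))
  expect_equal(sch$spacing, c(1, 2, 5, 10, 50))
  expect_equal(n_bins(sch), 3060)
  # per-range center counts and the anchor/end rule of range 1
  counts <- table(attr(sch, "range_index"))
  expect_equal(as.vector(counts), c(1000, 500, 900, 500, 160))
  r1 <- bin_centers(sch)[attr(sch, "range_index") == 1]
  expect_equal(r1[1], 500)
  expect_equal(r1[length(r1)], 1499)
})

test_that("the default digested scheme matches the printed design", {
  sch <- digested_scheme()
  expect_equal(nrow(sch), 6)
  expect_true(all(sch$width == 0.5))
  expect_true(all(sch$spacing == 1))
  expect_equal(n_bins(sch), 6794)
  r1 <- bin_centers(sch)[attr(sch, "range_index") == 1]
  expect_equal(range(r1), c(200, 998))
  # labels are fixed by the scheme alone
  expect_identical(bin_labels(sch), bin_labels(digested_scheme()))
})

test_that("bin_scheme rejects invalid range definitions", {
  expect_error(bin_scheme(10, 5, 1, 1), "start < end")
  expect_error(bin_scheme(c(0, 50), c(100, 150), 1, 1), "non-overlapping")
  expect_error(bin_scheme(0, 10, -1, 1), "width and spacing")
})

test_that("assign_bin applies tolerance, gaps and lower-center tie rule", {
  dig <- digested_scheme()
  expect_equal(assign_bin(1000.2, dig), "1000")
  expect_true(is.na(assign_bin(1000.4, dig)))          # 0.4 > 0.5/2
  expect_true(is.na(assign_bin(25000, intact_scheme())))  # outside ranges
  expect_true(is.na(assign_bin(999.5, dig)))  # 999-1000 seam not covered
  # exact midpoint between centers 500 and 501 (intact range 1 overlaps:
  # width 1.25 > spacing 1) resolves to the lower center
  expect_equal(assign_bin(500.5, intact_scheme()), "500")
  expect_equal(assign_bin(c(200, 998.2), dig, value = "center"),
               c(200, 998))
  expect_error(assign_bin(-5, dig), "> 0")
})

test_that("assign_bin agrees with the brute-force nearest-center oracle", {
  set.seed(101)
  for (sch in list(intact_scheme(), digested_scheme())) {
    lo <- min(sch$start) - 50
    hi <- max(sch$end) + 50
    mz <- runif(4000, lo, hi)
    expect_identical(assign_bin(mz, sch), brute_force_assign(mz, sch))
  }
  # a custom scheme with awkward spacings
  sch <- bin_scheme(c(100, 400), c(250, 1000), c(3, 12), c(7, 25))
  mz <- runif(2000, 50, 1100)
  expect_identical(assign_bin(mz, sch), brute_force_assign(mz, sch))
})

test_that("encoding follows the presence / max-intensity rules", {
  dig <- digested_scheme()
  pl <- peaklist(c(1000.2, 1000.1), c(50, 70), mode = "digested")
  bin_row <- encode_peaklist(pl, dig, "binary")
  expect_equal(sum(bin_row), 1)
  expect_equal(unname(bin_row["1000"]), 1)
  int_row <- encode_peaklist(pl, dig, "intensity")
  expect_equal(unname(int_row["1000"]), 70)      # max within bin
  expect_equal(unname(encode_peaklist(pl, dig, "intensity",
                                      aggregate = "sum")["1000"]), 120)
  # empty list encodes to all zeros
  expect_true(all(encode_peaklist(peaklist(mode = "digested"), dig) == 0))
  # binary encoding is invariant to monotone intensity rescaling
  pl2 <- peaklist(pl$peaks$mz, pl$peaks$intensity^3 + 1, mode = "digested")
  expect_identical(encode_peaklist(pl2, dig, "binary"), bin_row)
})

test_that("feature tables have scheme-fixed columns and manifest order", {
  dir <- withr::local_tempdir()
  m <- make_tmp_dataset(dir, n = 2)
  dig <- digested_scheme()
  train <- build_feature_table(m, "train", dig, "binary")
  score <- build_feature_table(m, "score", dig, "binary")
  expect_equal(dim(train$x), c(4, 6794))
  expect_true(all(train$x %in% 0:1))
  expect_identical(colnames(train$x), colnames(score$x))
  expect_identical(colnames(train$x), bin_labels(dig))
  expect_equal(rownames(train$x), m$spot_id[m$role == "train"])
  # the positive-class marker bins differ between classes
  expect_true(all(train$x[train$label == "positive", "800"] == 1))
  expect_true(all(train$x[train$label == "negative", "800"] == 0))
})

test_that("mode/scheme mismatches error unless forced", {
  dir <- withr::local_tempdir()
  m <- make_tmp_dataset(dir, n = 2, mode = "digested")
  expect_error(build_feature_table(m, "train", intact_scheme(), "binary"),
               "force")
  expect_silent(suppressWarnings(
    build_feature_table(m, "train", intact_scheme(), "binary",
                        force = TRUE)))
  # a spot with all peaks out of scheme range yields an all-zero row
  f <- file.path(dir, "far.csv")
  write_peaklist(peaklist(150, 5, mode = "digested"), f)
  m2 <- spot_manifest(c(m$spot_id, "far"), c(m$file, f),
                      c(m$label, "positive"), c(m$role, "train"),
                      c(m$mode, "digested"))
  expect_warning(ft <- build_feature_table(m2, "train", digested_scheme(),
                                           "binary"),
                 "outside the scheme")
  expect_true(all(ft$x["far", ] == 0))
})

test_that("schemes serialize to plain text and back", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scheme.csv")
  write_scheme(intact_scheme(), path)
  back <- read_scheme(path)
  expect_equal(as.data.frame(back), as.data.frame(intact_scheme()))
  expect_equal(bin_labels(back), bin_labels(intact_scheme()))
})

test_that("check_jitter flags widths narrower than 4 jitter sigmas", {
  # defaults respect the guiding principle for both default schemes
  expect_silent(res <- check_jitter(intact_scheme(), 1.8e-4))
  expect_true(all(res$ok))
  expect_silent(res <- check_jitter(digested_scheme(), 2e-5))
  expect_true(all(res$ok))
  # a jitter too large for the digested tolerances warns
  expect_warning(check_jitter(digested_scheme(), 2e-4), "4 \\* jitter")
})
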