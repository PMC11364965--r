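test_that("peak tables read with the m/z, RT, intensities layout", {
  path <- write_temp_csv(data.frame(mz = c(100.1, 200.2, 300.3),
                                    rt = c(1, 2, 3),
                                    s1 = c(10, 20, 30), s2 = c(1, 2, 3)))
  pt <- read_peak_table(path)
  expect_s3_class(pt, "peak_table")
  expect_equal(nrow(pt), 3L)
  expect_equal(attr(pt, "sample_names"), c("s1", "s2"))
  expect_equal(pt$mz, c(100.1, 200.2, 300.3))
  expect_equal(pt$row_index, 1:3)
})

test_that("size limit, column count and numeric checks are enforced", {
  path <- write_temp_csv(data.frame(mz = runif(100, 100, 1000),
                                    rt = runif(100, 0, 20)))
  expect_error(read_peak_table(path, max_bytes = 64), "byte limit")
  expect_s3_class(read_peak_table(path, max_bytes = Inf), "peak_table")

  one_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz", "100.5"), one_col)
  expect_error(read_peak_table(one_col), "at least 2 columns")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt", "100.5,1.0", "oops,2.0"), bad)
  expect_error(read_peak_table(bad), "row\\(s\\): 2")

  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("mz,rt,s1", header_only)
  expect_warning(pt <- read_peak_table(header_only), "no features")
  expect_equal(nrow(pt), 0L)
})

test_that("tolerances convert to Daltons at the reference m/z", {
  expect_equal(tolerance_in_da(tolerance(0.02, "da"), 123.4), 0.02)
  expect_equal(tolerance_in_da(tolerance(10, "ppm"), 500), 0.005)
  expect_equal(tolerance_in_da(tolerance(5, "ppm"), 200), 0.001)
  expect_error(tolerance(-1, "da"))
})

test_that("percent RT match follows the relative-deviation formula", {
  expect_equal(rt_match_percent(4.20, 4.20), 100)
  expect_equal(rt_match_percent(3.94, 4.20), 100 * (1 - 0.26 / 4.20))
  expect_equal(round(rt_match_percent(3.94, 4.20), 2), 93.81)
  expect_equal(rt_match_percent(20, 4), 0)  # clipped
  expect_error(rt_match_percent(1, 0), "undefined")
})

test_that("matching agrees with the brute-force oracle on random instances", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:100, 1)
    m <- sample(1:100, 1)
    db <- compound_db(data.frame(
      name = paste0("c", seq_len(m)), class = "x",
      monoisotopic_mass = runif(m, 100, 600),
      predicted_rt = runif(m, 1, 10)))
    rs <- builtin_ruleset(sample(c("monoisotopic", "mh"), 1))
    entries <- expand_database(db, rs)
    # half the features sit near real entries, half anywhere
    near <- sample(entries$theoretical_mz, ceiling(n / 2), replace = TRUE) +
      runif(ceiling(n / 2), -0.05, 0.05)
    pt <- peak_table(mz = c(near, runif(floor(n / 2), 100, 600)),
                     rt = runif(n, 0, 12))
    tol <- if (runif(1) < 0.5) tolerance(runif(1, 0.005, 0.05), "da")
           else tolerance(runif(1, 5, 80), "ppm")
    got <- match_features(pt, entries, tol)
    expect_identical(match_keys(got), match_keys(brute_force_match(pt, entries, tol)))
  }
})

test_that("annotation sets grow monotonically with tolerance", {
  set.seed(7)
  db <- compound_db(data.frame(name = paste0("c", 1:40), class = "x",
                               monoisotopic_mass = runif(40, 100, 500)))
  entries <- expand_database(db, "mh")
  pt <- peak_table(mz = runif(60, 100, 520), rt = runif(60, 0, 10))
  tols <- c(0.001, 0.01, 0.05, 0.2, 1)
  keys <- lapply(tols, function(t)
    match_keys(match_features(pt, entries, tolerance(t, "da"))))
  for (i in seq_along(tols)[-1]) {
    expect_true(all(keys[[i - 1]] %in% keys[[i]]))
  }
})

test_that("ppm matching equals the equivalent Da tolerance at a fixed entry", {
  db <- compound_db(data.frame(name = "one", class = "x",
                               monoisotopic_mass = 400))
  entries <- expand_database(db, "monoisotopic")
  mu <- entries$theoretical_mz[1]
  p <- 25
  da_equiv <- mu * p / 1e6
  # features at, inside, and outside the boundary (both sides)
  pt <- peak_table(mz = c(mu - 2 * da_equiv, mu - da_equiv, mu,
                          mu + da_equiv, mu + 2 * da_equiv),
                   rt = rep(1, 5))
  k_ppm <- match_keys(match_features(pt, entries, tolerance(p, "ppm")))
  k_da <- match_keys(match_features(pt, entries, tolerance(da_equiv, "da")))
  expect_identical(k_ppm, k_da)
  got <- match_features(pt, entries, tolerance(p, "ppm"))
  expect_setequal(got$row_index, 2:4)  # boundary inclusive both ways
})

test_that("isobaric entries all annotate the same feature", {
  db <- compound_db(data.frame(name = c("iso1", "iso2"), class = "x",
                               monoisotopic_mass = c(250.1000, 250.1005)))
  entries <- expand_database(db, "monoisotopic")
  pt <- peak_table(mz = 250.1002, rt = 1)
  got <- match_features(pt, entries, tolerance(0.02, "da"))
  expect_equal(nrow(got), 2L)
  expect_true(all(got$msi_level == 3L))
})

test_that("ranking orders by feature, then RT match, then |delta m/z|", {
  ann <- data.frame(
    row_index = c(2L, 1L, 1L, 1L, 1L),
    mz = 1, rt = 1,
    compound = c("e", "b", "a", "c", "d"),
    rule = "M",
    theoretical_mz = 1,
    delta_mz = c(0.001, 0.004, 0.002, 0.002, 0.003),
    predicted_rt = c(1, 2, 2, 2, NA),
    rt_match_pct = c(50, 60, 95, 95, NA),
    stringsAsFactors = FALSE)
  r <- rank_annotations(ann)
  expect_equal(r$compound, c("a", "c", "b", "d", "e"))
  expect_equal(r$row_index, c(1L, 1L, 1L, 1L, 2L))
  # permutation, nothing gained or lost
  expect_setequal(paste(ann$compound, ann$row_index),
                  paste(r$compound, r$row_index))
  expect_equal(nrow(rank_annotations(ann[0, ])), 0L)
})

test_that("deduplication keys on (compound, rule) and is idempotent", {
  ann <- data.frame(
    row_index = 1:5,
    compound = c("x", "x", "x", "y", "y"),
    rule = c("M+OH", "M+OH", "M+CH3", "M+OH", "M+OH"),
    stringsAsFactors = FALSE)
  d <- dedup_compounds(ann)
  expect_equal(nrow(d), 3L)  # x/M+OH, x/M+CH3, y/M+OH
  expect_equal(d$row_index, c(1L, 3L, 4L))
  expect_identical(dedup_compounds(d), d)
  all_unique <- data.frame(row_index = 1:3, compound = c("a", "b", "c"),
                           rule = "M", stringsAsFactors = FALSE)
  expect_equal(nrow(dedup_compounds(all_unique)), 3L)
})

test_that("match rate counts dedup hits over the reference list", {
  ref <- data.frame(name = paste0("r", 1:20), mz = seq(100, 481, by = 20))
  # 22 dedup'd annotations all landing on reference masses -> 110%
  ann <- data.frame(
    row_index = 1:22,
    mz = c(ref$mz, ref$mz[1:2] + 0.001),
    compound = paste0("c", 1:22), rule = "M",
    stringsAsFactors = FALSE)
  expect_equal(match_rate(ann, ref, tolerance(0.02, "da")), 110)
  # exactly one per reference -> 100%
  expect_equal(match_rate(ann[1:20, ], ref, tolerance(0.02, "da")), 100)
  # no overlap -> 0
  off <- ann[1:5, ]
  off$mz <- off$mz + 5
  expect_equal(match_rate(off, ref, tolerance(0.02, "da")), 0)
  expect_error(match_rate(ann, ref[0, ]), "empty reference")
})

test_that("screen composes the pipeline end to end", {
  db <- fixture_compounds()
  # experimental m/z values printed for biotransformed hormones, one sample col
  pt <- peak_table(mz = c(262.1596, 234.1195, 266.0744, 369.1448),
                   rt = c(3.6688, 5.7546, 5.4249, 3.4826),
                   intensities = data.frame(s1 = c(4, 3, 2, 1)))
  res <- screen(pt, db, ruleset = "biotransformations",
                tol = tolerance(0.02, "da"))
  expect_true(all(c("s1", "rt_match_pct", "theoretical_mz") %in% names(res)))
  hits <- paste(res$compound, res$rule)
  expect_true("Abscisic acid (ABA) M-OH+CH3" %in% hits)
  expect_true("Melatonin (MEL) M-CH3+OH" %in% hits)
  expect_true("2-methylthio-cis-zeatin M-NH2+OH" %in% hits)
  expect_true("Feruloyl serotonin M+OH" %in% hits)
  # empty peak table screens to an empty result
  empty <- screen(peak_table(numeric(0), numeric(0)), db, ruleset = "mh")
  expect_equal(nrow(empty), 0L)
})

test_that("unannotated features can be kept on request", {
  db <- tiny_db()
  pt <- peak_table(mz = c(db$monoisotopic_mass[1], 999.9), rt = c(4.2, 1))
  res <- screen(pt, db, ruleset = "monoisotopic", keep_unannotated = TRUE)
  expect_true(2L %in% res$row_index)
  expect_true(is.na(res$compound[res$row_index == 2L]))
})

test_that("screener CSV uses the display headers", {
  db <- tiny_db()
  pt <- peak_table(mz = db$monoisotopic_mass[1], rt = 4.0,
                   intensities = data.frame(leaf = 100))
  res <- screen(pt, db, ruleset = "monoisotopic")
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(res, path)
  out <- utils::read.csv(path, check.names = FALSE)
  expect_true(all(c("Compound name", "Biotransformation", "Actual m/z",
                    "Experimental m/z", "Experimental RT", "Predicted RT",
                    "%RT match", "leaf") %in% names(out)))
})
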