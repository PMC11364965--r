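make_ann <- function(rt_match_pct, rt = 5) {
  data.frame(row_index = seq_along(rt_match_pct), mz = 200, rt = rt,
             compound = paste0("c", seq_along(rt_match_pct)), rule = "M+H",
             delta_mz = 0, rt_match_pct = rt_match_pct,
             stringsAsFactors = FALSE)
}

test_that("retention rules apply strict thresholds per gradient status", {
  ann <- make_ann(c(95, 70, 40))
  expect_equal(apply_retention_rules(ann, "same_as_reference")$rt_match_pct, 95)
  expect_equal(apply_retention_rules(ann, "different")$rt_match_pct, c(95, 70))
  # 50 is not kept under 'different' (strict >)
  expect_equal(nrow(apply_retention_rules(make_ann(50), "different")), 0L)
  # direct injection keeps everything, including unscored rows
  ann$rt_match_pct[2] <- NA
  expect_equal(nrow(apply_retention_rules(ann, "direct_injection")), 3L)
})

test_that("the not-provided rule keeps RTs in (1, reequil_start)", {
  ann <- make_ann(c(NA, NA, NA), rt = c(0.5, 3.0, 16.0))
  kept <- apply_retention_rules(ann, "not_provided", reequil_start = 15)
  expect_equal(kept$rt, 3.0)
  # boundary is strict on both sides
  edge <- make_ann(c(NA, NA), rt = c(1, 15))
  expect_equal(nrow(apply_retention_rules(edge, "not_provided", 15)), 0L)
})

test_that("unscored annotations are dropped with a warning under % rules", {
  ann <- make_ann(c(80, NA))
  expect_warning(kept <- apply_retention_rules(ann, "same_as_reference"),
                 "without an RT match")
  expect_equal(kept$rt_match_pct, 80)
})

test_that("filtering never increases counts, over all rule branches", {
  set.seed(5)
  for (i in 1:20) {
    ann <- make_ann(sample(c(NA, 10, 55, 75, 95), 8, replace = TRUE),
                    rt = runif(8, 0, 20))
    for (gs in c("same_as_reference", "different", "not_provided",
                 "direct_injection")) {
      kept <- suppressWarnings(apply_retention_rules(ann, gs))
      expect_lte(nrow(kept), nrow(ann))
    }
  }
})

test_that("screen_study recovers spiked compounds inside the RT window", {
  db <- fixture_compounds()
  eligible <- db[!is.na(db$predicted_rt), ][1:10, ]
  sim <- simulate_peak_table(db, data.frame(compound = eligible$name,
                                            rule = "M+H"),
                             seed = 42)
  path <- write_temp_csv(as.data.frame(sim$peaks)[, -1])
  cfg <- list(study_id = "SYN001", gradient_status = "same_as_reference",
              peak_table_path = path)
  got <- screen_study(cfg, db)
  expect_true(all(eligible$name %in% got$compound))
  expect_true(all(got$rt_match_pct > 70))
  expect_equal(anyDuplicated(paste(got$compound, got$rule)), 0L)
  # RTs shifted far outside the window -> nothing survives
  shifted <- as.data.frame(sim$peaks)[, -1]
  shifted[[2]] <- shifted[[2]] + 15
  path2 <- write_temp_csv(shifted)
  cfg2 <- list(study_id = "SYN002", gradient_status = "same_as_reference",
               peak_table_path = path2)
  expect_equal(nrow(screen_study(cfg2, db)), 0L)
  # duplicate spikes of one compound count once
  sim3 <- simulate_peak_table(db, data.frame(
    compound = rep(eligible$name[1], 3), rule = "M+H"),
    seed = 7)
  path3 <- write_temp_csv(as.data.frame(sim3$peaks)[, -1])
  got3 <- screen_study(list(study_id = "SYN003",
                            gradient_status = "same_as_reference",
                            peak_table_path = path3), db)
  expect_equal(sum(got3$compound == eligible$name[1] & got3$rule == "M+H"), 1L)
})

test_that("unreadable study tables are skipped with a warning", {
  cfg <- list(study_id = "GONE", gradient_status = "different",
              peak_table_path = "/nonexistent/peaks.csv")
  expect_warning(res <- screen_study(cfg, fixture_compounds()), "skipped")
  expect_null(res)
})

test_that("class summaries count deduplicated compounds per class", {
  db <- fixture_compounds()
  ann <- data.frame(
    compound = c("Zeatin", "Kinetin", "6-Benzylaminopurine",
                 "Indole-3-acetic acid", "Indole-3-butyric acid"),
    rule = "M+H", row_index = 1:5, stringsAsFactors = FALSE)
  s <- class_summary(list(STUDY1 = ann), db)
  expect_equal(s$STUDY1[s$class == "cytokinins"], 3L)
  expect_equal(s$STUDY1[s$class == "auxins"], 2L)
  expect_equal(names(s)[1:2], c("class", "database_total"))
  # database totals come from the catalogue itself
  expect_equal(s$database_total[s$class == "tryptophan metabolism"],
               sum(db$class == "tryptophan metabolism"))
  # empty results give an all-zero column
  s0 <- class_summary(list(EMPTY = ann[0, ]), db)
  expect_true(all(s0$EMPTY == 0L))
  # order invariance
  s_rev <- class_summary(list(STUDY1 = ann[5:1, ]), db)
  expect_identical(s$STUDY1, s_rev$STUDY1)
})

test_that("unknown compounds are binned as unclassified with a warning", {
  db <- fixture_compounds()
  ann <- data.frame(compound = c("Zeatin", "mystery-42"), rule = "M+H",
                    row_index = 1:2, stringsAsFactors = FALSE)
  expect_warning(s <- class_summary(list(S = ann), db), "unclassified")
  expect_equal(s$S[s$class == "unclassified"], 1L)
  expect_equal(s$database_total[s$class == "unclassified"], 0L)
})

test_that("manifests validate gradient status and default reequil_start", {
  path <- write_temp_csv(data.frame(
    study_id = "ST1", species = "maize", ionization = "ESI_pos",
    gradient_status = "different", peak_table_path = "x.csv"))
  mf <- read_study_manifest(path)
  expect_equal(mf$reequil_start, 15)
  bad <- write_temp_csv(data.frame(
    study_id = "ST1", species = "maize", ionization = "ESI_pos",
    gradient_status = "sideways", peak_table_path = "x.csv"))
  expect_error(read_study_manifest(bad), "sideways")
})

test_that("meta_analysis composes screening and summarising over a manifest", {
  db <- fixture_compounds()
  # spike compounds whose masses are isolated, so counts are exact
  set1 <- c("Zeatin", "Serotonin", "Melatonin (MEL)", "Histidine", "Kinetin",
            "Jasmonic acid")
  set2 <- c("Indole-3-acetic acid", "6-Benzylaminopurine", "Coumaric acid",
            "Ferulic acid", "Quercetin", "Anthranilic acid")
  sim1 <- simulate_peak_table(db, data.frame(compound = set1, rule = "M+H"),
                              seed = 1)
  sim2 <- simulate_peak_table(db, data.frame(compound = set2, rule = "M+H"),
                              seed = 2)
  p1 <- write_temp_csv(as.data.frame(sim1$peaks)[, -1])
  p2 <- write_temp_csv(as.data.frame(sim2$peaks)[, -1])
  manifest <- data.frame(
    study_id = c("S1", "S2"), species = "x",
    ionization = "ESI_pos",
    gradient_status = "same_as_reference",
    peak_table_path = c(p1, p2), reequil_start = 15,
    stringsAsFactors = FALSE)
  res <- meta_analysis(manifest, db)
  expect_named(res, c("per_study", "summary"))
  expect_equal(sum(res$summary$S1), 6L)
  expect_equal(sum(res$summary$S2), 6L)
})
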