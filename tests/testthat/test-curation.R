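raw_rows <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  d$assay_type <- "IC50"
  d
}

test_that("pIC50 conversion matches the molar definition and round-trips", {
  expect_equal(ic50_to_pic50(1000), 6)
  expect_equal(ic50_to_pic50(1), 9)
  expect_equal(ic50_to_pic50(10000), 5)
  ic50 <- c(0.3, 7, 1500, 99999)
  expect_equal(10^(9 - ic50_to_pic50(ic50)), ic50)
  # strictly decreasing
  expect_true(all(diff(ic50_to_pic50(sort(ic50))) < 0))
  expect_error(ic50_to_pic50(0), "positive")
  expect_error(ic50_to_pic50(-5), "positive")
})

test_that("labeling thresholds: >6 active, <5 inactive, [5,6] intermediate", {
  expect_equal(label_compound(6.5), "active")
  expect_equal(label_compound(4.2), "inactive")
  expect_equal(label_compound(5.5), "intermediate")
  expect_equal(label_compound(c(5, 6)), c("intermediate", "intermediate"))
  expect_error(label_compound(NaN), "finite")
})

test_that("filter_rows drops censored relations, duplicates and noisy replicates", {
  rows <- raw_rows(
    compound_id = c("a", "b", "c"), smiles = c("C", "CC", "CCC"),
    relation = c("=", ">", "="), ic50_nM = c(10, 20, 30))
  out <- filter_rows(rows)
  expect_equal(nrow(out), 2)
  expect_setequal(out$compound_id, c("a", "c"))

  dup <- raw_rows(compound_id = c("a", "a"), smiles = "C",
                  relation = "=", ic50_nM = c(10, 10))
  expect_equal(nrow(filter_rows(dup)), 1)

  # replicates 10 nM and 10000 nM: pIC50 8 and 5, SD ~= 2.12 > 2 -> dropped
  expect_equal(sd(c(8, 5)), 2.1213, tolerance = 1e-4)
  noisy <- raw_rows(compound_id = c("x", "x", "y"), smiles = "C",
                    relation = "=", ic50_nM = c(10, 10000, 50))
  out <- filter_rows(noisy)
  expect_equal(out$compound_id, "y")
  rep <- attr(out, "curation_report")
  expect_equal(rep$dropped_replicate_sd, 1)

  # consistent replicates are collapsed to the mean pIC50
  twins <- raw_rows(compound_id = c("z", "z"), smiles = "C",
                    relation = "=", ic50_nM = c(100, 1000))
  out <- filter_rows(twins)
  expect_equal(out$pic50, mean(c(7, 6)))
})

test_that("filtering is idempotent and errors on empty/filtered-out input", {
  rows <- raw_rows(
    compound_id = c("a", "a", "b", "c", "d"), smiles = "C",
    relation = c("=", "=", "<", "=", "="), ic50_nM = c(10, 12, 5, NA, 77))
  once <- filter_rows(rows)
  twice <- filter_rows(once)
  expect_equal(twice[names(once)], once, ignore_attr = TRUE)
  expect_error(filter_rows(data.frame()), "non-empty")
  allbad <- raw_rows(compound_id = "a", smiles = "C", relation = ">", ic50_nM = 5)
  expect_error(filter_rows(allbad), "filtered out")
})

test_that("curation drops intermediates and reports class counts", {
  rows <- raw_rows(
    compound_id = letters[1:4], smiles = "C", relation = "=",
    ic50_nM = c(10, 5000, 1e5, 1))  # pIC50 8, 5.3, 4, 9
  recs <- curate_bioactivity(rows)
  expect_equal(nrow(recs), 3)
  expect_false(any(recs$label == "intermediate"))
  rep <- attr(recs, "curation_report")
  expect_equal(rep$dropped_intermediate, 1)
  expect_equal(rep$n_active, 2)
  expect_equal(rep$n_inactive, 1)
})

test_that("train/test split is exact, disjoint and seed-deterministic", {
  tab <- generate_bioactivity_table(400, active_frac = 0.75, seed = 5)
  recs <- curate_bioactivity(tab)
  n_act <- sum(recs$label == "active"); n_ina <- sum(recs$label == "inactive")
  sp <- split_train_test(recs, 40, 10, seed = 9)
  expect_equal(sp$counts$test_active, 40)
  expect_equal(sp$counts$test_inactive, 10)
  expect_equal(sp$counts$train_active, n_act - 40)
  expect_equal(sp$counts$train_inactive, n_ina - 10)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0)
  sp2 <- split_train_test(recs, 40, 10, seed = 9)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  sp3 <- split_train_test(recs, 0, 0, seed = 9)
  expect_equal(nrow(sp3$test), 0)
  expect_equal(nrow(sp3$train), nrow(recs))
  expect_error(split_train_test(recs, nrow(recs) + 1, 0, seed = 1), "exceed")
})

test_that("the published-scale split arithmetic holds (1314/275 minus 263/55)", {
  recs <- data.frame(
    compound_id = sprintf("c%04d", 1:(1314 + 275)), smiles = "C",
    pic50 = c(rep(7, 1314), rep(4, 275)),
    label = c(rep("active", 1314), rep("inactive", 275)))
  sp <- split_train_test(recs, 263, 55, seed = 1)
  expect_equal(sp$counts$train_active, 1051)
  expect_equal(sp$counts$train_inactive, 220)
})

test_that("bioactivity CSV round-trip and split serialization", {
  dir <- withr::local_tempdir()
  tab <- generate_bioactivity_table(60, seed = 2)
  csv <- file.path(dir, "raw.csv")
  names(tab)[1] <- "id"
  write.csv(tab, csv, row.names = FALSE)
  back <- read_bioactivity_csv(csv)
  expect_equal(nrow(back), nrow(tab))
  recs <- curate_bioactivity(back)
  sp <- split_train_test(recs, 5, 2, seed = 1)
  paths <- write_split(sp, dir, report = attr(recs, "curation_report"))
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[["report"]])
  expect_equal(rep$test_active, 5)
})
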