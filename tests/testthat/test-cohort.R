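# Cohort data model: label rule, patient typing, file I/O, standardization,
# splitting and table summaries.

test_that("label rule handles events, survivors and early censoring", {
  spec <- label_spec(60)
  expect_equal(assign_label(list(time_months = 40, event = 1), spec), "poor")
  expect_equal(assign_label(list(time_months = 70, event = 0), spec), "good")
  expect_equal(assign_label(list(time_months = 40, event = 0), spec), "undefined")
  # boundary: surviving exactly to the horizon counts as good
  expect_equal(assign_label(list(time_months = 60, event = 1), spec), "good")
  expect_error(assign_label(list(time_months = -1, event = 1), spec), "negative")
  expect_error(label_spec(horizon_months = 0))
})

test_that("an observed event never leaves the label undefined", {
  set.seed(1)
  lab <- assign_label(list(time_months = runif(500, 0, 200),
                           event = rep(1, 500)), label_spec())
  expect_false(any(lab == "undefined"))
})

test_that("patient typing follows the completeness partition with precedence", {
  full <- c(1, 2); holey <- c(1, NA)
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = full,
                                          label = "poor")), "I")
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = full,
                                          label = "undefined")), "II")
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = NULL,
                                          label = "poor")), "III")
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = c(NA, NA),
                                          label = "poor")), "III")
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = holey,
                                          label = "good")), "IV")
  # missing label dominates over masked cells
  expect_equal(classify_patient_type(list(expression = 1:3, clinical = holey,
                                          label = "undefined")), "II")
  expect_error(classify_patient_type(list(expression = NULL, clinical = full,
                                          label = "poor")), "expression")
})

test_that("typing is a partition and idempotent on a generated cohort", {
  gen <- toy_split_cohort(seed = 3)
  co <- gen$cohort
  expect_true(all(co$ptype %in% c("I", "II", "III", "IV")))
  again <- vapply(seq_along(co$ids), function(i) {
    classify_patient_type(get_record(co, co$ids[i]))
  }, "")
  expect_equal(again, co$ptype)
})

test_that("read_cohort joins tables, masks missing cells and types patients", {
  dir <- write_toy_cohort_files()
  co <- read_cohort(file.path(dir, "expression.csv"),
                    file.path(dir, "clinical.csv"),
                    file.path(dir, "survival.csv"))
  expect_equal(length(co$ids), 3L)
  expect_equal(co$label, c("poor", "good", "undefined"))
  # p2 is labeled (survived past the horizon) with one masked clinical cell
  expect_equal(co$ptype, c("I", "IV", "II"))
  # censoring p2 before the horizon removes its label: missing label (II)
  # takes precedence over the masked cell (IV)
  writeLines(c("id,time_months,event", "p1,40,1", "p2,30,0", "p3,40,0"),
             file.path(dir, "survival.csv"))
  co2 <- read_cohort(file.path(dir, "expression.csv"),
                     file.path(dir, "clinical.csv"),
                     file.path(dir, "survival.csv"))
  expect_equal(co2$ptype, c("I", "II", "II"))
})

test_that("read_cohort handles absent clinical/survival tables", {
  dir <- write_toy_cohort_files()
  co <- read_cohort(file.path(dir, "expression.csv"))
  expect_true(all(co$ptype == "III"))
  expect_true(all(co$label == "undefined"))
  co2 <- read_cohort(file.path(dir, "expression.csv"),
                     file.path(dir, "clinical.csv"))
  expect_true(all(co2$label == "undefined"))
})

test_that("read_cohort rejects malformed inputs with descriptive errors", {
  dir <- write_toy_cohort_files()
  writeLines(c("id,gene_a,gene_b", "p1,1,2", "p1,3,4"),
             file.path(dir, "dup.csv"))
  expect_error(read_cohort(file.path(dir, "dup.csv")), "duplicate")
  writeLines(c("id,gene_a", "p1,1", "p2,oops"), file.path(dir, "bad.csv"))
  expect_error(read_cohort(file.path(dir, "bad.csv")), "non-numeric")
  writeLines(c("id,age", "p9,44"), file.path(dir, "orphan.csv"))
  expect_error(read_cohort(file.path(dir, "expression.csv"),
                           file.path(dir, "orphan.csv")), "p9")
})

test_that("tab-delimited files are autodetected", {
  dir <- tempfile("tsv"); dir.create(dir)
  writeLines(c("id\tg1\tg2", "a\t1\t2", "b\t3\t4"), file.path(dir, "e.tsv"))
  co <- read_cohort(file.path(dir, "e.tsv"))
  expect_equal(co$gene_names, c("g1", "g2"))
  expect_equal(co$expression[, "g2"], c(a = 2, b = 4))
})

test_that("cohort round-trips through write_cohort/read_cohort", {
  gen <- toy_split_cohort(seed = 8, n_labeled = 30, n_unlabeled = 20)
  dir <- tempfile("rt")
  write_cohort(gen$cohort, dir)
  back <- read_cohort(file.path(dir, "expression.csv"),
                      file.path(dir, "clinical.csv"),
                      file.path(dir, "survival.csv"))
  expect_equal(back$expression, gen$cohort$expression, ignore_attr = TRUE)
  expect_equal(back$label, gen$cohort$label)
  expect_equal(back$ptype, gen$cohort$ptype)
})

test_that("standardize centers and scales on the fit split only", {
  dir <- write_toy_cohort_files()
  co <- read_cohort(file.path(dir, "expression.csv"),
                    file.path(dir, "clinical.csv"),
                    file.path(dir, "survival.csv"))
  co$split <- c("train", "train", "train")
  out <- standardize(co)
  # {1, 2.5, 0.5} standardized has mean 0, sd 1
  expect_equal(mean(out$cohort$expression[, "gene_a"]), 0)
  expect_equal(sd(out$cohort$expression[, "gene_a"]), 1)
  # closed form for {1,2,3}: (x - 2)/1 -> {-1, 0, 1}
  co$expression[, "gene_a"] <- c(1, 2, 3)
  out2 <- standardize(co)
  expect_equal(out2$cohort$expression[, "gene_a"], c(p1 = -1, p2 = 0, p3 = 1))
  # binary clinical column untouched; masked cell stays masked
  expect_equal(out$cohort$clinical[, "chemo"], co$clinical[, "chemo"])
  expect_true(is.na(out$cohort$clinical[2, "age"]))
  # reusing fitted stats transforms new data with train statistics
  co3 <- co
  co3$expression[, "gene_a"] <- c(4, 4, 4)
  out3 <- standardize(co3, stats = out2$stats)
  expect_equal(unname(out3$cohort$expression[, "gene_a"]), c(2, 2, 2))
})

test_that("standardization is idempotent given the same statistics", {
  gen <- toy_split_cohort(seed = 5)
  out <- standardize(gen$cohort, fit_on = "train")
  twice <- standardize(out$cohort, fit_on = "train")
  expect_lt(max(abs(twice$cohort$expression - standardize(out$cohort,
    stats = twice$stats)$cohort$expression)), 1e-12)
  # post-fit moments: |mean| < 1e-9, sd within 1e-9 of 1 per continuous column
  rows <- out$cohort$split %in% "train"
  mu <- colMeans(out$cohort$expression[rows, ])
  sdv <- apply(out$cohort$expression[rows, ], 2, sd)
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(sdv - 1)), 1e-9)
})

test_that("zero-variance columns fall back to sd 1 with a warning", {
  dir <- write_toy_cohort_files()
  co <- read_cohort(file.path(dir, "expression.csv"))
  co$split <- rep("train", 3)
  co$expression[, "gene_a"] <- 7
  expect_warning(out <- standardize(co), "zero-variance")
  expect_equal(unname(out$cohort$expression[, "gene_a"]), c(0, 0, 0))
})

test_that("summarize_cohort reproduces printed table percentages and ratios", {
  # encode the breast/NSCLC test-set class counts and unlabeled pools of the
  # study tables as fixtures and recompute their printed summaries
  mk <- function(n_good, n_poor, n_II, n_III) {
    n <- n_good + n_poor + n_II + n_III
    co <- structure(list(
      ids = sprintf("p%d", seq_len(n)),
      expression = matrix(0, n, 1, dimnames = list(NULL, "g")),
      clinical = matrix(0, n, 0),
      clinical_present = rep(FALSE, n),
      survival = data.frame(time_months = rep(61, n), event = rep(1, n)),
      label = c(rep("good", n_good), rep("poor", n_poor),
                rep("undefined", n_II + n_III)),
      ptype = c(rep("I", n_good + n_poor), rep("II", n_II), rep("III", n_III)),
      split = c(rep("test", n_good + n_poor), rep("unlabeled", n_II + n_III)),
      gene_names = "g", clinical_names = character(0)), class = "prog_cohort")
    summarize_cohort(co)
  }
  breast <- mk(62, 55, 1168, 114)
  test_row <- breast$labeled[breast$labeled$split == "test", ]
  expect_equal(test_row$imbalance_ratio, 1.13)
  expect_equal(breast$unlabeled$pct[breast$unlabeled$ptype == "II"], 91.11)
  expect_equal(breast$unlabeled$pct[breast$unlabeled$ptype == "III"], 8.89)
  nsclc <- mk(119, 52, 62, 40)
  expect_equal(nsclc$labeled$imbalance_ratio[nsclc$labeled$split == "test"], 2.29)
  # training-split percentages recomputed from printed counts
  tr <- mk(166, 183, 0, 0)
  expect_equal(tr$labeled$good_pct[tr$labeled$split == "test"], 47.56)
  balanced <- mk(50, 50, 0, 0)
  expect_equal(balanced$labeled$imbalance_ratio[balanced$labeled$split == "test"], 1)
})

test_that("split_cohort is deterministic, exhaustive and stratified", {
  gen <- toy_split_cohort(seed = 21, n_labeled = 100, n_unlabeled = 40)
  co <- gen$cohort
  s1 <- split_cohort(co, c(train = 0.8, test = 0.2), seed = 9)
  s2 <- split_cohort(co, c(train = 0.8, test = 0.2), seed = 9)
  expect_identical(s1$split, s2$split)
  labeled <- co$label %in% c("good", "poor")
  expect_equal(sum(s1$split[labeled] == "train"), 80)
  expect_equal(sum(s1$split[labeled] == "test"), 20)
  expect_true(all(s1$split[!labeled] == "unlabeled"))
  # stratification: class proportions within one patient of the target
  half <- split_cohort(co, c(train = 0.5, test = 0.5), seed = 4)
  for (lab in c("good", "poor")) {
    n_lab <- sum(co$label == lab)
    in_train <- sum(half$split == "train" & co$label == lab)
    expect_lte(abs(in_train - n_lab / 2), 1)
  }
  expect_error(split_cohort(co, c(0.7, 0.5)), "sum to 1")
  expect_error(split_cohort(co, c(1.2, -0.2)), "\\[0, 1\\]")
})

test_that("split manifest reports id, split, type and label for everyone", {
  gen <- toy_split_cohort(seed = 2, n_labeled = 40, n_unlabeled = 10)
  mf <- split_manifest(gen$cohort)
  expect_equal(nrow(mf), 50)
  expect_named(mf, c("id", "split", "ptype", "label"))
  expect_false(any(is.na(mf$split)))
})
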