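test_that("lab value classification uses inclusive bounds and handles missing ones", {
  expect_identical(classify_lab_value(5.0, 3.5, 9.1), "within")
  expect_identical(classify_lab_value(2.0, 3.5, 9.1), "below")
  expect_identical(classify_lab_value(12.0, 3.5, 9.1), "above")
  expect_identical(classify_lab_value(3.5, 3.5, 9.1), "within")
  expect_identical(classify_lab_value(9.1, 3.5, 9.1), "within")
  expect_identical(classify_lab_value(1.0, NA, 9.1), "within")   # no low bound
  expect_identical(classify_lab_value(99, 3.5, NA), "within")    # no high bound
  expect_identical(classify_lab_value("negative", 3.5, 9.1), "not_classifiable")
  expect_identical(classify_lab_value("<0.1", 0.5, 2), "below")
})

test_that("interpretation scoring is per label", {
  items <- generate_interpretation_set(120, seed = 5)
  perfect <- score_interpretations(items$gold_label, items)
  expect_equal(unname(perfect), c(100, 100, 100))
  all_within <- score_interpretations(rep("within", nrow(items)), items)
  expect_equal(unname(all_within[c("below", "above")]), c(0, 0))
  expect_equal(unname(all_within[["within"]]), 100)
  set.seed(99)
  rand <- sample(c("below", "within", "above"), 3000, replace = TRUE)
  items2 <- generate_interpretation_set(3000, seed = 6)
  acc <- score_interpretations(rand, items2)
  expect_true(all(abs(acc - 100 / 3) < 5))
})

test_that("per-class accuracy equals a brute-force recount", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    paths <- sample(pathologies(), n, replace = TRUE)
    correct <- sample(c(TRUE, FALSE), n, replace = TRUE)
    scores <- lapply(seq_len(n), function(i) {
      structure(list(pathology = paths[i], diagnosed_correctly = correct[i]),
                class = "case_score")
    })
    for (p in unique(paths)) {
      manual <- 100 * sum(correct[paths == p]) / sum(paths == p)
      expect_equal(per_class_accuracy(scores, p), manual)
    }
  }
  expect_error(per_class_accuracy(list(), "appendicitis"), "no cases")
})

test_that("group comparison matches a textbook Welch implementation", {
  set.seed(21)
  for (rep in 1:100) {
    a <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- compare_groups(a, b)
    expect_equal(got$p_value, welch_oracle(a, b), tolerance = 1e-10)
  }
  # Bonferroni is min(1, p * m), exactly
  x <- rnorm(20); y <- rnorm(20, 5)
  res <- compare_groups(x, y, n_comparisons = 5)
  expect_equal(res$p_corrected, min(1, res$p_value * 5))
  expect_lt(res$p_corrected, 0.001)
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1), n_comparisons = 5)
  expect_equal(same$p_corrected, 1)
  big <- compare_groups(rnorm(10), rnorm(10), n_comparisons = 1000)
  expect_equal(big$p_corrected, 1)
})

test_that("treatment scoring distinguishes essential, case-specific and support", {
  case <- tiny_case()  # received an appendectomy (free-text procedure)
  fl <- score_treatment_text(
    "Perform appendectomy, start IV fluids and analgesia, monitor closely, give antibiotics.",
    "appendicitis", case$procedures)
  expect_identical(unname(fl["appendectomy"]), "recommended")
  expect_identical(unname(fl["antibiotics"]), "recommended")
  expect_identical(unname(fl["support"]), "recommended")
  expect_identical(unname(fl["drainage"]), "not_applicable")

  # pancreatitis support requires all three elements
  panc <- generate_case(case_profile("pancreatitis", "uncomplicated", 2))
  only_fluids <- score_treatment_text("aggressive IV fluids", "pancreatitis",
                                      panc$procedures)
  expect_identical(unname(only_fluids["support"]), "missed")
  all_three <- score_treatment_text(
    "aggressive IV fluids, pain management with opioids, close monitoring",
    "pancreatitis", panc$procedures)
  expect_identical(unname(all_three["support"]), "recommended")

  empty <- score_treatment_text("", "appendicitis", case$procedures)
  expect_true(all(empty[names(empty) != "drainage"] == "missed"))
})

test_that("negated mentions are not counted as recommendations", {
  case <- tiny_case()
  fl <- score_treatment_text("No antibiotics needed. Recommend appendectomy and fluids.",
                             "appendicitis", case$procedures)
  expect_identical(unname(fl["antibiotics"]), "missed")
  expect_identical(unname(fl["appendectomy"]), "recommended")
})

test_that("treatment flags are conditioned on a correct diagnosis", {
  case <- tiny_case()
  good <- scripted_agent(c(
    "Action: Physical Examination\nAction Input:",
    "Final Diagnosis: acute appendicitis\nTreatment: appendectomy, antibiotics, fluids, analgesia, monitoring"))
  ep <- run_episode(case, good)
  sc <- score_episode(ep, case)
  expect_true(sc$diagnosed_correctly)
  expect_gt(length(sc$treatment_flags), 0)

  # metamorphic flip: same episode but a wrong diagnosis empties the flags
  ep$final_diagnosis_text <- "gastroenteritis"
  sc2 <- score_episode(ep, case)
  expect_false(sc2$diagnosed_correctly)
  expect_length(sc2$treatment_flags, 0)
})

test_that("required lab categories are met by any one member test", {
  case <- tiny_case()
  ep <- run_episode(case, scripted_agent(c(
    "Action: Laboratory Tests\nAction Input: WBC",
    "Final Diagnosis: acute appendicitis\nTreatment: appendectomy")))
  sc <- score_episode(ep, case)
  expect_true(sc$lab_categories_met[["inflammation"]])

  panc <- generate_case(case_profile("pancreatitis", "uncomplicated", 2))
  ep2 <- run_episode(panc, scripted_agent(c(
    "Action: Laboratory Tests\nAction Input: WBC",
    "Final Diagnosis: acute pancreatitis\nTreatment: fluids, analgesia, monitoring")))
  sc2 <- score_episode(ep2, panc)
  expect_true(sc2$lab_categories_met[["inflammation"]])
  expect_false(sc2$lab_categories_met[["pancreatic enzymes"]])
})
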