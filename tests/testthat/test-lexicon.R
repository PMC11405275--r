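test_that("lab request matching resolves panels, aliases and multi-test requests", {
  lex <- load_lab_lexicon()
  cbc <- match_lab_request("complete blood count", lex)
  expect_setequal(cbc, c("white blood cell count", "hemoglobin", "hematocrit",
                         "platelet count", "red blood cell count"))
  expect_identical(match_lab_request("CBC", lex), cbc)
  expect_identical(match_lab_request("quantum flux assay", lex), character(0))
  # normalization identity: canonical name under different case
  expect_identical(match_lab_request("LIPASE", lex), "lipase")
  # expansion is idempotent on an already-canonical test
  expect_identical(match_lab_request(match_lab_request("wbc", lex), lex),
                   "white blood cell count")
  multi <- match_lab_request("please run a CBC, lipase and lactate", lex)
  expect_true(all(c("lipase", "lactate", "white blood cell count") %in% multi))
})

test_that("imaging classification handles keywords and special exams", {
  lex <- load_imaging_lexicon()
  expect_equal(classify_imaging_request("abdominal ultrasound", lex),
               list(modality = "Ultrasound", region = "abdomen"))
  expect_equal(classify_imaging_request("MRCP", lex),
               list(modality = "MRI", region = "abdomen"))
  expect_equal(classify_imaging_request("CT urography", lex),
               list(modality = "CT", region = "abdomen"))
  expect_null(classify_imaging_request("imaging please", lex))
  expect_null(classify_imaging_request("", lex))
})

test_that("imaging classification agrees with a brute-force keyword oracle", {
  lex <- load_imaging_lexicon()
  # oracle: try every (modality, region) keyword pair independently
  oracle <- function(text) {
    t <- normalize_text(text)
    hits <- list()
    for (m in names(lex$modality_keywords)) {
      for (r in names(lex$region_keywords)) {
        m_hit <- any(vapply(lex$modality_keywords[[m]], function(kw)
          grepl(paste0("\\b", kw, "\\b"), t), logical(1)))
        r_hit <- any(vapply(lex$region_keywords[[r]], function(kw)
          grepl(paste0("\\b", kw, "\\b"), t), logical(1)))
        if (m_hit && r_hit) hits[[length(hits) + 1L]] <- list(modality = m, region = r)
      }
    }
    if (length(hits) == 1) hits[[1]] else NULL
  }
  set.seed(42)
  mods <- c("CT", "ultrasound", "MRI", "x-ray", "sonography", "computed tomography")
  regs <- c("abdomen", "chest", "head", "pelvis", "abdominal", "thorax")
  extra <- c("", "with contrast", "portable study", "evaluation requested")
  for (i in 1:200) {
    text <- paste(sample(mods, 1), sample(regs, 1), sample(extra, 1))
    got <- classify_imaging_request(text, lex)
    want <- oracle(text)
    if (!is.null(want)) expect_equal(got, want, info = text)
  }
})

test_that("diagnosis matching uses only the first mentioned diagnosis", {
  expect_true(match_diagnosis("Acute appendicitis with periappendiceal fat stranding",
                              "appendicitis"))
  expect_false(match_diagnosis("Gallstones", "cholecystitis"))
  expect_false(match_diagnosis("1. Pancreatitis 2. Cholecystitis", "cholecystitis"))
  expect_true(match_diagnosis("1. Pancreatitis 2. Cholecystitis", "pancreatitis"))
  expect_true(match_diagnosis("ACUTE CHOLECYSTITIS.", "cholecystitis"))
  expect_true(match_diagnosis("inflammation of the gallbladder", "cholecystitis"))
  expect_false(match_diagnosis("", "appendicitis"))
  expect_false(match_diagnosis(NA_character_, "appendicitis"))
})

test_that("diagnosis phrasings are disjoint across pathologies", {
  lex <- load_diagnosis_lexicon()
  for (p in pathologies()) {
    for (phrase in lex[[p]]) {
      matches <- vapply(pathologies(), function(q) match_diagnosis(phrase, q, lex),
                        logical(1))
      expect_identical(names(matches)[matches], p, info = phrase)
    }
  }
})
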