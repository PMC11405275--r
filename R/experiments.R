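# Robustness experiment drivers for the full-information task: named
# perturbations of prompt content and order, the run matrix over
# cases x variants x seeds, and aggregation.

#' Construct an experiment variant
#'
#' @param variant_id short unique name.
#' @param kind one of `baseline`, `instruction_phrasing`,
#'   `remove_system_instructions`, `remove_medical_terms`, `single_exam`,
#'   `order_permutation`, `abnormal_labs_only`, `no_summarization`.
#' @param parameters kind-specific parameter list (e.g. which exam, which
#'   permutation, which phrase).
#' @return an `experiment_variant` object.
#' @export
experiment_variant <- function(variant_id, kind = "baseline", parameters = list()) {
  kind <- match.arg(kind, c("baseline", "instruction_phrasing",
                            "remove_system_instructions", "remove_medical_terms",
                            "single_exam", "order_permutation",
                            "abnormal_labs_only", "no_summarization"))
  structure(list(variant_id = variant_id, kind = kind, parameters = parameters),
            class = "experiment_variant")
}

#' The six information-order permutations
#'
#' The canonical content order is physical examination, laboratory
#' results, imaging; the history of present illness is always first. One
#' variant per permutation of the three sections (3! = 6); each variant
#' contains exactly the same content spans as the baseline, permuted.
#'
#' @return list of six `experiment_variant`s (the canonical one first).
#' @export
make_order_permutations <- function() {
  sections <- c("pe", "labs", "imaging")
  perms <- list()
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) {
    if (length(unique(c(a, b, cc))) == 3) {
      perms[[length(perms) + 1L]] <- sections[c(a, b, cc)]
    }
  }
  canonical_first <- order(!vapply(perms, identical, logical(1), sections))
  perms <- perms[canonical_first]
  lapply(perms, function(p) {
    experiment_variant(paste0("order_", paste(p, collapse = "_")),
                       "order_permutation", list(order = p))
  })
}

#' The three single-exam variants
#'
#' Each keeps the history of present illness plus exactly one diagnostic
#' section: physical examination, laboratory results, or imaging.
#'
#' @return list of three `experiment_variant`s.
#' @export
make_single_exam_variants <- function() {
  lapply(c("pe", "labs", "imaging"), function(keep) {
    experiment_variant(paste0("single_", keep), "single_exam", list(keep = keep))
  })
}

#' Instruction-wording variants
#'
#' One variant per alternative phrase replacing "final diagnosis" in the
#' instructions, plus the baseline. An empty phrase set yields only the
#' baseline.
#'
#' @param phrase_set character vector of replacement phrases (e.g.
#'   `"main diagnosis"`, `"primary diagnosis"`).
#' @param include_removals also add the remove-system-instructions and
#'   remove-medical-terms variants.
#' @return list of `experiment_variant`s, baseline first.
#' @export
make_instruction_variants <- function(phrase_set = c("main diagnosis",
                                                     "primary diagnosis"),
                                      include_removals = FALSE) {
  out <- list(experiment_variant("baseline", "baseline"))
  for (ph in phrase_set) {
    out[[length(out) + 1L]] <- experiment_variant(
      paste0("phrase_", gsub("\\s+", "_", ph)), "instruction_phrasing",
      list(phrase = ph))
  }
  if (include_removals) {
    out[[length(out) + 1L]] <- experiment_variant(
      "no_system_instructions", "remove_system_instructions")
    out[[length(out) + 1L]] <- experiment_variant(
      "no_medical_terms", "remove_medical_terms")
  }
  out
}

#' Keep only abnormal laboratory results
#'
#' Drops every lab whose numeric value lies within its reference range
#' (inclusive bounds). Labs without a numeric value or without bounds are
#' kept — they cannot be judged normal. Idempotent.
#'
#' @param case a `patient_case`.
#' @return the case with filtered labs.
#' @export
filter_abnormal_labs <- function(case) {
  case$labs <- Filter(function(l) {
    classify_lab_value(l$value, l$ref_low, l$ref_high) != "within"
  }, case$labs)
  case
}

default_term_substitutions <- function() {
  c("physician" = "professional",
    "patient" = "individual",
    "emergency department" = "arrival area",
    "acute abdominal pain" = "severe stomach discomfort",
    "treatment plan" = "follow-up plan")
}

# Build the (possibly perturbed) full-information prompt for one case.
fi_prompt_for_variant <- function(case, variant, config = cdm_config(),
                                  guideline = load_guidelines(),
                                  summarizer = function(text) trim_words(text, 40)) {
  if (is.null(variant)) variant <- experiment_variant("baseline", "baseline")
  instructions <- read_template("fi_instructions", config$template_dir)
  order <- c("pe", "labs", "imaging")
  kind <- variant$kind
  if (kind == "abnormal_labs_only") case <- filter_abnormal_labs(case)
  parts <- build_fi_parts(case, guideline)
  if (kind == "order_permutation") order <- variant$parameters$order
  if (kind == "single_exam") order <- variant$parameters$keep
  if (kind == "instruction_phrasing") {
    ph <- variant$parameters$phrase
    instructions <- gsub("final diagnosis", tolower(ph), instructions,
                         ignore.case = FALSE, fixed = TRUE)
    instructions <- gsub("Final Diagnosis", totitle_phrase(ph), instructions,
                         fixed = TRUE)
  }
  if (kind == "remove_system_instructions") instructions <- ""
  if (kind == "remove_medical_terms") {
    subs <- variant$parameters$substitutions %||% default_term_substitutions()
    for (term in names(subs)) {
      instructions <- gsub(term, subs[[term]], instructions, ignore.case = TRUE)
    }
  }
  if (kind == "no_summarization") summarizer <- function(text) text
  assemble_fi_prompt(parts, instructions, order = order,
                     budget = config$budget, summarizer = summarizer)
}

totitle_phrase <- function(x) {
  gsub("(^|\\s)([a-z])", "\\1\\U\\2", x, perl = TRUE)
}

#' Run the full factorial case x variant x seed matrix
#'
#' Every cell is one single-shot full-information run. With a
#' `checkpoint_path`, finished cells are appended to a JSON-lines file and
#' skipped on re-run, so interrupted matrices resume. A failing cell is
#' recorded as failed and the matrix still aggregates.
#'
#' @param cases list of `patient_case`s.
#' @param agent_factory function `(case, seed) -> agent callable` (a
#'   deterministic scripted agent may ignore the seed hint).
#' @param variants list of `experiment_variant`s.
#' @param seeds integer vector.
#' @param config a [cdm_config()].
#' @param guideline from [load_guidelines()].
#' @param checkpoint_path optional JSON-lines checkpoint file.
#' @return data frame: case_id, pathology, variant_id, seed,
#'   diagnosis_text, correct, failed.
#' @export
run_matrix <- function(cases, agent_factory, variants, seeds,
                       config = cdm_config(), guideline = load_guidelines(),
                       checkpoint_path = NULL) {
  done <- list()
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    for (l in readLines(checkpoint_path, warn = FALSE)) {
      rec <- jsonlite::fromJSON(l)
      done[[paste(rec$case_id, rec$variant_id, rec$seed, sep = "\r")]] <- rec
    }
  }
  rows <- list()
  for (case in cases) {
    for (variant in variants) {
      for (seed in seeds) {
        key <- paste(case$case_id, variant$variant_id, seed, sep = "\r")
        if (!is.null(done[[key]])) {
          rows[[length(rows) + 1L]] <- as.data.frame(done[[key]],
                                                     stringsAsFactors = FALSE)
          next
        }
        cell <- tryCatch({
          agent <- agent_factory(case, seed)
          res <- run_fi(case, agent, variant, config, guideline)
          data.frame(case_id = case$case_id, pathology = case$pathology,
                     variant_id = variant$variant_id, seed = seed,
                     diagnosis_text = res$diagnosis_text %||% NA_character_,
                     correct = match_diagnosis(res$diagnosis_text, case$pathology),
                     failed = FALSE, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(case_id = case$case_id, pathology = case$pathology,
                     variant_id = variant$variant_id, seed = seed,
                     diagnosis_text = NA_character_, correct = FALSE,
                     failed = TRUE, stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- cell
        if (!is.null(checkpoint_path)) {
          cat(as.character(jsonlite::toJSON(as.list(cell), auto_unbox = TRUE,
                                            na = "null")),
              "\n", sep = "", file = checkpoint_path, append = TRUE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a run matrix
#'
#' Per (variant, pathology): per-seed accuracy is computed first, then its
#' mean and standard deviation across seeds, plus the delta of the mean
#' versus the baseline variant.
#'
#' @param matrix_df from [run_matrix()].
#' @param baseline_id variant id of the reference (default the canonical
#'   order variant if present, else `"baseline"`).
#' @return data frame: variant_id, pathology, n, mean_accuracy,
#'   sd_accuracy, delta_vs_baseline.
#' @export
aggregate_matrix <- function(matrix_df, baseline_id = NULL) {
  df <- matrix_df[!matrix_df$failed, , drop = FALSE]
  if (is.null(baseline_id)) {
    baseline_id <- if ("baseline" %in% df$variant_id) "baseline"
      else if ("order_pe_labs_imaging" %in% df$variant_id) "order_pe_labs_imaging"
      else df$variant_id[1]
  }
  per_seed <- stats::aggregate(correct ~ variant_id + pathology + seed,
                               data = df, FUN = function(x) 100 * mean(x))
  agg <- do.call(rbind, lapply(split(per_seed, list(per_seed$variant_id,
                                                    per_seed$pathology),
                                     drop = TRUE), function(d) {
    data.frame(variant_id = d$variant_id[1], pathology = d$pathology[1],
               n = nrow(d), mean_accuracy = mean(d$correct),
               sd_accuracy = stats::sd(d$correct), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  base <- agg[agg$variant_id == baseline_id, c("pathology", "mean_accuracy")]
  names(base)[2] <- "baseline_accuracy"
  agg <- merge(agg, base, by = "pathology", all.x = TRUE, sort = FALSE)
  agg$delta_vs_baseline <- agg$mean_accuracy - agg$baseline_accuracy
  agg$baseline_accuracy <- NULL
  agg[order(agg$variant_id, agg$pathology), ]
}
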