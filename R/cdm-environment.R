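# The interactive clinical decision-making environment: turn parsing,
# observation serving, conversation summarization under a token budget,
# and the episode loop with forced termination.

action_kinds <- function() c("physical_examination", "laboratory_tests", "imaging")

#' Environment configuration
#'
#' @param lab_lexicon,imaging_lexicon,diagnosis_lexicon lexicons (shipped
#'   defaults).
#' @param budget a [token_budget()].
#' @param max_turns safety cap on action turns per episode (default 15),
#'   preventing non-terminating agents.
#' @param summarize_threshold fraction of the token limit at which the
#'   conversation is summarized (default 0.9).
#' @param template_dir optional directory overriding shipped prompt
#'   templates.
#' @return a `cdm_config` object.
#' @export
cdm_config <- function(lab_lexicon = load_lab_lexicon(),
                       imaging_lexicon = load_imaging_lexicon(),
                       diagnosis_lexicon = load_diagnosis_lexicon(),
                       budget = token_budget(), max_turns = 15,
                       summarize_threshold = 0.9, template_dir = NULL) {
  structure(list(lab_lexicon = lab_lexicon, imaging_lexicon = imaging_lexicon,
                 diagnosis_lexicon = diagnosis_lexicon, budget = budget,
                 max_turns = max_turns, summarize_threshold = summarize_threshold,
                 template_dir = template_dir),
            class = "cdm_config")
}

# ---- turn parsing -------------------------------------------------------

extract_field <- function(text, pattern) {
  m <- regexpr(pattern, text, perl = TRUE)
  if (m[1] == -1) return(NULL)
  rest <- substr(text, m[1] + attr(m, "match.length"), nchar(text))
  stop_at <- regexpr("(?im)^\\s*(thoughts?|action|action\\s+input|final\\s+diagnosis|diagnosis|treatment)\\s*:",
                     rest, perl = TRUE)
  if (stop_at[1] != -1) rest <- substr(rest, 1, stop_at[1] - 1L)
  trimws(rest)
}

#' Parse one agent response into a structured turn
#'
#' The response is truncated at the first observation-marker phrase
#' ("Observation:"/"Observations:", any case) so an agent cannot write its
#' own observations. The labeled-field grammar extracts thoughts, action
#' and action input, or the final diagnosis and treatment. Deviations are
#' flags, never failures: a recognizable tool named in prose (no `Action:`
#' field) is honored with `free_text_action` set; an unrecognized tool sets
#' `hallucinated_tool`; a final turn without a treatment sets
#' `malformed_final`; an uninterpretable turn sets `missing_action_field`.
#'
#' @param raw_text one agent response.
#' @return a `parsed_turn` object with fields `thoughts`, `outcome`
#'   ("action" or "final"), `kind`, `input_text`, `diagnosis_text`,
#'   `treatment_text`, `tool_name`, `format_flags`.
#' @export
parse_turn <- function(raw_text) {
  text <- raw_text %||% ""
  obs <- regexpr("(?i)observations?\\s*:", text, perl = TRUE)
  if (obs[1] != -1) text <- substr(text, 1, obs[1] - 1L)
  flags <- character(0)
  thoughts <- extract_field(text, "(?im)^\\s*thoughts?\\s*:") %||% ""
  diag <- extract_field(text, "(?i)final\\s+diagnosis\\s*:") %||%
    extract_field(text, "(?im)^\\s*diagnosis\\s*:")
  treat <- extract_field(text, "(?im)^\\s*treatment(?:\\s+plan)?\\s*:")
  if (!is.null(diag)) {
    if (!nzchar(diag) || is.null(treat) || !nzchar(treat)) {
      flags <- c(flags, "malformed_final")
    }
    return(structure(list(
      thoughts = thoughts, outcome = "final", kind = NA_character_,
      input_text = NA_character_, diagnosis_text = diag,
      treatment_text = treat %||% NA_character_, tool_name = NA_character_,
      format_flags = flags, raw_text = raw_text), class = "parsed_turn"))
  }
  action_raw <- extract_field(text, "(?im)^\\s*action\\s*:")
  input_text <- extract_field(text, "(?im)^\\s*action\\s+input\\s*:") %||% ""
  kind <- NA_character_
  tool_name <- NA_character_
  if (!is.null(action_raw) && nzchar(action_raw)) {
    tool_name <- action_raw
    kind <- recognize_tool(action_raw)
    if (is.na(kind)) flags <- c(flags, "hallucinated_tool")
  } else {
    # tolerant fallback: recognize a tool named in prose
    kind <- recognize_tool(text)
    if (!is.na(kind)) {
      flags <- c(flags, "free_text_action")
      if (!nzchar(input_text)) input_text <- trimws(text)
    } else {
      flags <- c(flags, "missing_action_field")
    }
  }
  structure(list(
    thoughts = thoughts, outcome = "action", kind = kind,
    input_text = input_text, diagnosis_text = NA_character_,
    treatment_text = NA_character_, tool_name = tool_name,
    format_flags = flags, raw_text = raw_text), class = "parsed_turn")
}

recognize_tool <- function(text) {
  t <- normalize_text(text)
  if (grepl("physical exam", t)) return("physical_examination")
  if (grepl("\\blab(orator(y|ies))?\\b|\\blab tests?\\b|laboratory", t)) {
    return("laboratory_tests")
  }
  if (grepl("\\bimaging\\b|\\bradiology\\b", t)) return("imaging")
  NA_character_
}

# ---- environment state and observation serving --------------------------

new_env_state <- function(case, config) {
  list(case = case, imaging_cursor = integer(0), served_pe = FALSE,
       summarization_stage = "none", config = config)
}

#' Serve the observation for an action turn
#'
#' Physical examination returns the entire examination regardless of the
#' action input. Laboratory requests are matched against the lexicon; each
#' matched test is rendered with value, unit and reference range, a test
#' not recorded for the patient renders as "NA", and an unmatched request
#' returns "NA". Imaging requests return the next unserved report for the
#' (modality, region) pair in chronological order; when exhausted, the
#' agent is told no further reports of that combination are available. A
#' hallucinated tool draws a reminder of the available tools.
#'
#' @param state environment state (internal; created by [run_episode()]).
#' @param turn a `parsed_turn` with outcome "action".
#' @return list(text = observation text, state = updated state,
#'   requested_labs = canonical names, requested_imaging = list or NULL).
#' @export
serve_observation <- function(state, turn) {
  config <- state$config
  requested_labs <- character(0)
  requested_imaging <- NULL
  if ("hallucinated_tool" %in% turn$format_flags) {
    return(list(text = read_template("tool_reminder", config$template_dir),
                state = state, requested_labs = requested_labs,
                requested_imaging = requested_imaging))
  }
  if (is.na(turn$kind)) {
    return(list(text = read_template("format_reminder", config$template_dir),
                state = state, requested_labs = requested_labs,
                requested_imaging = requested_imaging))
  }
  if (turn$kind == "physical_examination") {
    state$served_pe <- TRUE
    text <- state$case$physical_exam_text
  } else if (turn$kind == "laboratory_tests") {
    requested_labs <- match_lab_request(turn$input_text, config$lab_lexicon)
    if (!length(requested_labs)) {
      text <- "NA"
    } else {
      have <- vapply(state$case$labs, function(l) l$canonical_name, character(1))
      lines <- vapply(requested_labs, function(cn) {
        i <- match(cn, have)
        if (is.na(i)) paste0(cn, ": NA") else render_lab_line(state$case$labs[[i]])
      }, character(1))
      text <- paste(lines, collapse = "\n")
    }
  } else { # imaging
    cls <- classify_imaging_request(turn$input_text, config$imaging_lexicon)
    if (is.null(cls)) {
      text <- "Please specify both an imaging modality (CT, Ultrasound, MRI, Radiograph) and an anatomical region."
    } else {
      requested_imaging <- cls
      key <- paste(cls$modality, cls$region, sep = "|")
      pool <- Filter(function(r) r$modality == cls$modality && r$region == cls$region,
                     state$case$reports)
      pool <- pool[order(vapply(pool, function(r) r$chart_time, character(1)))]
      idx <- (state$imaging_cursor[key] %||% NA)
      idx <- if (is.na(idx)) 1L else unname(idx) + 1L
      if (idx > length(pool)) {
        text <- paste0("We can no longer provide reports of the ", cls$modality,
                       " ", cls$region, " combination.")
      } else {
        r <- pool[[idx]]
        text <- paste0(r$modality, " ", r$region, " (", r$chart_time, "):\n",
                       r$findings_text)
      }
      state$imaging_cursor[key] <- min(idx, length(pool) + 1L)
    }
  }
  list(text = text, state = state, requested_labs = requested_labs,
       requested_imaging = requested_imaging)
}

# ---- conversation and summarization -------------------------------------

conversation_text <- function(spans) {
  paste(vapply(spans, function(s) s$text, character(1)), collapse = "\n\n")
}

#' Summarize served observations when the conversation nears the limit
#'
#' When the counted conversation length exceeds `summarize_threshold *
#' limit`, each not-yet-summarized observation span is replaced by its
#' summary, one span at a time and individually; the instructions and the
#' initial history of present illness are never touched. If every
#' observation is already summarized and the conversation still exceeds
#' the threshold, a forced diagnosis is signalled.
#'
#' @param spans conversation span list (internal representation).
#' @param config a [cdm_config()].
#' @param summarizer text -> summary function.
#' @return list(spans =, force = flag).
#' @export
maybe_summarize <- function(spans, config, summarizer) {
  threshold <- config$summarize_threshold * config$budget$limit
  if (config$budget$counter(conversation_text(spans)) <= threshold) {
    return(list(spans = spans, force = FALSE))
  }
  for (i in seq_along(spans)) {
    s <- spans[[i]]
    if (isTRUE(s$summarizable) && !isTRUE(s$summarized)) {
      spans[[i]]$text <- paste0("Summary of earlier observation:\n",
                                apply_summarizer(summarizer, s$text))
      spans[[i]]$summarized <- TRUE
      if (config$budget$counter(conversation_text(spans)) <= threshold) {
        return(list(spans = spans, force = FALSE))
      }
    }
  }
  list(spans = spans, force = TRUE)
}

# Hard guarantee that the prompt fits limit - reserve: shrink summarized
# observations further, then drop them oldest-first. Instructions and HPI
# are never touched.
enforce_budget <- function(spans, budget) {
  cap <- budget$limit - budget$reserve
  if (budget$counter(conversation_text(spans)) <= cap) return(spans)
  for (i in seq_along(spans)) {
    if (isTRUE(spans[[i]]$summarizable)) {
      spans[[i]]$text <- trim_words(spans[[i]]$text, 20L)
      spans[[i]]$summarized <- TRUE
      if (budget$counter(conversation_text(spans)) <= cap) return(spans)
    }
  }
  keep <- vapply(spans, function(s) !isTRUE(s$summarizable), logical(1))
  drop_order <- which(!keep)
  for (i in drop_order) {
    spans[[i]]$text <- ""
    if (budget$counter(conversation_text(spans)) <= cap) break
  }
  spans
}

# ---- episode loop -------------------------------------------------------

#' Run one interactive clinical decision-making episode
#'
#' The agent receives the task instructions and the history of present
#' illness, then alternates between requesting information (physical
#' examination, laboratory tests, imaging) and receiving observations,
#' until it issues a final diagnosis and treatment plan — or until the
#' token budget forces one. Formatting deviations are tolerated, served
#' anyway where interpretable, and tallied in `error_counts`. No state
#' leaks across cases: each episode starts fresh.
#'
#' @param case a `patient_case`; the gold pathology is never served.
#' @param agent callable `(prompt_text, stop_phrases) -> response text`.
#' @param config a [cdm_config()].
#' @return An `episode` object.
#' @export
run_episode <- function(case, agent, config = cdm_config()) {
  summarizer <- attr(agent, "summarizer") %||% function(text) trim_words(text, 40)
  instructions <- read_template("cdm_instructions", config$template_dir)
  spans <- list(
    list(name = "instructions", text = instructions, summarizable = FALSE),
    list(name = "hpi", text = paste0("History of Present Illness:\n", case$hpi_text),
         summarizable = FALSE)
  )
  state <- new_env_state(case, config)
  turns <- list()
  observations <- character(0)
  requested_labs <- character(0)
  requested_imaging <- list()
  errors <- c(next_action_errors = 0L, tool_hallucinations = 0L,
              diagnosis_format_errors = 0L)
  pe_first <- NA
  final_diag <- NULL
  final_treat <- NULL
  terminated_by <- NULL
  stop_phrases <- c("Observation:", "Observations:")

  finish_forced <- function() {
    spans[[length(spans) + 1L]] <<- list(
      name = "forced", text = read_template("forced_diagnosis", config$template_dir),
      summarizable = FALSE)
    spans <<- enforce_budget(spans, config$budget)
    resp <- agent(conversation_text(spans), stop_phrases)
    turn <- parse_turn(resp)
    turns[[length(turns) + 1L]] <<- unclass(turn)
    if (turn$outcome == "final") {
      if ("malformed_final" %in% turn$format_flags) {
        errors[["diagnosis_format_errors"]] <<- errors[["diagnosis_format_errors"]] + 1L
      }
      final_diag <<- turn$diagnosis_text
      final_treat <<- turn$treatment_text
    } else {
      errors[["diagnosis_format_errors"]] <<- errors[["diagnosis_format_errors"]] + 1L
      final_diag <<- trimws(resp %||% "")
      final_treat <<- NA_character_
    }
    terminated_by <<- "forced_diagnosis"
  }

  n_actions <- 0L
  while (is.null(terminated_by)) {
    sm <- maybe_summarize(spans, config, summarizer)
    spans <- sm$spans
    if (sm$force || n_actions >= config$max_turns) {
      finish_forced()
      break
    }
    spans_safe <- enforce_budget(spans, config$budget)
    resp <- tryCatch(agent(conversation_text(spans_safe), stop_phrases),
                     error = function(e) e)
    if (inherits(resp, "error")) {
      final_diag <- NA_character_
      final_treat <- NA_character_
      terminated_by <- "agent_failure"
      break
    }
    turn <- parse_turn(resp)
    turns[[length(turns) + 1L]] <- unclass(turn)
    spans[[length(spans) + 1L]] <- list(name = "turn", text = resp %||% "",
                                        summarizable = FALSE)
    if (any(c("missing_action_field", "free_text_action") %in% turn$format_flags)) {
      errors[["next_action_errors"]] <- errors[["next_action_errors"]] + 1L
    }
    if ("hallucinated_tool" %in% turn$format_flags) {
      errors[["tool_hallucinations"]] <- errors[["tool_hallucinations"]] + 1L
    }
    if (turn$outcome == "final") {
      if ("malformed_final" %in% turn$format_flags) {
        errors[["diagnosis_format_errors"]] <- errors[["diagnosis_format_errors"]] + 1L
      }
      final_diag <- turn$diagnosis_text
      final_treat <- turn$treatment_text
      terminated_by <- "model_diagnosis"
      break
    }
    n_actions <- n_actions + 1L
    if (is.na(pe_first)) {
      pe_first <- identical(turn$kind, "physical_examination")
    }
    served <- serve_observation(state, turn)
    state <- served$state
    observations <- c(observations, served$text)
    requested_labs <- c(requested_labs, served$requested_labs)
    if (!is.null(served$requested_imaging)) {
      requested_imaging[[length(requested_imaging) + 1L]] <- served$requested_imaging
    }
    spans[[length(spans) + 1L]] <- list(
      name = "observation", text = paste0("Observation:\n", served$text),
      summarizable = TRUE)
  }

  structure(list(
    case_id = case$case_id,
    turns = turns,
    observations = observations,
    requested_labs = unique(requested_labs),
    requested_imaging = requested_imaging,
    physical_exam_requested = state$served_pe,
    physical_exam_first = isTRUE(pe_first),
    error_counts = as.list(errors),
    final_diagnosis_text = final_diag,
    treatment_text = final_treat,
    terminated_by = terminated_by
  ), class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat("<episode> case ", x$case_id, ": ", length(x$turns), " turns, ",
      length(x$observations), " observations, terminated by ", x$terminated_by,
      "\n  final diagnosis: ", x$final_diagnosis_text %||% NA, "\n", sep = "")
  invisible(x)
}

#' Run the single-shot full-information task for one case
#'
#' Assembles the full-information prompt (optionally perturbed by an
#' experiment variant), makes one agent call and extracts the stated
#' diagnosis.
#'
#' @param case a `patient_case`.
#' @param agent callable `(prompt_text, stop_phrases) -> response text`.
#' @param variant optional [experiment_variant()]; `NULL` means baseline.
#' @param config a [cdm_config()].
#' @param guideline from [load_guidelines()].
#' @return list(diagnosis_text, response, prompt).
#' @export
run_fi <- function(case, agent, variant = NULL, config = cdm_config(),
                   guideline = load_guidelines()) {
  summarizer <- attr(agent, "summarizer") %||% function(text) trim_words(text, 40)
  prompt <- fi_prompt_for_variant(case, variant, config, guideline, summarizer)
  resp <- tryCatch(agent(prompt, character(0)), error = function(e) NA_character_)
  diag <- extract_diagnosis_text(resp)
  list(diagnosis_text = diag, response = resp, prompt = prompt)
}

# Pull the stated diagnosis out of a single-shot response; tolerant of the
# phrasing variants (final/main/primary diagnosis).
extract_diagnosis_text <- function(resp) {
  if (is.null(resp) || is.na(resp)) return(NA_character_)
  d <- extract_field(resp, "(?i)(final|main|primary)\\s+diagnosis\\s*:") %||%
    extract_field(resp, "(?im)^\\s*diagnosis\\s*:")
  if (!is.null(d) && nzchar(d)) d else trimws(resp)
}
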