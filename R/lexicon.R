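# Lexicons: dictionaries and matchers mapping free-text requests to
# canonical laboratory tests and panels, imaging (modality, region) pairs,
# and diagnosis texts to target pathologies. Content ships as editable YAML
# and is a reconstruction of standard clinical vocabulary.

.lexicon_cache <- new.env(parent = emptyenv())

#' Load the laboratory test lexicon
#'
#' The lexicon maps normalized aliases and abbreviations to canonical test
#' names, and panel names (CBC, BMP, liver function panel, renal function
#' panel, urinalysis, ...) to their member tests.
#'
#' @param path YAML file; default is the shipped configuration.
#' @return A `lab_lexicon` object.
#' @export
load_lab_lexicon <- function(path = NULL) {
  key <- path %||% "default_lab"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  cfg <- yaml::read_yaml(path %||% config_path("lab_lexicon.yaml"))
  synonym_map <- character(0)
  for (canon in names(cfg$tests)) {
    aliases <- unique(c(canon, unlist(cfg$tests[[canon]]$aliases)))
    for (a in normalize_text(aliases)) synonym_map[[a]] <- canon
  }
  panel_map <- list()
  panel_alias_map <- character(0)
  for (pname in names(cfg$panels)) {
    members <- unlist(cfg$panels[[pname]]$members)
    bad <- setdiff(members, names(cfg$tests))
    if (length(bad)) {
      stop("lab lexicon: panel '", pname, "' has unknown member(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    panel_map[[pname]] <- members
    for (a in normalize_text(unique(c(pname, unlist(cfg$panels[[pname]]$aliases))))) {
      panel_alias_map[[a]] <- pname
    }
  }
  lex <- structure(list(synonym_map = synonym_map, panel_map = panel_map,
                        panel_alias_map = panel_alias_map,
                        canonical = names(cfg$tests)),
                   class = "lab_lexicon")
  .lexicon_cache[[key]] <- lex
  lex
}

#' Match a free-text laboratory request to canonical test names
#'
#' Matching is normalization-then-exact first (exact alias beats panel name
#' beats substring), then longest-alias-substring on word boundaries, so a
#' request listing several tests ("CBC, lipase and lactate") resolves each
#' of them. Panels expand to all member tests; expansion is idempotent — a
#' request that is already a canonical name returns itself. An unmatched
#' request yields an empty vector; the environment renders that as "NA".
#'
#' @param request_text free-text request (one or more tests or panels).
#' @param lexicon a `lab_lexicon`; defaults to the shipped one.
#' @return character vector of canonical test names (possibly empty).
#' @export
match_lab_request <- function(request_text, lexicon = load_lab_lexicon()) {
  req <- normalize_text(request_text)
  if (!nzchar(req)) return(character(0))
  # exact whole-request matches take precedence: alias first, then panel
  if (req %in% names(lexicon$synonym_map)) {
    return(unname(lexicon$synonym_map[[req]]))
  }
  if (req %in% names(lexicon$panel_alias_map)) {
    return(lexicon$panel_map[[lexicon$panel_alias_map[[req]]]])
  }
  # substring scan: collect every alias/panel-alias occurrence with its
  # span, keep the longest non-overlapping spans (longest alias wins ties)
  spans <- find_alias_spans(req, c(names(lexicon$synonym_map),
                                   names(lexicon$panel_alias_map)))
  if (!nrow(spans)) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(spans))) {
    a <- spans$alias[i]
    if (a %in% names(lexicon$panel_alias_map)) {
      out <- c(out, lexicon$panel_map[[lexicon$panel_alias_map[[a]]]])
    } else {
      out <- c(out, lexicon$synonym_map[[a]])
    }
  }
  unique(out)
}

# Find non-overlapping word-boundary occurrences of aliases in normalized
# text, preferring longer aliases; result ordered by position.
find_alias_spans <- function(text_norm, aliases) {
  hits <- list()
  for (a in aliases) {
    pat <- paste0("\\b", regex_escape(a), "\\b")
    m <- gregexpr(pat, text_norm, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (j in seq_along(m)) {
      hits[[length(hits) + 1L]] <- data.frame(
        alias = a, start = m[j], end = m[j] + attr(m, "match.length")[j] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(alias = character(0), start = integer(0), end = integer(0)))
  }
  df <- do.call(rbind, hits)
  df <- df[order(-(df$end - df$start), df$start), , drop = FALSE]
  taken <- logical(nchar(text_norm))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      keep[i] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Load the imaging lexicon
#'
#' Keyword lists per modality and per anatomical region, plus a special-exam
#' map (MRCP, CT urography, KUB) resolving named exams directly. Load-time
#' validation enforces that no keyword appears under two modalities or two
#' regions — keywords must be uniquely identifying.
#'
#' @param path YAML file; default is the shipped configuration.
#' @return An `imaging_lexicon` object.
#' @export
load_imaging_lexicon <- function(path = NULL) {
  key <- path %||% "default_imaging"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  cfg <- yaml::read_yaml(path %||% config_path("imaging_lexicon.yaml"))
  mods <- lapply(cfg$modalities, function(k) normalize_text(unlist(k)))
  regs <- lapply(cfg$regions, function(k) normalize_text(unlist(k)))
  dup_m <- unlist(mods)[duplicated(unlist(mods))]
  dup_r <- unlist(regs)[duplicated(unlist(regs))]
  if (length(dup_m) || length(dup_r)) {
    stop("imaging lexicon: keyword(s) listed under two vocabularies: ",
         paste(unique(c(dup_m, dup_r)), collapse = ", "), call. = FALSE)
  }
  lex <- structure(list(modality_keywords = mods, region_keywords = regs,
                        special_map = cfg$special %||% list()),
                   class = "imaging_lexicon")
  .lexicon_cache[[key]] <- lex
  lex
}

#' Classify an imaging request or exam name to (modality, region)
#'
#' Special exam names (e.g. MRCP) are resolved before the keyword scan.
#' Otherwise the request must contain a modality keyword and a region
#' keyword; if several occur, the earliest occurrence of each vocabulary
#' decides. Missing modality or region yields `NULL`.
#'
#' @param request_text exam name or free-text imaging request.
#' @param lexicon an `imaging_lexicon`; defaults to the shipped one.
#' @return `list(modality =, region =)` or `NULL` when unclassifiable.
#' @export
classify_imaging_request <- function(request_text, lexicon = load_imaging_lexicon()) {
  req <- normalize_text(request_text)
  if (!nzchar(req)) return(NULL)
  for (sname in names(lexicon$special_map)) {
    if (contains_term(req, normalize_text(sname))) {
      sp <- lexicon$special_map[[sname]]
      region <- sp$region %||% first_keyword_hit(req, lexicon$region_keywords)
      if (is.null(region)) return(NULL)
      return(list(modality = sp$modality, region = region))
    }
  }
  modality <- first_keyword_hit(req, lexicon$modality_keywords)
  region <- first_keyword_hit(req, lexicon$region_keywords)
  if (is.null(modality) || is.null(region)) return(NULL)
  list(modality = modality, region = region)
}

# Earliest word-boundary keyword occurrence across a named keyword list;
# returns the owning name or NULL.
first_keyword_hit <- function(text_norm, keyword_sets) {
  best_pos <- Inf
  best <- NULL
  for (nm in names(keyword_sets)) {
    for (kw in keyword_sets[[nm]]) {
      pat <- paste0("\\b", regex_escape(kw), "\\b")
      m <- regexpr(pat, text_norm, perl = TRUE)
      if (m[1] != -1 && m[1] < best_pos) {
        best_pos <- m[1]
        best <- nm
      }
    }
  }
  best
}

#' Load the diagnosis lexicon
#'
#' Accepted alternative phrasings per pathology; phrasing lists must be
#' disjoint across pathologies (validated at load).
#'
#' @param path YAML file; default is the shipped configuration.
#' @return named list: pathology -> character vector of phrasings.
#' @export
load_diagnosis_lexicon <- function(path = NULL) {
  key <- path %||% "default_diagnosis"
  if (!is.null(.lexicon_cache[[key]])) return(.lexicon_cache[[key]])
  cfg <- yaml::read_yaml(path %||% config_path("diagnosis_lexicon.yaml"))
  cfg <- lapply(cfg, function(x) as.character(unlist(x)))
  all_phr <- normalize_text(unlist(cfg))
  if (anyDuplicated(all_phr)) {
    stop("diagnosis lexicon: phrasing(s) listed under two pathologies: ",
         paste(unique(all_phr[duplicated(all_phr)]), collapse = ", "),
         call. = FALSE)
  }
  .lexicon_cache[[key]] <- cfg
  cfg
}

default_diagnosis_lexicon <- function() load_diagnosis_lexicon()

#' Segment a diagnosis text into individual diagnosis mentions
#'
#' Splits on numbered or bulleted list markers, newlines, semicolons,
#' sentence breaks, and the connectives "and"/"with". The first non-empty
#' segment is "the first diagnosis mentioned".
#'
#' @param text diagnosis text.
#' @return character vector of trimmed segments.
#' @export
segment_diagnoses <- function(text) {
  t <- text
  t <- gsub("(^|\\s)\\d+\\s*[.)]", "\n", t)
  t <- gsub("(^|\n)\\s*[-*]\\s+", "\n", t)
  t <- gsub("\\.\\s+", "\n", t)
  t <- gsub("\\.$", "", t)
  t <- gsub(";", "\n", t, fixed = TRUE)
  t <- gsub("(?i)\\s+(and|with)\\s+", "\n", t, perl = TRUE)
  parts <- trimws(strsplit(t, "\n", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' Check a diagnosis text against the gold pathology
#'
#' Only the first diagnosis mentioned is examined: the text is segmented
#' with [segment_diagnoses()] and the first segment is scanned,
#' case-insensitively, for the gold pathology name or an accepted
#' alternative phrasing. A mention of a related finding without an
#' inflammatory term (e.g. "gallstones" for cholecystitis) does not count.
#'
#' @param diagnosis_text final-diagnosis span as extracted by the parser.
#' @param gold one of [pathologies()].
#' @param lexicon diagnosis lexicon; defaults to the shipped one.
#' @return logical flag.
#' @export
match_diagnosis <- function(diagnosis_text, gold, lexicon = load_diagnosis_lexicon()) {
  gold <- match.arg(gold, pathologies())
  if (is.null(diagnosis_text) || is.na(diagnosis_text)) return(FALSE)
  segs <- segment_diagnoses(diagnosis_text)
  if (!length(segs)) return(FALSE)
  first <- normalize_text(segs[[1]])
  terms <- unique(c(gold, lexicon[[gold]]))
  any(vapply(terms, function(tm) contains_term(first, normalize_text(tm)), logical(1)))
}
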