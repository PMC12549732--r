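TIMEPOINTS <- c("T0", "T3", "T6", "T12", "T18", "T24")

#' Pseudonymise an identifier
#'
#' Deterministic keyed digest of `(salt, raw_id)`: a fixed-length
#' lowercase-hex token that reveals nothing about the length or content
#' of the raw identifier. Different salts give unrelated tokens.
#'
#' @param raw_id Raw identifier (non-empty string).
#' @param salt Keying salt (non-empty string).
#' @return 32-character lowercase hex token.
#' @export
pseudonymise <- function(raw_id, salt) {
  if (!nzchar(raw_id)) abort_gw("empty raw_id", "gaitwin_validation_error")
  if (!nzchar(salt)) abort_gw("empty salt", "gaitwin_validation_error")
  md5_string(paste0(salt, "\x1f", raw_id))
}

# unit map for metric observations (UCUM-style; "1" = dimensionless)
metric_unit <- function(name) {
  if (name %in% c("strideT", "stepT")) return("s")
  if (grepl("^(strideT|stepT)_(SD1|SD2|std)$", name)) return("s")
  if (name %in% c("stanceT", "DS", "symm_stride", "symm_step") ||
      grepl("^DS_(SD1|SD2|std)$", name)) return("%")
  "1"
}

clinical_codes <- function() {
  list(
    list(code = "GW-SEX", display = "Sex", field = "sex", unit = NULL),
    list(code = "GW-GA", display = "Gestational age at birth", field = "ga_weeks", unit = "wk"),
    list(code = "GW-TWIN", display = "Twin pregnancy", field = "twin", unit = NULL),
    list(code = "GW-BWT", display = "Birth weight", field = "bw_g", unit = "g"),
    list(code = "GW-LEN-BIRTH", display = "Length at birth", field = "length_birth_cm", unit = "cm"),
    list(code = "GW-LEN", display = "Length at assessment", field = "length_t24_cm", unit = "cm"),
    list(code = "GW-WT", display = "Weight at assessment", field = "weight_t24_g", unit = "g"),
    list(code = "GW-WALKEXP", display = "Walking experience", field = "walk_exp_weeks", unit = "wk"),
    list(code = "GW-COG", display = "Cognitive standardised score", field = "cog_score", unit = "1"),
    list(code = "GW-RISK", display = "Clinical risk class", field = "risk", unit = NULL),
    list(code = "GW-GROUP", display = "Birth group", field = "group", unit = NULL))
}

#' Build a digital-twin document for one child
#'
#' Collects the child's clinical variables and the full metric battery
#' into an FHIR-flavoured document: a pseudonymised subject, demographic
#' fields, one coded observation per clinical variable and per metric
#' (values with UCUM-style units, local `GW-*` code system), a motor
#' assessment entry for the walking task, and an audit block. Brain
#' imaging and nutrition information are represented as presence/absence
#' codes. The raw child id never enters the document.
#'
#' @param child One-row child record.
#' @param metrics One-row metric `data.frame` for the same child.
#' @param timepoint One of `T0, T3, T6, T12, T18, T24`.
#' @param salt Pseudonymisation salt.
#' @param cfg_hash Configuration hash recorded in the audit block.
#' @param created Creation timestamp (override for reproducible output).
#' @return Object of class `twin_document`.
#' @export
build_twin <- function(child, metrics, timepoint = "T24", salt = "gaitwin",
                       cfg_hash = NA_character_,
                       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC")) {
  if (!identical(child$child_id, metrics$child_id))
    abort_gw("child and metrics ids differ", "gaitwin_validation_error")
  if (!timepoint %in% TIMEPOINTS)
    abort_gw("unknown timepoint", "gaitwin_validation_error")
  token <- pseudonymise(child$child_id, salt)

  obs <- list()
  add_obs <- function(code, display, value, unit) {
    if (is.null(value) || (is.numeric(value) && !is.finite(value)) ||
        (length(value) == 1 && is.na(value))) return()
    obs[[length(obs) + 1L]] <<- list(
      code = code, display = display,
      value = if (is.numeric(value)) as.numeric(value) else value,
      unit = unit, timepoint = timepoint)
  }
  for (cc in clinical_codes())
    add_obs(cc$code, cc$display, child[[cc$field]], cc$unit)
  # opaque presence codes covering the imaging / nutrition domains
  add_obs("GW-IMG", "Brain imaging available", FALSE, NULL)
  add_obs("GW-NUTR", "Nutrition data available", FALSE, NULL)
  for (m in metric_schema()) {
    v <- metrics[[m]]
    if (is.null(v)) next
    add_obs(paste0("GW-M-", m), paste("Gait metric", m), v,
            if (is.numeric(v)) metric_unit(m) else NULL)
  }

  doc <- structure(list(
    subject = token,
    demographics = list(sex = child$sex, ga_weeks = as.numeric(child$ga_weeks),
                        birth_date_surrogate = "2000-01-01"),
    observations = obs,
    assessments = list(list(task = "independent-walking",
                            timepoint = timepoint,
                            metrics_ref = paste0("metrics:", token, ":",
                                                 timepoint))),
    audit = list(created = created, config_hash = cfg_hash)
  ), class = "twin_document")
  validate_twin(doc)
  doc
}

#' Validate a twin document against its invariants
#'
#' Numeric observations must carry a unit, codes must be unique per
#' timepoint, and timepoints must come from the fixed grid.
#'
#' @param doc A `twin_document`.
#' @return `doc`, invisibly; otherwise a classed validation error naming
#'   the offending code.
#' @export
validate_twin <- function(doc) {
  keys <- character()
  for (o in doc$observations) {
    if (is.null(o$code) || is.null(o$timepoint) || is.null(o$value))
      abort_gw("observation missing code/value/timepoint",
               "gaitwin_validation_error")
    if (!o$timepoint %in% TIMEPOINTS)
      abort_gw(sprintf("observation %s: invalid timepoint", o$code),
               "gaitwin_validation_error")
    if (is.numeric(o$value) && (is.null(o$unit) || !nzchar(o$unit)))
      abort_gw(sprintf("numeric observation %s lacks a unit", o$code),
               "gaitwin_validation_error")
    key <- paste(o$code, o$timepoint)
    if (key %in% keys)
      abort_gw(sprintf("duplicate observation %s at %s", o$code, o$timepoint),
               "gaitwin_validation_error")
    keys <- c(keys, key)
  }
  invisible(doc)
}

#' Serialize / parse a twin document as an FHIR-flavoured JSON bundle
#'
#' The bundle holds one Patient-like resource followed by one
#' Observation-like resource per coded observation (resources mirror the
#' FHIR Patient/Observation shapes without claiming R4 conformance).
#' `from_fhir_json(to_fhir_json(doc))` reproduces the document
#' field-for-field.
#'
#' @param doc A `twin_document`.
#' @param json JSON string (or file path for `from_fhir_json` when
#'   `is_file = TRUE`).
#' @param is_file Treat `json` as a path.
#' @return JSON string (`to_fhir_json`); `twin_document` (`from_fhir_json`).
#' @export
to_fhir_json <- function(doc) {
  validate_twin(doc)
  entry <- list(list(resourceType = "Patient",
                     id = doc$subject,
                     gender = doc$demographics$sex,
                     birthDate = doc$demographics$birth_date_surrogate,
                     gestationalAgeWeeks = doc$demographics$ga_weeks))
  for (o in doc$observations) {
    res <- list(resourceType = "Observation",
                code = list(system = "urn:gaitwin:codes", code = o$code,
                            display = o$display),
                subject = paste0("Patient/", doc$subject),
                effectiveTimepoint = o$timepoint)
    if (is.numeric(o$value))
      res$valueQuantity <- list(value = o$value, unit = o$unit)
    else if (is.logical(o$value)) res$valueBoolean <- o$value
    else res$valueString <- as.character(o$value)
    entry[[length(entry) + 1L]] <- res
  }
  bundle <- list(resourceType = "Bundle", type = "collection",
                 subject = doc$subject,
                 assessments = doc$assessments,
                 audit = doc$audit,
                 entry = entry)
  jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' @rdname to_fhir_json
#' @export
from_fhir_json <- function(json, is_file = FALSE) {
  b <- tryCatch(
    jsonlite::parse_json(if (is_file) file(json) else json),
    error = function(e) abort_gw(paste0("malformed JSON: ", conditionMessage(e)),
                                 "gaitwin_parse_error"))
  if (is.null(b$entry) || !length(b$entry))
    abort_gw("malformed bundle: $entry missing", "gaitwin_parse_error")
  pat <- b$entry[[1]]
  if (!identical(pat$resourceType, "Patient"))
    abort_gw("malformed bundle: $entry[1] is not a Patient",
             "gaitwin_parse_error")
  obs <- lapply(b$entry[-1], function(res) {
    val <- if (!is.null(res$valueQuantity)) {
      if (is.null(res$valueQuantity$unit) || !nzchar(res$valueQuantity$unit))
        abort_gw(sprintf("numeric observation %s lacks a unit: $entry",
                         res$code$code), "gaitwin_parse_error")
      as.numeric(res$valueQuantity$value)
    } else if (!is.null(res$valueBoolean)) res$valueBoolean
    else res$valueString
    list(code = res$code$code, display = res$code$display, value = val,
         unit = if (!is.null(res$valueQuantity)) res$valueQuantity$unit else NULL,
         timepoint = res$effectiveTimepoint)
  })
  doc <- structure(list(
    subject = b$subject,
    demographics = list(sex = pat$gender,
                        ga_weeks = as.numeric(pat$gestationalAgeWeeks),
                        birth_date_surrogate = pat$birthDate),
    observations = obs,
    assessments = lapply(b$assessments, function(a)
      list(task = a$task, timepoint = a$timepoint, metrics_ref = a$metrics_ref)),
    audit = list(created = b$audit$created,
                 config_hash = b$audit$config_hash %||% NA_character_)
  ), class = "twin_document")
  validate_twin(doc)
  doc
}

# ---- RDF ------------------------------------------------------------------

ttl_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  gsub('"', '\\\\"', s)
}

ttl_literal <- function(value) {
  if (is.logical(value)) return(if (value) "true" else "false")
  if (is.numeric(value)) {
    if (is.finite(value) && value == round(value) && abs(value) < 1e15)
      return(sprintf('"%s"^^xsd:decimal', format(value, scientific = FALSE)))
    return(sprintf('"%s"^^xsd:double', formatC(value, digits = 15,
                                               format = "g")))
  }
  sprintf('"%s"', ttl_escape(as.character(value)))
}

ttl_header <- function() {
  paste0("@prefix gw: <urn:gaitwin:> .\n",
         "@prefix fhir: <http://hl7.org/fhir/> .\n",
         "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .\n\n")
}

serialize_triples <- function(triples) {
  lines <- sprintf("%s %s %s .", triples$subject, triples$predicate,
                   triples$object)
  paste0(ttl_header(), paste(sort(lines), collapse = "\n"), "\n")
}

#' Serialize a twin document as RDF Turtle
#'
#' Emits one typed patient node and one node per observation (code,
#' display, value, unit, timepoint, subject link) in a canonical form:
#' one triple per line, lines sorted lexicographically, so re-serializing
#' a parsed document is byte-identical.
#'
#' @param doc A `twin_document`.
#' @return Turtle text (single string).
#' @export
to_rdf_turtle <- function(doc) {
  validate_twin(doc)
  s <- character(); p <- character(); o <- character()
  add <- function(su, pr, ob) {
    s <<- c(s, su); p <<- c(p, pr); o <<- c(o, ob)
  }
  pat <- paste0("gw:patient-", doc$subject)
  add(pat, "a", "fhir:Patient")
  add(pat, "gw:sex", ttl_literal(doc$demographics$sex))
  add(pat, "gw:gaWeeks", ttl_literal(doc$demographics$ga_weeks))
  add(pat, "gw:birthDateSurrogate",
      ttl_literal(doc$demographics$birth_date_surrogate))
  for (ob in doc$observations) {
    node <- paste0("gw:obs-", doc$subject, "-", ob$timepoint, "-",
                   tolower(ob$code))
    add(node, "a", "fhir:Observation")
    add(node, "gw:code", ttl_literal(ob$code))
    add(node, "gw:display", ttl_literal(ob$display))
    add(node, "gw:value", ttl_literal(ob$value))
    if (!is.null(ob$unit)) add(node, "gw:unit", ttl_literal(ob$unit))
    add(node, "gw:timepoint", ttl_literal(ob$timepoint))
    add(node, "gw:subject", pat)
  }
  serialize_triples(data.frame(subject = s, predicate = p, object = o,
                               stringsAsFactors = FALSE))
}

#' Parse the Turtle subset emitted by this package
#'
#' Reads the one-triple-per-line canonical Turtle produced by
#' [to_rdf_turtle()] / [export_knowledge_graph()] back into a triple
#' table; `serialize_triples` of that table reproduces the input bytes.
#'
#' @param text Turtle text.
#' @return `data.frame` with `subject`, `predicate`, `object` columns.
#' @export
parse_turtle_subset <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^@prefix", lines) & nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^(\\S+) (\\S+) (.+) \\.$", lines))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    abort_gw(sprintf("unparseable Turtle line: %s", lines[bad][1]),
             "gaitwin_parse_error")
  data.frame(subject = vapply(m, `[`, "", 2L),
             predicate = vapply(m, `[`, "", 3L),
             object = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Export a knowledge graph over a set of twin documents
#'
#' Builds the concept graph linking children, examinations, the motor
#' task, metrics, risk factors and timepoints: `has_assessment`,
#' `of_task`, `measured_by`, `at_timepoint` and `has_risk_factor` edges
#' plus `instance_of` typing edges, emitted both as an edge table and as
#' canonical Turtle.
#'
#' @param docs List of `twin_document`s.
#' @return List with `edges` (`data.frame from, rel, to`) and `turtle`.
#' @export
export_knowledge_graph <- function(docs) {
  if (!length(docs)) abort_gw("need >= 1 document", "gaitwin_validation_error")
  edges <- list()
  add <- function(from, rel, to)
    edges[[length(edges) + 1L]] <<- data.frame(from = from, rel = rel,
                                               to = to,
                                               stringsAsFactors = FALSE)
  for (doc in docs) {
    child <- paste0("child-", doc$subject)
    add(child, "instance_of", "class:Child")
    risk_obs <- Filter(function(o) o$code == "GW-RISK", doc$observations)
    if (length(risk_obs))
      add(child, "has_risk_factor", paste0("risk-", risk_obs[[1]]$value))
    for (a in doc$assessments) {
      exam <- paste0("exam-", doc$subject, "-", a$timepoint)
      add(child, "has_assessment", exam)
      add(exam, "instance_of", "class:Examination")
      add(exam, "of_task", paste0("task-", a$task))
      add(paste0("task-", a$task), "instance_of", "class:MotorTask")
      add(exam, "at_timepoint", paste0("timepoint-", a$timepoint))
      add(paste0("timepoint-", a$timepoint), "instance_of", "class:Timepoint")
      for (o in doc$observations)
        if (startsWith(o$code, "GW-M-") && o$timepoint == a$timepoint) {
          mn <- paste0("metric-", sub("^GW-M-", "", o$code))
          add(exam, "measured_by", mn)
          add(mn, "instance_of", "class:Metric")
        }
    }
  }
  edf <- unique(do.call(rbind, edges))
  edf <- edf[order(edf$from, edf$rel, edf$to), ]
  rownames(edf) <- NULL
  ttl <- serialize_triples(data.frame(
    subject = paste0("gw:", edf$from),
    predicate = paste0("gw:", edf$rel),
    object = ifelse(startsWith(edf$to, "class:"),
                    paste0("gw:", sub(":", "-", edf$to)),
                    paste0("gw:", edf$to)),
    stringsAsFactors = FALSE))
  list(edges = edf, turtle = ttl)
}
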