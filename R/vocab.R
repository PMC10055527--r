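# OMOP-shaped input tables, concept sets and the ICD -> Phecode crosswalk.
#
# All inputs are flat comma-separated UTF-8 files with a header row.  Codes
# are matched exactly as strings after trimming whitespace; no dotted or
# undotted ICD normalization is attempted unless `strip_dots = TRUE`, since
# silent fuzzy matching hides data errors.

#' Roles a concept set may take
#'
#' The closed vocabulary of pregnancy-outcome and gender concept-set roles
#' used by the phenotyping rules.
#' @export
concept_set_roles <- c(
  "pregnancy_loss", "rpl_diagnosis", "history_of_loss", "live_birth",
  "control_exclusion", "incident_pregnancy", "gender_diverse"
)

#' Read a concept-set file
#'
#' A concept-set file has columns `set_name`, `role`, `concept_id`: one row
#' per concept, grouped into named sets, each set tagged with one of the
#' roles in [concept_set_roles] (pregnancy loss, RPL diagnosis, history of
#' loss, live birth, control exclusion, incident pregnancy, gender diverse).
#'
#' @param path Path to a CSV file with header `set_name,role,concept_id`.
#' @return A `concept_sets` data.frame with one row per concept membership.
#' @export
read_concept_sets <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("set_name", "role", "concept_id")
  if (!all(need %in% names(df))) {
    stop("concept-set file must have columns set_name, role, concept_id",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty concept-set file: ", path, call. = FALSE)
    return(as_concept_sets(df[, need]))
  }
  df <- df[, need]
  for (j in need) df[[j]] <- trimws(df[[j]])
  bad <- which(!df$role %in% concept_set_roles)
  if (length(bad)) {
    stop(sprintf("unknown concept-set role '%s' in row %d of %s",
                 df$role[bad[1]], bad[1], path), call. = FALSE)
  }
  as_concept_sets(df)
}

as_concept_sets <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("concept_sets", "data.frame")
  df
}

#' Write a concept-set collection
#'
#' Round-trips with [read_concept_sets()].
#' @param sets A `concept_sets` data.frame.
#' @param path Output CSV path.
#' @export
write_concept_sets <- function(sets, path) {
  write_study_csv(as.data.frame(sets)[, c("set_name", "role", "concept_id")],
                  path)
}

#' Concept identifiers carrying a given role
#'
#' Union of concept ids over all sets tagged with `role`.
#' @param sets A `concept_sets` data.frame.
#' @param role One of [concept_set_roles].
#' @export
concept_ids_for_role <- function(sets, role) {
  role <- match.arg(role, concept_set_roles)
  unique(sets$concept_id[sets$role == role])
}

#' Read an ICD to Phecode crosswalk
#'
#' The crosswalk maps `(vocabulary, code)` pairs to a Phecode, its label and
#' its phenotype category (e.g. "pregnancy complications").  The mapping must
#' be a function: duplicate `(vocabulary, code)` rows pointing at the same
#' Phecode are deduplicated, conflicting targets are an error.  Analogous
#' ICD9 and ICD10 codes assigned the same Phecode are thereby tested
#' together downstream.
#'
#' @param path CSV with columns `vocabulary,code,phecode,phecode_label,category`.
#' @param strip_dots If `TRUE`, remove "." from codes before keying
#'   (off by default; exact string matching is the contract).
#' @return A `phecode_map` data.frame keyed by `(vocabulary, code)`.
#' @export
read_phecode_map <- function(path, strip_dots = FALSE) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("vocabulary", "code", "phecode", "phecode_label", "category")
  if (!all(need %in% names(df))) {
    stop("phecode map must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  for (j in need) df[[j]] <- trimws(df[[j]])
  if (strip_dots) df$code <- gsub(".", "", df$code, fixed = TRUE)
  as_phecode_map(df)
}

as_phecode_map <- function(df) {
  df <- unique(df)
  key <- paste(df$vocabulary, df$code, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    k <- key[dup][1]
    stop(sprintf(
      "conflicting phecode assignments for (%s): a (vocabulary, code) pair must map to a single phecode",
      gsub("\r", ", ", k)), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("phecode_map", "data.frame")
  df
}

#' Write a Phecode crosswalk
#' @param map A `phecode_map` data.frame.
#' @param path Output CSV path.
#' @export
write_phecode_map <- function(map, path) {
  write_study_csv(as.data.frame(map)[, c("vocabulary", "code", "phecode",
                                         "phecode_label", "category")], path)
}

#' Map clinical events to Phecodes
#'
#' Total and deterministic: events whose `(vocabulary, concept_id)` pair is
#' absent from the crosswalk map to `NA` (unmapped is a valid outcome, never
#' an error).
#'
#' @param events Event data.frame with `vocabulary` and `concept_id` columns
#'   (a single event row also works).
#' @param map A `phecode_map`.
#' @return Character vector of phecode ids, `NA` where unmapped.
#' @export
map_events <- function(events, map) {
  key <- paste(trimws(events$vocabulary), trimws(events$concept_id),
               sep = "\r")
  mkey <- paste(map$vocabulary, map$code, sep = "\r")
  map$phecode[match(key, mkey)]
}

#' Map a single clinical event to a Phecode
#'
#' @param event One-row event data.frame (or list) with `vocabulary` and
#'   `concept_id`.
#' @param map A `phecode_map`.
#' @return The phecode id, or `NA_character_` when the code is unmapped.
#' @export
map_event <- function(event, map) {
  map_events(as.data.frame(event)[1, , drop = FALSE], map)[[1]]
}

# ------------------------------------------------------------------ readers

check_columns <- function(df, need, what) {
  if (!all(need %in% names(df))) {
    stop(what, " must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' Read a person table
#'
#' Columns: `person_id`, `birth_date` (YYYY-MM-DD, may be blank before
#' quality filtering), `gender_code` (female / male / other), `race`,
#' `ethnicity` (hispanic_or_latino / not_hispanic_or_latino / unknown).
#' @param path CSV path.
#' @export
read_persons <- function(path) {
  df <- check_columns(utils::read.csv(path, colClasses = "character"),
                      c("person_id", "birth_date", "gender_code",
                        "race", "ethnicity"), "person table")
  if (anyDuplicated(df$person_id)) {
    stop("person_id must be unique within a site", call. = FALSE)
  }
  df$birth_date <- as_study_date(df$birth_date, "birth_date")
  df
}

#' Read a clinical-event table
#'
#' Columns: `person_id`, `concept_id`, `vocabulary` (ICD9CM / ICD10CM /
#' SITE_LOCAL), `event_date`, optional `visit_id`.
#' @param path CSV path.
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (!"visit_id" %in% names(raw)) raw$visit_id <- NA_character_
  df <- check_columns(raw, c("person_id", "concept_id", "vocabulary",
                             "event_date", "visit_id"), "event table")
  df$event_date <- as_study_date(df$event_date, "event_date")
  bad <- !is.na(df$event_date) &
    (df$event_date < as.Date("1900-01-01") | df$event_date > Sys.Date())
  if (any(bad)) {
    stop(sprintf("%d event dates fall outside [1900-01-01, today]",
                 sum(bad)), call. = FALSE)
  }
  df
}

#' Read a visit table
#'
#' Columns: `person_id`, `visit_id`, `visit_date`; `(person_id, visit_id)`
#' must be unique.
#' @param path CSV path.
#' @export
read_visits <- function(path) {
  df <- check_columns(utils::read.csv(path, colClasses = "character"),
                      c("person_id", "visit_id", "visit_date"),
                      "visit table")
  if (anyDuplicated(df[, c("person_id", "visit_id")])) {
    stop("(person_id, visit_id) must be unique", call. = FALSE)
  }
  df$visit_date <- as_study_date(df$visit_date, "visit_date")
  df
}
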