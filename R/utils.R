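#' @importFrom data.table := .N .SD data.table as.data.table setDT setDF
#'   setorder fifelse rbindlist
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "person_id", "concept_id", "vocabulary", "event_date", "visit_id",
  "visit_date", "set_name", "role", "code", "phecode", "phecode_label",
  "category", "group", "index_date", "qualifying_rule", "birth_date",
  "gender_code", "race", "ethnicity", "phenotype", "idx_a", "idx_b", "idx_c",
  "loss_min", "hx_min", "n_visits", "age_at_index", "age_stratum",
  "visits_in_window", "record_span_years", "n_distinct_diagnoses",
  "gender_label", "adj_p", "raw_p", "crude_or", "adjusted_or", "significant",
  "direction", "redacted", "a", "b", "d", "analysis", "label",
  "neg_log10_p", "log10_or"
))

#' Evaluate code with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator calls are reproducible without clobbering the
#' session's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parse a calendar date column strictly
#'
#' @keywords internal
as_study_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop(sprintf("%s values not in YYYY-MM-DD format, e.g. '%s'",
                 what, as.character(x)[which(bad)[1]]), call. = FALSE)
  }
  out
}

# fixed writer so identical inputs give byte-identical files
write_study_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (inherits(df[[j]], "Date")) df[[j]] <- format(df[[j]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
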