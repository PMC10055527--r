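# Study-window diagnosis extraction and the binary person x phenotype
# matrix.  The window spans the whole record before the index date through
# `post_index_days` afterwards; presence is one-hot (a phenotype recorded
# five times counts once).

#' Restrict events to a person's study window
#'
#' Keeps events dated up to `index_date + post_index_days`; there is no
#' lower bound (any prior history counts).  Events on the index date are
#' kept.  Idempotent.
#'
#' @param events Event rows for one person.
#' @param index_date The person's index date.
#' @param post_index_days Days after index included in the window
#'   (default 365).
#' @return The windowed subset of `events`.
#' @export
window_events <- function(events, index_date, post_index_days = 365) {
  events[events$event_date <= index_date + post_index_days, , drop = FALSE]
}

#' Build the binary person x phenotype matrix
#'
#' Maps each cohort member's windowed events to Phecodes and one-hot-encodes
#' presence.  A phenotype becomes a candidate column when at least one
#' cohort member has it in their window; unmapped codes are excluded.
#'
#' @param cohort Cohort data.frame from [build_cohort()] (needs
#'   `person_id`, `group`, `index_date`).
#' @param events Event table.
#' @param map A `phecode_map`.
#' @param post_index_days Window extent after index (default 365).
#' @return A `phenotype_matrix`: sparse 0/1 matrix `M` (persons x
#'   phenotypes), `persons` (id + group), `phenotypes` (phecode, label,
#'   category), `post_index_days`.
#' @export
build_matrix <- function(cohort, events, map, post_index_days = 365) {
  stopifnot(nrow(cohort) > 0)
  ev <- as.data.table(events)[person_id %in% cohort$person_id]
  ev[, phecode := map_events(ev, map)]
  ev <- ev[!is.na(phecode)]
  idx <- cohort$index_date[match(ev$person_id, cohort$person_id)]
  ev <- ev[event_date <= idx + post_index_days]
  cells <- unique(ev[, .(person_id, phecode)])
  if (nrow(cells) == 0) stop("empty phenome: no mappable windowed events",
                             call. = FALSE)
  phen <- sort(unique(cells$phecode))
  M <- Matrix::sparseMatrix(
    i = match(cells$person_id, cohort$person_id),
    j = match(cells$phecode, phen),
    x = 1,
    dims = c(nrow(cohort), length(phen)),
    dimnames = list(cohort$person_id, phen))
  meta <- data.frame(
    phecode = phen,
    label = map$phecode_label[match(phen, map$phecode)],
    category = map$category[match(phen, map$phecode)],
    stringsAsFactors = FALSE)
  structure(list(M = M,
                 persons = cohort[, c("person_id", "group")],
                 phenotypes = meta,
                 post_index_days = post_index_days),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf(
    "phenotype_matrix: %d persons (%d RPL, %d Control) x %d phenotypes, window index+%d days\n",
    nrow(x$M), sum(x$persons$group == "RPL"),
    sum(x$persons$group == "Control"), ncol(x$M), x$post_index_days))
  invisible(x)
}

#' Per-phenotype 2x2 case-control counts
#'
#' @param pm A `phenotype_matrix`.
#' @param phecode A phenotype id present in the matrix.
#' @return list `a` (RPL with), `b` (RPL without), `c` (Control with),
#'   `d` (Control without).
#' @export
two_by_two <- function(pm, phecode) {
  j <- match(phecode, pm$phenotypes$phecode)
  if (is.na(j)) stop("unknown phenotype: ", phecode, call. = FALSE)
  pos <- pm$M[, j] > 0
  rpl <- pm$persons$group == "RPL"
  list(a = sum(pos & rpl), b = sum(!pos & rpl),
       c = sum(pos & !rpl), d = sum(!pos & !rpl))
}

#' Drop pregnancy-complication phenotype columns
#'
#' Removes every column whose Phecode category is "pregnancy complications",
#' as required before embedding, so the low-dimensional structure reflects
#' diagnoses leading to the outcome rather than indicating it.
#'
#' @param pm A `phenotype_matrix`.
#' @param category Category label to drop.
#' @return The filtered `phenotype_matrix`.
#' @export
drop_pregnancy_category <- function(pm, category = "pregnancy complications") {
  keep <- is.na(pm$phenotypes$category) | pm$phenotypes$category != category
  pm$M <- pm$M[, keep, drop = FALSE]
  pm$phenotypes <- pm$phenotypes[keep, , drop = FALSE]
  rownames(pm$phenotypes) <- NULL
  pm
}

#' Write a phenotype matrix as sparse triplets
#'
#' Writes `matrix_cells.csv` (person_id, phecode, 1) and
#' `matrix_phenotypes.csv` (column metadata) under `dir`.
#' @param pm A `phenotype_matrix`.
#' @param dir Output directory.
#' @export
write_matrix <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trip <- Matrix::summary(pm$M)
  cells <- data.frame(person_id = rownames(pm$M)[trip$i],
                      phecode = colnames(pm$M)[trip$j],
                      present = 1L)
  cells <- cells[order(cells$person_id, cells$phecode), ]
  write_study_csv(cells, file.path(dir, "matrix_cells.csv"))
  write_study_csv(pm$phenotypes, file.path(dir, "matrix_phenotypes.csv"))
  invisible(dir)
}
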