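# Cohort construction: RPL / Control classification with temporal rules,
# gender-inclusive filtering, quality filters, index dates and attrition.
#
# RPL qualifying rules, evaluated per person:
#   (a) rpl_dx            any RPL diagnosis record; index = its first date
#   (b) history_then_loss a pregnancy-loss record strictly after a recorded
#                         history-of-loss; index = first such loss
#   (c) two_losses_90d    two losses >= 90 days apart; index = second loss
#                         of the earliest qualifying pair
# The person's index date is the earliest date at which any rule is first
# satisfied; ties between rules resolve in the order a, b, c.
# Controls require >= 1 live-birth record and a whole-record absence of
# loss / RPL / history-of-loss / exclusion records; index = first live birth.

#' Cohort-construction configuration
#'
#' Quality-filter thresholds and the study-window length.  The filters stand
#' in for site demographic / data-quality / data-sufficiency screens: a
#' non-missing birth date, plausible reproductive age at index, at least one
#' visit, and an index date inside the person's recorded event span.
#'
#' @param age_range Allowed age-at-index interval in years (inclusive).
#' @param min_visits Minimum total visit count.
#' @param post_index_days Study-window extent after the index date, in days.
#' @export
cohort_config <- function(age_range = c(10, 60), min_visits = 1,
                          post_index_days = 365) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            min_visits >= 0, post_index_days >= 0)
  structure(list(age_range = age_range, min_visits = min_visits,
                 post_index_days = post_index_days),
            class = "cohort_config")
}

role_dates <- function(ev, sets, role) {
  ids <- concept_ids_for_role(sets, role)
  ev$event_date[ev$concept_id %in% ids]
}

#' Gender-inclusive demographic filter
#'
#' A person is included when their recorded gender code is female or when
#' they have any incident-pregnancy record, so that transgender, non-binary
#' and gender-diverse patients who have been pregnant are not excluded by
#' the gender field alone.  Included persons with any gender-diverse concept
#' record are labelled `tgd`, the rest `cis_woman`; excluded persons are
#' labelled `other`.
#'
#' @param persons Person table (see [read_persons()]).
#' @param events Event table.
#' @param sets Concept sets including `incident_pregnancy` and
#'   `gender_diverse` roles.
#' @return data.frame with `person_id`, `include`, `gender_label`.
#' @export
derive_inclusion_gender <- function(persons, events, sets) {
  ip_ids <- concept_ids_for_role(sets, "incident_pregnancy")
  gd_ids <- concept_ids_for_role(sets, "gender_diverse")
  has_ip <- persons$person_id %in%
    events$person_id[events$concept_id %in% ip_ids]
  has_gd <- persons$person_id %in%
    events$person_id[events$concept_id %in% gd_ids]
  include <- persons$gender_code == "female" | has_ip
  data.frame(
    person_id = persons$person_id,
    include = include,
    gender_label = ifelse(!include, "other",
                          ifelse(has_gd, "tgd", "cis_woman")),
    stringsAsFactors = FALSE)
}

#' Classify one person's record against the RPL rules
#'
#' @param events Event rows for a single person.
#' @param sets Concept sets.
#' @return `NULL` when the record does not qualify, otherwise a list with
#'   `index_date` (earliest satisfaction over the three rules) and
#'   `qualifying_rule` (`rpl_dx`, `history_then_loss` or `two_losses_90d`).
#' @export
classify_rpl <- function(events, sets) {
  rpl_d <- role_dates(events, sets, "rpl_diagnosis")
  loss_d <- sort(role_dates(events, sets, "pregnancy_loss"))
  hx_d <- role_dates(events, sets, "history_of_loss")

  idx_a <- if (length(rpl_d)) min(rpl_d) else as.Date(NA)
  idx_b <- as.Date(NA)
  if (length(hx_d) && length(loss_d)) {
    after <- loss_d[loss_d > min(hx_d)]
    if (length(after)) idx_b <- after[1]
  }
  idx_c <- as.Date(NA)
  if (length(loss_d) >= 2) {
    qual <- loss_d[loss_d - loss_d[1] >= 90]
    if (length(qual)) idx_c <- qual[1]
  }
  cand <- c(a = idx_a, b = idx_b, c = idx_c)
  if (all(is.na(cand))) return(NULL)
  best <- which.min(cand)   # ties resolve a, b, c by position
  list(index_date = cand[[best]],
       qualifying_rule = c("rpl_dx", "history_then_loss",
                           "two_losses_90d")[best])
}

#' Classify one person's record against the Control definition
#'
#' Qualifies with at least one live-birth record and a whole-record absence
#' of pregnancy-loss, RPL-diagnosis, history-of-loss and control-exclusion
#' records (no time restriction on the exclusions).
#' @param events Event rows for a single person.
#' @param sets Concept sets.
#' @return `NULL` when not qualifying, otherwise the first live-birth date.
#' @export
classify_control <- function(events, sets) {
  lb <- role_dates(events, sets, "live_birth")
  if (!length(lb)) return(NULL)
  for (r in c("pregnancy_loss", "rpl_diagnosis", "history_of_loss",
              "control_exclusion")) {
    if (length(role_dates(events, sets, r))) return(NULL)
  }
  min(lb)
}

# vectorized rule evaluation for whole sites
classify_all <- function(events, sets) {
  ev <- as.data.table(events)[, .(person_id, concept_id, event_date)]
  loss_ids <- concept_ids_for_role(sets, "pregnancy_loss")
  rpl_ids <- concept_ids_for_role(sets, "rpl_diagnosis")
  hx_ids <- concept_ids_for_role(sets, "history_of_loss")
  lb_ids <- concept_ids_for_role(sets, "live_birth")
  ex_ids <- concept_ids_for_role(sets, "control_exclusion")

  empty_idx <- function(col) {
    out <- data.table(person_id = character(), d = as.Date(character()))
    data.table::setnames(out, "d", col)
  }
  grp_min <- function(dt, col) {
    if (nrow(dt) == 0) return(empty_idx(col))
    out <- dt[, .(d = min(event_date)), by = person_id]
    data.table::setnames(out, "d", col)
  }

  a <- grp_min(ev[concept_id %in% rpl_ids], "idx_a")
  hx <- grp_min(ev[concept_id %in% hx_ids], "hx_min")
  loss <- ev[concept_id %in% loss_ids][order(person_id, event_date)]
  b <- grp_min(merge(loss, hx, by = "person_id")[event_date > hx_min],
               "idx_b")
  cc <- if (nrow(loss) == 0) empty_idx("idx_c") else {
    loss[, .(idx_c = {
      d <- event_date
      q <- d[d - d[1] >= 90]
      if (length(q)) q[1] else as.Date(NA)
    }), by = person_id][!is.na(idx_c)]
  }

  rpl <- merge(merge(a, b, by = "person_id", all = TRUE), cc,
               by = "person_id", all = TRUE)
  if (nrow(rpl)) {
    m <- as.matrix(rpl[, .(as.numeric(idx_a), as.numeric(idx_b),
                           as.numeric(idx_c))])
    best <- apply(m, 1, function(r) if (all(is.na(r))) NA_integer_
                  else which.min(r))
    rpl_df <- data.frame(
      person_id = rpl$person_id,
      group = "RPL",
      index_date = as.Date(apply(m, 1, min, na.rm = TRUE),
                           origin = "1970-01-01"),
      qualifying_rule = c("rpl_dx", "history_then_loss",
                          "two_losses_90d")[best],
      stringsAsFactors = FALSE)
    rpl_df <- rpl_df[!is.na(rpl_df$qualifying_rule), ]
  } else {
    rpl_df <- data.frame(person_id = character(), group = character(),
                         index_date = as.Date(character()),
                         qualifying_rule = character())
  }

  banned <- unique(ev[concept_id %in% c(loss_ids, rpl_ids, hx_ids, ex_ids),
                      person_id])
  lb <- grp_min(ev[concept_id %in% lb_ids & !person_id %in% banned],
                "index_date")
  ctrl_df <- if (nrow(lb)) {
    data.frame(person_id = lb$person_id, group = "Control",
               index_date = lb$index_date,
               qualifying_rule = "live_birth", stringsAsFactors = FALSE)
  } else {
    data.frame(person_id = character(), group = character(),
               index_date = as.Date(character()),
               qualifying_rule = character())
  }
  rbind(rpl_df, ctrl_df)
}

#' Apply demographic / data-quality / data-sufficiency filters
#'
#' Drops candidate cohort members failing, in order: missing birth date or
#' age at index outside `config$age_range` (demographics); index date
#' outside the person's recorded event span (data quality); fewer than
#' `config$min_visits` visits (data sufficiency).  Appends one attrition row
#' per step and group.
#'
#' @param candidates data.frame with `person_id`, `group`, `index_date`,
#'   `qualifying_rule`.
#' @param persons,events,visits Site tables.
#' @param config A [cohort_config()].
#' @return list with filtered `candidates` and the `attrition` rows.
#' @export
apply_quality_filters <- function(candidates, persons, events, visits,
                                  config = cohort_config()) {
  att <- list()
  note <- function(step, cand) {
    tab <- table(factor(cand$group, levels = c("RPL", "Control")))
    data.frame(step = step, group = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  att[[1]] <- note("classified", candidates)

  bd <- persons$birth_date[match(candidates$person_id, persons$person_id)]
  age <- as.numeric(candidates$index_date - bd) / 365.25
  keep <- !is.na(bd) & !is.na(age) &
    age >= config$age_range[1] & age <= config$age_range[2]
  candidates <- candidates[keep, , drop = FALSE]
  att[[2]] <- note("demographics", candidates)

  ev_sub <- as.data.table(events)[person_id %in% candidates$person_id]
  if (nrow(ev_sub)) {
    ev <- ev_sub[, .(first = min(event_date), last = max(event_date)),
                 by = person_id]
    span <- ev[match(candidates$person_id, ev$person_id)]
    keep <- !is.na(span$first) & candidates$index_date >= span$first &
      candidates$index_date <= span$last
    candidates <- candidates[keep, , drop = FALSE]
  } else {
    candidates <- candidates[0, , drop = FALSE]
  }
  att[[3]] <- note("data_quality", candidates)

  vcount <- table(visits$person_id)
  nv <- as.integer(vcount[candidates$person_id])
  nv[is.na(nv)] <- 0L
  candidates <- candidates[nv >= config$min_visits, , drop = FALSE]
  att[[4]] <- note("data_sufficiency", candidates)

  list(candidates = candidates, attrition = do.call(rbind, att))
}

#' Build the RPL / Control study cohort
#'
#' Full cohort construction: gender-inclusive demographic filter, RPL and
#' Control classification, quality filters, then per-person covariates —
#' age at index (years, from birth date), age stratum (`under35` iff
#' age < 35), visit count in the study window (visits dated up to index +
#' `post_index_days`), record span in years, and the number of distinct
#' mapped phenotypes in the window (when a crosswalk is supplied).
#'
#' @param persons,events,visits Site tables.
#' @param sets Concept sets covering all roles.
#' @param map Optional [read_phecode_map()] crosswalk; without it the
#'   distinct-diagnosis covariate is `NA`.
#' @param config A [cohort_config()].
#' @return list with `cohort` (one row per assigned person) and `attrition`.
#' @export
build_cohort <- function(persons, events, visits, sets, map = NULL,
                         config = cohort_config()) {
  unknown <- setdiff(unique(events$person_id), persons$person_id)
  if (length(unknown)) {
    stop(sprintf("%d person(s) appear in events but not in persons, e.g. '%s'",
                 length(unknown), unknown[1]), call. = FALSE)
  }
  att0 <- data.frame(step = "persons", group = c("RPL", "Control"),
                     n = nrow(persons), stringsAsFactors = FALSE)
  if (nrow(events) == 0) {
    empty <- data.frame(person_id = character(), group = character(),
                        index_date = as.Date(character()),
                        qualifying_rule = character())
    att <- rbind(att0, data.frame(step = "gender_inclusion",
                                  group = c("RPL", "Control"), n = 0L),
                 apply_quality_filters(empty, persons, events, visits,
                                       config)$attrition)
    return(list(cohort = cbind(empty, age_at_index = numeric(),
                               age_stratum = character(),
                               visits_in_window = integer(),
                               record_span_years = numeric(),
                               n_distinct_diagnoses = integer(),
                               gender_label = character(),
                               race = character(),
                               ethnicity = character()),
                attrition = att))
  }

  incl <- derive_inclusion_gender(persons, events, sets)
  kept <- incl$person_id[incl$include]
  att1 <- data.frame(step = "gender_inclusion", group = c("RPL", "Control"),
                     n = length(kept), stringsAsFactors = FALSE)

  ev_in <- events[events$person_id %in% kept, , drop = FALSE]
  candidates <- classify_all(ev_in, sets)
  qf <- apply_quality_filters(candidates, persons, events, visits, config)
  cohort <- qf$candidates

  bd <- persons$birth_date[match(cohort$person_id, persons$person_id)]
  cohort$age_at_index <- as.numeric(cohort$index_date - bd) / 365.25
  cohort$age_stratum <- ifelse(cohort$age_at_index < 35, "under35", "35plus")

  vt <- as.data.table(visits)[person_id %in% cohort$person_id]
  idx <- cohort$index_date[match(vt$person_id, cohort$person_id)]
  vw <- vt[visit_date <= idx + config$post_index_days, .N, by = person_id]
  cohort$visits_in_window <- vw$N[match(cohort$person_id, vw$person_id)]
  cohort$visits_in_window[is.na(cohort$visits_in_window)] <- 0L

  sp <- as.data.table(events)[person_id %in% cohort$person_id,
                              .(span = as.numeric(max(event_date) -
                                                    min(event_date)) / 365.25),
                              by = person_id]
  cohort$record_span_years <- sp$span[match(cohort$person_id, sp$person_id)]

  if (!is.null(map)) {
    ev <- as.data.table(events)[person_id %in% cohort$person_id]
    ev[, phecode := map_events(ev, map)]
    ev <- ev[!is.na(phecode)]
    idx <- cohort$index_date[match(ev$person_id, cohort$person_id)]
    ev <- ev[event_date <= idx + config$post_index_days]
    dc <- ev[, .(n = data.table::uniqueN(phecode)), by = person_id]
    cohort$n_distinct_diagnoses <- dc$n[match(cohort$person_id,
                                              dc$person_id)]
    cohort$n_distinct_diagnoses[is.na(cohort$n_distinct_diagnoses)] <- 0L
  } else {
    cohort$n_distinct_diagnoses <- NA_integer_
  }

  cohort$gender_label <- incl$gender_label[match(cohort$person_id,
                                                 incl$person_id)]
  pidx <- match(cohort$person_id, persons$person_id)
  cohort$race <- persons$race[pidx]
  cohort$ethnicity <- persons$ethnicity[pidx]
  rownames(cohort) <- NULL
  list(cohort = cohort, attrition = rbind(att0, att1, qf$attrition))
}
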