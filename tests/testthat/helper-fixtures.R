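# Shared fixture builders: tiny in-code concept sets, crosswalks and event
# tables, plus brute-force oracles used across test files.

toy_sets <- function() synthetic_concept_sets()

toy_map <- function() {
  read_phecode_map(system.file("extdata", "toy_phecode_map.csv",
                               package = "rplphewas"))
}

mk_events <- function(person_id, concept_id, day,
                      vocabulary = "SITE_LOCAL",
                      origin = as.Date("2015-01-01")) {
  n <- max(length(person_id), length(concept_id), length(day))
  if (length(person_id) == 0) n <- 0
  data.frame(person_id = rep_len(person_id, n),
             concept_id = rep_len(concept_id, n),
             vocabulary = rep_len(vocabulary, n),
             event_date = origin + rep_len(day, n),
             visit_id = rep(NA_character_, n), stringsAsFactors = FALSE)
}

mk_persons <- function(ids, birth = as.Date("1985-06-01"),
                       gender = "female", race = "white",
                       ethnicity = "not_hispanic_or_latino") {
  data.frame(person_id = ids, birth_date = birth, gender_code = gender,
             race = race, ethnicity = ethnicity, stringsAsFactors = FALSE)
}

mk_visits <- function(ids, n_each = 3, origin = as.Date("2015-01-01")) {
  n <- length(ids) * n_each
  data.frame(person_id = rep(ids, each = n_each),
             visit_id = rep_len(paste0("v", seq_len(max(n_each, 1))), n),
             visit_date = origin + rep_len(seq_len(max(n_each, 1)) * 30, n),
             stringsAsFactors = FALSE)
}

# Exhaustive pairwise RPL-rule oracle: evaluates every rule over all event
# pairs, independent of classify_rpl's single-pass logic.
oracle_rpl <- function(events, sets) {
  dat <- function(role) sort(events$event_date[
    events$concept_id %in% concept_ids_for_role(sets, role)])
  rpl_d <- dat("rpl_diagnosis"); loss_d <- dat("pregnancy_loss")
  hx_d <- dat("history_of_loss")
  cand <- list()
  if (length(rpl_d)) cand$rpl_dx <- min(rpl_d)
  best_b <- as.Date(NA)
  for (h in seq_along(hx_d)) for (l in seq_along(loss_d)) {
    if (loss_d[l] > hx_d[h] &&
        (is.na(best_b) || loss_d[l] < best_b)) best_b <- loss_d[l]
  }
  if (!is.na(best_b)) cand$history_then_loss <- best_b
  best_c <- as.Date(NA)
  if (length(loss_d) >= 2) {
    for (i in seq_along(loss_d)) for (j in seq_along(loss_d)) {
      if (j > i && as.numeric(loss_d[j] - loss_d[i]) >= 90 &&
          (is.na(best_c) || loss_d[j] < best_c)) best_c <- loss_d[j]
    }
  }
  if (!is.na(best_c)) cand$two_losses_90d <- best_c
  if (!length(cand)) return(NULL)
  dates <- do.call(c, cand)
  best <- which.min(dates)   # ties resolve in rule order a, b, c
  list(index_date = dates[[best]], qualifying_rule = names(cand)[best])
}

# random one-person record mixing outcome concepts; exercises the 89/90
# boundary by drawing gaps near 90 days
random_record <- function(sets) {
  n <- sample(1:7, 1)
  pool <- c("OMOP_LOSS", "OMOP_LOSS", "OMOP_RPL_DX", "OMOP_HX_LOSS",
            "OMOP_LIVEBIRTH", "OMOP_PRETERM_BIRTH")
  concepts <- sample(pool, n, replace = TRUE)
  days <- sample(c(0:30, 85:95, 170:190, 350:380), n, replace = TRUE)
  mk_events("p1", concepts, days)
}

# tiny deterministic association-results table for cross-site tests
mk_results <- function(phecode, or, adj_p, a = 50, c = 40,
                       analysis = "main") {
  n <- length(phecode)
  data.frame(phecode = phecode, label = phecode, category = "test",
             analysis = analysis,
             a = rep_len(a, n), b = 100, c = rep_len(c, n), d = 100,
             crude_or = or, adjusted_or = or,
             raw_p = adj_p, adj_p = adj_p,
             significant = adj_p < 0.05,
             direction = ifelse(or > 1, "positive", "negative"),
             fit_status = "ok", redacted = FALSE,
             stringsAsFactors = FALSE)
}
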