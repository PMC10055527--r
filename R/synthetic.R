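# Two-site synthetic OMOP-shaped EHR generator with known ground truth.
#
# The generator plants per-phenotype log odds ratios, group-specific age and
# visit-count distributions, and an optional utilization -> diagnosis slope,
# so that every downstream stage (phenotyping, matrix construction,
# association, cross-site comparison) can be validated against a truth table
# without any protected data.

SYN_CONCEPTS <- list(
  loss       = "OMOP_LOSS",
  rpl_dx     = "OMOP_RPL_DX",
  hx_loss    = "OMOP_HX_LOSS",
  live_birth = "OMOP_LIVEBIRTH",
  exclusion  = c("OMOP_PRETERM_BIRTH", "OMOP_ECTOPIC"),
  gender_div = "OMOP_GENDER_DIVERSE"
)

PHENOTYPE_CATEGORIES <- c(
  "genitourinary", "endocrine/metabolic", "mental disorders",
  "circulatory system", "digestive", "infectious diseases",
  "neoplasms", "pregnancy complications"
)

#' Concept sets used by the synthetic sites
#'
#' Seven sets covering every role: pregnancy loss, RPL diagnosis, history of
#' loss, live birth, control exclusions, incident pregnancy (any pregnancy
#' outcome record) and gender-diverse concepts.  These are synthetic
#' stand-ins for site-curated OMOP concept lists, structured the same way.
#' @return A `concept_sets` data.frame.
#' @export
synthetic_concept_sets <- function() {
  rows <- rbind(
    data.frame(set_name = "pregnancy_loss", role = "pregnancy_loss",
               concept_id = SYN_CONCEPTS$loss),
    data.frame(set_name = "rpl_diagnosis", role = "rpl_diagnosis",
               concept_id = SYN_CONCEPTS$rpl_dx),
    data.frame(set_name = "history_of_loss", role = "history_of_loss",
               concept_id = SYN_CONCEPTS$hx_loss),
    data.frame(set_name = "live_birth", role = "live_birth",
               concept_id = SYN_CONCEPTS$live_birth),
    data.frame(set_name = "control_exclusion", role = "control_exclusion",
               concept_id = SYN_CONCEPTS$exclusion),
    data.frame(set_name = "incident_pregnancy", role = "incident_pregnancy",
               concept_id = c(SYN_CONCEPTS$loss, SYN_CONCEPTS$live_birth,
                              SYN_CONCEPTS$rpl_dx)),
    data.frame(set_name = "gender_diverse", role = "gender_diverse",
               concept_id = SYN_CONCEPTS$gender_div)
  )
  as_concept_sets(rows)
}

#' Synthetic ICD -> Phecode crosswalk for a phenotype list
#'
#' Each phenotype gets one ICD10CM and one ICD9CM source code, both mapped
#' to the same Phecode so that the dual-vocabulary aggregation path is
#' exercised.  Categories cycle through a fixed list that includes
#' "pregnancy complications".
#' @param phenotypes Character vector of phecode ids.
#' @return A `phecode_map`.
#' @export
synthetic_phecode_map <- function(phenotypes) {
  n <- length(phenotypes)
  cat <- rep_len(PHENOTYPE_CATEGORIES, n)
  df <- rbind(
    data.frame(vocabulary = "ICD10CM",
               code = sprintf("SX%04d", seq_len(n)),
               phecode = phenotypes,
               phecode_label = paste("synthetic phenotype", phenotypes),
               category = cat),
    data.frame(vocabulary = "ICD9CM",
               code = sprintf("9%04d.1", seq_len(n)),
               phecode = phenotypes,
               phecode_label = paste("synthetic phenotype", phenotypes),
               category = cat)
  )
  as_phecode_map(df)
}

#' Configuration for one synthetic site
#'
#' Defaults emulate the UCSF-like site contrasts: cases older than controls
#' (age means 36.6 vs 33.4 years), near-equal visit medians (42 vs 41), a
#' lower Hispanic/Latino fraction among cases (11.7% vs 16.6%), and no
#' utilization -> diagnosis slope.  See [stanford_like_config()] for the
#' large-utilization-gap variant.
#'
#' @param n_rpl,n_control Persons per arm (must be > 0).
#' @param site_label Site name used in person ids and outputs.
#' @param seed Integer seed; the same config reproduces byte-identical CSVs.
#' @param age_model List: `mean_case`, `mean_control`, `sd`, `min`, `max`
#'   (years); ages are truncated-normal at the index date.
#' @param utilization_model List: `median_visits_case`,
#'   `median_visits_control`, `dispersion` (negative-binomial size).
#' @param planted_effects Named numeric: phenotype id -> planted log odds
#'   ratio for RPL vs Control.
#' @param baseline_prevalence Named numeric: phenotype id -> control-arm
#'   baseline probability; phenotypes missing here default to 0.10.
#' @param utilization_diagnosis_slope Log-odds of carrying any candidate
#'   diagnosis per additional visit (relative to the site median).
#' @param n_null_phenotypes Extra phenotypes with planted log OR 0, for FDR
#'   testing; baselines are spaced log-uniformly over [0.01, 0.20].
#' @param race_ethnicity_probs List with `race` (named probs, shared) and
#'   `ethnicity_case` / `ethnicity_control` (named probs over
#'   hispanic_or_latino / not_hispanic_or_latino / unknown).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_rpl = 2000, n_control = 2000,
                             site_label = "siteA", seed = 1,
                             age_model = list(mean_case = 36.6,
                                              mean_control = 33.4,
                                              sd = 6, min = 18, max = 55),
                             utilization_model = list(
                               median_visits_case = 42,
                               median_visits_control = 41,
                               dispersion = 1.5),
                             planted_effects = c("635.2" = log(2)),
                             baseline_prevalence = c("635.2" = 0.10),
                             utilization_diagnosis_slope = 0,
                             n_null_phenotypes = 10,
                             race_ethnicity_probs = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_rpl < 0 || n_control < 0) stop("counts must be >= 0", call. = FALSE)
  stopifnot(age_model$sd > 0, age_model$min < age_model$max,
            utilization_model$dispersion > 0,
            n_null_phenotypes >= 0)
  if (length(planted_effects) &&
      (is.null(names(planted_effects)) || any(names(planted_effects) == ""))) {
    stop("planted_effects must be a named numeric vector", call. = FALSE)
  }
  if (length(baseline_prevalence) &&
      (any(baseline_prevalence <= 0) || any(baseline_prevalence >= 1))) {
    stop("baseline prevalences must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(race_ethnicity_probs)) {
    race_ethnicity_probs <- list(
      race = c(white = 0.42, asian = 0.24, black = 0.07,
               other = 0.17, unknown = 0.10),
      ethnicity_case = c(hispanic_or_latino = 0.117,
                         not_hispanic_or_latino = 0.833, unknown = 0.05),
      ethnicity_control = c(hispanic_or_latino = 0.166,
                            not_hispanic_or_latino = 0.784, unknown = 0.05)
    )
  }
  structure(list(
    n_rpl = as.integer(n_rpl), n_control = as.integer(n_control),
    site_label = site_label, seed = as.integer(seed),
    age_model = age_model, utilization_model = utilization_model,
    planted_effects = planted_effects,
    baseline_prevalence = baseline_prevalence,
    utilization_diagnosis_slope = utilization_diagnosis_slope,
    n_null_phenotypes = as.integer(n_null_phenotypes),
    race_ethnicity_probs = race_ethnicity_probs
  ), class = "synthetic_config")
}

#' UCSF-like site configuration
#'
#' Near-equal visit medians (42 vs 41): utilization is essentially balanced
#' between arms, so visit-adjusted and unadjusted associations should agree.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @export
ucsf_like_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(site_label = "ucsf_like", seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

#' Stanford-like site configuration
#'
#' Large utilization gap between arms (visit medians 31 vs 14), a nonzero
#' utilization -> diagnosis slope, and a larger Hispanic/Latino contrast
#' (16.4% vs 29.3%): association estimates at this site should attenuate
#' when visit count is added as a covariate.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @export
stanford_like_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    site_label = "stanford_like", seed = seed,
    age_model = list(mean_case = 35.4, mean_control = 32.4,
                     sd = 6, min = 18, max = 55),
    utilization_model = list(median_visits_case = 31,
                             median_visits_control = 14, dispersion = 1.5),
    utilization_diagnosis_slope = 0.03,
    race_ethnicity_probs = list(
      race = c(white = 0.40, asian = 0.26, black = 0.05,
               other = 0.19, unknown = 0.10),
      ethnicity_case = c(hispanic_or_latino = 0.164,
                         not_hispanic_or_latino = 0.786, unknown = 0.05),
      ethnicity_control = c(hispanic_or_latino = 0.293,
                            not_hispanic_or_latino = 0.657, unknown = 0.05))
  )
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# mean parameter whose negative-binomial median equals `target`
# (deterministic grid search; qnbinom is a step function of mu)
nb_mu_for_median <- function(target, size) {
  if (target <= 0) return(0.01)
  mus <- seq(max(0.05, target / 3), target * 3 + 5, by = 0.05)
  med <- stats::qnbinom(0.5, size = size, mu = mus)
  hit <- which(med == target)
  if (!length(hit)) stop("no negative-binomial mean reaches median ", target)
  mus[hit[ceiling(length(hit) / 2)]]
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate one synthetic site
#'
#' Produces OMOP-shaped `persons`, `events` and `visits` tables plus a truth
#' table of planted effects.  Each RPL person satisfies exactly one
#' (uniformly chosen) qualifying rule: an RPL diagnosis code, a recorded
#' history of loss followed by a loss, or two losses at least 90 days apart.
#' Control persons carry one live-birth record and no loss or exclusion
#' records.  Candidate-phenotype events arise independently per person with
#' probability `plogis(qlogis(baseline) + logOR * I[case] +
#' slope * (visits - median))`, dated uniformly over the 3 years before
#' through 365 days after the index date.
#'
#' @param config A [synthetic_config()].
#' @param contamination_rate Fraction of Control persons who are truth-only
#'   prior-loss carriers: their candidate diagnoses follow the case model
#'   but no loss is recorded (must be in [0, 1)).
#' @return A `rpl_site` list: `persons`, `events`, `visits`, `truth`
#'   (phenotype-level), `person_truth` (person-level group + contamination),
#'   `concept_sets`, `phecode_map`, `config`.
#' @export
generate_site <- function(config, contamination_rate = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_rpl == 0 && config$n_control == 0) {
    stop("empty site: n_rpl and n_control are both zero", call. = FALSE)
  }
  if (contamination_rate < 0 || contamination_rate >= 1) {
    stop("contamination_rate must lie in [0, 1)", call. = FALSE)
  }
  with_seed(config$seed, generate_site_impl(config, contamination_rate))
}

generate_site_impl <- function(config, contamination_rate) {
  n_case <- config$n_rpl; n_ctrl <- config$n_control
  n <- n_case + n_ctrl
  case <- c(rep(1L, n_case), rep(0L, n_ctrl))
  pid <- sprintf("%s_%06d", config$site_label, seq_len(n))

  am <- config$age_model
  age <- rtruncnorm(n, ifelse(case == 1L, am$mean_case, am$mean_control),
                    am$sd, am$min, am$max)
  index_date <- as.Date("2012-01-01") +
    sample.int(as.integer(as.Date("2019-12-31") - as.Date("2012-01-01")),
               n, replace = TRUE)
  birth_date <- index_date - round(age * 365.25)

  # gender: a small male/other fraction stays includable through incident-
  # pregnancy records; a small fraction carries a gender-diverse concept
  gender_code <- sample(c("female", "male", "other"), n, replace = TRUE,
                        prob = c(0.995, 0.003, 0.002))
  tgd <- stats::runif(n) < 0.002

  rep_probs <- config$race_ethnicity_probs
  race <- sample(names(rep_probs$race), n, replace = TRUE,
                 prob = rep_probs$race)
  ethnicity <- character(n)
  ethnicity[case == 1L] <- sample(names(rep_probs$ethnicity_case),
                                  n_case, replace = TRUE,
                                  prob = rep_probs$ethnicity_case)
  ethnicity[case == 0L] <- sample(names(rep_probs$ethnicity_control),
                                  n_ctrl, replace = TRUE,
                                  prob = rep_probs$ethnicity_control)

  persons <- data.frame(person_id = pid, birth_date = birth_date,
                        gender_code = gender_code, race = race,
                        ethnicity = ethnicity, stringsAsFactors = FALSE)

  # visit counts: 1 + negative binomial tuned so the total median matches
  um <- config$utilization_model
  mu_case <- nb_mu_for_median(um$median_visits_case - 1L, um$dispersion)
  mu_ctrl <- nb_mu_for_median(um$median_visits_control - 1L, um$dispersion)
  n_visits <- 1L + stats::rnbinom(n, size = um$dispersion,
                                  mu = ifelse(case == 1L, mu_case, mu_ctrl))
  visit_offsets <- lapply(n_visits, function(k) sample(-1095:365, k,
                                                       replace = TRUE))
  visits <- data.frame(
    person_id = rep(pid, n_visits),
    visit_id = unlist(lapply(n_visits, seq_len), use.names = FALSE),
    visit_date = rep(index_date, n_visits) +
      unlist(visit_offsets, use.names = FALSE),
    stringsAsFactors = FALSE)
  visits$visit_id <- paste0("v", visits$visit_id)

  # outcome-defining events
  rule <- integer(n)
  rule[case == 1L] <- sample(1:3, n_case, replace = TRUE)
  ev <- list()
  loc_event <- function(ids, concepts, dates) {
    data.frame(person_id = ids, concept_id = concepts,
               vocabulary = "SITE_LOCAL", event_date = dates,
               visit_id = NA_character_, stringsAsFactors = FALSE)
  }
  ia <- which(rule == 1L)
  if (length(ia)) {
    ev$a <- loc_event(pid[ia], SYN_CONCEPTS$rpl_dx, index_date[ia])
  }
  ib <- which(rule == 2L)
  if (length(ib)) {
    gap <- sample(30:400, length(ib), replace = TRUE)
    ev$b <- rbind(
      loc_event(pid[ib], SYN_CONCEPTS$hx_loss, index_date[ib] - gap),
      loc_event(pid[ib], SYN_CONCEPTS$loss, index_date[ib]))
  }
  ic <- which(rule == 3L)
  if (length(ic)) {
    gap <- sample(90:400, length(ic), replace = TRUE)
    ev$c <- rbind(
      loc_event(pid[ic], SYN_CONCEPTS$loss, index_date[ic] - gap),
      loc_event(pid[ic], SYN_CONCEPTS$loss, index_date[ic]))
  }
  ictrl <- which(case == 0L)
  ev$ctrl <- loc_event(pid[ictrl], SYN_CONCEPTS$live_birth,
                       index_date[ictrl])
  if (any(tgd)) {
    ev$tgd <- loc_event(pid[tgd], SYN_CONCEPTS$gender_div,
                        index_date[tgd] - sample(0:1000, sum(tgd),
                                                 replace = TRUE))
  }

  # phenotype truth table: planted effects plus nulls
  planted <- config$planted_effects
  null_ids <- if (config$n_null_phenotypes > 0) {
    sprintf("null_%03d", seq_len(config$n_null_phenotypes))
  } else character(0)
  phen <- c(names(planted), null_ids)
  base <- c(
    vapply(names(planted), function(p)
      unname(config$baseline_prevalence[p] %||% NA_real_), 0),
    exp(seq(log(0.01), log(0.20),
            length.out = max(config$n_null_phenotypes, 1)))[
              seq_len(config$n_null_phenotypes)]
  )
  base[is.na(base)] <- 0.10
  logor <- c(unname(planted), rep(0, config$n_null_phenotypes))
  truth <- data.frame(phenotype = phen, planted_log_or = logor,
                      baseline_prevalence = base,
                      null = logor == 0, stringsAsFactors = FALSE)

  # truth-only prior-loss carriers among controls (unrecorded losses)
  contaminated <- rep(FALSE, n)
  if (contamination_rate > 0 && n_ctrl > 0) {
    contaminated[case == 0L] <- stats::runif(n_ctrl) < contamination_rate
  }
  case_like <- ifelse(case == 1L | contaminated, 1, 0)

  # candidate-phenotype events
  med_visits <- stats::median(n_visits)
  slope <- config$utilization_diagnosis_slope
  map <- synthetic_phecode_map(phen)
  icd10 <- map$code[match(phen, map$phecode)]
  icd9 <- map$code[nrow(map) / 2 + match(phen, map$phecode[
    seq_len(nrow(map) / 2)])]
  phen_ev <- vector("list", length(phen))
  for (j in seq_along(phen)) {
    pj <- stats::plogis(stats::qlogis(base[j]) + logor[j] * case_like +
                          slope * (n_visits - med_visits))
    hit <- which(stats::runif(n) < pj)
    if (!length(hit)) next
    voc <- sample(c("ICD10CM", "ICD9CM"), length(hit), replace = TRUE)
    phen_ev[[j]] <- data.frame(
      person_id = pid[hit],
      concept_id = ifelse(voc == "ICD10CM", icd10[j], icd9[j]),
      vocabulary = voc,
      event_date = index_date[hit] + sample(-1095:365, length(hit),
                                            replace = TRUE),
      visit_id = NA_character_, stringsAsFactors = FALSE)
  }
  events <- rbind(do.call(rbind, ev), do.call(rbind, phen_ev))
  events <- events[order(events$person_id, events$event_date,
                         events$concept_id), ]
  rownames(events) <- NULL

  structure(list(
    persons = persons, events = events, visits = visits, truth = truth,
    person_truth = data.frame(
      person_id = pid, group = ifelse(case == 1L, "RPL", "Control"),
      qualifying_rule = c("rpl_dx", "history_then_loss",
                          "two_losses_90d")[ifelse(rule == 0L, NA, rule)],
      index_date = index_date, contaminated = contaminated,
      stringsAsFactors = FALSE),
    concept_sets = synthetic_concept_sets(), phecode_map = map,
    config = config
  ), class = "rpl_site")
}

#' Generate a site with all planted effects forced to zero
#'
#' Same generator as [generate_site()] with every planted log odds ratio set
#' to 0, so the truth table is all-null; used for false-discovery-rate
#' property checks.
#' @param config A [synthetic_config()].
#' @export
generate_null_site <- function(config) {
  config$planted_effects[] <- 0
  generate_site(config)
}

#' Generate a site with unrecorded prior losses among Controls
#'
#' Emulates control-group contamination: a fraction of Control persons are
#' truth-only loss carriers whose candidate diagnoses follow the case model
#' while their recorded data still qualify them as Controls.  Planted
#' odds-ratio estimates attenuate toward 1 as the rate grows.
#' @param config A [synthetic_config()].
#' @param contamination_rate Fraction in [0, 1).
#' @export
generate_contaminated_controls <- function(config, contamination_rate) {
  generate_site(config, contamination_rate = contamination_rate)
}

#' Write a synthetic site to CSV files
#'
#' Writes `persons.csv`, `events.csv`, `visits.csv`, `truth.csv`,
#' `person_truth.csv`, `concept_sets.csv` and `phecode_map.csv` under `dir`.
#' @param site A `rpl_site` from [generate_site()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_site <- function(site, dir) {
  stopifnot(inherits(site, "rpl_site"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_study_csv(site$persons, file.path(dir, "persons.csv"))
  write_study_csv(site$events, file.path(dir, "events.csv"))
  write_study_csv(site$visits, file.path(dir, "visits.csv"))
  write_study_csv(site$truth, file.path(dir, "truth.csv"))
  write_study_csv(site$person_truth, file.path(dir, "person_truth.csv"))
  write_concept_sets(site$concept_sets, file.path(dir, "concept_sets.csv"))
  write_phecode_map(site$phecode_map, file.path(dir, "phecode_map.csv"))
  invisible(dir)
}

#' @export
print.rpl_site <- function(x, ...) {
  cat(sprintf(
    "Synthetic EHR site '%s': %d RPL + %d Control persons, %d events, %d phenotypes (%d null)\n",
    x$config$site_label, x$config$n_rpl, x$config$n_control,
    nrow(x$events), nrow(x$truth), sum(x$truth$null)))
  invisible(x)
}
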