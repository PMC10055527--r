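sets <- synthetic_concept_sets()

test_that("gender-inclusive filter admits by gender or incident pregnancy", {
  persons <- mk_persons(c("m1", "f1", "f2", "m2"),
                        gender = c("male", "female", "female", "male"))
  events <- rbind(mk_events("m1", "OMOP_LIVEBIRTH", 0),
                  mk_events("f2", "OMOP_GENDER_DIVERSE", 10))
  out <- derive_inclusion_gender(persons, events, sets)
  expect_equal(out$include, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$gender_label, c("cis_woman", "cis_woman", "tgd", "other"))
})

test_that("two losses qualify at >= 90 days apart, indexed at the second", {
  q <- classify_rpl(mk_events("p", c("OMOP_LOSS", "OMOP_LOSS"), c(0, 90)),
                    sets)
  expect_equal(q$qualifying_rule, "two_losses_90d")
  expect_equal(q$index_date, as.Date("2015-01-01") + 90)
  expect_null(classify_rpl(
    mk_events("p", c("OMOP_LOSS", "OMOP_LOSS"), c(0, 89)), sets))
})

test_that("history-then-loss requires a strictly later loss and earliest rule wins", {
  ev <- mk_events("p", c("OMOP_HX_LOSS", "OMOP_RPL_DX", "OMOP_LOSS"),
                  c(0, 50, 10))
  q <- classify_rpl(ev, sets)
  expect_equal(q$qualifying_rule, "history_then_loss")
  expect_equal(q$index_date, as.Date("2015-01-01") + 10)
  # same-day history + loss does not satisfy the history rule
  expect_null(classify_rpl(
    mk_events("p", c("OMOP_HX_LOSS", "OMOP_LOSS"), c(5, 5)), sets))
})

test_that("controls require a live birth and a whole-record exclusion screen", {
  lb <- mk_events("p", "OMOP_LIVEBIRTH", 0)
  expect_equal(classify_control(lb, sets), as.Date("2015-01-01"))
  # preterm-labor record five years later still excludes
  expect_null(classify_control(
    rbind(lb, mk_events("p", "OMOP_PRETERM_BIRTH", 5 * 365)), sets))
  # live birth + single loss: excluded from Control, not enough for RPL
  both <- rbind(lb, mk_events("p", "OMOP_LOSS", 200))
  expect_null(classify_control(both, sets))
  expect_null(classify_rpl(both, sets))
})

test_that("classification matches the exhaustive pairwise oracle and is sort-independent", {
  set.seed(99)
  for (i in 1:80) {
    ev <- random_record(sets)
    want <- oracle_rpl(ev, sets)
    got <- classify_rpl(ev, sets)
    shuffled <- classify_rpl(ev[sample(nrow(ev)), , drop = FALSE], sets)
    if (is.null(want)) {
      expect_null(got)
      expect_null(shuffled)
    } else {
      expect_equal(got, want)
      expect_equal(shuffled, want)
    }
  }
})

test_that("quality filters drop on the declared rules with non-increasing attrition", {
  origin <- as.Date("2015-01-01")
  persons <- mk_persons(c("ok", "nobd", "old"), birth = origin - 30 * 365)
  persons$birth_date[2] <- NA
  persons$birth_date[3] <- origin - 70 * 365
  cand <- data.frame(person_id = c("ok", "nobd", "old"), group = "RPL",
                     index_date = origin + 90,
                     qualifying_rule = "rpl_dx", stringsAsFactors = FALSE)
  events <- mk_events(c("ok", "nobd", "old"), "OMOP_RPL_DX",
                      c(0, 0, 0))
  events <- rbind(events, mk_events(c("ok", "nobd", "old"), "OMOP_LOSS",
                                    c(120, 120, 120)))
  visits <- mk_visits(c("ok", "nobd", "old"))
  out <- apply_quality_filters(cand, persons, events, visits)
  expect_equal(out$candidates$person_id, "ok")
  att <- out$attrition[out$attrition$group == "RPL", ]
  expect_equal(att$n[att$step == "classified"], 3)
  expect_equal(att$n[att$step == "demographics"], 1)
  expect_true(all(diff(att$n) <= 0))
})

test_that("attrition counts never increase across steps on random cohorts", {
  set.seed(5)
  origin <- as.Date("2015-01-01")
  for (i in 1:10) {
    n <- 30
    ids <- paste0("p", 1:n)
    persons <- mk_persons(ids, birth = origin - sample(3000:25000, n))
    persons$birth_date[sample(n, 3)] <- NA
    cand <- data.frame(person_id = ids,
                       group = sample(c("RPL", "Control"), n, TRUE),
                       index_date = origin + sample(0:400, n, TRUE),
                       qualifying_rule = "rpl_dx", stringsAsFactors = FALSE)
    events <- mk_events(rep(ids, 2), "OMOP_LOSS",
                        sample(-200:600, 2 * n, TRUE))
    visits <- mk_visits(sample(ids, 20))
    att <- apply_quality_filters(cand, persons, events, visits)$attrition
    for (g in c("RPL", "Control")) {
      expect_true(all(diff(att$n[att$group == g]) <= 0))
    }
  }
})

test_that("the 35-year age-stratum boundary is sharp at the index date", {
  origin <- as.Date("2015-06-01")
  persons <- mk_persons(c("young", "older"))
  persons$birth_date <- c(origin - round(34.9 * 365.25),
                          origin - ceiling(35.0 * 365.25))
  events <- rbind(
    mk_events(c("young", "older"), "OMOP_RPL_DX", 0,
              origin = origin),
    mk_events(c("young", "older"), "OMOP_LOSS", 30, origin = origin))
  visits <- mk_visits(c("young", "older"), origin = origin)
  bc <- build_cohort(persons, events, visits, sets)
  expect_equal(bc$cohort$age_stratum[bc$cohort$person_id == "young"],
               "under35")
  expect_equal(bc$cohort$age_stratum[bc$cohort$person_id == "older"],
               "35plus")
  expect_true(all(bc$cohort$age_at_index[
    bc$cohort$age_stratum == "under35"] < 35))
})

test_that("degenerate inputs: empty events and unknown persons", {
  persons <- mk_persons("p1")
  empty <- build_cohort(persons, mk_events(character(), character(),
                                           numeric()),
                        mk_visits(character(), 0), sets)
  expect_equal(nrow(empty$cohort), 0)
  expect_true(all(empty$attrition$n[empty$attrition$step != "persons"] == 0))
  expect_error(
    build_cohort(persons, mk_events("ghost", "OMOP_LOSS", 0),
                 mk_visits("p1"), sets),
    "ghost")
})

test_that("groups are disjoint and loss records never reach Control", {
  site <- generate_site(ucsf_like_config(seed = 21, n_rpl = 150,
                                         n_control = 150,
                                         n_null_phenotypes = 5))
  bc <- build_cohort(site$persons, site$events, site$visits,
                     site$concept_sets, map = site$phecode_map)
  expect_equal(anyDuplicated(bc$cohort$person_id), 0)
  loss_people <- unique(site$events$person_id[
    site$events$concept_id == "OMOP_LOSS"])
  ctrl <- bc$cohort$person_id[bc$cohort$group == "Control"]
  expect_length(intersect(loss_people, ctrl), 0)
})
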