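test_that("shared alignment is an inner join with accounted leftovers", {
  ra <- mk_results(c("A", "B", "C"), or = c(2, 0.5, 1.5),
                   adj_p = c(0.01, 0.02, 0.5))
  rb <- mk_results(c("B", "C", "D"), or = c(0.4, 2, 3),
                   adj_p = c(0.01, 0.04, 0.2))
  sh <- align_shared(ra, rb)
  expect_setequal(sh$phecode, c("B", "C"))
  expect_equal(length(attr(sh, "unmatched_a")) + nrow(sh), nrow(ra))
  expect_equal(length(attr(sh, "unmatched_b")) + nrow(sh), nrow(rb))
  expect_equal(nrow(align_shared(ra, ra)), nrow(ra))
  expect_error(align_shared(ra, mk_results("Z", 2, 0.1)), "no shared")
})

test_that("concordance classes follow the definitions, including discordance", {
  ra <- mk_results(c("A", "B", "C", "D", "E"),
                   or = c(2.0, 0.5, 0.5, 2.0, 1.2),
                   adj_p = c(0.01, 0.01, 0.01, 0.3, 0.3))
  rb <- mk_results(c("A", "B", "C", "D", "E"),
                   or = c(3.0, 0.6, 2.0, 2.0, 0.9),
                   adj_p = c(0.02, 0.04, 0.01, 0.01, 0.3))
  cls <- concordance_classes(align_shared(ra, rb))
  got <- stats::setNames(cls$concordance, cls$phecode)
  expect_equal(unname(got[c("A", "B", "C", "D", "E")]),
               c("validated_positive", "validated_negative", "discordant",
                 "single_site_only", "neither"))
})

test_that("concordance classes partition random shared sets (enumeration oracle)", {
  set.seed(14)
  n <- 100
  ra <- mk_results(paste0("P", 1:n), or = exp(rnorm(n)),
                   adj_p = runif(n))
  rb <- mk_results(paste0("P", 1:n), or = exp(rnorm(n)),
                   adj_p = runif(n))
  cls <- concordance_classes(align_shared(ra, rb))
  oracle <- character(n)
  for (i in 1:n) {
    sa <- ra$adj_p[i] < 0.05; sb <- rb$adj_p[i] < 0.05
    pa <- ra$adjusted_or[i] > 1; pb <- rb$adjusted_or[i] > 1
    oracle[i] <- if (sa && sb) {
      if (pa && pb) "validated_positive"
      else if (!pa && !pb) "validated_negative" else "discordant"
    } else if (sa || sb) "single_site_only" else "neither"
  }
  expect_equal(cls$concordance, oracle)
  expect_equal(sum(table(cls$concordance)), n)   # partition
})

test_that("hypergeometric overlap matches exhaustive enumeration and is symmetric", {
  expect_equal(overlap_enrichment(10, 3, 4, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(overlap_enrichment(50, 8, 20, 0), 1.0)
  expect_error(overlap_enrichment(10, 3, 4, 5), "exceeds")

  set.seed(20)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    ka <- sample(0:n, 1); kb <- sample(0:n, 1)
    x <- sample(0:min(ka, kb), 1)
    # enumerate all C(n, kb) draws of site-B hits among n shared candidates
    draws <- utils::combn(n, max(kb, 1), simplify = FALSE)
    if (kb == 0) draws <- list(integer(0))
    marked <- seq_len(ka)
    frac <- mean(vapply(draws,
                        function(d) sum(d %in% marked) >= x, TRUE))
    expect_equal(overlap_enrichment(n, ka, kb, x), frac,
                 tolerance = 1e-12)
    expect_equal(overlap_enrichment(n, ka, kb, x),
                 overlap_enrichment(n, kb, ka, x), tolerance = 1e-12)
  }
})

test_that("spearman correlation is rank-based and monotone-invariant", {
  x <- c(0.5, 1.2, 2.0, 3.5, 9.0)
  y <- exp(x)
  expect_equal(spearman_or(x, y)$r, 1.0)
  set.seed(25)
  a <- exp(rnorm(20)); b <- exp(rnorm(20))
  sp <- spearman_or(a, b)
  expect_equal(sp$r, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(spearman_or(log(a), log(b))$r, sp$r)
  expect_true(spearman_or(rep(1, 5), 1:5)$constant)
  expect_error(spearman_or(1:2, 1:2), "at least 3")
})

test_that("sensitivity attenuation percent changes follow the convention", {
  rm_ <- mk_results(c("A", "B"), or = c(2.0, 4.0), adj_p = c(0.01, 0.01))
  rs <- mk_results(c("A", "B"), or = c(1.0, 3.0), adj_p = c(0.01, 0.01),
                   analysis = "utilization")
  d <- sensitivity_delta(rm_, rs)
  expect_equal(sort(d$table$pct_change), c(25, 50))
  expect_equal(d$median_pct_change, 37.5)
  expect_equal(sensitivity_delta(rm_, rm_)$median_pct_change, 0)
  # scaling both OR vectors leaves percent changes unchanged
  rm2 <- rm_; rm2$adjusted_or <- rm2$adjusted_or * 3
  rs2 <- rs; rs2$adjusted_or <- rs2$adjusted_or * 3
  expect_equal(sensitivity_delta(rm2, rs2)$table$pct_change,
               d$table$pct_change)
  rnone <- mk_results(c("A", "B"), or = c(1, 1), adj_p = c(0.9, 0.9))
  expect_error(sensitivity_delta(rnone, rnone), "significant")
})

test_that("strata comparison uses the significant union with strict ties", {
  ry <- mk_results(c("A", "B", "C"), or = c(3, 2, 1.1),
                   adj_p = c(0.01, 0.01, 0.8))
  ro <- mk_results(c("A", "B", "C"), or = c(2, 2, 1.0),
                   adj_p = c(0.01, 0.3, 0.8))
  st <- strata_comparison(ry, ro)
  expect_equal(st$n_union, 2)              # C significant nowhere
  expect_equal(st$n_higher_young, 1)       # B ties -> not higher
  expect_equal(st$fraction_higher_young, 0.5)
  expect_lte(st$n_union, sum(ry$significant) + sum(ro$significant))
})

test_that("two sites with the same strong planted truth cross-validate", {
  planted <- c("614.5" = 1.1, "626.2" = 1.1, "642.1" = -1.1)
  run_site <- function(maker, seed) {
    site <- generate_site(maker(
      seed = seed, n_rpl = 1500, n_control = 1500,
      planted_effects = planted,
      baseline_prevalence = stats::setNames(rep(0.1, 3), names(planted)),
      n_null_phenotypes = 40))
    bc <- build_cohort(site$persons, site$events, site$visits,
                       site$concept_sets, map = site$phecode_map)
    pm <- build_matrix(bc$cohort, site$events, site$phecode_map)
    run_analysis(pm, bc$cohort)
  }
  ra <- run_site(ucsf_like_config, 41)
  rb <- run_site(ucsf_like_config, 42)
  comp <- compare_sites(ra, rb)
  cls <- stats::setNames(comp$shared$concordance, comp$shared$phecode)
  expect_equal(unname(cls["614.5"]), "validated_positive")
  expect_equal(unname(cls["626.2"]), "validated_positive")
  expect_equal(unname(cls["642.1"]), "validated_negative")
  expect_lt(comp$hypergeom_p_positive, 0.05)
  expect_gt(comp$spearman$r, 0)

  # a site with heavy utilization confounding still cross-validates the
  # planted positive effects through the intersection filter (negative
  # effects there are pushed toward the null by the utilization link)
  rc <- run_site(stanford_like_config, 43)
  comp2 <- compare_sites(ra, rc)
  cls2 <- stats::setNames(comp2$shared$concordance, comp2$shared$phecode)
  expect_equal(unname(cls2["614.5"]), "validated_positive")
  expect_equal(unname(cls2["626.2"]), "validated_positive")
  expect_false(cls2[["642.1"]] %in% c("validated_positive", "discordant"))
})
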