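mini_cohort <- function(n = 40) {
  set.seed(30)
  data.frame(
    person_id = paste0("p", 1:n),
    group = rep(c("RPL", "Control"), each = n / 2),
    index_date = as.Date("2016-01-01"),
    age_at_index = c(rnorm(n / 2, 37, 4), rnorm(n / 2, 33, 4)),
    age_stratum = "under35",
    visits_in_window = rpois(n, 20),
    record_span_years = runif(n, 0.5, 6),
    n_distinct_diagnoses = rpois(n, 8),
    gender_label = "cis_woman",
    race = sample(c("white", "asian"), n, TRUE),
    ethnicity = sample(c("hispanic_or_latino", "not_hispanic_or_latino"),
                       n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("cohort summary medians match a sort-and-middle oracle", {
  cohort <- mini_cohort()
  s <- cohort_summary(cohort)
  mid <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  rpl <- cohort$group == "RPL"
  age_row <- s$continuous[s$continuous$variable == "age", ]
  expect_equal(age_row$median_rpl, mid(cohort$age_at_index[rpl]))
  expect_equal(age_row$median_control, mid(cohort$age_at_index[!rpl]))
  expect_true(all(s$continuous$p_value >= 0 & s$continuous$p_value <= 1))
  expect_setequal(s$categorical$variable, c("race", "ethnicity",
                                            "gender_label"))
  expect_error(cohort_summary(cohort[rpl, ]), "both")
})

test_that("cloned groups give null comparison p-values", {
  half <- mini_cohort()[1:20, ]
  clone <- half
  clone$group <- "Control"
  clone$person_id <- paste0("c", 1:20)
  s <- cohort_summary(rbind(half, clone))
  expect_true(all(s$continuous$p_value > 0.99))
})

test_that("embedding is deterministic, 2-d, and refuses outcome-indicating columns", {
  set.seed(44)
  n <- 40
  M <- Matrix::Matrix(matrix(rbinom(n * 6, 1, 0.4), n, 6), sparse = TRUE)
  rownames(M) <- paste0("p", 1:n)
  colnames(M) <- paste0("ph", 1:6)
  pm <- structure(list(
    M = M,
    persons = data.frame(person_id = rownames(M),
                         group = rep(c("RPL", "Control"), n / 2)),
    phenotypes = data.frame(phecode = colnames(M), label = colnames(M),
                            category = "genitourinary"),
    post_index_days = 365), class = "phenotype_matrix")
  e1 <- embed_diagnoses(pm, seed = 7)
  e2 <- embed_diagnoses(pm, seed = 7)
  expect_identical(e1$coords, e2$coords)
  expect_equal(dim(e1$coords), c(n, 2))

  preg <- pm
  preg$phenotypes$category[2] <- "pregnancy complications"
  expect_error(embed_diagnoses(preg, seed = 7), "pregnancy")
})

test_that("well-separated diagnosis blocks separate in the embedding", {
  set.seed(50)
  n <- 60
  block <- rep(c(0, 1), each = n / 2)
  M <- cbind(matrix(rbinom(n * 5, 1, ifelse(block == 0, 0.9, 0.05)), n, 5),
             matrix(rbinom(n * 5, 1, ifelse(block == 0, 0.05, 0.9)), n, 5))
  rownames(M) <- paste0("p", 1:n)
  colnames(M) <- paste0("ph", 1:10)
  pm <- structure(list(
    M = Matrix::Matrix(M, sparse = TRUE),
    persons = data.frame(person_id = rownames(M),
                         group = ifelse(block == 0, "RPL", "Control")),
    phenotypes = data.frame(phecode = colnames(M), label = colnames(M),
                            category = "digestive"),
    post_index_days = 365), class = "phenotype_matrix")
  emb <- embed_diagnoses(pm, seed = 3)
  centers <- apply(emb$coords, 2, function(v) tapply(v, block, mean))
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  within <- mean(sqrt(rowSums((emb$coords -
                                 centers[block + 1, ])^2)))
  expect_gt(between, within)
})

test_that("coordinate group tests match exact rank-sum enumeration", {
  # {1,2} vs {3,4}: U = 0, two-sided exact p = 2/choose(4,2) = 1/3
  coords <- cbind(c(1, 2, 3, 4), c(5, 6, 7, 8))
  p <- coord_group_tests(coords, labels = c("a", "a", "b", "b"))
  expect_equal(unname(p[1]), 1 / 3, tolerance = 1e-12)
  # identical coordinate multisets: no evidence of a difference
  same <- cbind(rep(c(1, 2, 3), 2), rep(c(4, 5, 6), 2))
  p2 <- coord_group_tests(same, labels = rep(c("a", "b"), each = 3))
  expect_true(all(p2 >= 0.9))
  expect_error(coord_group_tests(coords, labels = rep("a", 4)), "two label")

  # randomized agreement with a brute-force rank-sum over all splits
  set.seed(60)
  for (i in 1:25) {
    v <- runif(8)
    lab <- sample(rep(c("a", "b"), each = 4))
    got <- coord_group_tests(cbind(v, v), labels = lab)[1]
    splits <- utils::combn(8, 4)
    w_obs <- sum(rank(v)[lab == "a"])
    w_all <- apply(splits, 2, function(ix) sum(rank(v)[ix]))
    mu <- 4 * (8 + 1) / 2
    p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    expect_equal(unname(got), p_exact, tolerance = 1e-8)
  }
})

test_that("plot data obey the volcano and log-log filters", {
  res <- mk_results(paste0("P", 1:6),
                    or = c(2, 0.5, 3, 1.5, 0.8, 2.5),
                    adj_p = c(0.01, 0.2, 0.001, 0.04, 0.01, 0.03),
                    a = c(50, 50, 5, 50, 50, 12),
                    c = c(40, 40, 5, 40, 40, 3))
  res$raw_p <- res$adj_p / 2
  res <- redact(res)
  ra <- res
  rb <- res
  comp <- compare_sites(ra, rb)
  out <- tempfile()
  paths <- make_plots(res, comp, out)
  vol <- utils::read.csv(paths$volcano_data)
  expect_setequal(vol$phecode, res$phecode[res$significant])
  ll <- utils::read.csv(paths$loglog_data)
  # P3 redacted (a=5, c=5 both sites) must be excluded from log-log points
  expect_false("P3" %in% ll$phecode)
  keep <- res$significant & !res$redacted &
    (res$a >= 10 | res$c >= 10)
  expect_setequal(ll$phecode, res$phecode[keep])
  man <- utils::read.csv(paths$manhattan_data)
  expect_equal(nrow(man), sum(!res$redacted))
})

test_that("the pipeline runs end to end, deterministically, and names failing stages", {
  out1 <- file.path(tempfile(), "run1")
  cfg <- list(out_dir = out1, seed = "5",
              site_a_n_rpl = "150", site_a_n_control = "150",
              site_b_n_rpl = "150", site_b_n_control = "150",
              site_b_profile = "stanford_like", n_null_phenotypes = "8")
  run_pipeline(cfg)
  need <- c("cohort_a.csv", "attrition_a.csv", "results_main_a.csv",
            "results_under35_a.csv", "results_over35_a.csv",
            "results_utilization_a.csv", "comparison.csv",
            "comparison_summary.json", "plots/manhattan_data.csv")
  for (f in need) expect_true(file.exists(file.path(out1, f)), label = f)

  out2 <- file.path(tempfile(), "run2")
  cfg$out_dir <- out2
  run_pipeline(cfg)
  expect_identical(readLines(file.path(out1, "results_main_a.csv")),
                   readLines(file.path(out2, "results_main_a.csv")))

  # a missing input aborts at the named stage
  bad <- cfg
  bad$out_dir <- file.path(tempfile(), "run3")
  bad$site_a_dir <- tempfile()
  expect_error(run_pipeline(bad), "simulate_a")
})
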