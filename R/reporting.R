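# Cohort summary tables, UMAP cohort visualization, the three plot types
# (Manhattan, volcano, log-log) and end-to-end pipeline orchestration.

#' Per-group cohort summary with comparison tests
#'
#' Medians of age at index, study-window visit count, record span and
#' distinct diagnosis count per group, with Welch two-sample t-tests on the
#' underlying per-person values; categorical race / ethnicity / gender
#' distributions are compared with chi-square tests.  Medians are reported
#' alongside the t-tests, as both describe the same underlying values.
#'
#' @param cohort Cohort table from [build_cohort()] (both groups present).
#' @return list: `n` (group sizes), `continuous` (variable, per-group
#'   median, t-test p), `categorical` (variable, chi-square p).
#' @export
cohort_summary <- function(cohort) {
  groups <- unique(cohort$group)
  if (length(groups) < 2) {
    stop("cohort summary needs both RPL and Control groups", call. = FALSE)
  }
  rpl <- cohort$group == "RPL"
  cont_vars <- c(age = "age_at_index", visits = "visits_in_window",
                 record_span_years = "record_span_years",
                 n_diagnoses = "n_distinct_diagnoses")
  cont <- do.call(rbind, lapply(names(cont_vars), function(nm) {
    v <- cohort[[cont_vars[[nm]]]]
    if (all(is.na(v))) return(NULL)
    tt <- stats::t.test(v[rpl], v[!rpl])   # Welch by default
    data.frame(variable = nm,
               median_rpl = stats::median(v[rpl], na.rm = TRUE),
               median_control = stats::median(v[!rpl], na.rm = TRUE),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  cat_vars <- intersect(c("race", "ethnicity", "gender_label"),
                        names(cohort))
  cat <- do.call(rbind, lapply(cat_vars, function(nm) {
    tab <- table(cohort$group, cohort[[nm]])
    p <- if (min(dim(tab)) < 2) NA_real_ else {
      suppressWarnings(stats::chisq.test(tab)$p.value)
    }
    data.frame(variable = nm, p_value = p, stringsAsFactors = FALSE)
  }))
  list(n = c(RPL = sum(rpl), Control = sum(!rpl)),
       continuous = cont, categorical = cat)
}

#' UMAP embedding of the diagnosis matrix
#'
#' Two-dimensional UMAP of the one-hot diagnosis matrix.  The input must
#' already have pregnancy-complication columns removed (see
#' [drop_pregnancy_category()]); a remaining pregnancy-category column is a
#' hard error, so the embedding cannot be driven by diagnoses that indicate
#' the outcome.  Deterministic for a fixed seed.
#'
#' @param pm A `phenotype_matrix` without pregnancy-complication columns.
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters (recorded in the
#'   result).
#' @return list: `coords` (n x 2 matrix), `person_id`, `group`, `seed`,
#'   `params`.
#' @export
embed_diagnoses <- function(pm, seed = 1, n_neighbors = 15,
                            min_dist = 0.1) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  if (any(!is.na(pm$phenotypes$category) &
          pm$phenotypes$category == "pregnancy complications")) {
    stop("pregnancy-complication columns must be dropped before embedding",
         call. = FALSE)
  }
  if (nrow(pm$M) < 10) stop("need at least 10 persons to embed",
                            call. = FALSE)
  if (ncol(pm$M) < 2) stop("need at least 2 phenotype columns to embed",
                           call. = FALSE)
  n_neighbors <- min(n_neighbors, nrow(pm$M) - 1)
  coords <- with_seed(seed, uwot::umap(
    as.matrix(pm$M), n_components = 2, n_neighbors = n_neighbors,
    min_dist = min_dist, n_threads = 1, n_sgd_threads = 1,
    batch = TRUE, verbose = FALSE))
  colnames(coords) <- c("umap1", "umap2")
  list(coords = coords, person_id = pm$persons$person_id,
       group = pm$persons$group, seed = seed,
       params = list(n_neighbors = n_neighbors, min_dist = min_dist))
}

#' Group-difference tests on embedding coordinates
#'
#' Two-sided Mann-Whitney U test per embedding dimension, comparing the
#' coordinate distributions between the two label groups.
#'
#' @param embedding Result of [embed_diagnoses()], or a coordinate matrix.
#' @param labels Two-level grouping vector (defaults to the embedding's
#'   RPL / Control groups).
#' @return Named numeric vector of p-values, one per dimension.
#' @export
coord_group_tests <- function(embedding, labels = NULL) {
  coords <- if (is.list(embedding)) embedding$coords else embedding
  labels <- labels %||% embedding$group
  lv <- unique(labels)
  if (length(lv) != 2) stop("need exactly two label groups", call. = FALSE)
  apply(coords, 2, function(v) {
    suppressWarnings(
      stats::wilcox.test(v[labels == lv[1]], v[labels == lv[2]],
                         alternative = "two.sided")$p.value)
  })
}

loglog_filter <- function(shared, threshold = 10) {
  keep_a <- !is.na(shared$a_a) & (shared$a_a >= threshold |
                                    shared$c_a >= threshold)
  keep_b <- !is.na(shared$a_b) & (shared$a_b >= threshold |
                                    shared$c_b >= threshold)
  shared[keep_a & keep_b, , drop = FALSE]
}

#' Standard association plots with their data tables
#'
#' Writes a Manhattan plot (-log10 raw p by phenotype category), a volcano
#' plot (log10 adjusted OR vs -log10 BH-adjusted p, significant rows only)
#' and, when a two-site comparison is supplied, a log-log plot of the two
#' sites' log10 odds ratios colored by concordance class.  Log-log points
#' keep only phenotypes with >= 10 patients in either group at both sites;
#' redacted rows never appear.  The numeric table behind each plot is also
#' written.  All log transforms are base 10.
#'
#' @param results An `association_results` table (after [redact()]).
#' @param comparison Optional result of [compare_sites()].
#' @param out_dir Output directory.
#' @return Named list of written file paths, invisibly.
#' @export
make_plots <- function(results, comparison = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  ok <- !results$redacted & !is.na(results$raw_p)
  man <- data.frame(phecode = results$phecode[ok],
                    category = results$category[ok],
                    neg_log10_p = -log10(pmax(results$raw_p[ok], 1e-300)),
                    stringsAsFactors = FALSE)
  paths$manhattan_data <- file.path(out_dir, "manhattan_data.csv")
  write_study_csv(man, paths$manhattan_data)
  if (nrow(man)) {
    g <- ggplot2::ggplot(man, ggplot2::aes(x = category, y = neg_log10_p)) +
      ggplot2::geom_jitter(width = 0.25, size = 0.6, alpha = 0.7) +
      ggplot2::labs(x = "phenotype category",
                    y = expression(-log[10] ~ "p (GAM)")) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    paths$manhattan_png <- file.path(out_dir, "manhattan.png")
    ggplot2::ggsave(paths$manhattan_png, g, width = 7, height = 4, dpi = 150)
  } else {
    warning("no rows pass the Manhattan-plot filter", call. = FALSE)
  }

  vok <- ok & results$significant & !is.na(results$adjusted_or)
  vol <- data.frame(phecode = results$phecode[vok],
                    log10_or = log10(results$adjusted_or[vok]),
                    neg_log10_p = -log10(pmax(results$adj_p[vok], 1e-300)),
                    stringsAsFactors = FALSE)
  paths$volcano_data <- file.path(out_dir, "volcano_data.csv")
  write_study_csv(vol, paths$volcano_data)
  if (nrow(vol)) {
    g <- ggplot2::ggplot(vol, ggplot2::aes(x = log10_or, y = neg_log10_p)) +
      ggplot2::geom_point(size = 0.8, alpha = 0.8) +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = expression(log[10] ~ "adjusted OR"),
                    y = expression(-log[10] ~ "adjusted p")) +
      ggplot2::theme_bw()
    paths$volcano_png <- file.path(out_dir, "volcano.png")
    ggplot2::ggsave(paths$volcano_png, g, width = 5, height = 4, dpi = 150)
  }

  if (!is.null(comparison)) {
    sh <- comparison$shared
    sh <- sh[sh$concordance %in% c("validated_positive",
                                   "validated_negative", "discordant"), ,
             drop = FALSE]
    sh <- loglog_filter(sh)
    ll <- data.frame(phecode = sh$phecode,
                     log10_or_a = log10(sh$or_a),
                     log10_or_b = log10(sh$or_b),
                     concordance = sh$concordance,
                     stringsAsFactors = FALSE)
    paths$loglog_data <- file.path(out_dir, "loglog_data.csv")
    write_study_csv(ll, paths$loglog_data)
    if (nrow(ll)) {
      g <- ggplot2::ggplot(ll, ggplot2::aes(x = log10_or_a, y = log10_or_b,
                                            color = concordance)) +
        ggplot2::geom_point(size = 1) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::labs(x = expression(log[10] ~ "OR, site A"),
                      y = expression(log[10] ~ "OR, site B")) +
        ggplot2::theme_bw()
      paths$loglog_png <- file.path(out_dir, "loglog.png")
      ggplot2::ggsave(paths$loglog_png, g, width = 5.5, height = 4,
                      dpi = 150)
    } else {
      warning("no rows pass the log-log plot filter", call. = FALSE)
    }
  }
  invisible(paths)
}

read_kv_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) stop("bad config line: ", paste(p, collapse = "="),
                            call. = FALSE)
    out[[trimws(p[1])]] <- trimws(paste(p[-1], collapse = "="))
  }
  out
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

load_or_simulate_site <- function(cfg, which, seed_offset) {
  pref <- paste0("site_", which, "_")
  if (!is.null(cfg[[paste0(pref, "dir")]])) {
    dir <- cfg[[paste0(pref, "dir")]]
    for (f in c("persons.csv", "events.csv", "visits.csv")) {
      if (!file.exists(file.path(dir, f))) {
        stop("missing input file: ", file.path(dir, f), call. = FALSE)
      }
    }
    list(persons = read_persons(file.path(dir, "persons.csv")),
         events = read_events(file.path(dir, "events.csv")),
         visits = read_visits(file.path(dir, "visits.csv")),
         concept_sets = read_concept_sets(file.path(dir,
                                                    "concept_sets.csv")),
         phecode_map = read_phecode_map(file.path(dir, "phecode_map.csv")))
  } else {
    seed <- as.integer(cfg$seed %||% 1) + seed_offset
    n_rpl <- as.integer(cfg[[paste0(pref, "n_rpl")]] %||% 1000)
    n_ctrl <- as.integer(cfg[[paste0(pref, "n_control")]] %||% 1000)
    maker <- if (identical(cfg[[paste0(pref, "profile")]], "stanford_like"))
      stanford_like_config else ucsf_like_config
    planted <- c("614.5" = log(2.5), "626.2" = log(2), "256.4" = log(1.8),
                 "642.1" = log(0.6))
    site <- generate_site(maker(
      seed = seed, n_rpl = n_rpl, n_control = n_ctrl,
      planted_effects = planted,
      baseline_prevalence = stats::setNames(rep(0.08, length(planted)),
                                            names(planted)),
      n_null_phenotypes = as.integer(cfg$n_null_phenotypes %||% 40)))
    site
  }
}

#' Run the full two-site study pipeline
#'
#' Orchestrates simulate (or load) -> phenotype -> matrix -> main /
#' age-stratified / utilization analyses -> cross-site comparison ->
#' summary, plots and redacted result tables, logging row counts per stage.
#' Deterministic given the config seed.
#'
#' Config is a plain-text `key=value` file (or an equivalent named list).
#' Keys: `out_dir`, `seed`, and per site either `site_a_dir` (directory of
#' persons/events/visits/concept_sets/phecode_map CSVs) or `site_a_n_rpl`,
#' `site_a_n_control`, `site_a_profile` (`ucsf_like` / `stanford_like`) to
#' simulate (same for `site_b_*`).
#'
#' @param config Path to a config file, or a named list.
#' @return Invisibly, a list of output paths and the in-memory comparison.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_kv_config(config) else config
  out_dir <- cfg$out_dir %||% stop("config needs out_dir", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
        sep = "", file = logf, append = TRUE)
  }

  sites <- list()
  results <- list()
  for (which in c("a", "b")) {
    site <- pipeline_stage(paste0("simulate_", which),
                           load_or_simulate_site(cfg, which,
                                                 seed_offset =
                                                   if (which == "a") 0 else 7))
    log_line("site %s: %d persons, %d events, %d visits", which,
             nrow(site$persons), nrow(site$events), nrow(site$visits))
    if (inherits(site, "rpl_site")) {
      write_site(site, file.path(out_dir, paste0("site_", which)))
    }

    built <- pipeline_stage(paste0("phenotype_", which), build_cohort(
      site$persons, site$events, site$visits, site$concept_sets,
      map = site$phecode_map))
    cohort <- built$cohort
    log_line("site %s cohort: %d RPL, %d Control", which,
             sum(cohort$group == "RPL"), sum(cohort$group == "Control"))
    write_study_csv(cohort, file.path(out_dir,
                                      sprintf("cohort_%s.csv", which)))
    write_study_csv(built$attrition,
                    file.path(out_dir, sprintf("attrition_%s.csv", which)))

    pm <- pipeline_stage(paste0("matrix_", which),
                         build_matrix(cohort, site$events,
                                      site$phecode_map))
    log_line("site %s matrix: %d x %d", which, nrow(pm$M), ncol(pm$M))

    res <- list()
    res$main <- pipeline_stage(paste0("associate_", which),
                               redact(run_analysis(pm, cohort)))
    res$under35 <- redact(run_analysis(pm, cohort, stratum = "under35"))
    res$over35 <- redact(run_analysis(pm, cohort, stratum = "35plus"))
    res$utilization <- redact(run_sensitivity(pm, cohort))
    for (nm in names(res)) {
      write_results(res[[nm]], file.path(
        out_dir, sprintf("results_%s_%s.csv", nm, which)))
    }
    log_line("site %s: %d candidates, %d significant (main)", which,
             nrow(res$main), sum(res$main$significant))

    summ <- cohort_summary(cohort)
    jsonlite::write_json(summ, file.path(out_dir,
                                         sprintf("summary_%s.json", which)),
                         auto_unbox = TRUE, digits = NA, na = "null")
    sites[[which]] <- list(site = site, cohort = cohort, pm = pm)
    results[[which]] <- res
  }

  comp <- pipeline_stage("compare",
                         compare_sites(results$a$main, results$b$main))
  write_study_csv(comp$shared, file.path(out_dir, "comparison.csv"))
  delta_a <- sensitivity_delta(results$a$main, results$a$utilization)
  delta_b <- sensitivity_delta(results$b$main, results$b$utilization)
  summary_json <- list(
    n_shared = comp$n_shared,
    overlap_counts = as.list(comp$overlap_counts),
    spearman_r = comp$spearman$r, spearman_p = comp$spearman$p,
    hypergeom_p_positive = comp$hypergeom_p_positive,
    hypergeom_p_negative = comp$hypergeom_p_negative,
    median_pct_or_change_a = delta_a$median_pct_change,
    median_pct_or_change_b = delta_b$median_pct_change)
  jsonlite::write_json(summary_json,
                       file.path(out_dir, "comparison_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("comparison: %d shared, overlaps +%d -%d ~%d",
           comp$n_shared, comp$overlap_counts[["positive"]],
           comp$overlap_counts[["negative"]],
           comp$overlap_counts[["discordant"]])

  pipeline_stage("report", make_plots(results$a$main, comp,
                                      file.path(out_dir, "plots")))
  invisible(list(out_dir = out_dir, comparison = comp, results = results))
}
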