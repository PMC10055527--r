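# Per-phenotype crude and confounder-adjusted association with RPL.
#
# Crude odds ratios come from the 2x2 table (the single-binary-predictor
# logistic MLE is the cross-product ratio ad/bc).  Adjusted odds ratios
# come from a binomial GAM with a penalized smoothing spline on age plus
# categorical race/ethnicity terms (and, in the utilization sensitivity
# analysis, the study-window visit count as a linear covariate).  P-values
# are Benjamini-Hochberg adjusted within each analysis run.

#' Model specification for adjusted fits
#'
#' @param k Spline basis dimension for the age smooth (>= 4); smoothness is
#'   selected by penalized likelihood.
#' @param covariates Categorical covariates taken from the cohort table
#'   (largest level is the reference; missing values become "unknown").
#' @param include_visits Add `visits_in_window` as a linear covariate
#'   (the healthcare-utilization sensitivity model).
#' @param alpha Significance threshold on the BH-adjusted p-value.
#' @export
model_spec <- function(k = 10, covariates = c("race", "ethnicity"),
                       include_visits = FALSE, alpha = 0.05) {
  stopifnot(k >= 4, alpha > 0, alpha < 1)
  structure(list(k = as.integer(k), covariates = covariates,
                 include_visits = include_visits, alpha = alpha),
            class = "model_spec")
}

#' Crude odds ratio from a 2x2 table
#'
#' The cross-product ratio `ad/bc` with a Wald p-value on the log scale.
#' Any zero cell triggers the 0.5 continuity correction (all four cells),
#' flagged in the result.
#'
#' @param counts list or vector with `a` (RPL with phenotype), `b` (RPL
#'   without), `c` (Control with), `d` (Control without).
#' @return list `or`, `p`, `corrected`.
#' @export
crude_or <- function(counts) {
  a <- counts[["a"]]; b <- counts[["b"]]
  cc <- counts[["c"]]; d <- counts[["d"]]
  stopifnot(a >= 0, b >= 0, cc >= 0, d >= 0)
  if (a + b == 0 || cc + d == 0) {
    stop("degenerate cohort: a group has zero members", call. = FALSE)
  }
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  lor <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = exp(lor), p = 2 * stats::pnorm(-abs(lor) / se),
       corrected = corrected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with p-values sorted ascending, the adjusted value at
#' rank i is `min_{j >= i} p(j) * m / j`, capped at 1, returned in input
#' order.
#' @param p Numeric vector of p-values in [0, 1].
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# ridge-penalized logistic IRLS; penalty excludes the intercept.
# Used as the quasi-separation fallback; Wald p-values use the penalized
# information matrix and are approximate.
ridge_logistic <- function(X, y, lambda = 0.5, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    score <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + pen
  list(beta = beta, cov = solve(H))
}

prep_factor <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  tab <- sort(table(x), decreasing = TRUE)
  factor(x, levels = names(tab))   # largest category = reference
}

#' Confounder-adjusted association for one phenotype
#'
#' Fits a binomial additive model `outcome ~ phenotype + s(age) +
#' covariates` with penalized-likelihood smoothness selection (mgcv), and
#' returns the exponentiated phenotype coefficient with its Wald p-value.
#' A constant phenotype is skipped; quasi-separation or non-convergence
#' falls back to a ridge-penalized logistic model with a fixed-knot cubic
#' age spline (5 interior knots), flagged `separation_fallback`.
#'
#' @param y Binary outcome vector (RPL = 1).
#' @param x Binary phenotype indicator.
#' @param covars data.frame with `age` (years) and any columns named in
#'   `spec$covariates` / `visits` when `spec$include_visits`; may be `NULL`
#'   for a covariate-free fit (which equals the crude estimate).
#' @param spec A [model_spec()].
#' @return list `adjusted_or`, `raw_p`, `fit_status`
#'   (`ok` / `separation_fallback` / `skipped`).
#' @export
fit_adjusted <- function(y, x, covars = NULL, spec = model_spec()) {
  if (length(unique(x)) < 2) {
    return(list(adjusted_or = NA_real_, raw_p = NA_real_,
                fit_status = "skipped"))
  }
  d <- data.frame(y = y, x = x)
  terms <- "x"
  has_age <- !is.null(covars) && "age" %in% names(covars)
  if (has_age) {
    d$age <- covars$age
    k_eff <- min(spec$k, length(unique(d$age)) - 1)
    if (k_eff >= 4) {
      terms <- c(terms, sprintf("s(age, k = %d)", k_eff))
    } else {
      terms <- c(terms, "age")
      has_age <- FALSE   # no smooth term left
    }
  }
  for (cv in intersect(spec$covariates, names(covars %||% list()))) {
    f <- prep_factor(covars[[cv]])
    if (nlevels(droplevels(f)) > 1) {
      d[[cv]] <- f
      terms <- c(terms, cv)
    }
  }
  if (spec$include_visits && "visits" %in% names(covars %||% list())) {
    if (length(unique(covars$visits)) > 1) {
      d$visits <- as.numeric(covars$visits)
      terms <- c(terms, "visits")
    }
  }
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))

  fit <- tryCatch({
    if (!has_age) {
      stats::glm(fml, family = stats::binomial(), data = d)
    } else if (nrow(d) >= 2000) {
      mgcv::bam(fml, family = stats::binomial(), data = d,
                discrete = TRUE, nthreads = 1)
    } else {
      mgcv::gam(fml, family = stats::binomial(), data = d,
                method = "REML")
    }
  }, error = function(e) NULL)

  est <- NULL
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    ix <- which(names(cf) == "x")
    b <- cf[ix]
    vc <- if (inherits(fit, "gam")) fit$Vp else stats::vcov(fit)
    se <- sqrt(vc[ix, ix])
    conv <- if (inherits(fit, "gam")) fit$converged else fit$converged
    if (isTRUE(conv) && is.finite(b) && is.finite(se) &&
        abs(b) < 15 && se < 10) {
      est <- list(adjusted_or = exp(unname(b)),
                  raw_p = 2 * stats::pnorm(-abs(b / se)),
                  fit_status = "ok")
    }
  }
  if (is.null(est)) {
    X <- cbind(`(Intercept)` = 1, x = x)
    if (!is.null(covars) && "age" %in% names(covars)) {
      kn <- stats::quantile(covars$age, probs = seq_len(5) / 6, names = FALSE)
      X <- cbind(X, splines::ns(covars$age, knots = unique(kn)))
    }
    for (cv in intersect(spec$covariates, names(covars %||% list()))) {
      f <- prep_factor(covars[[cv]])
      if (nlevels(droplevels(f)) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        X <- cbind(X, mm)
      }
    }
    if (spec$include_visits && "visits" %in% names(covars %||% list())) {
      X <- cbind(X, visits = as.numeric(covars$visits))
    }
    r <- ridge_logistic(X, y)
    b <- r$beta[2]; se <- sqrt(r$cov[2, 2])
    est <- list(adjusted_or = exp(b),
                raw_p = 2 * stats::pnorm(-abs(b / se)),
                fit_status = "separation_fallback")
  }
  est
}

cohort_covars <- function(cohort, spec) {
  cv <- data.frame(age = cohort$age_at_index)
  for (nm in spec$covariates) {
    if (nm %in% names(cohort)) cv[[nm]] <- cohort[[nm]]
  }
  if (spec$include_visits) cv$visits <- cohort$visits_in_window
  cv
}

#' Phenome-wide association scan
#'
#' Runs the crude and adjusted models for every candidate phenotype, applies
#' Benjamini-Hochberg adjustment across exactly the phenotypes tested in
#' this run (one multiple-testing family per analysis), and flags
#' significance at `spec$alpha` on the adjusted p-value.  With `stratum`
#' given, the cohort is restricted to that age stratum first and candidate
#' phenotypes are re-derived within it.
#'
#' @param pm A `phenotype_matrix`.
#' @param cohort Cohort table from [build_cohort()] (with `race` and
#'   `ethnicity` columns carried from the person table).
#' @param spec A [model_spec()].
#' @param stratum Optional `"under35"` or `"35plus"`.
#' @param analysis Label stored on each row (defaults to `main`, or the
#'   stratum name when stratified).
#' @return An `association_results` data.frame: one row per candidate
#'   phenotype with counts, crude and adjusted ORs, raw and BH-adjusted
#'   p-values, significance, direction, fit status and redaction flag.
#' @export
run_analysis <- function(pm, cohort, spec = model_spec(), stratum = NULL,
                         analysis = NULL) {
  cohort <- cohort[match(pm$persons$person_id, cohort$person_id), ]
  keep_rows <- rep(TRUE, nrow(cohort))
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, c("under35", "35plus"))
    keep_rows <- cohort$age_stratum == stratum
    if (!any(keep_rows)) stop("empty stratum: ", stratum, call. = FALSE)
  }
  analysis <- analysis %||%
    (if (is.null(stratum)) "main"
     else if (stratum == "under35") "under35" else "over35")

  M <- pm$M[keep_rows, , drop = FALSE]
  sub <- cohort[keep_rows, , drop = FALSE]
  cand <- which(Matrix::colSums(M) > 0)
  if (!length(cand)) stop("no candidate phenotypes in this analysis",
                          call. = FALSE)
  y <- as.integer(sub$group == "RPL")
  covars <- cohort_covars(sub, spec)

  n <- length(cand)
  out <- data.frame(
    phecode = pm$phenotypes$phecode[cand],
    label = pm$phenotypes$label[cand],
    category = pm$phenotypes$category[cand],
    analysis = analysis,
    a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_,
    crude_or = NA_real_, adjusted_or = NA_real_,
    raw_p = NA_real_, adj_p = NA_real_,
    significant = FALSE, direction = NA_character_,
    fit_status = NA_character_, redacted = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    xv <- as.integer(M[, cand[i]] > 0)
    a <- sum(xv == 1 & y == 1); b <- sum(xv == 0 & y == 1)
    cc <- sum(xv == 1 & y == 0); d <- sum(xv == 0 & y == 0)
    out$a[i] <- a; out$b[i] <- b; out$c[i] <- cc; out$d[i] <- d
    cr <- crude_or(list(a = a, b = b, c = cc, d = d))
    out$crude_or[i] <- cr$or
    ad <- fit_adjusted(y, xv, covars, spec)
    out$adjusted_or[i] <- ad$adjusted_or
    out$raw_p[i] <- ad$raw_p
    out$fit_status[i] <- ad$fit_status
  }
  out$adj_p <- bh_adjust(out$raw_p)
  out$significant <- !is.na(out$adj_p) & out$adj_p < spec$alpha
  out$direction <- ifelse(is.na(out$adjusted_or), NA_character_,
                          ifelse(out$adjusted_or > 1, "positive",
                                 "negative"))
  class(out) <- c("association_results", "data.frame")
  out
}

#' Healthcare-utilization sensitivity analysis
#'
#' Identical to [run_analysis()] with the study-window visit count appended
#' as a linear covariate; results are labelled `utilization`.  A constant
#' visit column is dropped with a warning (results then equal the main
#' analysis).
#' @inheritParams run_analysis
#' @export
run_sensitivity <- function(pm, cohort, spec = model_spec()) {
  spec$include_visits <- TRUE
  vis <- cohort$visits_in_window[match(pm$persons$person_id,
                                       cohort$person_id)]
  if (length(unique(vis)) < 2) {
    warning("visit count is constant; dropping the utilization covariate",
            call. = FALSE)
    spec$include_visits <- FALSE
  }
  run_analysis(pm, cohort, spec, analysis = "utilization")
}

#' Mask small-count phenotypes
#'
#' De-identification rule: when the positive counts are below `threshold`
#' in both groups (i.e. the phenotype reaches `threshold` patients in
#' neither the RPL nor the Control group), counts, odds ratios and p-values
#' are masked; the phenotype row itself is kept with its redaction flag.
#'
#' @param results An `association_results` data.frame.
#' @param threshold Count threshold (default 10).
#' @export
redact <- function(results, threshold = 10) {
  stopifnot(threshold >= 0)
  mask <- !is.na(results$a) & results$a < threshold &
    results$c < threshold
  results$redacted <- mask
  for (col in c("a", "b", "c", "d")) results[[col]][mask] <- NA_integer_
  for (col in c("crude_or", "adjusted_or", "raw_p", "adj_p")) {
    results[[col]][mask] <- NA_real_
  }
  results$direction[mask] <- NA_character_
  results$significant[mask] <- FALSE
  results
}

#' Write association results
#'
#' One row per phenotype and analysis; masked cells of redacted rows are
#' emitted as the literal token `REDACTED`.
#' @param results An `association_results` data.frame (after [redact()]).
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  masked <- c("a", "b", "c", "d", "crude_or", "adjusted_or",
              "raw_p", "adj_p", "direction")
  for (col in masked) {
    v <- as.character(df[[col]])
    v[df$redacted] <- "REDACTED"
    df[[col]] <- v
  }
  write_study_csv(df, path)
}
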