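# Cross-site validation of association results: shared-candidate alignment,
# concordance classes, hypergeometric overlap enrichment, rank correlation
# of odds ratios, sensitivity attenuation and age-strata comparison.

#' Align two result sets on their shared phenotypes
#'
#' Inner join on phenotype id of two association runs with the same analysis
#' label; unmatched ids are reported as attributes.
#'
#' @param res_a,res_b `association_results` data.frames.
#' @return data.frame with per-site odds ratios, adjusted p-values,
#'   significance and direction (`_a` / `_b` suffixes); attributes
#'   `unmatched_a`, `unmatched_b`.
#' @export
align_shared <- function(res_a, res_b) {
  shared <- intersect(res_a$phecode, res_b$phecode)
  if (!length(shared)) stop("no shared phenotypes between the two result sets",
                            call. = FALSE)
  ia <- match(shared, res_a$phecode)
  ib <- match(shared, res_b$phecode)
  out <- data.frame(
    phecode = shared,
    label = res_a$label[ia],
    or_a = res_a$adjusted_or[ia], or_b = res_b$adjusted_or[ib],
    adj_p_a = res_a$adj_p[ia], adj_p_b = res_b$adj_p[ib],
    sig_a = res_a$significant[ia], sig_b = res_b$significant[ib],
    a_a = res_a$a[ia], c_a = res_a$c[ia],
    a_b = res_b$a[ib], c_b = res_b$c[ib],
    redacted_a = res_a$redacted[ia], redacted_b = res_b$redacted[ib],
    stringsAsFactors = FALSE)
  attr(out, "unmatched_a") <- setdiff(res_a$phecode, shared)
  attr(out, "unmatched_b") <- setdiff(res_b$phecode, shared)
  out
}

#' Cross-site concordance classes
#'
#' Partitions the shared phenotypes: `validated_positive` (significant at
#' both sites, OR > 1 at both), `validated_negative` (significant at both,
#' OR < 1 at both), `discordant` (significant at both, opposite
#' directions), `single_site_only` (significant at exactly one site),
#' `neither`.  An odds ratio of exactly 1 counts as the negative direction
#' (deterministic tie-break).
#'
#' @param shared Output of [align_shared()].
#' @param alpha Per-site significance threshold on the adjusted p-value.
#' @return `shared` with a `concordance` column; attribute `overlap_counts`
#'   holds the positive / negative / discordant counts.
#' @export
concordance_classes <- function(shared, alpha = 0.05) {
  sig_a <- !is.na(shared$adj_p_a) & shared$adj_p_a < alpha
  sig_b <- !is.na(shared$adj_p_b) & shared$adj_p_b < alpha
  pos_a <- shared$or_a > 1
  pos_b <- shared$or_b > 1
  cls <- rep("neither", nrow(shared))
  cls[xor(sig_a, sig_b)] <- "single_site_only"
  both <- sig_a & sig_b
  cls[both & pos_a & pos_b] <- "validated_positive"
  cls[both & !pos_a & !pos_b] <- "validated_negative"
  cls[both & xor(pos_a, pos_b)] <- "discordant"
  shared$concordance <- cls
  attr(shared, "overlap_counts") <- c(
    positive = sum(cls == "validated_positive"),
    negative = sum(cls == "validated_negative"),
    discordant = sum(cls == "discordant"))
  shared
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail probability that at least `x` phenotypes fall in both sites'
#' significant lists by chance: `P(X >= x)` for X hypergeometric with
#' population `n_shared`, `k_a` successes and `k_b` draws.  Symmetric in
#' `k_a` and `k_b`.
#'
#' @param n_shared Shared candidate phenotype count.
#' @param k_a,k_b Per-site significant counts.
#' @param x Observed overlap.
#' @return The upper-tail probability.
#' @export
overlap_enrichment <- function(n_shared, k_a, k_b, x) {
  stopifnot(n_shared >= 0, k_a >= 0, k_b >= 0, x >= 0,
            k_a <= n_shared, k_b <= n_shared)
  if (x > min(k_a, k_b)) {
    stop("observed overlap exceeds min(k_a, k_b)", call. = FALSE)
  }
  stats::phyper(x - 1, m = k_a, n = n_shared - k_a, k = k_b,
                lower.tail = FALSE)
}

#' Spearman rank correlation of odds ratios
#'
#' @param or_a,or_b Paired odds-ratio vectors (>= 3 complete pairs).
#' @return list `r`, `p` (two-sided), `constant` flag; a constant vector
#'   leaves `r` undefined (`NA`) with `constant = TRUE`.
#' @export
spearman_or <- function(or_a, or_b) {
  ok <- stats::complete.cases(or_a, or_b)
  or_a <- or_a[ok]; or_b <- or_b[ok]
  if (length(or_a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(or_a)) < 2 || length(unique(or_b)) < 2) {
    return(list(r = NA_real_, p = NA_real_, constant = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(or_a, or_b, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, constant = FALSE)
}

#' Full two-site comparison
#'
#' Aligns shared phenotypes, classifies concordance, rank-correlates the
#' odds ratios, and tests whether the positive and negative significant
#' overlaps exceed chance with hypergeometric upper tails.
#'
#' @param res_a,res_b `association_results` from the two sites (same
#'   analysis label).
#' @param alpha Per-site significance threshold.
#' @return list: `shared` (classified table), `n_shared`,
#'   `overlap_counts`, `spearman` (list r/p), `hypergeom_p_positive`,
#'   `hypergeom_p_negative`.
#' @export
compare_sites <- function(res_a, res_b, alpha = 0.05) {
  shared <- concordance_classes(align_shared(res_a, res_b), alpha)
  sig_a <- !is.na(shared$adj_p_a) & shared$adj_p_a < alpha
  sig_b <- !is.na(shared$adj_p_b) & shared$adj_p_b < alpha
  n <- nrow(shared)
  counts <- attr(shared, "overlap_counts")
  kpa <- sum(sig_a & shared$or_a > 1); kpb <- sum(sig_b & shared$or_b > 1)
  kna <- sum(sig_a & shared$or_a <= 1); knb <- sum(sig_b & shared$or_b <= 1)
  both_sig <- shared$concordance %in%
    c("validated_positive", "validated_negative", "discordant")
  sp <- if (sum(both_sig) >= 3) {
    spearman_or(shared$or_a[both_sig], shared$or_b[both_sig])
  } else list(r = NA_real_, p = NA_real_, constant = NA)
  list(
    shared = shared, n_shared = n, overlap_counts = counts,
    n_significant_both = sum(both_sig),
    spearman = sp,
    hypergeom_p_positive = overlap_enrichment(n, kpa, kpb,
                                              counts[["positive"]]),
    hypergeom_p_negative = overlap_enrichment(n, kna, knb,
                                              counts[["negative"]]))
}

#' Odds-ratio attenuation between main and sensitivity runs
#'
#' Over the union of phenotypes significant in either the main or the
#' visit-adjusted run (excluding redacted or unestimated rows), computes
#' the per-phenotype percent change `100 * (OR_main - OR_sens) / OR_main`
#' (positive = decrease after utilization adjustment) and its median.
#'
#' @param res_main,res_sens `association_results` over the same phenotype
#'   universe.
#' @return list: `table` (phecode, or_main, or_sens, pct_change),
#'   `median_pct_change`.
#' @export
sensitivity_delta <- function(res_main, res_sens) {
  im <- match(res_sens$phecode, res_main$phecode)
  keep <- res_main$significant[im] | res_sens$significant
  keep <- !is.na(keep) & keep
  orm <- res_main$adjusted_or[im]
  ors <- res_sens$adjusted_or
  keep <- keep & !is.na(orm) & !is.na(ors) &
    !res_main$redacted[im] & !res_sens$redacted
  if (!any(keep)) stop("no phenotype is significant in either run",
                       call. = FALSE)
  tab <- data.frame(
    phecode = res_sens$phecode[keep],
    or_main = orm[keep], or_sens = ors[keep],
    pct_change = 100 * (orm[keep] - ors[keep]) / orm[keep],
    stringsAsFactors = FALSE)
  list(table = tab, median_pct_change = stats::median(tab$pct_change))
}

#' Compare odds ratios between age strata
#'
#' Over the union of phenotypes significant in either stratum, counts how
#' often the under-35 odds ratio strictly exceeds the 35-plus odds ratio
#' (ties count as not-higher).
#'
#' @param res_young,res_old `association_results` for the `under35` and
#'   `35plus` strata.
#' @return list: `table` (per-phenotype ORs and the indicator),
#'   `n_union`, `n_higher_young`, `fraction_higher_young`.
#' @export
strata_comparison <- function(res_young, res_old) {
  shared <- intersect(res_young$phecode, res_old$phecode)
  iy <- match(shared, res_young$phecode)
  io <- match(shared, res_old$phecode)
  keep <- (res_young$significant[iy] | res_old$significant[io]) &
    !is.na(res_young$adjusted_or[iy]) & !is.na(res_old$adjusted_or[io])
  if (!any(keep)) stop("no phenotype is significant in either stratum",
                       call. = FALSE)
  tab <- data.frame(
    phecode = shared[keep],
    or_young = res_young$adjusted_or[iy][keep],
    or_old = res_old$adjusted_or[io][keep],
    stringsAsFactors = FALSE)
  tab$higher_young <- tab$or_young > tab$or_old
  list(table = tab, n_union = nrow(tab),
       n_higher_young = sum(tab$higher_young),
       fraction_higher_young = mean(tab$higher_young))
}
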