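#' Paired comparison with a normality-gated test choice
#'
#' Runs a Shapiro-Wilk test on the paired differences `a - b`; when the
#' differences look normal (p >= `alpha`) a two-tailed paired t-test is
#' used, with the mean difference and its t-based CI, otherwise a Wilcoxon
#' matched-pairs signed-rank test with the Hodges-Lehmann pseudo-median
#' and its CI.  Zero differences are dropped by the Wilcoxon branch; ties
#' get average ranks.
#'
#' @param a,b paired metric vectors of equal length (`n >= 3`).
#' @param alpha normality-gate level (default 0.05) and CI level
#'   complement (CIs are `1 - alpha`).
#' @return list of class `paired_test` with `normality_p`, `test`
#'   (`"paired t"` or `"wilcoxon"`), `estimate` (difference a - b),
#'   `conf_low`, `conf_high`, `p_value`, `direction`, `degenerate`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  d <- a - b
  if (all(d == 0)) {
    return(structure(list(normality_p = 1, test = "degenerate",
                          estimate = 0, conf_low = 0, conf_high = 0,
                          p_value = 1, direction = "no difference",
                          degenerate = TRUE, n = length(d)),
                     class = "paired_test"))
  }
  sw <- if (length(unique(d)) > 2) stats::shapiro.test(d)$p.value else 0
  if (sw >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE, conf.level = 1 - alpha)
    res <- list(normality_p = sw, test = "paired t",
                estimate = unname(tt$estimate),
                conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, paired = TRUE, conf.int = TRUE, conf.level = 1 - alpha,
      exact = FALSE, correct = TRUE))
    # Hodges-Lehmann pseudo-median from the Walsh averages directly:
    # exactly antisymmetric, unlike the root-finding estimate
    walsh <- outer(d, d, "+")[upper.tri(diag(length(d)), diag = TRUE)] / 2
    res <- list(normality_p = sw, test = "wilcoxon",
                estimate = stats::median(walsh),
                conf_low = wt$conf.int[1], conf_high = wt$conf.int[2],
                p_value = wt$p.value)
  }
  res$direction <- if (res$estimate < 0) "favours lower a (b larger)" else
    if (res$estimate > 0) "favours lower b (a larger)" else "no difference"
  res$degenerate <- FALSE
  res$n <- length(d)
  structure(res, class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "<paired_test> %s (Shapiro-Wilk p = %.3g): estimate %.4g, CI [%.4g, %.4g], p = %.3g\n",
    x$test, x$normality_p, x$estimate, x$conf_low, x$conf_high, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length (`n >= 5`), neither
#'   constant.
#' @return list with `rho` and two-sided `p`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-variant best-case counts across a cohort
#'
#' For each patient, finds the strictly best variant of a metric; ties
#' are split equally among the tied variants and flagged.  Patients with
#' any missing cell are excluded (with a message).
#'
#' @param table numeric matrix or `data.frame`, patients in rows, variants
#'   in columns (`>= 2` variants), column names label the variants.
#' @param better `"lower"` or `"higher"`: the direction of a better value.
#' @return named numeric vector of best-case counts per variant, with
#'   attributes `n_patients` (patients used), `n_ties` (patients with a
#'   tied best).
#' @export
rank_by_variant <- function(table, better = c("lower", "higher")) {
  better <- match.arg(better)
  m <- as.matrix(table)
  if (ncol(m) < 2) stop("need at least 2 variants")
  keep <- stats::complete.cases(m)
  if (any(!keep))
    message(sum(!keep), " patient(s) excluded for missing cells")
  m <- m[keep, , drop = FALSE]
  counts <- stats::setNames(numeric(ncol(m)), colnames(m))
  n_ties <- 0L
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    bestv <- if (better == "lower") min(v) else max(v)
    winners <- which(v == bestv)
    if (length(winners) > 1) n_ties <- n_ties + 1L
    counts[winners] <- counts[winners] + 1 / length(winners)
  }
  attr(counts, "n_patients") <- nrow(m)
  attr(counts, "n_ties") <- n_ties
  counts
}

# metrics compared between techniques and their preferred direction
COHORT_METRICS <- c(CN = "higher", HI = "lower", DHD = "lower",
                    MU = "lower", D1cc_cord_cGy = "lower",
                    oeso_mean_cGy = "lower", V20Gy_pct = "lower",
                    V5Gy_pct = "lower", MLD_cGy = "lower")

#' Full cohort comparison report
#'
#' Builds, from a per-patient-per-variant metric table, the complete
#' comparison report: a paired test per metric (arc reference variant vs
#' the static technique), a mean +/- sd table per variant, the
#' correlation sets (paired lung-metric differences against PTV volume,
#' lung volume and the reciprocal CTV-cord distance; arc metrics against
#' the sphericity surrogate; homogeneity/conformity against isocentre
#' displacement and CTV-skin distance) and per-technique planning-
#' constraint pass percentages.
#'
#' @param cohort `data.frame` with one row per patient per variant;
#'   required columns: `patient`, `variant` (e.g. `"3DCRT"`,
#'   `"DCAT_00"`, ...), the metric columns of [plan_metrics()], and
#'   per-patient covariates `V_PTV_cm3`, `V_lung_cm3`, `d_CTV_cord_mm`,
#'   `d_CTV_skin_mm`, `psi_tilde`, `R_mm` (missing covariates just drop
#'   the affected correlations).
#' @param static_variant,arc_variant variant labels compared by the paired
#'   tests (defaults `"3DCRT"` and `"DCAT_45"`).
#' @param alpha level for the normality gate and CIs.
#' @return list of class `cohort_report` with elements `paired`,
#'   `summary`, `correlations`, `constraint_pass`, `best_counts`.
#' @export
cohort_report <- function(cohort, static_variant = "3DCRT",
                          arc_variant = "DCAT_45", alpha = 0.05) {
  if (!nrow(cohort)) stop("empty cohort")
  need <- c("patient", "variant")
  if (!all(need %in% names(cohort)))
    stop("cohort needs 'patient' and 'variant' columns")
  metrics <- intersect(names(COHORT_METRICS), names(cohort))
  arm <- function(variant, metric) {
    rows <- cohort[cohort$variant == variant, ]
    rows[[metric]][match(sort(unique(cohort$patient)), rows$patient)]
  }

  # paired tests: arc (reference collimator variant) vs static
  paired <- list()
  for (m in metrics) {
    a <- arm(arc_variant, m)
    b <- arm(static_variant, m)
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3) next
    res <- paired_compare(a[ok], b[ok], alpha)
    paired[[m]] <- res
  }
  skipped <- setdiff(metrics, names(paired))
  if (length(skipped))
    warning("metrics without enough paired data: ",
            paste(skipped, collapse = ", "))

  # mean +/- sd per variant
  variants <- unique(cohort$variant)
  summary_tab <- do.call(rbind, lapply(metrics, function(m) {
    row <- data.frame(metric = m)
    for (v in variants) {
      vals <- cohort[[m]][cohort$variant == v]
      row[[paste0(v, "_mean")]] <- mean(vals, na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- stats::sd(vals, na.rm = TRUE)
    }
    row
  }))

  # correlation sets on paired differences and arc-plan metrics
  per_patient <- cohort[!duplicated(cohort$patient),
                        intersect(c("patient", "V_PTV_cm3", "V_lung_cm3",
                                    "d_CTV_cord_mm", "d_CTV_skin_mm",
                                    "psi_tilde", "R_mm"), names(cohort)),
                        drop = FALSE]
  pts <- sort(unique(cohort$patient))
  per_patient <- per_patient[match(pts, per_patient$patient), , drop = FALSE]
  corr <- list()
  add_corr <- function(name, x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 5) return()
    if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
      corr[[name]] <<- list(rho = NA_real_, p = NA_real_, flagged = TRUE)
      return()
    }
    corr[[name]] <<- c(rank_correlation(x[ok], y[ok]), flagged = FALSE)
  }
  diff_of <- function(m) arm(arc_variant, m) - arm(static_variant, m)
  if ("MLD_cGy" %in% metrics) {
    dmld <- diff_of("MLD_cGy")
    add_corr("dMLD_vs_V_PTV", per_patient$V_PTV_cm3, dmld)
    add_corr("dMLD_vs_V_lung", per_patient$V_lung_cm3, dmld)
    add_corr("dMLD_vs_inv_d_cord", 1 / per_patient$d_CTV_cord_mm, dmld)
  }
  if (all(c("V20Gy_pct", "V5Gy_pct", "MLD_cGy") %in% metrics)) {
    add_corr("dV20_vs_dV5", diff_of("V20Gy_pct"), diff_of("V5Gy_pct"))
    add_corr("dMLD_vs_dV20", diff_of("V20Gy_pct"), diff_of("MLD_cGy"))
    add_corr("dMLD_vs_dV5", diff_of("V5Gy_pct"), diff_of("MLD_cGy"))
  }
  for (m in intersect(c("HI", "CN", "oeso_mean_cGy", "V20Gy_pct",
                        "V5Gy_pct", "MLD_cGy", "D1cc_cord_cGy"), metrics)) {
    add_corr(paste0(m, "_vs_psi_tilde"), per_patient$psi_tilde,
             arm(arc_variant, m))
  }
  for (m in intersect(c("HI", "CN"), metrics)) {
    add_corr(paste0(m, "_vs_R"), per_patient$R_mm, arm(arc_variant, m))
    add_corr(paste0(m, "_vs_d_skin"), per_patient$d_CTV_skin_mm,
             arm(arc_variant, m))
  }

  # planning-constraint pass percentage per variant
  cpass <- do.call(rbind, lapply(variants, function(v) {
    rows <- cohort[cohort$variant == v, ]
    checks <- lapply(seq_len(nrow(rows)),
                     function(i) check_constraints(rows[i, ]))
    per_constraint <- sapply(seq_len(nrow(checks[[1]])), function(ci)
      100 * mean(vapply(checks, function(ch) ch$pass[ci], logical(1)),
                 na.rm = TRUE))
    data.frame(variant = v,
               constraint = checks[[1]]$constraint,
               pass_pct = per_constraint)
  }))

  # per-patient ranking across arc collimator variants
  arc_variants <- setdiff(variants, static_variant)
  best <- list()
  if (length(arc_variants) >= 2) {
    for (m in metrics) {
      tab <- vapply(arc_variants, function(v) arm(v, m),
                    numeric(length(pts)))
      best[[m]] <- rank_by_variant(tab, better = COHORT_METRICS[[m]])
    }
  }

  structure(list(paired = paired, summary = summary_tab,
                 correlations = corr, constraint_pass = cpass,
                 best_counts = best,
                 static_variant = static_variant,
                 arc_variant = arc_variant,
                 n_patients = length(pts)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d patients, %s vs %s\n", x$n_patients,
              x$arc_variant, x$static_variant))
  for (m in names(x$paired)) {
    p <- x$paired[[m]]
    cat(sprintf("  %-14s %-9s estimate %10.4g  CI [%.4g, %.4g]  p = %.3g\n",
                m, p$test, p$estimate, p$conf_low, p$conf_high, p$p_value))
  }
  invisible(x)
}
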