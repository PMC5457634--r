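#' Relative dose difference field
#'
#' Per-point relative difference `100 * (D_eval - D_ref) / D_ref` (%),
#' where the reference is conventionally the measured distribution and the
#' evaluation the TPS-calculated one.  Points where the reference is below
#' `floor_frac` of its maximum are masked out (`NA`) to avoid blow-up
#' where the measured dose is near zero.
#'
#' @param evaluation,reference two [planar_dose()]s or [dose_grid()]s on
#'   the same geometry.
#' @param floor_frac reference floor as a fraction of the reference
#'   maximum (default 0.05).
#' @return numeric array (%) with `NA` at masked points.
#' @export
relative_difference <- function(evaluation, reference, floor_frac = 0.05) {
  stop_unless_same_geometry(evaluation, reference, "dose distributions")
  ref <- reference$values
  ev <- evaluation$values
  floor_abs <- floor_frac * max(ref)
  ok <- ref > floor_abs & ref > 0
  if (!any(ok)) stop("all points fall below the reference floor")
  out <- array(NA_real_, dim = dim(ref))
  out[ok] <- 100 * (ev[ok] - ref[ok]) / ref[ok]
  out
}

#' Per-medium mean and SD of a difference field for one plan
#'
#' @param diff_field array (%) from [relative_difference()]; `NA` points
#'   are ignored.
#' @param media a [medium_map()] aligned to the field.
#' @param media_names media to report (default lung, soft, bone).
#' @return `data.frame` with `medium`, `mean_pct`, `sd_pct`, `n_points`;
#'   media empty within the evaluated area are absent from the result.
#' @export
per_plan_region_stats <- function(diff_field, media,
                                  media_names = c("lung", "soft", "bone")) {
  if (!identical(dim(diff_field), dim(media$labels)))
    stop("difference field and medium map must share shape")
  rows <- lapply(media_names, function(mn) {
    code <- match(mn, media$levels) - 1L
    v <- diff_field[media$labels == code]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    data.frame(medium = mn, mean_pct = mean(v),
               sd_pct = if (length(v) > 1) stats::sd(v) else 0,
               n_points = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(medium = character(), mean_pct = numeric(),
                      sd_pct = numeric(), n_points = integer())
  out
}

#' Cohort error decomposition into systematic and random components
#'
#' Across a cohort of plans, per medium: the systematic error `M` is the
#' mean over plans of the per-plan mean differences; `Sigma` is the sample
#' SD over plans of those per-plan means; the random error `sigma` is the
#' root-mean-square over plans of the within-plan SDs.  All in percent.
#'
#' @param plan_stats list of `data.frame`s from
#'   [per_plan_region_stats()], one per plan (`n >= 2`).
#' @return `data.frame` of class `error_decomposition` with `medium`, `M`,
#'   `Sigma`, `sigma`, `n_plans`.
#' @export
decompose_errors <- function(plan_stats) {
  if (length(plan_stats) < 2)
    stop("need at least 2 plans (Sigma undefined otherwise)")
  all <- do.call(rbind, lapply(seq_along(plan_stats), function(i) {
    d <- plan_stats[[i]]
    if (nrow(d)) d$plan <- i
    d
  }))
  media <- unique(all$medium)
  rows <- lapply(media, function(mn) {
    d <- all[all$medium == mn, ]
    if (nrow(d) < 2) return(NULL)
    data.frame(medium = mn,
               M = mean(d$mean_pct),
               Sigma = stats::sd(d$mean_pct),
               sigma = sqrt(mean(d$sd_pct^2)),
               n_plans = nrow(d))
  })
  structure(do.call(rbind, rows),
            class = c("error_decomposition", "data.frame"))
}

#' Wilcoxon test of symmetry about zero for per-plan mean differences
#'
#' One-sample Wilcoxon signed-rank test that the per-plan mean relative
#' differences for one medium are symmetric about zero.
#'
#' @param means numeric vector of per-plan mean differences (%), `n >= 5`.
#' @return the p-value; all-zero input returns `p = 1` by convention (with
#'   a message).
#' @export
paired_symmetry_test <- function(means) {
  if (length(means) < 5) stop("need at least 5 plans")
  if (all(means == 0)) {
    message("all per-plan means are zero; p = 1 by convention")
    return(1)
  }
  suppressWarnings(stats::wilcox.test(means, mu = 0, exact = FALSE))$p.value
}
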