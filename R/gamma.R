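#' Gamma-index comparison parameters
#'
#' @param dd dose criterion, % of the normalization dose (default 3).
#' @param dta distance-to-agreement criterion in mm (default 3).
#' @param threshold low-dose threshold, % of the normalization dose;
#'   reference points below it are excluded from the map and from both the
#'   numerator and denominator of the pass rate (default 10).
#' @param norm `"global"`: the normalization dose is the global maximum of
#'   the reference distribution; `"local"`: the dose criterion applies
#'   relative to the local reference dose (the threshold still uses the
#'   global reference maximum).
#' @param cap search radius cap in mm (default `3 * dta`).
#' @param step search lattice step in mm (default `dta / 10`).
#' @param refine polish the lattice minimum with a local pattern search on
#'   the continuously interpolated evaluation (default `TRUE`); set
#'   `FALSE` to restrict the search to the lattice, e.g. when comparing
#'   against a lattice oracle at a matched step.
#' @return list of class `gamma_params`.
#' @export
gamma_params <- function(dd = 3, dta = 3, threshold = 10,
                         norm = c("global", "local"), cap = 3 * dta,
                         step = dta / 10, refine = TRUE) {
  norm <- match.arg(norm)
  if (!is.finite(dd) || dd <= 0) stop("dd must be > 0")
  if (!is.finite(dta) || dta <= 0) stop("dta must be > 0")
  if (!is.finite(threshold) || threshold < 0 || threshold >= 100)
    stop("threshold must be in [0, 100)")
  if (cap < dta) stop("search cap must be at least dta")
  if (step <= 0) stop("step must be > 0")
  structure(list(dd = dd, dta = dta, threshold = threshold, norm = norm,
                 cap = cap, step = step, refine = isTRUE(refine)),
            class = "gamma_params")
}

gamma_geom <- function(x) {
  if (inherits(x, "planar_dose"))
    list(values = x$values, dim = dim(x$values), spacing = x$spacing,
         origin = x$origin)
  else if (inherits(x, "dose_grid"))
    list(values = x$values, dim = dim(x$values), spacing = x$spacing,
         origin = x$origin)
  else stop("inputs must be planar_dose or dose_grid objects")
}

gamma_result <- function(gmap, ref, params) {
  evaluated <- !is.na(gmap)
  n <- sum(evaluated)
  if (n == 0)
    stop("no reference point above the low-dose threshold")
  g <- gmap[evaluated]
  structure(list(
    gamma = gmap, evaluated = evaluated,
    pass_pct = 100 * mean(g < 1),       # gamma exactly 1 fails "< 1"
    mean_gamma = mean(g),
    n_evaluated = n, params = params,
    spacing = ref$spacing, origin = ref$origin),
    class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%%/%g mm, threshold %g%%: pass %.2f%%, mean gamma %.3f (%d points)\n",
    x$params$dd, x$params$dta, x$params$threshold, x$pass_pct,
    x$mean_gamma, x$n_evaluated))
  invisible(x)
}

#' Gamma-index map between a reference and an evaluation distribution
#'
#' For every reference point r above the low-dose threshold,
#' \deqn{\gamma(r) = \min_{r'} \sqrt{\delta^2(r,r')/\Delta D^2 +
#'   |r'-r|^2/\Delta d^2}}
#' over evaluation positions r' within the search cap, with the
#' evaluation distribution interpolated bi-/trilinearly.  The reference is
#' conventionally the measured distribution and the evaluation the
#' TPS-calculated one.  Geometries may differ; evaluation positions
#' outside the evaluation grid are skipped.  The lattice minimum is
#' polished by a local pattern search.
#'
#' @param reference,evaluation two [planar_dose()]s or two [dose_grid()]s.
#' @param params a [gamma_params()].
#' @return a `gamma_result`: gamma map (reference geometry, `NA` below
#'   threshold), evaluated-point mask, pass fraction (% of evaluated
#'   points with gamma < 1) and mean gamma over evaluated points.
#' @export
gamma_map <- function(reference, evaluation, params = gamma_params()) {
  ref <- gamma_geom(reference)
  ev <- gamma_geom(evaluation)
  if (length(ref$dim) != length(ev$dim))
    stop("reference and evaluation must have the same dimensionality")
  norm_dose <- max(ref$values)
  g <- gamma_search_cpp(ref$values, ref$dim, ref$spacing, ref$origin,
                        ev$values, ev$dim, ev$spacing, ev$origin,
                        params$dd / 100, norm_dose,
                        params$norm == "local",
                        params$dta, params$cap, params$step,
                        params$threshold / 100 * norm_dose, params$refine)
  gmap <- array(g, dim = ref$dim)
  gamma_result(gmap, ref, params)
}

#' Exhaustive-lattice gamma oracle
#'
#' Independent reference implementation used to validate [gamma_map()]:
#' a plain minimum over a dense offset lattice (step at most `dta`/20)
#' inside the search cap, written in vectorized R with no shared search
#' code.  Guarded to small inputs (at most 64^2 reference points).
#'
#' @inheritParams gamma_map
#' @return a `gamma_result`.
#' @export
gamma_brute_force <- function(reference, evaluation,
                              params = gamma_params()) {
  ref <- gamma_geom(reference)
  ev <- gamma_geom(evaluation)
  if (prod(ref$dim) > 64^2)
    stop("gamma_brute_force is guarded to at most 64^2 reference points")
  if (length(ref$dim) != 2L)
    stop("gamma_brute_force handles planar distributions")
  norm_dose <- max(ref$values)
  dd_abs <- params$dd / 100 * norm_dose
  thr <- params$threshold / 100 * norm_dose
  step <- min(params$step, params$dta / 20)
  m <- floor(params$cap / step)
  offs <- expand.grid(ox = (-m:m) * step, oy = (-m:m) * step)
  offs$r2 <- offs$ox^2 + offs$oy^2
  offs <- offs[offs$r2 <= params$cap^2, ]

  xs <- ref$origin[1] + (seq_len(ref$dim[1]) - 1) * ref$spacing[1]
  ys <- ref$origin[2] + (seq_len(ref$dim[2]) - 1) * ref$spacing[2]
  px <- rep(xs, times = ref$dim[2])
  py <- rep(ys, each = ref$dim[1])
  Dr <- as.numeric(ref$values)
  act <- Dr >= thr
  ddv <- if (params$norm == "local") params$dd / 100 * Dr else
    rep(dd_abs, length(Dr))

  exs <- ev$origin[1] + (seq_len(ev$dim[1]) - 1) * ev$spacing[1]
  eys <- ev$origin[2] + (seq_len(ev$dim[2]) - 1) * ev$spacing[2]
  interp <- function(x, y) {
    gx <- (x - ev$origin[1]) / ev$spacing[1]
    gy <- (y - ev$origin[2]) / ev$spacing[2]
    ok <- gx >= 0 & gy >= 0 & gx <= ev$dim[1] - 1 & gy <= ev$dim[2] - 1
    i0 <- pmin(floor(gx), ev$dim[1] - 2)
    j0 <- pmin(floor(gy), ev$dim[2] - 2)
    tx <- gx - i0
    ty <- gy - j0
    i0[!ok] <- 0
    j0[!ok] <- 0
    id <- function(i, j) i + j * ev$dim[1] + 1
    v <- (1 - tx) * (1 - ty) * ev$values[id(i0, j0)] +
      tx * (1 - ty) * ev$values[id(i0 + 1, j0)] +
      (1 - tx) * ty * ev$values[id(i0, j0 + 1)] +
      tx * ty * ev$values[id(i0 + 1, j0 + 1)]
    v[!ok] <- NA_real_
    v
  }

  best <- rep(Inf, length(Dr))
  for (r in seq_len(nrow(offs))) {
    De <- interp(px + offs$ox[r], py + offs$oy[r])
    g2 <- ((De - Dr) / ddv)^2 + offs$r2[r] / params$dta^2
    upd <- !is.na(g2) & g2 < best
    best[upd] <- g2[upd]
  }
  gmap <- array(sqrt(best), dim = ref$dim)
  gmap[!act | !is.finite(gmap)] <- NA_real_
  gamma_result(gmap, ref, params)
}

#' Gamma summary sweep over criteria settings
#'
#' @param reference,evaluation as in [gamma_map()].
#' @param settings `data.frame` (or list of lists) with columns `dd`,
#'   `dta` and optionally `threshold` (% of the reference maximum;
#'   default 10).
#' @param ... forwarded to [gamma_params()] (e.g. `norm`).
#' @return `data.frame` with one row per setting: `dd`, `dta`,
#'   `threshold`, `pass_pct`, `mean_gamma`, `n_evaluated`.
#' @export
gamma_sweep <- function(reference, evaluation, settings, ...) {
  settings <- as.data.frame(settings)
  if (is.null(settings$threshold)) settings$threshold <- 10
  rows <- lapply(seq_len(nrow(settings)), function(i) {
    p <- gamma_params(dd = settings$dd[i], dta = settings$dta[i],
                      threshold = settings$threshold[i], ...)
    res <- gamma_map(reference, evaluation, p)
    data.frame(dd = p$dd, dta = p$dta, threshold = p$threshold,
               pass_pct = res$pass_pct, mean_gamma = res$mean_gamma,
               n_evaluated = res$n_evaluated)
  })
  do.call(rbind, rows)
}

#' Write a gamma map as a PNG image
#'
#' Blue pixels pass (gamma < 1), red pixels fail (gamma >= 1), with
#' intensity tracking the gamma value; sub-threshold points are white.
#'
#' @param result a `gamma_result`.
#' @param path destination PNG file.
#' @return `path`, invisibly.
#' @export
write_gamma_png <- function(result, path) {
  g <- result$gamma
  if (length(dim(g)) != 2L) stop("PNG export handles planar gamma maps")
  nx <- dim(g)[1]; ny <- dim(g)[2]
  img <- array(1, dim = c(ny, nx, 3))  # white background
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    v <- g[i, j]
    if (is.na(v)) next
    if (v < 1) {  # blue, darker towards gamma = 1
      img[ny - j + 1, i, ] <- c(1 - v, 1 - v, 1) * c(0.9, 0.9, 1)
    } else {      # red, darker with larger gamma
      s <- max(0, 1 - (v - 1) / 2)
      img[ny - j + 1, i, ] <- c(1, s * 0.6, s * 0.6)
    }
  }
  grDevices::png(path, width = nx, height = ny)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
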