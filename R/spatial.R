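#' Gaussian FWHM conversion factor
#'
#' `2 * sqrt(2 * log(2))`, approximately 2.3548: the full width at half
#' maximum of a normal density with unit standard deviation.
#' @export
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Fit a normal distribution along one axis
#'
#' Mean, sample standard deviation and full width at half maximum
#' (`FWHM = 2 sqrt(2 ln 2) sigma`) of a set of coordinates. Identical
#' coordinates give a degenerate fit with zero sigma and FWHM.
#'
#' @param x Numeric coordinates (length >= 2).
#' @return List `mu`, `sigma`, `fwhm`, `n`, `degenerate`.
#' @export
fit_axis_normal <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)))
  s <- stats::sd(x)
  degenerate <- s == 0
  list(mu = mean(x), sigma = s, fwhm = FWHM_FACTOR * s, n = length(x),
       degenerate = degenerate)
}

#' Central exposure ellipse
#'
#' The ellipse used to split the field of view into "central" (inside the
#' infrared-exposed surface) and "peripheral" cells. Defaults to the
#' exposure footprint axes with the major axis along x (the fiber is
#' assumed horizontal in the imaging frame).
#'
#' @param center Ellipse centre (x, y), micrometres.
#' @param major_axis_um,minor_axis_um Full axes, micrometres.
#' @param orientation_deg Major-axis orientation, degrees.
#' @return Object of class `central_ellipse`.
#' @export
central_ellipse <- function(center = c(0, 0), major_axis_um = 246,
                            minor_axis_um = 168, orientation_deg = 0) {
  stopifnot(length(center) == 2, minor_axis_um > 0,
            major_axis_um >= minor_axis_um)
  structure(list(center = as.numeric(center),
                 major_axis_um = major_axis_um,
                 minor_axis_um = minor_axis_um,
                 orientation_deg = orientation_deg),
            class = "central_ellipse")
}

#' Ellipse membership test
#'
#' A point is inside when `(x'/a)^2 + (y'/b)^2 <= 1` in the ellipse-aligned
#' frame, with `a`, `b` the semi-axes; the boundary counts as inside.
#'
#' @param x_um,y_um Point coordinates, micrometres (vectorised).
#' @param ellipse A [central_ellipse()].
#' @return Logical vector.
#' @export
ellipse_membership <- function(x_um, y_um, ellipse) {
  stopifnot(inherits(ellipse, "central_ellipse"))
  th <- ellipse$orientation_deg * pi / 180
  dx <- x_um - ellipse$center[1]
  dy <- y_um - ellipse$center[2]
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  (xr / (ellipse$major_axis_um / 2))^2 +
    (yr / (ellipse$minor_axis_um / 2))^2 <= 1
}

#' Align fields of view on the multiple-responder distribution maxima
#'
#' Each experiment's cell map is translated so the fitted per-axis normal
#' mean (the distribution maximum of a normal fit) of its multiple
#' responders (class 3x+4x) sits at the origin; no rotation is applied.
#' Experiments with fewer than two multiple responders cannot be centred
#' and are excluded with a warning. Per-axis normal fits are then computed
#' for each responder class, both pooled over the shifted overlay and per
#' experiment (summarised as mean +/- SEM of the per-experiment FWHMs).
#'
#' @param cell_map Data frame with columns `experiment_id`, `roi_id`,
#'   `x_um`, `y_um` and `class` (multiplicity labels as produced by
#'   [multiplicity_class()]); extra columns (e.g. `depth_um`) are carried
#'   through.
#' @return List of class `aligned_overlay`: `shifts` (per experiment),
#'   `cells` (shifted coordinates), `fits` (pooled per class x axis),
#'   `fits_per_experiment`, `fwhm_summary`, `excluded`.
#' @export
align_fovs <- function(cell_map) {
  need <- c("experiment_id", "roi_id", "x_um", "y_um", "class")
  stopifnot(all(need %in% names(cell_map)))
  exps <- unique(cell_map$experiment_id)

  shifts <- list(); excluded <- character(0)
  for (e in exps) {
    sub <- cell_map[cell_map$experiment_id == e & cell_map$class == "3x+4x", ]
    if (nrow(sub) < 2) {
      warning("experiment ", e,
              " has fewer than 2 multiple responders: excluded from overlay")
      excluded <- c(excluded, e)
      next
    }
    shifts[[e]] <- c(dx = -mean(sub$x_um), dy = -mean(sub$y_um))
  }
  if (length(shifts) == 0) stop("no experiment with multiple responders")

  keep <- cell_map$experiment_id %in% names(shifts)
  cells <- cell_map[keep, , drop = FALSE]
  sh <- do.call(rbind, shifts)
  cells$x_um <- cells$x_um + sh[cells$experiment_id, "dx"]
  cells$y_um <- cells$y_um + sh[cells$experiment_id, "dy"]

  classes <- c("1x", "2x", "3x+4x")
  fit_block <- function(df, label) {
    do.call(rbind, lapply(classes, function(cl) {
      do.call(rbind, lapply(c("x", "y"), function(ax) {
        v <- df[df$class == cl, paste0(ax, "_um")]
        if (length(v) < 2)
          return(data.frame(experiment_id = label, class = cl, axis = ax,
                            mu = NA_real_, sigma = NA_real_, fwhm = NA_real_,
                            n = length(v)))
        ft <- fit_axis_normal(v)
        data.frame(experiment_id = label, class = cl, axis = ax,
                   mu = ft$mu, sigma = ft$sigma, fwhm = ft$fwhm, n = ft$n)
      }))
    }))
  }
  fits <- fit_block(cells, "pooled")[, -1]
  fits_pe <- do.call(rbind, lapply(names(shifts), function(e)
    fit_block(cells[cells$experiment_id == e, , drop = FALSE], e)))

  ok <- !is.na(fits_pe$fwhm)
  fw <- stats::aggregate(fwhm ~ class + axis, data = fits_pe[ok, ],
                         FUN = function(v) c(m = mean(v),
                                             s = if (length(v) > 1)
                                               stats::sd(v) / sqrt(length(v)) else 0,
                                             n = length(v)))
  fwhm_summary <- data.frame(class = fw$class, axis = fw$axis,
                             mean_fwhm = fw$fwhm[, "m"],
                             sem_fwhm = fw$fwhm[, "s"],
                             n_experiments = fw$fwhm[, "n"])

  structure(list(shifts = data.frame(experiment_id = rownames(sh),
                                     dx_um = sh[, "dx"], dy_um = sh[, "dy"],
                                     row.names = NULL),
                 cells = cells, fits = fits,
                 fits_per_experiment = fits_pe,
                 fwhm_summary = fwhm_summary,
                 excluded = excluded),
            class = "aligned_overlay")
}

#' Central vs peripheral response fractions
#'
#' Splits cells by membership in the central exposure ellipse and reports
#' the percentage of responsive cells (any responsive energy, i.e. class
#' other than "0") inside and outside, plus, for each multiplicity class,
#' the percentage of its cells lying inside the ellipse.
#'
#' @param cell_map Data frame with `x_um`, `y_um`, `class` (aligned
#'   coordinates, e.g. `align_fovs(...)$cells`).
#' @param ellipse A [central_ellipse()].
#' @return List of class `location_fractions`: `central_responsive_pct`,
#'   `peripheral_responsive_pct`, `per_class` (central share per class),
#'   `n_inside`, `n_outside`.
#' @export
location_fractions <- function(cell_map, ellipse = central_ellipse()) {
  stopifnot(all(c("x_um", "y_um", "class") %in% names(cell_map)))
  inside <- ellipse_membership(cell_map$x_um, cell_map$y_um, ellipse)
  responsive <- cell_map$class != "0"
  central <- if (any(inside)) 100 * mean(responsive[inside]) else NA_real_
  peripheral <- if (any(!inside)) 100 * mean(responsive[!inside]) else NA_real_
  if (!any(inside) || !any(!inside))
    warning("one of the regions is empty: its percentage is undefined")
  classes <- c("1x", "2x", "3x+4x")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    sel <- cell_map$class == cl
    data.frame(class = cl, n_cells = sum(sel),
               central_share_pct = if (any(sel)) 100 * mean(inside[sel])
                                   else NA_real_)
  }))
  structure(list(central_responsive_pct = central,
                 peripheral_responsive_pct = peripheral,
                 per_class = per_class,
                 n_inside = sum(inside), n_outside = sum(!inside)),
            class = "location_fractions")
}

#' Build a cell map by joining geometry and multiplicity classes
#'
#' @param cells Data frame with `roi_id`, `x_um`, `y_um` (and optionally
#'   `experiment_id`, `depth_um`).
#' @param calls Response-call data frame (see [analyze_traces()]).
#' @return Data frame suitable for [align_fovs()].
#' @export
build_cell_map <- function(cells, calls) {
  cells <- .ensure_experiment(cells)
  calls <- .ensure_experiment(calls)
  mt <- multiplicity_categories(calls)
  key <- paste(mt$per_cell$experiment_id, mt$per_cell$roi_id, sep = "\r")
  cls <- stats::setNames(mt$per_cell$class, key)
  ck <- paste(cells$experiment_id, cells$roi_id, sep = "\r")
  cells$class <- unname(cls[ck])
  cells <- cells[!is.na(cells$class), , drop = FALSE]
  cells
}
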