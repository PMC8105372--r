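#' Write and read long-format trace tables
#'
#' Plain-CSV round trip of the [analyze_traces()] input schema.
#'
#' @param traces Data frame with columns `roi_id`, `trial`,
#'   `energy_density_J_cm2`, `frame`, `F`.
#' @param path File path.
#' @return `read_traces_csv` returns the data frame; `write_traces_csv`
#'   returns `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "trial", "energy_density_J_cm2", "frame", "F")
  if (!all(need %in% names(tr)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  tr
}

#' Render a synthetic experiment as a multi-page TIFF movie plus ROI mask
#'
#' Cells are drawn as Gaussian-profiled blobs on disk supports whose pixel
#' weights are normalised so the mean over each cell's mask pixels equals
#' its fluorescence value; mean-over-mask extraction of the rendered movie
#' therefore reproduces the input traces up to 16-bit quantisation. The
#' label mask assigns each cell's disk its 1-based index in `cells`
#' (cells must not overlap at the chosen radius). One movie holds a single
#' recording (one energy, one trial).
#'
#' @param cells Cell map (needs `roi_id`, `x_um`, `y_um`).
#' @param traces Long trace table restricted to one energy x trial.
#' @param movie_path,mask_path Output TIFF paths.
#' @param um_per_px Pixel size, micrometres.
#' @param cell_radius_um Disk radius of each rendered cell.
#' @param blob_sigma_um Gaussian profile width of the blob.
#' @param background Constant background level, fluorescence units.
#' @param full_scale Fluorescence value mapped to the 16-bit maximum;
#'   values above are clamped with a warning.
#' @param fov_um Field-of-view size (x, y), micrometres.
#' @return List with `full_scale`, `background`, `um_per_px` (needed to
#'   invert the rendering), invisibly.
#' @export
render_movie <- function(cells, traces, movie_path, mask_path,
                         fov_um = c(240, 240), um_per_px = 2,
                         cell_radius_um = 6, blob_sigma_um = 4,
                         background = 50, full_scale = NULL) {
  w <- floor(fov_um[1] / um_per_px)
  h <- floor(fov_um[2] / um_per_px)
  r_px <- cell_radius_um / um_per_px
  if (w < 2 * r_px || h < 2 * r_px)
    stop("pixel grid too small for the cell blobs")

  nf <- if (nrow(traces) > 0) max(traces$frame) else 1
  fmat <- if (nrow(traces) > 0) {
    tr <- traces[order(match(traces$roi_id, cells$roi_id), traces$frame), ]
    matrix(tr$F, nrow = nf)              # frames x cells present
  } else matrix(numeric(0), nrow = 0)
  present <- cells$roi_id[cells$roi_id %in% unique(traces$roi_id)]

  mask <- matrix(0L, nrow = h, ncol = w)
  weights <- vector("list", nrow(cells))
  pix <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i] / um_per_px + 0.5
    cy <- cells$y_um[i] / um_per_px + 0.5
    xs <- max(1, floor(cx - r_px)):min(w, ceiling(cx + r_px))
    ys <- max(1, floor(cy - r_px)):min(h, ceiling(cy + r_px))
    g <- expand.grid(y = ys, x = xs)
    d2 <- (g$x - cx)^2 + (g$y - cy)^2
    sel <- d2 <= r_px^2
    if (!any(sel)) stop("cell ", cells$roi_id[i], " renders to no pixels")
    g <- g[sel, ]; d2 <- d2[sel]
    wgt <- exp(-d2 / (2 * (blob_sigma_um / um_per_px)^2))
    wgt <- wgt / mean(wgt)               # mean over mask pixels = 1
    idx <- cbind(g$y, g$x)
    if (any(mask[idx] != 0)) stop("overlapping cells in the rendered mask")
    mask[idx] <- i
    weights[[i]] <- wgt
    pix[[i]] <- idx
  }

  if (is.null(full_scale)) {
    # headroom for the blob profile peak (weights exceed 1 at the centre)
    wmax <- if (length(weights) > 0) max(vapply(weights, max, 0)) else 1
    full_scale <- max(background, if (length(fmat)) max(fmat) * wmax else 1) *
      1.05
  }

  clipped <- FALSE
  frames <- lapply(seq_len(nf), function(fr) {
    img <- matrix(background, nrow = h, ncol = w)
    for (i in seq_len(nrow(cells))) {
      j <- match(cells$roi_id[i], present)
      if (is.na(j)) next
      img[pix[[i]]] <- weights[[i]] * fmat[fr, j]
    }
    v <- img / full_scale
    if (any(v > 1)) { clipped <<- TRUE; v <- pmin(v, 1) }
    pmax(v, 0)
  })
  if (clipped) warning("pixel values clamped at the 16-bit maximum")
  tiff::writeTIFF(frames, movie_path, bits.per.sample = 16,
                  compression = "none")
  tiff::writeTIFF(mask / 65535, mask_path, bits.per.sample = 16,
                  compression = "none")
  invisible(list(full_scale = full_scale, background = background,
                 um_per_px = um_per_px))
}

#' Extract per-ROI traces from a movie TIFF and a label mask
#'
#' Mean over each label's mask pixels, per frame, scaled back to
#' fluorescence units. The inverse of [render_movie()].
#'
#' @param movie_path Multi-page TIFF movie.
#' @param mask_path Label-image TIFF (labels stored as value * 65535).
#' @param full_scale Fluorescence value that maps to the 16-bit maximum.
#' @return Data frame `roi` (integer label), `frame`, `F`.
#' @export
extract_traces_tiff <- function(movie_path, mask_path, full_scale) {
  frames <- tiff::readTIFF(movie_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  mask <- round(tiff::readTIFF(mask_path) * 65535)
  labels <- sort(unique(as.vector(mask)))
  labels <- labels[labels > 0]
  out <- lapply(seq_along(frames), function(fr) {
    img <- frames[[fr]] * full_scale
    data.frame(roi = labels, frame = fr,
               F = vapply(labels, function(l) mean(img[mask == l]), 0))
  })
  do.call(rbind, out)
}
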