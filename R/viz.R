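#' @title Gaze heat maps
#' @description Gaussian kernel-density heat maps of gaze samples,
#'   rendered over schematic stimulus placeholders with a
#'   green-yellow-red colormap.
#' @name viz
NULL

#' Gaze density map
#'
#' Isotropic Gaussian kernel density of gaze samples on a regular grid
#' covering the screen. Each valid sample contributes one unnormalised
#' Gaussian bump (truncated at 4 bandwidths), so intensities are
#' additive: the map of pooled samples equals the sum of the per-subset
#' maps at the same bandwidth. A peak-normalised copy is kept for
#' colormapping.
#'
#' @param x,y Gaze coordinates (pixels), e.g. pooled over subjects.
#' @param valid Logical validity flags (recycled).
#' @param bandwidth Kernel SD in pixels (default 40 px, about one degree
#'   of visual angle at the acquisition geometry).
#' @param cell Grid cell size in pixels (downsampling factor).
#' @param width,height Screen size in pixels.
#' @return A `heat_map`: `intensity` (rows = y bins, unnormalised),
#'   `normalized` (peak 1), grid metadata.
#' @export
gaze_density <- function(x, y, valid = TRUE, bandwidth = 40, cell = 4,
                         width = 1920, height = 1080) {
  valid <- rep_len(valid, length(x))
  keep <- valid & !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("no valid samples")
  nx <- ceiling(width / cell); ny <- ceiling(height / cell)
  gx <- (seq_len(nx) - 0.5) * cell
  gy <- (seq_len(ny) - 0.5) * cell
  grid <- matrix(0, nrow = ny, ncol = nx)
  r <- 4 * bandwidth
  for (s in seq_along(x)) {
    ix <- which(abs(gx - x[s]) <= r)
    iy <- which(abs(gy - y[s]) <= r)
    if (!length(ix) || !length(iy)) next
    kx <- stats::dnorm(gx[ix], x[s], bandwidth)
    ky <- stats::dnorm(gy[iy], y[s], bandwidth)
    grid[iy, ix] <- grid[iy, ix] + outer(ky, kx)
  }
  structure(list(intensity = grid, normalized = grid / max(grid),
                 cell = cell, bandwidth = bandwidth,
                 width = width, height = height, n_samples = length(x)),
            class = "heat_map")
}

#' Gaze density of one stimulus over sessions
#'
#' Pools the raw samples of one stimulus across sessions (e.g. all
#' subjects of a group) and computes their density map.
#'
#' @param sessions List of [session_log()].
#' @param task,stimulus Stimulus selector.
#' @param ... Passed to [gaze_density()].
#' @return A `heat_map`.
#' @export
group_gaze_density <- function(sessions, task, stimulus, ...) {
  key <- series_key(as.integer(task), as.integer(stimulus))
  xs <- ys <- vs <- numeric(0)
  for (ses in sessions) {
    ser <- ses$series[[key]]
    if (is.null(ser)) next
    xs <- c(xs, ser$samples$x); ys <- c(ys, ser$samples$y)
    vs <- c(vs, ser$samples$valid)
  }
  gaze_density(xs, ys, as.logical(vs), ...)
}

# green -> yellow -> red colormap on [0,1]
heat_colormap <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(1, 2 * v)
  g <- pmin(1, 2 * (1 - v))
  b <- rep(0, length(v))
  cbind(r, g, b)
}

#' Schematic face placeholder image
#'
#' Generates a grey schematic face (head oval, eyes, nose, mouth) inside
#' the default single-face AOI geometry, or a grid of small faces for
#' matrix stimuli — a redistributable stand-in for the photographic
#' stimuli when rendering heat-map overlays. Synthetic: no photographic
#' content.
#'
#' @param kind `"single"` or `"matrix"`.
#' @param cells For matrices, named list of cell [aoi_rect()].
#' @param width,height,cell Grid geometry matching [gaze_density()].
#' @return RGB array (rows x cols x 3) in `[0, 1]`.
#' @export
placeholder_face <- function(kind = c("single", "matrix"), cells = NULL,
                             width = 1920, height = 1080, cell = 4) {
  kind <- match.arg(kind)
  nx <- ceiling(width / cell); ny <- ceiling(height / cell)
  img <- array(0.92, dim = c(ny, nx, 3))
  gx <- (seq_len(nx) - 0.5) * cell
  gy <- (seq_len(ny) - 0.5) * cell
  draw_face <- function(img, cx, cy, w, h) {
    X <- matrix(gx, ny, nx, byrow = TRUE); Y <- matrix(gy, ny, nx)
    head <- ((X - cx) / (w / 2))^2 + ((Y - cy) / (h / 2))^2 <= 1
    for (ch in 1:3) { pl <- img[, , ch]; pl[head] <- 0.75; img[, , ch] <- pl }
    feat <- (abs(X - (cx - w * 0.18)) < w * 0.08 & abs(Y - (cy - h * 0.15)) < h * 0.05) |
            (abs(X - (cx + w * 0.18)) < w * 0.08 & abs(Y - (cy - h * 0.15)) < h * 0.05) |
            (abs(X - cx) < w * 0.04 & abs(Y - (cy + h * 0.05)) < h * 0.12) |
            (abs(X - cx) < w * 0.18 & abs(Y - (cy + h * 0.3)) < h * 0.04)
    for (ch in 1:3) { pl <- img[, , ch]; pl[feat] <- 0.35; img[, , ch] <- pl }
    img
  }
  if (kind == "single") {
    img <- draw_face(img, 960, 540, 600, 780)
  } else {
    stopifnot(!is.null(cells))
    for (rc in cells)
      img <- draw_face(img, (rc$x_min + rc$x_max) / 2, (rc$y_min + rc$y_max) / 2,
                       0.7 * (rc$x_max - rc$x_min), 0.9 * (rc$y_max - rc$y_min))
  }
  img
}

#' Render a heat map over a background image
#'
#' Alpha-blends the colormapped (green-yellow-red) normalised heat map
#' over a background RGB array and writes a PNG. Deterministic given
#' identical inputs. Intensities below `floor` stay transparent so the
#' background shows through where gaze never landed.
#'
#' @param map A `heat_map`.
#' @param background RGB array with the map's grid dimensions, or `NULL`
#'   for a plain grey background.
#' @param out Output PNG path.
#' @param alpha Maximum overlay opacity.
#' @param floor Normalised intensity below which nothing is drawn.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(map, background = NULL, out, alpha = 0.6,
                           floor = 0.05) {
  stopifnot(inherits(map, "heat_map"))
  dims <- dim(map$normalized)
  if (is.null(background))
    background <- array(0.92, dim = c(dims, 3))
  if (!all(dim(background)[1:2] == dims))
    stop("background dimensions do not match the heat-map grid")
  v <- map$normalized
  colr <- heat_colormap(as.vector(v))
  a <- ifelse(as.vector(v) < floor, 0, alpha * as.vector(v))
  img <- background
  for (ch in 1:3) {
    bg <- as.vector(background[, , ch])
    img[, , ch] <- matrix(bg * (1 - a) + colr[, ch] * a, dims[1], dims[2])
  }
  png::writePNG(img, out)
  invisible(out)
}
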