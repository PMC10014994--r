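#' Delaunay triangulation of scattered points (Bowyer-Watson)
#'
#' Incremental insertion with a super-triangle; suitable for the few dozen to
#' few thousand points of a field survey. Coordinates are rescaled to the unit
#' box internally for numerical stability. Requires at least 3 points, not all
#' collinear, with no duplicated coordinates.
#'
#' @param x,y point coordinates (metres, any projected CRS).
#' @return integer matrix, one row per triangle, columns the three vertex
#'   indices into `x`/`y`.
#' @export
delaunay_triangulation <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) abort("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("coordinates must be finite")
  if (anyDuplicated(cbind(x, y))) {
    abort("duplicated coordinates; average coincident points first")
  }
  scale <- max(diff(range(x)), diff(range(y)))
  if (scale <= 0) abort("all points coincide in one dimension and are collinear")
  xs <- (x - min(x)) / scale
  ys <- (y - min(y)) / scale
  # collinearity: max twice-area over point triples against the first edge
  base <- which.max((xs - xs[1])^2 + (ys - ys[1])^2)
  cross <- (xs[base] - xs[1]) * (ys - ys[1]) - (ys[base] - ys[1]) * (xs - xs[1])
  if (max(abs(cross)) < 1e-12) abort("all points are collinear")

  px <- c(xs, -100, 100, 0.5)
  py <- c(ys, -100, -100, 300)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1L)
  cc <- matrix(circumcircle(px[tris], py[tris]), nrow = 1L)

  for (i in seq_len(n)) {
    bad <- which((px[i] - cc[, 1L])^2 + (py[i] - cc[, 2L])^2 <=
                   cc[, 3L] * (1 + 1e-12))
    # boundary of the cavity: edges of bad triangles not shared by two of them
    e <- rbind(tris[bad, c(1L, 2L), drop = FALSE],
               tris[bad, c(2L, 3L), drop = FALSE],
               tris[bad, c(3L, 1L), drop = FALSE])
    ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    boundary <- e[ekey %in% names(which(table(ekey) == 1L)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    new_tris <- cbind(boundary, i)
    tris <- rbind(tris, new_tris)
    cc <- rbind(cc, circumcircle_rows(px, py, new_tris))
  }
  keep <- tris[, 1L] <= n & tris[, 2L] <= n & tris[, 3L] <= n
  out <- tris[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  # canonical vertex order and row order for deterministic output
  out <- t(apply(out, 1L, sort))
  out[order(out[, 1L], out[, 2L], out[, 3L]), , drop = FALSE]
}

# circumcenter (ux, uy) and squared radius r2 of triangle(s) given as
# 3-column coordinate matrices
circumcircle <- function(tx, ty) {
  tx <- matrix(tx, ncol = 3L)
  ty <- matrix(ty, ncol = 3L)
  ax <- tx[, 1L]; ay <- ty[, 1L]
  bx <- tx[, 2L]; by <- ty[, 2L]
  cx <- tx[, 3L]; cy <- ty[, 3L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

circumcircle_rows <- function(px, py, tris) {
  circumcircle(cbind(px[tris[, 1L]], px[tris[, 2L]], px[tris[, 3L]]),
               cbind(py[tris[, 1L]], py[tris[, 2L]], py[tris[, 3L]]))
}

#' Piecewise-linear interpolation at query points
#'
#' Evaluates the piecewise-linear (barycentric) interpolant over the Delaunay
#' triangulation of the sample points at arbitrary query locations. Exact at
#' the sample points; `NA` outside the convex hull (no extrapolation).
#' Duplicate sample coordinates are averaged first (with a warning).
#'
#' @param points data.frame with columns `x`, `y`, `h` (or `H`).
#' @param qx,qy query coordinates.
#' @return numeric vector of interpolated values, `NA` outside the hull.
#' @export
interpolate_at <- function(points, qx, qy) {
  pts <- normalize_points(points)
  tris <- delaunay_triangulation(pts$x, pts$y)
  barycentric_eval(pts$x, pts$y, pts$h, tris, qx, qy)
}

normalize_points <- function(points) {
  points <- as.data.frame(points)
  if (!"h" %in% names(points) && "H" %in% names(points)) {
    points$h <- points$H
  }
  check_columns(points, c("x", "y", "h"), "points")
  key <- paste(points$x, points$y)
  if (anyDuplicated(key)) {
    warning("duplicate coordinates averaged before triangulation",
            call. = FALSE)
    points <- aggregate(h ~ x + y, data = points, FUN = mean)
  }
  points
}

barycentric_eval <- function(px, py, pz, tris, qx, qy) {
  out <- rep(NA_real_, length(qx))
  eps <- 1e-9
  for (t in seq_len(nrow(tris))) {
    i <- tris[t, ]
    x1 <- px[i[1L]]; y1 <- py[i[1L]]
    x2 <- px[i[2L]]; y2 <- py[i[2L]]
    x3 <- px[i[3L]]; y3 <- py[i[3L]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
    l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
    l3 <- 1 - l1 - l2
    sel <- is.na(out) & l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (any(sel)) {
      out[sel] <- l1[sel] * pz[i[1L]] + l2[sel] * pz[i[2L]] + l3[sel] * pz[i[3L]]
    }
  }
  # a linear interpolant cannot overshoot its data; clip fp slack at edges
  pmin(pmax(out, min(pz)), max(pz))
}

#' Interpolate a diversity surface onto a regular grid
#'
#' Transforms per-quadrat point values of the Shannon index into a continuous
#' surface by piecewise-linear barycentric interpolation on the Delaunay
#' triangulation of the quadrat locations. Square cells are sized so the grid
#' covers the points' bounding box padded by one cell on each side; cells
#' outside the convex hull of the points are missing (`NA`) — no
#' extrapolation.
#'
#' @param points data.frame with columns `x`, `y`, `h` (or `H`); e.g. the
#'   `per_unit` table of [per_unit_diversity()].
#' @param nx,ny number of grid cells in x and y (default 100 each).
#' @return object of class `diversity_grid`: list with `x0`, `y0` (lower-left
#'   cell-centre origin), `cellsize`, `nx`, `ny`, and `values`, an `ny` x `nx`
#'   matrix (row 1 = southernmost row).
#' @export
interpolate_diversity <- function(points, nx = 100, ny = 100) {
  pts <- normalize_points(points)
  if (nx < 3L || ny < 3L) abort("grid must be at least 3 x 3")
  tris <- delaunay_triangulation(pts$x, pts$y)
  cellsize <- max(diff(range(pts$x)) / (nx - 2), diff(range(pts$y)) / (ny - 2))
  if (cellsize <= 0) abort("degenerate point extent")
  x0 <- min(pts$x) - cellsize
  y0 <- min(pts$y) - cellsize
  gx <- x0 + (seq_len(nx) - 1L) * cellsize
  gy <- y0 + (seq_len(ny) - 1L) * cellsize
  q <- expand.grid(x = gx, y = gy)
  v <- barycentric_eval(pts$x, pts$y, pts$h, tris, q$x, q$y)
  structure(list(x0 = x0, y0 = y0, cellsize = cellsize,
                 nx = as.integer(nx), ny = as.integer(ny),
                 values = matrix(v, nrow = ny, ncol = nx, byrow = TRUE)),
            class = "diversity_grid")
}

#' @export
print.diversity_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("diversity_grid: %d x %d cells of %.2f m, %d inside hull, H in [%.4f, %.4f]\n",
              x$nx, x$ny, x$cellsize, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
as.data.frame.diversity_grid <- function(x, ...) {
  gx <- x$x0 + (seq_len(x$nx) - 1L) * x$cellsize
  gy <- x$y0 + (seq_len(x$ny) - 1L) * x$cellsize
  data.frame(x = rep(gx, times = x$ny), y = rep(gy, each = x$nx),
             h = as.vector(t(x$values)))
}

#' Write a diversity grid as an ESRI ASCII raster
#'
#' Plain-text grid interchange: NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/
#' NODATA_VALUE header followed by rows from north to south. Cell centres are
#' registered to the grid origin, so the lower-left corner is offset by half a
#' cell.
#'
#' @param grid a [interpolate_diversity()] result.
#' @param path output file.
#' @param nodata missing-value marker (default -9999).
#' @return invisibly, the path.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "diversity_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", grid$nx),
               sprintf("NROWS %d", grid$ny),
               sprintf("XLLCORNER %.6f", grid$x0 - grid$cellsize / 2),
               sprintf("YLLCORNER %.6f", grid$y0 - grid$cellsize / 2),
               sprintf("CELLSIZE %.6f", grid$cellsize),
               sprintf("NODATA_VALUE %s", format(nodata))), con)
  v <- grid$values
  v[is.na(v)] <- nodata
  for (row in rev(seq_len(grid$ny))) {
    writeLines(paste(format(v[row, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Presence overlay of focal species on the sampling units
#'
#' Labels every sampling unit by the presence of up to two focal species
#' (e.g. the two copal-producing Bursera species): `none`, `first_only`,
#' `second_only`, or `both`. With a single focal species the labels are `none`
#' / `first_only`; with an empty list all units are `none`. When a diversity
#' result is supplied its per-unit H is joined on, so the H range spanned by
#' occupied units can be read off directly.
#'
#' @param dataset a [survey_dataset()].
#' @param species_ids character vector of 0, 1 or 2 species ids.
#' @param diversity optional [per_unit_diversity()] result.
#' @return data.frame `unit_id`, `x`, `y`, `presence` (and `H` if `diversity`
#'   given).
#' @export
species_presence_overlay <- function(dataset, species_ids, diversity = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (length(species_ids) > 2L) abort("at most two focal species supported")
  unknown <- setdiff(species_ids, dataset$taxa$species_id)
  if (length(unknown) > 0L) {
    abort("unknown species id(s): %s", paste(unknown, collapse = ", "))
  }
  out <- dataset$units[, c("unit_id", "x", "y")]
  obs <- dataset$observations
  present <- function(sp) out$unit_id %in% obs$unit_id[obs$species_id == sp]
  p1 <- if (length(species_ids) >= 1L) present(species_ids[[1L]]) else
    rep(FALSE, nrow(out))
  p2 <- if (length(species_ids) >= 2L) present(species_ids[[2L]]) else
    rep(FALSE, nrow(out))
  out$presence <- ifelse(p1 & p2, "both",
                         ifelse(p1, "first_only",
                                ifelse(p2, "second_only", "none")))
  if (!is.null(diversity)) {
    stopifnot(inherits(diversity, "diversity_result"))
    out$H <- diversity$per_unit$H[match(out$unit_id,
                                        diversity$per_unit$unit_id)]
  }
  rownames(out) <- NULL
  out
}
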