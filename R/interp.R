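# Scattered-data interpolation over the sensor sites.
#
# The map interpolator needs a planar triangulation of at most a couple of
# dozen sensor sites; none of the attached numerical libraries provides one,
# so a compact Bowyer-Watson incremental Delaunay triangulation is
# implemented here. It is entirely adequate at this problem size and keeps
# the piecewise-linear interpolant exact at the nodes and bounded by the
# input range.

#' Delaunay triangulation of a planar point set
#'
#' Incremental Bowyer-Watson construction. Intended for the small site
#' counts of an insole layout; degenerate (duplicate) points are rejected.
#'
#' @param x,y Point coordinates (length >= 3).
#' @return Integer matrix with one triangle per row (vertex indices into
#'   `x`/`y`), counter-clockwise.
#' @export
delaunay_triangulate <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (anyDuplicated(cbind(x, y))) stop("duplicate points in triangulation input")
  # super-triangle comfortably enclosing all sites
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1) * 20
  px <- c(x, cx - span, cx + span, cx)
  py <- c(y, cy - span, cy - span, cy + span)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circum <- function(tri) {
    ax <- px[tri[1]]; ay <- py[tri[1]]
    bx <- px[tri[2]]; by <- py[tri[2]]
    gx <- px[tri[3]]; gy <- py[tri[3]]
    d <- 2 * (ax * (by - gy) + bx * (gy - ay) + gx * (ay - by))
    if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - gy) + (bx^2 + by^2) * (gy - ay) +
             (gx^2 + gy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (gx - bx) + (bx^2 + by^2) * (ax - gx) +
             (gx^2 + gy^2) * (bx - ax)) / d
    c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
  }
  ccs <- list(circum(tris[[1]]))
  for (i in seq_len(n)) {
    bad <- vapply(ccs, function(cc) {
      (px[i] - cc[1])^2 + (py[i] - cc[2])^2 <= cc[3] * (1 + 1e-12)
    }, logical(1))
    # boundary of the cavity: edges of bad triangles that appear exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(3, 1)]))))
    key <- paste(edges[, 1], edges[, 2])
    keep_edge <- !(key %in% key[duplicated(key)])
    tris <- tris[!bad]
    ccs <- ccs[!bad]
    for (e in which(keep_edge)) {
      tri <- c(edges[e, 1], edges[e, 2], i)
      tris[[length(tris) + 1L]] <- tri
      ccs[[length(ccs) + 1L]] <- circum(tri)
    }
  }
  real <- vapply(tris, function(tr) all(tr <= n), logical(1))
  out <- do.call(rbind, tris[real])
  # orient counter-clockwise
  for (k in seq_len(nrow(out))) {
    tr <- out[k, ]
    ar <- (px[tr[2]] - px[tr[1]]) * (py[tr[3]] - py[tr[1]]) -
      (px[tr[3]] - px[tr[1]]) * (py[tr[2]] - py[tr[1]])
    if (ar < 0) out[k, ] <- tr[c(1, 3, 2)]
  }
  out
}

# Piecewise-linear evaluation of scattered (x, y, v) at query points.
# Returns NA outside the convex hull of the sites.
linear_scatter_interp <- function(x, y, v, qx, qy) {
  tris <- delaunay_triangulate(x, y)
  out <- rep(NA_real_, length(qx))
  todo <- rep(TRUE, length(qx))
  eps <- 1e-9
  for (k in seq_len(nrow(tris))) {
    tr <- tris[k, ]
    ax <- x[tr[1]]; ay <- y[tr[1]]
    bx <- x[tr[2]]; by <- y[tr[2]]
    gx <- x[tr[3]]; gy <- y[tr[3]]
    det <- (by - gy) * (ax - gx) + (gx - bx) * (ay - gy)
    if (abs(det) < 1e-12) next
    idx <- which(todo)
    if (!length(idx)) break
    l1 <- ((by - gy) * (qx[idx] - gx) + (gx - bx) * (qy[idx] - gy)) / det
    l2 <- ((gy - ay) * (qx[idx] - gx) + (ax - gx) * (qy[idx] - gy)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    hit <- idx[inside]
    out[hit] <- l1[inside] * v[tr[1]] + l2[inside] * v[tr[2]] +
      l3[inside] * v[tr[3]]
    todo[hit] <- FALSE
  }
  out
}

# Thin-plate-spline radial basis interpolation (smooth optional variant).
rbf_scatter_interp <- function(x, y, v, qx, qy) {
  n <- length(x)
  d <- sqrt(outer(x, x, `-`)^2 + outer(y, y, `-`)^2)
  phi <- ifelse(d > 0, d^2 * log(d), 0)
  A <- rbind(cbind(phi, 1, x, y),
             cbind(t(cbind(1, x, y)), matrix(0, 3, 3)))
  w <- solve(A, c(v, 0, 0, 0))
  dq <- sqrt(outer(qx, x, `-`)^2 + outer(qy, y, `-`)^2)
  phq <- ifelse(dq > 0, dq^2 * log(dq), 0)
  as.vector(phq %*% w[1:n]) + w[n + 1] + w[n + 2] * qx + w[n + 3] * qy
}

#' Interpolate per-sensor values into a plantar map
#'
#' Spreads one scalar per sensor site of the requested kind over the foot
#' template: piecewise-linear interpolation on the Delaunay triangulation of
#' the sites (exact at every node and bounded by the input range), with
#' cells inside the foot mask but outside the sites' convex hull filled by
#' the nearest site's value. Cells containing a sensor are stamped with that
#' sensor's exact value. A smooth thin-plate-spline variant is available via
#' `method = "rbf"` (node-exact but not range-bounded).
#'
#' @param values Numeric vector, one value per channel of `kind`, in the
#'   layout's canonical channel order.
#' @param layout A [sensor_layout()] (one foot).
#' @param template A [foot_template()].
#' @param kind `"pressure"` or `"temperature"`.
#' @param units Unit string stored with the map (default `"N"` for pressure,
#'   `"degC"` for temperature).
#' @param method `"linear"` (default) or `"rbf"`.
#' @param phase Optional stance-phase label stored with the map.
#' @return Object of class `plantar_map`: `grid` (matrix, `NA` outside the
#'   mask), `mask`, `xs`, `ys`, `resolution_mm`, `units`, `kind`, `phase`
#'   and `sites` (the per-sensor inputs).
#' @export
interpolate_map <- function(values, layout, template,
                            kind = c("pressure", "temperature"),
                            units = NULL, method = c("linear", "rbf"),
                            phase = NULL) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  stopifnot(inherits(template, "foot_template"))
  chans <- layout_channels(layout, kind)
  if (length(values) != nrow(chans))
    stop(sprintf("expected %d values for the %s channels, got %d",
                 nrow(chans), kind, length(values)))
  if (nrow(chans) < 3) stop("at least 3 sensor sites are required")
  # collinearity check via the centred coordinate matrix rank
  xy <- cbind(chans$x_mm - mean(chans$x_mm), chans$y_mm - mean(chans$y_mm))
  if (svd(xy)$d[2] < 1e-8 * max(svd(xy)$d[1], 1))
    stop("sensor sites are collinear; a planar interpolant needs spread in 2-D")
  if (is.null(units)) units <- if (kind == "pressure") "N" else "degC"

  inside <- which(template$mask)                       # column-major indices
  qy <- template$ys[row(template$mask)[inside]]
  qx <- template$xs[col(template$mask)[inside]]
  vals <- if (method == "linear") {
    v <- linear_scatter_interp(chans$x_mm, chans$y_mm, values, qx, qy)
    miss <- is.na(v)
    if (any(miss)) {                                  # nearest-site fill
      d2 <- outer(qx[miss], chans$x_mm, `-`)^2 + outer(qy[miss], chans$y_mm, `-`)^2
      v[miss] <- values[max.col(-d2, ties.method = "first")]
    }
    v
  } else {
    rbf_scatter_interp(chans$x_mm, chans$y_mm, values, qx, qy)
  }
  grid <- matrix(NA_real_, nrow = nrow(template$mask), ncol = ncol(template$mask))
  grid[inside] <- vals
  # stamp the cell holding each sensor with its exact input; ties between
  # equidistant cell centres resolve toward the foot axis so that mirrored
  # layouts stamp mirrored cells
  ri <- vapply(chans$y_mm, function(y) {
    d <- abs(template$ys - y)
    which(d <= min(d) + 1e-9)[1]
  }, integer(1))
  ci <- vapply(chans$x_mm, function(x) {
    d <- abs(template$xs - x)
    cand <- which(d <= min(d) + 1e-9)
    cand[which.min(abs(template$xs[cand]))]
  }, integer(1))
  grid[cbind(ri, ci)] <- values
  structure(list(grid = grid, mask = template$mask,
                 xs = template$xs, ys = template$ys,
                 resolution_mm = template$resolution_mm,
                 units = units, kind = kind, phase = phase,
                 sites = data.frame(id = chans$id, x_mm = chans$x_mm,
                                    y_mm = chans$y_mm, row = ri, col = ci,
                                    value = values)),
            class = "plantar_map")
}

#' @export
print.plantar_map <- function(x, ...) {
  rng <- range(x$grid, na.rm = TRUE)
  cat(sprintf("<plantar_map> %s%s: %d x %d grid @ %g mm, range %.3g..%.3g %s\n",
              x$kind, if (is.null(x$phase)) "" else paste0(" [", x$phase, "]"),
              nrow(x$grid), ncol(x$grid), x$resolution_mm,
              rng[1], rng[2], x$units))
  invisible(x)
}

#' Plot a plantar map
#'
#' Base-graphics heat map of the interpolated field with the sensor sites
#' overlaid.
#'
#' @param x A `plantar_map`.
#' @param col Colour palette (default [grDevices::hcl.colors()] "YlOrRd").
#' @param show_sites Overlay sensor positions (default TRUE).
#' @param ... Passed to [graphics::image()].
#' @export
plot.plantar_map <- function(x, col = grDevices::hcl.colors(64, "YlOrRd",
                                                            rev = TRUE),
                             show_sites = TRUE, ...) {
  graphics::image(x$xs, x$ys, t(x$grid), col = col, asp = 1,
                  xlab = "medio-lateral (mm)", ylab = "heel-toe (mm)",
                  main = sprintf("%s map (%s)%s", x$kind, x$units,
                                 if (is.null(x$phase)) "" else
                                   paste0(" - ", x$phase)), ...)
  if (show_sites)
    graphics::points(x$sites$x_mm, x$sites$y_mm, pch = 21, bg = "white")
  invisible(x)
}

#' Write a plantar map grid as a delimited matrix file
#'
#' @param map A `plantar_map`.
#' @param path Output path (tab-separated matrix, `NA` outside the mask;
#'   row 1 is the heel row).
#' @return `path`, invisibly.
#' @export
write_map_matrix <- function(map, path) {
  stopifnot(inherits(map, "plantar_map"))
  utils::write.table(map$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
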