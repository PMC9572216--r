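#' Parametric foot outline half-width
#'
#' The foot template is a closed outline built from three pieces along the
#' heel-to-toe axis y: a circular heel arc of radius `width/2`, a gently
#' tapering midfoot, and a quarter-ellipse toe cap starting at 72% of foot
#' length. The outline is symmetric about the long axis; `half_width(y)`
#' gives the lateral extent at height y.
#'
#' @keywords internal
foot_half_width <- function(y, foot_length_mm, foot_width_mm) {
  r <- foot_width_mm / 2
  ym <- 0.72 * foot_length_mm        # start of the toe cap
  wm <- 0.95 * r                     # forefoot half-width at the cap base
  hw <- numeric(length(y))
  heel <- y >= 0 & y <= r
  mid <- y > r & y <= ym
  toe <- y > ym & y <= foot_length_mm
  hw[heel] <- sqrt(pmax(0, r^2 - (r - y[heel])^2))
  hw[mid] <- r + (wm - r) * (y[mid] - r) / (ym - r)
  hw[toe] <- wm * sqrt(pmax(0, 1 - ((y[toe] - ym) / (foot_length_mm - ym))^2))
  hw[y < 0 | y > foot_length_mm] <- -Inf   # outside along the long axis
  hw
}

#' Build a rasterized foot template
#'
#' Rasterizes the parametric foot outline onto a regular grid and returns
#' the inside-foot mask. Grid rows run from the heel (row 1) toward the
#' toes; columns run medial to lateral, centred on the long axis. Cell
#' centres are used for the inside test, so the construction is fully
#' deterministic. If a layout is supplied, every sensor must fall inside
#' the outline; an offending sensor is rejected by id.
#'
#' @param layout Optional [sensor_layout()] to validate against the outline.
#' @param foot_length_mm Foot length in mm (default 260).
#' @param foot_width_mm Foot width in mm (default 95).
#' @param resolution_mm Grid cell size in mm (default 1).
#' @return Object of class `foot_template`: list with `xs`, `ys` (cell-centre
#'   coordinates), `mask` (logical matrix, rows = y), `resolution_mm`,
#'   `foot_length_mm`, `foot_width_mm`, and `outline` (polygon data frame).
#' @export
build_template <- function(layout = NULL, foot_length_mm = 260,
                           foot_width_mm = 95, resolution_mm = 1) {
  stopifnot(foot_length_mm > 0, foot_width_mm > 0, resolution_mm > 0)
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "sensor_layout"))
    hw <- foot_half_width(layout$y_mm, foot_length_mm, foot_width_mm)
    out <- which(abs(layout$x_mm) > hw)
    if (length(out))
      stop("sensor(s) outside the foot outline: ",
           paste(layout$id[out], collapse = ", "))
  }
  half_span <- foot_width_mm / 2
  nx <- 2L * ceiling(half_span / resolution_mm)          # even: symmetric grid
  xs <- (seq_len(nx) - (nx + 1) / 2) * resolution_mm     # centred on the axis
  ny <- ceiling(foot_length_mm / resolution_mm)
  ys <- (seq_len(ny) - 0.5) * resolution_mm
  hw <- foot_half_width(ys, foot_length_mm, foot_width_mm)
  mask <- outer(hw, abs(xs), `>=`)                       # [ny, nx]
  yy <- seq(0, foot_length_mm, length.out = 400)
  hwp <- foot_half_width(yy, foot_length_mm, foot_width_mm)
  outline <- data.frame(x = c(hwp, rev(-hwp)), y = c(yy, rev(yy)))
  structure(list(xs = xs, ys = ys, mask = mask,
                 resolution_mm = resolution_mm,
                 foot_length_mm = foot_length_mm,
                 foot_width_mm = foot_width_mm,
                 outline = outline),
            class = "foot_template")
}

#' @export
print.foot_template <- function(x, ...) {
  cat(sprintf("<foot_template> %g x %g mm at %g mm: %d x %d grid, %d cells inside\n",
              x$foot_length_mm, x$foot_width_mm, x$resolution_mm,
              length(x$ys), length(x$xs), sum(x$mask)))
  invisible(x)
}

#' Area of the template outline
#'
#' Shoelace area of the discretized outline polygon, in mm^2. The rasterized
#' mask area (`sum(mask) * resolution^2`) converges to this as the
#' resolution refines.
#'
#' @param template A [foot_template()].
#' @return Area in mm^2.
#' @export
template_outline_area <- function(template) {
  p <- template$outline
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p$x * p$y[i2] - p$x[i2] * p$y)) / 2
}
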