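#' Sensor layout of one insole
#'
#' The layout declares, per channel, its id, kind (`pressure` or
#' `temperature`), foot side and 2-D position in the foot-local frame:
#' origin at the heel centre, +y toward the toes, +x toward the lateral
#' side. A full insole carries 16 pressure and 8 temperature channels; the
#' declared row order *is* the canonical channel order used by the frame
#' codec.
#'
#' The layout shipped with the package
#' (`inst/extdata/sensor_layout_synthetic.csv`) is a synthetic
#' reconstruction of a typical plantar placement — 3 toe, 5 metatarsal,
#' 2 lateral-midfoot, 2 arch and 4 heel pressure sites, and 1 hallux,
#' 3 metatarsal, 1 midfoot and 3 heel temperature sites on a 260 mm foot —
#' not measured coordinates. All map code is driven by the layout file, so
#' users with a physical insole substitute their own.
#'
#' @param layout Data frame with columns `id`, `kind`, `foot`, `x_mm`,
#'   `y_mm`.
#' @return A validated `sensor_layout` data frame.
#' @export
sensor_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  req <- c("id", "kind", "foot", "x_mm", "y_mm")
  if (!all(req %in% names(layout)))
    stop("layout needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(layout$id)) stop("sensor ids must be unique")
  if (!all(layout$kind %in% c("pressure", "temperature")))
    stop("kind must be 'pressure' or 'temperature'")
  if (!all(layout$foot %in% c("L", "R"))) stop("foot must be 'L' or 'R'")
  for (ft in unique(layout$foot)) {
    k <- layout$kind[layout$foot == ft]
    if (sum(k == "pressure") != 16L || sum(k == "temperature") != 8L)
      stop("each foot needs exactly 16 pressure and 8 temperature channels (foot ",
           ft, " has ", paste(k, collapse = "+"), ")")
  }
  class(layout) <- c("sensor_layout", "data.frame")
  layout
}

#' Read a sensor layout file
#'
#' @param path CSV layout file (`id,kind,foot,x_mm,y_mm`). Defaults to the
#'   synthetic layout shipped with the package.
#' @param foot Optionally restrict to one foot side.
#' @return A [sensor_layout()] data frame.
#' @export
read_sensor_layout <- function(path = system.file("extdata",
                                                  "sensor_layout_synthetic.csv",
                                                  package = "insolemetry"),
                               foot = NULL) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(foot)) {
    foot <- match.arg(foot, c("L", "R"))
    if (!any(lay$foot == foot)) {
      # mirror the stored side when the requested one is absent
      lay$x_mm <- -lay$x_mm
      lay$foot <- foot
    } else {
      lay <- lay[lay$foot == foot, , drop = FALSE]
    }
    rownames(lay) <- NULL
  }
  sensor_layout(lay)
}

#' Default synthetic insole layout
#'
#' @param foot `"L"` or `"R"`; the right foot mirrors the stored left-foot
#'   x coordinates.
#' @return A [sensor_layout()] for one foot.
#' @export
default_sensor_layout <- function(foot = "L") {
  read_sensor_layout(foot = foot)
}

#' Mirror a layout to the opposite foot
#'
#' Negates the medio-lateral coordinate and flips the foot tag.
#'
#' @param layout A [sensor_layout()].
#' @return The mirrored [sensor_layout()].
#' @export
mirror_layout <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  layout$x_mm <- -layout$x_mm
  layout$foot <- ifelse(layout$foot == "L", "R", "L")
  layout
}

#' Select the channels of one kind, in canonical order
#' @param layout A [sensor_layout()].
#' @param kind `"pressure"` or `"temperature"`.
#' @return The layout rows of that kind.
#' @export
layout_channels <- function(layout, kind = c("pressure", "temperature")) {
  kind <- match.arg(kind)
  out <- layout[layout$kind == kind, , drop = FALSE]
  rownames(out) <- NULL
  out
}
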