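#' Minimum-convex-polygon range area
#'
#' Convex hull of occurrence points with the enclosed area in km2.  In
#' geodesic mode (default) the area is computed on the WGS84 spheroid
#' (\code{geosphere::areaPolygon}), which keeps published extent-of-
#' occurrence figures projection-honest; planar mode applies the
#' shoelace formula to the raw coordinates (area in squared coordinate
#' units) and exists for abstract/test geometry.  Fewer than three
#' distinct non-collinear points give area 0 with a warning.
#'
#' @param occ data.frame (or matrix) with longitude and latitude in the
#'   first two columns, WGS84 decimal degrees.
#' @param mode \code{"geodesic"} (default) or \code{"planar"}.
#' @return List with \code{areaKm2}, \code{hull} (the hull vertices, in
#'   order) and \code{nPoints}.
#' @examples
#' sq <- data.frame(lon = c(0, 1, 1, 0, 0.5), lat = c(0, 0, 1, 1, 0.5))
#' mcpArea(sq, mode = "planar")$areaKm2  # 1 (planar units)
#' @export
mcpArea <- function(occ, mode = c("geodesic", "planar")) {
  mode <- match.arg(mode)
  xy <- as.matrix(occ[, 1:2])
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) stop("invalid coordinates")
  if (mode == "geodesic" &&
      (any(abs(xy[, 1]) > 180) || any(abs(xy[, 2]) > 90)))
    stop("coordinates outside lon [-180,180] / lat [-90,90]")
  if (nrow(xy) < 1L) stop("at least one occurrence point required")
  uq <- unique(xy)
  degenerate <- function() {
    warning("fewer than 3 non-collinear points: range area is 0")
    list(areaKm2 = 0, hull = uq, nPoints = nrow(xy))
  }
  if (nrow(uq) < 3L) return(degenerate())
  h <- grDevices::chull(uq)
  hull <- uq[h, , drop = FALSE]
  area <- if (mode == "planar") {
    x <- hull[, 1]; y <- hull[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  } else {
    abs(geosphere::areaPolygon(hull)) / 1e6
  }
  if (area == 0) return(degenerate())
  list(areaKm2 = area, hull = hull, nPoints = nrow(xy))
}

#' MCP area in km2
#'
#' Convenience wrapper around [mcpArea()] returning just the geodesic
#' area.
#'
#' @inheritParams mcpArea
#' @return Area in km2.
#' @export
mcpAreaKm2 <- function(occ, mode = c("geodesic", "planar")) {
  mcpArea(occ, mode)$areaKm2
}

#' Degraded-habitat percentage
#'
#' \code{100 * degraded / area}, reported to one decimal as in published
#' conservation assessments.  The ratio is computed exactly before
#' rounding.
#'
#' @param areaKm2 Range area, km2 (> 0).
#' @param degradedKm2 Degraded area within the range, km2 (between 0 and
#'   \code{areaKm2}).
#' @return Percentage rounded to one decimal.
#' @examples
#' degradedPercent(923514, 52604)  # 5.7
#' degradedPercent(390082, 11093)  # 2.8
#' @export
degradedPercent <- function(areaKm2, degradedKm2) {
  if (areaKm2 <= 0) stop("area must be positive")
  if (degradedKm2 < 0 || degradedKm2 > areaKm2)
    stop("degraded area must lie between 0 and the range area")
  round(100 * degradedKm2 / areaKm2, 1)
}

#' Suggest a Red List category
#'
#' Advisory heuristic, not a full IUCN criteria A--E evaluation: Data
#' Deficient when only one locality is known or required inputs are
#' missing; Least Concern when the extent of occurrence is at least
#' 20,000 km2 (the criterion B1 Vulnerable bound) with under 50% habitat
#' degradation; otherwise \code{"review"}, flagging the case for a human
#' decision.
#'
#' @param areaKm2 Extent of occurrence, km2.
#' @param degradedPct Degraded-habitat percentage (optional; missing
#'   counts as missing input).
#' @param nLocalities Number of known localities.
#' @return One of \code{"LC"}, \code{"DD"}, \code{"review"}.
#' @examples
#' redlistSuggest(382451, degradedPct = 5, nLocalities = 30)  # "LC"
#' redlistSuggest(10, nLocalities = 1)                        # "DD"
#' @export
redlistSuggest <- function(areaKm2, degradedPct = NA, nLocalities) {
  if (areaKm2 < 0) stop("area must be non-negative")
  if (nLocalities <= 1 || is.na(areaKm2) || is.na(degradedPct))
    return("DD")
  if (areaKm2 >= 20000 && degradedPct < 50) return("LC")
  "review"
}

#' Range report for one lineage
#'
#' Combines the MCP extent of occurrence, an optional user-supplied
#' degraded-area figure (habitat overlays are external inputs), and the
#' Red List suggestion into one record.
#'
#' @param occ Occurrence data.frame (lon, lat in WGS84).
#' @param degradedKm2 Degraded area within the range, km2 (optional).
#' @return List of class \code{rangeReport}: \code{areaKm2},
#'   \code{degradedKm2}, \code{degradedPct}, \code{nLocalities},
#'   \code{suggestedCategory}, \code{areaMethod}.
#' @export
rangeReport <- function(occ, degradedKm2 = NA) {
  m <- mcpArea(occ)
  pct <- if (!is.na(degradedKm2) && m$areaKm2 > 0)
    degradedPercent(m$areaKm2, degradedKm2) else NA_real_
  structure(list(
    areaKm2 = m$areaKm2,
    degradedKm2 = degradedKm2,
    degradedPct = pct,
    nLocalities = m$nPoints,
    suggestedCategory = redlistSuggest(m$areaKm2, pct, m$nPoints),
    areaMethod = "geodesic polygon area on the WGS84 spheroid"),
    class = "rangeReport")
}

#' @export
print.rangeReport <- function(x, ...) {
  cat(sprintf("Range: %.0f km2 over %d localities", x$areaKm2, x$nLocalities))
  if (!is.na(x$degradedPct))
    cat(sprintf("; %.0f km2 (%.1f%%) degraded", x$degradedKm2, x$degradedPct))
  cat(sprintf("\nSuggested Red List category: %s (advisory)\n",
              x$suggestedCategory))
  invisible(x)
}

#' Read an occurrence table
#'
#' Delimited text with longitude and latitude columns (named
#' \code{lon}/\code{lat} or the first two columns).
#'
#' @param path Path to the file.
#' @return data.frame with columns \code{lon}, \code{lat}.
#' @export
readOccurrences <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (all(c("lon", "lat") %in% names(df))) df[, c("lon", "lat")]
  else stats::setNames(df[, 1:2], c("lon", "lat"))
}
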