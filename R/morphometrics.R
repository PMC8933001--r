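#' Convex-hull area of a 2-D point set
#'
#' Area (µm²) of the convex hull of protrusion-tip coordinates, used to
#' quantify a SOP's protrusion extension. The hull vertices come from
#' [grDevices::chull()] and the area from the shoelace formula; collinear
#' input has area 0.
#'
#' @param points A 2-column matrix or data frame of x/y coordinates (µm),
#'   >= 3 points.
#' @return The hull area in µm².
#' @examples
#' convex_hull_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
convex_hull_area <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("`points` must be a 2-column numeric matrix", call. = FALSE)
  if (nrow(pts) < 3L)
    stop("need >= 3 points for a hull area", call. = FALSE)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) return(0)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Normalise axon lengths to the longest axon in a row
#'
#' Each length is divided by the row maximum, so the longest axon maps to 1
#' and all values lie in (0, 1].
#'
#' @param lengths Positive axon lengths measured in one row.
#' @return Relative lengths in (0, 1].
#' @examples
#' normalize_axon_lengths(c(10, 20, 40))
#' @export
normalize_axon_lengths <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("no lengths supplied", call. = FALSE)
  if (any(!is.finite(lengths) | lengths <= 0))
    stop("all lengths must be finite and > 0", call. = FALSE)
  lengths / max(lengths)
}
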