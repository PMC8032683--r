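#' Displacement between two points, optionally under periodic boundaries
#'
#' Returns the vector from `a` to `b`. When an orthorhombic `box` is supplied,
#' each component is wrapped by the minimum-image convention into
#' `(-L/2, L/2]`, so the displacement points to the nearest periodic image of
#' `b`.
#'
#' @param a,b Numeric length-3 coordinates in nm.
#' @param box Either `NULL` (no periodicity) or a numeric length-3 vector of
#'   positive orthorhombic box lengths in nm.
#' @return A numeric length-3 displacement in nm.
#' @examples
#' displacement(c(0, 0, 0), c(9, 0, 0), box = c(10, 10, 10)) # c(-1, 0, 0)
#' @export
displacement <- function(a, b, box = NULL) {
  d <- as.numeric(b) - as.numeric(a)
  if (is.null(box)) {
    return(d)
  }
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, all(box > 0))
  d <- d - box * round(d / box)
  # round() maps exactly-half components to -L/2; fold them onto +L/2
  low <- d <= -box / 2
  d[low] <- d[low] + box[low]
  d
}

#' Euclidean distance between two points
#'
#' @inheritParams displacement
#' @return Distance in nm (minimum-image distance when `box` is given).
#' @examples
#' grain_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
grain_distance <- function(a, b, box = NULL) {
  sqrt(sum(displacement(a, b, box)^2))
}

#' Angle formed at a vertex
#'
#' The angle between the arms `x - y` and `z - y`, i.e. the angle at the
#' middle point `y` of the ordered triple `(x, y, z)`. For three collinear
#' points with `y` between the ends the angle is pi; the value always lies in
#' `[0, pi]`. The cosine is clamped to `[-1, 1]` before `acos()` so that
#' floating-point round-off never yields `NaN`.
#'
#' @param x,y,z Numeric length-3 coordinates in nm; `y` is the vertex.
#' @inheritParams displacement
#' @return Angle in radians, in `[0, pi]`.
#' @examples
#' angle_at_vertex(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # pi / 2
#' angle_at_vertex(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)) # pi
#' @export
angle_at_vertex <- function(x, y, z, box = NULL) {
  v <- displacement(y, x, box)
  w <- displacement(y, z, box)
  nv <- sqrt(sum(v^2))
  nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) {
    abort("angle_at_vertex(): zero-length arm (coincident points).",
      class = "betagrain_degenerate_geometry"
    )
  }
  cosang <- sum(v * w) / (nv * nw)
  acos(max(-1, min(1, cosang)))
}

# Vectorised minimum-image wrap of an n x 3 displacement matrix.
wrap_min_image <- function(d, box) {
  if (is.null(box)) {
    return(d)
  }
  for (k in 1:3) {
    dk <- d[, k] - box[k] * round(d[, k] / box[k])
    low <- dk <= -box[k] / 2
    dk[low] <- dk[low] + box[k]
    d[, k] <- dk
  }
  d
}
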