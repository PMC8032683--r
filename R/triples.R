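#' Detection parameters for aligned-triple search
#'
#' A triple of grains on pairwise-distinct peptides is *aligned* when both
#' end-to-center distances are at most `epsilon` and the angle at the center
#' grain is at least `alpha * pi`. The defaults, `alpha = 0.89` and
#' `epsilon = 0.7` nm, are the operating point used throughout the package's
#' validations; they correspond to an angle of at least about 160 degrees,
#' i.e. near-collinearity, at the backbone-grain spacings of cross-beta
#' lattices.
#'
#' @param alpha Angular threshold in `[0, 1]`; the condition is
#'   angle >= `alpha * pi`.
#' @param epsilon Distance threshold in nm, > 0.
#' @param use_pbc Apply the minimum-image convention using the frame's box
#'   (off by default; only orthorhombic boxes are supported).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(alpha = 0.89, epsilon = 0.7, use_pbc = FALSE) {
  alpha <- as.numeric(alpha)
  epsilon <- as.numeric(epsilon)
  if (is.na(alpha) || alpha < 0 || alpha > 1) {
    abort("detection_params(): alpha must lie in [0, 1].")
  }
  if (is.na(epsilon) || epsilon <= 0) {
    abort("detection_params(): epsilon must be > 0 (nm).")
  }
  structure(
    list(alpha = alpha, epsilon = epsilon, use_pbc = isTRUE(use_pbc)),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(
    "<detection_params> alpha = %g (angle >= %.2f rad), epsilon = %g nm, pbc = %s\n",
    x$alpha, x$alpha * pi, x$epsilon, x$use_pbc
  ))
  invisible(x)
}

#' Test one triple of grains for alignment
#'
#' Checks the aligned-triple criterion for grains `x`, `y`, `z` with `y` as
#' the center: the three grains lie on pairwise-distinct peptides, both
#' `x`--`y` and `y`--`z` distances are at most `epsilon`, and the angle at
#' `y` is at least `alpha * pi`. Coincident grains (a zero-length arm) are
#' never aligned. Symmetric under swapping `x` and `z`.
#'
#' @param x,y,z One-row data frames (grain rows of a [cg_frame()]), with
#'   `y` the candidate center.
#' @param params A [detection_params()].
#' @param box Box lengths used when `params$use_pbc` is `TRUE`.
#' @return `TRUE` or `FALSE`.
#' @export
is_aligned <- function(x, y, z, params = detection_params(), box = NULL) {
  peps <- c(x$peptide_id, y$peptide_id, z$peptide_id)
  if (anyDuplicated(peps)) {
    return(FALSE)
  }
  b <- if (params$use_pbc) box else NULL
  px <- c(x$x, x$y, x$z)
  py <- c(y$x, y$y, y$z)
  pz <- c(z$x, z$y, z$z)
  if (grain_distance(px, py, b) > params$epsilon) return(FALSE)
  if (grain_distance(py, pz, b) > params$epsilon) return(FALSE)
  ang <- tryCatch(
    angle_at_vertex(px, py, pz, b),
    betagrain_degenerate_geometry = function(e) NA_real_
  )
  !is.na(ang) && ang >= params$alpha * pi
}

#' Epsilon-neighborhoods on other peptides
#'
#' For every grain, the set of grains lying on a *different* peptide within
#' `epsilon`. Built with a uniform spatial grid of cell size `epsilon`
#' (cell lists), which returns exactly the brute-force epsilon-neighborhood;
#' the grid only prunes candidates. With `use_pbc`, minimum-image distances
#' in the frame's orthorhombic box are used instead.
#'
#' @param frame A [cg_frame()].
#' @param epsilon Cutoff distance in nm.
#' @param use_pbc Use the minimum-image convention with the frame's box.
#' @return A list, named by `grain_id`, of integer vectors of neighbor
#'   `grain_id`s (sorted).
#' @export
neighbor_candidates <- function(frame, epsilon, use_pbc = FALSE) {
  n <- nrow(frame)
  gid <- frame$grain_id
  out <- setNames(rep(list(integer()), n), as.character(gid))
  if (n < 2L) return(out)
  pairs <- neighbor_pairs(frame, epsilon, use_pbc)
  if (nrow(pairs) == 0L) return(out)
  # symmetrise (pairs are stored once with i < j)
  from <- c(pairs$i, pairs$j)
  to <- c(pairs$j, pairs$i)
  sets <- split(gid[to], from)
  out[as.character(gid[as.integer(names(sets))])] <-
    lapply(sets, function(v) sort(as.integer(v)))
  out
}

# Row-index pairs (i < j) on different peptides within epsilon.
neighbor_pairs <- function(frame, epsilon, use_pbc = FALSE) {
  n <- nrow(frame)
  coords <- frame_coords(frame)
  pep <- frame$peptide_id
  box <- if (use_pbc) frame_box(frame) else NULL
  if (!is.null(box)) {
    # exact O(n^2) scan with minimum-image distances
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L, from = 2:n)
    d <- wrap_min_image(coords[j, , drop = FALSE] - coords[i, , drop = FALSE], box)
    keep <- rowSums(d^2) <= epsilon^2 & pep[i] != pep[j]
    return(tibble(i = i[keep], j = j[keep]))
  }
  # cell list: grains binned into cubes of side epsilon; neighbors can only
  # sit in the 27 surrounding cells
  cell <- floor(sweep(coords, 2, rep(epsilon, 3), "/"))
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cells <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  acc_i <- list()
  acc_j <- list()
  for (o in seq_len(nrow(offsets))) {
    shifted <- sweep(cell, 2, offsets[o, ], "+")
    tkey <- paste(shifted[, 1], shifted[, 2], shifted[, 3], sep = ",")
    hits <- cells[tkey]
    len <- lengths(hits)
    if (all(len == 0L)) next
    ii <- rep(seq_len(n), len)
    jj <- unlist(hits, use.names = FALSE)
    keep <- ii < jj
    acc_i[[o]] <- ii[keep]
    acc_j[[o]] <- jj[keep]
  }
  i <- unlist(acc_i, use.names = FALSE)
  j <- unlist(acc_j, use.names = FALSE)
  if (length(i) == 0L) return(tibble(i = integer(), j = integer()))
  d2 <- rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2)
  keep <- d2 <= epsilon^2 & pep[i] != pep[j]
  tibble(i = i[keep], j = j[keep])
}

#' Find all aligned triples in a frame
#'
#' Enumerates every triple of grains on pairwise-distinct peptides whose
#' end-to-center distances are both at most `epsilon` and whose angle at the
#' center is at least `alpha * pi`. Each geometric alignment is reported
#' once, in canonical form with `end_a < end_b` (the criterion is symmetric
#' in the two ends). The neighbor grid only restricts the candidate set, so
#' the result is identical to naive enumeration over all ordered triples.
#'
#' @param frame A [cg_frame()].
#' @param params A [detection_params()].
#' @return A tibble with integer columns `end_a`, `center`, `end_b`
#'   (grain ids, `end_a < end_b`), ordered by (`center`, `end_a`, `end_b`).
#' @examples
#' frame <- make_parallel_sheet(sheet_spec(n_strands = 3, strand_len = 1))
#' find_aligned_triples(frame)
#' @export
find_aligned_triples <- function(frame, params = detection_params()) {
  empty <- tibble(end_a = integer(), center = integer(), end_b = integer())
  n <- nrow(frame)
  if (n < 3L) return(empty)
  coords <- frame_coords(frame)
  pep <- frame$peptide_id
  gid <- frame$grain_id
  box <- if (params$use_pbc) frame_box(frame) else NULL

  pairs <- neighbor_pairs(frame, params$epsilon, params$use_pbc)
  if (nrow(pairs) == 0L) return(empty)
  from <- c(pairs$i, pairs$j)
  to <- c(pairs$j, pairs$i)
  nb <- split(to, from)

  # expand, per center, all unordered pairs of its neighbors
  centers <- as.integer(names(nb))
  cand <- lapply(seq_along(nb), function(k) {
    v <- nb[[k]]
    if (length(v) < 2L) return(NULL)
    pr <- utils::combn(sort(v), 2L)
    cbind(centers[k], pr[1, ], pr[2, ])
  })
  cand <- do.call(rbind, cand)
  if (is.null(cand)) return(empty)
  ci <- cand[, 1]; ai <- cand[, 2]; bi <- cand[, 3]
  keep <- pep[ai] != pep[bi]
  ci <- ci[keep]; ai <- ai[keep]; bi <- bi[keep]
  if (length(ci) == 0L) return(empty)

  v <- coords[ai, , drop = FALSE] - coords[ci, , drop = FALSE]
  w <- coords[bi, , drop = FALSE] - coords[ci, , drop = FALSE]
  if (!is.null(box)) {
    v <- wrap_min_image(v, box)
    w <- wrap_min_image(w, box)
  }
  nv <- sqrt(rowSums(v^2))
  nw <- sqrt(rowSums(w^2))
  ok <- nv > 0 & nw > 0
  cosang <- rep(NA_real_, length(ci))
  cosang[ok] <- rowSums(v[ok, , drop = FALSE] * w[ok, , drop = FALSE]) /
    (nv[ok] * nw[ok])
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang)
  keep <- ok & ang >= params$alpha * pi
  ci <- ci[keep]; ai <- ai[keep]; bi <- bi[keep]

  out <- tibble(
    end_a = as.integer(pmin(gid[ai], gid[bi])),
    center = as.integer(gid[ci]),
    end_b = as.integer(pmax(gid[ai], gid[bi]))
  )
  arrange(distinct(out), .data$center, .data$end_a, .data$end_b)
}
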