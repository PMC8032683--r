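#' Construct a coarse-grained frame
#'
#' A frame is a tibble with one row per backbone grain and the columns
#' `grain_id`, `peptide_id`, `residue_index` (all 0-based integers),
#' `residue_name`, `atom_name` (character) and `x`, `y`, `z` (nm). The
#' orthorhombic box lengths, title and frame index travel as attributes.
#'
#' @param grains A data frame with the columns listed above.
#' @param box `NULL` or numeric length-3 box lengths in nm (zeros mean
#'   "no box").
#' @param title Title string of the frame (first line of a .gro block).
#' @param frame_index 0-based position of the frame in its trajectory.
#' @return A tibble of class `cg_frame`.
#' @export
cg_frame <- function(grains, box = NULL, title = "betagrain frame",
                     frame_index = 0L) {
  grains <- as_tibble(grains)
  needed <- c(
    "grain_id", "peptide_id", "residue_index", "residue_name",
    "atom_name", "x", "y", "z"
  )
  missing <- setdiff(needed, names(grains))
  if (length(missing) > 0) {
    abort(paste0(
      "cg_frame(): missing grain columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  coords <- as.matrix(grains[, c("x", "y", "z")])
  if (nrow(grains) > 0 && !all(is.finite(coords))) {
    abort("cg_frame(): non-finite grain coordinates.")
  }
  if (anyDuplicated(grains$grain_id)) {
    abort("cg_frame(): grain_id values must be unique within a frame.")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3L)
    if (all(box == 0)) box <- NULL
  }
  structure(grains,
    box = box, title = title, frame_index = as.integer(frame_index),
    class = c("cg_frame", class(tibble())))
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf(
    "<cg_frame> %d grains, %d peptides%s\n", nrow(x),
    dplyr::n_distinct(x$peptide_id),
    if (is.null(frame_box(x))) "" else {
      sprintf(", box %.3f x %.3f x %.3f nm",
        frame_box(x)[1], frame_box(x)[2], frame_box(x)[3])
    }
  ))
  NextMethod()
}

#' Frame accessors
#'
#' @param frame A [cg_frame()].
#' @return `frame_box()` gives the box lengths (or `NULL`), `frame_title()`
#'   the title string, `frame_coords()` the n x 3 coordinate matrix in nm.
#' @export
frame_box <- function(frame) attr(frame, "box", exact = TRUE)

#' @rdname frame_box
#' @export
frame_title <- function(frame) {
  attr(frame, "title", exact = TRUE) %||% "betagrain frame"
}

#' @rdname frame_box
#' @export
frame_coords <- function(frame) {
  m <- as.matrix(frame[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Construct a trajectory from frames
#'
#' A trajectory is an ordered list of frames sharing one layout, plus the
#' group length GL (residues per peptide) used to partition grains into
#' peptides.
#'
#' @param frames List of [cg_frame()] objects with identical grain counts.
#' @param group_length Integer GL >= 1.
#' @return An object of class `cg_trajectory` (a list of frames).
#' @export
cg_trajectory <- function(frames, group_length) {
  group_length <- as.integer(group_length)
  stopifnot(length(frames) >= 1L, group_length >= 1L)
  counts <- vapply(frames, nrow, integer(1))
  if (length(unique(counts)) > 1L) {
    abort(paste0(
      "cg_trajectory(): frames differ in grain count: ",
      paste(unique(counts), collapse = ", ")
    ), class = "betagrain_format_error")
  }
  structure(frames, group_length = group_length, class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d frame(s) x %d grains, GL = %d\n",
    length(x), nrow(x[[1]]), attr(x, "group_length")
  ))
  invisible(x)
}

#' @export
as_tibble.cg_trajectory <- function(x, ...) {
  bind_rows(lapply(seq_along(x), function(i) {
    mutate(as_tibble(as.data.frame(x[[i]])), frame_index = i - 1L,
      .before = 1L)
  }))
}

#' @rdname frame_box
#' @param traj A [cg_trajectory()].
#' @export
trajectory_group_length <- function(traj) attr(traj, "group_length", exact = TRUE)
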