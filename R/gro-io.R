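#' Read a Gromos87 (.gro) structure or multi-frame trajectory
#'
#' Reads one or more concatenated Gromos87 blocks (the dialect GROMACS
#' `trjconv` emits for multi-frame .gro output) into a [cg_trajectory()].
#' Atom lines are parsed by fixed columns, never by whitespace; velocity
#' columns, if present, are ignored. Coordinates are taken as nm.
#'
#' Residues are enumerated in order of first appearance: a new residue starts
#' whenever the (residue number, residue name) pair changes between
#' consecutive atom lines. The file's residue numbers are used only to detect
#' these boundaries because Gromos87 numbers wrap at five digits. The k-th
#' residue of a frame (0-based) then belongs to peptide `k %/% GL` at
#' position `k %% GL`.
#'
#' Only orthorhombic boxes are interpreted: the first three numbers of the
#' box line. Extra (triclinic) fields are read but ignored with a warning.
#'
#' @param source Path to a .gro file, or a character vector of its lines.
#' @param group_length Integer GL >= 1: number of residues per peptide.
#' @return A [cg_trajectory()].
#' @examples
#' frame <- make_parallel_sheet(sheet_spec(n_strands = 3, strand_len = 4))
#' path <- tempfile(fileext = ".gro")
#' write_gro(frame, path)
#' traj <- read_gro(path, group_length = 4)
#' length(traj)
#' @export
read_gro <- function(source, group_length) {
  group_length <- as.integer(group_length)
  if (is.na(group_length) || group_length < 1L) {
    abort("read_gro(): group_length must be an integer >= 1.")
  }
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  # drop trailing blank lines (editors often add one)
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) < 3L) {
    abort("read_gro(): input too short to contain a Gromos87 block.",
      class = "betagrain_format_error")
  }

  frames <- list()
  idx <- 1L
  while (idx <= length(lines)) {
    title <- lines[idx]
    if (idx + 1L > length(lines)) {
      abort(sprintf("read_gro(): truncated block at line %d.", idx),
        class = "betagrain_format_error")
    }
    n_atoms <- suppressWarnings(as.integer(trimws(lines[idx + 1L])))
    if (is.na(n_atoms) || n_atoms < 0L) {
      abort(sprintf(
        "read_gro(): line %d: expected an atom count, got '%s'.",
        idx + 1L, lines[idx + 1L]
      ), class = "betagrain_format_error")
    }
    body_start <- idx + 2L
    body_end <- body_start + n_atoms - 1L
    if (body_end + 1L > length(lines)) {
      abort(sprintf(
        "read_gro(): block starting at line %d declares %d atoms but the file ends early.",
        idx, n_atoms
      ), class = "betagrain_format_error")
    }
    body <- if (n_atoms > 0) lines[body_start:body_end] else character()
    frames[[length(frames) + 1L]] <- parse_gro_block(
      title, body, lines[body_end + 1L],
      first_line = body_start, frame_index = length(frames)
    )
    idx <- body_end + 2L
  }

  frames <- lapply(frames, assign_peptides, group_length = group_length)
  cg_trajectory(frames, group_length)
}

parse_gro_block <- function(title, body, box_line, first_line, frame_index) {
  n <- length(body)
  if (n > 0) {
    bad <- which(nchar(body) < 44L)
    if (length(bad) > 0) {
      abort(sprintf(
        "read_gro(): line %d: atom line shorter than the 44 fixed columns.",
        first_line + bad[1] - 1L
      ), class = "betagrain_parse_error")
    }
  }
  res_num_raw <- substr(body, 1L, 5L)
  res_name <- trimws(substr(body, 6L, 10L))
  atom_name <- trimws(substr(body, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(body, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(body, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(body, 37L, 44L)))
  res_num <- suppressWarnings(as.integer(res_num_raw))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(res_num))
  if (length(bad) > 0) {
    abort(sprintf(
      "read_gro(): line %d: malformed fixed-column atom line '%s'.",
      first_line + bad[1] - 1L, body[bad[1]]
    ), class = "betagrain_parse_error")
  }

  box_fields <- suppressWarnings(as.numeric(strsplit(trimws(box_line), "\\s+")[[1]]))
  if (length(box_fields) < 3L || any(is.na(box_fields[1:3]))) {
    abort(sprintf(
      "read_gro(): line %d: malformed box line '%s'.",
      first_line + n, box_line
    ), class = "betagrain_parse_error")
  }
  if (length(box_fields) > 3L && any(box_fields[-(1:3)] != 0)) {
    warn("read_gro(): triclinic box fields present; only the three orthorhombic lengths are used.")
  }
  box <- box_fields[1:3]

  # residue boundary = change of (residue number, residue name) between
  # consecutive atom lines; absolute numbers are unreliable (5-digit wrap)
  if (n > 0) {
    key <- paste(res_num, res_name, sep = "\r")
    new_res <- c(TRUE, key[-1] != key[-n])
    res_ordinal <- cumsum(new_res) - 1L
  } else {
    res_ordinal <- integer()
  }

  grains <- tibble(
    grain_id = seq_len(n) - 1L,
    peptide_id = 0L, # assigned once GL is known
    residue_index = res_ordinal, # residue ordinal for now
    residue_name = res_name,
    atom_name = atom_name,
    x = x, y = y, z = z
  )
  cg_frame(grains, box = box, title = title, frame_index = frame_index)
}

# Convert per-frame residue ordinals (stored in residue_index by the block
# parser) into the peptide_id / residue_index partition implied by GL.
assign_peptides <- function(frame, group_length) {
  if (nrow(frame) == 0) return(frame)
  res_ordinal <- frame$residue_index
  n_res <- max(res_ordinal) + 1L
  rem <- n_res %% group_length
  if (rem != 0L) {
    abort(sprintf(
      "read_gro(): %d residues are not an exact multiple of GL = %d (remainder %d).",
      n_res, group_length, rem
    ), class = "betagrain_grouping_error")
  }
  frame$peptide_id <- res_ordinal %/% group_length
  frame$residue_index <- res_ordinal %% group_length
  frame
}

#' Write a frame as a Gromos87 (.gro) block
#'
#' Emits the title line, the atom count, fixed-column atom lines
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`) and the box line. Residue and atom
#' numbers wrap modulo 100000 (the Gromos87 five-column convention), so
#' frames with more than 99999 atoms are written with wrapped serials.
#' Positions are quantised to 0.001 nm by the `%8.3f` fields; [read_gro()]
#' round-trips the result to within that quantisation.
#'
#' @param frame A [cg_frame()].
#' @param sink Output path, or a connection.
#' @param append Append to an existing file (used to build multi-frame
#'   trajectories by concatenation).
#' @return `sink`, invisibly.
#' @export
write_gro <- function(frame, sink, append = FALSE) {
  stopifnot(inherits(frame, "cg_frame") || is.data.frame(frame))
  n <- nrow(frame)
  # residue serials: one per distinct (peptide, residue) in file order
  res_key <- paste(frame$peptide_id, frame$residue_index, sep = "\r")
  new_res <- if (n > 0) c(TRUE, res_key[-1] != res_key[-n]) else logical()
  res_serial <- (cumsum(new_res) - 1L) %% 100000L + 1L
  atom_serial <- (seq_len(n) - 1L) %% 100000L + 1L

  lines <- c(
    frame_title(frame),
    sprintf("%5d", n),
    if (n > 0) {
      sprintf(
        "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
        res_serial, substr(frame$residue_name, 1L, 5L),
        substr(frame$atom_name, 1L, 5L), atom_serial,
        frame$x, frame$y, frame$z
      )
    },
    {
      box <- frame_box(frame) %||% c(0, 0, 0)
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
    }
  )
  if (inherits(sink, "connection")) {
    writeLines(lines, sink)
  } else {
    cat(paste0(lines, "\n", collapse = ""), file = sink, append = append)
  }
  invisible(sink)
}

#' Keep only backbone grains
#'
#' Restricts a frame to grains whose atom name matches (default `"BB"`, the
#' MARTINI backbone bead), for inputs that also carry side-chain beads.
#' Grain ids are reassigned compactly; the peptide and residue assignment of
#' the surviving grains is preserved (side-chain beads share their residue's
#' assignment, so dropping them leaves the partition intact).
#'
#' @param frame A [cg_frame()].
#' @param atom_name Atom name to keep.
#' @return A [cg_frame()] containing only the matching grains.
#' @export
filter_backbone <- function(frame, atom_name = "BB") {
  keep <- frame$atom_name == atom_name
  if (!any(keep)) {
    abort(sprintf(
      "filter_backbone(): no grains named '%s'; pass the backbone atom name used in your file.",
      atom_name
    ), class = "betagrain_format_error")
  }
  out <- frame[keep, , drop = FALSE]
  out$grain_id <- seq_len(nrow(out)) - 1L
  cg_frame(out,
    box = frame_box(frame), title = frame_title(frame),
    frame_index = attr(frame, "frame_index") %||% 0L
  )
}
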