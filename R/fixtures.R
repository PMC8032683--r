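#' Specification of an ideal (optionally jittered) beta-sheet lattice
#'
#' Describes a rectangular lattice of backbone grains: `n_strands` peptides
#' (one per lattice row) of `strand_len` residues each. The default
#' inter-strand spacing, 0.48 nm, matches the backbone-to-backbone distance
#' across hydrogen-bonded beta-strands; the default intra-strand spacing of
#' 0.55 nm is chosen so that lattice diagonals
#' (`sqrt(0.48^2 + 0.55^2) ~ 0.73` nm) stay outside the default 0.7 nm
#' cutoff, which keeps the fixture's ground truth in closed form: an
#' `S x L` lattice has exactly `L * (S - 2)` aligned triples and `L`
#' components at the default thresholds. Gaussian positional jitter emulates
#' the distorted lattices that coarse-grained self-assembly simulations
#' produce.
#'
#' @param n_strands Number of strands (peptides), >= 1.
#' @param strand_len Residues per strand (the group length), >= 1.
#' @param inter_strand,intra_strand Lattice spacings in nm.
#' @param jitter Standard deviation (nm) of isotropic Gaussian noise added
#'   to every coordinate; 0 for an ideal lattice.
#' @param seed Integer seed for the jitter (generators are pure functions of
#'   their spec).
#' @param residue_names Character vector cycled along each strand.
#' @return A list of class `sheet_spec`.
#' @export
sheet_spec <- function(n_strands, strand_len, inter_strand = 0.48,
                       intra_strand = 0.55, jitter = 0, seed = 1L,
                       residue_names = "ALA") {
  stopifnot(
    n_strands >= 1, strand_len >= 1, inter_strand > 0, intra_strand > 0,
    jitter >= 0, length(residue_names) >= 1
  )
  structure(
    list(
      n_strands = as.integer(n_strands), strand_len = as.integer(strand_len),
      inter_strand = inter_strand, intra_strand = intra_strand,
      jitter = jitter, seed = as.integer(seed),
      residue_names = as.character(residue_names)
    ),
    class = "sheet_spec"
  )
}

#' Generate an ideal parallel beta-sheet frame
#'
#' Grain `(s, i)` (strand `s`, residue `i`, both 0-based) sits at
#' `(inter_strand * s, intra_strand * i, 0)` plus seeded Gaussian jitter.
#' Strand `s` is peptide `s`; the group length equals `strand_len`.
#'
#' @param spec A [sheet_spec()].
#' @return A [cg_frame()] with `n_strands * strand_len` grains.
#' @examples
#' frame <- make_parallel_sheet(sheet_spec(n_strands = 12, strand_len = 32))
#' nrow(frame) # 384
#' @export
make_parallel_sheet <- function(spec) {
  stopifnot(inherits(spec, "sheet_spec"))
  s <- rep(seq_len(spec$n_strands) - 1L, each = spec$strand_len)
  i <- rep(seq_len(spec$strand_len) - 1L, times = spec$n_strands)
  n <- length(s)
  pos <- cbind(spec$inter_strand * s, spec$intra_strand * i, 0)
  if (spec$jitter > 0) {
    pos <- pos + withr::with_seed(
      spec$seed,
      matrix(rnorm(3L * n, sd = spec$jitter), ncol = 3L)
    )
  }
  names_cycle <- rep_len(spec$residue_names, spec$strand_len)
  cg_frame(
    tibble(
      grain_id = seq_len(n) - 1L,
      peptide_id = s,
      residue_index = i,
      residue_name = rep(names_cycle, times = spec$n_strands),
      atom_name = "BB",
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    ),
    title = sprintf(
      "ideal parallel sheet %d x %d", spec$n_strands, spec$strand_len
    )
  )
}

#' Generate an ideal antiparallel beta-sheet frame
#'
#' Identical grain positions to [make_parallel_sheet()]; strand direction
#' alternates, encoded only in the residue ordering (residue indices and
#' names run backwards on odd strands). Because detection uses positions
#' only, its results equal the parallel case -- itself a documented property
#' of the method.
#'
#' @inheritParams make_parallel_sheet
#' @return A [cg_frame()].
#' @export
make_antiparallel_sheet <- function(spec) {
  frame <- make_parallel_sheet(spec)
  odd <- frame$peptide_id %% 2L == 1L
  L <- spec$strand_len
  frame$residue_index[odd] <- L - 1L - frame$residue_index[odd]
  names_cycle <- rep_len(spec$residue_names, L)
  frame$residue_name <- names_cycle[frame$residue_index + 1L]
  attr(frame, "title") <- sprintf(
    "ideal antiparallel sheet %d x %d", spec$n_strands, spec$strand_len
  )
  frame
}

#' Generate an ideal single-peptide helix
#'
#' One peptide with grains on an ideal helix; a negative control for the
#' distinct-peptide constraint of triple detection (a single peptide can
#' never produce an aligned triple).
#'
#' @param n_residues Number of grains, >= 1.
#' @param rise Rise per residue along the axis, nm.
#' @param radius Helix radius, nm.
#' @param turn Rotation per residue, radians (default 100 degrees).
#' @param origin Offset added to all coordinates, nm.
#' @return A [cg_frame()] with one peptide.
#' @export
make_helix <- function(n_residues, rise = 0.15, radius = 0.23,
                       turn = 100 * pi / 180, origin = c(0, 0, 0)) {
  stopifnot(n_residues >= 1)
  i <- seq_len(n_residues) - 1L
  cg_frame(
    tibble(
      grain_id = i,
      peptide_id = 0L,
      residue_index = i,
      residue_name = "ALA",
      atom_name = "BB",
      x = origin[1] + radius * cos(i * turn),
      y = origin[2] + radius * sin(i * turn),
      z = origin[3] + rise * i
    ),
    title = sprintf("ideal helix n = %d", n_residues)
  )
}

#' Generate random-coil peptides in a box
#'
#' Each peptide is a seeded random walk with a fixed step length (default
#' 0.35 nm, the MARTINI backbone bond length) starting at a uniformly random
#' position in a cubic box. Deterministic given the seed.
#'
#' @param n_peptides Number of peptides.
#' @param gl Residues per peptide (group length).
#' @param box Cubic box edge, nm (> 0).
#' @param seed Integer seed.
#' @param step Walk step length, nm.
#' @return A [cg_frame()] with box attribute `c(box, box, box)`.
#' @export
make_random_coil <- function(n_peptides, gl, box, seed = 1L, step = 0.35) {
  stopifnot(n_peptides >= 1, gl >= 1, box > 0)
  pos <- withr::with_seed(as.integer(seed), {
    out <- matrix(0, nrow = n_peptides * gl, ncol = 3L)
    row <- 1L
    for (p in seq_len(n_peptides)) {
      at <- runif(3L, 0, box)
      for (i in seq_len(gl)) {
        out[row, ] <- at
        row <- row + 1L
        d <- rnorm(3L)
        at <- at + step * d / sqrt(sum(d^2))
      }
    }
    out
  })
  cg_frame(
    tibble(
      grain_id = seq_len(n_peptides * gl) - 1L,
      peptide_id = rep(seq_len(n_peptides) - 1L, each = gl),
      residue_index = rep(seq_len(gl) - 1L, times = n_peptides),
      residue_name = "ALA",
      atom_name = "BB",
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    ),
    box = c(box, box, box),
    title = sprintf("random coil %d x %d", n_peptides, gl)
  )
}

#' Apply a rigid transform to a frame
#'
#' Rotates and translates every grain position; useful for invariance
#' checks, since detection depends only on relative geometry.
#'
#' @param frame A [cg_frame()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Numeric length-3 offset in nm.
#' @return The transformed [cg_frame()].
#' @export
transform_frame <- function(frame, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  pos <- frame_coords(frame) %*% t(rotation)
  frame$x <- pos[, 1] + translation[1]
  frame$y <- pos[, 2] + translation[2]
  frame$z <- pos[, 3] + translation[3]
  frame
}

#' A uniformly random rotation matrix
#'
#' @param seed Integer seed.
#' @return A 3 x 3 rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    m <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    q <- q %*% diag(sign(diag(qr.R(qr_))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
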