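#' Coarse-grain a PDB protein to one backbone bead per residue
#'
#' Maps an all-atom or united-atom PDB structure to MARTINI-style backbone
#' grains: for each standard residue, one grain named `"BB"` is placed at
#' the unweighted centroid of its N, CA, C and O atoms (missing members are
#' skipped; a residue with none of them is dropped). With `ca_only` the
#' grain sits on CA instead. Angstrom coordinates are converted to nm.
#'
#' The exact backbone mapping used by MARTINI tooling varies; the centroid
#' of the four backbone atoms is this package's deterministic stand-in for
#' the backbone center of mass and is close to it for standard residues.
#'
#' Peptide ids are assigned per PDB chain in order of first appearance
#' (0-based); residue index is the 0-based position within the chain. The
#' group length is therefore not used for mapped frames -- chains define the
#' peptides explicitly.
#'
#' Altloc handling keeps the highest-occupancy location of each atom (ties:
#' first in file). HETATM residues are skipped unless their residue name is
#' in `keep_hetatm` (e.g. `"BTN"` for biotinylated termini).
#'
#' @param pdb_source Path to a PDB file.
#' @param model 1-based model number (for multi-model NMR files).
#' @param ca_only Place beads on CA atoms instead of backbone centroids.
#' @param keep_hetatm Character vector of HETATM residue names to map too.
#' @return A [cg_frame()] with one grain per mapped residue.
#' @export
map_backbone <- function(pdb_source, model = 1L, ca_only = FALSE,
                         keep_hetatm = character()) {
  pdb <- bio3d::read.pdb(pdb_source, multi = TRUE, rm.alt = FALSE,
    verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  model <- as.integer(model)
  if (model < 1L || model > n_models) {
    abort(sprintf(
      "map_backbone(): model %d requested but the file has %d model(s).",
      model, n_models
    ), class = "betagrain_index_error")
  }
  coords <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  atoms <- as_tibble(pdb$atom[, c(
    "type", "elety", "alt", "resid", "chain", "resno", "insert", "o"
  )])
  atoms$x <- coords[, 1]
  atoms$y <- coords[, 2]
  atoms$z <- coords[, 3]
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  atoms <- filter(
    atoms,
    .data$type == "ATOM" | .data$resid %in% keep_hetatm
  )
  backbone <- if (ca_only) "CA" else c("N", "CA", "C", "O")
  atoms <- filter(atoms, .data$elety %in% backbone)
  if (nrow(atoms) == 0L) {
    abort("map_backbone(): no protein backbone atoms found.",
      class = "betagrain_empty_structure")
  }

  # highest-occupancy altloc per atom position (ties: first in file)
  atoms <- atoms |>
    mutate(.file_order = row_number()) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    arrange(desc(.data$o), .data$.file_order, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$.file_order)

  # residues in file order of first appearance
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  res_ordinal <- as.integer(factor(res_key, levels = unique(res_key)))

  beads <- atoms |>
    mutate(.res = res_ordinal) |>
    group_by(.data$.res) |>
    summarise(
      chain = .data$chain[1],
      residue_name = .data$resid[1],
      x = mean(.data$x) / 10,
      y = mean(.data$y) / 10,
      z = mean(.data$z) / 10,
      .groups = "drop"
    ) |>
    arrange(.data$.res)

  chain_levels <- unique(beads$chain)
  peptide_id <- as.integer(factor(beads$chain, levels = chain_levels)) - 1L
  residue_index <- stats::ave(
    seq_len(nrow(beads)), peptide_id,
    FUN = function(ix) seq_along(ix) - 1L
  )

  cg_frame(
    tibble(
      grain_id = seq_len(nrow(beads)) - 1L,
      peptide_id = peptide_id,
      residue_index = as.integer(residue_index),
      residue_name = beads$residue_name,
      atom_name = "BB",
      x = beads$x, y = beads$y, z = beads$z
    ),
    title = sprintf(
      "backbone-mapped %s (model %d)", basename(as.character(pdb_source)),
      model
    )
  )
}

#' Write a synthetic cross-beta fibril as a PDB file
#'
#' Generates an idealised parallel in-register amyloid-like fibril --
#' `n_chains` extended beta-strands stacked 4.8 Angstrom apart along the
#' fibril axis, each of `n_residues` residues with backbone atoms N, CA, C,
#' O -- and writes it as a multi-chain PDB. This is a *synthetic* stand-in
#' with the cross-beta geometry of deposited amyloid fibril structures
#' (e.g. a 12-chain, 32-residue-per-chain beta-amyloid fibril), intended for
#' validating the mapping + detection pipeline without external downloads.
#'
#' @param path Output PDB path.
#' @param n_chains Number of strands (PDB chains A, B, ...).
#' @param n_residues Residues per chain.
#' @param n_models Number of MODEL blocks (additional models are rigidly
#'   shifted copies, for exercising model selection).
#' @return `path`, invisibly.
#' @export
write_synthetic_fibril_pdb <- function(path, n_chains = 12L,
                                       n_residues = 32L, n_models = 1L) {
  stopifnot(n_chains >= 1, n_chains <= 26, n_residues >= 1, n_models >= 1)
  res_cycle <- c("VAL", "PHE", "ALA", "GLY")
  lines <- c(
    "HEADER    SYNTHETIC CROSS-BETA FIBRIL (GENERATED, NOT A DEPOSITED STRUCTURE)",
    "TITLE     IDEALISED PARALLEL IN-REGISTER FIBRIL FOR PIPELINE VALIDATION"
  )
  for (m in seq_len(n_models)) {
    if (n_models > 1L) lines <- c(lines, sprintf("MODEL     %4d", m))
    shift <- (m - 1L) * c(1, 1, 1) # Angstrom offset between models
    serial <- 1L
    for (ch in seq_len(n_chains)) {
      for (i in seq_len(n_residues)) {
        x0 <- 3.5 * (i - 1L)
        z0 <- 4.8 * (ch - 1L)
        atoms <- rbind(
          c(x0 - 1.2, 0.5, z0), # N
          c(x0, 0.0, z0), # CA
          c(x0 + 1.2, -0.5, z0), # C
          c(x0 + 1.2, -1.7, z0) # O
        )
        names_ <- c("N", "CA", "C", "O")
        for (k in 1:4) {
          lines <- c(lines, sprintf(
            "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, sprintf(" %-3s", names_[k]),
            res_cycle[(i - 1L) %% length(res_cycle) + 1L],
            LETTERS[ch], i,
            atoms[k, 1] + shift[1], atoms[k, 2] + shift[2],
            atoms[k, 3] + shift[3], 1.00, 0.00
          ))
          serial <- serial + 1L
        }
      }
      lines <- c(lines, sprintf("TER   %5d", serial))
      serial <- serial + 1L
    }
    if (n_models > 1L) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
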