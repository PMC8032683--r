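gro_block <- function(title, atom_lines, box = "   0.00000   0.00000   0.00000") {
  c(title, sprintf("%5d", length(atom_lines)), atom_lines, box)
}

atom_line <- function(resnum, resname, atomname, atomnum, x, y, z, vel = "") {
  paste0(
    sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resnum, resname, atomname, atomnum,
      x, y, z
    ),
    vel
  )
}

test_that("a minimal two-residue block parses into one peptide", {
  lines <- gro_block("two residues", c(
    atom_line(1, "ALA", "BB", 1, 0.1, 0.2, 0.3),
    atom_line(2, "GLY", "BB", 2, 0.4, 0.5, 0.6)
  ))
  traj <- read_gro(lines, group_length = 2)
  expect_length(traj, 1L)
  f <- traj[[1]]
  expect_equal(nrow(f), 2L)
  expect_equal(f$peptide_id, c(0L, 0L))
  expect_equal(f$residue_index, c(0L, 1L))
  expect_equal(f$residue_name, c("ALA", "GLY"))
  expect_equal(f$x, c(0.1, 0.4))
  expect_equal(trajectory_group_length(traj), 2L)
})

test_that("concatenated blocks become ordered frames with equal layout", {
  block <- gro_block("t", c(
    atom_line(1, "ALA", "BB", 1, 0.1, 0.2, 0.3),
    atom_line(2, "GLY", "BB", 2, 0.4, 0.5, 0.6)
  ))
  traj <- read_gro(c(block, block), group_length = 2)
  expect_length(traj, 2L)
  expect_identical(lapply(traj[[1]], c), lapply(traj[[2]], c))
  expect_equal(attr(traj[[2]], "frame_index"), 1L)
})

test_that("velocity columns are tolerated and ignored", {
  vel <- sprintf("%8.4f%8.4f%8.4f", 0.1, -0.2, 0.3)
  lines <- gro_block("v", c(
    atom_line(1, "ALA", "BB", 1, 0.1, 0.2, 0.3, vel),
    atom_line(2, "GLY", "BB", 2, 0.4, 0.5, 0.6, vel)
  ))
  f <- read_gro(lines, group_length = 2)[[1]]
  expect_equal(f$z, c(0.3, 0.6))
})

test_that("residue boundaries come from (number, name) changes, not absolute numbers", {
  # residue numbers wrap at five digits: 99999 is followed by 0
  lines <- gro_block("wrap", c(
    atom_line(99999, "ALA", "BB", 1, 0, 0, 0),
    atom_line(0, "ALA", "BB", 2, 0.5, 0, 0),
    # same residue spread over two atoms (backbone + side chain)
    atom_line(1, "LYS", "BB", 3, 1, 0, 0),
    atom_line(1, "LYS", "SC1", 4, 1.2, 0, 0)
  ))
  f <- read_gro(lines, group_length = 3)[[1]]
  expect_equal(f$residue_index, c(0L, 1L, 2L, 2L))
  expect_equal(f$peptide_id, rep(0L, 4))
})

test_that("an (LDLK)3-sized system maps 100 peptides of GL 12", {
  spec <- sheet_spec(
    n_strands = 100, strand_len = 12,
    residue_names = c(
      "LEU", "ASP", "LEU", "LYS", "LEU", "ASP", "LEU", "LYS",
      "LEU", "ASP", "LEU", "LYS"
    )
  )
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(make_parallel_sheet(spec), path)
  traj <- read_gro(path, group_length = 12)
  f <- traj[[1]]
  expect_equal(nrow(f), 1200L)
  expect_equal(sort(unique(f$peptide_id)), 0:99)
  expect_true(all(table(f$peptide_id) == 12L))
})

test_that("write/read round-trips frames up to 0.001 nm quantisation", {
  frames <- list(
    make_random_coil(5, 7, box = 4, seed = 9),
    make_parallel_sheet(sheet_spec(12, 32))
  )
  gls <- c(7L, 32L)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    path <- withr::local_tempfile(fileext = ".gro")
    write_gro(f, path)
    g <- read_gro(path, group_length = gls[k])[[1]]
    expect_equal(nrow(g), nrow(f))
    expect_equal(g$residue_name, f$residue_name)
    expect_equal(g$atom_name, f$atom_name)
    expect_equal(g$peptide_id, f$peptide_id)
    expect_equal(g$residue_index, f$residue_index)
    expect_lte(max(abs(frame_coords(g) - frame_coords(f))), 5e-4 + 1e-12)
  }
})

test_that("the box line carries the orthorhombic lengths", {
  f <- make_random_coil(2, 3, box = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(f, path)
  last <- tail(readLines(path), 1)
  expect_equal(
    as.numeric(strsplit(trimws(last), "\\s+")[[1]]),
    c(10, 10, 10)
  )
  g <- read_gro(path, group_length = 3)[[1]]
  expect_equal(frame_box(g), c(10, 10, 10))
})

test_that("triclinic extra box fields are ignored with a warning", {
  lines <- gro_block(
    "tric",
    c(
      atom_line(1, "ALA", "BB", 1, 0, 0, 0),
      atom_line(2, "ALA", "BB", 2, 0.5, 0, 0)
    ),
    box = "  10.0  10.0  10.0   0.0   0.0   5.0   0.0   0.0   0.0"
  )
  expect_warning(traj <- read_gro(lines, group_length = 2), "triclinic")
  expect_equal(frame_box(traj[[1]]), c(10, 10, 10))
})

test_that("malformed input produces errors naming the problem", {
  good <- atom_line(1, "ALA", "BB", 1, 0, 0, 0)
  # malformed fixed-column line, by line number
  expect_error(
    read_gro(c("t", "    2", good, "1ALA BB 2 bad", "0 0 0"), 2),
    "line 4",
    class = "betagrain_parse_error"
  )
  # declared atom count exceeds the block body
  expect_error(
    read_gro(c("t", "    5", good, "   0.0 0.0 0.0"), 1),
    class = "betagrain_format_error"
  )
  # residue total not a multiple of GL, naming the remainder
  three <- c(
    atom_line(1, "ALA", "BB", 1, 0, 0, 0),
    atom_line(2, "ALA", "BB", 2, 0.5, 0, 0),
    atom_line(3, "ALA", "BB", 3, 1, 0, 0)
  )
  expect_error(
    read_gro(gro_block("t", three), group_length = 2),
    "remainder 1",
    class = "betagrain_grouping_error"
  )
})

test_that("filter_backbone keeps matching grains and stays a partition", {
  lines <- gro_block("mixed", c(
    atom_line(1, "LYS", "BB", 1, 0, 0, 0),
    atom_line(1, "LYS", "SC1", 2, 0.2, 0, 0),
    atom_line(2, "ALA", "BB", 3, 0.5, 0, 0)
  ))
  f <- read_gro(lines, group_length = 2)[[1]]
  bb <- filter_backbone(f)
  expect_equal(nrow(bb), 2L)
  expect_equal(bb$grain_id, c(0L, 1L))
  expect_equal(bb$residue_index, c(0L, 1L))
  # identity on pure-backbone frames
  pure <- make_parallel_sheet(sheet_spec(3, 4))
  expect_equal(
    as.data.frame(filter_backbone(pure)),
    as.data.frame(pure)
  )
  expect_error(
    filter_backbone(pure, atom_name = "SC1"),
    "atom name",
    class = "betagrain_format_error"
  )
})

test_that("frames of a trajectory must agree in grain count", {
  b1 <- gro_block("a", c(atom_line(1, "ALA", "BB", 1, 0, 0, 0)))
  b2 <- gro_block("b", c(
    atom_line(1, "ALA", "BB", 1, 0, 0, 0),
    atom_line(2, "ALA", "BB", 2, 0.5, 0, 0)
  ))
  expect_error(
    read_gro(c(b1, b2), group_length = 1),
    class = "betagrain_format_error"
  )
})
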