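analyze_frame <- function(frame, params = detection_params()) {
  triples <- find_aligned_triples(frame, params)
  components <- connected_components(triples, frame)
  frame_statistics(frame, triples, components)
}

test_that("a frame without triples reports zeros and an empty composition", {
  st <- analyze_frame(make_helix(30))
  expect_equal(st$n_triples, 0L)
  expect_equal(st$n_components, 0L)
  expect_equal(st$n_grains_in_sheets, 0L)
  expect_equal(st$fraction_in_sheets, 0)
  expect_length(st$composition[[1]], 0L)
})

test_that("the poly-ALA lattice is fully in sheets with composition {ALA: 384}", {
  st <- analyze_frame(make_parallel_sheet(sheet_spec(12, 32)))
  expect_equal(st$fraction_in_sheets, 1.0)
  expect_equal(st$composition[[1]], c(ALA = 384L))
  # integer identity, not approximate
  expect_identical(
    st$fraction_in_sheets * st$n_grains, as.numeric(st$n_grains_in_sheets)
  )
})

test_that("composition counts sheet-grain instances by residue name", {
  # alternating ASP/LYS lattice: 4 strands x 10 residues, all in sheets
  f <- make_parallel_sheet(
    sheet_spec(4, 10, residue_names = c("ASP", "LYS"))
  )
  st <- analyze_frame(f)
  expect_equal(st$fraction_in_sheets, 1.0)
  expect_equal(st$composition[[1]], c(ASP = 20L, LYS = 20L))
  expect_equal(residue_ratio(st, "ASP", "LYS"), 1.0)
  # per-component compositions sum exactly to the aggregate
  percomp <- st$per_component[[1]]
  expect_equal(sum(purrr::map_int(percomp$composition, sum)), 40L)
  expect_equal(sum(percomp$n_grains), st$n_grains_in_sheets)
})

test_that("residue ratios use instance counts with undefined/infinity markers", {
  expect_equal(residue_ratio(c(ASP = 10, LYS = 10), "ASP", "LYS"), 1.0)
  expect_equal(residue_ratio(c(LYS = 20, ASP = 10), "LYS", "ASP"), 2.0)
  expect_true(is.na(residue_ratio(c(ALA = 5), "ASP", "LYS")))
  expect_identical(residue_ratio(c(LYS = 7), "LYS", "ASP"), Inf)
})

test_that("non-standard residue names are first-class composition keys", {
  f <- make_parallel_sheet(
    sheet_spec(3, 4, residue_names = c("BTN", "GLY", "GLY", "ALA"))
  )
  st <- analyze_frame(f)
  expect_equal(
    st$composition[[1]],
    c(ALA = 3L, BTN = 3L, GLY = 6L)
  )
})

test_that("trajectory statistics treat frames independently and in order", {
  f <- make_parallel_sheet(sheet_spec(4, 6))
  traj <- cg_trajectory(list(f, f), group_length = 6)
  st <- trajectory_statistics(traj)
  expect_equal(nrow(st), 2L)
  expect_equal(st$frame_index, 0:1)
  expect_identical(st$n_triples[1], st$n_triples[2])
  expect_identical(st$composition[[1]], st$composition[[2]])
  one <- trajectory_statistics(cg_trajectory(list(f), 6))
  expect_equal(nrow(one), 1L)
  expect_identical(as.data.frame(one[1, ]), as.data.frame(st[1, ]))
})

test_that("a lattice forming over frames gives monotone triple counts", {
  # frames shrink a uniformly scaled lattice onto the ideal spacings:
  # triples appear only once the inter-strand gap crosses epsilon
  base <- make_parallel_sheet(sheet_spec(12, 32))
  scales <- c(3, 2.5, 2, 1.4, 1)
  frames <- lapply(scales, function(s) {
    f <- base
    f$x <- f$x * s
    f$y <- f$y * s
    f$z <- f$z * s
    f
  })
  st <- trajectory_statistics(cg_trajectory(frames, 32))
  expect_true(all(diff(st$n_triples) >= 0))
  expect_equal(st$n_triples[1], 0L)
  expect_equal(st$n_triples[5], 320L)
  expect_equal(st$fraction_in_sheets[5], 1.0)
})

test_that("per-frame counts respect the structural identities", {
  for (seed in c(3, 9)) {
    f <- make_random_coil(10, 10, box = 4, seed = seed)
    st <- analyze_frame(f)
    expect_lte(st$n_components, st$n_triples)
    expect_equal(sum(st$composition[[1]]), st$n_grains_in_sheets)
    expect_equal(
      sum(st$per_component[[1]]$n_grains), st$n_grains_in_sheets
    )
    expect_identical(
      st$fraction_in_sheets * st$n_grains,
      as.numeric(st$n_grains_in_sheets)
    )
  }
})

test_that("statistics are invariant under a global rigid transform", {
  f <- make_random_coil(10, 10, box = 4, seed = 3)
  g <- transform_frame(f, random_rotation(5), c(-2, 4, 1))
  a <- analyze_frame(f)
  b <- analyze_frame(g)
  expect_identical(a$n_triples, b$n_triples)
  expect_identical(a$n_components, b$n_components)
  expect_identical(a$composition[[1]], b$composition[[1]])
  expect_identical(a$fraction_in_sheets, b$fraction_in_sheets)
})

test_that("composition_table unnests compositions in tidy long form", {
  f <- make_parallel_sheet(sheet_spec(4, 10, residue_names = c("ASP", "LYS")))
  st <- trajectory_statistics(cg_trajectory(list(f), 10))
  long <- composition_table(st)
  expect_equal(names(long), c("frame_index", "residue_name", "count"))
  expect_equal(sum(long$count), 40L)
})

test_that("CSV and JSON reports carry the documented schema", {
  f <- make_parallel_sheet(sheet_spec(4, 10, residue_names = c("ASP", "LYS")))
  params <- detection_params()
  st <- trajectory_statistics(cg_trajectory(list(f), 10), params)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_stats_csv(st, csv)
  got <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(
    names(got),
    c("frame", "n_triples", "n_components", "n_grains_in_sheets",
      "fraction_in_sheets")
  )
  expect_equal(got$n_triples, st$n_triples)
  write_stats_json(st, js, params)
  doc <- jsonlite::read_json(js)
  expect_equal(doc$parameters$alpha, 0.89)
  expect_equal(doc$n_frames, 1L)
  expect_equal(doc$frames[[1]]$composition$ASP, 20L)
  expect_length(doc$frames[[1]]$components, st$n_components[1])
})

test_that("component labels are a total assignment with -1 outside sheets", {
  sheet <- make_parallel_sheet(sheet_spec(4, 6))
  tr <- find_aligned_triples(sheet)
  comp <- connected_components(tr, sheet)
  lab <- component_labels(sheet, comp)
  expect_equal(nrow(lab), nrow(sheet))
  expect_true(all(lab$component_id >= 1L))
  helix <- make_helix(20)
  lab2 <- component_labels(
    helix,
    connected_components(find_aligned_triples(helix), helix)
  )
  expect_true(all(lab2$component_id == -1L))
})
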