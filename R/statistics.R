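#' Per-frame summary of detected beta-sheet structure
#'
#' Collects the counts the analysis overlays report for one frame: number of
#' aligned triples, number of sheet components, number and fraction of grains
#' belonging to any sheet, and the residue-type composition of the sheet
#' grains (each sheet grain counted once under its residue name). Components
#' have disjoint grain sets, so their grain counts sum exactly to
#' `n_grains_in_sheets`.
#'
#' @param frame A [cg_frame()].
#' @param triples Tibble from [find_aligned_triples()] computed on `frame`.
#' @param components Tibble from [connected_components()] computed on
#'   `triples`.
#' @return A one-row tibble: `frame_index`, `n_grains`, `n_triples`,
#'   `n_components`, `n_grains_in_sheets`, `fraction_in_sheets`,
#'   `composition` (list column of named counts) and `per_component`
#'   (list column of per-component tibbles).
#' @export
frame_statistics <- function(frame, triples, components) {
  if (!"composition" %in% names(components)) {
    components <- annotate_components(components, frame)
  }
  sheet_grains <- grains_in_sheets(components)
  res_of <- setNames(frame$residue_name, as.character(frame$grain_id))
  composition <- count_residues(unname(res_of[as.character(sheet_grains)]))
  per_component <- select(
    components, "component_id", "n_triples", "n_grains", "n_peptides",
    "composition"
  )
  n <- nrow(frame)
  tibble(
    frame_index = as.integer(attr(frame, "frame_index") %||% 0L),
    n_grains = n,
    n_triples = nrow(triples),
    n_components = nrow(components),
    n_grains_in_sheets = length(sheet_grains),
    fraction_in_sheets = if (n > 0) length(sheet_grains) / n else 0,
    composition = list(composition),
    per_component = list(per_component)
  )
}

#' Ratio of two residue types among sheet grains
#'
#' The ratio of instance counts of two residue names in a composition, e.g.
#' the aspartate-to-lysine ratio that characterises alternating charged
#' lattices. A 0/0 ratio is reported as `NA` (undefined) and x/0 as `Inf`,
#' as markers rather than errors, so per-frame time series stay aligned.
#'
#' @param stats A one-row tibble from [frame_statistics()], or a named
#'   composition vector.
#' @param name_a,name_b Residue names (numerator, denominator).
#' @return A single number, `NA` or `Inf`.
#' @examples
#' residue_ratio(c(ASP = 10, LYS = 10), "ASP", "LYS") # 1
#' @export
residue_ratio <- function(stats, name_a, name_b) {
  comp <- if (is.data.frame(stats)) stats$composition[[1]] else stats
  a <- as.numeric(comp[name_a])
  b <- as.numeric(comp[name_b])
  if (is.na(a)) a <- 0
  if (is.na(b)) b <- 0
  if (b == 0) {
    return(if (a == 0) NA_real_ else Inf)
  }
  a / b
}

#' Per-frame statistics for a whole trajectory
#'
#' Runs triple detection, component gluing and [frame_statistics()] on every
#' frame independently and binds the per-frame rows. Frames are independent
#' units of work: the result does not depend on the order they are
#' processed in.
#'
#' @param traj A [cg_trajectory()].
#' @param params A [detection_params()].
#' @return A tibble with one row per frame (in frame order), carrying the
#'   detection parameters and group length as attributes.
#' @export
trajectory_statistics <- function(traj, params = detection_params()) {
  stats <- lapply(seq_along(traj), function(i) {
    frame <- traj[[i]]
    attr(frame, "frame_index") <- i - 1L
    withCallingHandlers(
      {
        triples <- find_aligned_triples(frame, params)
        components <- connected_components(triples, frame)
        frame_statistics(frame, triples, components)
      },
      error = function(e) {
        abort(sprintf("trajectory_statistics(): frame %d failed.", i - 1L),
          parent = e)
      }
    )
  })
  out <- bind_rows(stats)
  attr(out, "params") <- params
  attr(out, "group_length") <- trajectory_group_length(traj)
  out
}

#' Composition counts in long (tidy) form
#'
#' @param stats A tibble of per-frame statistics
#'   ([trajectory_statistics()] or [frame_statistics()] rows).
#' @return A tibble with columns `frame_index`, `residue_name`, `count`.
#' @export
composition_table <- function(stats) {
  rows <- purrr::map2(stats$frame_index, stats$composition, function(fi, comp) {
    if (length(comp) == 0L) {
      return(NULL)
    }
    tibble(
      frame_index = fi, residue_name = names(comp),
      count = as.integer(comp)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(
      frame_index = integer(), residue_name = character(),
      count = integer()
    )
  }
  out
}

#' Write per-frame statistics as CSV
#'
#' One row per frame with the columns `frame`, `n_triples`, `n_components`,
#' `n_grains_in_sheets`, `fraction_in_sheets` (stable schema; list columns
#' are omitted -- use [write_stats_json()] for compositions and
#' per-component detail).
#'
#' @param stats Tibble of per-frame statistics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_csv <- function(stats, path) {
  flat <- tibble(
    frame = stats$frame_index,
    n_triples = stats$n_triples,
    n_components = stats$n_components,
    n_grains_in_sheets = stats$n_grains_in_sheets,
    fraction_in_sheets = stats$fraction_in_sheets
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' Write per-frame statistics as JSON
#'
#' The CSV schema of [write_stats_csv()] plus, per frame, the aggregate
#' residue-type `composition` map and a `components` array with each
#' component's id, triple/grain/peptide counts and composition.
#'
#' @inheritParams write_stats_csv
#' @param params Optional [detection_params()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path, params = NULL) {
  params <- params %||% attr(stats, "params")
  frames <- lapply(seq_len(nrow(stats)), function(i) {
    pc <- stats$per_component[[i]]
    list(
      frame = stats$frame_index[i],
      n_grains = stats$n_grains[i],
      n_triples = stats$n_triples[i],
      n_components = stats$n_components[i],
      n_grains_in_sheets = stats$n_grains_in_sheets[i],
      fraction_in_sheets = stats$fraction_in_sheets[i],
      composition = as.list(stats$composition[[i]]),
      components = lapply(seq_len(nrow(pc)), function(k) {
        list(
          component_id = pc$component_id[k],
          n_triples = pc$n_triples[k],
          n_grains = pc$n_grains[k],
          n_peptides = pc$n_peptides[k],
          composition = as.list(pc$composition[[k]])
        )
      })
    )
  })
  doc <- list(
    parameters = if (is.null(params)) NULL else {
      list(
        alpha = params$alpha, epsilon = params$epsilon,
        use_pbc = params$use_pbc
      )
    },
    n_frames = nrow(stats),
    frames = frames
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-grain component labels
#'
#' Total assignment of grains to sheet components: grains outside every
#' component carry the sentinel id `-1`, so external viewers can colour a
#' structure by component.
#'
#' @param frame A [cg_frame()].
#' @param components Tibble from [connected_components()].
#' @return A tibble with `grain_id`, `peptide_id`, `residue_name`,
#'   `component_id`.
#' @export
component_labels <- function(frame, components) {
  label <- setNames(
    rep(-1L, nrow(frame)),
    as.character(frame$grain_id)
  )
  for (i in seq_len(nrow(components))) {
    label[as.character(components$grain_ids[[i]])] <- components$component_id[i]
  }
  tibble(
    grain_id = frame$grain_id,
    peptide_id = frame$peptide_id,
    residue_name = frame$residue_name,
    component_id = unname(label[as.character(frame$grain_id)])
  )
}
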