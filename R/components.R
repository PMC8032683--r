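#' Do two aligned triples overlap?
#'
#' Two triples overlap when they share at least two of their three grains.
#' Membership is set-wise: a grain shared as an end of one triple and the
#' center of the other still counts.
#'
#' @param a,b Triples, as length-3 vectors of grain ids or one-row tibbles
#'   with columns `end_a`, `center`, `end_b`.
#' @return `TRUE` or `FALSE`.
#' @export
are_overlapping <- function(a, b) {
  ga <- triple_grains(a)
  gb <- triple_grains(b)
  length(intersect(ga, gb)) >= 2L
}

triple_grains <- function(t) {
  if (is.data.frame(t)) {
    as.integer(c(t$end_a, t$center, t$end_b))
  } else {
    as.integer(t)
  }
}

#' Glue overlapping triples into sheet components
#'
#' Builds the overlap graph (vertices: aligned triples; edges: pairs sharing
#' at least two grains) and returns its connected components, the method's
#' putative beta-sheets. Candidate overlapping pairs are generated from a
#' grain-to-triples index -- two triples can only overlap if they co-occur
#' on some grain -- and merged with union-find (path compression), which is
#' output-equivalent to the quadratic scan over all triple pairs.
#'
#' Components are ordered by decreasing grain count, ties broken by the
#' smallest member grain id, and numbered `1, 2, ...` in that order, so the
#' output is deterministic and invariant to the input order of the triples.
#'
#' @param triples Tibble from [find_aligned_triples()].
#' @param frame Optional [cg_frame()]; when given, each component also
#'   reports its peptide ids and residue-name composition.
#' @return A tibble with one row per component: `component_id`, `n_triples`,
#'   `n_grains`, `grain_ids` (list of sorted integer vectors), `triples`
#'   (list of member-triple tibbles), and, with `frame`, `n_peptides`,
#'   `peptide_ids` and `composition` (list of named counts).
#' @export
connected_components <- function(triples, frame = NULL) {
  m <- nrow(triples)
  empty <- tibble(
    component_id = integer(), n_triples = integer(), n_grains = integer(),
    grain_ids = list(), triples = list()
  )
  if (m == 0L) {
    return(if (is.null(frame)) empty else annotate_components(empty, frame))
  }
  tg <- cbind(triples$end_a, triples$center, triples$end_b)

  # candidate pairs: triples co-occurring on a grain
  by_grain <- split(rep(seq_len(m), 3L), as.vector(tg))
  cand <- lapply(by_grain, function(v) {
    if (length(v) < 2L) return(NULL)
    utils::combn(sort(unique(v)), 2L)
  })
  cand <- do.call(cbind, cand)

  parent <- seq_len(m)
  find_root <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { # path compression
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }

  if (!is.null(cand)) {
    p <- cand[1, ]
    q <- cand[2, ]
    dup <- duplicated(p * (m + 1) + q)
    p <- p[!dup]; q <- q[!dup]
    # shared-grain count between each candidate pair (triples are id-triples)
    shared <- integer(length(p))
    for (k in 1:3) {
      shared <- shared + (tg[p, k] == tg[q, 1]) + (tg[p, k] == tg[q, 2]) +
        (tg[p, k] == tg[q, 3])
    }
    for (e in which(shared >= 2L)) {
      rp <- find_root(p[e])
      rq <- find_root(q[e])
      if (rp != rq) parent[rq] <- rp
    }
  }

  root <- vapply(seq_len(m), find_root, integer(1))
  groups <- unname(split(seq_len(m), root))
  comp <- tibble(
    n_triples = lengths(groups),
    grain_ids = lapply(groups, function(ix) {
      sort(unique(as.vector(tg[ix, , drop = FALSE])))
    }),
    triples = lapply(groups, function(ix) triples[ix, , drop = FALSE])
  )
  comp$n_grains <- lengths(comp$grain_ids)
  min_gid <- map_int(comp$grain_ids, function(g) g[1])
  ord <- order(-comp$n_grains, min_gid)
  comp <- comp[ord, ]
  comp$component_id <- seq_len(nrow(comp))
  comp <- select(
    comp, "component_id", "n_triples", "n_grains", "grain_ids", "triples"
  )
  if (is.null(frame)) comp else annotate_components(comp, frame)
}

annotate_components <- function(comp, frame) {
  pep_of <- setNames(frame$peptide_id, as.character(frame$grain_id))
  res_of <- setNames(frame$residue_name, as.character(frame$grain_id))
  comp$peptide_ids <- lapply(comp$grain_ids, function(g) {
    sort(unique(unname(pep_of[as.character(g)])))
  })
  comp$n_peptides <- lengths(comp$peptide_ids)
  comp$composition <- lapply(comp$grain_ids, function(g) {
    count_residues(unname(res_of[as.character(g)]))
  })
  comp
}

count_residues <- function(names) {
  if (length(names) == 0L) {
    return(integer())
  }
  tab <- table(names)
  setNames(as.integer(tab), names(tab))
}

#' Grains belonging to any sheet component
#'
#' @param components Tibble from [connected_components()].
#' @return Sorted integer vector: the union of all components' grain ids.
#' @export
grains_in_sheets <- function(components) {
  g <- unlist(components$grain_ids, use.names = FALSE)
  if (is.null(g)) return(integer())
  sort(unique(g))
}
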