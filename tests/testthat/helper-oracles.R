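# Independent oracles, deliberately written as plain enumerations so they
# share no code path with the package's grid/union-find implementations.

# Literal enumeration over all triples of grains: every unordered set
# {a, b, c} is tested with each of its three grains as the center, exactly
# as the O(n^3) triple loop would. Distances come from a full pairwise
# matrix, angles from the raw arccos formula.
brute_force_triples <- function(frame, params = detection_params()) {
  empty <- tibble::tibble(
    end_a = integer(), center = integer(), end_b = integer()
  )
  n <- nrow(frame)
  if (n < 3L) return(empty)
  coords <- as.matrix(frame[, c("x", "y", "z")])
  pep <- frame$peptide_id
  gid <- frame$grain_id
  D <- as.matrix(stats::dist(coords))
  cmb <- utils::combn(n, 3L)
  rows <- list()
  for (r in 1:3) {
    ctr <- cmb[r, ]
    ends <- cmb[-r, , drop = FALSE]
    a <- ends[1, ]
    b <- ends[2, ]
    ok <- pep[a] != pep[b] & pep[a] != pep[ctr] & pep[b] != pep[ctr] &
      D[cbind(a, ctr)] <= params$epsilon & D[cbind(ctr, b)] <= params$epsilon &
      D[cbind(a, ctr)] > 0 & D[cbind(ctr, b)] > 0
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]; ctr <- ctr[ok]
    v <- coords[a, , drop = FALSE] - coords[ctr, , drop = FALSE]
    w <- coords[b, , drop = FALSE] - coords[ctr, , drop = FALSE]
    cosang <- rowSums(v * w) /
      (sqrt(rowSums(v^2)) * sqrt(rowSums(w^2)))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    keep <- ang >= params$alpha * pi
    if (!any(keep)) next
    rows[[r]] <- tibble::tibble(
      end_a = as.integer(pmin(gid[a[keep]], gid[b[keep]])),
      center = as.integer(gid[ctr[keep]]),
      end_b = as.integer(pmax(gid[a[keep]], gid[b[keep]]))
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(dplyr::distinct(out), center, end_a, end_b)
}

# O(n^2) pairwise epsilon-neighborhood scan (different-peptide pairs only).
brute_force_neighbors <- function(frame, epsilon) {
  n <- nrow(frame)
  gid <- frame$grain_id
  coords <- as.matrix(frame[, c("x", "y", "z")])
  out <- stats::setNames(rep(list(integer()), n), as.character(gid))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    hit <- which(d <= epsilon & frame$peptide_id != frame$peptide_id[i] &
      seq_len(n) != i)
    out[[as.character(gid[i])]] <- sort(as.integer(gid[hit]))
  }
  out
}

# Quadratic scan over all triple pairs + breadth-first search: the literal
# overlap-graph component algorithm. Returns the partition as a list of
# sorted triple row-index vectors.
bfs_components <- function(triples) {
  m <- nrow(triples)
  if (m == 0L) return(list())
  tg <- cbind(triples$end_a, triples$center, triples$end_b)
  adj <- rep(list(integer()), m)
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      if (length(intersect(tg[p, ], tg[q, ])) >= 2L) {
        adj[[p]] <- c(adj[[p]], q)
        adj[[q]] <- c(adj[[q]], p)
      }
    }
  }
  seen <- logical(m)
  comps <- list()
  for (s in seq_len(m)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer()
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      nxt <- adj[[v]][!seen[adj[[v]]]]
      seen[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# Canonical form of a partition over triple rows, for set comparison.
canonical_partition <- function(groups) {
  sorted <- unname(lapply(groups, function(g) unname(sort(g))))
  keys <- vapply(sorted, function(g) paste(g, collapse = ","), character(1))
  sorted[order(keys)]
}

# Partition implied by connected_components() output, as triple row indices
# of the `triples` tibble it was computed from.
partition_from_components <- function(components, triples) {
  key <- paste(triples$end_a, triples$center, triples$end_b)
  lapply(components$triples, function(tt) {
    sort(match(paste(tt$end_a, tt$center, tt$end_b), key))
  })
}

# A seeded random multi-peptide frame for oracle comparisons: dense enough
# that aligned triples actually occur.
random_test_frame <- function(seed, n_min = 100L, n_max = 200L) {
  p <- withr::with_seed(seed, {
    n_pep <- sample(5:20, 1L)
    gl <- max(2L, round(stats::runif(1, n_min, n_max) / n_pep))
    while (gl * n_pep > n_max) gl <- gl - 1L
    while (gl * n_pep < n_min) gl <- gl + 1L
    box <- stats::runif(1, 3, 5)
    list(n_pep = n_pep, gl = gl, box = box)
  })
  make_random_coil(p$n_pep, p$gl, p$box, seed = seed)
}

triple_key <- function(triples) {
  paste(triples$end_a, triples$center, triples$end_b)
}
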