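#' Topological update parameters
#'
#' @param t1_threshold_fraction fraction of the tissue-mean junction length
#'   below which an edge is eliminated by a T1 transition (strict `<`).
#'   Default 0.03 (3% of the average edge length).
#' @param l_new length of the newly expanded edge after a T1. The default
#'   `NULL` means "twice the current elimination length", i.e.
#'   `2 * t1_threshold_fraction * mean(edge length)` evaluated when the
#'   transition fires, which keeps the new edge strictly above threshold and
#'   prevents immediate re-collapse.
#' @return a `vm_topology_params` list.
#' @export
topology_params <- function(t1_threshold_fraction = 0.03, l_new = NULL) {
  stopifnot(t1_threshold_fraction > 0, t1_threshold_fraction < 1,
            is.null(l_new) || l_new > 0)
  structure(list(t1_threshold_fraction = t1_threshold_fraction, l_new = l_new),
            class = "vm_topology_params")
}

#' Junctions shorter than the T1 threshold
#'
#' Returns every junction whose minimum-image length is strictly below
#' `t1_threshold_fraction` times the tissue-mean junction length, in
#' deterministic junction-id order (ascending `i`, then `j`).
#'
#' @param mesh a `vm_mesh`.
#' @param params a [topology_params()] object.
#' @return a tibble with columns `i`, `j`, `length` and the scalar attribute
#'   `mean_length`.
#' @export
detect_short_edges <- function(mesh, params = topology_params()) {
  jn <- mesh_junctions(mesh)
  dx <- wrap_delta(mesh$v[jn[, 2], 1] - mesh$v[jn[, 1], 1], mesh$box[1])
  dy <- wrap_delta(mesh$v[jn[, 2], 2] - mesh$v[jn[, 1], 2], mesh$box[2])
  l <- sqrt(dx^2 + dy^2)
  lbar <- mean(l)
  keep <- l < params$t1_threshold_fraction * lbar
  out <- tibble::tibble(i = jn[keep, 1], j = jn[keep, 2], length = l[keep])
  attr(out, "mean_length") <- lbar
  out
}

# cells whose loop contains vertex i
cells_with_vertex <- function(mesh, i) {
  fl <- mesh$flat
  unique(fl$cell_of[fl$idx0 == i - 1L])
}

# position of value x in vector v (first match), or 0
match1 <- function(x, v) {
  p <- match(x, v)
  if (is.na(p)) 0L else p
}

#' T1 transition (neighbour exchange) on one junction
#'
#' Collapses the junction `i-j` to its midpoint and expands a new edge of
#' length `l_new` perpendicular to the old one. The two cells that shared the
#' edge each lose one side; the two cells at its endpoints each gain one.
#' `(N_v, N_c, E)` are conserved unless the transition leaves a two-sided
#' cell, which is then extruded via [remove_cell()] — the endpoint of
#' differentiation-driven elimination.
#'
#' @param mesh a `vm_mesh`.
#' @param junction integer length-2 vertex pair.
#' @param params a [topology_params()] object (supplies `l_new`).
#' @return the updated mesh; the attribute `removed_cells` lists cells
#'   extruded as a consequence (indices valid at the moment of each removal),
#'   and `t1_info` records old/new edge angles. If the local configuration
#'   does not admit a T1 (e.g. the flipped edge would duplicate an existing
#'   junction), the mesh is returned unchanged with attribute `skipped`.
#' @export
t1_transition <- function(mesh, junction, params = topology_params()) {
  i <- junction[1]; j <- junction[2]
  ci <- cells_with_vertex(mesh, i)
  cj <- cells_with_vertex(mesh, j)
  P <- Q <- 0L
  for (a in intersect(ci, cj)) {
    loop <- mesh$cells[[a]]
    n <- length(loop)
    pi_ <- match1(i, loop)
    if (pi_ && loop[pi_ %% n + 1L] == j) P <- a
    pj_ <- match1(j, loop)
    if (pj_ && loop[pj_ %% n + 1L] == i) Q <- a
  }
  if (!P || !Q) stop("junction does not exist in the mesh")
  R <- setdiff(ci, c(P, Q))
  S <- setdiff(cj, c(P, Q))
  if (length(R) != 1L || length(S) != 1L || R == S) {
    attr(mesh, "skipped") <- TRUE
    warning("T1 skipped: junction not in a flippable configuration")
    return(mesh)
  }

  d <- c(wrap_delta(mesh$v[j, 1] - mesh$v[i, 1], mesh$box[1]),
         wrap_delta(mesh$v[j, 2] - mesh$v[i, 2], mesh$box[2]))
  lold <- sqrt(sum(d^2))
  l_new <- params$l_new
  if (is.null(l_new)) {
    jn <- mesh_junctions(mesh)
    dx <- wrap_delta(mesh$v[jn[, 2], 1] - mesh$v[jn[, 1], 1], mesh$box[1])
    dy <- wrap_delta(mesh$v[jn[, 2], 2] - mesh$v[jn[, 1], 2], mesh$box[2])
    l_new <- 2 * params$t1_threshold_fraction * mean(sqrt(dx^2 + dy^2))
  }
  mid <- mesh$v[i, ] + d / 2
  u <- c(-d[2], d[1]) / lold     # unit perpendicular, pointing into cell P
  mesh$v[i, ] <- (mid + 0.5 * l_new * u) %% mesh$box
  mesh$v[j, ] <- (mid - 0.5 * l_new * u) %% mesh$box

  # rewire loops: P loses j, Q loses i; R gains j immediately before i
  # (R ran ..., q2, i, ... and the spoke i-q2 is re-homed to j), S gains i
  # immediately before j, keeping both traversals of the flipped edge paired
  mesh$cells[[P]] <- setdiff(mesh$cells[[P]], j)
  mesh$cells[[Q]] <- setdiff(mesh$cells[[Q]], i)
  mesh$cells[[R]] <- append(mesh$cells[[R]], j, after = match1(i, mesh$cells[[R]]) - 1L)
  mesh$cells[[S]] <- append(mesh$cells[[S]], i, after = match1(j, mesh$cells[[S]]) - 1L)
  mesh <- mesh_rebuild_flat(mesh)

  removed <- integer(0)
  for (a in sort(c(P, Q), decreasing = TRUE)) {  # descending: indices stay valid
    if (length(mesh$cells[[a]]) == 2L) {
      mesh <- remove_cell(mesh, a)
      removed <- c(removed, a, attr(mesh, "removed_cells"))
    }
  }
  attr(mesh, "removed_cells") <- removed
  attr(mesh, "t1_info") <- list(old_angle = atan2(d[2], d[1]),
                                new_angle = atan2(u[2], u[1]),
                                l_old = lold, l_new = l_new,
                                cells = c(P = P, Q = Q, R = R, S = S))
  mesh
}

#' Remove a two-sided cell (apical extrusion endpoint)
#'
#' A two-sided cell consists of two vertices joined by a pair of parallel
#' junctions. Removal deletes the cell and both its vertices and re-stitches
#' the two neighbouring cells along a single new junction, subtracting
#' `(2, 1, 3)` from `(N_v, N_c, E)`. If a neighbour is left two-sided the
#' removal cascades.
#'
#' @param mesh a `vm_mesh`.
#' @param alpha index of a cell with exactly 2 sides.
#' @return updated mesh; attribute `removed_cells` lists any cascaded
#'   removals.
#' @export
remove_cell <- function(mesh, alpha) {
  loop <- mesh$cells[[alpha]]
  if (length(loop) != 2L) {
    stop("remove_cell requires a two-sided cell (got ", length(loop), " sides)")
  }
  i <- loop[1]; j <- loop[2]
  nbrs <- setdiff(unique(c(cells_with_vertex(mesh, i), cells_with_vertex(mesh, j))),
                  alpha)
  if (length(nbrs) != 2L) stop("two-sided cell without exactly two neighbours")
  if (any(lengths(mesh$cells[nbrs]) < 4L)) {
    stop("removal would leave a neighbour with fewer than 2 sides")
  }
  for (a in nbrs) {
    mesh$cells[[a]] <- setdiff(mesh$cells[[a]], c(i, j))
  }
  mesh$cells[[alpha]] <- NULL

  # drop the two orphaned vertices and renumber
  keep <- rep(TRUE, nrow(mesh$v)); keep[c(i, j)] <- FALSE
  newid <- cumsum(keep)
  mesh$v <- mesh$v[keep, , drop = FALSE]
  mesh$cells <- lapply(mesh$cells, function(lp) as.integer(newid[lp]))
  mesh <- mesh_rebuild_flat(mesh)

  # cascade: a 4-sided neighbour is left two-sided and must go too
  removed <- integer(0)
  repeat {
    two <- which(lengths(mesh$cells) == 2L)
    if (!length(two)) break
    mesh <- remove_cell(mesh, two[1])
    removed <- c(removed, two[1], attr(mesh, "removed_cells"))
  }
  attr(mesh, "removed_cells") <- removed
  mesh
}

#' Divide a cell through opposite edge midpoints
#'
#' One cleavage endpoint is the midpoint of an edge selected with probability
#' proportional to edge length; the other is the midpoint of the opposite
#' edge (for an odd side count, the nearer of the two mid-opposite candidates
#' by Euclidean midpoint distance, ties to the lower edge index). Adds
#' `(2, 1, 3)` to `(N_v, N_c, E)`; both daughters inherit the parent's clone.
#'
#' @param mesh a `vm_mesh`.
#' @param alpha index of the dividing cell (>= 3 sides).
#' @return a list with `mesh`, `daughters` (the two cell indices: the parent
#'   slot and the appended cell), `new_edge_angle` (angle of the daughter
#'   interface to the DV axis) and `edges` (the split edge indices).
#' @export
divide_cell <- function(mesh, alpha) {
  loop <- mesh$cells[[alpha]]
  n <- length(loop)
  if (n < 3L) stop("cannot divide a cell with fewer than 3 sides")
  p <- cell_polygon(mesh, alpha)
  k1 <- c(2:n, 1)
  elen <- sqrt((p[k1, 1] - p[, 1])^2 + (p[k1, 2] - p[, 2])^2)
  mids <- (p + p[k1, , drop = FALSE]) / 2

  e1 <- sample.int(n, 1L, prob = elen)
  if (n %% 2 == 0) {
    e2 <- (e1 - 1L + n %/% 2L) %% n + 1L
  } else {
    cand <- (e1 - 1L + c(n %/% 2L, n %/% 2L + 1L)) %% n + 1L
    dd <- sqrt(rowSums((mids[cand, , drop = FALSE] -
                          matrix(mids[e1, ], 2, 2, byrow = TRUE))^2))
    cand <- cand[order(dd, cand)]
    e2 <- cand[1]
  }

  a_id <- nrow(mesh$v) + 1L
  b_id <- nrow(mesh$v) + 2L
  mesh$v <- rbind(mesh$v,
                  mids[e1, ] %% mesh$box,
                  mids[e2, ] %% mesh$box)

  cyc <- function(from, to) {        # loop positions from..to inclusive, cyclic
    if (from <= to) from:to else c(from:n, 1:to)
  }
  dA <- c(a_id, loop[cyc(e1 %% n + 1L, e2)], b_id)
  dB <- c(b_id, loop[cyc(e2 %% n + 1L, e1)], a_id)

  # neighbours across the split edges gain the new midpoint vertex
  insert_mid <- function(mesh, va, vb, newv) {
    for (cc in intersect(cells_with_vertex(mesh, va), cells_with_vertex(mesh, vb))) {
      if (cc == alpha) next
      lp <- mesh$cells[[cc]]
      pos <- match1(vb, lp)
      if (pos && lp[pos %% length(lp) + 1L] == va) {
        mesh$cells[[cc]] <- append(lp, newv, after = pos)
      }
    }
    mesh
  }
  mesh <- insert_mid(mesh, loop[e1], loop[e1 %% n + 1L], a_id)
  mesh <- insert_mid(mesh, loop[e2], loop[e2 %% n + 1L], b_id)

  mesh$cells[[alpha]] <- as.integer(dA)
  mesh$cells[[length(mesh$cells) + 1L]] <- as.integer(dB)
  mesh <- mesh_rebuild_flat(mesh)

  dab <- c(wrap_delta(mesh$v[b_id, 1] - mesh$v[a_id, 1], mesh$box[1]),
           wrap_delta(mesh$v[b_id, 2] - mesh$v[a_id, 2], mesh$box[2]))
  list(mesh = mesh, daughters = c(alpha, length(mesh$cells)),
       new_edge_angle = atan2(dab[2], dab[1]), edges = c(e1, e2))
}
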