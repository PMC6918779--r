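#' Periodic polygonal mesh on the unwrapped torus
#'
#' A `vm_mesh` represents the apical surface of the epithelium as a polygonal
#' tiling of a flat periodic rectangle (the unwrapped torus): `x` is the
#' dorsoventral (DV) coordinate, `y` the anterioposterior (AP) coordinate,
#' both half-open in `[0, L)`. Cells are counter-clockwise vertex loops; every
#' interior vertex is trivalent, so on the torus `V - E + F = 0`, `2E = 3V`
#' and the mean polygon side count is exactly 6.
#'
#' @param v numeric matrix `N_v x 2` of vertex positions.
#' @param cells list of integer vectors, one counter-clockwise loop per cell.
#' @param box numeric length-2, the periodic box `(L_DV, L_AP)`.
#' @return an object of class `vm_mesh` with fields `v`, `cells`, `box` and a
#'   cached flat loop representation used by the force kernel.
#' @export
vm_mesh <- function(v, cells, box) {
  stopifnot(is.matrix(v), ncol(v) == 2, is.list(cells), length(box) == 2,
            all(box > 0))
  v[, 1] <- v[, 1] %% box[1]
  v[, 2] <- v[, 2] %% box[2]
  m <- structure(list(v = v, cells = cells, box = as.numeric(box)),
                 class = "vm_mesh")
  mesh_rebuild_flat(m)
}

# Rebuild the 0-based flat loop arrays consumed by the C++ kernel. Must be
# called after every topological change.
mesh_rebuild_flat <- function(mesh) {
  ns <- lengths(mesh$cells)
  mesh$flat <- list(
    idx0 = as.integer(unlist(mesh$cells, use.names = FALSE) - 1L),
    ptr0 = as.integer(c(0L, cumsum(ns))),
    cell_of = rep.int(seq_along(mesh$cells), ns)
  )
  mesh
}

#' @export
print.vm_mesh <- function(x, ...) {
  cat(sprintf("<vm_mesh> %d cells, %d vertices, box %.3f x %.3f (DV x AP)\n",
              n_cells(x), n_vertices(x), x$box[1], x$box[2]))
  invisible(x)
}

#' Mesh counts
#' @param mesh a `vm_mesh`.
#' @return integer count.
#' @export
n_cells <- function(mesh) length(mesh$cells)

#' @rdname n_cells
#' @export
n_vertices <- function(mesh) nrow(mesh$v)

#' @rdname n_cells
#' @export
n_edges <- function(mesh) nrow(mesh_junctions(mesh))

#' Undirected junction list
#'
#' Each junction (edge) of the tiling, as a two-column matrix of vertex index
#' pairs with `i < j`, sorted lexicographically so downstream processing is
#' deterministic.
#'
#' @param mesh a `vm_mesh`.
#' @return integer matrix with columns `i`, `j`.
#' @export
mesh_junctions <- function(mesh) {
  fl <- mesh$flat
  from <- fl$idx0 + 1L
  to <- flat_next_vertex(fl)
  und <- cbind(i = pmin(from, to), j = pmax(from, to))
  und <- unique(und)
  und[order(und[, 1], und[, 2]), , drop = FALSE]
}

# vertex id at the next position around each loop, aligned with flat idx
flat_next_vertex <- function(fl) {
  nxt <- seq_along(fl$idx0) + 1L
  ends <- fl$ptr0[-1]                       # 0-based exclusive ends
  starts <- fl$ptr0[-length(fl$ptr0)] + 1L  # 1-based starts
  nxt[ends] <- starts
  fl$idx0[nxt] + 1L
}

#' Number of sides of every cell
#' @param mesh a `vm_mesh`.
#' @return integer vector, one entry per cell.
#' @export
cell_sides <- function(mesh) lengths(mesh$cells)

# Minimum-image displacement(s) on a periodic interval.
wrap_delta <- function(d, L) d - L * round(d / L)

#' Unwrapped vertex coordinates of one cell
#'
#' Reconstructs the loop in continuous coordinates by accumulating
#' minimum-image displacements from the first vertex, so that cells straddling
#' the periodic seam are handled exactly.
#'
#' @param mesh a `vm_mesh`.
#' @param alpha cell index.
#' @return numeric matrix `n x 2`.
#' @export
cell_polygon <- function(mesh, alpha) {
  loop <- mesh$cells[[alpha]]
  p <- mesh$v[loop, , drop = FALSE]
  dx <- wrap_delta(diff(p[, 1]), mesh$box[1])
  dy <- wrap_delta(diff(p[, 2]), mesh$box[2])
  cbind(p[1, 1] + cumsum(c(0, dx)), p[1, 2] + cumsum(c(0, dy)))
}

#' Cell area and perimeter
#'
#' Shoelace area and summed minimum-image edge lengths of the unwrapped
#' polygon. Area is positive for the counter-clockwise loops the mesh
#' maintains; a non-positive value indicates a corrupted (flipped or
#' self-intersecting) loop and raises an error.
#'
#' @param mesh a `vm_mesh`.
#' @param alpha cell index.
#' @return scalar area (nondimensional; the reference unit is 23 um^2).
#' @export
cell_area <- function(mesh, alpha) {
  p <- cell_polygon(mesh, alpha)
  n <- nrow(p)
  k1 <- c(2:n, 1)
  a <- 0.5 * sum(p[, 1] * p[k1, 2] - p[k1, 1] * p[, 2])
  if (!is.finite(a) || a <= 0) {
    stop(sprintf("degenerate loop in cell %d (signed area %.3g)", alpha, a))
  }
  a
}

#' @rdname cell_area
#' @export
cell_perimeter <- function(mesh, alpha) {
  p <- cell_polygon(mesh, alpha)
  n <- nrow(p)
  k1 <- c(2:n, 1)
  sum(sqrt((p[k1, 1] - p[, 1])^2 + (p[k1, 2] - p[, 2])^2))
}

#' Cell centroids, wrapped into the box
#' @param mesh a `vm_mesh`.
#' @return numeric matrix `N_c x 2`.
#' @export
cell_centroids <- function(mesh) {
  out <- matrix(0, n_cells(mesh), 2)
  for (a in seq_len(n_cells(mesh))) {
    p <- cell_polygon(mesh, a)
    n <- nrow(p)
    k1 <- c(2:n, 1)
    cr <- p[, 1] * p[k1, 2] - p[k1, 1] * p[, 2]
    A <- 0.5 * sum(cr)
    out[a, ] <- c(sum((p[, 1] + p[k1, 1]) * cr), sum((p[, 2] + p[k1, 2]) * cr)) / (6 * A)
  }
  cbind(out[, 1] %% mesh$box[1], out[, 2] %% mesh$box[2])
}

#' Build a defect-free hexagonal tiling of the torus
#'
#' Constructs a brick-wall hexagonal tiling with `n_rows x n_cols` six-sided
#' cells. Rows are offset by a fraction `q` of the cell width chosen so the
#' tiling closes periodically for any `n_rows >= 2` (`q = 1/2` for even row
#' counts, `(n_rows + 1) / (2 n_rows)` for odd ones, so odd grids such as
#' 15 x 15 close without defects). Every vertex is trivalent and every cell
#' has exactly six sides; shapes relax to near-regular hexagons under the
#' mechanics.
#'
#' @param n_rows,n_cols number of cell rows (AP) and columns (DV); both >= 2.
#' @param box optional box `(L_DV, L_AP)`; by default cells have unit area and
#'   near-regular proportions (`height/width = sqrt(3)/2`).
#' @return a `vm_mesh` with `n_rows * n_cols` cells.
#' @export
build_hexagonal_tissue <- function(n_rows, n_cols, box = NULL) {
  if (n_rows < 3 || n_cols < 2) {
    # two rows give vertical edges of exactly half the box height, where the
    # minimum-image convention is ambiguous
    stop("need at least 3 rows and 2 columns for periodic closure")
  }
  if (is.null(box)) {
    w <- sqrt(2 / sqrt(3))      # unit cell area with height/width = sqrt(3)/2
    h <- sqrt(3) / 2 * w
    box <- c(n_cols * w, n_rows * h)
  }
  w <- box[1] / n_cols
  h <- box[2] / n_rows
  q <- if (n_rows %% 2 == 0) 0.5 else (n_rows + 1) / (2 * n_rows)
  a <- ((seq_len(n_rows) - 1) * q) %% 1   # row offsets in units of w

  # vertex ids: per horizontal line r, corners (type 0) then T-points (type 1)
  vid <- function(r, type, c) {
    r <- r %% n_rows; c <- c %% n_cols
    2L * (r * n_cols + c) + type + 1L
  }
  nv <- 2L * n_rows * n_cols
  v <- matrix(0, nv, 2)
  for (r in 0:(n_rows - 1)) {
    rp <- (r - 1) %% n_rows
    for (c in 0:(n_cols - 1)) {
      v[vid(r, 0, c), ] <- c((a[r + 1] + c) * w, r * h)
      v[vid(r, 1, c), ] <- c((a[rp + 1] + c) * w, r * h)
    }
  }

  cells <- vector("list", n_rows * n_cols)
  for (r in 0:(n_rows - 1)) {
    rp <- (r - 1) %% n_rows
    rn <- (r + 1) %% n_rows
    kb_off <- floor(a[r + 1] - a[rp + 1]) + 1   # bottom T column offset
    kt_off <- floor(a[r + 1] - a[rn + 1]) + 1   # top interior corner offset
    for (c in 0:(n_cols - 1)) {
      cells[[r * n_cols + c + 1]] <- c(
        vid(r, 0, c), vid(r, 1, c + kb_off), vid(r, 0, c + 1),
        vid(rn, 1, c + 1), vid(rn, 0, c + kt_off), vid(rn, 1, c)
      )
    }
  }
  vm_mesh(v, cells, box)
}

#' Audit all mesh invariants
#'
#' Checks trivalence, the toroidal Euler relation (`V - E + F = 0`,
#' `2E = 3V`, mean side count 6), gap/overlap-free tiling (cell areas sum to
#' the box area), minimum side count, loop orientation, and consistency of
#' the two directed traversals of every junction.
#'
#' @param mesh a `vm_mesh`.
#' @return character vector of violations; `character(0)` means the mesh is
#'   sound.
#' @export
topology_audit <- function(mesh) {
  bad <- character(0)
  fl <- mesh$flat
  nc <- n_cells(mesh); nv <- n_vertices(mesh)

  if (any(lengths(mesh$cells) < 3)) {
    bad <- c(bad, "cell with fewer than 3 sides")
  }
  tab <- tabulate(fl$idx0 + 1L, nbins = nv)
  if (any(tab != 3L)) {
    bad <- c(bad, sprintf("%d vertices are not trivalent", sum(tab != 3L)))
  }
  # every directed edge must appear exactly once, and its reverse exactly once
  from <- fl$idx0 + 1L
  to <- flat_next_vertex(fl)
  key <- paste(from, to)
  if (anyDuplicated(key)) {
    bad <- c(bad, "duplicated directed edge (inconsistent loops)")
  }
  if (!setequal(key, paste(to, from))) {
    bad <- c(bad, "directed edge without reverse partner")
  }
  ne <- length(from) / 2
  if (nv - ne + nc != 0) {
    bad <- c(bad, sprintf("Euler relation violated: V-E+F = %g", nv - ne + nc))
  }
  areas <- try(vapply(seq_len(nc), function(a) cell_area(mesh, a), 0),
               silent = TRUE)
  if (inherits(areas, "try-error")) {
    bad <- c(bad, "non-positive or degenerate cell loop")
  } else {
    rel <- abs(sum(areas) - prod(mesh$box)) / prod(mesh$box)
    if (rel > 1e-8) {
      bad <- c(bad, sprintf("tiling gap/overlap: relative area defect %.3g", rel))
    }
  }
  bad
}
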