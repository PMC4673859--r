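# Triangulated surface meshes and in-plane propagation.
#
# A mesh is a set of triangular panels grouped into named surfaces. Each panel
# carries an orthonormal tangent frame (origin at its first vertex, first axis
# along vertex1 -> vertex2, normal fixed by vertex winding); molecule positions
# are (panel, local 2-D coordinates) in that frame. Shared edges are found by
# matching endpoint coordinates; unmatched edges are reflective boundaries.

#' Build a triangulated surface mesh
#'
#' Panels are matched into a mesh by identifying edges whose endpoints
#' coincide within `tolerance`. Edges matched to exactly one other panel
#' become crossable shared edges; unmatched edges are reflective boundaries.
#' An edge shared by more than two panels, a zero-area panel, or two panels
#' sharing more than one edge (coincident panels) is an error.
#'
#' @param panels list of 3x3 numeric matrices, one per panel; rows are the
#'   three vertices (x, y, z) in micrometres. Winding fixes the normal.
#' @param surfaces character vector of surface labels, recycled along panels.
#' @param tolerance endpoint-matching tolerance (micrometres).
#' @return an object of class `surface_mesh`.
#' @examples
#' sq <- list(rbind(c(0,0,0), c(1,0,0), c(1,1,0)),
#'            rbind(c(0,0,0), c(1,1,0), c(0,1,0)))
#' m <- build_mesh(sq, c("fast", "slow"))
#' m$surface_area
#' @export
build_mesh <- function(panels, surfaces = "surface", tolerance = 1e-9) {
  if (length(panels) < 1) stop("need at least one panel")
  if (!(tolerance > 0)) stop("tolerance must be > 0")
  np <- length(panels)
  surfaces <- rep_len(as.character(surfaces), np)
  surf_names <- unique(surfaces)
  surf_id <- match(surfaces, surf_names)

  V <- lapply(seq_len(np), function(i) {
    p <- as.matrix(panels[[i]])
    storage.mode(p) <- "double"
    if (!all(dim(p) == c(3L, 3L)))
      stop(sprintf("panel %d: expected a 3x3 vertex matrix", i))
    unname(p)
  })

  origin <- matrix(0, np, 3)
  e1 <- matrix(0, np, 3); e2 <- matrix(0, np, 3); nrm <- matrix(0, np, 3)
  bx <- numeric(np); cx <- numeric(np); cy <- numeric(np); area <- numeric(np)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (i in seq_len(np)) {
    v <- V[[i]]
    u <- v[2, ] - v[1, ]; w <- v[3, ] - v[1, ]
    n <- cross3(u, w)
    a2 <- sqrt(sum(n^2))
    scale <- max(sum(u^2), sum(w^2))
    if (scale == 0 || a2 <= 1e-12 * scale)
      stop(sprintf("panel %d is degenerate (zero area)", i))
    origin[i, ] <- v[1, ]
    e1[i, ] <- u / sqrt(sum(u^2))
    nrm[i, ] <- n / a2
    e2[i, ] <- cross3(nrm[i, ], e1[i, ])
    bx[i] <- sum(u * e1[i, ])
    cx[i] <- sum(w * e1[i, ])
    cy[i] <- sum(w * e2[i, ])
    area[i] <- a2 / 2
  }

  # edge matching via endpoint keys rounded at the tolerance scale
  digits <- max(0L, min(12L, as.integer(ceiling(-log10(tolerance)))))
  vkey <- function(x) {
    x <- round(x, digits)
    x[x == 0] <- 0  # normalise -0
    paste(sprintf("%.*f", digits, x), collapse = ",")
  }
  edge_from <- integer(0); edge_k <- integer(0)
  keys <- character(0); starts <- character(0)
  for (i in seq_len(np)) {
    v <- V[[i]]
    for (k in 1:3) {
      k2 <- k %% 3 + 1
      a <- vkey(v[k, ]); b <- vkey(v[k2, ])
      edge_from <- c(edge_from, i); edge_k <- c(edge_k, k)
      keys <- c(keys, paste(sort(c(a, b)), collapse = "|"))
      starts <- c(starts, a)
    }
  }
  edge_nb <- matrix(0L, np, 3)
  edge_nbe <- matrix(0L, np, 3)
  edge_flip <- matrix(0L, np, 3)
  grp <- split(seq_along(keys), keys)
  for (g in grp) {
    if (length(g) > 2) {
      stop(sprintf("edge shared by more than 2 panels (panels %s)",
                   paste(unique(edge_from[g]), collapse = ", ")))
    }
    if (length(g) == 2) {
      i <- g[1]; j <- g[2]
      pi_ <- edge_from[i]; pj <- edge_from[j]
      if (pi_ == pj)
        stop(sprintf("panel %d shares an edge with itself (degenerate)", pi_))
      edge_nb[pi_, edge_k[i]] <- pj
      edge_nbe[pi_, edge_k[i]] <- edge_k[j]
      edge_nb[pj, edge_k[j]] <- pi_
      edge_nbe[pj, edge_k[j]] <- edge_k[i]
      fl <- as.integer(starts[i] != starts[j])
      edge_flip[pi_, edge_k[i]] <- fl
      edge_flip[pj, edge_k[j]] <- fl
    }
  }
  # coincident panels share all three edges; more than one shared edge between
  # the same pair means the mesh is degenerate
  for (i in seq_len(np)) {
    nbs <- edge_nb[i, ][edge_nb[i, ] > 0]
    if (anyDuplicated(nbs))
      stop(sprintf("panels %d and %d share more than one edge (coincident or degenerate panels)",
                   i, nbs[duplicated(nbs)][1]))
  }

  surface_area <- vapply(seq_along(surf_names),
                         function(s) sum(area[surf_id == s]), numeric(1))
  names(surface_area) <- surf_names

  structure(list(
    np = np, nsurf = length(surf_names),
    surfaces = surf_names, surf = as.integer(surf_id),
    vertices = V,
    origin = origin, e1 = e1, e2 = e2, normal = nrm,
    bx = bx, cx = cx, cy = cy, area = area,
    edge_nb = edge_nb, edge_nbe = edge_nbe, edge_flip = edge_flip,
    surface_area = surface_area, tolerance = tolerance
  ), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d panels, %d surface(s)\n", x$np, x$nsurf))
  for (s in seq_along(x$surfaces))
    cat(sprintf("  %-12s %4d panels, area %.4g um^2\n", x$surfaces[s],
                sum(x$surf == s), x$surface_area[s]))
  nb <- sum(x$edge_nb == 0)
  cat(sprintf("  shared edges: %d, boundary edges: %d\n",
              sum(x$edge_nb > 0) / 2, nb))
  invisible(x)
}

#' Molecule position on a mesh
#'
#' A position is a panel identifier plus 2-D coordinates in that panel's
#' tangent frame (micrometres).
#'
#' @param panel panel index (1-based).
#' @param local numeric length-2 local coordinates.
#' @export
surface_position <- function(panel, local) {
  structure(list(panel = as.integer(panel), local = as.numeric(local)),
            class = "surface_position")
}

#' Convert a surface position to 3-D world coordinates
#'
#' Local (0, 0) maps to the panel's first vertex.
#'
#' @param pos a [surface_position()].
#' @param mesh a [build_mesh()] result.
#' @return numeric length-3 point (micrometres).
#' @export
to_world <- function(pos, mesh) {
  p <- pos$panel
  if (p < 1 || p > mesh$np) stop("unknown panel")
  mesh$origin[p, ] + pos$local[1] * mesh$e1[p, ] + pos$local[2] * mesh$e2[p, ]
}

#' Project a 3-D point into a panel's tangent frame
#'
#' Inverse of [to_world()] for points lying in the panel plane.
#'
#' @param point numeric length-3 world coordinates.
#' @param mesh a mesh.
#' @param panel panel index.
#' @export
from_world <- function(point, mesh, panel) {
  if (panel < 1 || panel > mesh$np) stop("unknown panel")
  d <- as.numeric(point) - mesh$origin[panel, ]
  surface_position(panel, c(sum(d * mesh$e1[panel, ]), sum(d * mesh$e2[panel, ])))
}

#' Local coordinates from barycentric weights
#'
#' @param mesh a mesh.
#' @param panel panel index.
#' @param w numeric length-3 barycentric weights (normalised internally).
#' @export
bary_to_local <- function(mesh, panel, w) {
  w <- w / sum(w)
  c(w[2] * mesh$bx[panel] + w[3] * mesh$cx[panel], w[3] * mesh$cy[panel])
}

#' Propagate an in-plane displacement across a mesh
#'
#' Straight-line motion in the starting panel's tangent plane; a shared edge
#' rotates the residual displacement into the neighbouring panel's plane
#' (geodesic unfolding), a boundary edge reflects it specularly. With
#' `confine = TRUE`, edges leading to a panel of a different surface are also
#' treated as reflective.
#'
#' @param start a [surface_position()].
#' @param displacement numeric length-2, in the start panel's frame (um).
#' @param mesh a mesh.
#' @param max_crossings error if more panels than this are entered.
#' @param confine reflect at surface-to-surface edges.
#' @param record_path also return the 3-D polyline travelled.
#' @return list with `position` (surface_position), `crossings` (data.frame of
#'   panels entered, with surfaces), and optionally `path` (matrix of 3-D
#'   points).
#' @export
propagate <- function(start, displacement, mesh, max_crossings = 1000,
                      confine = FALSE, record_path = FALSE) {
  if (max_crossings < 1) stop("max_crossings must be >= 1")
  if (start$panel < 1 || start$panel > mesh$np) stop("unknown panel")
  res <- propagate_cpp(mesh, start$panel, start$local,
                       as.numeric(displacement), as.integer(max_crossings),
                       confine, record_path)
  if (res$status != 0)
    stop("propagation exceeded max_crossings (step size too large for panel size)")
  cr <- data.frame(panel = res$crossings,
                   surface = mesh$surfaces[mesh$surf[res$crossings]],
                   stringsAsFactors = FALSE)
  out <- list(position = surface_position(res$panel, res$local), crossings = cr)
  if (record_path) out$path <- res$path
  out
}

#' Random positions on a surface
#'
#' Panels are chosen with probability proportional to area, points uniformly
#' within each panel. Consumes R's RNG stream.
#'
#' @param mesh a mesh.
#' @param n number of positions.
#' @param surface a surface name, or `"all"` for the whole mesh.
#' @return list with integer vector `panel` and n x 2 matrix `local`.
#' @export
random_positions <- function(mesh, n, surface = "all") {
  if (identical(surface, "all")) {
    idx <- seq_len(mesh$np)
  } else {
    s <- match(surface, mesh$surfaces)
    if (is.na(s)) stop(sprintf("unknown surface '%s'", surface))
    idx <- which(mesh$surf == s)
  }
  if (n == 0) return(list(panel = integer(0), local = matrix(0, 0, 2)))
  cum <- cumsum(mesh$area[idx])
  u <- runif(n) * cum[length(cum)]
  pick <- idx[findInterval(u, cum) + 1L]
  a <- runif(n); b <- runif(n)
  fold <- a + b > 1
  a[fold] <- 1 - a[fold]; b[fold] <- 1 - b[fold]
  local <- cbind(a * mesh$bx[pick] + b * mesh$cx[pick], b * mesh$cy[pick])
  list(panel = pick, local = local)
}

#' Export mesh panels as TSV
#'
#' One row per panel: panel id, surface, and the nine vertex coordinates.
#'
#' @param mesh a mesh.
#' @param path output file.
#' @export
export_panels_tsv <- function(mesh, path) {
  rows <- vapply(seq_len(mesh$np), function(i) {
    v <- mesh$vertices[[i]]
    paste(c(i, mesh$surfaces[mesh$surf[i]],
            sprintf("%.9g", as.vector(t(v)))), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("panel", "surface",
                       paste0(rep(c("x", "y", "z"), 3), rep(1:3, each = 3))),
                     collapse = "\t"), rows), path)
  invisible(path)
}
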