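#' Triangulated surface mesh
#'
#' Container for a triangulated cortical surface: an `m x 3` matrix of
#' vertex coordinates (mm) and a `k x 3` integer matrix of triangles
#' (1-based vertex indices).  The constructor validates the mesh
#' (index bounds, no repeated vertex within a triangle, no duplicate
#' vertex coordinates, edges shared by at most two triangles) and
#' precomputes the edge list and the 1-ring adjacency sets `N(i)` used
#' by the discrete Laplace-Beltrami operators.
#'
#' @param vertices numeric matrix, `m x 3`, one vertex per row (mm).
#' @param triangles integer matrix, `k x 3`, vertex indices (1-based).
#' @return An object of class `trimesh` with components `vertices`,
#'   `triangles`, `edges` (`E x 2`, each row sorted), `adjacency`
#'   (list of integer vectors, the 1-ring `N(i)`), and `edge_triangles`
#'   (`E x 2` incident triangle indices, `NA` for boundary edges).
#' @examples
#' tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' tet$adjacency[[1]]
#' @export
trimesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L)
    stop("vertices must be an m x 3 matrix")
  m <- nrow(vertices)
  if (m == 0L)
    stop("empty mesh")
  if (ncol(triangles) != 3L)
    stop("triangles must be a k x 3 matrix")
  if (nrow(triangles) > 0L) {
    if (anyNA(triangles) || min(triangles) < 1L || max(triangles) > m)
      stop("triangle vertex index out of range")
    rep_v <- triangles[, 1L] == triangles[, 2L] |
      triangles[, 1L] == triangles[, 3L] |
      triangles[, 2L] == triangles[, 3L]
    if (any(rep_v))
      stop("triangle ", which(rep_v)[1L], " repeats a vertex")
  }
  if (anyDuplicated(vertices))
    stop("two vertices share identical coordinates")

  ed <- .edge_table(triangles, m)
  structure(
    list(vertices = vertices, triangles = triangles,
         edges = ed$edges, edge_triangles = ed$edge_triangles,
         adjacency = ed$adjacency),
    class = "trimesh")
}

# Build unique edge list, per-edge incident triangles and 1-ring adjacency.
# Errors if any edge is shared by more than two triangles (non-manifold).
.edge_table <- function(triangles, m) {
  k <- nrow(triangles)
  if (k == 0L) {
    return(list(edges = matrix(integer(), 0L, 2L),
                edge_triangles = matrix(integer(), 0L, 2L),
                adjacency = rep(list(integer()), m)))
  }
  # three directed half-edges per triangle, endpoints sorted
  i1 <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  i2 <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  tri_id <- rep.int(seq_len(k), 3L)
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  key <- (as.double(lo) - 1) * m + as.double(hi)
  ord <- order(key)
  key <- key[ord]; lo <- lo[ord]; hi <- hi[ord]; tri_id <- tri_id[ord]
  first <- !duplicated(key)
  edge_id <- cumsum(first)
  n_edge <- edge_id[length(edge_id)]
  edges <- cbind(lo[first], hi[first])
  mult <- tabulate(edge_id, n_edge)
  if (any(mult > 2L))
    stop("non-manifold edge: edge (", edges[which(mult > 2L)[1L], 1L], ", ",
         edges[which(mult > 2L)[1L], 2L], ") belongs to more than 2 triangles")
  edge_triangles <- matrix(NA_integer_, n_edge, 2L)
  pos <- ifelse(first, 1L, 2L)
  edge_triangles[cbind(edge_id, pos)] <- tri_id
  adjacency <- lapply(split(c(edges[, 2L], edges[, 1L]),
                            factor(c(edges[, 1L], edges[, 2L]),
                                   levels = seq_len(m))),
                      function(x) sort(unique(x)))
  names(adjacency) <- NULL
  list(edges = edges, edge_triangles = edge_triangles, adjacency = adjacency)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a [trimesh()].
#' @return integer vertex count `m`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Validate a triangulated mesh
#'
#' Reports the connectivity diagnostics used before operator assembly:
#' connected components, boundary edges (one incident triangle),
#' non-manifold edges (more than two incident triangles -- always 0 for
#' meshes built by [trimesh()], which rejects them), degenerate
#' (zero-area) triangles, and isolated vertices.
#'
#' @param mesh a [trimesh()].
#' @return A list with counts `n_components`, `n_boundary_edges`,
#'   `n_nonmanifold_edges`, `n_degenerate_triangles`,
#'   `n_isolated_vertices` and a logical `clean` that is `TRUE` iff
#'   there is one component, no non-manifold edge and no degenerate
#'   triangle.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  m <- n_vertices(mesh)
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
  comp <- igraph::components(g)
  n_boundary <- sum(is.na(mesh$edge_triangles[, 2L]))
  areas <- .triangle_areas_cross(mesh)
  scale2 <- if (nrow(mesh$edges) > 0L)
    max(.edge_lengths(mesh))^2 else 1
  n_degen <- sum(areas <= 1e-12 * scale2)
  n_isolated <- sum(lengths(mesh$adjacency) == 0L)
  res <- list(
    n_components = as.integer(comp$no),
    n_boundary_edges = n_boundary,
    n_nonmanifold_edges = 0L,
    n_degenerate_triangles = n_degen,
    n_isolated_vertices = n_isolated)
  res$clean <- res$n_components == 1L && res$n_nonmanifold_edges == 0L &&
    res$n_degenerate_triangles == 0L
  res
}

.edge_lengths <- function(mesh) {
  d <- mesh$vertices[mesh$edges[, 1L], , drop = FALSE] -
    mesh$vertices[mesh$edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# cross-product triangle areas (used by validate_mesh and as test oracle)
.triangle_areas_cross <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(numeric())
  a <- mesh$vertices[tr[, 2L], , drop = FALSE] -
    mesh$vertices[tr[, 1L], , drop = FALSE]
  b <- mesh$vertices[tr[, 3L], , drop = FALSE] -
    mesh$vertices[tr[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}
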