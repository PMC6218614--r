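#' Stabilized Heron triangle area
#'
#' Area of a triangle from its three side lengths using Kahan's
#' numerically stabilized rearrangement of Heron's formula: with sides
#' sorted `a >= b >= c`,
#' `area = sqrt((a+(b+c)) * (c-(a-b)) * (c+(a-b)) * (a+(b-c))) / 4`.
#' Unlike the textbook form this does not lose all significant digits
#' on needle-like triangles.  Vectorized over triples.
#'
#' @param a,b,c side lengths (any order), all positive.
#' @param tol relative tolerance on the triangle inequality; violations
#'   beyond `tol * max(side)` raise an error, violations within it are
#'   clamped to zero area.
#' @return numeric vector of areas.
#' @examples
#' triangle_area_stable(3, 4, 5)  # 6
#' @export
triangle_area_stable <- function(a, b, c, tol = 1e-10) {
  if (any(a <= 0 | b <= 0 | c <= 0))
    stop("side lengths must be positive")
  hi <- pmax(a, b, c)
  lo <- pmin(a, b, c)
  mid <- (a + b + c) - hi - lo
  slack <- lo - (hi - mid)          # >= 0 iff triangle inequality holds
  if (any(slack < -tol * hi))
    stop("triangle inequality violated: sides (",
         paste(format(c(a[1], b[1], c[1])), collapse = ", "), ") ...")
  slack <- pmax(slack, 0)
  0.25 * sqrt((hi + (mid + lo)) * slack * (lo + (hi - mid)) *
                (hi + (mid - lo)))
}

#' Geometric quantities of a triangle mesh
#'
#' Precomputes everything the Laplace-Beltrami operators consume:
#' per-edge lengths, per-triangle areas (stabilized Heron), per-corner
#' cotangents, per-edge opposite-angle cotangents, per-vertex mixed
#' Voronoi areas and the total surface area.
#'
#' The mixed area of vertex `i` sums, over its incident triangles `T`:
#' the Voronoi region of `i` in `T` if `T` is non-obtuse;
#' `area(T) / 2` if the angle of `T` at `i` is obtuse; and
#' `area(T) / 4` if `T` is obtuse at another corner.  The Voronoi
#' region inside a non-obtuse triangle is evaluated by the circumcenter
#' decomposition `(|e1|^2 cot(opp1) + |e2|^2 cot(opp2)) / 8`, so the
#' mixed regions tile the surface exactly.  Angles whose cosine is
#' within `1e-12` of zero are treated as non-obtuse.
#'
#' @param mesh a [trimesh()].
#' @return An object of class `mesh_geometry`: `edge_lengths` (E),
#'   `triangle_areas` (k), `corner_cots` (`k x 3`, cotangent at each
#'   corner), `edge_cots` (`E x 2`, cotangents of the one or two angles
#'   opposite each edge; second column `NA` on boundary edges),
#'   `mixed_areas` (m), `total_area`.
#' @export
mesh_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  tr <- mesh$triangles
  m <- n_vertices(mesh)
  el <- .edge_lengths(mesh)
  if (any(el <= 0)) stop("zero-length edge")
  k <- nrow(tr)
  p1 <- mesh$vertices[tr[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[tr[, 2L], , drop = FALSE]
  p3 <- mesh$vertices[tr[, 3L], , drop = FALSE]
  s1 <- sqrt(rowSums((p2 - p3)^2))  # opposite corner 1
  s2 <- sqrt(rowSums((p1 - p3)^2))
  s3 <- sqrt(rowSums((p1 - p2)^2))
  areas <- triangle_area_stable(s1, s2, s3)
  if (any(areas <= 0))
    stop("degenerate triangle (zero area): triangle ",
         which(areas <= 0)[1L])
  # cot at corner c = (adjacent^2 sum - opposite^2) / (4 area)
  cot1 <- (s2^2 + s3^2 - s1^2) / (4 * areas)
  cot2 <- (s1^2 + s3^2 - s2^2) / (4 * areas)
  cot3 <- (s1^2 + s2^2 - s3^2) / (4 * areas)
  corner_cots <- cbind(cot1, cot2, cot3)

  # map triangle corners to edge rows: edge opposite corner 1 is (v2,v3)
  ekey <- function(i, j) (as.double(pmin(i, j)) - 1) * m + pmax(i, j)
  edge_key <- ekey(mesh$edges[, 1L], mesh$edges[, 2L])
  e_opp1 <- match(ekey(tr[, 2L], tr[, 3L]), edge_key)
  e_opp2 <- match(ekey(tr[, 1L], tr[, 3L]), edge_key)
  e_opp3 <- match(ekey(tr[, 1L], tr[, 2L]), edge_key)
  n_edge <- nrow(mesh$edges)
  edge_cots <- matrix(NA_real_, n_edge, 2L)
  all_er <- c(e_opp1, e_opp2, e_opp3)
  all_ct <- c(cot1, cot2, cot3)
  ord <- order(all_er)
  col <- ifelse(duplicated(all_er[ord]), 2L, 1L)  # at most 2 per edge
  edge_cots[cbind(all_er[ord], col)] <- all_ct[ord]

  # mixed Voronoi areas
  cosines <- cbind((s2^2 + s3^2 - s1^2) / (2 * s2 * s3),
                   (s1^2 + s3^2 - s2^2) / (2 * s1 * s3),
                   (s1^2 + s2^2 - s3^2) / (2 * s1 * s2))
  obtuse_at <- apply(cosines, 1L, function(x) {
    w <- which(x < -1e-12)
    if (length(w)) w[1L] else 0L
  })
  contrib <- matrix(0, k, 3L)
  nonobt <- obtuse_at == 0L
  if (any(nonobt)) {
    # Voronoi area at corner: (1/8) * sum over the two incident edges of
    # |edge|^2 * cot(angle opposite that edge)
    contrib[nonobt, 1L] <- (s3[nonobt]^2 * cot3[nonobt] +
                              s2[nonobt]^2 * cot2[nonobt]) / 8
    contrib[nonobt, 2L] <- (s3[nonobt]^2 * cot3[nonobt] +
                              s1[nonobt]^2 * cot1[nonobt]) / 8
    contrib[nonobt, 3L] <- (s2[nonobt]^2 * cot2[nonobt] +
                              s1[nonobt]^2 * cot1[nonobt]) / 8
  }
  for (c in 1:3) {
    obt <- obtuse_at == c
    if (any(obt)) {
      contrib[obt, c] <- areas[obt] / 2
      contrib[obt, -c] <- areas[obt] / 4
    }
  }
  mixed <- numeric(m)
  for (c in 1:3) {
    s <- rowsum(contrib[, c], group = tr[, c])
    ids <- as.integer(rownames(s))
    mixed[ids] <- mixed[ids] + s[, 1L]
  }

  structure(
    list(edge_lengths = el, triangle_areas = areas,
         corner_cots = corner_cots, edge_cots = edge_cots,
         obtuse_at = obtuse_at,
         mixed_areas = mixed, total_area = sum(areas)),
    class = "mesh_geometry")
}

#' @export
print.mesh_geometry <- function(x, ...) {
  cat(sprintf(
    "mesh_geometry: %d edges, %d triangles, total area %.6g mm^2\n",
    length(x$edge_lengths), length(x$triangle_areas), x$total_area))
  invisible(x)
}

# row index of an edge (i, j) in mesh$edges, error if absent
.edge_row <- function(mesh, edge) {
  i <- min(edge[1L], edge[2L]); j <- max(edge[1L], edge[2L])
  r <- which(mesh$edges[, 1L] == i & mesh$edges[, 2L] == j)
  if (!length(r)) stop("edge (", i, ", ", j, ") not in mesh")
  r[1L]
}

#' Cotangents of the angles opposite an edge
#'
#' Returns the cotangent(s) of the angle(s) opposite the edge in its
#' one (boundary) or two (interior) incident triangles.
#'
#' @param mesh a [trimesh()].
#' @param geometry the matching [mesh_geometry()].
#' @param edge length-2 integer vector of vertex indices.
#' @return numeric vector of length 1 (boundary edge) or 2.
#' @export
cotangent_pair <- function(mesh, geometry, edge) {
  r <- .edge_row(mesh, edge)
  ct <- geometry$edge_cots[r, ]
  ct[!is.na(ct)]
}

#' Mixed Voronoi area of a vertex
#'
#' @param mesh a [trimesh()].
#' @param geometry the matching [mesh_geometry()].
#' @param vertex vertex index.
#' @return the mixed area (mm^2); errors on isolated vertices.
#' @export
mixed_area <- function(mesh, geometry, vertex) {
  if (length(mesh$adjacency[[vertex]]) == 0L)
    stop("vertex ", vertex, " is isolated")
  geometry$mixed_areas[vertex]
}
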