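#' Quasi-equidistant spherical electrode montage
#'
#' Places `n_sensors` electrodes on a spherical cap with a
#' deterministic Fibonacci-spiral construction, giving a dense,
#' near-equidistant layout (the synthetic analogue of a geodesic
#' sensor net).
#'
#' @param n_sensors number of electrodes (>= 4).
#' @param head_radius scalp sphere radius (mm).
#' @param polar_coverage angular extent of the cap in degrees, measured
#'   from the vertex (`180` covers the whole sphere).
#' @return An object of class `montage`: a data frame with columns
#'   `label`, `x`, `y`, `z` (mm) and attribute `head_radius`.
#' @examples
#' mon <- make_montage(127, head_radius = 85, polar_coverage = 130)
#' @export
make_montage <- function(n_sensors, head_radius = 85, polar_coverage = 130) {
  if (n_sensors < 4) stop("need at least 4 sensors")
  if (polar_coverage <= 0 || polar_coverage > 180)
    stop("polar_coverage must be in (0, 180] degrees")
  zmin <- cos(polar_coverage * pi / 180)
  k <- seq_len(n_sensors)
  z <- 1 - (k - 0.5) / n_sensors * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- head_radius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  df <- data.frame(label = sprintf("E%03d", k),
                   x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                   stringsAsFactors = FALSE)
  structure(df, head_radius = head_radius, class = c("montage", "data.frame"))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("montage: %d sensors on a %.4g mm sphere\n",
              nrow(x), attr(x, "head_radius")))
  invisible(x)
}

.montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

#' Read / write an electrode montage
#'
#' Plain whitespace-delimited text, one sensor per line:
#' `label x y z` (mm).  The head radius is recovered as the mean
#' sensor norm on read.
#'
#' @param path file path.
#' @return [read_montage()] returns a `montage`;
#'   [write_montage()] returns `path` invisibly.
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$label)) stop("duplicate sensor labels")
  r <- mean(sqrt(df$x^2 + df$y^2 + df$z^2))
  structure(df, head_radius = r, class = c("montage", "data.frame"))
}

#' @rdname read_montage
#' @param montage a `montage`.
#' @export
write_montage <- function(montage, path) {
  writeLines(sprintf("%s %.17g %.17g %.17g", montage$label,
                     montage$x, montage$y, montage$z), path)
  invisible(path)
}

# Closed-form surface potential of a current dipole in a homogeneous
# conducting sphere (insulating exterior), derived from the Legendre
# series of the interior Neumann problem:
#   phi(r) = (1 / 4 pi sigma) q . [ 2 (r - r0) / d^3
#            + ( r / a + (r - r0) / d ) / (a F) ],
#   F = a + d - (r . r0) / a,
# with electrode r on the sphere |r| = a, dipole moment q at r0, and
# d = |r - r0|.  Inputs in meters; returns the n x 3 matrix of
# potentials per unit moment along x, y, z (volts per A m).
.dipole_potential_sphere <- function(elec, r0, a, conductivity) {
  dvec <- sweep(elec, 2L, r0)
  d <- sqrt(rowSums(dvec^2))
  F <- a + d - as.numeric(elec %*% r0) / a
  G <- 2 * dvec / d^3 + (elec / a + dvec / d) / (a * F)
  G / (4 * pi * conductivity)
}

#' Analytic spherical-head leadfield
#'
#' Leadfield matrix of unit current dipoles at the source positions,
#' computed with the closed-form potential of a dipole inside a
#' homogeneous conducting sphere whose surface carries the electrodes.
#' All columns are re-referenced to the average reference, so each
#' column sums to zero across channels.  Units: positions mm, dipole
#' moments nA m, potentials microvolts.
#'
#' @param montage a [make_montage()] (or any `montage`).
#' @param sources an `m x 3` matrix of source positions (mm) or a
#'   [trimesh()] whose vertices are used.  All sources must lie
#'   strictly inside the scalp sphere.
#' @param conductivity scalar tissue conductivity (S/m).
#' @return An object of class `leadfield`: an `n x 3m` matrix whose
#'   columns are grouped per source as (x, y, z) unit-dipole
#'   topographies, with attributes `n_sources`, `reference`
#'   (`"average"`) and `source_positions`.
#' @export
spherical_leadfield <- function(montage, sources, conductivity = 0.33) {
  if (inherits(sources, "trimesh")) sources <- sources$vertices
  sources <- as.matrix(sources)
  stopifnot(ncol(sources) == 3L)
  a_mm <- attr(montage, "head_radius")
  rad <- sqrt(rowSums(sources^2))
  if (any(rad >= a_mm * (1 - 1e-9)))
    stop("source on or outside the scalp sphere (max radius ",
         format(max(rad)), " mm, scalp ", format(a_mm), " mm)")
  elec <- .montage_positions(montage) * 1e-3  # m
  a <- a_mm * 1e-3
  m <- nrow(sources)
  n <- nrow(elec)
  L <- matrix(0, n, 3L * m)
  for (j in seq_len(m)) {
    blk <- .dipole_potential_sphere(elec, sources[j, ] * 1e-3, a,
                                    conductivity)
    # V per (A m) -> uV per (nA m): 1e6 * 1e-9
    L[, (3L * j - 2L):(3L * j)] <- blk * 1e-3
  }
  L <- sweep(L, 2L, colMeans(L))  # average reference
  structure(L, n_sources = m, reference = "average",
            source_positions = sources, class = c("leadfield", "matrix"))
}

#' Read / write a leadfield matrix
#'
#' Plain text: a header line `"n m"` (channels, sources) followed by
#' `n` rows of `3 m` numbers at full double precision, so a round trip
#' is bit-lossless.
#'
#' @param path file path.
#' @return [read_leadfield()] returns a `leadfield` matrix;
#'   [write_leadfield()] returns `path` invisibly.
#' @export
read_leadfield <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(path, ": no header")
  hdr <- .parse_nums(lines[1], 1L, path, 2)
  n <- as.integer(hdr[1]); m <- as.integer(hdr[2])
  if (length(lines) - 1L != n)
    stop(path, ": header claims ", n, " channels but file has ",
         length(lines) - 1L, " rows")
  L <- t(vapply(seq_len(n), function(i)
    .parse_nums(lines[1L + i], 1L + i, path, 3L * m), numeric(3L * m)))
  if (n == 1L) L <- matrix(L, nrow = 1L)
  structure(L, n_sources = m, reference = "unknown",
            class = c("leadfield", "matrix"))
}

#' @rdname read_leadfield
#' @param L a leadfield matrix (`n x 3m`).
#' @export
write_leadfield <- function(L, path) {
  m <- ncol(L) / 3L
  if (m != round(m)) stop("leadfield must have 3m columns")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(L), as.integer(m)), con)
  for (i in seq_len(nrow(L)))
    writeLines(paste(sprintf("%.17g", L[i, ]), collapse = " "), con)
  invisible(path)
}
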