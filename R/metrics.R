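#' Residual variance and goodness of fit
#'
#' `RV = sum((b - bhat)^2) / sum(b^2)` -- the fraction of data power
#' the reconstruction leaves unexplained -- and
#' `GOF = 100 * (1 - RV)` in percent.  `GOF = 100` means a perfect
#' fit, `GOF = 0` (i.e. `bhat = 0`) means the model explains nothing;
#' negative GOF is possible when `RV > 1`.
#'
#' @param b measured channel data (non-zero vector).
#' @param bhat reconstructed channel data, same length.
#' @return `residual_variance()`: RV as a fraction;
#'   `goodness_of_fit()`: GOF in percent.
#' @export
residual_variance <- function(b, bhat) {
  if (length(b) != length(bhat)) stop("length mismatch")
  denom <- sum(b^2)
  if (denom == 0) stop("b is all zeros")
  sum((b - bhat)^2) / denom
}

#' @rdname residual_variance
#' @export
goodness_of_fit <- function(b, bhat) {
  100 * (1 - residual_variance(b, bhat))
}

#' Similarity between two source-power distributions
#'
#' Residual-variance-style deviation between normed source-power
#' vectors (each in `[0, 1]`):
#' `100 * sum((ref - test)^2) / sum(ref^2)` percent.  `0` means the
#' solutions are identical; values above 100 are possible.  Used to
#' quantify how far a Laplacian-regularized solution deviates from the
#' no-Laplacian reference.
#'
#' @param power_ref reference normed power vector (not all-zero).
#' @param power_test comparison normed power vector, same length.
#' @return percent deviation.
#' @export
solution_similarity <- function(power_ref, power_test) {
  if (length(power_ref) != length(power_test)) stop("length mismatch")
  denom <- sum(power_ref^2)
  if (denom == 0) stop("reference power is all zeros")
  100 * sum((power_ref - power_test)^2) / denom
}

#' Normed per-node source power
#'
#' Per node, the squared Euclidean norm of the (x, y, z) dipole moment
#' (`type = "power"`, the default) or the plain norm
#' (`type = "amplitude"`), normalized by the maximum so values lie in
#' `[0, 1]`.  An all-zero estimate maps to all zeros.
#'
#' @param estimate a `source_estimate`, or a `3m` vector / `3m x 1`
#'   matrix of moments.
#' @param type `"power"` or `"amplitude"`.
#' @param normalize divide by the maximum (default `TRUE`).
#' @return numeric vector of length `m`.
#' @export
node_power <- function(estimate, type = c("power", "amplitude"),
                       normalize = TRUE) {
  type <- match.arg(type)
  J <- if (inherits(estimate, "source_estimate")) estimate$J else estimate
  J <- as.numeric(J)
  if (length(J) %% 3L != 0L) stop("estimate length must be 3m")
  m <- length(J) / 3L
  Jm <- matrix(J, nrow = 3L)
  p <- colSums(Jm^2)
  if (type == "amplitude") p <- sqrt(p)
  if (normalize) {
    mx <- max(p)
    if (mx > 0) p <- p / mx
  }
  p
}

#' 50 percent activity mask
#'
#' Sets every entry strictly below `fraction` of the maximum to zero;
#' entries at exactly the threshold survive.  Idempotent, never changes
#' the argmax, never increases a value.
#'
#' @param power non-negative activity vector.
#' @param fraction mask level relative to the maximum (default 0.5).
#' @return the masked vector.
#' @export
threshold_mask <- function(power, fraction = 0.5) {
  mx <- max(power)
  if (mx <= 0) return(power)
  ifelse(power < fraction * mx, 0, power)
}

#' Center of mass of an activity distribution
#'
#' Power-weighted mean of the node positions over the (usually
#' 50-percent-masked) support.
#'
#' @param positions `m x 3` node positions (mm).
#' @param masked_power non-negative weights with at least one positive
#'   entry.
#' @return length-3 position (mm).
#' @export
center_of_mass <- function(positions, masked_power) {
  if (sum(masked_power) <= 0) stop("all-zero mask")
  as.numeric(crossprod(as.matrix(positions), masked_power) /
               sum(masked_power))
}

#' Maximum-amplitude location
#'
#' The mesh node with the maximal activity; ties are broken by the
#' lowest node index (deterministic).
#'
#' @param positions `m x 3` node positions (mm).
#' @param power activity vector of length `m`.
#' @return list with `index` and `point` (length-3, mm).
#' @export
max_amplitude_location <- function(positions, power) {
  if (!length(power)) stop("empty power vector")
  i <- which.max(power)  # first maximum
  list(index = i, point = as.numeric(positions[i, ]))
}

#' Localization error
#'
#' Euclidean distance between estimated and simulated source locations.
#'
#' @param est_point,true_point length-3 positions (mm).
#' @return distance (mm).
#' @export
localization_error <- function(est_point, true_point) {
  sqrt(sum((est_point - true_point)^2))
}

#' Source depth
#'
#' Distance between a source (simulated or estimated) and the nearest
#' sensor of the montage.
#'
#' @param point length-3 position (mm).
#' @param montage a `montage`.
#' @return depth (mm).
#' @export
source_depth <- function(point, montage) {
  pos <- .montage_positions(montage)
  if (!nrow(pos)) stop("empty montage")
  min(sqrt(rowSums(sweep(pos, 2L, point)^2)))
}

#' Depth shift
#'
#' `depth_sim - depth_est` (mm, signed): positive when the simulated
#' source was deeper than the estimated one, i.e. the estimate is
#' biased toward the surface.
#'
#' @param depth_sim,depth_est non-negative depths (mm).
#' @return signed shift (mm).
#' @export
depth_shift <- function(depth_sim, depth_est) {
  depth_sim - depth_est
}

#' Count local maxima of a nodal field
#'
#' A local maximum is a mesh node whose amplitude is strictly larger
#' than that of every 1-ring neighbor; the count proxies the number of
#' false-positive source blobs.
#'
#' @param mesh a [trimesh()].
#' @param power activity vector, one value per mesh vertex.
#' @return integer count.
#' @export
count_local_maxima <- function(mesh, power) {
  if (length(power) != n_vertices(mesh))
    stop("power length must equal the vertex count")
  sum(vapply(seq_along(power), function(i) {
    nb <- mesh$adjacency[[i]]
    length(nb) > 0L && all(power[i] > power[nb])
  }, logical(1)))
}

#' Full per-dataset comparison measures
#'
#' Computes every comparison measure for one estimate of a
#' single-source dataset: COM- and MA-based localization errors and
#' depth shifts (on the 50-percent-masked normed power), source depths,
#' local-maxima count (unmasked power), residual variance, goodness of
#' fit, and optionally the similarity deviation from a reference power
#' distribution.
#'
#' @param J source-moment vector (`3m`) or `source_estimate`.
#' @param b measured data vector.
#' @param bhat reconstructed data vector.
#' @param mesh the source-space [trimesh()].
#' @param montage the sensor `montage`.
#' @param true_point simulated source position (length-3, mm).
#' @param reference_power optional normed power of the no-Laplacian
#'   solution for the similarity measure.
#' @param power_type `"power"` or `"amplitude"` (see [node_power()]).
#' @return a one-row `data.frame` with the metric columns.
#' @export
compute_metrics <- function(J, b, bhat, mesh, montage, true_point,
                            reference_power = NULL,
                            power_type = "power") {
  pw <- node_power(J, type = power_type)
  masked <- threshold_mask(pw)
  pos <- mesh$vertices
  com <- center_of_mass(pos, masked)
  ma <- max_amplitude_location(pos, masked)
  d_sim <- source_depth(true_point, montage)
  d_com <- source_depth(com, montage)
  d_ma <- source_depth(ma$point, montage)
  rv <- residual_variance(b, bhat)
  data.frame(
    localization_error_com = localization_error(com, true_point),
    localization_error_ma = localization_error(ma$point, true_point),
    depth_sim = d_sim,
    depth_est_com = d_com,
    depth_est_ma = d_ma,
    depth_shift_com = depth_shift(d_sim, d_com),
    depth_shift_ma = depth_shift(d_sim, d_ma),
    n_local_maxima = count_local_maxima(mesh, pw),
    rv = rv,
    gof = 100 * (1 - rv),
    similarity_to_reference = if (is.null(reference_power)) NA_real_
    else solution_similarity(reference_power, pw))
}
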