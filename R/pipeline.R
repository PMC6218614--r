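#' Simulation source space of a cortical mesh
#'
#' Positions used to *simulate* sources: the barycenters of the
#' inverse mesh's triangles.  They lie on the discrete surface but
#' never coincide with a source-space node, which avoids the inverse
#' crime (evaluating the inverse on data generated from its own
#' discretization).
#'
#' @param mesh the inverse-space [trimesh()].
#' @return a `k x 3` matrix of simulation positions (mm).
#' @export
simulation_source_space <- function(mesh) {
  tr <- mesh$triangles
  bc <- (mesh$vertices[tr[, 1L], , drop = FALSE] +
           mesh$vertices[tr[, 2L], , drop = FALSE] +
           mesh$vertices[tr[, 3L], , drop = FALSE]) / 3
  dmin <- min(vapply(seq_len(nrow(bc)), function(i)
    min(rowSums(sweep(mesh$vertices[tr[i, ], , drop = FALSE],
                      2L, bc[i, ])^2)), numeric(1)))
  if (dmin <= 0)
    stop("inverse crime: simulation position coincides with a mesh node")
  bc
}

#' Add channel noise at an exact signal-to-noise ratio
#'
#' Adds zero-mean white Gaussian noise rescaled so that
#' `RMS(signal) / RMS(noise)` equals `snr` exactly.  The noise is
#' re-referenced to the average reference before scaling so noisy data
#' stay average-referenced.  `snr = Inf` returns the input unchanged.
#'
#' @param clean clean channel vector (microvolts).
#' @param snr positive signal-to-noise ratio (RMS ratio), or `Inf`.
#' @param seed integer seed (deterministic noise).
#' @return noisy channel vector.
#' @export
add_noise <- function(clean, snr, seed) {
  if (!(snr > 0)) stop("snr must be positive")
  if (is.infinite(snr)) return(clean)
  .with_seed(seed, {
    e <- stats::rnorm(length(clean))
    e <- e - mean(e)
    e <- e * sqrt(sum(clean^2) / sum(e^2)) / snr
    clean + e
  })
}

#' Simulate single-dipole EEG datasets
#'
#' Draws `n_datasets` source positions from the simulation source
#' space (triangle barycenters -- see [simulation_source_space()]),
#' gives each a random unit orientation scaled by `moment_magnitude`,
#' computes the clean channel data through the analytic spherical
#' leadfield at the *simulation* positions (never the inverse
#' leadfield), and optionally adds noise at an exact SNR.  Exactly one
#' source is active per dataset.  Fully deterministic under `seed`.
#'
#' @param mesh the inverse-space [trimesh()].
#' @param montage the sensor `montage`.
#' @param n_datasets number of datasets (>= 1).
#' @param moment_magnitude dipole moment magnitude (nA m).
#' @param seed integer seed.
#' @param snr signal-to-noise ratio (`Inf` = noiseless).
#' @param conductivity head conductivity (S/m), as in
#'   [spherical_leadfield()].
#' @return list of datasets, each a list with `true_position`,
#'   `moment` (length-3, nA m), `clean`, `data` (noisy or clean),
#'   `snr`, `seed`.
#' @export
simulate_datasets <- function(mesh, montage, n_datasets,
                              moment_magnitude = 10, seed = 1,
                              snr = Inf, conductivity = 0.33) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  sim_pos <- simulation_source_space(mesh)
  draws <- .with_seed(seed, {
    idx <- sample.int(nrow(sim_pos), n_datasets,
                      replace = n_datasets > nrow(sim_pos))
    ori <- matrix(stats::rnorm(3L * n_datasets), n_datasets, 3L)
    ori <- ori / sqrt(rowSums(ori^2))
    noise_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
    list(idx = idx, ori = ori, noise_seeds = noise_seeds)
  })
  Lsim <- spherical_leadfield(montage, sim_pos[draws$idx, , drop = FALSE],
                              conductivity = conductivity)
  lapply(seq_len(n_datasets), function(i) {
    mom <- moment_magnitude * draws$ori[i, ]
    blk <- unclass(Lsim)[, (3L * i - 2L):(3L * i), drop = FALSE]
    clean <- as.numeric(blk %*% mom)
    list(true_position = sim_pos[draws$idx[i], ],
         moment = mom,
         clean = clean,
         data = add_noise(clean, snr, draws$noise_seeds[i]),
         snr = snr,
         seed = draws$noise_seeds[i])
  })
}

#' Select sigma from scan tables
#'
#' The satisfying set contains every `sigma` whose cortical solution
#' keeps `GOF >= gof_min` percent *and* deviates from the no-Laplacian
#' solution by at least `dev_min` percent, for every `alpha` in the
#' grid.  `sigma_star` is the arithmetic mean of the satisfying set
#' (e.g. a set `{0.07, 0.06, 0.05, 0.04, 0.03}` selects `0.05`).
#'
#' @param gof,deviation matrices (`|sigma| x |alpha|`) of GOF and
#'   similarity-deviation percentages.
#' @param sigma_grid the sigma values indexing the rows.
#' @param gof_min,dev_min the two acceptance thresholds (percent).
#' @return list with `satisfying` (sigma values), `sigma_star`
#'   (`NA` when empty) and `no_admissible` flag.
#' @export
select_sigma <- function(gof, deviation, sigma_grid,
                         gof_min = 90, dev_min = 10) {
  ok <- apply(gof >= gof_min & deviation >= dev_min, 1L, all)
  satisfying <- sigma_grid[ok]
  list(satisfying = satisfying,
       sigma_star = if (length(satisfying)) mean(satisfying) else NA_real_,
       no_admissible = !any(ok))
}

#' Scan sigma against GOF and similarity deviation
#'
#' For every combination of `sigma` and `alpha`, computes the cortical
#' LORETA estimate (truncated-SVD operator with tolerance ratio
#' `alpha`), its goodness of fit to the data, and the deviation of its
#' normed source power from the depth-weighted no-Laplacian estimate
#' at the same `alpha`.  Large `sigma` attenuates the Laplacian (small
#' deviation); small `sigma` smooths strongly (low GOF).  The selected
#' `sigma_star` is the mean of the satisfying set; an empty set is
#' flagged `no_admissible`.  With `refine = TRUE` a second, linearly
#' spaced pass over the satisfying interval of the first stage is run.
#'
#' @param L inverse-space leadfield.
#' @param mesh the source-space [trimesh()].
#' @param scheme Laplace-Beltrami scheme (see [laplacian_schemes()]).
#' @param data measured channel vector.
#' @param sigma_grid positive sigma values (typically log-spaced).
#' @param alpha_grid tSVD tolerance ratios in `(0, 1]`.
#' @param omega depth weights (defaults to [depth_weights()] of `L`).
#' @param gof_min,dev_min selection thresholds (percent).
#' @param refine run the two-stage (log then linear) refinement.
#' @param power_type see [node_power()].
#' @return An object of class `sigma_scan`: `gof` and `deviation`
#'   tables (`|sigma| x |alpha|`), `sigma_grid`, `alpha_grid`,
#'   `satisfying`, `sigma_star`, `no_admissible`, and `stage1` (the
#'   coarse scan) when refined.
#' @export
sigma_scan <- function(L, mesh, scheme, data, sigma_grid, alpha_grid,
                       omega = depth_weights(L), gof_min = 90,
                       dev_min = 10, refine = FALSE,
                       power_type = "power") {
  if (!length(sigma_grid) || !length(alpha_grid)) stop("empty grid")
  if (any(sigma_grid <= 0)) stop("sigma values must be positive")
  stiff <- assemble_stiffness(mesh, scheme)
  w0 <- build_weighting(omega = omega, mode = "depth-only")
  p_ref <- lapply(alpha_grid, function(a) {
    est <- estimate_sources(inverse_operator_tsvd(L, w0, a), data)
    node_power(est, type = power_type)
  })
  gof <- dev <- matrix(NA_real_, length(sigma_grid), length(alpha_grid),
                       dimnames = list(signif(sigma_grid, 6),
                                       signif(alpha_grid, 6)))
  for (si in seq_along(sigma_grid)) {
    w <- build_weighting(omega = omega, B = stiff,
                         sigma = sigma_grid[si], mode = "cortical")
    for (ai in seq_along(alpha_grid)) {
      est <- estimate_sources(inverse_operator_tsvd(L, w, alpha_grid[ai]),
                              data, L = L)
      gof[si, ai] <- goodness_of_fit(data, est$bhat)
      dev[si, ai] <- solution_similarity(
        p_ref[[ai]], node_power(est, type = power_type))
    }
  }
  sel <- select_sigma(gof, dev, sigma_grid, gof_min, dev_min)
  res <- structure(
    c(list(gof = gof, deviation = dev, sigma_grid = sigma_grid,
           alpha_grid = alpha_grid, scheme = scheme), sel),
    class = "sigma_scan")
  if (refine && !res$no_admissible && length(res$satisfying) > 1L) {
    sub <- seq(min(res$satisfying), max(res$satisfying), length.out = 11L)
    res2 <- sigma_scan(L, mesh, scheme, data, sub, alpha_grid,
                       omega = omega, gof_min = gof_min,
                       dev_min = dev_min, refine = FALSE,
                       power_type = power_type)
    res2$stage1 <- res
    return(res2)
  }
  res
}

#' @export
print.sigma_scan <- function(x, ...) {
  cat(sprintf("sigma scan ('%s'): %d sigma x %d alpha; sigma* = %s\n",
              x$scheme, length(x$sigma_grid), length(x$alpha_grid),
              if (x$no_admissible) "none admissible"
              else format(x$sigma_star)))
  invisible(x)
}

#' Choose the SVD cutoff index for one dataset
#'
#' For each candidate SCI, derives `alpha` from the operator's
#' singular spectrum ([alpha_from_sci()]), builds the truncated-SVD
#' inverse, and evaluates the MA localization error and the
#' local-maxima count.  The chosen SCI minimizes the localization
#' error; ties are broken by fewer local maxima, then by the smaller
#' SCI.
#'
#' @param L inverse-space leadfield.
#' @param w a [build_weighting()] object (cortical or depth-only).
#' @param mesh the source-space [trimesh()].
#' @param montage the sensor `montage`.
#' @param dataset one dataset from [simulate_datasets()] (needs
#'   `true_position` and `data`).
#' @param sci_list integer candidate cutoff indices.
#' @param power_type see [node_power()].
#' @return list with `sci`, `alpha` and the per-candidate `table`.
#' @export
alpha_selection <- function(L, w, mesh, montage, dataset, sci_list,
                            power_type = "power") {
  base <- inverse_operator_tsvd(L, w, beta = .Machine$double.eps)
  sv <- base$singular_values
  rows <- lapply(sci_list, function(sci) {
    a <- alpha_from_sci(sv, sci)
    est <- estimate_sources(inverse_operator_tsvd(L, w, a$alpha), dataset$data)
    pw <- node_power(est, type = power_type)
    ma <- max_amplitude_location(mesh$vertices, threshold_mask(pw))
    data.frame(sci = sci, scv = a$scv, alpha = a$alpha,
               localization_error_ma =
                 localization_error(ma$point, dataset$true_position),
               n_local_maxima = count_local_maxima(mesh, pw))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$localization_error_ma, tab$n_local_maxima, tab$sci)
  list(sci = tab$sci[ord[1L]], alpha = tab$alpha[ord[1L]], table = tab)
}

#' Benchmark configuration
#'
#' Bundles every knob of the simulation benchmark with the default
#' study conditions: a corrugated cortex-like surface of about 1,000
#' nodes, 64 sensors, 100 noiseless single-dipole datasets, all four
#' Laplace-Beltrami schemes with per-scheme `sigma`, and SCI = 1 for
#' the tSVD tolerance.
#'
#' @param target_nodes,corrugation_amplitude,corrugation_frequency,axis_scales,cortex_radius,mesh_seed
#'   cortex generator settings (see [make_cortex_surface()]).
#' @param n_sensors,head_radius,polar_coverage montage settings.
#' @param conductivity head conductivity (S/m).
#' @param n_datasets,moment_magnitude,snr,seed simulation settings.
#' @param schemes Laplacian schemes to benchmark (beside the
#'   no-Laplacian reference).
#' @param sigma either `NULL` (the default) -- derive each scheme's
#'   sigma at run time by the sigma-scan selection procedure on a
#'   bilateral two-dipole dataset at `scan_snr` -- or a named vector of
#'   fixed per-scheme sigma values.
#' @param scan_snr,scan_alpha_grid,scan_decades settings of the
#'   sigma-derivation scan: SNR of its noisy dataset, tSVD tolerance
#'   ratios, and the number of log10 decades below `eta^2` covered by
#'   the coarse grid.
#' @param sqrt_depth_weights use column-norm depth weights (the
#'   original LORETA convention) instead of the column-energy variant;
#'   see [depth_weights()].
#' @param sci SVD cutoff index used to derive each method's tSVD
#'   tolerance.
#' @param power_type see [node_power()].
#' @return a named list of class `benchmark_config`.
#' @export
benchmark_config <- function(target_nodes = 1000,
                             corrugation_amplitude = 0.15,
                             corrugation_frequency = c(6, 8),
                             axis_scales = c(1, 0.8, 0.92),
                             cortex_radius = 55,
                             mesh_seed = 42,
                             n_sensors = 64,
                             head_radius = 85,
                             polar_coverage = 140,
                             conductivity = 0.33,
                             n_datasets = 100,
                             moment_magnitude = 10,
                             snr = Inf,
                             seed = 1,
                             schemes = laplacian_schemes(),
                             sigma = NULL,
                             scan_snr = 20,
                             scan_alpha_grid = c(0.01, 0.005, 0.0025),
                             scan_decades = 10,
                             sqrt_depth_weights = TRUE,
                             sci = 1L,
                             power_type = "power") {
  schemes <- vapply(schemes, .match_scheme, character(1), USE.NAMES = FALSE)
  if (!is.null(sigma) && !all(schemes %in% names(sigma)))
    stop("missing sigma for scheme(s): ",
         paste(setdiff(schemes, names(sigma)), collapse = ", "))
  structure(as.list(environment()), class = "benchmark_config")
}

# Bilateral two-dipole dataset (z-oriented, mirrored across the x-z
# plane) used by the sigma-derivation scan, mimicking a bilateral
# auditory activation.
.bilateral_scan_data <- function(mesh, montage, moment_magnitude,
                                 conductivity, snr, seed) {
  bc <- simulation_source_space(mesh)
  lat <- which(bc[, 2L] > 0.6 * max(bc[, 2L]))
  j1 <- lat[which.max(bc[lat, 3L])]
  mirror <- bc[j1, ] * c(1, -1, 1)
  j2 <- which.min(rowSums(sweep(bc, 2L, mirror)^2))
  Lp <- spherical_leadfield(montage, bc[c(j1, j2), , drop = FALSE],
                            conductivity = conductivity)
  clean <- as.numeric(unclass(Lp) %*% rep(c(0, 0, moment_magnitude), 2))
  add_noise(clean, snr, seed)
}

# sigma* per scheme from the scan; deterministic fallbacks when the
# satisfying set is empty: first restrict alpha to <= 0.0025 (the move
# used when large alphas admit no sigma), then take the sigma with the
# largest worst-alpha deviation among those keeping GOF above threshold,
# then the largest worst-alpha deviation outright.
.derive_sigma <- function(L, mesh, scheme, data, omega, alpha_grid,
                          decades, gof_min = 90, dev_min = 10) {
  st <- assemble_stiffness(mesh, scheme)
  eta <- largest_singular_value(Matrix::crossprod(st$B))
  grid <- eta * 10^seq(-decades, 0)
  sc <- sigma_scan(L, mesh, scheme, data, grid, alpha_grid,
                   omega = omega, gof_min = gof_min, dev_min = dev_min,
                   refine = TRUE)
  if (!sc$no_admissible) return(sc$sigma_star)
  small_a <- alpha_grid[alpha_grid <= 0.0025]
  if (length(small_a) && length(small_a) < length(alpha_grid)) {
    sc2 <- sigma_scan(L, mesh, scheme, data, grid, small_a,
                      omega = omega, gof_min = gof_min,
                      dev_min = dev_min, refine = TRUE)
    if (!sc2$no_admissible) return(sc2$sigma_star)
  }
  worst_dev <- apply(sc$deviation, 1L, min)
  gof_ok <- apply(sc$gof >= gof_min, 1L, all)
  if (any(gof_ok)) return(grid[gof_ok][which.max(worst_dev[gof_ok])])
  grid[which.max(worst_dev)]
}

#' Run the operator-comparison benchmark
#'
#' Executes the full simulation protocol: generate the cortex-like
#' mesh, montage and inverse leadfield; derive each scheme's sigma by
#' the scan-selection procedure (unless fixed values are configured);
#' build one truncated-SVD inverse operator per method (depth-weighted
#' no-Laplacian reference plus one cortical LORETA operator per
#' configured scheme, each with its tolerance derived from the
#' configured SCI); simulate single-dipole datasets off-node (inverse
#' crime avoided); and evaluate every comparison measure for every
#' method on every dataset.  Deterministic under the config seed.
#'
#' @param config a [benchmark_config()].
#' @param quiet suppress progress messages.
#' @return An object of class `benchmark`: `table` (one row per
#'   dataset per method), `summary` (per-method means plus Pearson and
#'   Spearman correlations between simulated and estimated depths),
#'   `config`, `sigma` (per-scheme values used), `beta` (per-method
#'   tolerance ratios used).
#' @export
run_benchmark <- function(config = benchmark_config(), quiet = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  cf <- config
  mesh <- make_cortex_surface(
    target_nodes = cf$target_nodes,
    corrugation_amplitude = cf$corrugation_amplitude,
    corrugation_frequency = cf$corrugation_frequency,
    axis_scales = cf$axis_scales, radius = cf$cortex_radius,
    seed = cf$mesh_seed)
  montage <- make_montage(cf$n_sensors, cf$head_radius, cf$polar_coverage)
  L <- spherical_leadfield(montage, mesh, conductivity = cf$conductivity)
  omega <- depth_weights(L, sqrt_weights = cf$sqrt_depth_weights)
  geom <- mesh_geometry(mesh)
  sigma <- cf$sigma
  if (is.null(sigma)) {
    scan_data <- .bilateral_scan_data(mesh, montage, cf$moment_magnitude,
                                      cf$conductivity, cf$scan_snr,
                                      seed = cf$seed + 1L)
    sigma <- vapply(cf$schemes, function(s) {
      sg <- .derive_sigma(L, mesh, s, scan_data, omega,
                          cf$scan_alpha_grid, cf$scan_decades)
      if (!quiet)
        message(sprintf("[%s] sigma* for '%s': %.4g",
                        format(Sys.time(), "%H:%M:%S"), s, sg))
      sg
    }, numeric(1))
    names(sigma) <- cf$schemes
  }
  methods_w <- c(
    list("no-laplacian" = build_weighting(omega = omega,
                                          mode = "depth-only")),
    stats::setNames(lapply(cf$schemes, function(s)
      build_weighting(omega = omega,
                      B = assemble_stiffness(mesh, s, geom),
                      sigma = sigma[[s]], mode = "cortical")),
      cf$schemes))
  ops <- list(); beta <- numeric(0)
  for (nm in names(methods_w)) {
    base <- inverse_operator_tsvd(L, methods_w[[nm]],
                                  beta = .Machine$double.eps)
    b <- alpha_from_sci(base$singular_values, cf$sci)$alpha
    ops[[nm]] <- inverse_operator_tsvd(L, methods_w[[nm]], b)
    beta[nm] <- b
    if (!quiet)
      message(sprintf("[%s] operator '%s': beta = %.3g",
                      format(Sys.time(), "%H:%M:%S"), nm, b))
  }
  datasets <- simulate_datasets(mesh, montage, cf$n_datasets,
                                moment_magnitude = cf$moment_magnitude,
                                seed = cf$seed, snr = cf$snr,
                                conductivity = cf$conductivity)
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    ref_est <- estimate_sources(ops[["no-laplacian"]], ds$data, L = L)
    ref_pw <- node_power(ref_est, type = cf$power_type)
    for (nm in names(ops)) {
      est <- if (nm == "no-laplacian") ref_est
      else estimate_sources(ops[[nm]], ds$data, L = L)
      met <- compute_metrics(est, ds$data, est$bhat, mesh, montage,
                             ds$true_position,
                             reference_power =
                               if (nm == "no-laplacian") NULL else ref_pw,
                             power_type = cf$power_type)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(dataset = di, method = nm,
                         stringsAsFactors = FALSE), met)
    }
    if (!quiet)
      message(sprintf("[%s] dataset %d/%d done",
                      format(Sys.time(), "%H:%M:%S"), di, length(datasets)))
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, summary = .benchmark_summary(tab),
                 config = cf, sigma = sigma, beta = beta, mesh = mesh,
                 montage = montage),
            class = "benchmark")
}

.benchmark_summary <- function(tab) {
  num_cols <- c("localization_error_com", "localization_error_ma",
                "depth_shift_com", "depth_shift_ma", "n_local_maxima",
                "rv", "gof")
  out <- lapply(split(tab, tab$method), function(d) {
    means <- colMeans(d[, num_cols, drop = FALSE])
    data.frame(method = d$method[1L], t(means),
               depth_cor_com = stats::cor(d$depth_sim, d$depth_est_com),
               depth_cor_ma = stats::cor(d$depth_sim, d$depth_est_ma),
               depth_rank_cor_com = stats::cor(d$depth_sim, d$depth_est_com,
                                               method = "spearman"),
               depth_rank_cor_ma = stats::cor(d$depth_sim, d$depth_est_ma,
                                              method = "spearman"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # no-laplacian reference first, then schemes in canonical order
  ord <- match(out$method, c("no-laplacian", laplacian_schemes()))
  out[order(ord), , drop = FALSE]
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("benchmark: %d datasets x %d methods on %d nodes\n",
              x$config$n_datasets, length(unique(x$table$method)),
              n_vertices(x$mesh)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write the per-dataset benchmark table
#'
#' Tab-separated text with one header row; columns are `dataset`,
#' `method` and the [compute_metrics()] fields.
#'
#' @param bench a `benchmark` (or its `table`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  tab <- if (inherits(bench, "benchmark")) bench$table else bench
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
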