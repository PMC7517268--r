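# Group-integrity statistics: per-state Phi, mean-Phi threshold surfaces,
# Fano factors, normalisation, weighted peak positions, and the
# local-versus-global integrity difference across timescales.

#' Integrated information for every collective state
#'
#' @param tpm a [phi_tpm()].
#' @param scope `"main_complex"` (default; Phi of the subset with the
#'   greatest Phi, the convention used for all reported surfaces) or
#'   `"full_system"`.
#' @param cut_scheme passed to [big_phi()].
#' @return a `phi_state_table`: data.frame with one row per collective
#'   state (`state`, `label`, `phi`, `subsystem`, `cut_from`, `cut_to`)
#'   and the full `phi_result` objects in the `results` attribute.
#' @export
phi_per_state <- function(tpm, scope = c("main_complex", "full_system"),
                          cut_scheme = c("cut_one", "exhaustive")) {
  scope <- match.arg(scope)
  cut_scheme <- match.arg(cut_scheme)
  tpm <- as_phi_tpm(tpm)
  n <- n_nodes(tpm)
  states <- 0:(2^n - 1L)
  results <- lapply(states, function(s) {
    if (scope == "main_complex") {
      main_complex(tpm, s, cut_scheme)$result
    } else {
      big_phi(tpm, s, seq_len(n), cut_scheme)
    }
  })
  d <- data.frame(
    state = states,
    label = apply(all_state_bits(n), 1, paste0, collapse = ""),
    phi = vapply(results, `[[`, numeric(1), "big_phi"),
    subsystem = vapply(results, function(r)
      paste(r$subsystem, collapse = ","), character(1)),
    cut_from = vapply(results, function(r)
      paste(r$mip_cut$from, collapse = ","), character(1)),
    cut_to = vapply(results, function(r)
      paste(r$mip_cut$to, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(d, "results") <- results
  attr(d, "scope") <- scope
  class(d) <- c("phi_state_table", "data.frame")
  d
}

#' Mean, variance and Fano factor of per-state Phi
#'
#' Unweighted statistics over all `2^N` collective states (not weighted
#' by state occupancy).  The variance is the population variance (divisor
#' `2^N`).  The Fano factor is `var / mean`, undefined (`NA`) when the
#' mean is zero.
#'
#' @param phi per-state Phi values: numeric vector or a `phi_state_table`.
#' @return scalar.
#' @export
mean_phi <- function(phi) mean(phi_values(phi))

#' @rdname mean_phi
#' @export
variance_phi <- function(phi) {
  x <- phi_values(phi)
  mean((x - mean(x))^2)
}

#' @rdname mean_phi
#' @param m,v mean and variance, as returned by [mean_phi()] and
#'   [variance_phi()].
#' @export
fano_factor <- function(m, v) {
  if (m == 0) return(NA_real_)
  v / m
}

phi_values <- function(phi) {
  if (inherits(phi, "phi_state_table")) phi$phi else as.numeric(phi)
}

# Cell grids ---------------------------------------------------------------

#' Default threshold grids
#'
#' The grids used when none is given: distance 50-1000 mm, visual-field
#' widths including the narrow (0.18pi-0.56pi) and wide (1.6pi-2pi)
#' regions discussed in the analyses, turning rates 0-0.1 rad/step, and
#' for the global setting centre-of-mass radii 100-600 mm with angular
#' deviations pi/16-pi.
#'
#' @param setting `"local"` or `"global"`.
#' @return named list of grid vectors.
#' @export
default_grid <- function(setting = c("local", "global")) {
  setting <- match.arg(setting)
  if (setting == "local") {
    list(xi_D = c(50, 100, 200, 400, 600, 800, 1000),
         xi_VF = pi * c(0.18, 0.36, 0.56, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 1.9, 2.0),
         xi_TR = c(0, 0.001, 0.005, 0.01, 0.05, 0.1))
  } else {
    list(Xi_CM = c(100, 200, 300, 400, 500, 600),
         Xi_AD = pi * c(1 / 16, 1 / 8, 1 / 4, 1 / 2, 3 / 4, 1))
  }
}

#' Mean-Phi surface over a threshold grid
#'
#' For every grid cell: encode the trajectory, estimate the TPM, compute
#' Phi for all `2^N` collective states, and record the unweighted mean
#' and population variance.
#'
#' @param traj a [trajectory()].
#' @param grid named list of threshold vectors (`xi_D`, `xi_VF`, `xi_TR`
#'   for the local setting; `Xi_CM`, `Xi_AD` for the global one); the
#'   surface covers their Cartesian product.  Default: [default_grid()].
#' @param dt_frames resampling stride (timescale `dt_frames / fps` s).
#' @param setting `"local"` or `"global"`.
#' @param scope passed to [phi_per_state()].
#' @param ... further arguments to the encoder (convention flags).
#' @return a `phi_surface`: data.frame with one row per cell (threshold
#'   coordinates, `mean_phi`, `var_phi`, `fano`, `n_states`) plus the
#'   per-state Phi tables in the `per_state` attribute; metadata in
#'   attributes `setting`, `dt_frames`, `n`, `scope`.
#' @export
phi_surface <- function(traj, grid = NULL, dt_frames = 1,
                        setting = c("local", "global"),
                        scope = c("main_complex", "full_system"), ...) {
  setting <- match.arg(setting)
  scope <- match.arg(scope)
  grid <- grid %||% default_grid(setting)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  per_state <- vector("list", nrow(cells))
  mean_v <- var_v <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    thr <- if (setting == "local") {
      local_thresholds(cells$xi_D[i], cells$xi_VF[i], cells$xi_TR[i])
    } else {
      global_thresholds(Xi_AD = cells$Xi_AD[i], Xi_CM = cells$Xi_CM[i])
    }
    seq_i <- if (setting == "local") {
      local_collective_state(traj, thr, dt_frames, ...)
    } else {
      global_collective_state(traj, thr, dt_frames, ...)
    }
    tab <- phi_per_state(estimate_tpm(seq_i), scope = scope)
    per_state[[i]] <- tab
    mean_v[i] <- mean_phi(tab)
    var_v[i] <- variance_phi(tab)
  }
  out <- cbind(cells,
               mean_phi = mean_v, var_phi = var_v,
               fano = ifelse(mean_v == 0, NA_real_, var_v / mean_v),
               n_states = 2^n_individuals(traj))
  attr(out, "per_state") <- per_state
  attr(out, "setting") <- setting
  attr(out, "dt_frames") <- dt_frames
  attr(out, "n") <- n_individuals(traj)
  attr(out, "scope") <- scope
  class(out) <- c("phi_surface", "data.frame")
  out
}

surface_axes <- function(surface) {
  setdiff(names(surface), c("mean_phi", "var_phi", "fano", "n_states",
                            "mean_phi_norm"))
}

#' Normalise a surface by its maximum mean Phi
#'
#' Divides `mean_phi` by the maximum over a region (all cells by
#' default), adding a `mean_phi_norm` column; the maximum cell maps
#' to 1.
#'
#' @param surface a [phi_surface()].
#' @param region optional logical vector (or predicate on the surface
#'   data.frame) choosing the cells whose maximum defines the scale,
#'   e.g. `function(d) d$xi_VF < pi` for the narrow-field region.
#' @return the surface with an added `mean_phi_norm` column and a
#'   `phi_max` attribute.
#' @export
normalize_surface <- function(surface, region = NULL) {
  sel <- if (is.null(region)) rep(TRUE, nrow(surface))
         else if (is.function(region)) region(surface) else as.logical(region)
  m <- max(surface$mean_phi[sel])
  if (m <= 0) stop("cannot normalise: maximum mean Phi in the region is 0")
  surface$mean_phi_norm <- surface$mean_phi / m
  attr(surface, "phi_max") <- m
  surface
}

#' Weighted mean position of the high-Phi region
#'
#' Over the cells with `mean_phi > fraction * max(mean_phi)`, the mean of
#' the cell coordinates weighted by `mean_phi`.
#'
#' @param surface a [phi_surface()].
#' @param fraction threshold fraction of the maximum (default 0.5).
#' @return named numeric vector of threshold-space coordinates.
#' @export
weighted_mean_position <- function(surface, fraction = 0.5) {
  m <- max(surface$mean_phi)
  if (m <= 0) stop("all-zero surface has no weighted position")
  sel <- surface$mean_phi > fraction * m
  w <- surface$mean_phi[sel]
  axes <- surface_axes(surface)
  vapply(axes, function(a) sum(surface[[a]][sel] * w) / sum(w), numeric(1))
}

#' Mean of the k largest cells of a surface
#'
#' @param surface a [phi_surface()] (or numeric vector of cell values).
#' @param k number of peak cells (default 20); if fewer cells exist, all
#'   are used.
#' @return scalar mean of the top-k `mean_phi` values.
#' @export
top_k_mean <- function(surface, k = 20) {
  x <- if (is.numeric(surface)) surface else surface$mean_phi
  mean(head(sort(x, decreasing = TRUE), k))
}

#' Local minus global integrity
#'
#' Difference between the average peak mean-Phi of the local and the
#' global parameter settings: `top_k_mean(local) - top_k_mean(global)`.
#' Positive values mean the global (mean-field) reference underestimates
#' the integrity generated by the local interactions.
#'
#' @param local_surface,global_surface [phi_surface()]s at the same
#'   timescale.
#' @param k number of peak cells (default 20).
#' @return scalar difference.
#' @export
local_global_difference <- function(local_surface, global_surface, k = 20) {
  top_k_mean(local_surface, k) - top_k_mean(global_surface, k)
}

#' Correlation between mean Phi and its Fano factor
#'
#' Pearson correlation across cells of `mean_phi` against
#' `var_phi / mean_phi`.  Cells with undefined Fano factor (zero mean)
#' are excluded and counted; if either variable is constant the
#' correlation is undefined and `NA` is returned.
#'
#' @param mean_phi,fano numeric vectors, or a single [phi_surface()] as
#'   the first argument.
#' @return list with `r` (Pearson coefficient or `NA`), `n_used` and
#'   `n_excluded`.
#' @export
phi_fano_correlation <- function(mean_phi, fano = NULL) {
  if (is.data.frame(mean_phi)) {
    fano <- mean_phi$fano
    mean_phi <- mean_phi$mean_phi
  }
  ok <- !is.na(fano) & !is.na(mean_phi)
  m <- mean_phi[ok]; f <- fano[ok]
  r <- if (length(m) < 2 || stats::sd(m) == 0 || stats::sd(f) == 0) {
    NA_real_
  } else {
    stats::cor(m, f)
  }
  list(r = r, n_used = sum(ok), n_excluded = sum(!ok))
}

#' Write a surface as long-format CSV
#'
#' One row per cell: threshold coordinates, timescale, group size,
#' `mean_phi`, `var_phi`, `fano`.
#'
#' @param surface a [phi_surface()].
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  d <- as.data.frame(surface)
  d$dt_frames <- attr(surface, "dt_frames")
  d$n <- attr(surface, "n")
  d$setting <- attr(surface, "setting")
  d$scope <- attr(surface, "scope")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
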