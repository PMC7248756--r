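# Quasi-harmonic configurational entropy, the Schlitter upper bound, entropy
# differences from covariance determinants, and PCA of global motions.
#
# All entropies are reported per mole (J mol^-1 K^-1). Eigenvalues of the
# mass-weighted covariance carry units of amu A^2; the dimensionless
# combination entering both formulas is
#   a_i = hbar / sqrt(kB T lambda_i)   (lambda_i in SI),
# with Schlitter per-mode (R/2) ln(1 + e^2 / a_i^2) and quasi-harmonic
# per-mode R [a/(e^a - 1) - ln(1 - e^-a)].

.kB <- 1.380649e-23        # J/K (CODATA exact)
.hbar <- 1.054571817e-34   # J s
.amu <- 1.66053906660e-27  # kg
.Rgas <- 8.314462618       # J/(mol K)
.A2 <- 1e-20               # m^2 per A^2

#' Covariance of atomic fluctuations
#'
#' Covariance (denominator n, i.e. the maximum-likelihood estimate of the
#' fluctuation second moment) of the Cartesian coordinates of the selected
#' atoms over the window, optionally after superposing every frame on the
#' window-mean structure (removing overall translation/rotation) and
#' optionally mass-weighted as `M^(1/2) S M^(1/2)`.
#'
#' @param traj an `oligo_traj`
#' @param selection atom indices (default all atoms)
#' @param window analysis window (default whole trajectory)
#' @param mass_weighted weight by per-atom masses (required by the entropy
#'   estimators)
#' @param fit superpose frames on the window-mean structure first (default
#'   TRUE); when TRUE the six rigid-body modes are null and are dropped by
#'   default in the entropy estimators.
#' @param temperature_K temperature associated with the ensemble (default 300)
#' @param masses per-atom masses in amu; default from the atom table elements
#' @return object of class `covariance_model`: `matrix` (3N x 3N, symmetric),
#'   `masses`, `mass_weighted`, `fit`, `n_frames`, `temperature_K`,
#'   `fit_reference` (mean structure, N x 3), `rank_deficient` flag.
#' @export
fluctuation_covariance <- function(traj, selection = NULL, window = NULL,
                                   mass_weighted = TRUE, fit = TRUE,
                                   temperature_K = 300, masses = NULL) {
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  widx <- resolve_window(traj, window)
  xyz <- traj$xyz[widx, xyz_cols(selection), drop = FALSE]
  if (is.null(masses)) masses <- atom_masses(traj$atoms[selection, , drop = FALSE])
  ref <- NULL
  if (fit) {
    ms <- mean_structure(xyz, seq_along(selection))
    xyz <- ms$fitted_xyz
    ref <- ms$ref
  } else {
    ref <- coord_mat(colMeans(xyz))
  }
  centered <- sweep(xyz, 2L, colMeans(xyz))
  S <- crossprod(centered) / nrow(centered)
  S <- (S + t(S)) / 2
  if (mass_weighted) {
    w <- sqrt(rep(masses, each = 3L))
    S <- S * tcrossprod(w)
  }
  structure(list(matrix = S, masses = masses, mass_weighted = mass_weighted,
                 fit = fit, n_frames = length(widx),
                 temperature_K = temperature_K, fit_reference = ref,
                 selection = selection,
                 rank_deficient = length(widx) < 3L * length(selection)),
            class = "covariance_model")
}

#' Build a covariance model from an explicit matrix
#'
#' For analytic fixtures and for feeding externally computed covariances into
#' the entropy estimators.
#'
#' @param matrix symmetric PSD matrix, 3N x 3N (or any d x d for abstract
#'   mode spectra), already in the convention declared by `mass_weighted`
#'   (amu A^2 if mass-weighted, A^2 otherwise).
#' @param masses per-atom masses in amu (optional metadata)
#' @param mass_weighted whether `matrix` is mass-weighted
#' @param temperature_K ensemble temperature
#' @param fit whether rigid-body motion was removed (controls the default
#'   number of dropped modes in the estimators)
#' @return a `covariance_model`
#' @export
covariance_model <- function(matrix, masses = NULL, mass_weighted = TRUE,
                             temperature_K = 300, fit = FALSE) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (max(abs(matrix - t(matrix))) > 1e-10 * max(1, max(abs(matrix))))
    stop("covariance matrix not symmetric")
  structure(list(matrix = (matrix + t(matrix)) / 2, masses = masses,
                 mass_weighted = mass_weighted, fit = fit,
                 n_frames = NA_integer_, temperature_K = temperature_K,
                 fit_reference = NULL, selection = NULL,
                 rank_deficient = NA),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("<covariance_model> %d x %d, %smass-weighted, fit=%s, n_frames=%s, T=%g K\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$mass_weighted) "" else "not ", x$fit,
              x$n_frames, x$temperature_K))
  invisible(x)
}

# eigenvalues (descending) with negative-tolerance check; retained = all but
# the dropped_modes smallest
cov_spectrum <- function(cov, dropped_modes) {
  ev <- eigen(cov$matrix, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10 * max(sum(abs(ev)), 1)
  if (any(ev < -tol))
    stop("covariance has negative eigenvalue ", min(ev), " beyond tolerance")
  ev <- pmax(ev, 0)
  d <- length(ev)
  if (dropped_modes >= d) stop("dropped_modes >= matrix dimension")
  retained <- if (dropped_modes > 0L) ev[seq_len(d - dropped_modes)] else ev
  list(all = ev, retained = retained)
}

default_dropped <- function(cov, dropped_modes) {
  if (!is.null(dropped_modes)) return(as.integer(dropped_modes))
  if (isTRUE(cov$fit)) 6L else 0L
}

#' Schlitter configurational entropy (upper bound)
#'
#' `S = (R/2) sum_i ln(1 + kB T e^2 lambda_i / hbar^2)` over the retained
#' eigenvalues of the mass-weighted covariance, reported per mole. With
#' rigid-body motion removed by fitting, the six null modes are dropped by
#' default (removing the singularity of the Cartesian covariance).
#'
#' @param cov a mass-weighted `covariance_model`
#' @param dropped_modes number of smallest eigenvalues to skip (default 6 when
#'   the covariance was rigid-body fitted, else 0)
#' @return object of class `entropy_result` with `value` (J mol^-1 K^-1),
#'   `method`, `dropped_modes`, `per_mode` contributions
#' @export
schlitter_entropy <- function(cov, dropped_modes = NULL) {
  stopifnot(inherits(cov, "covariance_model"))
  if (!cov$mass_weighted) stop("Schlitter entropy needs a mass-weighted covariance")
  dm <- default_dropped(cov, dropped_modes)
  sp <- cov_spectrum(cov, dm)
  fac <- .kB * cov$temperature_K * exp(2) / .hbar^2 * .amu * .A2  # per (amu A^2)
  per_mode <- (.Rgas / 2) * log1p(fac * sp$retained)
  entropy_result("schlitter", sum(per_mode), dm, per_mode)
}

#' Quasi-harmonic configurational entropy
#'
#' Per retained mode, `omega_i = sqrt(kB T / lambda_i)` and
#' `a_i = hbar omega_i / (kB T)`; the harmonic-oscillator entropy
#' `R [a/(e^a - 1) - ln(1 - e^-a)]` is summed over modes. Stiff modes
#' (lambda -> 0+) contribute 0; exactly zero retained eigenvalues error.
#'
#' @inheritParams schlitter_entropy
#' @return an `entropy_result`
#' @export
quasiharmonic_entropy <- function(cov, dropped_modes = NULL) {
  stopifnot(inherits(cov, "covariance_model"))
  if (!cov$mass_weighted) stop("quasi-harmonic entropy needs a mass-weighted covariance")
  dm <- default_dropped(cov, dropped_modes)
  sp <- cov_spectrum(cov, dm)
  lam <- sp$retained
  if (any(lam <= 0)) {
    # a sample covariance from fewer than 3N frames is rank deficient; its
    # null modes are stiff-limit (zero-contribution) modes, not data
    if (isTRUE(cov$rank_deficient)) {
      keep <- lam > 1e-12 * max(lam)
      dm <- dm + sum(!keep)
      lam <- lam[keep]
    } else {
      stop("non-positive eigenvalue among retained modes; drop more modes")
    }
  }
  kT <- .kB * cov$temperature_K
  alpha <- .hbar / sqrt(kT * lam * .amu * .A2)   # = hbar omega / kB T
  per_mode <- .Rgas * (alpha / expm1(alpha) - log(-expm1(-alpha)))
  entropy_result("quasiharmonic", sum(per_mode), dm, per_mode)
}

entropy_result <- function(method, value, dropped_modes, per_mode = NULL) {
  structure(list(method = method, value = value,
                 dropped_modes = dropped_modes,
                 per_mode_contributions = per_mode),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> %s: %.4g J/(mol K) over %d mode(s), %d dropped\n",
              x$method, x$value, length(x$per_mode_contributions),
              x$dropped_modes))
  invisible(x)
}

#' Entropy difference from covariance determinants
#'
#' `dS = (R/2) ln(det sigma_a / det sigma_b)` over the retained-mode subspace
#' (pseudo-determinant: both spectra truncated to the same number of modes),
#' per mole. Computed as a sum of log-eigenvalue differences to avoid
#' overflow at large 3N.
#'
#' @param cov_a,cov_b `covariance_model`s of identical dimension
#' @param dropped_modes modes dropped from each spectrum (default from the
#'   models' fit flags, which must agree)
#' @return difference in J mol^-1 K^-1 (a > b positive)
#' @export
entropy_difference <- function(cov_a, cov_b, dropped_modes = NULL) {
  stopifnot(inherits(cov_a, "covariance_model"), inherits(cov_b, "covariance_model"))
  if (!all(dim(cov_a$matrix) == dim(cov_b$matrix)))
    stop("covariance dimensionality mismatch: ", nrow(cov_a$matrix), " vs ",
         nrow(cov_b$matrix))
  dma <- default_dropped(cov_a, dropped_modes)
  dmb <- default_dropped(cov_b, dropped_modes)
  if (dma != dmb) stop("models imply different dropped-mode counts; pass dropped_modes")
  la <- cov_spectrum(cov_a, dma)$retained
  lb <- cov_spectrum(cov_b, dma)$retained
  if (any(la <= 0) || any(lb <= 0))
    stop("zero eigenvalue among retained modes; drop more modes")
  (.Rgas / 2) * sum(log(la) - log(lb))
}

#' Principal components of a covariance model
#'
#' @param cov a `covariance_model`
#' @param k number of leading modes (default all)
#' @return list(values = eigenvalues descending, vectors = d x k orthonormal)
#' @export
pca_modes <- function(cov, k = NULL) {
  d <- nrow(cov$matrix)
  if (is.null(k)) k <- d
  stopifnot(k >= 1L, k <= d)
  e <- eigen(cov$matrix, symmetric = TRUE)
  list(values = e$values[seq_len(k)], vectors = e$vectors[, seq_len(k), drop = FALSE])
}

#' Project a trajectory onto covariance eigenvectors
#'
#' Frames are (optionally) superposed on the covariance fit reference, centered
#' on the mean structure, and projected on each mode. Mass weighting follows
#' the covariance model so projections live in the same space as its
#' eigenvectors.
#'
#' @param traj an `oligo_traj`
#' @param cov the `covariance_model` whose selection/reference to use
#' @param modes eigenvector matrix from [pca_modes()]
#' @param window frames to project (default all)
#' @return list(projections = n_frames x k matrix, extremes = data.frame of
#'   min/max frame indices per mode)
#' @export
project_trajectory <- function(traj, cov, modes, window = NULL) {
  sel <- cov$selection
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  if (nrow(modes) != 3L * length(sel))
    stop("mode dimension does not match the covariance selection")
  widx <- resolve_window(traj, window)
  xyz <- traj$xyz[widx, xyz_cols(sel), drop = FALSE]
  ref <- cov$fit_reference
  if (isTRUE(cov$fit) && !is.null(ref)) xyz <- fit_frames(xyz, ref, seq_along(sel))
  center <- if (!is.null(ref)) coord_vec(ref) else colMeans(xyz)
  centered <- sweep(xyz, 2L, center)
  if (cov$mass_weighted && !is.null(cov$masses))
    centered <- sweep(centered, 2L, sqrt(rep(cov$masses, each = 3L)), `*`)
  proj <- centered %*% modes
  extremes <- data.frame(mode = seq_len(ncol(proj)),
                         min_frame = widx[apply(proj, 2L, which.min)],
                         max_frame = widx[apply(proj, 2L, which.max)])
  list(projections = proj, extremes = extremes, time_ns = traj$time_ns[widx])
}
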