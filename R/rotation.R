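# Trimer-trimer rotation metric.
#
# The hexamer is two stacked trimers. Per frame, subunit centers of geometry
# are taken over C-alpha atoms of the oligomerization domain (default residues
# 85-149, author numbering); all atoms are C-alpha so the centroid equals the
# center of mass. The rotation of one trimer relative to the other is the
# signed angle, about the instantaneous trimer-trimer axis, between the
# in-plane radial vectors of the paired subunits, averaged over the three
# cross-trimer pairs.

#' Center of geometry of a selection
#'
#' Unweighted mean position of the selected atoms (for an all-C-alpha
#' selection this equals the center of mass).
#'
#' @param frame an `oligo_frame`
#' @param chains,residue_range,atom_name forwarded to [select_atoms()]
#' @return length-3 numeric vector (Angstrom)
#' @export
center_of_geometry <- function(frame, chains = NULL, residue_range = NULL,
                               atom_name = NULL) {
  idx <- select_atoms(frame, chains = chains, resno = residue_range,
                      elety = atom_name)
  colMeans(coord_mat(frame$xyz)[idx, , drop = FALSE])
}

#' Instantaneous trimer-trimer axis
#'
#' Unit vector from the center of geometry of the trimer2 chains to that of
#' the trimer1 chains (over the topology's CoM residue range, C-alpha atoms),
#' defining the internal z-axis of the hexamer.
#'
#' @param frame an `oligo_frame`
#' @param topology a [hexamer_topology()]
#' @return unit length-3 vector
#' @export
trimer_axis <- function(frame, topology) {
  c1 <- center_of_geometry(frame, topology$trimer1_chains,
                           topology$com_residue_range, "CA")
  c2 <- center_of_geometry(frame, topology$trimer2_chains,
                           topology$com_residue_range, "CA")
  d <- c1 - c2
  n <- sqrt(sum(d^2))
  if (n < 1e-8) stop("coincident trimer centroids; axis undefined")
  d / n
}

cross3 <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                           a[3L] * b[1L] - a[1L] * b[3L],
                           a[1L] * b[2L] - a[2L] * b[1L])

# signed angle carrying v_ref onto v about unit axis u, in (-180, 180] degrees
signed_angle <- function(v_ref, v, u) {
  atan2(sum(cross3(v_ref, v) * u), sum(v_ref * v)) * 180 / pi
}

# chain centroid lookup over the CoM range for all six chains, vectorized
# across frames: returns list(ch -> n_frames x 3 matrix)
chain_centroids <- function(traj, topology) {
  chains <- c(topology$trimer1_chains, topology$trimer2_chains)
  out <- vector("list", length(chains))
  names(out) <- chains
  for (ch in chains) {
    idx <- select_atoms(traj, chains = ch, resno = topology$com_residue_range,
                        elety = "CA")
    out[[ch]] <- cbind(rowMeans(traj$xyz[, 3L * idx - 2L, drop = FALSE]),
                       rowMeans(traj$xyz[, 3L * idx - 1L, drop = FALSE]),
                       rowMeans(traj$xyz[, 3L * idx, drop = FALSE]))
  }
  out
}

# per-frame pair angles from precomputed centroids; rows = frames, cols = pairs
pair_angles_from_centroids <- function(cent, topology) {
  nf <- nrow(cent[[1L]])
  c1 <- (cent[[topology$trimer1_chains[1L]]] + cent[[topology$trimer1_chains[2L]]] +
           cent[[topology$trimer1_chains[3L]]]) / 3
  c2 <- (cent[[topology$trimer2_chains[1L]]] + cent[[topology$trimer2_chains[2L]]] +
           cent[[topology$trimer2_chains[3L]]]) / 3
  ax <- c1 - c2
  axn <- sqrt(rowSums(ax^2))
  if (any(axn < 1e-8)) stop("coincident trimer centroids; axis undefined")
  ax <- ax / axn
  ang <- matrix(NA_real_, nf, 3L)
  for (p in seq_len(3L)) {
    pr <- topology$pairing[[p]]
    v1 <- cent[[pr[1L]]] - c1                     # trimer1 subunit radial vector
    v2 <- cent[[pr[2L]]] - c2                     # partner radial vector
    # project onto the plane perpendicular to the axis
    v1 <- v1 - ax * rowSums(v1 * ax)
    v2 <- v2 - ax * rowSums(v2 * ax)
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    if (any(n1 < 1e-6) || any(n2 < 1e-6))
      stop("subunit centroid lies on the trimer axis; pair angle undefined")
    # signed angle from the trimer1 vector to the partner vector about the
    # axis pointing toward trimer1; positive = partner shifted clockwise when
    # viewed down the axis from the trimer1 side (screw sense, invariant
    # under exchanging the two trimer roles)
    cr <- cbind(v1[, 2L] * v2[, 3L] - v1[, 3L] * v2[, 2L],
                v1[, 3L] * v2[, 1L] - v1[, 1L] * v2[, 3L],
                v1[, 1L] * v2[, 2L] - v1[, 2L] * v2[, 1L])
    ang[, p] <- atan2(-rowSums(cr * ax), rowSums(v1 * v2)) * 180 / pi
  }
  colnames(ang) <- vapply(topology$pairing, paste, "", collapse = "-")
  ang
}

# bring the three pair angles to a common 360-degree branch around their median
unwrap_to_median <- function(a) {
  med <- apply(a, 1L, median)
  a + 360 * round((med - a) / 360)
}

#' Trimer-trimer rotation angle of one frame
#'
#' For each cross-trimer pair (X in trimer 1, Y in trimer 2), the vectors from
#' each trimer's center of mass to its subunit's center of mass are projected
#' onto the plane perpendicular to the trimer axis, and the signed angle
#' between them is taken about the axis; the reported angle is the arithmetic
#' mean of the three pair angles (after unwrapping to a common branch).
#' Positive = clockwise shift of the partner trimer when viewed down the axis
#' from the trimer-1 side.
#'
#' @param frame an `oligo_frame`
#' @param topology a [hexamer_topology()]
#' @return list with `mean_angle` (degrees) and `pair_angles` (named length-3)
#' @export
rotation_angle <- function(frame, topology) {
  tr <- as_trajectory(frame)
  ang <- pair_angles_from_centroids(chain_centroids(tr, topology), topology)
  ang <- unwrap_to_median(ang)
  list(mean_angle = mean(ang[1L, ]), pair_angles = ang[1L, ])
}

#' Rotation-angle time series with windowed statistics
#'
#' @param traj an `oligo_traj`
#' @param topology a [hexamer_topology()]
#' @param smoothing_window_ns boxcar width for a smoothed presentation series
#'   (0 = off). Window statistics always use the unsmoothed per-frame means.
#' @param stats_window time window for mean/sd: `c(t0, t1)` ns,
#'   `list(last_ns = )`, `list(last_frac = )`, or NULL for the whole trajectory.
#' @return object of class `rotation_result`: per-frame pair angles, per-frame
#'   means, optional smoothed series, and window mean/sd.
#' @export
rotation_series <- function(traj, topology, smoothing_window_ns = 0,
                            stats_window = NULL) {
  ang <- pair_angles_from_centroids(chain_centroids(traj, topology), topology)
  ang <- unwrap_to_median(ang)
  per_frame_mean <- rowMeans(ang)
  widx <- resolve_window(traj, stats_window)
  smoothed <- NULL
  if (smoothing_window_ns > 0) {
    dt <- if (n_frames(traj) > 1L) diff(traj$time_ns[1:2]) else Inf
    k <- max(1L, round(smoothing_window_ns / dt))
    if (k > 1L) {
      kern <- rep(1 / k, k)
      smoothed <- as.numeric(stats::filter(per_frame_mean, kern, sides = 2L))
    } else smoothed <- per_frame_mean
  }
  structure(list(time_ns = traj$time_ns,
                 per_frame_pair_angles = ang,
                 per_frame_mean = per_frame_mean,
                 smoothed_mean = smoothed,
                 smoothing_window_ns = smoothing_window_ns,
                 window_mean = mean(per_frame_mean[widx]),
                 window_std = if (length(widx) > 1L) sd(per_frame_mean[widx]) else 0,
                 window_definition = range(traj$time_ns[widx])),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("<rotation_result> %d frames; window [%.4g, %.4g] ns: %.3f +/- %.3f deg\n",
              length(x$per_frame_mean), x$window_definition[1L],
              x$window_definition[2L], x$window_mean, x$window_std))
  invisible(x)
}

#' Tabulate a rotation result
#' @param x a `rotation_result`
#' @param ... unused
#' @return data.frame with time_ns, the three pair angles, and mean_deg
#' @export
as.data.frame.rotation_result <- function(x, ...) {
  df <- data.frame(time_ns = x$time_ns, x$per_frame_pair_angles,
                   mean_deg = x$per_frame_mean, check.names = FALSE)
  names(df)[2:4] <- paste0("pair", 1:3, "_deg")
  df
}
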