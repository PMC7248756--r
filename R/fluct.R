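# Superposition, RMSD/RMSF, B-factor conversion, and the Arg43 N-domain
# pair-distance monitor.

# Kabsch: optimal proper rotation + translation carrying mob onto ref
# (n x 3 matrices). Returns list(R, t) with y = x %*% R + t.
kabsch <- function(mob, ref) {
  stopifnot(nrow(mob) == nrow(ref), nrow(mob) >= 3L)
  cm <- colMeans(mob); cr <- colMeans(ref)
  x <- sweep(mob, 2L, cm); y <- sweep(ref, 2L, cr)
  s <- svd(crossprod(x, y))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L)
    stop("degenerate (collinear) fit selection")
  dsign <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  list(R = R, t = cr - as.numeric(cm %*% R))
}

#' Least-squares rigid superposition of one frame onto another
#'
#' Optimal proper rotation (Kabsch) and translation minimizing the RMSD over
#' the fit selection, unweighted. The transform is applied to all atoms of the
#' mobile frame.
#'
#' @param mobile,reference `oligo_frame`s with identical atom tables.
#' @param fit_selection atom indices used to fit (>= 3, non-collinear);
#'   default all atoms.
#' @return list(frame = transformed `oligo_frame`, rmsd_fit = fitted RMSD in
#'   Angstrom, R = rotation, t = translation)
#' @export
superpose <- function(mobile, reference, fit_selection = NULL) {
  if (is.null(fit_selection)) fit_selection <- seq_len(nrow(mobile$atoms))
  m <- coord_mat(mobile$xyz); r <- coord_mat(reference$xyz)
  tr <- kabsch(m[fit_selection, , drop = FALSE], r[fit_selection, , drop = FALSE])
  m2 <- m %*% tr$R + matrix(tr$t, nrow(m), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((m2[fit_selection, , drop = FALSE] -
                               r[fit_selection, , drop = FALSE])^2)))
  out <- mobile
  out$xyz <- coord_vec(m2)
  list(frame = out, rmsd_fit = rmsd, R = tr$R, t = tr$t)
}

# fit every frame of traj onto ref coordinates (n x 3) over sel; returns the
# fitted xyz matrix
fit_frames <- function(xyz, ref, sel) {
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    m <- coord_mat(xyz[f, ])
    tr <- kabsch(m[sel, , drop = FALSE], ref[sel, , drop = FALSE])
    out[f, ] <- coord_vec(m %*% tr$R + matrix(tr$t, nrow(m), 3L, byrow = TRUE))
  }
  out
}

#' RMSD time series after superposition
#'
#' Per frame: superpose on the reference over `fit_selection`, then RMSD over
#' `measure_selection`. Distinct fit and measure selections reproduce the
#' whole-complex-fit vs own-domain-fit contrast used to separate global
#' domain movements from internal structural change.
#'
#' @param traj an `oligo_traj`
#' @param reference an `oligo_frame`
#' @param fit_selection,measure_selection atom index vectors (default: all
#'   atoms; `measure_selection` defaults to `fit_selection`)
#' @return numeric vector (Angstrom) with attribute `time_ns`
#' @export
rmsd_series <- function(traj, reference, fit_selection = NULL,
                        measure_selection = NULL) {
  if (is.null(fit_selection)) fit_selection <- seq_len(n_atoms(traj))
  if (is.null(measure_selection)) measure_selection <- fit_selection
  ref <- coord_mat(reference$xyz)
  out <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    m <- coord_mat(traj$xyz[f, ])
    tr <- kabsch(m[fit_selection, , drop = FALSE], ref[fit_selection, , drop = FALSE])
    m2 <- m %*% tr$R + matrix(tr$t, nrow(m), 3L, byrow = TRUE)
    out[f] <- sqrt(mean(rowSums((m2[measure_selection, , drop = FALSE] -
                                   ref[measure_selection, , drop = FALSE])^2)))
  }
  attr(out, "time_ns") <- traj$time_ns
  out
}

# window-mean reference structure after iterative fitting (two passes)
mean_structure <- function(xyz, sel, tol = 1e-6, max_iter = 2L) {
  ref <- coord_mat(colMeans(xyz))
  for (it in seq_len(max_iter)) {
    fitted <- fit_frames(xyz, ref, sel)
    new_ref <- coord_mat(colMeans(fitted))
    delta <- max(abs(new_ref - ref))
    ref <- new_ref
    xyz <- fitted
    if (delta < tol) break
  }
  list(ref = ref, fitted_xyz = xyz)
}

#' Per-residue RMSF profile with B-factor conversion
#'
#' Each window frame is superposed on the window-mean structure (itself
#' refined by a second fit pass) over all heavy atoms of the selection;
#' per-atom RMSF is taken about the mean position, per-residue values are the
#' mean over the residue's heavy atoms, and residues are aggregated over the
#' six monomers by `aggregation`. B-factors are attached as
#' `(8 pi^2 / 3) RMSF^2`.
#'
#' @param traj an `oligo_traj`
#' @param topology a [hexamer_topology()] (defines the six chains)
#' @param window analysis window (default final half; see [rotation_series()])
#' @param aggregation `"mean"` or `"max"` over the six monomers
#' @return object of class `fluct_profile`: data.frame columns `resno`,
#'   `rmsf_A`, `bfactor_A2`, plus per-chain matrix in attribute `per_chain`.
#'   The VMD-style color-scale metadata (offset 0.10, midpoint 0.28) ride
#'   along as attributes for downstream renderers; no coloring is done here.
#' @export
rmsf_profile <- function(traj, topology, window = list(last_frac = 0.5),
                         aggregation = c("mean", "max")) {
  aggregation <- match.arg(aggregation)
  widx <- resolve_window(traj, window)
  chains <- c(topology$trimer1_chains, topology$trimer2_chains)
  sel <- select_atoms(traj, chains = chains, heavy_only = TRUE)
  xyz <- traj$xyz[widx, xyz_cols(sel), drop = FALSE]
  at <- traj$atoms[sel, , drop = FALSE]
  ms <- mean_structure(xyz, seq_along(sel))
  dev2 <- sweep(ms$fitted_xyz, 2L, coord_vec(ms$ref))^2
  # per-atom msf = mean over frames of squared displacement (summed over x,y,z)
  msf_xyz <- colMeans(dev2)
  msf_atom <- msf_xyz[c(TRUE, FALSE, FALSE)] + msf_xyz[c(FALSE, TRUE, FALSE)] +
    msf_xyz[c(FALSE, FALSE, TRUE)]
  rmsf_atom <- sqrt(msf_atom)
  key <- paste(at$chain, at$resno)
  res_rmsf <- tapply(rmsf_atom, key, mean)
  res_chain <- vapply(strsplit(names(res_rmsf), " "), `[`, "", 1L)
  res_no <- as.integer(vapply(strsplit(names(res_rmsf), " "), `[`, "", 2L))
  resnos <- sort(unique(res_no))
  per_chain <- matrix(NA_real_, length(resnos), length(chains),
                      dimnames = list(resnos, chains))
  for (i in seq_along(res_rmsf))
    per_chain[as.character(res_no[i]), res_chain[i]] <- res_rmsf[i]
  agg <- apply(per_chain, 1L, if (aggregation == "mean") function(v) mean(v, na.rm = TRUE)
                              else function(v) max(v, na.rm = TRUE))
  out <- data.frame(resno = resnos, rmsf_A = as.numeric(agg))
  out$bfactor_A2 <- rmsf_to_bfactor(out$rmsf_A)
  structure(out, per_chain = per_chain, aggregation = aggregation,
            window_ns = range(traj$time_ns[widx]),
            color_scale = c(offset = 0.10, midpoint = 0.28),
            class = c("fluct_profile", "data.frame"))
}

#' Convert RMSF to crystallographic B-factors
#'
#' `B = (8 pi^2 / 3) RMSF^2`, with RMSF in Angstrom and B in Angstrom^2.
#'
#' @param rmsf_A numeric RMSF values (Angstrom), or a `fluct_profile`
#' @return numeric B-factors (Angstrom^2)
#' @export
rmsf_to_bfactor <- function(rmsf_A) {
  if (inherits(rmsf_A, "fluct_profile")) rmsf_A <- rmsf_A$rmsf_A
  if (any(rmsf_A < 0)) stop("negative RMSF")
  (8 * pi^2 / 3) * rmsf_A^2
}

#' Inter-trimer N-domain pair distances (Arg43 C-alpha monitor)
#'
#' Distance series between the chosen atom (default C-alpha of residue 43) of
#' every trimer-1 chain and every trimer-2 chain: all nine inter-trimer chain
#' pairs, with the three canonical (topology-paired) combinations tagged.
#' Frames at or below the DNA-binding-competence threshold (default 26 A) are
#' flagged.
#'
#' @param traj an `oligo_traj`
#' @param topology a [hexamer_topology()]
#' @param resno residue number (default 43)
#' @param elety atom name (default "CA")
#' @param competence_threshold_A flag threshold in Angstrom (default 26)
#' @return data.frame: chain_a, chain_b, canonical, time_ns, distance_A,
#'   competent (distance <= threshold). Chains lacking the residue are skipped
#'   with a warning.
#' @export
domain_pair_distances <- function(traj, topology, resno = 43L, elety = "CA",
                                  competence_threshold_A = 26) {
  canon <- vapply(topology$pairing, paste, "", collapse = "-")
  out <- list()
  for (ca in topology$trimer1_chains) for (cb in topology$trimer2_chains) {
    sp <- contact_spec("arg43",
                       list(chain = ca, resno = resno, atoms = elety),
                       list(chain = cb, resno = resno, atoms = elety))
    d <- tryCatch(distance_series(traj, sp), error = function(e) {
      warning("pair ", ca, "-", cb, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(d)) next
    out[[length(out) + 1L]] <- data.frame(
      chain_a = ca, chain_b = cb,
      canonical = paste0(ca, "-", cb) %in% canon,
      time_ns = traj$time_ns, distance_A = as.numeric(d),
      competent = as.numeric(d) <= competence_threshold_A)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chain_a = character(), chain_b = character(),
               canonical = logical(), time_ns = numeric(),
               distance_A = numeric(), competent = logical())
  attr(res, "competence_threshold_A") <- competence_threshold_A
  res
}
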