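# Ground-truthed synthetic inputs: rigid-body hexamer trajectories with an
# injected trimer-trimer rotation time course, per-subunit wobble, salt-bridge
# probe geometry and an N-domain (Arg43) separation course; and Gaussian
# pseudo-trajectories with a specified covariance for entropy validation.
#
# The hexamer emulates two trimers of rigid subunits stacked as triangles:
# trimer 1 (chains A,B,C) in the plane z = +h/2, trimer 2 (D,E,F) eclipsed
# beneath it at z = -h/2 with the paired subunit directly below its partner.
# The whole of trimer 2's oligomerization domain rotates about the z axis by
# theta(t) = theta0 + (theta_eq - theta0)(1 - exp(-t/tau)) + eps(t),
# clockwise viewed from trimer 1 (so the analysis convention reports +theta).
# Alpha4 probe atoms sit on a circle near the interface plane, phased so the
# R78 guanidino / D82 carboxylate distance shrinks monotonically with theta
# and reaches the contact distance (default 3 A) at theta_contact.
# N-domain/Arg43 arms are placed on fixed radial spokes per cross-trimer pair
# with a prescribed, optionally time-varying pair separation; they wobble with
# their subunit but deliberately do not follow the trimer rotation, mimicking
# peripheral domains that decouple from the core rotation.

# evaluate with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic hexamer trajectory
#'
#' Defaults describe the stated world the generator emulates: subunit
#' centroids 20 A from the trimer axis, trimer planes 25 A apart, a rotation
#' time course relaxing from `theta0_deg` to `theta_eq_deg` with time constant
#' `tau_ns`, optional AR(1) angle noise and per-subunit rigid wobble, and
#' alpha4 probes reaching 3 A contact at `theta_contact_deg`.
#'
#' @param triangle_radius_A distance of subunit centroids from the axis
#' @param axial_separation_A distance between the two trimer planes
#' @param theta0_deg,theta_eq_deg,tau_ns rotation course parameters
#' @param noise_deg stationary sd of AR(1) noise added to theta (0 = off)
#' @param noise_rho AR(1) coefficient of the theta noise
#' @param wobble_A per-subunit rigid-body jitter amplitude (rms displacement)
#' @param wobble_rho AR(1) coefficient of the wobble
#' @param atom_jitter_A iid per-coordinate Gaussian jitter applied to every
#'   atom (for RMSF closed-form validation; 0 = off)
#' @param n_frames,frame_interval_ns sampling
#' @param include_ndomain place N-domain blobs and Arg43 probes
#' @param ndomain_offset_A radial offset of the N-domain arm beyond the
#'   triangle radius
#' @param arg43_start_A,arg43_end_A Arg43 C-alpha pair separation at the first
#'   and last frame (linear course)
#' @param probe_radius_A radius of the alpha4 probe circle (must not exceed
#'   the triangle radius)
#' @param theta_contact_deg rotation at which the R78-D82 probes touch
#' @param probe_contact_A closest-approach distance at contact
#' @param seed RNG seed (determinism contract: same spec + seed = identical
#'   output)
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(triangle_radius_A = 20, axial_separation_A = 25,
                           theta0_deg = 0, theta_eq_deg = 0, tau_ns = 100,
                           noise_deg = 0, noise_rho = 0.9,
                           wobble_A = 0, wobble_rho = 0.9,
                           atom_jitter_A = 0,
                           n_frames = 100L, frame_interval_ns = 1,
                           include_ndomain = TRUE, ndomain_offset_A = 15,
                           arg43_start_A = 40, arg43_end_A = NULL,
                           probe_radius_A = 20, theta_contact_deg = 22,
                           probe_contact_A = 3.0, seed = 1L) {
  if (is.null(arg43_end_A)) arg43_end_A <- arg43_start_A
  sp <- as.list(environment())
  lens <- c(sp$triangle_radius_A, sp$axial_separation_A, sp$probe_radius_A,
            sp$probe_contact_A, sp$arg43_start_A, sp$arg43_end_A)
  if (any(lens <= 0)) stop("length scales must be positive")
  if (sp$probe_radius_A > sp$triangle_radius_A)
    stop("probe radius exceeds triangle radius (steric nonsense)")
  if (sp$n_frames < 1L) stop("need at least one frame")
  if (sp$frame_interval_ns <= 0) stop("frame interval must be positive")
  structure(sp, class = "synthetic_spec")
}

# deterministic compact pseudo-C-alpha blob of n atoms, centered at origin
blob_template <- function(n, pitch = 1.5, radius = 4) {
  j <- seq_len(n) - 1
  m <- cbind(radius * cos(2 * pi * j / 3.6),
             radius * sin(2 * pi * j / 3.6),
             pitch * (j - (n - 1) / 2) * 10 / n)
  sweep(m, 2L, colMeans(m))
}

# AR(1) series, stationary sd `s`, n rows x k cols
ar1 <- function(n, k, s, rho) {
  if (s == 0) return(matrix(0, n, k))
  e <- matrix(rnorm(n * k, sd = s * sqrt(1 - rho^2)), n, k)
  out <- matrix(0, n, k)
  out[1L, ] <- rnorm(k, sd = s)
  if (n > 1L) for (i in 2:n) out[i, ] <- rho * out[i - 1L, ] + e[i, ]
  out
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# rotation matrix from a rotation vector (axis * angle, radians)
rotvec_mat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  u <- v / th
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a rigid-body hexamer trajectory with ground truth
#'
#' See [synthetic_spec()] for the geometry. Chains A-F each carry a 65-residue
#' pseudo-C-alpha oligomerization blob (residues 85-149, centered exactly on
#' the subunit centroid), alpha4 probe atoms (K75 NZ; R78 NH1/NH2/NE; D82
#' OD1/OD2/O, plus their C-alphas), and optionally an N-domain blob (residues
#' 1-71) with the Arg43 C-alpha probe.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `trajectory` (an `oligo_traj`) and `truth`: per-frame
#'   applied rotation `theta_deg` (and its noise-free part `theta_ideal_deg`),
#'   per-frame R78-D82 probe distance `probe_dist_A`, Arg43 pair separation
#'   `arg43_dist_A`, ideal subunit centroids, per-residue RMSF implied by
#'   `atom_jitter_A` (NA when wobble makes it analytically intractable), and
#'   the spec itself.
#' @export
generate_hexamer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    t1 <- c("A", "B", "C"); t2 <- c("F", "E", "D")  # t2[i] pairs with t1[i]
    phi <- c(90, 210, 330)                           # pair azimuths, degrees
    h <- spec$axial_separation_A
    rp <- spec$probe_radius_A
    g <- spec$probe_contact_A / 2
    dR <- 8; dD <- -8                                # alpha4 probe phase, deg
    thc <- spec$theta_contact_deg
    nf <- spec$n_frames
    tns <- (seq_len(nf) - 1) * spec$frame_interval_ns

    theta_ideal <- spec$theta0_deg +
      (spec$theta_eq_deg - spec$theta0_deg) * (1 - exp(-tns / spec$tau_ns))
    theta <- theta_ideal + as.numeric(ar1(nf, 1L, spec$noise_deg, spec$noise_rho))
    span <- if (nf > 1L) tns / tns[nf] else 0
    d43 <- spec$arg43_start_A + (spec$arg43_end_A - spec$arg43_start_A) * span

    pol <- function(r, az_deg, z)
      c(r * cos(az_deg * pi / 180), r * sin(az_deg * pi / 180), z)

    cblob <- blob_template(65L)
    nblob <- if (spec$include_ndomain) blob_template(70L, pitch = 1.2, radius = 3.5) else NULL

    build_chain <- function(chain, pair_idx, upper) {
      az <- phi[pair_idx]
      zs <- if (upper) 1 else -1
      ctr <- pol(spec$triangle_radius_A, az, zs * h / 2)
      atoms <- list(); xyz <- list(); grp <- list()
      add <- function(resno, resid, elety, element, pos, group) {
        atoms[[length(atoms) + 1L]] <<- data.frame(
          chain = chain, resno = resno, resid = resid, elety = elety,
          element = element, occ = 1, altloc = "", het = FALSE, ins = "")
        xyz[[length(xyz) + 1L]] <<- pos
        grp[[length(grp) + 1L]] <<- group
      }
      # oligomerization blob, residues 85-149, centroid = subunit center
      for (j in seq_len(65L))
        add(84L + j, "ALA", "CA", "C", ctr + cblob[j, ], "core")
      # alpha4 probes near the interface plane. Trimer-2 probes are phased
      # +theta_contact ahead of the opposite probe type's trimer-1 azimuth, so
      # clockwise rotation by theta_contact brings R78 of one chain into
      # register with D82 of its partner (both directions).
      if (upper) { azR <- az + dR; azD <- az + dD }
      else { azR <- az + dD + thc; azD <- az + dR + thc }
      away <- function(extra) zs * (g + extra)       # push away from interface
      add(75L, "LYS", "CA", "C", pol(rp, azR - 2, away(2.5)), "core")
      add(75L, "LYS", "NZ", "N", pol(rp, azR - 2, away(0.3)), "core")
      add(78L, "ARG", "CA", "C", pol(rp, azR, away(2.5)), "core")
      add(78L, "ARG", "NH1", "N", pol(rp, azR, away(0)), "core")
      add(78L, "ARG", "NH2", "N", pol(rp, azR, away(0.5)), "core")
      add(78L, "ARG", "NE", "N", pol(rp, azR, away(0.9)), "core")
      add(82L, "ASP", "CA", "C", pol(rp, azD, away(2.5)), "core")
      add(82L, "ASP", "OD1", "O", pol(rp, azD, away(0)), "core")
      add(82L, "ASP", "OD2", "O", pol(rp, azD, away(0.4)), "core")
      add(82L, "ASP", "O", "O", pol(rp, azD, away(1.2)), "core")
      if (spec$include_ndomain) {
        r43 <- spec$triangle_radius_A + spec$ndomain_offset_A
        p43 <- pol(r43, az, 0)                        # z set per frame
        add(43L, "ARG", "CA", "C", p43, "arg43")
        nctr <- pol(r43 + 4, az, 0)
        for (j in seq_len(70L)) {
          rn <- if (j < 43L) j else j + 1L            # residues 1-71 minus 43
          add(rn, "ALA", "CA", "C", nctr + nblob[j, ], "ndom")
        }
      }
      list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz),
           group = unlist(grp), center = ctr, upper = upper, zsign = zs)
    }

    chains <- list()
    for (i in 1:3) {
      chains[[t1[i]]] <- build_chain(t1[i], i, upper = TRUE)
      chains[[t2[i]]] <- build_chain(t2[i], i, upper = FALSE)
    }
    chain_order <- c("A", "B", "C", "D", "E", "F")
    atoms <- do.call(rbind, lapply(chains[chain_order], `[[`, "atoms"))
    rownames(atoms) <- NULL
    base <- do.call(rbind, lapply(chains[chain_order], `[[`, "xyz"))
    group <- unlist(lapply(chains[chain_order], `[[`, "group"))
    chain_of <- rep(chain_order, vapply(chains[chain_order],
                                        function(c) nrow(c$xyz), 0L))
    n_at <- nrow(base)

    # wobble streams: per chain, AR(1) translation (3) + rotation vector (3)
    wtr <- list(); wrot <- list()
    for (ch in chain_order) {
      wtr[[ch]] <- ar1(nf, 3L, spec$wobble_A / sqrt(3), spec$wobble_rho)
      wrot[[ch]] <- ar1(nf, 3L, (spec$wobble_A / 5) / sqrt(3), spec$wobble_rho)
    }

    lower <- chain_of %in% t2
    core <- group == "core"
    is43 <- group == "arg43"
    ndom <- group == "ndom"

    xyz_mat <- matrix(NA_real_, nf, 3L * n_at)
    centroids <- array(NA_real_, c(nf, 3L, 6L), dimnames = list(NULL, NULL, chain_order))
    probe_dist <- numeric(nf)
    for (f in seq_len(nf)) {
      m <- base
      # trimer-2 core rotates clockwise (viewed from trimer 1, +z) by theta
      Rz <- rot_z(-theta[f])
      sel <- lower & core
      m[sel, ] <- m[sel, , drop = FALSE] %*% t(Rz)
      # Arg43 arms: set pair separation for this frame
      if (spec$include_ndomain) {
        zoff <- d43[f] / 2
        m[is43, 3L] <- ifelse(lower[is43], -zoff, zoff)
        m[ndom, 3L] <- m[ndom, 3L] + ifelse(lower[ndom], -zoff, zoff)
      }
      # per-subunit rigid wobble about the (current) subunit core centroid
      if (spec$wobble_A > 0) {
        for (ch in chain_order) {
          cs <- chain_of == ch
          cc <- colMeans(m[cs & core, , drop = FALSE])
          Rw <- rotvec_mat(wrot[[ch]][f, ])
          m[cs, ] <- sweep(sweep(m[cs, , drop = FALSE], 2L, cc) %*% t(Rw),
                           2L, cc + wtr[[ch]][f, ], `+`)
        }
      }
      if (spec$atom_jitter_A > 0)
        m <- m + matrix(rnorm(length(m), sd = spec$atom_jitter_A), nrow(m), 3L)
      xyz_mat[f, ] <- coord_vec(m)
      for (i in 1:3) {
        centroids[f, , t1[i]] <- chains[[t1[i]]]$center
        centroids[f, , t2[i]] <- as.numeric(rot_z(-theta[f]) %*% chains[[t2[i]]]$center)
      }
      # closed-form R78(NH1)-D82(OD1) cross-pair distance (closest group pair)
      dpsi <- (thc - theta[f]) * pi / 180
      probe_dist[f] <- sqrt((2 * rp * sin(dpsi / 2))^2 + (2 * g)^2)
    }

    traj <- trajectory(atoms, xyz_mat, time_ns = tns, source = "synthetic hexamer")
    rmsf_true <- if (spec$wobble_A == 0)
      spec$atom_jitter_A * sqrt(3) else NA_real_
    truth <- list(theta_deg = theta, theta_ideal_deg = theta_ideal,
                  probe_dist_A = probe_dist,
                  arg43_dist_A = if (spec$include_ndomain) d43 else NULL,
                  centroids = centroids, rmsf_per_residue_A = rmsf_true,
                  time_ns = tns, spec = spec)
    list(trajectory = traj, truth = truth)
  })
}

#' Generate a Gaussian pseudo-trajectory with known covariance
#'
#' Frames are independent draws about a fixed, deterministic mean structure:
#' `x_f = mu + L z_f` with `Sigma = L L'` the requested coordinate covariance
#' (A^2). The analytic Schlitter and quasi-harmonic entropies of the true
#' mass-weighted covariance `M^(1/2) Sigma M^(1/2)` are emitted alongside for
#' convergence checks.
#'
#' @param sigma coordinate covariance, `3N x 3N` symmetric PSD (A^2), or a
#'   length-`3N` vector of variances for a diagonal covariance
#' @param masses per-atom masses in amu (length N)
#' @param n_frames number of independent frames
#' @param seed RNG seed
#' @param temperature_K ensemble temperature for the analytic entropies
#' @return list(trajectory, truth) where truth holds `sigma`, `masses`,
#'   `schlitter_J_molK`, `quasiharmonic_J_molK`
#' @export
generate_gaussian_trajectory <- function(sigma, masses, n_frames, seed = 1L,
                                         temperature_K = 300) {
  if (is.null(dim(sigma))) sigma <- diag(sigma, nrow = length(sigma))
  d <- nrow(sigma)
  if (d != 3L * length(masses))
    stop("sigma dimension must be 3 x length(masses)")
  if (max(abs(sigma - t(sigma))) > 1e-10 * max(1, max(abs(sigma))))
    stop("sigma not symmetric")
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values), 1))
    stop("sigma not positive semidefinite")
  ev <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(ev), d)
  n <- length(masses)
  mu <- coord_vec(blob_template(n, pitch = 2, radius = 5))
  xyz <- with_seed(seed, {
    z <- matrix(rnorm(n_frames * d), n_frames, d)
    sweep(z %*% t(L), 2L, mu, `+`)
  })
  atoms <- data.frame(chain = "A", resno = seq_len(n), resid = "GLY",
                      elety = "CA", element = "C", occ = 1, altloc = "",
                      het = FALSE, ins = "")
  traj <- trajectory(atoms, xyz, time_ns = (seq_len(n_frames) - 1) * 1e-3,
                     source = "synthetic gaussian")
  w <- sqrt(rep(masses, each = 3L))
  mw <- sigma * tcrossprod(w)
  cm <- covariance_model(mw, masses = masses, mass_weighted = TRUE,
                         temperature_K = temperature_K, fit = FALSE)
  # analytic entropies over the strictly positive modes (null modes are
  # stiff-limit modes contributing zero)
  ev_mw <- eigen(mw, symmetric = TRUE, only.values = TRUE)$values
  nzero <- sum(ev_mw <= 1e-12 * max(ev_mw, 1))
  truth <- list(sigma = sigma, masses = masses,
                schlitter_J_molK = if (nzero == d) 0 else
                  schlitter_entropy(cm, dropped_modes = nzero)$value,
                quasiharmonic_J_molK = if (nzero == d) 0 else
                  quasiharmonic_entropy(cm, dropped_modes = nzero)$value)
  list(trajectory = traj, truth = truth)
}
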