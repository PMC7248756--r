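# frozen closed forms (derived by hand from the per-mode formulas):
#   Schlitter single mode with (kB T e^2 / hbar^2) lambda = e^2 - 1:
#     S = (R/2) ln(e^2) = R = 8.314463 J/(mol K)
#   quasi-harmonic mode at alpha = hbar omega / kB T = 1:
#     S = R [1/(e - 1) - ln(1 - 1/e)] = R * 1.0406518 = 8.652461 J/(mol K)
.Rgas <- 8.314462618
.fac <- 1.380649e-23 * 300 * exp(2) / 1.054571817e-34^2 * 1.66053906660e-27 * 1e-20

test_that("fluctuation_covariance: statics, diagonal recovery, tumbling", {
  g <- make_hexamer(theta0_deg = 4, theta_eq_deg = 4, n_frames = 5,
                    include_ndomain = FALSE)
  cov0 <- fluctuation_covariance(g$trajectory, fit = FALSE)
  expect_lt(max(abs(cov0$matrix)), 1e-12)

  # samples from a known diagonal Gaussian recover variances within
  # sampling-theory tolerance 3 v sqrt(2/n)
  set.seed(10)
  v <- runif(30, 0.1, 1)
  gg <- generate_gaussian_trajectory(v, rep(1, 10), n_frames = 4000, seed = 2)
  cv <- fluctuation_covariance(gg$trajectory, mass_weighted = FALSE, fit = FALSE)
  expect_true(all(abs(diag(cv$matrix) - v) < 3 * v * sqrt(2 / 4000) + 0.01))

  # rigidly tumbling, internally static body: fitted covariance ~ 0
  m <- blob30()
  set.seed(12)
  xyz <- t(vapply(1:50, function(f) {
    R <- random_rotation()
    as.numeric(t(m %*% t(R) + matrix(rnorm(3, sd = 5), 30, 3, byrow = TRUE)))
  }, numeric(90)))
  tr <- trajectory(frame_from_coords(m)$atoms, xyz)
  cvt <- fluctuation_covariance(tr, mass_weighted = FALSE, fit = TRUE)
  expect_lt(max(eigen(cvt$matrix, symmetric = TRUE, only.values = TRUE)$values),
            1e-6)
})

test_that("fitted covariance has a six-mode rigid-body null space", {
  g <- make_hexamer(atom_jitter_A = 0.2, n_frames = 300,
                    include_ndomain = FALSE, seed = 6)
  sel <- select_atoms(g$trajectory, chains = "A")
  cv <- fluctuation_covariance(g$trajectory, selection = sel, fit = TRUE,
                               mass_weighted = FALSE)
  ev <- sort(eigen(cv$matrix, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(ev[6] , 1e-6 * median(ev))
  expect_gt(ev[7], 1e-3 * median(ev))
})

test_that("Schlitter entropy closed forms and guards", {
  expect_equal(schlitter_entropy(covariance_model(matrix(0, 3, 3)),
                                 dropped_modes = 0)$value, 0)
  lam <- (exp(2) - 1) / .fac
  cm <- covariance_model(matrix(lam), mass_weighted = TRUE)
  expect_equal(schlitter_entropy(cm, dropped_modes = 0)$value, .Rgas,
               tolerance = 1e-9)
  expect_error(schlitter_entropy(covariance_model(matrix(1),
                                                  mass_weighted = FALSE)),
               "mass-weighted")
  expect_error(covariance_model(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("quasi-harmonic entropy closed forms, limits and bound", {
  lam_alpha1 <- 1.054571817e-34^2 / (1.380649e-23 * 300) /
    (1.66053906660e-27 * 1e-20)
  cm <- covariance_model(matrix(lam_alpha1), mass_weighted = TRUE)
  expect_equal(quasiharmonic_entropy(cm, dropped_modes = 0)$value,
               .Rgas * 1.0406518, tolerance = 1e-6)
  # stiff-mode limit: contribution -> 0
  stiff <- covariance_model(matrix(lam_alpha1 * 1e-6), mass_weighted = TRUE)
  expect_lt(quasiharmonic_entropy(stiff, dropped_modes = 0)$value, 1e-3)
  expect_error(quasiharmonic_entropy(covariance_model(matrix(0)),
                                     dropped_modes = 0), "non-positive")

  # Schlitter is an upper bound on every random PSD fixture
  set.seed(30)
  for (rep in 1:5) {
    d <- 9
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) / d * 0.1
    cm2 <- covariance_model(S, mass_weighted = TRUE)
    s <- schlitter_entropy(cm2, dropped_modes = 0)$value
    q <- quasiharmonic_entropy(cm2, dropped_modes = 0)$value
    expect_gte(s, q)
    # orthogonal change of basis leaves both invariant
    Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    cm3 <- covariance_model(Q %*% S %*% t(Q), mass_weighted = TRUE)
    expect_equal(schlitter_entropy(cm3, dropped_modes = 0)$value, s,
                 tolerance = 1e-6)
    expect_equal(quasiharmonic_entropy(cm3, dropped_modes = 0)$value, q,
                 tolerance = 1e-6)
  }
})

test_that("entropy_difference closed forms and sampling behavior", {
  S <- diag(runif(12, 0.5, 2))
  ca <- covariance_model(S, mass_weighted = TRUE)
  expect_equal(entropy_difference(ca, ca, dropped_modes = 0), 0)
  cb <- covariance_model(2 * S, mass_weighted = TRUE)
  expect_equal(entropy_difference(cb, ca, dropped_modes = 0),
               .Rgas / 2 * 12 * log(2), tolerance = 1e-9)
  expect_error(entropy_difference(ca, covariance_model(diag(3))),
               "mismatch")
  # sampled Gaussian fixtures approach the closed form
  v <- rep(0.4, 15)
  ga <- generate_gaussian_trajectory(2 * v, rep(12, 5), 6000, seed = 3)
  gb <- generate_gaussian_trajectory(v, rep(12, 5), 6000, seed = 4)
  cva <- fluctuation_covariance(ga$trajectory, fit = FALSE, masses = rep(12, 5))
  cvb <- fluctuation_covariance(gb$trajectory, fit = FALSE, masses = rep(12, 5))
  expect_equal(entropy_difference(cva, cvb, dropped_modes = 0),
               .Rgas / 2 * 15 * log(2), tolerance = 0.15 * .Rgas / 2 * 15 * log(2))
})

test_that("pca_modes recovers planted structure", {
  cm <- covariance_model(diag(c(4, rep(1, 8))), mass_weighted = FALSE)
  p <- pca_modes(cm, 2)
  expect_equal(p$values[1], 4)
  expect_equal(abs(p$vectors[1, 1]), 1, tolerance = 1e-9)
  # planted two-mode covariance
  set.seed(40)
  d <- 12
  u1 <- rnorm(d); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- rnorm(d); u2 <- u2 - sum(u2 * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  S <- 5 * tcrossprod(u1) + 2 * tcrossprod(u2) + 0.01 * diag(d)
  p2 <- pca_modes(covariance_model(S, mass_weighted = FALSE), 2)
  expect_gt(abs(sum(p2$vectors[, 1] * u1)), 0.999)
  expect_gt(abs(sum(p2$vectors[, 2] * u2)), 0.999)
  # full basis is orthonormal
  pf <- pca_modes(covariance_model(S, mass_weighted = FALSE))
  expect_lt(max(abs(crossprod(pf$vectors) - diag(d))), 1e-8)
})

test_that("projection separates rotation from wobble (the PCA argument)", {
  # evolving rotation: the dominant mode tracks the rotation time course
  g <- make_hexamer(theta0_deg = 10, theta_eq_deg = 22, tau_ns = 100,
                    wobble_A = 0.15, n_frames = 300, include_ndomain = FALSE,
                    seed = 8)
  sel <- select_atoms(g$trajectory, resno = c(85, 149), elety = "CA")
  cv <- fluctuation_covariance(g$trajectory, selection = sel)
  pm <- pca_modes(cv, 3)
  pr <- project_trajectory(g$trajectory, cv, pm$vectors)
  rot <- rotation_series(g$trajectory, topo)
  expect_gt(abs(cor(pr$projections[, 1], rot$per_frame_mean)), 0.9)
  expect_equal(pr$extremes$mode, 1:3)

  # wobble only: no mode correlates strongly with the apparent angle
  gw <- make_hexamer(wobble_A = 0.3, n_frames = 300,
                     include_ndomain = FALSE, seed = 9)
  cvw <- fluctuation_covariance(gw$trajectory,
                                selection = select_atoms(gw$trajectory,
                                                         resno = c(85, 149),
                                                         elety = "CA"))
  pmw <- pca_modes(cvw, 3)
  prw <- project_trajectory(gw$trajectory, cvw, pmw$vectors)
  rotw <- rotation_series(gw$trajectory, topo)
  expect_lt(abs(cor(prw$projections[, 1], rotw$per_frame_mean)), 0.6)

  # static trajectory projects to zero
  g0 <- make_hexamer(theta0_deg = 5, theta_eq_deg = 5, n_frames = 4,
                     include_ndomain = FALSE)
  cv0 <- fluctuation_covariance(g0$trajectory, fit = FALSE)
  pr0 <- project_trajectory(g0$trajectory, cv0, diag(ncol(cv0$matrix))[, 1:2])
  expect_lt(max(abs(pr0$projections)), 1e-9)
})
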