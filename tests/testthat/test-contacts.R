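# distance-series fixture: two atoms whose separation follows `d`
two_atom_traj <- function(d) {
  at <- data.frame(chain = c("A", "B"), resno = c(1L, 1L), resid = "GLY",
                   elety = c("NZ", "OD1"), element = c("N", "O"), occ = 1,
                   altloc = "", het = FALSE, ins = "")
  xyz <- cbind(0, 0, 0, d, 0, 0)
  trajectory(at, xyz)
}

nz_od1 <- contact_spec("t", list(chain = "A", resno = 1, atoms = "NZ"),
                       list(chain = "B", resno = 1, atoms = "OD1"))

test_that("distance_series: constants, group min reduction, truth match", {
  tr <- two_atom_traj(rep(3, 5))
  expect_equal(as.numeric(distance_series(tr, nz_od1)), rep(3, 5))

  # NH1 at 4 A, NH2 at 2.8 A from the acceptor: min reduction gives 2.8
  at <- data.frame(chain = c("A", "A", "B"), resno = c(1L, 1L, 2L),
                   resid = c("ARG", "ARG", "ASP"),
                   elety = c("NH1", "NH2", "OD1"), element = c("N", "N", "O"),
                   occ = 1, altloc = "", het = FALSE, ins = "")
  tr2 <- trajectory(at, matrix(c(4, 0, 0, 2.8, 0, 0, 0, 0, 0), nrow = 1))
  sp <- contact_spec("g", list(chain = "A", resno = 1, atoms = c("NH1", "NH2")),
                     list(chain = "B", resno = 2, atoms = "OD1"))
  expect_equal(as.numeric(distance_series(tr2, sp)), 2.8)
  # min-reduction series is frame-wise <= any specific pair
  sp1 <- contact_spec("p", list(chain = "A", resno = 1, atoms = "NH1"),
                      list(chain = "B", resno = 2, atoms = "OD1"))
  expect_lte(distance_series(tr2, sp)[1], distance_series(tr2, sp1)[1])

  # linear 8 -> 3 A course matches the generating table exactly
  course <- seq(8, 3, length.out = 11)
  tr3 <- two_atom_traj(course)
  expect_equal(as.numeric(distance_series(tr3, nz_od1)), course,
               tolerance = 1e-12)
  expect_error(distance_series(tr3, contact_spec(
    "bad", list(chain = "A", resno = 99, atoms = "NZ"),
    list(chain = "B", resno = 1, atoms = "OD1"))), "unresolvable")
})

test_that("occupancy conventions are strict at both thresholds", {
  expect_equal(contact_occupancy(rep(2.8, 10)), 1.0)
  expect_equal(contact_occupancy(rep(c(2.8, 3.5), 5)), 0.5)
  expect_equal(contact_occupancy(rep(3.0, 10)), 0.0)   # strict <
  # monotone non-decreasing in the cutoff
  set.seed(4)
  s <- runif(200, 2, 5)
  cuts <- seq(2, 5, by = 0.25)
  occ <- vapply(cuts, function(cc) contact_occupancy(s, cutoff_A = cc), 0)
  expect_true(all(diff(occ) >= 0))
  # windowing by time
  s2 <- c(rep(5, 5), rep(2.5, 5))
  expect_equal(contact_occupancy(s2, window = list(last_frac = 0.5),
                                 time_ns = 0:9), 1.0)
})

test_that("score_hbond_table reproduces constructed per-hexamer counts", {
  # hold the probe contact at exactly theta_contact for 4 of 6 directed pairs:
  # rotate to contact and displace two chains' D82 acceptors out of reach
  g <- make_hexamer(theta0_deg = 22, theta_eq_deg = 22, theta_contact_deg = 22,
                    probe_contact_A = 2.8, n_frames = 10,
                    include_ndomain = FALSE)
  tr <- g$trajectory
  # push chain D and E D82 oxygens 10 A upward: breaks acceptors for the
  # C.R78->D.D82 and B.R78->E.D82 instances only
  mask <- tr$atoms$chain %in% c("D", "E") & tr$atoms$resno == 82 &
    tr$atoms$elety %in% c("OD1", "OD2", "O")
  tr$xyz[, 3 * which(mask)] <- tr$xyz[, 3 * which(mask)] - 10
  cand <- data.frame(name = "R78-D82", donor_resno = 78L,
                     donor_atoms = "NH1/NH2/NE", acceptor_resno = 82L,
                     acceptor_atoms = "OD1/OD2", scope = "paired")
  tab <- score_hbond_table(tr, topo, cand, window = NULL)
  expect_equal(tab$count_per_hexamer, 4L)
  expect_lte(tab$count_per_hexamer, 6L)

  # untouched contact geometry: all six instances at occupancy exactly 1
  tab6 <- score_hbond_table(g$trajectory, topo, cand, window = NULL)
  expect_equal(tab6$count_per_hexamer, 6L)
  expect_equal(tab6$max_occupancy, 1.0)

  # all pairs >= 3 A: empty report, full table retrievable
  g_far <- make_hexamer(n_frames = 4, include_ndomain = FALSE)
  tab0 <- score_hbond_table(g_far$trajectory, topo, cand, window = NULL)
  expect_equal(nrow(tab0), 0L)
  expect_equal(attr(tab0, "all")$count_per_hexamer, 0L)
})

test_that("exactly 50% occupancy is not scored (strictly more required)", {
  # distance alternates 2.9 / 3.1 over an even count within one chain pair
  at <- data.frame(chain = c("A", "F"), resno = c(78L, 82L),
                   resid = c("ARG", "ASP"), elety = c("NH1", "OD1"),
                   element = c("N", "O"), occ = 1, altloc = "", het = FALSE,
                   ins = "")
  d <- rep(c(2.9, 3.1), 5)
  tr <- trajectory(rbind(at, within(at, chain <- c("B", "E")),
                         within(at, chain <- c("C", "D"))),
                   cbind(0, 0, 0, d, 0, 0,
                         20, 0, 0, 20 + d, 0, 0,
                         40, 0, 0, 40 + d, 0, 0))
  cand <- data.frame(name = "half", donor_resno = 78L, donor_atoms = "NH1",
                     acceptor_resno = 82L, acceptor_atoms = "OD1",
                     scope = "paired")
  tab <- suppressWarnings(
    score_hbond_table(tr, topo, cand, window = NULL, keep_zero = TRUE))
  expect_equal(tab$count_per_hexamer, 0L)
  expect_equal(tab$max_occupancy, 0.5)
})

test_that("saltbridge_panel covers pairs in both directions and warns on gaps", {
  g <- make_hexamer(n_frames = 3, include_ndomain = FALSE)
  panel <- saltbridge_panel(g$trajectory, topo)
  r78 <- panel[panel$contact == "R78_D82", ]
  expect_equal(nrow(r78), 6 * 3)                    # 3 pairs x 2 dirs x 3 frames
  expect_setequal(unique(paste(r78$chain_a, r78$chain_b)),
                  c("A F", "F A", "B E", "E B", "C D", "D C"))
  # eclipsed geometry: all series equal the recorded truth
  expect_equal(r78$distance_A, rep(g$truth$probe_dist_A, 6), tolerance = 1e-9)

  # remove one chain's probe atoms -> warning, remaining series survive
  tr <- g$trajectory
  keep <- !(tr$atoms$chain == "A" & tr$atoms$resno == 78)
  tr2 <- trajectory(tr$atoms[keep, ],
                    tr$xyz[, xyz_cols_test(which(keep)), drop = FALSE])
  expect_warning(p2 <- saltbridge_panel(tr2, topo), "skipping")
  expect_lt(nrow(p2), nrow(panel))
})
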