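test_that("multi-model PDB reading preserves atoms, order and coordinates", {
  f <- write_tmp_pdb(mini_pdb_lines())
  tr <- read_pdb_trajectory(f)
  expect_equal(n_frames(tr), 2L)
  expect_equal(n_atoms(tr), 4L)
  expect_equal(tr$atoms$chain, c("A", "A", "B", "B"))
  expect_equal(tr$atoms$resno, c(85L, 86L, 85L, 86L))
  expect_equal(tr$xyz[1, 1:3], c(0, 0, 0))
  expect_equal(tr$xyz[2, 4:6], c(1.1, 0, 0))
})

test_that("altloc policies pick the right atom", {
  lines <- c(
    "ATOM      1  CA AALA A  10       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A  10       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB  ALA A  10       3.000   0.000   0.000  1.00  0.00           C",
    "END")
  f <- write_tmp_pdb(lines)
  tr <- read_pdb_trajectory(f)                       # default: occupancy
  expect_equal(n_atoms(tr), 2L)
  expect_equal(tr$xyz[1, 1], 1.0)                    # altloc A, occ 0.6
  tr_first <- read_pdb_trajectory(f, altloc_policy = "first")
  expect_equal(tr_first$xyz[1, 1], 1.0)
  tr_all <- read_pdb_trajectory(f, altloc_policy = "all")
  expect_equal(n_atoms(tr_all), 3L)
})

test_that("reader errors: bad record, zero atoms, model mismatch", {
  bad <- mini_pdb_lines()
  bad[2] <- "ATOM      1  CA  ALA A  85       x.xxx   0.000   0.000  1.00  0.00           C"
  expect_error(read_pdb_trajectory(write_tmp_pdb(bad)), "line 2")
  expect_error(read_pdb_trajectory(write_tmp_pdb(c("HEADER", "END"))), "zero atoms")
  uneven <- mini_pdb_lines()[-3]                     # drop one atom from model 1
  expect_error(read_pdb_trajectory(write_tmp_pdb(uneven)), "different atom set")
  expect_error(read_pdb_trajectory(tempfile()), "no such file")
})

test_that("write/read round trip reproduces coordinates to PDB precision", {
  g <- make_hexamer(theta0_deg = 7, theta_eq_deg = 7, n_frames = 3,
                    wobble_A = 0.3, seed = 5)
  f <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(g$trajectory, f)
  tr2 <- read_pdb_trajectory(f)
  expect_equal(n_frames(tr2), 3L)
  expect_equal(tr2$atoms$elety, g$trajectory$atoms$elety)
  expect_equal(tr2$atoms$resno, g$trajectory$atoms$resno)
  expect_lt(max(abs(tr2$xyz - g$trajectory$xyz)), 1e-3 + 1e-9)
})

test_that("select_atoms: ranges, heavy-only, coverage, unknown chain", {
  g <- make_hexamer(n_frames = 1)
  tr <- g$trajectory
  idx <- select_atoms(tr, chains = "A", resno = c(85, 149), elety = "CA")
  expect_length(idx, 65L)
  expect_equal(attr(idx, "coverage"), 1)
  # residues 50-60 exist only in the N-domain blob; 43 is a single CA
  idx43 <- select_atoms(tr, chains = "A", resno = 43, elety = "CA")
  expect_length(idx43, 1L)
  # requesting a range with gaps reports partial coverage (72-84 only has
  # the three probe residues 75, 78, 82)
  idx_gap <- select_atoms(tr, chains = "A", resno = c(72, 84))
  expect_equal(attr(idx_gap, "coverage"), 3 / 13)
  expect_error(select_atoms(tr, chains = "Z"), "unknown chain")
  expect_error(select_atoms(tr, chains = "A", resno = c(200, 300)),
               "empty")
  # heavy-only drops hydrogens
  at <- tr$atoms[1:2, ]
  at$element[2] <- "H"
  hy <- trajectory(at, tr$xyz[1, 1:6, drop = FALSE])
  expect_length(select_atoms(hy, heavy_only = TRUE), 1L)
})

test_that("expand_assembly relabels, transforms exactly, and validates", {
  g <- make_hexamer(n_frames = 1, include_ndomain = FALSE)
  tr <- g$trajectory
  abc <- select_atoms(tr, chains = c("A", "B", "C"))
  fr <- frame_from_coords(matrix(tr$xyz[1, xyz_cols_test(abc)], ncol = 3,
                                 byrow = TRUE))
  fr$atoms <- tr$atoms[abc, ]
  # identity relabeling duplicates coordinates under new chains
  ident <- list(list(R = diag(3), t = c(0, 0, 0),
                     chain_map = c(A = "D", B = "E", C = "F")))
  out <- expand_assembly(fr, ident)
  expect_setequal(unique(out$atoms$chain), c("A", "B", "C", "D", "E", "F"))
  expect_equal(out$xyz[seq_along(fr$xyz)], fr$xyz)
  expect_equal(out$xyz[-seq_along(fr$xyz)], fr$xyz)
  # closed-form 60 degree rotation about z
  Rz <- rot_z_deg(60)
  out2 <- expand_assembly(fr, list(list(R = Rz, t = c(0, 0, 0),
                                        chain_map = c(A = "D", B = "E", C = "F"))))
  m <- matrix(fr$xyz, ncol = 3, byrow = TRUE)
  expect_equal(matrix(out2$xyz, ncol = 3, byrow = TRUE)[-seq_len(nrow(m)), ],
               m %*% t(Rz), tolerance = 1e-12)
  # intra-chain distances preserved
  d0 <- dist(m[1:20, ])
  d1 <- dist(matrix(out2$xyz, ncol = 3, byrow = TRUE)[nrow(m) + 1:20, ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  # improper transform and chain collisions are rejected
  refl <- diag(c(-1, 1, 1))
  expect_error(expand_assembly(fr, list(list(R = refl, t = c(0, 0, 0),
                                             chain_map = c(A = "D")))),
               "improper")
  expect_error(expand_assembly(fr, list(list(R = diag(3), t = c(0, 0, 0),
                                             chain_map = c(A = "B")))),
               "collision")
})

test_that("hexamer_topology validates its invariants", {
  expect_error(hexamer_topology(trimer1_chains = c("A", "B", "C"),
                                trimer2_chains = c("C", "D", "E")),
               "overlap")
  expect_error(hexamer_topology(pairing = list(c("A", "B"), c("C", "D"),
                                               c("E", "F"))),
               "span")
  expect_error(hexamer_topology(n_domain_range = c(1, 70)), "partition")
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_topology_json(topo, f)
  t2 <- read_topology_json(f)
  expect_equal(t2$pairing, topo$pairing)
  expect_equal(t2$com_residue_range, topo$com_residue_range)
  expect_equal(t2$probe_atoms$R78_guanidino$atoms, c("NH1", "NH2", "NE"))
})
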