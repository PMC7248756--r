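# Shared fixture builders. Everything is generated in code; no binary data.

topo <- hexamer_topology()

# quick hexamer generator with test-friendly defaults
make_hexamer <- function(...) {
  generate_hexamer_trajectory(synthetic_spec(...))
}

# a minimal hand-written two-model PDB text (2 chains x 2 atoms)
mini_pdb_lines <- function() {
  c("MODEL        1",
    "ATOM      1  CA  ALA A  85       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  86       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA B  85       0.000   2.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA B  86       0.000   3.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A  85       0.100   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  86       1.100   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA B  85       0.000   2.100   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA B  86       0.000   3.100   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# a frame of n atoms at given coordinates (single chain, CA pseudo-atoms)
frame_from_coords <- function(m, chain = "A", elety = "CA", element = "C",
                              resno = NULL) {
  n <- nrow(m)
  if (is.null(resno)) resno <- seq_len(n)
  at <- data.frame(chain = chain, resno = resno, resid = "ALA", elety = elety,
                   element = element, occ = 1, altloc = "", het = FALSE,
                   ins = "")
  get_frame(trajectory(at, matrix(as.numeric(t(m)), nrow = 1)), 1)
}

rot_z_deg <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y_deg <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# apply a global rigid motion to every frame of a trajectory
transform_traj <- function(traj, R, t) {
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.numeric(t(m %*% t(R) +
                               matrix(t, nrow(m), 3, byrow = TRUE)))
  }
  out <- traj
  out$xyz <- xyz
  out
}

# xyz column indices for atom indices (mirrors the internal layout)
xyz_cols_test <- function(idx) as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

# reproducible 30-atom blob
blob30 <- function() {
  set.seed(2)
  matrix(rnorm(90, sd = 4), ncol = 3)
}

# random proper rotation (seeded by caller)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
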