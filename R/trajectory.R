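#' @importFrom stats sd var rnorm runif cor median setNames
#' @importFrom utils head tail write.table
NULL

# ---- containers -------------------------------------------------------------

#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames sharing one atom table. Coordinates
#' are stored as an `n_frames x 3N` matrix in Angstrom, columns grouped per atom
#' as (x1, y1, z1, x2, y2, z2, ...), the layout used by most MD post-processing
#' codes.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `element`, `occ`, `altloc`, `het` describing the N atoms (author residue
#'   numbering is preserved exactly).
#' @param xyz numeric matrix `n_frames x 3N` (a numeric vector of length `3N`
#'   is accepted for a single frame).
#' @param time_ns numeric vector of frame times in ns, strictly increasing.
#' @param source provenance string.
#' @return object of class `oligo_traj`.
#' @export
trajectory <- function(atoms, xyz, time_ns = NULL, source = "constructed") {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(is.data.frame(atoms), is.matrix(xyz))
  need <- c("chain", "resno", "resid", "elety", "element", "occ", "altloc", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but atom table implies ", 3L * nrow(atoms))
  if (nrow(xyz) < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(time_ns)) time_ns <- seq_len(nrow(xyz)) - 1
  if (length(time_ns) != nrow(xyz)) stop("time_ns length mismatch")
  if (any(time_ns < 0)) stop("negative frame time")
  if (nrow(xyz) > 1L && any(diff(time_ns) <= 0)) stop("time_ns must be strictly increasing")
  structure(list(atoms = atoms, xyz = xyz, time_ns = as.numeric(time_ns),
                 source = source),
            class = "oligo_traj")
}

#' Number of frames / atoms in a trajectory
#' @param traj an `oligo_traj`
#' @return integer count
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Extract a single frame
#'
#' @param traj an `oligo_traj`
#' @param i frame index
#' @return an `oligo_frame`: the atom table plus one coordinate vector.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  structure(list(atoms = traj$atoms, xyz = traj$xyz[i, ],
                 time_ns = traj$time_ns[i]),
            class = "oligo_frame")
}

#' Promote a frame to a one-frame trajectory
#' @param frame an `oligo_frame`
#' @return an `oligo_traj` with a single frame
#' @export
as_trajectory <- function(frame) {
  stopifnot(inherits(frame, "oligo_frame"))
  trajectory(frame$atoms, matrix(frame$xyz, nrow = 1L), frame$time_ns,
             source = "frame")
}

#' @export
print.oligo_traj <- function(x, ...) {
  cat(sprintf("<oligo_traj> %d frame(s), %d atoms, %d chain(s) [%s], t = %.4g..%.4g ns\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ""),
              x$time_ns[1], x$time_ns[n_frames(x)]))
  invisible(x)
}

#' @export
print.oligo_frame <- function(x, ...) {
  cat(sprintf("<oligo_frame> %d atoms, t = %.4g ns\n", nrow(x$atoms), x$time_ns))
  invisible(x)
}

# reshape one frame's coordinate vector to an N x 3 matrix
coord_mat <- function(xyz_vec) matrix(xyz_vec, ncol = 3L, byrow = TRUE)
# inverse of coord_mat
coord_vec <- function(m) as.numeric(t(m))
# xyz column indices for atom indices
xyz_cols <- function(idx) as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))

# ---- element handling -------------------------------------------------------

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, K = 39.098, NA. = 22.990, CL = 35.45,
                     MG = 24.305, FE = 55.845, ZN = 65.38, CA. = 40.078)

#' Atomic masses for an atom table
#' @param atoms atom data.frame (as in [trajectory()])
#' @return numeric vector of masses in amu
#' @export
atom_masses <- function(atoms) {
  el <- toupper(atoms$element)
  m <- .element_masses[el]
  names(m) <- NULL
  if (anyNA(m)) {
    bad <- unique(el[is.na(m)])
    warning("unknown element(s) ", paste(bad, collapse = ","), "; using 12.011")
    m[is.na(m)] <- 12.011
  }
  m
}

# infer element from a PDB atom name when columns 77-78 are blank
infer_element <- function(elety) {
  nm <- gsub("[0-9' ]", "", elety)
  el <- toupper(substr(nm, 1L, 1L))
  # two-letter ions/metals written flush left in full 4-char names
  two <- toupper(substr(nm, 1L, 2L))
  el[two %in% c("CL", "MG", "FE", "ZN", "NA")] <- two[two %in% c("CL", "MG", "FE", "ZN", "NA")]
  el
}

# ---- PDB reading ------------------------------------------------------------

#' Read a (multi-model) PDB file as a trajectory
#'
#' One frame per `MODEL` record; a file without `MODEL` records yields a single
#' frame. Hydrogens are retained (use `heavy_only` selections downstream).
#' Alternate locations are resolved per the chosen policy; insertion codes are
#' appended to the residue key. `HETATM` records are kept and flagged.
#'
#' @param path PDB file path.
#' @param altloc_policy `"occupancy"` (default: keep the highest-occupancy
#'   altloc, ties broken by file order), `"first"` (first listed), or `"all"`
#'   (keep every altloc; duplicate keys then allowed).
#' @param frame_interval_ns nominal time between models, used to stamp frames.
#' @return an `oligo_traj`.
#' @export
read_pdb_trajectory <- function(path, altloc_policy = c("occupancy", "first", "all"),
                                frame_interval_ns = 1) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) stop("zero atoms in ", path)

  # frame id per line: cumulative MODEL count (0 when no MODEL records)
  fid <- cumsum(is_model)
  afid <- fid[is_atom]
  if (max(fid) == 0L) afid <- rep(1L, sum(is_atom))
  al <- lines[is_atom]
  lineno <- which(is_atom)

  num <- function(s, from, to, what) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v))
      stop("unparsable ", what, " in PDB record at line ",
           lineno[which(is.na(v))[1L]])
    v
  }
  elety <- trimws(substr(al, 13L, 16L))
  altloc <- substr(al, 17L, 17L)
  resid <- trimws(substr(al, 18L, 20L))
  chain <- substr(al, 22L, 22L)
  resno <- as.integer(num(al, 23L, 26L, "residue number"))
  icode <- trimws(substr(al, 27L, 27L))
  x <- num(al, 31L, 38L, "x"); y <- num(al, 39L, 46L, "y"); z <- num(al, 47L, 54L, "z")
  occ <- suppressWarnings(as.numeric(substr(al, 55L, 60L)))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(al, 77L, 78L))
  element[element == ""] <- infer_element(elety[element == ""])
  het <- substr(al, 1L, 6L) == "HETATM"
  reskey <- paste0(resno, icode)

  atoms_all <- data.frame(chain = chain, resno = resno, resid = resid,
                          elety = elety, element = toupper(element), occ = occ,
                          altloc = trimws(altloc), het = het, ins = icode,
                          frame = afid, x = x, y = y, z = z,
                          stringsAsFactors = FALSE)

  resolve <- function(df) {
    if (altloc_policy == "all" || all(df$altloc == "")) return(df)
    key <- paste(df$chain, df$resno, df$ins, df$elety, sep = "\r")
    keep <- logical(nrow(df))
    for (k in split(seq_len(nrow(df)), key)) {
      if (length(k) == 1L) { keep[k] <- TRUE; next }
      pick <- switch(altloc_policy,
                     occupancy = k[which.max(df$occ[k])],
                     first = k[1L])
      keep[pick] <- TRUE
    }
    df[keep, , drop = FALSE]
  }

  frames <- split(atoms_all, atoms_all$frame)
  frames <- lapply(frames, resolve)
  key0 <- with(frames[[1L]], paste(chain, resno, ins, elety, altloc, sep = "\r"))
  if (altloc_policy != "all" && anyDuplicated(key0))
    stop("duplicate atom key after altloc resolution: ",
         key0[duplicated(key0)][1L])
  for (i in seq_along(frames)) {
    ki <- with(frames[[i]], paste(chain, resno, ins, elety, altloc, sep = "\r"))
    if (length(ki) != length(key0) || any(ki != key0))
      stop("model ", i, " has a different atom set/order than model 1")
  }
  xyz <- t(vapply(frames, function(df) coord_vec(as.matrix(df[, c("x", "y", "z")])),
                  numeric(3L * nrow(frames[[1L]]))))
  if (length(frames) == 1L) xyz <- matrix(xyz, nrow = 1L)
  at <- frames[[1L]][, c("chain", "resno", "resid", "elety", "element",
                         "occ", "altloc", "het", "ins")]
  rownames(at) <- NULL
  trajectory(at, xyz, time_ns = (seq_along(frames) - 1) * frame_interval_ns,
             source = path)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' Coordinates are written with the standard 8.3 fixed format, so a round trip
#' preserves them to 1e-3 Angstrom.
#'
#' @param traj an `oligo_traj`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb_trajectory <- function(traj, path) {
  at <- traj$atoms
  nf <- n_frames(traj)
  serial <- seq_len(nrow(at)) %% 100000L
  # atom-name column rules: 1-3 char names start in column 14
  nm <- ifelse(nchar(at$elety) >= 4L, substr(at$elety, 1L, 4L),
               paste0(" ", formatC(at$elety, width = -3)))
  recname <- ifelse(at$het, "HETATM", "ATOM  ")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    m <- coord_mat(traj$xyz[f, ])
    writeLines(sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       recname, serial, nm, substr(paste0(at$altloc, " "), 1L, 1L),
                       at$resid, at$chain, at$resno,
                       substr(paste0(at$ins, " "), 1L, 1L),
                       m[, 1L], m[, 2L], m[, 3L], at$occ, 0,
                       formatC(at$element, width = 2)), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- selection --------------------------------------------------------------

#' Select atoms by chain / residue range / atom name
#'
#' Returns indices into the atom table in input order (chain, residue, atom
#' order as read). Selections silently skip residues absent from the structure
#' (crystal gaps) but report the covered fraction of the requested residue
#' range as attribute `coverage`.
#'
#' @param x an `oligo_traj` or `oligo_frame` (or an atom data.frame).
#' @param chains chain ids to keep (NULL = all). Unknown chain ids error.
#' @param resno residue numbers to keep; a length-2 vector is treated as an
#'   inclusive range (NULL = all).
#' @param elety atom names to keep (NULL = all).
#' @param heavy_only drop hydrogens.
#' @param het NA = keep both ATOM and HETATM; TRUE/FALSE to restrict.
#' @param allow_empty permit an empty result (default FALSE: empty errors).
#' @return integer vector of atom indices with attribute `coverage`.
#' @export
select_atoms <- function(x, chains = NULL, resno = NULL, elety = NULL,
                         heavy_only = FALSE, het = NA, allow_empty = FALSE) {
  at <- if (is.data.frame(x)) x else x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(at$chain))
    if (length(unknown)) stop("unknown chain id(s): ", paste(unknown, collapse = ","))
    keep <- keep & at$chain %in% chains
  }
  rset <- NULL
  if (!is.null(resno)) {
    rset <- if (length(resno) == 2L) seq(resno[1L], resno[2L]) else resno
    keep <- keep & at$resno %in% rset
  }
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (heavy_only) keep <- keep & at$element != "H"
  if (!is.na(het)) keep <- keep & at$het == het
  idx <- which(keep)
  if (!length(idx) && !allow_empty) stop("empty atom selection")
  cov <- if (is.null(rset)) 1 else {
    present <- unique(at$resno[idx])
    length(intersect(rset, present)) / length(rset)
  }
  attr(idx, "coverage") <- cov
  idx
}

# ---- assembly expansion -----------------------------------------------------

#' Expand an assembly by applying rigid transforms with chain relabeling
#'
#' Used to build a biological hexamer from a trimer deposited with crystal
#' symmetry (the operators must be supplied explicitly; they are not deduced
#' from the file).
#'
#' @param frame an `oligo_frame`
#' @param transforms list of transforms, each
#'   `list(R = 3x3 rotation, t = length-3 translation, chain_map = named
#'   character vector old -> new)`. Rotations must be proper (det +1,
#'   orthonormal).
#' @return an `oligo_frame` containing the original atoms plus the transformed
#'   copies under their new chain ids.
#' @export
expand_assembly <- function(frame, transforms) {
  stopifnot(inherits(frame, "oligo_frame"))
  at <- frame$atoms
  m <- coord_mat(frame$xyz)
  new_at <- list(at); new_xyz <- list(m)
  seen <- unique(at$chain)
  for (tr in transforms) {
    R <- tr$R; tt <- tr$t; cm <- tr$chain_map
    stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)), length(tt) == 3L)
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) stop("transform rotation not orthonormal")
    if (det(R) < 0) stop("improper transform (det(R) = ", round(det(R), 3), ")")
    sel <- at$chain %in% names(cm)
    if (!any(sel)) stop("chain_map matches no chains")
    newc <- unname(cm[at$chain[sel]])
    if (any(newc %in% seen)) stop("chain-id collision: ",
                                  paste(intersect(newc, seen), collapse = ","))
    seen <- c(seen, unique(newc))
    a2 <- at[sel, , drop = FALSE]
    a2$chain <- newc
    new_at <- c(new_at, list(a2))
    new_xyz <- c(new_xyz, list(m[sel, , drop = FALSE] %*% t(R) +
                                 matrix(tt, nrow = sum(sel), ncol = 3L, byrow = TRUE)))
  }
  at_out <- do.call(rbind, new_at)
  rownames(at_out) <- NULL
  structure(list(atoms = at_out,
                 xyz = coord_vec(do.call(rbind, new_xyz)),
                 time_ns = frame$time_ns),
            class = "oligo_frame")
}

# ---- hexamer topology -------------------------------------------------------

#' Describe the hexamer topology
#'
#' Encodes the chain grouping into two trimers, the cross-trimer subunit
#' pairing, the residue ranges used for rotation centers of mass and for the
#' N/C domain split, and named probe-atom groups. Defaults follow the BsArgR
#' conventions: trimers A,B,C / D,E,F paired A-F, B-E, C-D; rotation CoM over
#' C-alpha of residues 85-149; N domain 1-71, C domain 72-149; probe groups for
#' the Lys75/Arg78/Asp82 salt-bridge triad and the Arg43 C-alpha.
#'
#' @param trimer1_chains,trimer2_chains three chain ids each, disjoint.
#' @param pairing list of length-2 chain vectors, one chain of each trimer per
#'   pair, covering every chain exactly once.
#' @param com_residue_range inclusive residue interval for rotation centroids.
#' @param n_domain_range,c_domain_range inclusive residue intervals; must abut.
#' @param probe_atoms named list, each `list(resno =, atoms =)`.
#' @return object of class `hexamer_topology`.
#' @export
hexamer_topology <- function(trimer1_chains = c("A", "B", "C"),
                             trimer2_chains = c("D", "E", "F"),
                             pairing = list(c("A", "F"), c("B", "E"), c("C", "D")),
                             com_residue_range = c(85L, 149L),
                             n_domain_range = c(1L, 71L),
                             c_domain_range = c(72L, 149L),
                             probe_atoms = list(
                               K75_amine = list(resno = 75L, atoms = "NZ"),
                               R78_guanidino = list(resno = 78L, atoms = c("NH1", "NH2", "NE")),
                               D82_carboxylate = list(resno = 82L, atoms = c("OD1", "OD2")),
                               D82_backbone_O = list(resno = 82L, atoms = "O"),
                               ARG43_CA = list(resno = 43L, atoms = "CA"))) {
  stopifnot(length(trimer1_chains) == 3L, length(trimer2_chains) == 3L)
  if (length(intersect(trimer1_chains, trimer2_chains)))
    stop("trimer chain sets overlap")
  all_ch <- c(trimer1_chains, trimer2_chains)
  pc <- unlist(pairing)
  if (length(pairing) != 3L || !setequal(pc, all_ch) || anyDuplicated(pc))
    stop("pairing must cover each of the six chains exactly once")
  for (p in pairing)
    if (!(p[1L] %in% trimer1_chains && p[2L] %in% trimer2_chains) &&
        !(p[2L] %in% trimer1_chains && p[1L] %in% trimer2_chains))
      stop("each pair must span the two trimers")
  # orient pairs as (trimer1 chain, trimer2 chain)
  pairing <- lapply(pairing, function(p)
    if (p[1L] %in% trimer1_chains) p else rev(p))
  if (com_residue_range[1L] > com_residue_range[2L]) stop("empty com_residue_range")
  if (n_domain_range[2L] + 1L != c_domain_range[1L])
    stop("n_domain and c_domain ranges must partition the chain")
  structure(list(trimer1_chains = trimer1_chains, trimer2_chains = trimer2_chains,
                 pairing = pairing, com_residue_range = as.integer(com_residue_range),
                 n_domain_range = as.integer(n_domain_range),
                 c_domain_range = as.integer(c_domain_range),
                 probe_atoms = probe_atoms),
            class = "hexamer_topology")
}

#' @export
print.hexamer_topology <- function(x, ...) {
  cat(sprintf("<hexamer_topology> trimers %s / %s; pairs %s; CoM %d-%d; N %d-%d, C %d-%d\n",
              paste(x$trimer1_chains, collapse = ""),
              paste(x$trimer2_chains, collapse = ""),
              paste(vapply(x$pairing, paste, "", collapse = "-"), collapse = ","),
              x$com_residue_range[1L], x$com_residue_range[2L],
              x$n_domain_range[1L], x$n_domain_range[2L],
              x$c_domain_range[1L], x$c_domain_range[2L]))
  invisible(x)
}

#' Read/write a hexamer topology as JSON
#' @param path JSON file
#' @return a `hexamer_topology`
#' @export
read_topology_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("trimer1_chains", "trimer2_chains", "com_residue_range",
              "n_domain_range", "c_domain_range"))
    if (!is.null(j[[f]])) args[[f]] <- j[[f]]
  if (!is.null(j$pairing)) {
    p <- j$pairing
    args$pairing <- if (is.matrix(p)) lapply(seq_len(nrow(p)), function(i) p[i, ])
                    else lapply(p, unlist)
  }
  if (!is.null(j$probe_atoms))
    args$probe_atoms <- lapply(j$probe_atoms, function(p)
      list(resno = as.integer(p$resno), atoms = unlist(p$atoms)))
  do.call(hexamer_topology, args)
}

#' @rdname read_topology_json
#' @param topology a `hexamer_topology`
#' @export
write_topology_json <- function(topology, path) {
  x <- unclass(topology)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# resolve the time window of a trajectory.
# window: NULL (whole), numeric c(t0, t1) in ns, list(last_ns =) or list(last_frac =)
resolve_window <- function(traj, window) {
  t <- traj$time_ns
  if (is.null(window)) return(seq_along(t))
  if (is.list(window)) {
    tmax <- t[length(t)]
    if (!is.null(window$last_ns)) {
      window <- c(tmax - window$last_ns, tmax)
    } else if (!is.null(window$last_frac)) {
      window <- c(tmax - window$last_frac * (tmax - t[1L]), tmax)
    } else stop("window list must name last_ns or last_frac")
  }
  idx <- which(t >= window[1L] & t <= window[2L])
  if (!length(idx)) stop("empty stats window [", window[1L], ", ", window[2L], "] ns")
  idx
}
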