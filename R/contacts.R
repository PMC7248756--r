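# Charged-group distance series and hydrogen-bond occupancy scoring.
#
# Hydrogen bonds / salt bridges are scored by heavy-atom donor-acceptor
# distance only (no angle term): an interaction counts when the distance is
# strictly below the cutoff (default 3 A) in strictly more than the occupancy
# threshold (default 50%) of the frames of the scoring window (default the
# final 500 ns, expressed as a trajectory fraction for shorter inputs).
# Chemically symmetric atoms (NH1/NH2, OD1/OD2) are treated as one group via a
# min reduction.

#' Define a contact between two atom groups
#'
#' @param name label for the contact
#' @param site_a,site_b atom descriptors: `list(chain =, resno =, atoms =)`
#'   (`chain` may be NULL when the spec is a per-subunit template).
#' @param reduction `"min"` (default; group treated collectively) or
#'   `"pair"` (sites must resolve to single atoms).
#' @return object of class `contact_spec`
#' @export
contact_spec <- function(name, site_a, site_b, reduction = c("min", "pair")) {
  reduction <- match.arg(reduction)
  for (s in list(site_a, site_b))
    if (is.null(s$resno) || is.null(s$atoms) || !length(s$atoms))
      stop("contact sites need resno and a non-empty atoms vector")
  structure(list(name = name, site_a = site_a, site_b = site_b,
                 reduction = reduction),
            class = "contact_spec")
}

resolve_site <- function(traj, site, what = "site") {
  idx <- select_atoms(traj, chains = site$chain, resno = site$resno,
                      elety = site$atoms, allow_empty = TRUE)
  if (!length(idx))
    stop("unresolvable ", what, ": chain ", site$chain %||% "*",
         " resno ", site$resno, " atoms ", paste(site$atoms, collapse = "/"))
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance time series between two atom groups
#'
#' Per frame, the chosen reduction over all site_a x site_b atom pairs
#' (default the minimum, so e.g. guanidino NH1/NH2/NE vs carboxylate OD1/OD2
#' is a single group-to-group distance).
#'
#' @param traj an `oligo_traj`
#' @param spec a [contact_spec()]
#' @return numeric vector of Angstrom, one per frame, with attribute `time_ns`
#' @export
distance_series <- function(traj, spec) {
  ia <- resolve_site(traj, spec$site_a, "site_a")
  ib <- resolve_site(traj, spec$site_b, "site_b")
  if (spec$reduction == "pair" && (length(ia) != 1L || length(ib) != 1L))
    stop("reduction 'pair' requires single-atom sites")
  d <- rep(Inf, n_frames(traj))
  for (a in ia) {
    ax <- traj$xyz[, 3L * a - 2L]; ay <- traj$xyz[, 3L * a - 1L]; az <- traj$xyz[, 3L * a]
    for (b in ib) {
      db <- sqrt((ax - traj$xyz[, 3L * b - 2L])^2 +
                 (ay - traj$xyz[, 3L * b - 1L])^2 +
                 (az - traj$xyz[, 3L * b])^2)
      d <- pmin(d, db)
    }
  }
  attr(d, "time_ns") <- traj$time_ns
  d
}

#' Fraction of frames below a distance cutoff
#'
#' @param series distance series (from [distance_series()], or any numeric
#'   vector with a `time_ns` attribute or accompanied by `time_ns`).
#' @param cutoff_A strict cutoff in Angstrom (default 3.0; a frame at exactly
#'   the cutoff does not count).
#' @param window scoring window (see [rotation_series()] window forms); NULL =
#'   all frames.
#' @param time_ns frame times if `series` carries none.
#' @return occupancy fraction between 0 and 1
#' @export
contact_occupancy <- function(series, cutoff_A = 3.0, window = NULL,
                              time_ns = attr(series, "time_ns")) {
  if (is.null(window)) {
    idx <- seq_along(series)
  } else {
    if (is.null(time_ns)) stop("window given but series has no time_ns")
    idx <- resolve_window(list(time_ns = time_ns), window)
  }
  mean(series[idx] < cutoff_A)
}

#' Salt-bridge distance panel across the trimer interface
#'
#' For each cross-trimer subunit pair and each direction (residue on chain X
#' vs partner group on chain Y, and vice versa), the distance series for the
#' Arg78 guanidino / Asp82 carboxylate, Lys75 Nz / Asp82 carboxylate, and
#' Lys75 Nz / Asp82 backbone O probes. Pairs whose probe atoms are missing on
#' a chain are skipped with a warning.
#'
#' @param traj an `oligo_traj`
#' @param topology a [hexamer_topology()] whose `probe_atoms` define
#'   `R78_guanidino`, `D82_carboxylate`, `K75_amine`, `D82_backbone_O`.
#' @param probes named list of (site_a_name, site_b_name) probe pairs.
#' @return data.frame in long layout: contact, chain_a, chain_b, time_ns,
#'   distance_A
#' @export
saltbridge_panel <- function(traj, topology,
                             probes = list(
                               R78_D82 = c("R78_guanidino", "D82_carboxylate"),
                               K75_D82sc = c("K75_amine", "D82_carboxylate"),
                               K75_D82bb = c("K75_amine", "D82_backbone_O"))) {
  out <- list()
  for (pn in names(probes)) {
    pa <- topology$probe_atoms[[probes[[pn]][1L]]]
    pb <- topology$probe_atoms[[probes[[pn]][2L]]]
    if (is.null(pa) || is.null(pb))
      stop("topology lacks probe group(s) for ", pn)
    for (pair in topology$pairing) {
      for (dir in list(pair, rev(pair))) {
        sp <- contact_spec(pn,
                           list(chain = dir[1L], resno = pa$resno, atoms = pa$atoms),
                           list(chain = dir[2L], resno = pb$resno, atoms = pb$atoms))
        d <- tryCatch(distance_series(traj, sp), error = function(e) {
          warning("skipping ", pn, " ", dir[1L], "-", dir[2L], ": ",
                  conditionMessage(e))
          NULL
        })
        if (is.null(d)) next
        out[[length(out) + 1L]] <-
          data.frame(contact = pn, chain_a = dir[1L], chain_b = dir[2L],
                     time_ns = traj$time_ns, distance_A = as.numeric(d))
      }
    }
  }
  do.call(rbind, out)
}

#' Score a table of candidate hydrogen bonds per hexamer
#'
#' Each candidate (a donor/acceptor residue-atom template) is instantiated
#' once per subunit: for `scope = "within"` donor and acceptor sit on the same
#' chain; for `scope = "paired"` the acceptor sits on the donor chain's
#' cross-trimer partner. An instance is scored when its distance is < `cutoff_A`
#' in strictly more than `min_occupancy` of the window frames;
#' `count_per_hexamer` is the number of scored instances (maximum six).
#' Candidates referencing residues absent from a chain skip that instance with
#' a warning rather than failing (crystal gaps).
#'
#' @param traj an `oligo_traj`
#' @param topology a [hexamer_topology()]
#' @param candidates data.frame with columns `name`, `donor_resno`,
#'   `donor_atoms` (list or "/"-separated string), `acceptor_resno`,
#'   `acceptor_atoms`, and optional `scope` ("within" or "paired").
#' @param cutoff_A distance criterion, strict (default 3.0).
#' @param min_occupancy occupancy criterion, strict (default 0.5).
#' @param window scoring window; default the final half of the trajectory
#'   (the "final 500 ns" convention expressed as a fraction; pass
#'   `list(last_ns = 500)` for the absolute form).
#' @param keep_zero keep candidates with count 0 in the returned table
#'   (default FALSE, matching the reported-table convention; the full set is
#'   attached as attribute `all`).
#' @return data.frame: name, donor, acceptor, scope, count_per_hexamer,
#'   max_occupancy
#' @export
score_hbond_table <- function(traj, topology, candidates, cutoff_A = 3.0,
                              min_occupancy = 0.5,
                              window = list(last_frac = 0.5),
                              keep_zero = FALSE) {
  widx <- resolve_window(traj, window)
  chains <- c(topology$trimer1_chains, topology$trimer2_chains)
  partner <- character()
  for (p in topology$pairing) { partner[p[1L]] <- p[2L]; partner[p[2L]] <- p[1L] }
  split_atoms <- function(x) if (is.list(x)) unlist(x) else strsplit(x, "/")[[1L]]
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    scope <- if (!is.null(cand$scope) && !is.na(cand$scope)) cand$scope else "within"
    da <- split_atoms(cand$donor_atoms[[1L]] %||% cand$donor_atoms)
    aa <- split_atoms(cand$acceptor_atoms[[1L]] %||% cand$acceptor_atoms)
    count <- 0L
    occs <- numeric()
    for (ch in chains) {
      ach <- if (scope == "paired") partner[[ch]] else ch
      sp <- contact_spec(cand$name,
                         list(chain = ch, resno = cand$donor_resno, atoms = da),
                         list(chain = ach, resno = cand$acceptor_resno, atoms = aa))
      d <- tryCatch(distance_series(traj, sp), error = function(e) {
        warning("candidate ", cand$name, " skipped on chain ", ch, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(d)) next
      occ <- mean(d[widx] < cutoff_A)
      occs <- c(occs, occ)
      if (occ > min_occupancy) count <- count + 1L
    }
    rows[[i]] <- data.frame(
      name = cand$name,
      donor = sprintf("%d(%s)", cand$donor_resno, paste(da, collapse = "/")),
      acceptor = sprintf("%d(%s)", cand$acceptor_resno, paste(aa, collapse = "/")),
      scope = scope, count_per_hexamer = count,
      max_occupancy = if (length(occs)) max(occs) else NA_real_)
  }
  full <- do.call(rbind, rows)
  out <- if (keep_zero) full else full[full$count_per_hexamer > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- full
  attr(out, "window_ns") <- range(traj$time_ns[widx])
  out
}
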