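# Chirality-constrained Monte-Carlo sequence/rotamer design on a sampled
# backbone. Positions with backbone phi < 0 receive L-amino acids,
# phi > 0 receive D-amino acids (Gly is allowed anywhere); the anchor is
# fixed. Gly and Ala are penalized to enhance chemical diversity and
# Pro/D-Pro are favored to restrain backbone flexibility.

#' Compact canonical rotamer library
#'
#' chi in \{-60, 60, 180\} per rotatable bond for L identities; D rotamers
#' are the exact sign mirrors.
#'
#' @param identity Three-letter code.
#' @return Matrix with one rotamer per row (`nchi` columns; a single
#'   zero-column row for identities without rotatable chis).
#' @export
rotamer_library <- function(identity) {
  topo <- residue_topology(identity)
  if (topo$nchi == 0) return(matrix(numeric(0), 1, 0))
  m <- as.matrix(expand.grid(rep(list(c(-60, 60, 180)), topo$nchi)))
  colnames(m) <- paste0("chi", seq_len(topo$nchi))
  if (topo$chirality == "D") m <- -m
  m
}

#' Design palette: allowed identities and composition terms
#'
#' @param exclude Identities never designed (default Cys and Met,
#'   synthesis liabilities; applied to both enantiomers).
#' @param gly_penalty,ala_penalty Energy added per designed Gly/Ala.
#' @param pro_bonus Energy added per designed Pro/D-Pro (negative =
#'   favored).
#' @param allow_gly Allow Gly at any position.
#' @return A `DesignPalette` list.
#' @export
design_palette <- function(exclude = c("CYS", "MET"), gly_penalty = 1,
                           ala_penalty = 1, pro_bonus = -0.5,
                           allow_gly = TRUE) {
  structure(list(exclude = toupper(exclude), gly_penalty = gly_penalty,
                 ala_penalty = ala_penalty, pro_bonus = pro_bonus,
                 allow_gly = allow_gly),
            class = "DesignPalette")
}

#' Monte-Carlo schedule for design
#'
#' @param n_moves Total identity/rotamer substitution attempts.
#' @param t_start,t_end Temperature ladder endpoints (geometric).
#' @param n_stages Ladder stages (temperatures strictly decreasing).
#' @param seed Integer seed.
#' @return An `MCSchedule` list.
#' @export
mc_schedule <- function(n_moves = 5000, t_start = 3, t_end = 0.3,
                        n_stages = 10, seed = 1) {
  if (n_moves <= 0) stop("iterations must be > 0")
  if (t_end >= t_start) stop("temperatures must be strictly decreasing")
  structure(list(n_moves = n_moves, t_start = t_start, t_end = t_end,
                 n_stages = n_stages, seed = seed),
            class = "MCSchedule")
}

#' Per-position chirality of a closed backbone
#'
#' Applies the phi-sign rule per position; anchor positions report their
#' own fixed chirality.
#'
#' @param pose A cyclic `PeptidePose`.
#' @return Character vector (`"L"` / `"D"`; anchor keeps its own flag).
#' @export
position_chiralities <- function(pose) {
  tor <- pose_torsions(pose)
  out <- assign_chirality(tor$phi)
  out[is.na(out)] <- "L"   # open-chain terminus: phi undefined
  chir <- pose_chirality(pose)
  out[pose$anchor_mask] <- chir[pose$anchor_mask]
  out
}

# identities allowed at one position given its chirality and backbone phi
position_identities <- function(chirality, phi, palette) {
  base_l <- setdiff(names(.nchi), c("GLY", "PRO", palette$exclude))
  ids <- if (chirality == "D") {
    unname(.d_codes[setdiff(base_l, "GLY")])
  } else base_l
  ids <- setdiff(ids, c(palette$exclude))
  pro <- if (chirality == "D") "DPR" else "PRO"
  rng <- pro_phi_range(if (chirality == "D") "D" else "L")
  if (!is.na(phi) && phi >= rng[1] && phi <= rng[2] &&
      !pro %in% palette$exclude) {
    ids <- c(ids, pro)
  }
  if (palette$allow_gly) ids <- c(ids, "GLY")
  ids
}

design_energy_params <- function(palette, params) {
  params$gly_penalty <- palette$gly_penalty
  params$ala_penalty <- palette$ala_penalty
  params$pro_bonus <- palette$pro_bonus
  params
}

# energy of residue i's side-chain atoms (CB and beyond) against target
# + all other peptide heavy atoms. Matches the full potential's steric
# exclusions (only the 1-4 pairs CB(i)-N(i+1) and CB(i)-C(i-1) are
# skipped) and adds a distance-weighted polar-contact term standing in
# for the side-chain hydrogen-bond classes, so Monte-Carlo moves see the
# same landscape the final scoring reports (up to the H-bond angle
# criterion, applied only at final scoring).
sidechain_env_energy <- function(pose, i, txyz, tradius, params) {
  a <- pose_heavy_atoms(pose)
  bb <- c("N", "CA", "C", "O")
  mine <- a$residue == i & !(a$name %in% bb)
  if (!any(mine)) return(0)
  sc <- a[mine, , drop = FALSE]
  n <- pose_length(pose)
  env <- a[a$residue != i, , drop = FALSE]
  succ <- if (pose$cyclic) (i %% n) + 1 else i + 1
  pred <- if (pose$cyclic) ((i - 2) %% n) + 1 else i - 1
  excl14 <- (env$residue == succ & env$name == "N") |
    (env$residue == pred & env$name == "C")
  scm <- as.matrix(sc[, c("x", "y", "z")])
  is_cb <- sc$name == "CB"
  e <- steric_cross(scm[!is_cb, , drop = FALSE], sc$radius[!is_cb],
                    as.matrix(env[, c("x", "y", "z")]), env$radius,
                    params) +
    steric_cross(scm[is_cb, , drop = FALSE], sc$radius[is_cb],
                 as.matrix(env[!excl14, c("x", "y", "z")]),
                 env$radius[!excl14], params)
  if (!is.null(txyz)) {
    e <- e + steric_cross(scm, sc$radius, txyz, tradius, params)
  }
  # polar-contact proxy for the heavy-atom hydrogen-bond classes
  donors <- c("OG", "OG1", "OH", "NZ", "NE", "NH1", "NH2", "ND1",
              "NE2", "ND2", "NE1")
  acceptors <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                 "ND1", "NE2")
  polar_e <- function(A, B) {
    if (nrow(A) == 0 || nrow(B) == 0) return(0)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d <- sqrt(pmax(d2, 0))
    f <- pmin(1, pmax(0, (params$hbond_heavy_dist - d) /
                          (params$hbond_heavy_dist - 2.7)))
    f[d < 2.0] <- 0
    sum(params$hbond_weight * f)
  }
  sc_d <- scm[sc$name %in% donors, , drop = FALSE]
  sc_a <- scm[sc$name %in% acceptors, , drop = FALSE]
  env_amat <- as.matrix(env[env$name %in% acceptors, c("x", "y", "z"),
                            drop = FALSE])
  env_dmat <- as.matrix(env[env$name %in% donors, c("x", "y", "z"),
                            drop = FALSE])
  e <- e + polar_e(sc_d, env_amat) + polar_e(sc_a, env_dmat)
  if (!is.null(txyz)) {
    ta_env <- attr(txyz, "polar")
    if (!is.null(ta_env)) {
      e <- e + polar_e(sc_d, ta_env$acceptors) +
        polar_e(sc_a, ta_env$donors)
    }
  }
  e
}

target_polar_sets <- function(target) {
  donors <- c("OG", "OG1", "OH", "NZ", "NE", "NH1", "NH2", "ND1",
              "NE2", "ND2", "NE1", "N")
  acceptors <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                 "ND1", "NE2")
  a <- target$atoms
  list(donors = as.matrix(a[a$name %in% donors, c("x", "y", "z"),
                            drop = FALSE]),
       acceptors = as.matrix(a[a$name %in% acceptors, c("x", "y", "z"),
                               drop = FALSE]))
}

composition_of <- function(identity, palette) {
  if (identity == "GLY") return(palette$gly_penalty)
  if (identity %in% c("ALA", "DAL")) return(palette$ala_penalty)
  if (identity %in% c("PRO", "DPR")) return(palette$pro_bonus)
  0
}

#' Monte-Carlo sequence and rotamer design against a target
#'
#' Metropolis sampling over (identity, rotamer) moves at every non-anchor
#' position under a geometric temperature ladder, followed by a local chi
#' grid refinement (+/-10 degrees in 2.5 degree steps) of the best state.
#' The hotspot anchor is never touched. Reproducible under
#' `schedule$seed`.
#'
#' @param pose A closed, clash-screened backbone (`PeptidePose`).
#' @param target A `TargetStructure` (or NULL for target-free packing).
#' @param palette A `DesignPalette`.
#' @param schedule An `MCSchedule`.
#' @param params Energy parameters.
#' @param refine Run the chi grid refinement (default TRUE).
#' @param with_metrics Attach an `InterfaceReport` (default TRUE when a
#'   target is given).
#' @return A `DesignRecord`: list with `pose`, `sequence`, `chirality`,
#'   `chi`, `energy` (design-context `EnergyBreakdown`), `interface`
#'   (`InterfaceReport` or NULL), `trajectory` (best energy per stage)
#'   and `seed`.
#' @export
design <- function(pose, target = NULL, palette = design_palette(),
                   schedule = mc_schedule(), params = energy_params(),
                   refine = TRUE, with_metrics = !is.null(target)) {
  n <- pose_length(pose)
  chir <- position_chiralities(pose)
  tor <- pose_torsions(pose)
  free <- which(!pose$anchor_mask)
  choices <- vector("list", n)
  for (i in free) {
    ids <- position_identities(chir[i], tor$phi[i], palette)
    if (length(ids) == 0) {
      stop("configuration error: empty palette at position ", i)
    }
    choices[[i]] <- lapply(ids, function(id) {
      list(identity = id, rotamers = rotamer_library(id))
    })
  }
  params <- design_energy_params(palette, params)
  txyz <- NULL; tradius <- NULL
  if (!is.null(target)) {
    txyz <- as.matrix(target$atoms[, c("x", "y", "z")])
    tradius <- target$atoms$radius
  }

  if (!is.null(target)) {
    attr(txyz, "polar") <- target_polar_sets(target)
  }
  # initial state: first palette identity / rotamer at every free
  # position, so the search never leaves the allowed palette
  cur <- pose
  for (i in free) {
    first <- choices[[i]][[1]]
    chi0 <- if (ncol(first$rotamers) == 0) numeric(0) else
      as.numeric(first$rotamers[1, ])
    cur <- set_sidechain(cur, i, first$identity, chi0)
  }

  set.seed(schedule$seed)
  temps <- exp(seq(log(schedule$t_start), log(schedule$t_end),
                   length.out = schedule$n_stages))
  moves_per <- ceiling(schedule$n_moves / schedule$n_stages)
  # energies are tracked relative to the initial state; a move's exact
  # delta only involves pairs touching the changed side chain
  e_cur <- 0
  best <- list(pose = cur, e = e_cur)
  traj <- numeric(0)
  for (tt in temps) {
    for (mv in seq_len(moves_per)) {
      i <- free[sample.int(length(free), 1)]
      ch <- choices[[i]]
      pick <- ch[[sample.int(length(ch), 1)]]
      nrot <- nrow(pick$rotamers)
      chi <- if (ncol(pick$rotamers) == 0) numeric(0) else
        as.numeric(pick$rotamers[sample.int(nrot, 1), ])
      cand <- set_sidechain(cur, i, pick$identity, chi)
      de <- sidechain_env_energy(cand, i, txyz, tradius, params) +
        composition_of(pick$identity, palette) -
        sidechain_env_energy(cur, i, txyz, tradius, params) -
        composition_of(pose_sequence(cur)[i], palette)
      if (de <= 0 || stats::runif(1) < exp(-de / tt)) {
        cur <- cand
        e_cur <- e_cur + de
        if (e_cur < best$e - 1e-12) {
          best <- list(pose = cur, e = e_cur)
        }
      }
    }
    traj <- c(traj, best$e)
  }
  cur <- best$pose

  if (refine) {
    for (i in free) {
      topo <- cur$topologies[[i]]
      if (topo$nchi == 0) next
      chi <- pose_chi(cur, i)
      e0 <- sidechain_env_energy(cur, i, txyz, tradius, params)
      for (k in seq_along(chi)) {
        for (d in seq(-10, 10, by = 2.5)) {
          if (d == 0) next
          trial <- chi; trial[k] <- wrap180(trial[k] + d)
          cand <- set_sidechain(cur, i, topo$name3, trial)
          e1 <- sidechain_env_energy(cand, i, txyz, tradius, params)
          if (e1 < e0 - 1e-12) {
            cur <- cand; chi <- trial; e0 <- e1
          }
        }
      }
    }
  }

  en <- score(cur, target, params, context = "design")
  rec <- structure(list(
    pose = cur, sequence = pose_sequence(cur),
    chirality = pose_chirality(cur),
    chi = lapply(seq_len(n), function(i) tryCatch(pose_chi(cur, i),
                                                  error = function(e)
                                                    numeric(0))),
    energy = en,
    interface = if (with_metrics && !is.null(target))
      interface_report(cur, target, params) else NULL,
    trajectory = traj, seed = schedule$seed),
    class = "DesignRecord")
  rec
}

#' @export
print.DesignRecord <- function(x, ...) {
  cat("DesignRecord:", design_sequence_string(x), sprintf(
    " E %.3f%s\n", x$energy$total,
    if (!is.null(x$interface)) sprintf(", dG %.3f",
                                       x$interface$interaction_energy)
    else ""))
  invisible(x)
}

#' One-letter sequence string (D residues lower case)
#' @param record A `DesignRecord` (or a `PeptidePose`).
#' @return Character scalar, e.g. `"GpSYvTg..."`.
#' @export
design_sequence_string <- function(record) {
  pose <- if (inherits(record, "DesignRecord")) record$pose else record
  three <- pose_sequence(pose)
  one <- c(GLY = "G", ALA = "A", SER = "S", THR = "T", VAL = "V",
           LEU = "L", ILE = "I", PRO = "P", PHE = "F", TYR = "Y",
           TRP = "W", ASP = "D", ASN = "N", GLU = "E", GLN = "Q",
           LYS = "K", ARG = "R", HIS = "H", CYS = "C", MET = "M")
  out <- vapply(three, function(t3) {
    if (t3 %in% names(one)) return(unname(one[t3]))
    l <- .l_of_d[[t3]]
    tolower(unname(one[l]))
  }, character(1))
  paste(out, collapse = "")
}

#' Rank design records by interface metrics
#'
#' Stable ordering by the documented composite key: interaction energy
#' (ascending, primary), then buried interface area (descending), then
#' shape complementarity (descending), then total hydrogen-bond count
#' (descending).
#'
#' @param records List of `DesignRecord`s carrying interface reports.
#' @return The reordered list.
#' @export
rank_designs <- function(records) {
  if (length(records) == 0) return(records)
  get <- function(f) vapply(records, f, numeric(1))
  for (r in records) {
    if (is.null(r$interface)) stop("ranking error: record without metrics")
  }
  ie <- get(function(r) r$interface$interaction_energy)
  bs <- get(function(r) r$interface$buried_sasa)
  sc <- get(function(r) ifelse(is.na(r$interface$sc), -Inf,
                               r$interface$sc))
  hb <- get(function(r) r$interface$inter_hbond_count +
              r$interface$intra_hbond_count)
  records[order(ie, -bs, -sc, -hb)]
}
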