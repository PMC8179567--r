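# Sequence-specific conformational landscape: sample closed conformers of
# a designed sequence in the absence of the target, repack side chains,
# and assess pre-organization from the energy-vs-RMSD funnel.

#' Predict the conformational energy landscape of a designed macrocycle
#'
#' Draws `n_samples` closure attempts with per-position Ramachandran bins
#' matching each position's designed chirality (achiral positions sample
#' both halves), repacks side chains with identities fixed (greedy
#' rotamer choice, two passes), and scores each conformer without the
#' target. The design conformation itself is injected as sample 0. All
#' residues are free here: the anchor mask is ignored by contract (there
#' is no target present).
#'
#' @param record A `DesignRecord` (or a cyclic `PeptidePose`).
#' @param n_samples Number of closure attempts (> 0).
#' @param seed Integer seed.
#' @param params Energy parameters.
#' @param rmsd_selection `"backbone"` (default) or `"heavy"`.
#' @return Data frame of `FunnelPoint` rows: `id` (0 = the design),
#'   `energy`, `rmsd` (Angstrom to the design), `closure_bond_error`.
#' @export
predict_landscape <- function(record, n_samples = 2000, seed = 1,
                              params = energy_params(),
                              rmsd_selection = c("backbone", "heavy")) {
  rmsd_selection <- match.arg(rmsd_selection)
  if (n_samples <= 0) stop("parameter error: n_samples must be > 0")
  design_pose <- if (inherits(record, "DesignRecord")) record$pose else
    record
  if (!design_pose$cyclic) stop("landscape needs a cyclic pose")
  n <- pose_length(design_pose)
  design_pose$anchor_mask <- rep(FALSE, n)  # no target: all residues free
  seqs <- pose_sequence(design_pose)
  chir <- pose_chirality(design_pose)
  binset <- lapply(seq_len(n), function(i) {
    ch <- switch(chir[i], L = "L", D = "D", "achiral")
    bins_for_chirality(default_rama_bins(), ch, strict = TRUE)
  })

  e_design <- score(design_pose, NULL, params, context = "filter")$total
  pts <- list(data.frame(id = 0, energy = e_design, rmsd = 0,
                         closure_bond_error = if (design_pose$cyclic)
                           closure_residual(design_pose)$bond else NA))
  for (k in seq_len(n_samples)) {
    set.seed(seed + k)
    phi <- numeric(n); psi <- numeric(n)
    for (i in seq_len(n)) {
      s <- sample_phi_psi(1, binset[[i]])
      phi[i] <- s$phi; psi[i] <- s$psi
    }
    piv <- sort(sample.int(n, 3))
    sols <- solve_closure(phi, psi, pivots = piv, build = FALSE)
    if (length(sols) == 0) next
    sol <- sols[[sample.int(length(sols), 1)]]
    sol <- solution_pose(sol,
                         topologies = lapply(design_pose$topologies,
                                             function(t) t$name3))
    if (!closure_valid(sol)) next
    po <- sol$pose
    po <- repack_sidechains(po, record, params)
    e <- score(po, NULL, params, context = "filter")$total
    r <- pose_rmsd(po, design_pose, rmsd_selection)
    pts[[length(pts) + 1]] <- data.frame(
      id = k, energy = e, rmsd = r,
      closure_bond_error = sol$residual$bond)
  }
  do.call(rbind, pts)
}

# greedy rotamer repack, identities fixed; two passes over positions
repack_sidechains <- function(pose, record, params) {
  n <- pose_length(pose)
  chi0 <- if (inherits(record, "DesignRecord")) record$chi else
    lapply(seq_len(n), function(i) tryCatch(pose_chi(record, i),
                                            error = function(e) numeric(0)))
  for (i in seq_len(n)) {
    topo <- pose$topologies[[i]]
    chi <- chi0[[i]]
    if (topo$has_cb || topo$nchi > 0) {
      pose <- set_sidechain(pose, i, topo$name3,
                            if (topo$nchi > 0) chi[seq_len(topo$nchi)]
                            else numeric(0))
    }
  }
  for (pass in 1:2) {
    for (i in seq_len(n)) {
      topo <- pose$topologies[[i]]
      if (topo$nchi == 0) next
      lib <- rotamer_library(topo$name3)
      e_best <- sidechain_env_energy(pose, i, NULL, NULL, params)
      for (k in seq_len(nrow(lib))) {
        cand <- set_sidechain(pose, i, topo$name3, as.numeric(lib[k, ]))
        e <- sidechain_env_energy(cand, i, NULL, NULL, params)
        if (e < e_best - 1e-12) {
          pose <- cand; e_best <- e
        }
      }
    }
  }
  pose
}

#' Funnel verdict from a landscape table
#'
#' A design is pre-organized ("funneled") when its lowest-energy sampled
#' conformer lies within `cutoff` of the designed conformation.
#'
#' @param points Data frame from [predict_landscape()] (>= 10 rows).
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @return A `LandscapeVerdict`: list with `lowest_energy_rmsd`,
#'   `median_rmsd_low5pct` (median RMSD of the lowest-5%-energy samples),
#'   `pass` (lowest-energy RMSD < cutoff) and `cutoff`.
#' @export
funnel_verdict <- function(points, cutoff = 1.0) {
  if (nrow(points) < 10) {
    stop("insufficient-samples error: need at least 10 landscape points")
  }
  i_min <- which.min(points$energy)
  k <- max(1, ceiling(0.05 * nrow(points)))
  low <- points[order(points$energy)[seq_len(k)], ]
  structure(list(lowest_energy_rmsd = points$rmsd[i_min],
                 median_rmsd_low5pct = stats::median(low$rmsd),
                 pass = points$rmsd[i_min] < cutoff, cutoff = cutoff),
            class = "LandscapeVerdict")
}

#' @export
print.LandscapeVerdict <- function(x, ...) {
  cat(sprintf(
    "LandscapeVerdict: lowest-E rmsd %.2f A (cutoff %.1f) -> %s; low-5%% median %.2f A\n",
    x$lowest_energy_rmsd, x$cutoff, if (x$pass) "PASS" else "FAIL",
    x$median_rmsd_low5pct))
  invisible(x)
}
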