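# Anchored closure sampling: draw ring torsions from the Ramachandran
# bins, solve the triaxial closure in a floating frame, graft each closed
# ring onto the fixed anchor, and screen against the target.

#' Sample closed poly-Gly macrocycle backbones on an anchored hotspot
#'
#' Each attempt draws phi/psi for every ring position from the weighted
#' bins, picks a random pivot triplet among non-anchor residues, solves
#' the closure, rigidly grafts each solution onto the anchor (the ring is
#' built with ideal geometry, so the anchor's N/CA/C triad matches
#' exactly up to the anchor's own deviation from ideal geometry; anchor
#' coordinates are then set bit-identically), and rejects poses whose
#' backbone clashes with the target. Attempts are independently seeded
#' (`seed` + attempt index), so results do not depend on execution order.
#'
#' @param anchor A `HotspotAnchor` placed relative to `target`.
#' @param target A `TargetStructure`.
#' @param n_residues Ring size (7-12).
#' @param n_attempts Number of sampling attempts (<= 0 gives an empty
#'   list).
#' @param bins Ramachandran bin table.
#' @param seed Integer seed.
#' @param clash_factor Hard-sphere rejection threshold as a fraction of
#'   summed van der Waals radii (default 0.6).
#' @param params Energy parameters used for the per-solution score.
#' @param pivots Optional fixed pivot triplet (default: random per
#'   attempt).
#' @param max_solutions Cap on returned solutions (default Inf).
#' @return List of `ClosureSolution` objects; each carries `pose`
#'   (anchored, clash-screened), `energy` (an `EnergyBreakdown` in the
#'   peptide+target context) and `attempt`. Attribute `"stats"` reports
#'   per-stage counts (attempts, closed, clash_rejected, kept).
#' @export
sample_closed_backbones <- function(anchor, target, n_residues = 9,
                                    n_attempts = 1000,
                                    bins = default_rama_bins(),
                                    seed = 1, clash_factor = 0.6,
                                    params = energy_params(),
                                    pivots = NULL,
                                    max_solutions = Inf) {
  if (n_residues < 7 || n_residues > 12) {
    stop("ring size must be within [7, 12]")
  }
  if (n_attempts <= 0) return(structure(list(), stats = c(
    attempts = 0, closed = 0, clash_rejected = 0, kept = 0)))
  ta <- target$atoms
  txyz <- as.matrix(ta[, c("x", "y", "z")])
  aa <- anchor$atoms[anchor$atoms$element != "H", , drop = FALSE]
  aratio <- .min_contact_ratio_cpp(as.matrix(aa[, c("x", "y", "z")]),
                                   vdw_radius(aa$element),
                                   txyz, ta$radius)
  if (aratio < clash_factor) {
    stop("anchor-clash error: anchor overlaps the target (contact ratio ",
         sprintf("%.2f", aratio), ")")
  }
  anchor_ref <- list(index = 1, N = anchor_xyz(anchor, "N"),
                     CA = anchor_xyz(anchor, "CA"),
                     C = anchor_xyz(anchor, "C"))
  topo <- c(list(anchor$identity), rep(list("GLY"), n_residues - 1))

  out <- list()
  n_closed <- 0; n_clash <- 0
  for (att in seq_len(n_attempts)) {
    set.seed(seed + att)
    s <- sample_phi_psi(n_residues, bins)
    piv <- if (is.null(pivots)) {
      sort(sample(2:n_residues, 3))
    } else sort(pivots)
    sols <- solve_closure(s$phi, s$psi, pivots = piv)
    for (sol in sols) {
      if (!closure_valid(sol)) next
      n_closed <- n_closed + 1
      pose <- sol$pose
      pose$topologies <- lapply(topo, residue_topology)
      # re-anchor: superpose ring residue 1 backbone onto the anchor triad
      mob <- rbind(atom_xyz(pose, 1, "N"), atom_xyz(pose, 1, "CA"),
                   atom_xyz(pose, 1, "C"))
      ref <- rbind(anchor_ref$N, anchor_ref$CA, anchor_ref$C)
      fit <- superpose_kabsch(mob, ref)
      pose$atoms[, c("x", "y", "z")] <-
        apply_transform(as.matrix(pose$atoms[, c("x", "y", "z")]), fit)
      for (nm in c("N", "CA", "C")) {
        selr <- pose$atoms$residue == 1 & pose$atoms$name == nm
        pose$atoms[selr, c("x", "y", "z")] <- matrix(anchor_ref[[nm]], 1)
      }
      pose <- graft_anchor_sidechain(pose, 1, anchor)
      pa <- pose_heavy_atoms(pose)
      ratio <- .min_contact_ratio_cpp(as.matrix(pa[, c("x", "y", "z")]),
                                      pa$radius, txyz, ta$radius)
      if (ratio < clash_factor) {
        n_clash <- n_clash + 1
        next
      }
      sol$pose <- pose
      sol$energy <- score(pose, target, params, context = "filter")
      sol$attempt <- att
      out[[length(out) + 1]] <- sol
      if (length(out) >= max_solutions) break
    }
    if (length(out) >= max_solutions) break
  }
  structure(out, stats = c(attempts = n_attempts, closed = n_closed,
                           clash_rejected = n_clash,
                           kept = length(out)))
}
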