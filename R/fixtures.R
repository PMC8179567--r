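# Deterministic generators of synthetic test structures: a small rigid
# beta-sheet slab with a shallow groove (a geometric stand-in for a flat
# protein-protein interface) and exactly closed ideal macrocycles. All
# fixtures are built in code at run time; none emulates any particular
# protein's sequence or epitope.

#' Build a toy two-strand beta-sheet target with a groove site
#'
#' Two antiparallel extended strands (alternating Val/Ala, chi1 = 180)
#' form a rigid slab; the gap between the strands leaves a shallow
#' groove. A hotspot site (C-alpha position + outward normal) is defined
#' above the groove midpoint, chosen so that an aromatic rotamer scan can
#' succeed. Coordinates are jittered by a seeded ~0.02 Angstrom noise, so
#' different seeds give different coordinates with identical topology.
#'
#' @param seed Integer seed.
#' @param n_per_strand Residues per strand (default 10).
#' @param strand_gap Inter-strand spacing in Angstrom (default 5.4).
#' @return A `TargetStructure` with attributes `hotspot_site` and
#'   `hotspot_normal`.
#' @export
make_toy_target <- function(seed = 1, n_per_strand = 10,
                            strand_gap = 5.4) {
  ids <- rep(c("VAL", "ALA"), length.out = n_per_strand)
  chi <- lapply(ids, function(id) if (id == "VAL") 180 else numeric(0))
  strand <- function() {
    build_chain(as.list(ids), phi = rep(-120, n_per_strand),
                psi = rep(125, n_per_strand), chi = chi)
  }
  s1 <- strand()
  s2 <- strand()
  # antiparallel partner: rotate 180 degrees about the strand (x) axis
  # midline, then offset in y
  x2 <- as.matrix(s2$atoms[, c("x", "y", "z")])
  R <- rodrigues(c(1, 0, 0), pi)
  x2 <- x2 %*% t(R)
  x2[, 1] <- -x2[, 1] + max(s1$atoms$x)   # reverse direction
  x2[, 2] <- x2[, 2] + strand_gap
  s2$atoms[, c("x", "y", "z")] <- x2
  a1 <- pose_as_structure(s1, chain = "A")$atoms
  a2 <- pose_as_structure(s2, chain = "A")$atoms
  a2$resno <- a2$resno + n_per_strand
  atoms <- rbind(a1, a2)
  set.seed(seed)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(atoms), sd = 0.02), ncol = 3)
  ts <- new_target_structure(atoms, source = sprintf("toy-target-seed%d",
                                                     seed))
  mid <- c(mean(range(atoms$x)), mean(range(atoms$y)), 0)
  # the slab lies near z = 0 with side chains pointing +/-z; the site
  # sits above the groove between the strands
  attr(ts, "hotspot_site") <- mid + c(0, 0, 6.5)
  attr(ts, "hotspot_normal") <- c(0, 0, 1)
  ts
}

#' Build a toy complex: the toy target plus a docked Tyr "partner"
#'
#' Places a tyrosine on the toy target's groove site by rotamer scan and
#' stores it as chain "B" residue 1, giving a complex from which
#' [extract_hotspot()] can pull a hotspot with known chi angles.
#'
#' @param seed Integer seed.
#' @param identity Residue to dock (default `"TYR"`).
#' @return A `TargetStructure` with chains A (target) and B (partner
#'   residue); attribute `"chi"` holds the placed rotamer.
#' @export
make_toy_complex <- function(seed = 1, identity = "TYR") {
  ts <- make_toy_target(seed)
  anchor <- rotamer_scan_place(ts, identity,
                               site = attr(ts, "hotspot_site"),
                               normal = attr(ts, "hotspot_normal"))
  b <- data.frame(chain = "B", resno = 1, insert = "",
                  resid = anchor$identity, name = anchor$atoms$name,
                  element = anchor$atoms$element, x = anchor$atoms$x,
                  y = anchor$atoms$y, z = anchor$atoms$z,
                  radius = vdw_radius(anchor$atoms$element), o = 1, b = 0,
                  stringsAsFactors = FALSE)
  out <- new_target_structure(rbind(ts$atoms, b), source = ts$source)
  attr(out, "chi") <- anchor$chi
  attr(out, "hotspot_site") <- attr(ts, "hotspot_site")
  attr(out, "hotspot_normal") <- attr(ts, "hotspot_normal")
  out
}

.macrocycle_patterns <- list(
  # base (phi, psi) per position, recycled around the ring
  alternating = list(phi = c(-140, 140), psi = c(130, -130)),
  # heterochiral turn-rich hexapeptide: closes exactly and carries three
  # transannular backbone hydrogen bonds; with per-position chirality
  # assigned by the phi-sign rule it sits at the bottom of its own
  # conformational landscape
  turns = list(phi = c(64, 177, -89, 75, 89, -130),
               psi = c(-35, -11, 42, 73, 1, 84)),
  helical = list(phi = c(-60), psi = c(-45))
)

#' Build an exactly closed ideal-geometry macrocycle
#'
#' Takes a torsion template (recycled to ring size), solves the triaxial
#' closure for three spread pivots, and returns the solution whose pivot
#' torsions deviate least from the template. The returned pose closes to
#' numerical precision; its backbone hydrogen-bond count is measured at
#' generation and declared in attribute `"declared_hbonds"`.
#'
#' @param n_residues Ring size (6-12).
#' @param pattern `"alternating"` (mixed-chirality strand-like, the
#'   default), `"turns"`, or `"helical"`; or a list with `phi`/`psi`
#'   templates.
#' @param topologies Residue identities (default all Gly).
#' @param pivots Optional pivot triplet (default: three evenly spread
#'   positions).
#' @return A cyclic `PeptidePose` with attributes `declared_hbonds` and
#'   `template` (the torsion template used).
#' @export
make_ideal_macrocycle <- function(n_residues = 8,
                                  pattern = "alternating",
                                  topologies = NULL, pivots = NULL) {
  if (n_residues < 6 || n_residues > 12) {
    stop("ring size must be within [6, 12]")
  }
  tpl <- if (is.list(pattern)) pattern else .macrocycle_patterns[[pattern]]
  if (is.null(tpl)) stop("unknown pattern: ", pattern)
  phi <- rep(tpl$phi, length.out = n_residues)
  psi <- rep(tpl$psi, length.out = n_residues)
  piv <- if (is.null(pivots)) {
    c(1, 1 + floor(n_residues / 3), 1 + floor(2 * n_residues / 3))
  } else sort(pivots)
  sols <- solve_closure(phi, psi, pivots = piv, topologies = topologies)
  sols <- Filter(closure_valid, sols)
  if (length(sols) == 0) {
    stop("generation error: pattern '",
         if (is.character(pattern)) pattern else "custom",
         "' is infeasible for n = ", n_residues)
  }
  dev <- vapply(sols, function(s) {
    sum(abs(wrap180(s$phi[piv] - phi[piv]))) +
      sum(abs(wrap180(s$psi[piv] - psi[piv])))
  }, numeric(1))
  pose <- sols[[which.min(dev)]]$pose
  attr(pose, "declared_hbonds") <- count_backbone_hbonds(pose)
  attr(pose, "template") <- list(phi = phi, psi = psi, pivots = piv)
  pose
}
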