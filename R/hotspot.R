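# Hotspot anchoring: extract a fixed anchor residue from a bound partner
# chain, or place one on a bare surface site by rotamer scanning. The
# anchor's coordinates are immutable through all downstream sampling and
# design.

new_hotspot_anchor <- function(identity, atoms, source, chi = numeric(0)) {
  topo <- residue_topology(identity)
  structure(list(identity = topo$name3, chirality = topo$chirality,
                 atoms = atoms, chi = chi, source = source, topo = topo),
            class = "HotspotAnchor")
}

#' @export
print.HotspotAnchor <- function(x, ...) {
  cat(sprintf("HotspotAnchor: %s (%s), %d atoms, source %s, chi [%s]\n",
              x$identity, x$chirality, nrow(x$atoms), x$source,
              paste(sprintf("%.0f", x$chi), collapse = ", ")))
  invisible(x)
}

anchor_xyz <- function(anchor, name) {
  i <- which(anchor$atoms$name == name)
  if (length(i) == 0) stop("anchor missing atom ", name)
  as.numeric(anchor$atoms[i[1], c("x", "y", "z")])
}

#' Extract a hotspot anchor residue from a bound partner chain
#'
#' Copies the named residue's atoms verbatim as the anchor; the rest of
#' the partner chain is discarded. Pair with [filter_chains()] to obtain
#' the target (the remaining chains).
#'
#' @param complex A `TargetStructure` holding target and partner chains.
#' @param partner_chain Chain ID of the bound partner.
#' @param residue_number Residue number of the hotspot in that chain.
#' @return A `HotspotAnchor` with measured chi angles.
#' @export
extract_hotspot <- function(complex, partner_chain, residue_number) {
  a <- complex$atoms
  sel <- a$chain == partner_chain & a$resno == residue_number
  if (!any(sel)) {
    stop("lookup error: residue ", residue_number, " not found in chain ",
         partner_chain)
  }
  res <- a[sel, , drop = FALSE]
  identity <- res$resid[1]
  atoms <- data.frame(name = res$name, element = res$element,
                      x = res$x, y = res$y, z = res$z,
                      stringsAsFactors = FALSE)
  chi <- tryCatch(structure_chi(complex, partner_chain, residue_number),
                  error = function(e) numeric(0))
  new_hotspot_anchor(identity, atoms, source = "complex-extraction",
                     chi = chi)
}

#' Default rotamer set for hotspot scanning
#'
#' A compact canonical chi library: gauche+/gauche-/trans per rotatable
#' bond, with +/-20 degree sub-samples around each chi1/chi2 value.
#'
#' @param identity Three-letter code.
#' @return Matrix, one rotamer per row, `nchi` columns.
#' @export
scan_rotamer_set <- function(identity) {
  topo <- residue_topology(identity)
  if (topo$nchi == 0) return(matrix(numeric(0), 1, 0))
  base <- c(-60, 60, 180)
  sub <- c(-20, 0, 20)
  vals1 <- sort(wrap180(as.numeric(outer(base, sub, "+"))))
  cols <- c(list(vals1),
            rep(list(base), max(0, topo$nchi - 1)))
  if (topo$nchi >= 2) {
    cols[[2]] <- sort(wrap180(as.numeric(outer(base, sub, "+"))))
  }
  as.matrix(expand.grid(cols))
}

build_anchor_at_site <- function(identity, site, normal, chi) {
  topo <- residue_topology(identity)
  # canonical residue with a generic beta-strand backbone
  pose <- build_chain(list(topo), phi = -120, psi = 130,
                      chi = list(chi[seq_len(topo$nchi)]))
  ca <- atom_xyz(pose, 1, "CA")
  cb_dir <- if (topo$has_cb) {
    v <- atom_xyz(pose, 1, "CB") - ca
    v / sqrt(sum(v^2))
  } else c(0, 0, 1)
  nz <- -normal / sqrt(sum(normal^2))  # side chain points at the surface
  R1 <- rotation_between(cb_dir, nz)
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, ca) %*% t(R1)
  # deterministic roll: put the backbone N-C axis along a reference
  # perpendicular to the normal
  idxN <- which(pose$atoms$name == "N")[1]
  idxC <- which(pose$atoms$name == "C")[1]
  ax <- xyz[idxC, ] - xyz[idxN, ]
  ax <- ax - sum(ax * nz) * nz
  ref <- c(1, 0, 0)
  ref <- ref - sum(ref * nz) * nz
  if (sqrt(sum(ref^2)) < 1e-6) {
    ref <- c(0, 1, 0); ref <- ref - sum(ref * nz) * nz
  }
  if (sqrt(sum(ax^2)) > 1e-8) {
    a1 <- ax / sqrt(sum(ax^2)); r1 <- ref / sqrt(sum(ref^2))
    cosang <- min(1, max(-1, sum(a1 * r1)))
    sgn <- sign(sum(cross3(a1, r1) * nz))
    if (sgn == 0) sgn <- 1
    R2 <- rodrigues(nz, sgn * acos(cosang))
    xyz <- xyz %*% t(R2)
  }
  xyz <- sweep(xyz, 2, site, `+`)
  pose$atoms[, c("x", "y", "z")] <- xyz
  pose
}

#' Place a hotspot residue on a surface site by rotamer scan
#'
#' Builds the residue with its C-alpha at `site` and its side chain
#' directed along `-normal` (into the surface), scans the rotamer set,
#' scores each rotamer against the target, and returns the lowest-energy
#' rotamer with no hard clash. Ties break lexicographically on
#' (chi1, chi2, ...).
#'
#' @param target A `TargetStructure`.
#' @param identity Residue identity to place (e.g. `"TRP"`).
#' @param site C-alpha position (numeric 3-vector).
#' @param normal Outward surface normal at the site.
#' @param rotamer_set Matrix of chi rows (default [scan_rotamer_set()]).
#' @param clash_factor Hard-clash threshold as a fraction of contact
#'   distance (default 0.6).
#' @param params Energy parameters.
#' @return A `HotspotAnchor`; attribute `"scan"` holds every scanned
#'   rotamer with its score and clash flag.
#' @export
rotamer_scan_place <- function(target, identity, site, normal,
                               rotamer_set = scan_rotamer_set(identity),
                               clash_factor = 0.6,
                               params = energy_params()) {
  if (nrow(rotamer_set) == 0) stop("no-placement error: empty rotamer set")
  ta <- target$atoms
  txyz <- as.matrix(ta[, c("x", "y", "z")])
  report <- data.frame(rotamer = seq_len(nrow(rotamer_set)),
                       score = NA_real_, clash = NA)
  poses <- vector("list", nrow(rotamer_set))
  for (k in seq_len(nrow(rotamer_set))) {
    po <- build_anchor_at_site(identity, site, normal,
                               as.numeric(rotamer_set[k, ]))
    pa <- pose_heavy_atoms(po)
    ratio <- .min_contact_ratio_cpp(as.matrix(pa[, c("x", "y", "z")]),
                                    pa$radius, txyz, ta$radius)
    report$clash[k] <- ratio < clash_factor
    report$score[k] <- steric_cross(as.matrix(pa[, c("x", "y", "z")]),
                                    pa$radius, txyz, ta$radius, params)
    poses[[k]] <- po
  }
  ok <- which(!report$clash)
  if (length(ok) == 0) stop("no-placement error: every rotamer clashes")
  scores <- report$score[ok]
  best <- ok[order(scores,
                   apply(rotamer_set[ok, , drop = FALSE], 1, paste,
                         collapse = "/"))][1]
  # lexicographic tie-break on chi values among equal scores
  ties <- ok[abs(report$score[ok] - min(scores)) < 1e-12]
  if (length(ties) > 1) {
    m <- rotamer_set[ties, , drop = FALSE]
    best <- ties[do.call(order, as.data.frame(m))[1]]
  }
  po <- poses[[best]]
  a <- po$atoms[po$atoms$element != "H", , drop = FALSE]
  anchor <- new_hotspot_anchor(
    identity,
    data.frame(name = a$name, element = a$element, x = a$x, y = a$y,
               z = a$z, stringsAsFactors = FALSE),
    source = "rotamer-scan", chi = as.numeric(rotamer_set[best, ]))
  attr(anchor, "scan") <- cbind(report,
                                as.data.frame(rotamer_set))
  anchor
}

#' Extend poly-Gly arms from an anchor residue
#'
#' Builds an open chain with the anchor interior: `n_nterm` glycines
#' before it and `n_cterm` after, all in extended torsions, ready for
#' closure sampling. The anchor's backbone coordinates are set exactly;
#' its side chain is carried over verbatim.
#'
#' @param anchor A `HotspotAnchor`.
#' @param n_nterm,n_cterm Number of Gly residues on each side (3-6).
#' @return An open `PeptidePose` of length `1 + n_nterm + n_cterm` with
#'   the anchor position masked immutable.
#' @export
extend_polygly <- function(anchor, n_nterm = 4, n_cterm = 4) {
  if (n_nterm < 3 || n_nterm > 6 || n_cterm < 3 || n_cterm > 6) {
    stop("parameter error: arm lengths must be within [3, 6]")
  }
  n <- 1 + n_nterm + n_cterm
  k <- n_nterm + 1
  topo <- c(rep(list("GLY"), n_nterm), list(anchor$identity),
            rep(list("GLY"), n_cterm))
  pose <- build_chain(topo, phi = rep(-180, n), psi = rep(180, n),
                      anchor = list(index = k,
                                    N = anchor_xyz(anchor, "N"),
                                    CA = anchor_xyz(anchor, "CA"),
                                    C = anchor_xyz(anchor, "C")))
  graft_anchor_sidechain(pose, k, anchor)
}

# replace residue k's built side chain (and O, if present in the anchor)
# with the anchor's exact atoms
graft_anchor_sidechain <- function(pose, k, anchor) {
  bb <- c("N", "CA", "C", "H")
  a <- pose$atoms
  a <- a[!(a$residue == k & !(a$name %in% bb)), , drop = FALSE]
  extra <- anchor$atoms[!(anchor$atoms$name %in% c(bb, "OXT")) &
                          anchor$atoms$element != "H", , drop = FALSE]
  newrows <- data.frame(residue = k, name = extra$name,
                        element = extra$element, x = extra$x, y = extra$y,
                        z = extra$z, stringsAsFactors = FALSE)
  a <- rbind(a, newrows)
  a <- a[order(a$residue), , drop = FALSE]
  pose$atoms <- a
  pose$anchor_mask[k] <- TRUE
  pose
}
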