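# Simplified decomposable energy function used for filtering (E > 0),
# design optimization and ranking. Deliberately small and fully
# documented: a 6-12 Lennard-Jones steric term with a linear ramp below
# 0.6x contact distance (scores stay finite in clashes), a geometric
# hydrogen-bond term, a Ramachandran bin term, and a sequence-composition
# term active only during design. No solvation or electrostatics (stated
# limitation). The scale is arbitrary (kcal/mol-like); the E > 0 filter
# threshold is configurable.

#' Default energy parameters
#'
#' @return Named list: `lj_eps` (well depth per heavy-atom pair),
#'   `lj_ramp` (fraction of contact distance below which the potential
#'   continues linearly), `hbond_weight` (energy per ideal hydrogen bond),
#'   `hbond_dist` / `hbond_angle` (H...A cutoff, Angstrom / D-H...A cutoff,
#'   degrees), `hbond_heavy_dist` (heavy-atom D...A cutoff for classes
#'   without explicit hydrogens), `rama_weight`, `gly_penalty`,
#'   `ala_penalty`, `pro_bonus` (composition term, design context only).
#' @export
energy_params <- function() {
  list(lj_eps = 0.05, lj_ramp = 0.6, hbond_weight = -0.5,
       hbond_dist = 2.5, hbond_angle = 120, hbond_heavy_dist = 3.2,
       rama_weight = 0.5, gly_penalty = 1, ala_penalty = 1,
       pro_bonus = -0.5)
}

# 6-12 LJ on contact-normalized distance x = r / (ri + rj), minimum -eps
# at x = 1, linear continuation below x = ramp.
lj_energy <- function(x, eps, ramp = 0.6) {
  x <- pmax(x, 1e-6)
  e <- eps * (x^-12 - 2 * x^-6)
  e_r <- eps * (ramp^-12 - 2 * ramp^-6)
  slope <- eps * (-12 * ramp^-13 + 12 * ramp^-7)
  below <- x < ramp
  e[below] <- e_r + slope * (x[below] - ramp)
  e
}

pose_heavy_atoms <- function(pose) {
  a <- pose$atoms[pose$atoms$element != "H", , drop = FALSE]
  a$radius <- vdw_radius(a$element)
  a
}

target_atoms <- function(target) {
  a <- target$atoms
  data.frame(residue = paste0(a$chain, a$resno), name = a$name,
             element = a$element, x = a$x, y = a$y, z = a$z,
             radius = a$radius, stringsAsFactors = FALSE)
}

# Nonbonded exclusion mask for intra-peptide steric pairs: same residue
# always excluded; for adjacent residues (cyclic-aware) backbone-backbone
# pairs and the 1-4 pairs C(i)-CB(i+1), CB(i)-N(i+1) are excluded.
intra_pair_included <- function(a, n, cyclic) {
  m <- nrow(a)
  res <- a$residue
  bb <- a$name %in% c("N", "CA", "C", "O")
  inc <- matrix(TRUE, m, m)
  same <- outer(res, res, "==")
  inc[same] <- FALSE
  ringdist <- function(i, j) {
    d <- abs(i - j)
    if (cyclic) pmin(d, n - d) else d
  }
  adj <- outer(res, res, ringdist) == 1
  inc[adj & outer(bb, bb, "&")] <- FALSE
  succ <- if (cyclic) outer(res, res, function(i, j) (i %% n) + 1 == j)
          else outer(res, res, function(i, j) i + 1 == j)
  x14 <- (succ & outer(a$name == "C", a$name == "CB", "&")) |
    (succ & outer(a$name == "CB", a$name == "N", "&"))
  inc[x14 | t(x14)] <- FALSE
  inc[lower.tri(inc, diag = TRUE)] <- FALSE
  inc
}

steric_intra <- function(pose, params) {
  a <- pose_heavy_atoms(pose)
  m <- nrow(a)
  if (m < 2) return(0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r0 <- outer(a$radius, a$radius, "+")
  inc <- intra_pair_included(a, pose_length(pose), pose$cyclic)
  x <- (d / r0)[inc]
  sum(lj_energy(x, params$lj_eps, params$lj_ramp))
}

steric_cross <- function(coordsA, radiiA, coordsB, radiiB, params) {
  if (nrow(coordsA) == 0 || nrow(coordsB) == 0) return(0)
  d2 <- outer(rowSums(coordsA^2), rowSums(coordsB^2), "+") -
    2 * coordsA %*% t(coordsB)
  d <- sqrt(pmax(d2, 0))
  x <- d / outer(radiiA, radiiB, "+")
  # beyond 2.5x contact the LJ tail is negligible; skip for speed
  near <- x < 2.5
  if (!any(near)) return(0)
  sum(lj_energy(x[near], params$lj_eps, params$lj_ramp))
}

#' Detect hydrogen bonds within a pose and across to a target
#'
#' Backbone-backbone bonds use the explicit amide hydrogen: H...acceptor
#' distance below `hbond_dist` and D-H...A angle above `hbond_angle`
#' (adjacent ring neighbours excluded). Classes without built hydrogens
#' (side chains; the target) use a heavy-atom donor...acceptor criterion
#' (`hbond_heavy_dist`, base-donor-acceptor angle >= 90 degrees), a
#' documented simplification.
#'
#' @param pose A `PeptidePose`.
#' @param target Optional `TargetStructure` for intermolecular bonds.
#' @param params See [energy_params()].
#' @return Data frame (`HBondRecord` rows): donor/acceptor residue and
#'   atom, `dist` (Angstrom), `angle` (degrees; NA for heavy-atom pairs),
#'   `class` (`intramolecular-backbone`, `intramolecular-sidechain`,
#'   `intermolecular`), `strength` (0-1 geometric falloff).
#' @export
detect_hbonds <- function(pose, target = NULL, params = energy_params()) {
  n <- pose_length(pose)
  a <- pose$atoms
  recs <- list()
  empty <- data.frame(donor_res = character(0), donor_atom = character(0),
                      acceptor_res = character(0),
                      acceptor_atom = character(0), dist = numeric(0),
                      angle = numeric(0), class = character(0),
                      strength = numeric(0), stringsAsFactors = FALSE)
  pairdist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  angles_at <- function(base, mid, far) {
    # angle base-mid-far, all k x 3 matrices
    u <- base - mid; v <- far - mid
    cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
    acos(pmin(1, pmax(-1, cosang))) * DEG
  }

  # backbone-backbone (and peptide-N -> target) via the explicit amide H
  hs <- a[a$name == "H", , drop = FALSE]
  Hm <- as.matrix(hs[, c("x", "y", "z")])
  ns <- a[a$name == "N", , drop = FALSE]
  Nm <- as.matrix(ns[, c("x", "y", "z")])[match(hs$residue, ns$residue), ,
                                          drop = FALSE]
  explicit_scan <- function(acc_m, acc_res, acc_name, class, ring) {
    if (nrow(hs) == 0 || nrow(acc_m) == 0) return(NULL)
    d <- pairdist(Hm, acc_m)
    ok <- d <= params$hbond_dist
    if (ring) {
      dd <- abs(outer(hs$residue, as.numeric(acc_res), "-"))
      if (pose$cyclic) dd <- pmin(dd, n - dd)
      ok <- ok & dd >= 2
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    ang <- angles_at(Nm[idx[, 1], , drop = FALSE],
                     Hm[idx[, 1], , drop = FALSE],
                     acc_m[idx[, 2], , drop = FALSE])
    keep <- ang >= params$hbond_angle
    if (!any(keep)) return(NULL)
    idx <- idx[keep, , drop = FALSE]; ang <- ang[keep]
    dk <- d[idx]
    fd <- pmin(1, pmax(0, (params$hbond_dist - dk) /
                           (params$hbond_dist - 1.9)))
    fa <- pmin(1, pmax(0, (ang - params$hbond_angle) /
                           (180 - params$hbond_angle)))
    data.frame(donor_res = if (ring) hs$residue[idx[, 1]] else
                 paste0("P", hs$residue[idx[, 1]]),
               donor_atom = "N",
               acceptor_res = if (ring) acc_res[idx[, 2]] else
                 as.character(acc_res[idx[, 2]]),
               acceptor_atom = acc_name[idx[, 2]],
               dist = dk, angle = ang, class = class,
               strength = fd * fa, stringsAsFactors = FALSE)
  }
  os <- a[a$name == "O", , drop = FALSE]
  recs$bb <- explicit_scan(as.matrix(os[, c("x", "y", "z")]),
                           os$residue, os$name,
                           "intramolecular-backbone", ring = TRUE)

  # heavy-atom donor/acceptor classes (side chains; the target)
  donor_names <- c("OG", "OG1", "OH", "NZ", "NE", "NH1", "NH2", "ND1",
                   "NE2", "ND2", "NE1")
  acceptor_names <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                      "ND1", "NE2")
  with_parents <- function(tbl) {
    # nearest same-residue heavy neighbour of each atom, for the
    # base-donor-acceptor angle
    m <- as.matrix(tbl[, c("x", "y", "z")])
    par <- matrix(NA_real_, nrow(tbl), 3)
    for (r in unique(tbl$res_lab)) {
      rows <- which(tbl$res_lab == r)
      if (length(rows) < 2) next
      sub <- m[rows, , drop = FALSE]
      d <- pairdist(sub, sub)
      diag(d) <- Inf
      par[rows, ] <- sub[apply(d, 1, which.min), , drop = FALSE]
    }
    par
  }
  heavy_scan <- function(dtbl, dpar, atbl, class) {
    if (nrow(dtbl) == 0 || nrow(atbl) == 0) return(NULL)
    Dm <- as.matrix(dtbl[, c("x", "y", "z")])
    Am <- as.matrix(atbl[, c("x", "y", "z")])
    d <- pairdist(Dm, Am)
    ok <- d <= params$hbond_heavy_dist & d >= 2.0 &
      outer(dtbl$res_lab, atbl$res_lab, "!=")
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    base <- dpar[idx[, 1], , drop = FALSE]
    ang <- rep(NA_real_, nrow(idx))
    hasb <- !is.na(base[, 1])
    if (any(hasb)) {
      ang[hasb] <- angles_at(base[hasb, , drop = FALSE],
                             Dm[idx[hasb, 1], , drop = FALSE],
                             Am[idx[hasb, 2], , drop = FALSE])
    }
    keep <- is.na(ang) | ang >= 90
    if (!any(keep)) return(NULL)
    idx <- idx[keep, , drop = FALSE]; ang <- ang[keep]
    dk <- d[idx]
    fd <- pmin(1, pmax(0, (params$hbond_heavy_dist - dk) /
                           (params$hbond_heavy_dist - 2.7)))
    data.frame(donor_res = dtbl$res_lab[idx[, 1]],
               donor_atom = dtbl$name[idx[, 1]],
               acceptor_res = atbl$res_lab[idx[, 2]],
               acceptor_atom = atbl$name[idx[, 2]],
               dist = dk, angle = ang, class = class, strength = fd,
               stringsAsFactors = FALSE)
  }
  pep <- a[a$element != "H", , drop = FALSE]
  pep$res_lab <- paste0("P", pep$residue)
  pep_par <- with_parents(pep)
  dpe <- pep$name %in% donor_names
  ape <- pep$name %in% acceptor_names
  recs$sc <- heavy_scan(pep[dpe, , drop = FALSE],
                        pep_par[dpe, , drop = FALSE],
                        pep[ape, , drop = FALSE],
                        "intramolecular-sidechain")
  if (!is.null(target)) {
    cache <- attr(target, "hb_cache")
    if (is.null(cache)) {
      tat <- target$atoms
      tat$res_lab <- paste0("T", tat$chain, tat$resno)
      cache <- list(tat = tat, par = with_parents(tat))
    }
    tat <- cache$tat
    tat_par <- cache$par
    dta <- tat$name %in% c(donor_names, "N")
    ata <- tat$name %in% acceptor_names
    recs$pt <- heavy_scan(pep[dpe, , drop = FALSE],
                          pep_par[dpe, , drop = FALSE],
                          tat[ata, , drop = FALSE], "intermolecular")
    recs$tp <- heavy_scan(tat[dta, , drop = FALSE],
                          tat_par[dta, , drop = FALSE],
                          pep[ape, , drop = FALSE], "intermolecular")
    ta <- tat[ata, , drop = FALSE]
    recs$ht <- explicit_scan(as.matrix(ta[, c("x", "y", "z")]),
                             ta$res_lab, ta$name, "intermolecular",
                             ring = FALSE)
  }
  recs <- Filter(Negate(is.null), recs)
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Count intramolecular backbone hydrogen bonds of a pose
#'
#' @param pose A `PeptidePose`.
#' @param params See [energy_params()].
#' @return Integer count (rigid-motion invariant).
#' @export
count_backbone_hbonds <- function(pose, params = energy_params()) {
  hb <- detect_hbonds(pose, target = NULL, params = params)
  sum(hb$class == "intramolecular-backbone")
}

rama_term <- function(pose, params, bins = default_rama_bins()) {
  tor <- pose_torsions(pose)
  chir <- pose_chirality(pose)
  tot <- 0
  for (i in seq_len(nrow(tor))) {
    if (is.na(tor$phi[i]) || is.na(tor$psi[i])) next
    fam <- if (chir[i] == "D") "D"
           else if (chir[i] == "L") "L"
           else if (assign_chirality(tor$phi[i]) == "D") "D" else "L"
    lab <- bin_of(tor$phi[i], tor$psi[i], family = fam, bins = bins)
    w <- bins$weight[bins$label == lab]
    tot <- tot + params$rama_weight * (-log(max(w, 1e-6)))
  }
  tot
}

composition_term <- function(pose, params) {
  seqs <- pose_sequence(pose)
  free <- !pose$anchor_mask
  sum((seqs == "GLY" & free) * params$gly_penalty) +
    sum((seqs %in% c("ALA", "DAL") & free) * params$ala_penalty) +
    sum((seqs %in% c("PRO", "DPR") & free) * params$pro_bonus)
}

#' Score a pose with the simplified decomposable potential
#'
#' @param pose A `PeptidePose` with complete heavy atoms and amide H.
#' @param target Optional `TargetStructure`; when present, peptide-target
#'   steric and hydrogen-bond terms are included.
#' @param params See [energy_params()].
#' @param context `"filter"` (no composition term) or `"design"`.
#' @return An `EnergyBreakdown`: list with `steric`, `hbond`, `rama`,
#'   `composition`, `total` (= sum of terms) and `context`.
#' @export
score <- function(pose, target = NULL, params = energy_params(),
                  context = c("filter", "design")) {
  context <- match.arg(context)
  need <- c("N", "CA", "C", "O")
  for (i in seq_len(pose_length(pose))) {
    have <- pose$atoms$name[pose$atoms$residue == i]
    miss <- setdiff(need, have)
    if (length(miss) > 0) {
      stop("scoring error: residue ", i, " missing atom(s) ",
           paste(miss, collapse = ","))
    }
  }
  st <- steric_intra(pose, params)
  if (!is.null(target)) {
    pa <- pose_heavy_atoms(pose)
    ta <- target$atoms
    st <- st + steric_cross(as.matrix(pa[, c("x", "y", "z")]), pa$radius,
                            as.matrix(ta[, c("x", "y", "z")]), ta$radius,
                            params)
  }
  hb <- detect_hbonds(pose, target, params)
  hbe <- sum(params$hbond_weight * hb$strength)
  ra <- rama_term(pose, params)
  co <- if (context == "design") composition_term(pose, params) else 0
  structure(list(steric = st, hbond = hbe, rama = ra, composition = co,
                 total = st + hbe + ra + co, context = context,
                 hbond_records = hb),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf(
    "EnergyBreakdown (%s): total %.3f = steric %.3f + hbond %.3f + rama %.3f + comp %.3f\n",
    x$context, x$total, x$steric, x$hbond, x$rama, x$composition))
  invisible(x)
}

#' Peptide-target interaction energy
#'
#' E(complex) - E(peptide) - E(target): with this potential, exactly the
#' cross steric and cross hydrogen-bond terms.
#'
#' @param pose A `PeptidePose`.
#' @param target A `TargetStructure`.
#' @param params See [energy_params()].
#' @return Numeric scalar.
#' @export
interaction_energy <- function(pose, target, params = energy_params()) {
  pa <- pose_heavy_atoms(pose)
  ta <- target$atoms
  st <- steric_cross(as.matrix(pa[, c("x", "y", "z")]), pa$radius,
                     as.matrix(ta[, c("x", "y", "z")]), ta$radius, params)
  hb <- detect_hbonds(pose, target, params)
  inter <- hb$class == "intermolecular"
  st + sum(params$hbond_weight * hb$strength[inter])
}
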