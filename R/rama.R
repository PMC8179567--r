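# Coarse Ramachandran (ABEGO-style) bins covering both chiral halves of
# the plot. The upper-case bins A (helical), B (strand), G and E (their
# positive-phi counterparts) tile the full torus and form the standard
# L-oriented labelling; the lower-case bins a/b/g/e are the exact sign
# mirrors and tile the torus again, D-oriented. Labels are therefore
# unique within a family; sampling may draw from any weighted subset.

#' Default Ramachandran bin table
#'
#' Eight half-open rectangular bins on the (phi, psi) torus, in two
#' mirror-image families. Family `"L"`: A (phi in \[-180, 0), psi in
#' \[-75, 50)), B (phi < 0, remaining psi), G (phi in \[0, 180), psi in
#' \[-100, 100)), E (phi >= 0, remaining psi). Family `"D"` holds their
#' sign-negated mirrors a, b, g, e. Psi intervals are half-open mod 360.
#' Default weights put the preferred regions (A, B, a, b) at 1 and the
#' G/E/g/e bins at half weight.
#'
#' @return Data frame with columns `label`, `family`, `phi_lo`, `phi_hi`,
#'   `psi_lo`, `psi_hi` (degrees; intervals `[lo, hi)` mod 360 for psi) and
#'   `weight`.
#' @export
default_rama_bins <- function() {
  data.frame(
    label  = c("A", "B", "G", "E", "a", "b", "g", "e"),
    family = c("L", "L", "L", "L", "D", "D", "D", "D"),
    phi_lo = c(-180, -180, 0, 0, 0, 0, -180, -180),
    phi_hi = c(0, 0, 180, 180, 180, 180, 0, 0),
    psi_lo = c(-75, 50, -100, 100, -50, 75, -100, 100),
    psi_hi = c(50, 285, 100, 260, 75, 310, 100, 260),
    weight = c(1, 1, 0.5, 0.5, 1, 1, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

in_interval_mod360 <- function(x, lo, hi) {
  # half-open [lo, hi) on the circle
  ((x - lo) %% 360) < ((hi - lo) %% 360)
}

#' Ramachandran bin of a (phi, psi) pair
#'
#' Within a family the bins are disjoint and cover the torus, so every
#' point maps to exactly one label. The mapping is mirror-symmetric:
#' `bin_of(-phi, -psi, family = "D")` is `mirror_bin(bin_of(phi, psi))`.
#'
#' @param phi,psi Torsions in degrees.
#' @param family `"L"` (labels A/B/G/E) or `"D"` (labels a/b/g/e).
#' @param bins Bin table as from [default_rama_bins()].
#' @return Single-character bin label.
#' @export
bin_of <- function(phi, psi, family = c("L", "D"),
                   bins = default_rama_bins()) {
  family <- match.arg(family)
  phi <- wrap180(phi); psi <- wrap180(psi)
  fam <- bins[bins$family == family, , drop = FALSE]
  for (j in seq_len(nrow(fam))) {
    phiok <- if (fam$phi_lo[j] < 0) phi < 0 else phi >= 0
    if (phiok && in_interval_mod360(psi, fam$psi_lo[j], fam$psi_hi[j])) {
      return(fam$label[j])
    }
  }
  stop("no bin for phi=", phi, " psi=", psi)  # unreachable: bins tile
}

#' Mirrored bin label
#' @param label Character vector of bin labels.
#' @return Labels of the sign-negated partner bins (`"A"` -> `"a"`, ...).
#' @export
mirror_bin <- function(label) {
  up <- c(A = "a", B = "b", G = "g", E = "e")
  dn <- stats::setNames(names(up), up)
  unname(ifelse(label %in% names(up), up[label], dn[label]))
}

#' Sample (phi, psi) from weighted Ramachandran bins
#'
#' Chooses a bin with probability proportional to its weight, then draws
#' (phi, psi) uniformly within it. Reproducible: driven entirely by the
#' current RNG state (seed with [set.seed()]).
#'
#' @param n Number of samples.
#' @param bins Bin table (any subset of rows; rows with zero weight are
#'   never chosen).
#' @return Data frame with columns `phi`, `psi`, `label`.
#' @export
sample_phi_psi <- function(n = 1, bins = default_rama_bins()) {
  w <- bins$weight
  if (nrow(bins) == 0 || all(w <= 0)) {
    stop("configuration error: no bin with positive weight")
  }
  j <- sample.int(nrow(bins), n, replace = TRUE, prob = pmax(w, 0))
  phi <- stats::runif(n, bins$phi_lo[j], bins$phi_hi[j])
  span <- (bins$psi_hi[j] - bins$psi_lo[j]) %% 360
  psi <- wrap180(bins$psi_lo[j] + stats::runif(n) * span)
  data.frame(phi = wrap180(phi), psi = psi, label = bins$label[j],
             stringsAsFactors = FALSE)
}

#' Chirality implied by a backbone phi torsion
#'
#' Positions with phi < 0 are designed as L-amino acids; phi > 0 becomes D.
#' The measure-zero boundary phi = 0 is assigned L by convention.
#'
#' @param phi Torsion(s) in degrees, in (-180, 180].
#' @return Character vector of `"L"` / `"D"`.
#' @export
assign_chirality <- function(phi) {
  ifelse(phi > 0, "D", "L")
}

#' Restrict a bin table to the regions of one chirality
#'
#' L positions live at phi < 0 (preferred bins A and B; the mirrored g/e
#' bins occupy the remaining, rarely used phi < 0 area); D positions at
#' phi > 0 (a, b, plus G/E).
#'
#' @param bins Bin table.
#' @param chirality `"L"`, `"D"` or `"achiral"` (all bins, e.g. for Gly).
#' @param strict If TRUE keep only the preferred full-weight bins of that
#'   chirality; if FALSE keep every bin on that side of the plot.
#' @return Filtered bin table.
#' @export
bins_for_chirality <- function(bins = default_rama_bins(),
                               chirality = c("achiral", "L", "D"),
                               strict = TRUE) {
  chirality <- match.arg(chirality)
  if (chirality == "achiral") return(bins)
  side <- if (chirality == "L") bins$phi_hi <= 0 else bins$phi_lo >= 0
  if (strict) side <- side & bins$weight >= 1
  bins[side, , drop = FALSE]
}

#' Proline phi sampling range
#'
#' Pro's ring constrains phi to about -60 degrees; D-Pro mirrors it.
#'
#' @param chirality `"L"` or `"D"`.
#' @return Length-2 numeric (degrees).
#' @export
pro_phi_range <- function(chirality = c("L", "D")) {
  chirality <- match.arg(chirality)
  if (chirality == "L") c(-75, -55) else c(55, 75)
}
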