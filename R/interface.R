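# Interface ranking metrics: Shrake-Rupley solvent accessible surface
# area, buried interface area, and the Lawrence-Colman shape
# complementarity statistic.

structure_coords_radii <- function(x) {
  if (inherits(x, "PeptidePose")) {
    a <- pose_heavy_atoms(x)
    list(xyz = as.matrix(a[, c("x", "y", "z")]), radius = a$radius)
  } else if (inherits(x, "TargetStructure")) {
    a <- x$atoms
    if (anyNA(a$radius)) stop("atom without radius in structure")
    list(xyz = as.matrix(a[, c("x", "y", "z")]), radius = a$radius)
  } else if (is.matrix(x)) {
    list(xyz = x[, 1:3, drop = FALSE], radius = attr(x, "radius"))
  } else {
    stop("unsupported structure type: ", class(x)[1])
  }
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Rolls a probe over each atom's expanded sphere, sampled with a
#' deterministic golden-spiral dot set, and counts dots not buried by any
#' neighbour.
#'
#' @param x A `TargetStructure`, `PeptidePose` (heavy atoms), or n x 3
#'   matrix with a `radius` attribute.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param dot_density Dots per atom (default 960).
#' @return List with `total` (Angstrom^2) and `per_atom`.
#' @export
sasa <- function(x, probe_radius = 1.4, dot_density = 960) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  s <- structure_coords_radii(x)
  if (is.null(s$radius) || anyNA(s$radius)) {
    stop("every atom needs a radius")
  }
  res <- .sasa_cpp(s$xyz, s$radius, probe_radius, as.integer(dot_density),
                   FALSE)
  list(total = sum(res$area), per_atom = as.numeric(res$area))
}

merge_structures <- function(a, b) {
  sa <- structure_coords_radii(a)
  sb <- structure_coords_radii(b)
  xyz <- rbind(sa$xyz, sb$xyz)
  attr(xyz, "radius") <- c(sa$radius, sb$radius)
  xyz
}

#' Buried interface area of a two-body complex
#'
#' SASA(a) + SASA(b) - SASA(complex): the two-sided total buried on both
#' partners, symmetric in its arguments.
#'
#' @param a,b Structures (see [sasa()]).
#' @param probe_radius,dot_density As in [sasa()].
#' @return Buried area in Angstrom^2 (>= 0 up to dot noise).
#' @export
buried_interface_area <- function(a, b, probe_radius = 1.4,
                                  dot_density = 960) {
  sa <- structure_coords_radii(a)
  sb <- structure_coords_radii(b)
  if (nrow(sa$xyz) == 0 || nrow(sb$xyz) == 0) {
    stop("empty selection in buried_interface_area")
  }
  ab <- merge_structures(a, b)
  sasa(a, probe_radius, dot_density)$total +
    sasa(b, probe_radius, dot_density)$total -
    sasa(ab, probe_radius, dot_density)$total
}

body_surface_dots <- function(s, dot_density) {
  res <- .sasa_cpp(s$xyz, s$radius, 0, as.integer(dot_density), TRUE)
  list(dots = res$dots, normals = res$normals, owner = res$owner)
}

#' Lawrence-Colman shape complementarity
#'
#' Generates van der Waals surface dots for each body (self-buried dots
#' removed), keeps the dots within `interface_cutoff` of the opposing
#' surface, and scores each interface dot against its nearest opposing dot
#' as S = (n_a . -n_b) * exp(-w d^2). The statistic is the mean of the two
#' per-surface medians; 1 means perfect complementarity.
#'
#' @param a,b Structures in contact.
#' @param interface_cutoff Distance (Angstrom) from the opposing surface
#'   within which dots count as interface (default 1.5).
#' @param w Gaussian distance weight (default 0.5 per Angstrom^2).
#' @param dot_density Dots per atom (default 240; the statistic is a
#'   median, robust to density).
#' @return `sc` in [-1, 1].
#' @export
shape_complementarity <- function(a, b, interface_cutoff = 1.5, w = 0.5,
                                  dot_density = 240) {
  sa <- structure_coords_radii(a)
  sb <- structure_coords_radii(b)
  # restrict to atoms near the other body to keep the dot sets small
  lim <- 8
  nn_ab <- .nearest_cpp(sa$xyz, sb$xyz)
  nn_ba <- .nearest_cpp(sb$xyz, sa$xyz)
  keep_a <- nn_ab$dist < lim
  keep_b <- nn_ba$dist < lim
  if (!any(keep_a) || !any(keep_b)) {
    stop("undefined interface: bodies are not in contact")
  }
  da <- body_surface_dots(list(xyz = sa$xyz[keep_a, , drop = FALSE],
                               radius = sa$radius[keep_a]), dot_density)
  db <- body_surface_dots(list(xyz = sb$xyz[keep_b, , drop = FALSE],
                               radius = sb$radius[keep_b]), dot_density)
  if (nrow(da$dots) == 0 || nrow(db$dots) == 0) {
    stop("undefined interface: no surface dots")
  }
  na_b <- .nearest_cpp(da$dots, db$dots)
  nb_a <- .nearest_cpp(db$dots, da$dots)
  ia <- na_b$dist <= interface_cutoff
  ib <- nb_a$dist <= interface_cutoff
  if (!any(ia) || !any(ib)) {
    stop("undefined interface: no dots within the interface cutoff")
  }
  s_of <- function(dots_n, idx, other_n, d) {
    rowSums(dots_n * -other_n[idx, , drop = FALSE]) * exp(-w * d^2)
  }
  s_a <- s_of(da$normals[ia, , drop = FALSE], na_b$index[ia],
              db$normals, na_b$dist[ia])
  s_b <- s_of(db$normals[ib, , drop = FALSE], nb_a$index[ib],
              da$normals, nb_a$dist[ib])
  (stats::median(s_a) + stats::median(s_b)) / 2
}

#' Full interface report for a peptide-target complex
#'
#' @param pose A `PeptidePose`.
#' @param target A `TargetStructure`.
#' @param params Energy parameters (see [energy_params()]).
#' @param dot_density Dots per atom for the SASA terms.
#' @return An `InterfaceReport`: list with `interaction_energy`,
#'   `buried_sasa` (Angstrom^2), `sc`, `inter_hbond_count`,
#'   `intra_hbond_count`.
#' @export
interface_report <- function(pose, target, params = energy_params(),
                             dot_density = 240) {
  hb <- detect_hbonds(pose, target, params)
  sc_val <- tryCatch(shape_complementarity(pose, target,
                                           dot_density = dot_density),
                     error = function(e) NA_real_)
  structure(list(
    interaction_energy = interaction_energy(pose, target, params),
    buried_sasa = buried_interface_area(pose, target,
                                        dot_density = dot_density),
    sc = sc_val,
    inter_hbond_count = sum(hb$class == "intermolecular"),
    intra_hbond_count = sum(hb$class != "intermolecular")),
    class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf(
    "InterfaceReport: dG %.3f, buried SASA %.1f A^2, Sc %.3f, HB inter/intra %d/%d\n",
    x$interaction_energy, x$buried_sasa, x$sc, x$inter_hbond_count,
    x$intra_hbond_count))
  invisible(x)
}
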