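# PeptidePose: ordered residues with coordinates, torsions and chirality
# flags. Atoms live in one data frame (residue, name, element, x, y, z);
# torsions are measured from coordinates, never cached, so the two can
# never disagree.

new_pose <- function(topologies, atoms, cyclic = FALSE,
                     anchor_mask = NULL) {
  n <- length(topologies)
  if (is.null(anchor_mask)) anchor_mask <- rep(FALSE, n)
  structure(list(topologies = topologies, atoms = atoms, cyclic = cyclic,
                 anchor_mask = anchor_mask),
            class = "PeptidePose")
}

#' @export
print.PeptidePose <- function(x, ...) {
  cat(sprintf("PeptidePose: %d residues (%s), %d atoms%s\n",
              length(x$topologies),
              paste(pose_sequence(x), collapse = "-"),
              nrow(x$atoms),
              if (x$cyclic) ", cyclic" else ""))
  invisible(x)
}

#' Number of residues in a pose
#' @param pose A `PeptidePose`.
#' @return Integer.
#' @export
pose_length <- function(pose) length(pose$topologies)

#' Residue identities of a pose
#' @param pose A `PeptidePose`.
#' @return Character vector of three-letter codes (D residues use CCD codes).
#' @export
pose_sequence <- function(pose) {
  vapply(pose$topologies, function(t) t$name3, character(1))
}

#' Per-residue chirality flags of a pose
#' @param pose A `PeptidePose`.
#' @return Character vector (`"L"`, `"D"`, `"achiral"`).
#' @export
pose_chirality <- function(pose) {
  vapply(pose$topologies, function(t) t$chirality, character(1))
}

atom_xyz <- function(pose, res, name) {
  i <- which(pose$atoms$residue == res & pose$atoms$name == name)
  if (length(i) != 1) {
    stop("atom lookup failed: residue ", res, " atom ", name)
  }
  as.numeric(pose$atoms[i, c("x", "y", "z")])
}

#' Extract a coordinate matrix from a pose
#'
#' @param pose A `PeptidePose`.
#' @param selection `"bb3"` (N, CA, C), `"backbone"` (N, CA, C, O),
#'   `"heavy"` (all non-hydrogen) or `"all"`.
#' @return n x 3 matrix with rownames `"<residue>:<atom>"`.
#' @export
pose_coords <- function(pose, selection = c("backbone", "bb3", "heavy",
                                            "all")) {
  selection <- match.arg(selection)
  a <- pose$atoms
  keep <- switch(selection,
    bb3 = a$name %in% c("N", "CA", "C"),
    backbone = a$name %in% c("N", "CA", "C", "O"),
    heavy = a$element != "H",
    all = rep(TRUE, nrow(a)))
  a <- a[keep, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste0(a$residue, ":", a$name)
  m
}

replace_coords <- function(pose, selection, coords) {
  a <- pose$atoms
  key <- paste0(a$residue, ":", a$name)
  idx <- match(rownames(coords), key)
  stopifnot(!anyNA(idx))
  a[idx, c("x", "y", "z")] <- coords
  pose$atoms <- a
  pose
}

prev_res <- function(i, n, cyclic) {
  if (i > 1) i - 1 else if (cyclic) n else NA_integer_
}
next_res <- function(i, n, cyclic) {
  if (i < n) i + 1 else if (cyclic) 1 else NA_integer_
}

#' Measure backbone torsions of a pose
#'
#' phi, psi and omega are measured directly from the coordinates with the
#' IUPAC sign convention. Angles that need a neighbour beyond an open
#' chain's terminus are `NA`; for a cyclic pose every angle is defined.
#'
#' @param pose A `PeptidePose`.
#' @return Data frame with columns `phi`, `psi`, `omega` (degrees).
#' @export
pose_torsions <- function(pose) {
  n <- pose_length(pose)
  cyc <- pose$cyclic
  phi <- psi <- ome <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- prev_res(i, n, cyc)
    nx <- next_res(i, n, cyc)
    Ni <- atom_xyz(pose, i, "N"); CAi <- atom_xyz(pose, i, "CA")
    Ci <- atom_xyz(pose, i, "C")
    if (!is.na(p)) {
      phi[i] <- measure_dihedral(atom_xyz(pose, p, "C"), Ni, CAi, Ci)
    }
    if (!is.na(nx)) {
      Nn <- atom_xyz(pose, nx, "N")
      psi[i] <- measure_dihedral(Ni, CAi, Ci, Nn)
      ome[i] <- measure_dihedral(CAi, Ci, Nn, atom_xyz(pose, nx, "CA"))
    }
  }
  data.frame(phi = phi, psi = psi, omega = ome)
}

#' Measure side-chain chi torsions of one residue
#'
#' @param pose A `PeptidePose`.
#' @param i Residue index (1-based).
#' @return Numeric vector of length `nchi` for that identity (degrees).
#' @export
pose_chi <- function(pose, i) {
  topo <- pose$topologies[[i]]
  if (topo$nchi == 0) return(numeric(0))
  chain <- chi_atom_chains(topo)
  vapply(chain, function(atoms) {
    measure_dihedral(atom_xyz(pose, i, atoms[1]), atom_xyz(pose, i, atoms[2]),
                     atom_xyz(pose, i, atoms[3]), atom_xyz(pose, i, atoms[4]))
  }, numeric(1))
}

# atom quadruples defining chi1..chik, derived from the z-matrix rows whose
# torsion is chi_k with zero offset
chi_atom_chains <- function(topo) {
  sc <- topo$sidechain
  out <- list()
  for (k in seq_len(topo$nchi)) {
    r <- sc[!is.na(sc$chi) & sc$chi == k & sc$off == 0, ][1, ]
    out[[k]] <- c(r$r1, r$r2, r$r3, r$atom)
  }
  out
}

build_sidechain_coords <- function(topo, chi, N, CA, C) {
  placed <- list(N = N, CA = CA, C = C)
  out <- list()
  if (topo$has_cb) {
    cb <- place_atom(C, N, CA, .bb$b_CACB, .bb$a_NCACB, topo$t_cb)
    placed$CB <- cb
    out[["CB"]] <- cb
  }
  sc <- topo$sidechain
  if (!is.null(sc)) {
    if (length(chi) == 0 && topo$nchi > 0) {
      chi <- rep(180, topo$nchi) * (if (topo$chirality == "D") -1 else 1)
    }
    if (length(chi) < topo$nchi) {
      stop("residue ", topo$name3, " needs ", topo$nchi, " chi angles")
    }
    for (j in seq_len(nrow(sc))) {
      r <- sc[j, ]
      tors <- if (is.na(r$chi)) r$tors else wrap180(chi[r$chi] + r$off)
      p <- place_atom(placed[[r$r1]], placed[[r$r2]], placed[[r$r3]],
                      r$bond, r$angle, tors)
      placed[[r$atom]] <- p
      out[[r$atom]] <- p
    }
  }
  out
}

#' Build a peptide chain from internal coordinates
#'
#' Sequentially places backbone atoms with ideal bond lengths and angles
#' (NeRF-style three-atom frame extension), then adds carbonyl O, amide H
#' and side chains. Building then re-measuring returns the requested
#' torsions (round-trip identity). If `cyclic = TRUE` the supplied torsions
#' are trusted to describe a closed ring (e.g. a kinematic-closure
#' solution); the closing-bond geometry can be checked with
#' [closure_residual()].
#'
#' @param topologies List of `ResidueTopology` (or character codes).
#' @param phi,psi,omega Numeric vectors of backbone torsions (degrees).
#'   `phi[1]` is unused for an open chain; `omega` defaults to all-trans.
#' @param chi List (one numeric vector per residue) of side-chain torsions.
#'   Requesting chi for Gly is an error.
#' @param cyclic Logical; mark the pose head-to-tail cyclic.
#' @param anchor Optional list `list(index =, N =, CA =, C =)`: after
#'   building, the chain is rigidly superposed so residue `index`'s N, CA, C
#'   coincide with the given coordinates, which are then set exactly.
#' @return A `PeptidePose`.
#' @export
build_chain <- function(topologies, phi, psi, omega = NULL, chi = NULL,
                        cyclic = FALSE, anchor = NULL) {
  topologies <- lapply(topologies, function(t) {
    if (inherits(t, "ResidueTopology")) t else residue_topology(t)
  })
  n <- length(topologies)
  if (length(phi) != n || length(psi) != n) {
    stop("torsion list length must match topology list")
  }
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(chi)) chi <- rep(list(numeric(0)), n)
  for (i in seq_len(n)) {
    if (length(chi[[i]]) > 0 && topologies[[i]]$nchi == 0) {
      stop("invalid torsion: chi requested for ", topologies[[i]]$name3)
    }
  }

  Npos <- CApos <- Cpos <- vector("list", n)
  Npos[[1]] <- c(0, 0, 0)
  CApos[[1]] <- c(.bb$b_NCA, 0, 0)
  th <- .bb$a_NCAC / DEG
  Cpos[[1]] <- CApos[[1]] + .bb$b_CAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    Npos[[i + 1]] <- place_atom(Npos[[i]], CApos[[i]], Cpos[[i]],
                                .bb$b_CN, .bb$a_CACN, psi[i])
    CApos[[i + 1]] <- place_atom(CApos[[i]], Cpos[[i]], Npos[[i + 1]],
                                 .bb$b_NCA, .bb$a_CNCA, omega[i])
    Cpos[[i + 1]] <- place_atom(Cpos[[i]], Npos[[i + 1]], CApos[[i + 1]],
                                .bb$b_CAC, .bb$a_NCAC, phi[i + 1])
  }

  res_v <- integer(0); name_v <- character(0)
  xyz_m <- vector("list", 0)
  add <- function(res, name, xyz) {
    res_v[[length(res_v) + 1]] <<- res
    name_v[[length(name_v) + 1]] <<- name
    xyz_m[[length(xyz_m) + 1]] <<- xyz
  }
  for (i in seq_len(n)) {
    add(i, "N", Npos[[i]])
    add(i, "CA", CApos[[i]])
    add(i, "C", Cpos[[i]])
    # carbonyl O anti to the next N (dihedral N-CA-C-O = psi - 180)
    ps <- if (!is.na(psi[i])) psi[i] else 180
    add(i, "O", place_atom(Npos[[i]], CApos[[i]], Cpos[[i]],
                           .bb$b_CO, .bb$a_CACO, wrap180(ps - 180)))
    sc <- build_sidechain_coords(topologies[[i]], chi[[i]],
                                 Npos[[i]], CApos[[i]], Cpos[[i]])
    for (nm in names(sc)) add(i, nm, sc[[nm]])
    # amide H in the peptide plane, trans to the following CA
    if (topologies[[i]]$base != "PRO") {
      p <- prev_res(i, n, cyclic)
      if (!is.na(p) && !is.null(Cpos[[p]])) {
        add(i, "H", place_atom(CApos[[p]], Cpos[[p]], Npos[[i]],
                               .bb$b_NH, .bb$a_CNH, 0))
      } else {
        add(i, "H", place_atom(Cpos[[i]], CApos[[i]], Npos[[i]],
                               .bb$b_NH, .bb$a_CNH, 180))
      }
    }
  }
  co <- do.call(rbind, xyz_m)
  atoms <- data.frame(residue = res_v, name = name_v,
                      element = vapply(name_v, element_of, character(1)),
                      x = co[, 1], y = co[, 2], z = co[, 3],
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  pose <- new_pose(topologies, atoms, cyclic = cyclic)

  if (!is.null(anchor)) {
    k <- anchor$index
    mob <- rbind(Npos[[k]], CApos[[k]], Cpos[[k]])
    ref <- rbind(anchor$N, anchor$CA, anchor$C)
    fit <- superpose_kabsch(mob, ref)
    xyz <- apply_transform(as.matrix(pose$atoms[, c("x", "y", "z")]), fit)
    pose$atoms[, c("x", "y", "z")] <- xyz
    for (nm in c("N", "CA", "C")) {
      sel <- pose$atoms$residue == k & pose$atoms$name == nm
      pose$atoms[sel, c("x", "y", "z")] <- matrix(anchor[[nm]], 1)
    }
    pose$anchor_mask[k] <- TRUE
  }
  pose
}

#' Closing-bond geometry of a cyclic pose
#'
#' @param pose A cyclic `PeptidePose`.
#' @return List with `bond` (C(n)-N(1) length error, Angstrom, relative to
#'   the ideal 1.329), `angle_c` and `angle_n` (errors at the closing C and
#'   N, degrees) and the raw measured values.
#' @export
closure_residual <- function(pose) {
  n <- pose_length(pose)
  if (!pose$cyclic) stop("closure_residual needs a cyclic pose")
  Cn <- atom_xyz(pose, n, "C"); N1 <- atom_xyz(pose, 1, "N")
  CAn <- atom_xyz(pose, n, "CA"); CA1 <- atom_xyz(pose, 1, "CA")
  blen <- sqrt(sum((Cn - N1)^2))
  a_c <- bond_angle(CAn, Cn, N1)
  a_n <- bond_angle(Cn, N1, CA1)
  list(bond = abs(blen - .bb$b_CN), angle_c = abs(a_c - .bb$a_CACN),
       angle_n = abs(a_n - .bb$a_CNCA),
       bond_length = blen, angle_c_value = a_c, angle_n_value = a_n)
}

#' Replace the side chain (identity + rotamer) of one residue
#'
#' Rebuilds the residue's side chain at ideal geometry on the existing
#' backbone. Backbone atoms (and every other residue) are untouched.
#' Refuses to touch anchor residues.
#'
#' @param pose A `PeptidePose`.
#' @param i Residue index.
#' @param identity Three-letter code for the new identity.
#' @param chi Numeric vector of chi torsions (degrees).
#' @return Modified `PeptidePose`.
#' @export
set_sidechain <- function(pose, i, identity, chi = numeric(0)) {
  if (pose$anchor_mask[i]) stop("residue ", i, " is anchored: immutable")
  topo <- if (inherits(identity, "ResidueTopology")) identity else
    residue_topology(identity)
  N <- atom_xyz(pose, i, "N"); CA <- atom_xyz(pose, i, "CA")
  C <- atom_xyz(pose, i, "C")
  sc <- build_sidechain_coords(topo, chi, N, CA, C)
  a <- pose$atoms
  bb <- c("N", "CA", "C", "O", "H")
  drop <- a$residue == i & !(a$name %in% bb)
  a <- a[!drop, , drop = FALSE]
  if (length(sc) > 0) {
    newrows <- do.call(rbind, lapply(names(sc), function(nm) {
      data.frame(residue = i, name = nm, element = element_of(nm),
                 x = sc[[nm]][1], y = sc[[nm]][2], z = sc[[nm]][3],
                 stringsAsFactors = FALSE)
    }))
    a <- rbind(a, newrows)
  }
  a <- a[order(a$residue), , drop = FALSE]
  pose$atoms <- a
  pose$topologies[[i]] <- topo
  pose
}

#' Mirror a pose through the z = 0 plane
#'
#' Negates all z coordinates and swaps every residue topology for its
#' enantiomer, so the result is a chemically valid mirror image.
#'
#' @param pose A `PeptidePose`.
#' @return Mirrored `PeptidePose`.
#' @export
mirror_pose <- function(pose) {
  pose$atoms$z <- -pose$atoms$z
  pose$topologies <- lapply(pose$topologies, function(t) {
    if (t$chirality == "achiral") return(t)
    residue_topology(mirror_identity(t$name3))
  })
  pose
}

#' Enantiomeric identity code
#' @param identity Three-letter code.
#' @return The mirror identity code (`"ALA"` -> `"DAL"`, `"GLY"` -> `"GLY"`).
#' @export
mirror_identity <- function(identity) {
  identity <- toupper(identity)
  if (identity == "GLY") return("GLY")
  if (identity %in% names(.d_codes)) return(unname(.d_codes[identity]))
  if (identity %in% names(.l_of_d)) return(unname(.l_of_d[identity]))
  stop("unknown identity: ", identity)
}
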