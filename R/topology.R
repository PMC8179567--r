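# Ideal internal-coordinate geometry (Engh-Huber-style reference values).
# All lengths in Angstrom, all angles/torsions in degrees.

.bb <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  b_NH = 1.010, b_CACB = 1.530,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7,
  a_CACO = 120.8, a_CNH = 119.2, a_NCACB = 110.5,
  # dihedral(C, N, CA, CB): fixes the CA stereocentre; L is negative
  t_CB_L = -122.5
)

#' Ideal backbone geometry constants
#'
#' Reference bond lengths and angles used for all internal-coordinate chain
#' building (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom and
#' standard angles).
#'
#' @return Named list of lengths (Angstrom) and angles (degrees).
#' @export
backbone_geometry <- function() .bb

# Side-chain z-matrix rows: atom, three reference atoms, bond, angle,
# torsion. A torsion entry is either a fixed number or "x<k>[+/-offset]"
# meaning chi_k plus a constant offset. Reference atoms must already be
# placed (backbone atoms N/CA/C always are).
.sc_row <- function(atom, r1, r2, r3, bond, angle, tors, chi = NA_integer_,
                    off = 0) {
  data.frame(atom = atom, r1 = r1, r2 = r2, r3 = r3, bond = bond,
             angle = angle, tors = tors, chi = chi, off = off,
             stringsAsFactors = FALSE)
}

.sidechains <- local({
  x <- function(k, off = 0) list(tors = NA_real_, chi = k, off = off)
  f <- function(v) list(tors = v, chi = NA_integer_, off = 0)
  row <- function(atom, r1, r2, r3, bond, angle, spec) {
    .sc_row(atom, r1, r2, r3, bond, angle, spec$tors, spec$chi, spec$off)
  }
  ring6 <- function(prefix = "C") {
    # six-membered aromatic ring grown from CG, CD1/CD2 already placed
    rbind(
      row("CE1", "CB", "CG", "CD1", 1.39, 120.7, f(180)),
      row("CE2", "CB", "CG", "CD2", 1.39, 120.7, f(180)),
      row("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, f(0))
    )
  }
  list(
    GLY = NULL,
    ALA = NULL,  # CB is placed by the backbone builder
    SER = row("OG", "N", "CA", "CB", 1.417, 110.8, x(1)),
    THR = rbind(
      row("OG1", "N", "CA", "CB", 1.433, 109.6, x(1)),
      row("CG2", "N", "CA", "CB", 1.521, 110.5, x(1, 120))
    ),
    VAL = rbind(
      row("CG1", "N", "CA", "CB", 1.521, 110.5, x(1)),
      row("CG2", "N", "CA", "CB", 1.521, 110.5, x(1, -120))
    ),
    LEU = rbind(
      row("CG",  "N", "CA", "CB", 1.530, 116.3, x(1)),
      row("CD1", "CA", "CB", "CG", 1.521, 110.7, x(2)),
      row("CD2", "CA", "CB", "CG", 1.521, 110.7, x(2, 120))
    ),
    ILE = rbind(
      row("CG1", "N", "CA", "CB", 1.530, 110.4, x(1)),
      row("CG2", "N", "CA", "CB", 1.521, 110.5, x(1, -120)),
      row("CD1", "CA", "CB", "CG1", 1.513, 113.8, x(2))
    ),
    PRO = rbind(
      # fixed "down" pucker; the CD-N bond is implied, not rebuilt
      row("CG", "N", "CA", "CB", 1.492, 104.5, f(30)),
      row("CD", "CA", "CB", "CG", 1.503, 106.1, f(-35))
    ),
    PHE = rbind(
      row("CG",  "N", "CA", "CB", 1.502, 113.8, x(1)),
      row("CD1", "CA", "CB", "CG", 1.384, 120.7, x(2)),
      row("CD2", "CA", "CB", "CG", 1.384, 120.7, x(2, 180)),
      ring6()
    ),
    TYR = rbind(
      row("CG",  "N", "CA", "CB", 1.512, 113.9, x(1)),
      row("CD1", "CA", "CB", "CG", 1.389, 120.8, x(2)),
      row("CD2", "CA", "CB", "CG", 1.389, 120.8, x(2, 180)),
      ring6(),
      row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, f(180))
    ),
    TRP = rbind(
      row("CG",  "N", "CA", "CB", 1.498, 113.6, x(1)),
      row("CD1", "CA", "CB", "CG", 1.365, 126.9, x(2)),
      row("CD2", "CA", "CB", "CG", 1.433, 126.6, x(2, 180)),
      row("NE1", "CB", "CG", "CD1", 1.374, 110.2, f(180)),
      row("CE2", "CB", "CG", "CD2", 1.409, 107.2, f(180)),
      row("CE3", "CD1", "CG", "CD2", 1.398, 133.9, f(180)),
      row("CZ2", "CE3", "CD2", "CE2", 1.394, 122.4, f(0)),
      row("CZ3", "CE2", "CD2", "CE3", 1.382, 118.6, f(0)),
      row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, f(0))
    ),
    ASP = rbind(
      row("CG",  "N", "CA", "CB", 1.516, 112.6, x(1)),
      row("OD1", "CA", "CB", "CG", 1.249, 118.4, x(2)),
      row("OD2", "CA", "CB", "CG", 1.249, 118.4, x(2, 180))
    ),
    ASN = rbind(
      row("CG",  "N", "CA", "CB", 1.516, 112.6, x(1)),
      row("OD1", "CA", "CB", "CG", 1.231, 120.8, x(2)),
      row("ND2", "CA", "CB", "CG", 1.328, 116.4, x(2, 180))
    ),
    GLU = rbind(
      row("CG", "N", "CA", "CB", 1.530, 114.1, x(1)),
      row("CD", "CA", "CB", "CG", 1.516, 112.6, x(2)),
      row("OE1", "CB", "CG", "CD", 1.249, 118.4, x(3)),
      row("OE2", "CB", "CG", "CD", 1.249, 118.4, x(3, 180))
    ),
    GLN = rbind(
      row("CG", "N", "CA", "CB", 1.530, 114.1, x(1)),
      row("CD", "CA", "CB", "CG", 1.516, 112.6, x(2)),
      row("OE1", "CB", "CG", "CD", 1.231, 120.8, x(3)),
      row("NE2", "CB", "CG", "CD", 1.328, 116.4, x(3, 180))
    ),
    LYS = rbind(
      row("CG", "N", "CA", "CB", 1.530, 114.1, x(1)),
      row("CD", "CA", "CB", "CG", 1.520, 111.3, x(2)),
      row("CE", "CB", "CG", "CD", 1.520, 111.3, x(3)),
      row("NZ", "CG", "CD", "CE", 1.489, 111.9, x(4))
    ),
    ARG = rbind(
      row("CG", "N", "CA", "CB", 1.530, 114.1, x(1)),
      row("CD", "CA", "CB", "CG", 1.520, 111.3, x(2)),
      row("NE", "CB", "CG", "CD", 1.461, 112.0, x(3)),
      row("CZ", "CG", "CD", "NE", 1.329, 124.2, x(4)),
      row("NH1", "CD", "NE", "CZ", 1.326, 120.0, f(0)),
      row("NH2", "CD", "NE", "CZ", 1.326, 120.0, f(180))
    ),
    HIS = rbind(
      row("CG",  "N", "CA", "CB", 1.497, 113.8, x(1)),
      row("ND1", "CA", "CB", "CG", 1.378, 122.7, x(2)),
      row("CD2", "CA", "CB", "CG", 1.356, 131.2, x(2, 180)),
      row("CE1", "CB", "CG", "ND1", 1.321, 109.0, f(180)),
      row("NE2", "CB", "CG", "CD2", 1.374, 107.2, f(180))
    ),
    CYS = row("SG", "N", "CA", "CB", 1.808, 113.8, x(1)),
    MET = rbind(
      row("CG", "N", "CA", "CB", 1.530, 114.1, x(1)),
      row("SD", "CA", "CB", "CG", 1.803, 112.7, x(2)),
      row("CE", "CB", "CG", "SD", 1.791, 100.9, x(3))
    )
  )
})

.nchi <- c(GLY = 0, ALA = 0, SER = 1, THR = 1, VAL = 1, LEU = 2, ILE = 2,
           PRO = 0, PHE = 2, TYR = 2, TRP = 2, ASP = 2, ASN = 2, GLU = 3,
           GLN = 3, LYS = 4, ARG = 4, HIS = 2, CYS = 1, MET = 3)

# CCD three-letter codes for the D-enantiomers
.d_codes <- c(ALA = "DAL", SER = "DSN", THR = "DTH", VAL = "DVA",
              LEU = "DLE", ILE = "DIL", PRO = "DPR", PHE = "DPN",
              TYR = "DTY", TRP = "DTR", ASP = "DAS", ASN = "DSG",
              GLU = "DGL", GLN = "DGN", LYS = "DLY", ARG = "DAR",
              HIS = "DHI", CYS = "DCY", MET = "MED")
.l_of_d <- stats::setNames(names(.d_codes), .d_codes)

#' Residue topology for an amino-acid identity
#'
#' Builds the ideal-geometry topology of one residue: backbone constants,
#' side-chain z-matrix, number of rotatable chi angles and chirality. D
#' topologies are exact mirrors of their L partners: every fixed torsion
#' (including the CB-placing improper) is sign-negated, so a D chain built
#' with negated torsions is the mirror image of the L chain.
#'
#' @param identity Three-letter code, upper case. L codes (`"ALA"`, ...),
#'   D codes (`"DAL"`, `"DPR"`, ...), or `"GLY"`.
#' @return Object of class `ResidueTopology`: list with `name3` (code as
#'   written to PDB), `base` (parent L identity), `chirality` (`"L"`,
#'   `"D"` or `"achiral"`), `nchi`, `sidechain` (z-matrix data frame or
#'   NULL), `has_cb`, `t_cb` (CB improper, degrees).
#' @export
residue_topology <- function(identity) {
  identity <- toupper(identity)
  is_d <- identity %in% names(.l_of_d)
  base <- if (is_d) .l_of_d[[identity]] else identity
  if (!base %in% names(.nchi)) {
    stop("unknown residue identity: ", identity)
  }
  chir <- if (base == "GLY") "achiral" else if (is_d) "D" else "L"
  sc <- .sidechains[[base]]
  t_cb <- if (base == "GLY") NA_real_ else .bb$t_CB_L * (if (is_d) -1 else 1)
  if (!is.null(sc) && is_d) {
    fx <- is.na(sc$chi)
    sc$tors[fx] <- -sc$tors[fx]
    sc$off[!fx] <- -sc$off[!fx]   # chi offsets mirror too
  }
  structure(list(name3 = identity, base = base, chirality = chir,
                 nchi = unname(.nchi[[base]]), sidechain = sc,
                 has_cb = base != "GLY", t_cb = t_cb),
            class = "ResidueTopology")
}

#' @export
print.ResidueTopology <- function(x, ...) {
  cat("ResidueTopology", x$name3, sprintf("(%s, %d chi)\n", x$chirality,
                                          x$nchi))
  invisible(x)
}

#' Supported residue identities
#'
#' @param chirality `"L"`, `"D"` or `"all"`.
#' @return Character vector of three-letter codes (D identities use their
#'   CCD codes; `"GLY"` is listed for both chiralities).
#' @export
supported_identities <- function(chirality = c("all", "L", "D")) {
  chirality <- match.arg(chirality)
  l <- names(.nchi)
  d <- c(unname(.d_codes), "GLY")
  switch(chirality, all = unique(c(l, d)), L = l, D = d)
}

element_of <- function(atom_name) {
  el <- substr(gsub("[0-9]", "", atom_name), 1, 1)
  if (!el %in% c("C", "N", "O", "S", "H")) {
    stop("unsupported element for atom ", atom_name)
  }
  el
}

# Bondi-style van der Waals radii (Angstrom)
.vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Van der Waals radius for an element
#' @param element Character vector of element symbols (C, N, O, S, H).
#' @return Radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw[element]
  if (anyNA(r)) stop("no radius for element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}
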