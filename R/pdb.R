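# PDB input/output. Parsing and fixed-column formatting are delegated to
# bio3d; this layer adds altLoc resolution, chain filtering, D-residue
# recognition, van der Waals radius assignment, and the head-to-tail LINK
# record for cyclic peptides.

#' @importFrom bio3d read.pdb write.pdb
NULL

.standard_aa <- NULL  # populated at load from topology tables

known_residue_codes <- function() {
  c(names(.nchi), unname(.d_codes))
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (PDB v3.3; first model only for
#' multi-model entries). Alternate locations are resolved to the highest
#' occupancy, ties broken toward altLoc 'A'. Waters and heteroatoms are
#' dropped; D-amino acids are recognized by their CCD codes (DAL, DPR,
#' DPN, DTR, DTY, DSN, DTH, DVA, DLE, DIL, DAS, DGL, DSG, DGN, DLY, DAR,
#' DHI, DCY, MED) whether written as ATOM or HETATM.
#'
#' @param path Path to a `.pdb` or `.pdb.gz` file.
#' @param chain_filter Optional character vector of chain IDs to retain.
#' @param unknown `"skip"` (warn and drop atoms of unrecognized residue
#'   types) or `"fail"`.
#' @return A `TargetStructure`: immutable list with `atoms` (data frame:
#'   chain, resno, insert, resid, name, element, x, y, z, radius, o, b),
#'   `cyclic_links` (rows parsed from LINK records) and `source`.
#' @export
read_pdb <- function(path, chain_filter = NULL,
                     unknown = c("skip", "fail")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("parse error: no ATOM records in ",
                                       path)
  known <- known_residue_codes()
  keep <- (a$type == "ATOM" & a$resid %in% known) |
    (a$type == "HETATM" & a$resid %in% known)
  bad <- setdiff(unique(a$resid[!keep & a$resid != "HOH"]), known)
  if (length(bad) > 0) {
    msg <- paste("unknown residue type(s) skipped:",
                 paste(bad, collapse = ", "))
    if (unknown == "fail") stop(msg) else warning(msg)
  }
  a <- a[keep, , drop = FALSE]
  if (!is.null(chain_filter)) a <- a[a$chain %in% chain_filter, ,
                                     drop = FALSE]
  if (nrow(a) == 0) stop("no atoms retained from ", path)
  a$insert[is.na(a$insert)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  # resolve altLoc: highest occupancy, then altLoc 'A', per atom site;
  # file order is restored afterwards
  a$alt[is.na(a$alt)] <- ""
  a$.ord <- seq_len(nrow(a))
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(key, -a$o, a$alt != "A", a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                           sep = "|")), , drop = FALSE]
  a <- a[order(a$.ord), , drop = FALSE]
  el <- vapply(a$elety, function(nm) {
    e <- tryCatch(element_of(nm), error = function(e) NA_character_)
    e
  }, character(1))
  drop_el <- is.na(el)
  if (any(drop_el)) a <- a[!drop_el, , drop = FALSE]
  el <- el[!drop_el]
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, name = a$elety, element = el,
                      x = a$x, y = a$y, z = a$z,
                      radius = vdw_radius(el), o = a$o, b = a$b,
                      stringsAsFactors = FALSE)
  links <- parse_link_records(path)
  new_target_structure(atoms, source = path, links = links)
}

parse_link_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- grep("^LINK", readLines(con, warn = FALSE), value = TRUE)
  if (length(lines) == 0) return(NULL)
  data.frame(
    atom1 = trimws(substr(lines, 13, 16)),
    res1 = trimws(substr(lines, 18, 20)),
    chain1 = substr(lines, 22, 22),
    resno1 = suppressWarnings(as.integer(substr(lines, 23, 26))),
    atom2 = trimws(substr(lines, 43, 46)),
    res2 = trimws(substr(lines, 48, 50)),
    chain2 = substr(lines, 52, 52),
    resno2 = suppressWarnings(as.integer(substr(lines, 53, 56))),
    stringsAsFactors = FALSE)
}

new_target_structure <- function(atoms, source = NA_character_,
                                 links = NULL) {
  rownames(atoms) <- NULL
  ts <- structure(list(atoms = atoms, cyclic_links = links,
                       source = source),
                  class = "TargetStructure")
  # immutable after load: hydrogen-bond lookup tables are precomputed
  tat <- atoms
  tat$res_lab <- paste0("T", tat$chain, tat$resno)
  attr(ts, "hb_cache") <- list(tat = tat, par = hb_parents(tat))
  ts
}

# nearest same-residue heavy neighbour of every atom (hydrogen-bond
# base-angle reference)
hb_parents <- function(tbl) {
  m <- as.matrix(tbl[, c("x", "y", "z")])
  par <- matrix(NA_real_, nrow(tbl), 3)
  for (r in unique(tbl$res_lab)) {
    rows <- which(tbl$res_lab == r)
    if (length(rows) < 2) next
    sub <- m[rows, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(sub^2), "+") - 2 * sub %*% t(sub)
    diag(d2) <- Inf
    par[rows, ] <- sub[apply(d2, 1, which.min), , drop = FALSE]
  }
  par
}

#' @export
print.TargetStructure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("TargetStructure: %d atoms, chain(s) %s (%s)\n",
              nrow(x$atoms), paste(ch, collapse = ","),
              if (is.na(x$source)) "in memory" else x$source))
  invisible(x)
}

#' Retain selected chains of a structure
#' @param ts A `TargetStructure`.
#' @param chains Character vector of chain IDs.
#' @return A new `TargetStructure` (retained atoms are unaltered).
#' @export
filter_chains <- function(ts, chains) {
  a <- ts$atoms[ts$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in chain(s) ", paste(chains,
                                                        collapse = ","))
  new_target_structure(a, source = ts$source, links = ts$cyclic_links)
}

#' Convert a `PeptidePose` to a `TargetStructure` atom table
#'
#' @param pose A `PeptidePose`.
#' @param chain Chain ID to assign.
#' @param heavy_only Drop hydrogens.
#' @return A `TargetStructure`.
#' @export
pose_as_structure <- function(pose, chain = "P", heavy_only = TRUE) {
  a <- pose$atoms
  if (heavy_only) a <- a[a$element != "H", , drop = FALSE]
  seqs <- pose_sequence(pose)
  atoms <- data.frame(chain = chain, resno = a$residue, insert = "",
                      resid = seqs[a$residue], name = a$name,
                      element = a$element, x = a$x, y = a$y, z = a$z,
                      radius = vdw_radius(a$element), o = 1, b = 0,
                      stringsAsFactors = FALSE)
  new_target_structure(atoms, source = NA_character_)
}

#' Reconstruct a `PeptidePose` from parsed PDB atoms
#'
#' Inverse of writing a pose out: one chain is taken as an ordered peptide;
#' topologies come from the residue codes. A LINK record joining the last
#' residue's C to the first residue's N (or `cyclic = TRUE`) marks the
#' pose head-to-tail cyclic.
#'
#' @param ts A `TargetStructure`.
#' @param chain Chain ID to extract (default: first chain).
#' @param cyclic Logical or `NA` (auto-detect from LINK records).
#' @return A `PeptidePose`.
#' @export
structure_as_pose <- function(ts, chain = NULL, cyclic = NA) {
  a <- ts$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  resnos <- unique(a$resno)
  topo <- lapply(resnos, function(r) {
    residue_topology(a$resid[a$resno == r][1])
  })
  atoms <- data.frame(residue = match(a$resno, resnos), name = a$name,
                      element = a$element, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  if (is.na(cyclic)) {
    l <- ts$cyclic_links
    cyclic <- !is.null(l) &&
      any(l$atom1 == "C" & l$atom2 == "N" & l$chain1 == chain &
            l$chain2 == chain)
  }
  new_pose(topo, atoms, cyclic = cyclic)
}

#' Write a peptide pose (optionally with its target) to a PDB file
#'
#' Writes fixed-column PDB v3.3 ATOM records through bio3d, with correct
#' three-letter codes for D residues. A cyclic pose gets one LINK record
#' connecting the last residue's C to the first residue's N. A complex is
#' written as separate chains (peptide chain "P", target chains as stored).
#'
#' @param pose A `PeptidePose` (or NULL to write only `target`).
#' @param path Output path.
#' @param target Optional `TargetStructure` written alongside.
#' @param chain Chain ID for the peptide.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(pose, path, target = NULL, chain = "P") {
  parts <- list()
  if (!is.null(pose)) {
    if (anyNA(pose$atoms[, c("x", "y", "z")])) {
      stop("pose has incomplete coordinates")
    }
    parts$pep <- pose_as_structure(pose, chain = chain,
                                   heavy_only = FALSE)$atoms
  }
  if (!is.null(target)) parts$tgt <- target$atoms
  all <- do.call(rbind, unname(parts))
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(all[, c("x", "y", "z")]))),
                     type = rep("ATOM", nrow(all)),
                     resno = all$resno, resid = all$resid,
                     eleno = seq_len(nrow(all)), elety = all$name,
                     chain = all$chain, insert = all$insert,
                     o = all$o, b = all$b, elesy = all$element)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  if (!is.null(pose) && pose$cyclic) {
    n <- pose_length(pose)
    seqs <- pose_sequence(pose)
    link <- sprintf(
      "LINK         C   %-3s %s%4d                 N   %-3s %s%4d                %5.2f",
      seqs[n], chain, n, seqs[1], chain, 1, .bb$b_CN)
    lines <- readLines(path)
    iend <- grep("^END", lines)
    ins <- if (length(iend) > 0) min(iend) else length(lines) + 1
    writeLines(c(lines[seq_len(ins - 1)], link,
                 lines[seq(ins, length(lines))]), path)
  }
  invisible(path)
}

#' Fetch a PDB entry from the RCSB (network required)
#'
#' Convenience helper kept outside the core library path: no test or
#' pipeline stage depends on it.
#'
#' @param accession 4-character PDB ID.
#' @param dest Destination file (default: tempfile).
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(accession, dest = tempfile(fileext = ".pdb")) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb",
                 toupper(accession))
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}

#' Measure side-chain chi angles of a residue in a structure
#'
#' @param ts A `TargetStructure`.
#' @param chain Chain ID.
#' @param resno Residue number.
#' @return Numeric vector of chi torsions (degrees).
#' @export
structure_chi <- function(ts, chain, resno) {
  a <- ts$atoms[ts$atoms$chain == chain & ts$atoms$resno == resno, ,
                drop = FALSE]
  if (nrow(a) == 0) stop("residue ", resno, " not found in chain ", chain)
  topo <- residue_topology(a$resid[1])
  g <- function(nm) {
    i <- which(a$name == nm)
    if (length(i) == 0) stop("missing atom ", nm, " in residue ", resno)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  vapply(chi_atom_chains(topo), function(ch) {
    measure_dihedral(g(ch[1]), g(ch[2]), g(ch[3]), g(ch[4]))
  }, numeric(1))
}
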