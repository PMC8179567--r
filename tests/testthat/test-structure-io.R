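test_that("write-read round-trips coordinates, sequence and torsions", {
  set.seed(41)
  for (k in 1:8) {
    n <- sample(5:9, 1)
    ids <- sample(c("GLY", "ALA", "DAL", "SER", "DPR", "TYR", "DLE"),
                  n, replace = TRUE)
    phi <- runif(n, -179, 179); psi <- runif(n, -179, 179)
    chi <- lapply(ids, function(id) {
      runif(residue_topology(id)$nchi, -179, 179)
    })
    po <- build_chain(as.list(ids), phi, psi, chi = chi)
    path <- tempfile(fileext = ".pdb")
    write_pdb(po, path)
    ts <- read_pdb(path)
    po2 <- structure_as_pose(ts, cyclic = FALSE)
    expect_identical(pose_sequence(po2), pose_sequence(po))
    xa <- pose_coords(po, "heavy"); xb <- pose_coords(po2, "heavy")
    expect_identical(rownames(xa), rownames(xb))
    expect_lt(max(abs(xa - xb)), 1e-3 + 1e-9)
    ta <- pose_torsions(po); tb <- pose_torsions(po2)
    expect_lt(max(abs(wrapd(ta$phi[-1] - tb$phi[-1]))), 0.1)
    expect_lt(max(abs(wrapd(ta$psi[-n] - tb$psi[-n]))), 0.1)
    unlink(path)
  }
})

test_that("cyclic poses get exactly one closing LINK record", {
  po <- make_ideal_macrocycle(8)
  path <- tempfile(fileext = ".pdb")
  write_pdb(po, path)
  lines <- readLines(path)
  links <- grep("^LINK", lines, value = TRUE)
  expect_length(links, 1)
  expect_match(links, " C ")
  expect_match(links, " N ")
  ts <- read_pdb(path)
  po2 <- structure_as_pose(ts)
  expect_true(po2$cyclic)
  unlink(path)
})

test_that("D-proline is written with code DPR in the residue field", {
  po <- build_chain(list("DPR", "GLY", "GLY"), c(60, -70, 60),
                    c(-40, 150, 120))
  path <- tempfile(fileext = ".pdb")
  write_pdb(po, path)
  lines <- grep("^ATOM", readLines(path), value = TRUE)
  codes <- unique(trimws(substr(lines, 18, 20)))
  expect_true("DPR" %in% codes)
  # column position check on one DPR atom line
  l <- lines[trimws(substr(lines, 18, 20)) == "DPR"][1]
  expect_identical(substr(l, 18, 20), "DPR")
  unlink(path)
})

test_that("chain filtering retains atoms unaltered", {
  cx <- make_toy_complex(1)
  path <- tempfile(fileext = ".pdb")
  write_pdb(NULL, path, target = cx)
  both <- read_pdb(path)
  only_a <- read_pdb(path, chain_filter = "A")
  expect_setequal(unique(both$atoms$chain), c("A", "B"))
  expect_identical(unique(only_a$atoms$chain), "A")
  ref <- both$atoms[both$atoms$chain == "A", ]
  rownames(ref) <- NULL
  got <- only_a$atoms
  rownames(got) <- NULL
  expect_identical(got, ref)
  expect_identical(filter_chains(both, "B")$atoms$chain,
                   both$atoms$chain[both$atoms$chain == "B"])
  unlink(path)
})

test_that("altLoc resolution prefers occupancy, then altLoc A", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.40  0.00           C",
    "ATOM      3  CA BALA A   1      12.639   7.071  -5.147  0.60  0.00           C",
    "ATOM      4  C   ALA A   1      10.729   6.859  -4.194  1.00  0.00           C",
    "ATOM      5  O   ALA A   1       9.580   7.190  -4.493  1.00  0.00           O",
    "ATOM      6  CB AALA A   1      11.795   4.616  -4.715  0.50  0.00           C",
    "ATOM      7  CB BALA A   1      12.795   3.616  -4.715  0.50  0.00           C",
    "END"), path)
  ts <- read_pdb(path)
  ca <- ts$atoms[ts$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 12.639, tolerance = 1e-6)  # higher occupancy wins
  cb <- ts$atoms[ts$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 11.795, tolerance = 1e-6)  # tie: altLoc A wins
  unlink(path)
})

test_that("unknown residues are skipped with a warning or fail on demand", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "HETATM    3  C1  XYZ A   2       0.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_warning(ts <- read_pdb(path), "XYZ")
  expect_false("XYZ" %in% ts$atoms$resid)
  expect_error(suppressWarnings(read_pdb(path, unknown = "fail")), "XYZ")
  unlink(path)
})

test_that("garbled input produces a parse error", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c("this is not", "a pdb file"), path)
  expect_error(read_pdb(path))
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("atoms carry Bondi-style radii", {
  cx <- make_toy_complex(2)
  r <- cx$atoms$radius
  expect_true(all(r[cx$atoms$element == "C"] == 1.70))
  expect_true(all(r[cx$atoms$element == "N"] == 1.55))
  expect_true(all(r[cx$atoms$element == "O"] == 1.52))
})

test_that("coordinates agree with bio3d's own reading of a written file", {
  po <- make_ideal_macrocycle(7)
  path <- tempfile(fileext = ".pdb")
  write_pdb(po, path)
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  ts <- read_pdb(path)
  expect_equal(nrow(ts$atoms), nrow(ref$atom))
  expect_equal(ts$atoms$x, ref$atom$x, tolerance = 1e-9)
  unlink(path)
})
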