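test_that("the steric potential has its minimum at contact distance", {
  p <- energy_params()
  lj <- macrocycler:::lj_energy
  expect_equal(lj(1, p$lj_eps), -p$lj_eps, tolerance = 1e-12)
  h <- 1e-5
  deriv <- (lj(1 + h, p$lj_eps) - lj(1 - h, p$lj_eps)) / (2 * h)
  expect_lt(abs(deriv), 1e-6)
  # strictly increasing repulsion from contact down to half contact
  xs <- seq(1, 0.5, by = -0.05)
  es <- lj(xs, p$lj_eps)
  expect_true(all(diff(es) > 0))
  # finite in deep clashes thanks to the linear ramp
  expect_true(is.finite(lj(1e-3, p$lj_eps)))
})

test_that("an isolated residue has zero hydrogen-bond energy", {
  po <- build_chain(list("SER"), 0, 0, chi = list(60))
  s <- score(po)
  expect_equal(s$hbond, 0)
  expect_equal(nrow(s$hbond_records), 0)
  expect_equal(s$total, s$steric + s$hbond + s$rama + s$composition)
})

test_that("the steric term matches a brute-force pairwise oracle", {
  set.seed(51)
  for (k in 1:4) {
    n <- 6
    ids <- sample(c("ALA", "SER", "LEU", "DAL", "GLY"), n, replace = TRUE)
    po <- build_chain(as.list(ids), runif(n, -170, 170),
                      runif(n, -170, 170))
    expect_equal(macrocycler:::steric_intra(po, energy_params()),
                 oracle_steric_intra(po), tolerance = 1e-9)
  }
  # cyclic case (wrap-around adjacency)
  po <- make_ideal_macrocycle(8)
  expect_equal(macrocycler:::steric_intra(po, energy_params()),
               oracle_steric_intra(po), tolerance = 1e-9)
})

test_that("missing atoms give a scoring error naming the atom", {
  po <- build_chain(rep(list("GLY"), 3), rep(-60, 3), rep(-45, 3))
  po$atoms <- po$atoms[!(po$atoms$residue == 2 & po$atoms$name == "O"), ]
  expect_error(score(po), "residue 2 missing atom")
})

test_that("hydrogen bonds are detected by geometric criteria", {
  # hand-built four-residue open chain: residues 1 and 4 arranged so the
  # amide H of residue 4 meets the carbonyl O of residue 1 at 2.0 A
  base <- build_chain(rep(list("GLY"), 4), rep(-120, 4), rep(120, 4))
  O1 <- macrocycler:::atom_xyz(base, 1, "O")
  H4 <- macrocycler:::atom_xyz(base, 4, "H")
  N4 <- macrocycler:::atom_xyz(base, 4, "N")
  # translate residue 4 (whole residue, rigid) so that H...O = 2.0 A
  # along the N-H direction extended: D-H...A angle becomes 180
  nh <- (H4 - N4) / sqrt(sum((H4 - N4)^2))
  target_H <- O1 - 2.0 * nh
  shift <- target_H - H4
  po <- base
  sel <- po$atoms$residue == 4
  po$atoms[sel, c("x", "y", "z")] <-
    sweep(as.matrix(po$atoms[sel, c("x", "y", "z")]), 2, shift, `+`)
  hb <- detect_hbonds(po)
  bb <- hb[hb$class == "intramolecular-backbone", ]
  expect_equal(nrow(bb), 1)
  expect_equal(bb$dist, 2.0, tolerance = 1e-6)
  expect_gt(bb$angle, 160)
  # independent geometric re-check of the record
  expect_equal(bb$donor_res, 4)
  expect_equal(bb$acceptor_res, 1)
  # stretched to 3.5 A: no bond
  po2 <- base
  target_H2 <- O1 - 3.5 * nh
  shift2 <- target_H2 - H4
  po2$atoms[sel, c("x", "y", "z")] <-
    sweep(as.matrix(po2$atoms[sel, c("x", "y", "z")]), 2, shift2, `+`)
  hb2 <- detect_hbonds(po2)
  expect_equal(sum(hb2$class == "intramolecular-backbone"), 0)
})

test_that("complex hydrogen-bond classes partition by atom ownership", {
  ts <- make_toy_target(3)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  sols <- sample_closed_backbones(an, ts, 8, n_attempts = 30, seed = 2)
  expect_gt(length(sols), 0)
  po <- sols[[1]]$pose
  hb <- detect_hbonds(po, ts)
  if (nrow(hb) > 0) {
    # peptide residues are labelled P*/<int>, target residues T*
    inter <- hb$class == "intermolecular"
    both_pep <- !grepl("^T", hb$donor_res) & !grepl("^T", hb$acceptor_res)
    expect_true(all(xor(inter, both_pep)))
  }
  expect_identical(count_backbone_hbonds(po),
                   sum(detect_hbonds(po)$class ==
                         "intramolecular-backbone"))
})

test_that("an extended open chain has zero backbone hydrogen bonds", {
  po <- build_chain(rep(list("GLY"), 6), rep(180, 6), rep(180, 6))
  expect_equal(count_backbone_hbonds(po), 0)
})

test_that("every term is rigid-motion invariant and mirror invariant", {
  po <- make_ideal_macrocycle(8)
  s0 <- score(po)
  set.seed(52)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- macrocycler:::rodrigues(ax, 1.234)
  po2 <- po
  po2$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(po$atoms[, c("x", "y", "z")]) %*% t(R), 2,
          c(5, -3, 2), `+`)
  s1 <- score(po2)
  expect_equal(s1$total, s0$total, tolerance = 1e-9)
  expect_equal(count_backbone_hbonds(po2), count_backbone_hbonds(po))
  s2 <- score(mirror_pose(po))
  expect_equal(s2$steric, s0$steric, tolerance = 1e-9)
  expect_equal(s2$hbond, s0$hbond, tolerance = 1e-9)
  expect_equal(s2$rama, s0$rama, tolerance = 1e-9)
})

test_that("interaction energy equals complex minus parts", {
  ts <- make_toy_target(4)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  sols <- sample_closed_backbones(an, ts, 8, n_attempts = 25, seed = 4)
  expect_gt(length(sols), 0)
  po <- sols[[1]]$pose
  p <- energy_params()
  e_cplx <- score(po, ts, p)$total
  e_pep <- score(po, NULL, p)$total
  expect_equal(interaction_energy(po, ts, p), e_cplx - e_pep,
               tolerance = 1e-9)
})
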