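test_that("dihedral follows the IUPAC convention on planar cases", {
  # trans (anti) arrangement
  expect_equal(measure_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                c(1, 0, 0)), 180)
  # cis (eclipsed)
  expect_equal(measure_dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                                c(0, 1, 0)), 0)
  expect_error(measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                c(3, 1, 0)), "degenerate")
})

test_that("dihedral matches an independent projection-formula oracle", {
  set.seed(11)
  for (k in 1:1000) {
    p <- matrix(rnorm(12), 4, 3)
    ref <- tryCatch(oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                    error = function(e) NA)
    if (is.na(ref)) next
    expect_lt(abs(wrapd(measure_dihedral(p[1, ], p[2, ], p[3, ],
                                         p[4, ]) - ref)), 1e-9)
  }
})

test_that("dihedrals are rigid-motion invariant and mirror antisymmetric", {
  set.seed(12)
  for (k in 1:50) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    d0 <- measure_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- macrocycler:::rodrigues(ax, runif(1, 0, 2 * pi))
    tr <- rnorm(3)
    q <- t(apply(p, 1, function(x) as.numeric(R %*% x) + tr))
    expect_lt(abs(wrapd(measure_dihedral(q[1, ], q[2, ], q[3, ],
                                         q[4, ]) - d0)), 1e-9)
    m <- p; m[, 3] <- -m[, 3]
    dm <- measure_dihedral(m[1, ], m[2, ], m[3, ], m[4, ])
    expect_lt(abs(wrapd(dm + d0)), 1e-9)
  }
})

test_that("chain building round-trips requested torsions", {
  set.seed(13)
  for (k in 1:25) {
    n <- sample(4:9, 1)
    ids <- sample(c("GLY", "ALA", "SER", "LEU", "DAL", "DLE", "TYR"),
                  n, replace = TRUE)
    phi <- runif(n, -179, 179)
    psi <- runif(n, -179, 179)
    chi <- lapply(ids, function(id) {
      nc <- residue_topology(id)$nchi
      runif(nc, -179, 179)
    })
    po <- build_chain(as.list(ids), phi, psi, chi = chi)
    tor <- pose_torsions(po)
    expect_lt(max(abs(wrapd(tor$phi[-1] - phi[-1]))), 1e-6)
    expect_lt(max(abs(wrapd(tor$psi[-n] - psi[-n]))), 1e-6)
    expect_lt(max(abs(wrapd(tor$omega[-n] - 180))), 1e-6)
    for (i in seq_len(n)) {
      if (length(chi[[i]]) > 0) {
        expect_lt(max(abs(wrapd(pose_chi(po, i) - chi[[i]]))), 1e-6)
      }
    }
  }
})

test_that("an all-trans extended chain has 3.80 A C-alpha spacing", {
  po <- build_chain(rep(list("GLY"), 6), rep(180, 6), rep(180, 6))
  ca <- pose_coords(po, "bb3")
  ca <- ca[grep(":CA$", rownames(ca)), ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.80) < 0.01))
})

test_that("chi requested for Gly raises an invalid-torsion error", {
  expect_error(build_chain(list("GLY"), 0, 0, chi = list(60)),
               "invalid torsion")
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(14)
  x <- matrix(rnorm(30), 10, 3)
  fit <- superpose_kabsch(x, x)
  expect_lt(fit$rmsd, 1e-12)
  for (k in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    R <- macrocycler:::rodrigues(ax, runif(1, 0, 2 * pi))
    y <- sweep(x %*% t(R), 2, rnorm(3), `+`)
    f <- superpose_kabsch(y, x)
    expect_lt(f$rmsd, 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  }
  # enantiomers cannot be superposed by a proper rotation
  m <- x; m[, 3] <- -m[, 3]
  f <- superpose_kabsch(m, x)
  expect_gt(f$rmsd, 0.1)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  expect_error(superpose_kabsch(x[1:2, ], x[1:2, ]), "insufficient")
})

test_that("pose RMSD agrees with closed forms and a bio3d oracle", {
  set.seed(15)
  po <- build_chain(rep(list("ALA"), 5), runif(5, -179, 179),
                    runif(5, -179, 179))
  expect_equal(pose_rmsd(po, po, "backbone"), 0, tolerance = 1e-12)
  # displace one atom by d with the rest fixed: rmsd <= d/sqrt(N) (the
  # bound is attained without re-fitting; superposition can only reduce)
  po2 <- po
  i <- which(po2$atoms$name == "O")[2]
  d <- 0.4
  po2$atoms$x[i] <- po2$atoms$x[i] + d
  nsel <- sum(po$atoms$name %in% c("N", "CA", "C", "O"))
  expect_lte(pose_rmsd(po, po2, "backbone"), d / sqrt(nsel) + 1e-9)
  expect_gt(pose_rmsd(po, po2, "backbone"), 0.5 * d / sqrt(nsel))
  # random torsion perturbation: equals independent Kabsch via bio3d
  po3 <- build_chain(rep(list("ALA"), 5), runif(5, -179, 179),
                     runif(5, -179, 179))
  xa <- pose_coords(po, "backbone")
  xb <- pose_coords(po3, "backbone")
  fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(xb)),
                                         mobile = as.numeric(t(xa))))
  ref <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) -
                              xb)^2)))
  expect_equal(pose_rmsd(po, po3, "backbone"), ref, tolerance = 1e-6)
})

test_that("a D chain built with negated torsions mirrors the L chain", {
  set.seed(16)
  ids_l <- c("LEU", "TYR", "SER", "ALA")
  ids_d <- c("DLE", "DTY", "DSN", "DAL")
  phi <- runif(4, -179, 179); psi <- runif(4, -179, 179)
  chi <- lapply(ids_l, function(id) {
    runif(residue_topology(id)$nchi, -179, 179)
  })
  poL <- build_chain(as.list(ids_l), phi, psi, chi = chi)
  poD <- build_chain(as.list(ids_d), -phi, -psi,
                     chi = lapply(chi, function(v) -v))
  mL <- mirror_pose(poL)
  xa <- pose_coords(mL, "heavy")
  xb <- pose_coords(poD, "heavy")
  expect_identical(rownames(xa), rownames(xb))
  expect_lt(superpose_kabsch(xa, xb)$rmsd, 1e-9)
})
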