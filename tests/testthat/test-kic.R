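test_that("re-solving a closed ring recovers its pivot torsions", {
  set.seed(31)
  for (n in c(7, 9)) {
    piv <- c(2, 4, 6)
    found <- 0
    for (trial in 1:6) {
      s <- sample_phi_psi(n)
      sols <- solve_closure(s$phi, s$psi, pivots = piv)
      if (length(sols) == 0) next
      found <- found + 1
      ref <- sols[[1]]
      again <- solve_closure(ref$phi, ref$psi, pivots = piv)
      dmin <- min(vapply(again, function(z) {
        max(abs(wrapd(solution_pivot_torsions(z) -
                        solution_pivot_torsions(ref))))
      }, numeric(1)))
      expect_lt(dmin, 1e-4)
      if (found >= 2) break
    }
    expect_gte(found, 1)
  }
})

test_that("every returned solution closes with ideal geometry", {
  set.seed(32)
  checked <- 0
  while (checked < 3) {
    s <- sample_phi_psi(8)
    sols <- solve_closure(s$phi, s$psi, pivots = c(2, 5, 7))
    for (sol in sols) {
      r <- closure_residual(sol$pose)
      expect_lt(abs(r$bond_length - 1.329), 0.01)
      expect_lt(r$angle_c, 1)
      expect_lt(r$angle_n, 1)
      # pivot N-CA-C angles restored to the ideal value
      for (p in sol$pivots) {
        a <- bond_angle(macrocycler:::atom_xyz(sol$pose, p, "N"),
                        macrocycler:::atom_xyz(sol$pose, p, "CA"),
                        macrocycler:::atom_xyz(sol$pose, p, "C"))
        expect_lt(abs(a - 111.2), 1e-3)
      }
      # non-pivot torsions preserved exactly
      np <- setdiff(1:8, sol$pivots)
      expect_lt(max(abs(wrapd(sol$phi[np] - s$phi[np]))), 1e-6)
      checked <- checked + 1
    }
    expect_lte(length(sols), 16)
  }
})

test_that("infeasible torsion sets yield an empty list, not an error", {
  # a wildly stretched template cannot satisfy the triangle inequality
  phi <- rep(180, 12); psi <- rep(180, 12)
  sols <- solve_closure(phi, psi, pivots = c(2, 4, 6))
  expect_identical(sols, list())
})

test_that("the solution set matches the numerical scan oracle", {
  # one fixed feasible instance; the acceptance suite scans more sizes
  set.seed(42)
  n <- 7; piv <- c(2, 4, 6)
  s <- NULL
  for (k in 1:10) {
    s <- sample_phi_psi(n)
    if (length(solve_closure(s$phi, s$psi, pivots = piv)) > 0) break
  }
  sols <- solve_closure(s$phi, s$psi, pivots = piv)
  osols <- oracle_closure_solutions(s$phi, s$psi, piv, n)
  expect_equal(length(sols), length(osols))
  storsions <- lapply(sols, solution_pivot_torsions)
  for (o in osols) {
    dmin <- min(vapply(storsions, function(r) max(abs(wrapd(r - o))),
                       numeric(1)))
    expect_lt(dmin, 1e-3)
  }
})

test_that("mirroring the problem mirrors the solution set", {
  set.seed(34)
  n <- 8; piv <- c(3, 5, 7)
  for (k in 1:10) {
    s <- sample_phi_psi(n)
    sols <- solve_closure(s$phi, s$psi, pivots = piv)
    if (length(sols) > 0) break
  }
  msols <- solve_closure(-s$phi, -s$psi, pivots = piv)
  expect_equal(length(sols), length(msols))
  for (sol in sols) {
    mirrored <- pose_coords(mirror_pose(sol$pose), "bb3")
    dmin <- min(vapply(msols, function(z) {
      superpose_kabsch(pose_coords(z$pose, "bb3"), mirrored)$rmsd
    }, numeric(1)))
    expect_lt(dmin, 1e-6)
  }
})

test_that("anchored sampling honors determinism, size and the anchor", {
  ts <- make_toy_target(1)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  expect_identical(
    sample_closed_backbones(an, ts, 9, n_attempts = 0, seed = 1),
    structure(list(), stats = c(attempts = 0, closed = 0,
                                clash_rejected = 0, kept = 0)))
  for (nr in c(8, 9, 10)) {
    sols <- sample_closed_backbones(an, ts, nr, n_attempts = 40,
                                    seed = 5)
    expect_gt(length(sols), 0)
    for (sol in sols[seq_len(min(3, length(sols)))]) {
      expect_equal(pose_length(sol$pose), nr)
      expect_true(closure_valid(sol))
      # anchor backbone coordinates are bit-identical to the anchor
      for (nm in c("N", "CA", "C")) {
        expect_identical(macrocycler:::atom_xyz(sol$pose, 1, nm),
                         macrocycler:::anchor_xyz(an, nm))
      }
      expect_true(sol$pose$anchor_mask[1])
    }
  }
  a <- sample_closed_backbones(an, ts, 9, n_attempts = 25, seed = 7)
  b <- sample_closed_backbones(an, ts, 9, n_attempts = 25, seed = 7)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$pose$atoms, b[[i]]$pose$atoms)
  }
})

test_that("an anchor buried in the target raises an anchor-clash error", {
  ts <- make_toy_target(1)
  # drop the anchor C-alpha straight onto a target atom
  hit <- as.numeric(ts$atoms[10, c("x", "y", "z")])
  bad <- rotamer_scan_place(ts, "ALA", attr(ts, "hotspot_site"),
                            attr(ts, "hotspot_normal"))
  bad$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(bad$atoms[, c("x", "y", "z")]), 2,
          as.numeric(hit - anchor_xyz_safe(bad)), `+`)
  expect_error(sample_closed_backbones(bad, ts, 9, n_attempts = 5,
                                       seed = 1), "anchor-clash")
})
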