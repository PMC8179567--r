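test_that("hotspot extraction copies the residue verbatim", {
  cx <- make_toy_complex(1)
  an <- extract_hotspot(cx, "B", 1)
  expect_identical(an$identity, "TYR")
  src <- cx$atoms[cx$atoms$chain == "B", ]
  expect_identical(an$atoms$x, src$x)
  expect_identical(an$atoms$y, src$y)
  expect_identical(an$atoms$z, src$z)
  # chi measured from coordinates match the docked rotamer
  expect_lt(max(abs(wrapd(an$chi - attr(cx, "chi")))), 1e-6)
  expect_error(extract_hotspot(cx, "B", 9999), "lookup error")
  expect_error(extract_hotspot(cx, "Z", 1), "lookup error")
})

test_that("rotamer scan returns the scored argmin among non-clashers", {
  ts <- make_toy_target(1)
  site <- attr(ts, "hotspot_site")
  nrm <- attr(ts, "hotspot_normal")
  an <- rotamer_scan_place(ts, "TRP", site, nrm)
  scan <- attr(an, "scan")
  ok <- scan[!scan$clash, ]
  expect_equal(min(ok$score), ok$score[which.min(ok$score)])
  expect_equal(unname(an$chi),
               unname(as.numeric(
                 scan[!scan$clash, ][which.min(ok$score),
                                     -(1:3)])))
  # independent re-scoring of the winning rotamer
  po <- macrocycler:::build_anchor_at_site("TRP", site, nrm, an$chi)
  pa <- macrocycler:::pose_heavy_atoms(po)
  e <- macrocycler:::steric_cross(as.matrix(pa[, c("x", "y", "z")]),
                                  pa$radius,
                                  as.matrix(ts$atoms[, c("x", "y", "z")]),
                                  ts$atoms$radius, energy_params())
  expect_equal(e, min(ok$score), tolerance = 1e-9)
  # determinism
  an2 <- rotamer_scan_place(ts, "TRP", site, nrm)
  expect_identical(an$atoms, an2$atoms)
})

test_that("a single non-clashing rotamer is returned as-is", {
  ts <- make_toy_target(1)
  rs <- matrix(c(180, 80), 1, 2)
  an <- rotamer_scan_place(ts, "TYR", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"), rotamer_set = rs)
  expect_equal(unname(an$chi), c(180, 80))
  expect_error(
    rotamer_scan_place(ts, "TYR", attr(ts, "hotspot_site"),
                       attr(ts, "hotspot_normal"),
                       rotamer_set = matrix(numeric(0), 0, 2)),
    "empty rotamer set")
})

test_that("a clashing global minimum falls back to the next rotamer", {
  ts <- make_toy_target(1)
  site <- attr(ts, "hotspot_site"); nrm <- attr(ts, "hotspot_normal")
  rs <- matrix(c(-60, 60, 60, -60), 2, 2)   # two TYR rotamers
  free <- rotamer_scan_place(ts, "TYR", site, nrm, rotamer_set = rs)
  winner <- unname(free$chi)
  loser <- rs[which(apply(rs, 1, function(r) !all(r == winner)))[1], ]
  # drop a blocking atom exactly onto the winner's OH position
  po <- macrocycler:::build_anchor_at_site("TYR", site, nrm, winner)
  oh <- macrocycler:::atom_xyz(po, 1, "OH")
  block <- ts
  block$atoms <- rbind(block$atoms, data.frame(
    chain = "A", resno = 999, insert = "", resid = "ALA", name = "O",
    element = "O", x = oh[1], y = oh[2], z = oh[3], radius = 1.52,
    o = 1, b = 0, stringsAsFactors = FALSE))
  an <- rotamer_scan_place(block, "TYR", site, nrm, rotamer_set = rs)
  expect_equal(unname(an$chi), unname(loser))
})

test_that("poly-Gly extension keeps the anchor interior and untouched", {
  cx <- make_toy_complex(1)
  an <- extract_hotspot(cx, "B", 1)
  po <- extend_polygly(an, 4, 4)
  expect_equal(pose_length(po), 9)
  expect_identical(pose_sequence(po)[5], "TYR")
  expect_true(all(pose_sequence(po)[-5] == "GLY"))
  expect_true(po$anchor_mask[5])
  for (nm in c("N", "CA", "C")) {
    expect_identical(macrocycler:::atom_xyz(po, 5, nm),
                     macrocycler:::anchor_xyz(an, nm))
  }
  # side-chain atoms carried over exactly
  cg <- an$atoms[an$atoms$name == "CG", ]
  expect_identical(macrocycler:::atom_xyz(po, 5, "CG"),
                   as.numeric(cg[1, c("x", "y", "z")]))
  expect_error(extend_polygly(an, 2, 4), "parameter error")
  expect_error(extend_polygly(an, 4, 7), "parameter error")
})

test_that("hotspot + 4 N-terminal + 4 C-terminal Gly gives a 9-mer chain", {
  ts <- make_toy_target(2)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  po <- extend_polygly(an, 4, 4)
  expect_equal(pose_length(po), 9)
  expect_false(po$cyclic)
  tor <- pose_torsions(po)
  # arms built extended
  expect_true(all(abs(wrapd(tor$psi[1:3] - 180)) < 1e-6))
})

test_that("anchor coordinates survive sampling and design unchanged", {
  ts <- make_toy_target(1)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  sols <- sample_closed_backbones(an, ts, 8, n_attempts = 40, seed = 11)
  expect_gt(length(sols), 0)
  rec <- design(sols[[1]]$pose, ts,
                schedule = mc_schedule(n_moves = 60, seed = 3))
  expect_identical(rec$sequence[1], "TRP")
  anchor_names <- an$atoms$name[an$atoms$element != "H"]
  for (nm in anchor_names) {
    expect_lt(max(abs(macrocycler:::atom_xyz(rec$pose, 1, nm) -
                        macrocycler:::anchor_xyz(an, nm))), 1e-6)
  }
})
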