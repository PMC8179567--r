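test_that("position chiralities follow the phi-sign rule", {
  po <- make_ideal_macrocycle(8, "alternating")
  tor <- pose_torsions(po)
  expect_identical(position_chiralities(po),
                   ifelse(tor$phi > 0, "D", "L"))
  m <- mirror_pose(po)
  expect_identical(position_chiralities(m),
                   ifelse(position_chiralities(po) == "L", "D", "L"))
  # an all-L backbone
  poL <- build_chain(rep(list("GLY"), 5), rep(-70, 5), rep(-40, 5))
  expect_true(all(position_chiralities(poL) == "L"))
})

test_that("a single-identity palette forces the sequence", {
  po <- make_ideal_macrocycle(8)
  pal <- design_palette(exclude = setdiff(names(macrocycler:::.nchi),
                                          c("SER")),
                        allow_gly = FALSE)
  rec <- design(po, NULL, pal, mc_schedule(n_moves = 120, seed = 2))
  chir <- position_chiralities(po)
  expect_true(all(rec$sequence[chir == "L"] == "SER"))
  expect_true(all(rec$sequence[chir == "D"] == "DSN"))
  # reported energy equals a direct rescoring of the returned pose
  p <- macrocycler:::design_energy_params(pal, energy_params())
  expect_equal(rec$energy$total,
               score(rec$pose, NULL, p, context = "design")$total,
               tolerance = 1e-9)
})

test_that("MC design finds the exhaustive optimum on a tiny problem", {
  # 8-ring with all but two positions frozen as anchors; one allowed
  # identity with three rotamers at each free position: 9 states
  po <- make_ideal_macrocycle(8)
  po$anchor_mask <- rep(TRUE, 8)
  free <- c(3, 6)
  po$anchor_mask[free] <- FALSE
  chir <- position_chiralities(po)
  id_at <- ifelse(chir[free] == "D", "DVA", "VAL")
  pal <- design_palette(exclude = setdiff(names(macrocycler:::.nchi),
                                          "VAL"),
                        allow_gly = FALSE)
  p <- macrocycler:::design_energy_params(pal, energy_params())
  # exhaustive enumeration oracle
  rots <- rotamer_library("VAL")
  states <- expand.grid(a = seq_len(nrow(rots)), b = seq_len(nrow(rots)))
  evals <- apply(states, 1, function(s) {
    q <- set_sidechain(po, free[1], id_at[1],
                       as.numeric(rotamer_library(id_at[1])[s["a"], ]))
    q <- set_sidechain(q, free[2], id_at[2],
                       as.numeric(rotamer_library(id_at[2])[s["b"], ]))
    score(q, NULL, p, context = "design")$total
  })
  best_exh <- min(evals)
  hits <- 0
  for (sd in 1:20) {
    rec <- design(po, NULL, pal,
                  mc_schedule(n_moves = 150, seed = sd), refine = FALSE)
    if (abs(rec$energy$total - best_exh) < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("designed identities always match backbone chirality", {
  ts <- make_toy_target(1)
  an <- rotamer_scan_place(ts, "TRP", attr(ts, "hotspot_site"),
                           attr(ts, "hotspot_normal"))
  sols <- sample_closed_backbones(an, ts, 9, n_attempts = 40, seed = 21)
  expect_gt(length(sols), 0)
  rec <- design(sols[[1]]$pose, ts,
                schedule = mc_schedule(n_moves = 120, seed = 5))
  tor <- pose_torsions(rec$pose)
  d_codes <- supported_identities("D")
  for (i in seq_along(rec$sequence)) {
    if (rec$pose$anchor_mask[i] || rec$sequence[i] == "GLY") next
    if (tor$phi[i] > 0) {
      expect_true(rec$sequence[i] %in% d_codes)
    } else {
      expect_true(rec$sequence[i] %in% names(macrocycler:::.nchi))
    }
  }
})

test_that("Gly/Ala penalties reduce Gly+Ala content", {
  # the compact turn-rich ring leaves cramped interior positions where
  # small residues win on sterics alone unless penalized
  po <- make_ideal_macrocycle(6, "turns")
  frac_ga <- function(pal, sd) {
    rec <- design(po, NULL, pal, mc_schedule(n_moves = 100, seed = sd),
                  refine = FALSE)
    mean(rec$sequence %in% c("GLY", "ALA", "DAL"))
  }
  pal_on <- design_palette(gly_penalty = 1, ala_penalty = 1)
  pal_off <- design_palette(gly_penalty = 0, ala_penalty = 0)
  on <- vapply(1:20, function(sd) frac_ga(pal_on, sd), numeric(1))
  off <- vapply(1:20, function(sd) frac_ga(pal_off, sd), numeric(1))
  tst <- stats::t.test(on, off, alternative = "less")
  expect_lt(tst$p.value, 0.05)
})

test_that("design is deterministic under its seed", {
  po <- make_ideal_macrocycle(7)
  a <- design(po, NULL, schedule = mc_schedule(n_moves = 80, seed = 9))
  b <- design(po, NULL, schedule = mc_schedule(n_moves = 80, seed = 9))
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$chi, b$chi)
  expect_equal(a$energy$total, b$energy$total, tolerance = 1e-12)
  # best-so-far trajectory is monotone non-increasing
  expect_true(all(diff(a$trajectory) <= 1e-12))
})

test_that("ranking follows the documented composite key", {
  mk <- function(ie, bs, sc, hb) {
    structure(list(interface = structure(
      list(interaction_energy = ie, buried_sasa = bs, sc = sc,
           inter_hbond_count = hb, intra_hbond_count = 0),
      class = "InterfaceReport")), class = "DesignRecord")
  }
  r1 <- mk(-5, 100, 0.5, 1)
  r2 <- mk(-7, 90, 0.4, 0)
  r3 <- mk(-5, 120, 0.3, 2)
  out <- rank_designs(list(r1, r2, r3))
  # independent re-sort oracle
  key <- list(c(-5, 100, 0.5, 1), c(-7, 90, 0.4, 0), c(-5, 120, 0.3, 2))
  ord <- order(sapply(key, `[`, 1), -sapply(key, `[`, 2),
               -sapply(key, `[`, 3), -sapply(key, `[`, 4))
  expect_identical(out, list(r1, r2, r3)[ord])
  expect_identical(rank_designs(list(r1)), list(r1))
  expect_error(rank_designs(list(structure(list(interface = NULL),
                                           class = "DesignRecord"))),
               "ranking error")
})

test_that("sequence strings use lower case for D residues", {
  po <- build_chain(list("TYR", "DPR", "GLY"), c(NA, 60, -70),
                    c(130, -40, 150), chi = list(c(180, 80), numeric(0),
                                                 numeric(0)))
  expect_identical(design_sequence_string(po), "YpG")
})
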