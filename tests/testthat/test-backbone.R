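test_that("chain growth honours ideal covalent geometry", {
  m <- build_chain_from_torsions(matrix(c(-60, -40, 180, -60, -40, 180),
                                        ncol = 3, byrow = TRUE))
  cn <- sqrt(sum((atom_coords(m, "N", 2) - atom_coords(m, "C", 1))^2))
  expect_equal(cn, 1.329, tolerance = 1e-12)
  nca <- sqrt(sum((atom_coords(m, "CA", 1) - atom_coords(m, "N", 1))^2))
  expect_equal(nca, 1.458, tolerance = 1e-12)
  expect_error(build_chain_from_torsions(matrix(numeric(0), 0, 3)), "one residue")
})

test_that("an ideal helix shows helical geometry and no clashes", {
  h <- build_chain_from_torsions(matrix(rep(c(-57, -47, 180), 8),
                                        ncol = 3, byrow = TRUE))
  ca <- atom_coords(h, "CA")
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  # rise per residue along the principal axis ~ 1.5 A
  cc <- sweep(ca, 2, colMeans(ca))
  axis <- svd(cc)$v[, 1]
  rise <- abs(mean(diff(cc %*% axis)))
  expect_true(abs(rise - 1.5) < 0.15)
  expect_equal(check_clashes(h), 0L)
})

test_that("build/measure round trip reconstructs torsions", {
  # 100 random torsion lists; worst-case reconstruction error < 1e-5 degrees
  set.seed(11)
  worst <- 0
  for (k in 1:100) {
    n <- sample(3:12, 1)
    tor <- cbind(phi = runif(n, -180, 179), psi = runif(n, -180, 179),
                 omega = runif(n, -180, 179))
    m <- build_chain_from_torsions(tor)
    mt <- measure_torsions(m)
    dd <- abs(((mt - tor) + 180) %% 360 - 180)
    worst <- max(worst, dd[cbind(2:n, 1)], dd[cbind(1:(n - 1), 2)],
                 dd[cbind(1:(n - 1), 3)])
  }
  expect_lt(worst, 1e-5)
})

test_that("measured torsions agree with an independent dihedral oracle", {
  m <- fixture_chain(8)
  mt <- measure_torsions(m)
  Nc <- atom_coords(m, "N"); CAc <- atom_coords(m, "CA"); Cc <- atom_coords(m, "C")
  for (i in 2:7) {
    expect_equal(unname(mt[i, "phi"]),
                 oracle_dihedral(Cc[i - 1, ], Nc[i, ], CAc[i, ], Cc[i, ]),
                 tolerance = 1e-9)
    expect_equal(unname(mt[i, "psi"]),
                 oracle_dihedral(Nc[i, ], CAc[i, ], Cc[i, ], Nc[i + 1, ]),
                 tolerance = 1e-9)
  }
  expect_true(is.na(mt[1, "phi"]))
  expect_true(is.na(mt[8, "psi"]))
})

test_that("an ideal strand classifies as all-B", {
  s <- build_chain_from_torsions(matrix(rep(c(-120, 130, 180), 6),
                                        ncol = 3, byrow = TRUE))
  st <- measure_torsions(s)
  expect_true(all(classify_abego(st[2:5, "phi"], st[2:5, "psi"]) == "B"))
})

test_that("colinear atoms raise a degenerate-geometry error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("clash counting matches brute force and spec examples", {
  one <- build_chain_from_torsions(matrix(c(0, -40, 180), 1, 3))
  expect_equal(check_clashes(one), 0L)
  m <- fixture_chain(10, seed = 21)
  expect_equal(check_clashes(m), oracle_clash_count(m))
  # two superposed copies of a residue clash
  dup <- backbone_model(rbind(one$xyz, one$xyz, one$xyz))
  expect_gt(check_clashes(dup), 0L)
})

test_that("torsion sampling is deterministic and class-faithful", {
  segH <- segment_spec("H1", length = 10)
  t1 <- sample_torsions_for_segment(segH, rng_seed = 7)
  t2 <- sample_torsions_for_segment(segH, rng_seed = 7)
  expect_identical(t1, t2)
  expect_true(all(classify_abego(t1[, "phi"], t1[, "psi"], t1[, "omega"]) == "A"))

  segL <- segment_spec("L2", abego = "GB")
  tl <- sample_torsions_for_segment(segL, rng_seed = 1)
  expect_equal(classify_abego(tl[1, "phi"], tl[1, "psi"], tl[1, "omega"]), "G")
  expect_equal(classify_abego(tl[2, "phi"], tl[2, "psi"], tl[2, "omega"]), "B")

  # sampling must not disturb the caller's RNG stream
  set.seed(5); a <- runif(1)
  set.seed(5); invisible(sample_torsions_for_segment(segH, rng_seed = 3))
  expect_identical(runif(1), a)

  segO <- segment_spec("L2", abego = "OO")
  expect_error(sample_torsions_for_segment(segO, rng_seed = 1), "cis")
  expect_silent(sample_torsions_for_segment(segO, rng_seed = 1, allow_cis = TRUE))
})

test_that("compactness and cavity metrics behave on reference shapes", {
  # fully extended 30-residue chain fails a 12 A compactness bound
  ext <- build_chain_from_torsions(matrix(rep(c(-120, 130, 180), 30),
                                          ncol = 3, byrow = TRUE))
  f <- compactness_and_cavity_filter(ext, rg_max = 12)
  expect_false(f$pass)
  expect_equal(f$radius_of_gyration, oracle_rg(ext), tolerance = 1e-9)

  one <- build_chain_from_torsions(matrix(c(0, -40, 180), 1, 3))
  f1 <- compactness_and_cavity_filter(one, rg_max = 5)
  expect_true(f1$pass)
  expect_equal(f1$cavity_volume, 0)
  expect_lt(f1$radius_of_gyration, 1.5)

  # hollow shell encloses a cavity; voxel count oracle says > 27 A^3 for a
  # shell leaving a >3x3x3 A empty interior
  shell <- shell_points(200, 5)
  expect_gte(cavity_volume(shell), 27)
})

test_that("clash count, Rg and cavity volume are rigid-motion invariant", {
  m <- build_chain_from_torsions(matrix(rep(c(-57, -47, 180), 14),
                                        ncol = 3, byrow = TRUE))
  set.seed(31)
  for (k in 1:3) {
    rt <- random_rigid_transform()
    m2 <- transform_model(m, rt)
    expect_equal(check_clashes(m2), check_clashes(m))
    expect_equal(radius_of_gyration(m2), radius_of_gyration(m),
                 tolerance = 1e-9)
    expect_equal(cavity_volume(m2), cavity_volume(m), tolerance = 1e-9)
  }
})
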