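motif_fix <- make_idealized_motif()

# one scaffold shared by the grafting tests
scaffold_fix <- local({
  sel <- rank_and_select_blueprints(
    enumerate_blueprints(make_topology_stats(1)), 10)
  res <- assemble_stagewise(as_blueprint(sel, 1), motif = make_idealized_motif(),
                            n_tries_per_stage = 60, rng_seed = 5,
                            filters = pipeline_filters())
  res$candidates[[1]]
})

test_that("kabsch recovers exact transforms and never reflects", {
  set.seed(13)
  pts <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_superpose(pts, pts)$rmsd, 0, tolerance = 1e-9)
  for (k in 1:5) {
    rt <- random_rigid_transform()
    moved <- transform_coords(pts, rt$rotation, rt$translation)
    fit <- kabsch_superpose(pts, moved)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(fit$rotation, rt$rotation, tolerance = 1e-8)
    expect_equal(fit$translation, rt$translation, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  # mirrored points: optimum is strictly positive, rotation stays proper
  mirror <- pts %*% diag(c(-1, 1, 1))
  fm <- kabsch_superpose(mirror, pts)
  expect_gt(fm$rmsd, 0.1)
  expect_equal(det(fm$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch is optimal against 1000 random rigid transforms", {
  set.seed(17)
  a <- matrix(rnorm(18), 6, 3)
  b <- matrix(rnorm(18), 6, 3)
  best <- kabsch_superpose(a, b)$rmsd
  for (k in 1:1000) {
    rt <- random_rigid_transform()
    # candidate transform also centers b's centroid like the optimum does
    moved <- transform_coords(sweep(a, 2, colMeans(a)), rt$rotation,
                              colMeans(b))
    rmsd <- sqrt(mean(rowSums((moved - b)^2)))
    expect_lte(best, rmsd + 1e-12)
  }
})

test_that("degenerate or mismatched inputs are rejected", {
  expect_error(kabsch_superpose(matrix(0, 3, 3), matrix(0, 4, 3)), "shape")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "rank")
})

test_that("self-grafting is the identity", {
  scaffold <- scaffold_fix
  loop <- attr(scaffold, "ranges")$L1
  self <- extract_motif_from_model(scaffold, (min(loop) - 1):(max(loop) + 1))
  g <- graft_motif_into_scaffold(scaffold, self, loop_range = loop)
  expect_true(g$accepted)
  expect_lt(g$closure_rmsd, 1e-9)
  expect_equal(g$model$xyz, scaffold$xyz, tolerance = 1e-9)
  expect_equal(n_residues(g$model), n_residues(scaffold))
})

test_that("displaced anchors fail the closure threshold", {
  scaffold <- scaffold_fix
  shifted <- motif_fix
  # displace only the post-anchor so the misfit cannot be absorbed by the
  # rigid superposition
  shifted$model$xyz[21:24, ] <-
    sweep(shifted$model$xyz[21:24, ], 2, c(5, 0, 0), "+")
  g <- graft_motif_into_scaffold(scaffold, shifted, target_loop = "L1",
                                 closure_threshold = 0.5)
  expect_false(g$accepted)
  expect_gt(g$closure_rmsd, 0.5)
})

test_that("grafting commutes with rigid motion of the scaffold", {
  scaffold <- scaffold_fix
  set.seed(23)
  rt <- random_rigid_transform()
  g0 <- graft_motif_into_scaffold(scaffold, motif_fix, "L1")
  g1 <- graft_motif_into_scaffold(transform_model(scaffold, rt), motif_fix, "L1")
  expect_equal(g1$model$xyz,
               transform_coords(g0$model$xyz, rt$rotation, rt$translation),
               tolerance = 1e-6)
  expect_equal(g1$closure_rmsd, g0$closure_rmsd, tolerance = 1e-9)
})

test_that("motif extraction from a parsed structure copies coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(motif_model(motif_fix), f)
  parsed <- read_pdb(f)
  m <- extract_motif_from_complex(parsed, "A", 1:6)
  expect_equal(n_residues(motif_model(m)), 6)
  expect_equal(m$sequence, c("H", "R", "G", "D", "F", "P"))
  expect_equal(motif_model(m)$xyz, motif_model(motif_fix)$xyz,
               tolerance = 1e-3)  # PDB precision
  expect_error(extract_motif_from_complex(parsed, "A", 4:9), "not found")
  expect_error(extract_motif_from_complex(parsed, "B", 1:6), "not found")
})

test_that("loop/motif length mismatch beyond 2 residues is rejected", {
  scaffold <- scaffold_fix
  big <- motif_definition(build_chain_from_torsions(
    matrix(rep(c(-120, 130, 180), 9), ncol = 3, byrow = TRUE)))
  expect_error(graft_motif_into_scaffold(scaffold, big, "L1"),
               "more than 2")
  expect_error(graft_motif_into_scaffold(scaffold, motif_fix, "L9"),
               "lookup error")
})
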