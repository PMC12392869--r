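test_that("SASA matches analytic sphere values", {
  # isolated sphere: 4 pi (r + probe)^2
  a1 <- sum(sasa(matrix(0, 1, 3), 1.7))
  expect_equal(a1, 4 * pi * 3.1^2, tolerance = 0.01)
  # two atoms far apart: additivity
  far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), 1.7)
  expect_equal(sum(far), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # overlapping pair at 2 A: closed-form spherical-cap oracle within 2%
  near <- sum(sasa(rbind(c(0, 0, 0), c(2, 0, 0)), 1.7))
  expect_equal(near, oracle_two_sphere_area(1.7, 1.7, 2), tolerance = 0.02)
  # and an asymmetric pair
  near2 <- sum(sasa(rbind(c(0, 0, 0), c(2.5, 0, 0)), c(1.55, 1.9)))
  expect_equal(near2, oracle_two_sphere_area(1.55, 1.9, 2.5), tolerance = 0.02)
})

test_that("SASA is converged at the default point count", {
  m <- fixture_chain(8, seed = 3)
  r <- sasa_radii(m$atom)
  a960 <- sum(sasa(m$xyz, r, n_points = 960))
  a4000 <- sum(sasa(m$xyz, r, n_points = 4000))
  expect_lt(abs(a960 - a4000) / a4000, 0.01)
  expect_error(sasa(m$xyz, r, n_points = 60), "92")
  expect_error(sasa(matrix(0, 1, 3), -1), "positive")
  # coincident atoms must not blow up
  expect_silent(sasa(matrix(0, 2, 3, byrow = TRUE), 1.7))
})

test_that("buried interface area behaves at the limits", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b_far <- matrix(c(50, 0, 0), 1, 3)
  expect_equal(interface_buried_area(a, b_far, 1.7, 1.7), 0)
  b_on <- matrix(c(0.5, 0, 0), 1, 3)
  expect_gt(interface_buried_area(a, b_on, 1.7, 1.7), 0)
  # invariance under joint rigid motion
  set.seed(7)
  pa <- matrix(rnorm(15, sd = 2), 5, 3)
  pb <- sweep(matrix(rnorm(9, sd = 2), 3, 3), 2, c(4, 0, 0), "+")
  base <- interface_buried_area(pa, pb, 1.7, 1.7)
  rt <- random_rigid_transform()
  moved <- interface_buried_area(
    transform_coords(pa, rt$rotation, rt$translation),
    transform_coords(pb, rt$rotation, rt$translation), 1.7, 1.7)
  expect_equal(moved, base, tolerance = 1e-6)
})

one_residue_design <- function(letter, at = c(0, 0, 0)) {
  m <- build_chain_from_torsions(matrix(c(0, -40, 180), 1, 3),
                                 sequence = letter)
  m$xyz <- sweep(m$xyz, 2, at - m$xyz[2, ], "+")  # put CA at `at`
  m
}

target_one <- function(class, at = c(3, 0, 0)) {
  pseudo_target(data.frame(x = at[1], y = at[2], z = at[3], radius = 1.7,
                           class = class))
}

test_that("contact energy reproduces single-pair kernel values", {
  # hydrophobic pair at 3.0 A sits on the kernel plateau: exactly -1
  d <- one_residue_design("V")
  card <- contact_and_ddg_proxy(d, target_one("hydrophobic", c(3, 0, 0)))
  expect_equal(card$ddg_proxy, -1)
  # far target: all interface metrics vanish
  card_far <- contact_and_ddg_proxy(d, target_one("hydrophobic", c(60, 0, 0)))
  expect_equal(card_far$ddg_proxy, 0)
  expect_equal(card_far$contact_surface, 0)
  expect_equal(card_far$interface_buried_area, 0)
  # kernel decays linearly between 3.5 and 5 A
  card_mid <- contact_and_ddg_proxy(d, target_one("hydrophobic", c(4.25, 0, 0)))
  expect_equal(card_mid$ddg_proxy, -0.5, tolerance = 1e-9)
  # opposite charges attract, like charges repel, donor-acceptor favourable
  dk <- one_residue_design("K")
  expect_equal(contact_and_ddg_proxy(dk, target_one("negative"))$ddg_proxy, -2)
  expect_equal(contact_and_ddg_proxy(dk, target_one("positive"))$ddg_proxy, 2)
  ds <- one_residue_design("S")
  expect_equal(contact_and_ddg_proxy(ds, target_one("acceptor"))$ddg_proxy, -1.5)
})

test_that("correct charge placement scores better than swapped charges", {
  motif <- make_idealized_motif()
  tg <- make_pseudo_target(1)
  swapped <- tg
  swapped$atoms$class[1:2] <- rev(swapped$atoms$class[1:2])
  good <- contact_and_ddg_proxy(motif_model(motif), tg)$ddg_proxy
  bad <- contact_and_ddg_proxy(motif_model(motif), swapped)$ddg_proxy
  expect_lt(good, bad)
  expect_lt(good, 0)
})

test_that("contact energy is additive over disjoint interface patches", {
  motif <- make_idealized_motif()
  tg <- make_pseudo_target(1)
  full <- contact_and_ddg_proxy(motif_model(motif), tg)$ddg_proxy
  parts <- vapply(seq_len(nrow(tg$atoms)), function(i) {
    sub <- pseudo_target(tg$atoms[i, , drop = FALSE])
    contact_and_ddg_proxy(motif_model(motif), sub)$ddg_proxy
  }, numeric(1))
  expect_equal(full, sum(parts), tolerance = 1e-9)
})

test_that("score card invariants hold on a posed design", {
  motif <- make_idealized_motif()
  card <- contact_and_ddg_proxy(motif_model(motif), make_pseudo_target(0))
  expect_gte(card$interface_buried_area, 0)
  expect_lte(card$contact_surface, card$interface_buried_area + 1e-9)
})

test_that("ranking is deterministic, threshold-aware and dominance-consistent", {
  cards <- list(
    structure(list(design_id = "b", ddg_proxy = -2, sasa_total = 100,
                   interface_buried_area = 50, contact_surface = 30,
                   clash_count = 0L, pass = TRUE), class = "score_card"),
    structure(list(design_id = "a", ddg_proxy = -2, sasa_total = 100,
                   interface_buried_area = 50, contact_surface = 30,
                   clash_count = 0L, pass = TRUE), class = "score_card"),
    structure(list(design_id = "c", ddg_proxy = -5, sasa_total = 100,
                   interface_buried_area = 80, contact_surface = 60,
                   clash_count = 0L, pass = TRUE), class = "score_card"),
    structure(list(design_id = "d", ddg_proxy = -1, sasa_total = 100,
                   interface_buried_area = 10, contact_surface = 5,
                   clash_count = 2L, pass = FALSE), class = "score_card"))
  r <- rank_designs(cards)
  expect_equal(r$design_id, c("c", "a", "b"))  # best energy first, tie by id
  # permuted input gives the identical order
  r2 <- rank_designs(rev(cards))
  expect_equal(r2, r)
  # a dominated card never outranks its dominator
  expect_lt(which(r$design_id == "c"), which(r$design_id == "a"))
  # thresholds filter
  r3 <- rank_designs(cards, thresholds = list(max_ddg = -3))
  expect_equal(r3$design_id, "c")
  r4 <- rank_designs(cards, thresholds = list(max_ddg = -100))
  expect_equal(nrow(r4), 0)
})
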