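gates3 <- sortseq_gate_manifest(concentrations_nM = c(1, 10, 100))

toy_counts <- function() {
  counts <- matrix(c(100, 200, 700,
                     50, 250, 700,
                     10, 90, 900), nrow = 3, byrow = FALSE,
                   dimnames = list(c("v1", "v2", "v3"), gates3$gate_id))
  sortseq_counts(counts, reference = c(100, 200, 700), gates = gates3)
}

test_that("enrichment ratios match a hand-computed spreadsheet oracle", {
  data <- toy_counts()
  e0 <- enrichment_ratios(data, pseudocount = 0)
  # identical frequencies pre/post -> 0
  expect_equal(unname(e0[, 1]), c(0, 0, 0), tolerance = 1e-12)
  # hand calculation, alpha = 0: log2((c/T)/(c0/T0))
  T0 <- 1000
  expect_equal(e0["v1", 2], log2((50 / 1000) / (100 / T0)), tolerance = 1e-12)
  expect_equal(e0["v3", 3], log2((900 / 1000) / (700 / T0)), tolerance = 1e-12)
  # frequency doubling with alpha = 0 -> exactly +1
  dbl <- sortseq_counts(matrix(c(400, 600, 200, 800), 2,
                               dimnames = list(c("a", "b"), NULL)),
                        reference = c(200, 800),
                        gates = sortseq_gate_manifest(c(1, 10)))
  expect_equal(enrichment_ratios(dbl, 0)["a", 1], 1, tolerance = 1e-12)
  # pseudocounted frequencies sum to one per gate
  f <- gate_frequencies(data, pseudocount = 1)
  expect_equal(unname(colSums(f)), rep(1, 3), tolerance = 1e-12)
  # alpha = 0 with a variant absent from the reference is undefined
  bad <- sortseq_counts(matrix(c(1, 1, 1, 1), 2), reference = c(0, 2),
                        gates = sortseq_gate_manifest(c(1, 10)))
  expect_error(enrichment_ratios(bad, 0), "undefined")
})

test_that("KD estimation recovers truth from noiseless counts", {
  kds <- c(a = 10)
  more <- c(a = 10, b = 1, c = 100, d = 1000)
  ss <- simulate_sortseq_counts(more, sortseq_gate_manifest(
    concentrations_nM = 10^seq(-1, 3, length.out = 6)),
    depth = 1e5, expectation = TRUE)
  est <- estimate_kd_from_sorts(ss)
  est <- est[match(names(more), est$variant), ]
  expect_true(all(abs(est$kd_nM - more) / more < 0.10))
  expect_true(all(est$status == "converged"))
})

test_that("edge-case variants get range flags, twins get equal estimates", {
  gates <- sortseq_gate_manifest(concentrations_nM = c(1, 10, 100))
  counts <- matrix(c(500, 500, 500,
                     500, 500, 500,
                     0, 0, 0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("t1", "t2", "dead"), gates$gate_id))
  data <- sortseq_counts(counts, reference = c(400, 400, 400), gates = gates)
  est <- estimate_kd_from_sorts(data)
  expect_identical(est$kd_nM[est$variant == "t1"],
                   est$kd_nM[est$variant == "t2"])
  expect_equal(est$status[est$variant == "dead"], "above-range")
  single <- sortseq_counts(counts[, 1, drop = FALSE], c(400, 400, 400),
                           gates[1, , drop = FALSE])
  expect_error(estimate_kd_from_sorts(single), "identifiability")
})

test_that("KD estimation is monotone in the true KD on noiseless data", {
  kd_grid <- 10^seq(-0.5, 3.5, length.out = 8)
  names(kd_grid) <- paste0("g", seq_along(kd_grid))
  ss <- simulate_sortseq_counts(kd_grid, sortseq_gate_manifest(
    concentrations_nM = 10^seq(-1, 3, length.out = 5)),
    depth = 1e6, expectation = TRUE)
  est <- estimate_kd_from_sorts(ss)
  est <- est[match(names(kd_grid), est$variant), ]
  expect_true(all(diff(est$kd_nM) > 0))
  expect_equal(cor(est$kd_nM, kd_grid, method = "spearman"), 1)
})

test_that("KD recovery stays accurate under multinomial noise", {
  kds <- 10^seq(0, 3, length.out = 10)
  names(kds) <- paste0("v", seq_along(kds))
  ss <- simulate_sortseq_counts(kds, sortseq_gate_manifest(
    concentrations_nM = 10^seq(-1, 3, length.out = 5)),
    depth = 1e5, seed = 42)
  est <- estimate_kd_from_sorts(ss)
  est <- est[match(names(kds), est$variant), ]
  expect_lt(median(abs(est$kd_nM - kds) / kds), 0.25)
})

test_that("entropy hits the exact uniform and point-mass limits", {
  aa <- sort(unique(binderforge:::AA3TO1))
  flat <- matrix(0, 2, 20, dimnames = list(NULL, aa))
  ssm <- ssm_matrix(flat, parent = c("A", "G"))
  expect_equal(ssm_entropy_profile(ssm), rep(log2(20), 2), tolerance = 1e-12)

  point <- matrix(Inf, 1, 20, dimnames = list(NULL, aa))
  ssm2 <- ssm_matrix(point, parent = "A")  # parent cell forced to 0
  expect_equal(ssm_entropy_profile(ssm2), 0, tolerance = 1e-12)

  two <- matrix(Inf, 1, 20, dimnames = list(NULL, aa))
  two[1, "C"] <- 0
  ssm3 <- ssm_matrix(two, parent = "A")
  expect_equal(ssm_entropy_profile(ssm3), 1, tolerance = 1e-12)

  # entropy depends only on the multiset of tolerances, not on which
  # amino acid carries which value: permute the non-parent cells
  set.seed(8)
  d <- matrix(runif(20, 0, 3), 1, 20, dimnames = list(NULL, aa))
  base <- ssm_entropy_profile(ssm_matrix(d, "A"))
  d2 <- d
  nonparent <- setdiff(aa, "A")
  d2[1, nonparent] <- d[1, sample(nonparent)]
  base2 <- ssm_entropy_profile(ssm_matrix(d2, "A"))
  expect_equal(base, base2, tolerance = 1e-12)
  expect_true(all(base >= 0 & base <= log2(20)))
})

test_that("specificity labels follow the fold-change rule", {
  aff <- function(ids, kd, status = "converged")
    data.frame(variant = ids, kd_nM = kd, status = status)
  a <- aff(c("x", "y", "z"), c(1, 1, 1e6),
           c("converged", "converged", "above-range"))
  b <- aff(c("x", "y", "z"), c(1000, 2, 1e6),
           c("converged", "converged", "above-range"))
  lab <- classify_specificity(a, b)
  expect_equal(lab$label[lab$variant == "x"], "specific_a5b1")  # 1 nM vs 1 uM
  expect_equal(lab$label[lab$variant == "y"], "cross_reactive") # 1 vs 2 nM
  expect_equal(lab$label[lab$variant == "z"], "nonbinder")      # both out
  expect_error(classify_specificity(a, b[1:2, ]), "unmatched")
})

test_that("combination libraries enumerate the full Cartesian product", {
  parent <- "MKTAYIAKQR"
  subs5 <- data.frame(position = c(1, 3, 5, 7, 9), aa = c("A", "S", "F", "W", "L"))
  lib5 <- build_combination_library(subs5, parent)
  expect_length(lib5, 2^5)
  expect_true(parent %in% lib5)
  subs8 <- data.frame(position = 1:8, aa = c("A", "S", "F", "W", "L", "V", "C", "D"))
  expect_length(build_combination_library(subs8, parent), 2^8)
  # no substitutions -> just the parent
  expect_equal(build_combination_library(data.frame(position = integer(0),
                                                    aa = character(0)), parent),
               parent)
  # several options at one position multiply as (1 + options)
  multi <- data.frame(position = c(2, 2, 4), aa = c("A", "S", "G"))
  expect_length(build_combination_library(multi, parent), 3 * 2)
  # substitution equal to the parent residue is dropped with a warning
  expect_warning(same <- build_combination_library(
    data.frame(position = 1, aa = "M"), parent), "parent")
  expect_equal(same, parent)
})
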