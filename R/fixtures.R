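#' Seeded synthetic fixtures
#'
#' Every input the pipeline consumes can be regenerated from a seed: topology
#' occurrence statistics (standing in for a fold-survey of ferredoxin-like
#' domains), an idealized RGD hotspot-loop motif, a pseudo-target abstracting
#' the integrin binding groove (charged RGD anchor pair plus a hydrophobic
#' pocket), sort-seq count tables and binding-assay data.  Fixtures are
#' byte-reproducible per seed; nothing is downloaded.
#'
#' @name fixtures
NULL

#' Synthetic topology occurrence statistics
#'
#' Plausible counts for the ferredoxin-fold degrees of freedom: six ABEGO
#' string options per loop, five lengths per helix, six strand-pairing
#' combinations, fixed strand lengths of five residues.  L1 options are all
#' four residues long so the loop can host the four-residue RGDF interior of
#' the idealized motif.  Counts decay roughly geometrically with rank, with
#' seed-controlled jitter.
#'
#' @param seed integer seed
#' @return a [topology_stats()]
#' @export
make_topology_stats <- function(seed = 0) {
  loop_opts <- list(
    L1 = c("AGAB", "AGAA", "BGAB", "AGBB", "BAAB", "GBBA"),
    L2 = c("AG", "GA", "GB", "BA", "AB", "GG"),
    L3 = c("BGG", "BGE", "BGB", "GBA", "AAG", "GGA"),
    L4 = c("GEG", "EAG", "EBG", "EEE", "ABG", "GBA"),
    L5 = c("EA", "EG", "EB", "AG", "GB", "AE")
  )
  helix_opts <- list(H1 = c(12, 11, 13, 10, 14), H2 = c(13, 12, 11, 10, 14))
  sheet_opts <- c("2-1-3-4-anti", "1-2-3-4-anti", "2-1-4-3-anti",
                  "3-1-2-4-mix", "2-3-1-4-anti", "1-3-2-4-mix")
  with_seed(seed, {
    decay <- function(k) round(800 * exp(-(seq_len(k) - 1) / 1.4) *
                                 stats::runif(k, 0.8, 1.25)) + 5
    topology_stats(
      loop_abego_counts = lapply(loop_opts, function(o)
        stats::setNames(decay(length(o)), o)),
      helix_length_counts = lapply(helix_opts, function(o)
        stats::setNames(decay(length(o)), as.character(o))),
      sheet_combination_counts = stats::setNames(decay(length(sheet_opts)),
                                                 sheet_opts),
      strand_lengths = c(E1 = 5L, E2 = 5L, E3 = 5L, E4 = 5L)
    )
  })
}

# fixed torsions of the idealized six-residue H-R-G-D-F-P hotspot loop:
# strand-like anchors, an RGD turn drawn from common loop geometry
MOTIF_TORSIONS <- matrix(c(
  -120, 135, 180,   # H (anchor_pre, strand-like)
  -70, -25, 180,    # R
  85, 5, 180,       # G (left-handed turn)
  -95, 10, 180,     # D
  -125, 125, 180,   # F
  -60, -40, 180     # P (anchor_post, helix-start-like)
), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("phi", "psi", "omega")))

#' Idealized RGD hotspot-loop motif
#'
#' Six residues H-R-G-D-F-P built from fixed torsions: the first and last
#' residues are the anchors, R-G-D-F is the grafted interior.
#'
#' @return a [motif_definition()]
#' @export
make_idealized_motif <- function() {
  model <- build_chain_from_torsions(MOTIF_TORSIONS,
                                     sequence = c("H", "R", "G", "D", "F", "P"))
  motif_definition(model, source = list(kind = "fixture", name = "rgd_idealized"))
}

#' Pseudo-target rewarding RGD-like poses
#'
#' An abstract binding groove placed around the idealized motif: one
#' negatively charged anchor offset from the arginine, one positive
#' (cation-like) anchor offset from the aspartate (the two anchors sit 6-9
#' Angstrom apart), and a three-atom hydrophobic pocket near the
#' phenylalanine.  Small seed-controlled jitter keeps distinct seeds
#' distinguishable while preserving the geometry.
#'
#' @param seed integer seed
#' @return a [pseudo_target()]
#' @export
make_pseudo_target <- function(seed = 0) {
  motif <- make_idealized_motif()
  ca <- atom_coords(motif_model(motif), "CA")
  # directions point away from the anchor midpoint, i.e. away from the side
  # where the scaffold body attaches to the loop
  mid <- (ca[1, ] + ca[6, ]) / 2
  out_dir <- function(p) vunit(p - mid)
  r_ca <- ca[2, ]; d_ca <- ca[4, ]; f_ca <- ca[5, ]
  with_seed(seed, {
    jit <- function() stats::runif(3, -0.2, 0.2)
    neg <- r_ca + 4.0 * out_dir(r_ca) + jit()
    pos <- d_ca + 4.0 * out_dir(d_ca) + jit()
    # keep the charged anchor pair 6-9 A apart by pushing each further out
    # along its own direction (never toward the loop)
    iter <- 0L
    while (vnorm(neg - pos) < 6 && iter < 40L) {
      neg <- neg + 0.25 * out_dir(r_ca)
      pos <- pos + 0.25 * out_dir(d_ca)
      iter <- iter + 1L
    }
    while (vnorm(neg - pos) > 9 && iter < 80L &&
           vnorm(neg - r_ca) > 3.4 && vnorm(pos - d_ca) > 3.4) {
      neg <- neg - 0.2 * out_dir(r_ca)
      pos <- pos - 0.2 * out_dir(d_ca)
      iter <- iter + 1L
    }
    hyd <- t(vapply(1:3, function(i)
      f_ca + (3.5 + 0.5 * i) * out_dir(f_ca) +
        c(0.8 * (i - 2), 0.5 * (i - 2)^2 - 0.5, 0) + jit(), numeric(3)))
    atoms <- data.frame(
      x = c(neg[1], pos[1], hyd[, 1]),
      y = c(neg[2], pos[2], hyd[, 2]),
      z = c(neg[3], pos[3], hyd[, 3]),
      radius = c(1.52, 1.7, rep(1.9, 3)),
      class = c("negative", "positive", rep("hydrophobic", 3))
    )
    pseudo_target(atoms, annotations = list(
      "RGD-anchor pair" = c(1L, 2L), "hydrophobic pocket" = 3:5))
  })
}

#' Default sort-seq gate manifest
#'
#' @param concentrations_nM gate concentrations (default five log-spaced
#'   0.1-1000 nM)
#' @param target sorted target label
#' @param round sort round
#' @param fraction_collected sorted-cell fraction recorded per gate
#' @return gates data.frame for [sortseq_counts()]
#' @export
sortseq_gate_manifest <- function(concentrations_nM = 10^seq(-1, 3, length.out = 5),
                                  target = "a5b1", round = 1,
                                  fraction_collected = 0.3) {
  data.frame(gate_id = sprintf("%s_r%d_c%g", target, round, concentrations_nM),
             round = round, target = target,
             concentration_nM = concentrations_nM,
             fraction_collected = fraction_collected)
}

#' Simulate sort-seq counts from known affinities
#'
#' The reference pool is uniform; for the gate at concentration `c` a
#' variant's selection probability is proportional to its pool frequency
#' times the occupancy `c / (c + K_D)`.  Counts are multinomial draws of
#' `depth` reads per gate, or exact expectation counts (`expectation =
#' TRUE`) for noise-free recovery experiments.
#'
#' @param true_kds_nM named numeric vector of true dissociation constants
#' @param gates gate manifest, see [sortseq_gate_manifest()]
#' @param depth reads per gate (default 1e5)
#' @param seed integer seed
#' @param expectation return expected counts instead of sampled counts
#' @return a [sortseq_counts()]
#' @export
simulate_sortseq_counts <- function(true_kds_nM,
                                    gates = sortseq_gate_manifest(),
                                    depth = 1e5, seed = 0,
                                    expectation = FALSE) {
  stopifnot(depth > 0, nrow(gates) >= 2)
  v <- length(true_kds_nM)
  if (is.null(names(true_kds_nM))) names(true_kds_nM) <- paste0("v", seq_len(v))
  f0 <- rep(1 / v, v)
  probs <- vapply(gates$concentration_nM, function(c) {
    w <- f0 * c / (c + true_kds_nM)
    w / sum(w)
  }, numeric(v))
  ref <- rep(round(depth / v), v)
  counts <- if (expectation) {
    depth * probs
  } else {
    with_seed(seed, {
      vapply(seq_len(nrow(gates)), function(g)
        as.numeric(stats::rmultinom(1, depth, probs[, g])), numeric(v))
    })
  }
  rownames(counts) <- names(true_kds_nM)
  sortseq_counts(counts, ref, gates)
}

#' Simulate binding-assay tables
#'
#' Forward models of the three binding assays, returned as tidy data.frames
#' matching the fitting interfaces.
#'
#' * `bli`: 1:1 kinetic trace pairs over several analyte concentrations;
#'   columns `series_id`, `phase`, `time_s`, `response`, `conc_nM`.
#' * `dose`: saturation MFI curve; columns `series_id`, `conc_nM`, `response`.
#' * `competition`: one descending curve per competitor with shared
#'   plateaus; columns `series_id`, `conc_nM`, `response`.
#'
#' @param kind "bli", "dose" or "competition"
#' @param params named list overriding the defaults printed in the details
#' @param noise Gaussian noise SD in response units
#' @param seed integer seed for the noise
#' @return tidy data.frame for the matching `fit_*` function
#' @export
simulate_binding_data <- function(kind = c("bli", "dose", "competition"),
                                  params = list(), noise = 0, seed = 0) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("configuration error: unknown kind",
                                            call. = FALSE))
  if (kind == "bli") {
    p <- utils::modifyList(list(kon = 1e6, koff = 3.1e-4, rmax = 1,
                                concentrations_nM = c(0.25, 0.5, 1, 2, 4),
                                association_time = 1200,
                                dissociation_time = 1800, n_points = 60), params)
    rows <- lapply(seq_along(p$concentrations_nM), function(i) {
      tr <- simulate_1to1_trace(p$kon, p$koff, p$rmax, p$concentrations_nM[i],
                                p$association_time, p$dissociation_time,
                                p$n_points, noise_sd = noise, seed = seed + i,
                                series_id = paste0("s", i))
      do.call(rbind, lapply(tr, function(t)
        data.frame(series_id = t$series_id, phase = t$phase, time_s = t$time,
                   response = t$response, conc_nM = t$concentration_nM)))
    })
    do.call(rbind, rows)
  } else if (kind == "dose") {
    p <- utils::modifyList(list(kd_nM = 1.9, background = 100, maximum = 10000,
                                concentrations_nM = 10^seq(-2, 3,
                                                           length.out = 12)),
                           params)
    mfi <- p$background + (p$maximum - p$background) *
      p$concentrations_nM / (p$concentrations_nM + p$kd_nM)
    if (noise > 0) mfi <- mfi + with_seed(seed, stats::rnorm(length(mfi), 0, noise))
    data.frame(series_id = "dose", conc_nM = p$concentrations_nM, response = mfi)
  } else {
    p <- utils::modifyList(list(kds_nM = c(NN_C1 = 0.9, FN = 612,
                                           RGD_peptide = 150000),
                                c_l_nM = 5, kd_l_nM = 1.9,
                                maximum = 9000, minimum = 300,
                                concentrations_nM = 10^seq(-2, 6,
                                                           length.out = 14)),
                           params)
    ec50 <- p$kds_nM * (1 + p$c_l_nM / p$kd_l_nM)
    rows <- lapply(seq_along(ec50), function(i) {
      mfi <- p$minimum + (p$maximum - p$minimum) /
        (1 + p$concentrations_nM / ec50[i])
      if (noise > 0) {
        mfi <- mfi + with_seed(seed + i, stats::rnorm(length(mfi), 0, noise))
      }
      data.frame(series_id = names(ec50)[i], conc_nM = p$concentrations_nM,
                 response = mfi)
    })
    do.call(rbind, rows)
  }
}

#' Write a fixture set with its manifest
#'
#' Materializes the default fixtures under `out_dir` (topology statistics
#' CSV, motif PDB, pseudo-target JSON, sort-seq counts CSV + gate JSON) and
#' writes `manifest.json` recording the seed, the generator parameters and
#' an md5 checksum per file, so regeneration can be verified byte for byte.
#'
#' @param out_dir output directory (created if missing)
#' @param seed integer seed used for every stochastic fixture
#' @return invisibly, the manifest as a list
#' @export
write_fixture_set <- function(out_dir, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(stats = file.path(out_dir, "topology_stats.csv"),
             motif = file.path(out_dir, "rgd_motif.pdb"),
             target = file.path(out_dir, "pseudo_target.json"),
             counts = file.path(out_dir, "sortseq_counts.csv"),
             gates = file.path(out_dir, "sortseq_gates.json"))
  write_topology_stats(make_topology_stats(seed), paths[["stats"]])
  motif <- make_idealized_motif()
  write_pdb(motif_model(motif), paths[["motif"]])
  write_pseudo_target(make_pseudo_target(seed), paths[["target"]])
  kds <- 10^seq(0, 3, length.out = 10)
  names(kds) <- paste0("v", seq_along(kds))
  ss <- simulate_sortseq_counts(kds, depth = 1e5, seed = seed)
  write_sortseq_counts(ss, paths[["counts"]], paths[["gates"]])
  manifest <- list(name = "binderforge_default_fixtures", seed = seed,
                   parameters = list(sortseq_kds_nM = as.list(kds),
                                     sortseq_depth = 1e5),
                   files = as.list(paths),
                   checksums = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
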