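#' Staged assembly of ferredoxin backbones
#'
#' Backbones are grown in three stages rather than in one shot, mirroring
#' how the fold is nucleated around its binding loop: stage 1 builds
#' E1 + L1 + H1 (with L1 torsions taken from a supplied motif when one is
#' given), stage 2 extends by the beta-hairpin arm L2 + E2 + L3 + E3 and
#' requires E2 to pair with E1, and stage 3 completes the fold with
#' L4 + H2 + L5 + E4 before a global compactness / cavity filter.
#'
#' @name assemble
NULL

STAGE_ELEMENTS <- list(c("E1", "L1", "H1"),
                       c("L2", "E2", "L3", "E3"),
                       c("L4", "H2", "L5", "E4"))

# default placeholder letters by secondary structure
placeholder_letter <- c(E = "V", H = "A", L = "G")

#' Assembly filter configuration
#'
#' @param clash_min_distance clash threshold, Angstrom
#' @param pairing_max_distance max N...O distance counted as a strand
#'   pairing contact, Angstrom
#' @param pairing_min_pairs contacts required to accept E1/E2 pairing
#' @param rg_max compactness bound; `NULL` = [default_rg_max()] of the length
#' @param cavity_volume_max cavity bound, Angstrom^3
#' @param sd_scale multiplier on the torsion-sampling standard deviations
#'   (< 1 concentrates draws near the ideal secondary-structure torsions)
#' @return named list used by [assemble_stagewise()]
#' @export
assembly_filters <- function(clash_min_distance = 2.8,
                             pairing_max_distance = 3.5,
                             pairing_min_pairs = 2,
                             rg_max = NULL,
                             cavity_volume_max = 20,
                             sd_scale = 1) {
  list(clash_min_distance = clash_min_distance,
       pairing_max_distance = pairing_max_distance,
       pairing_min_pairs = pairing_min_pairs,
       rg_max = rg_max, cavity_volume_max = cavity_volume_max,
       sd_scale = sd_scale)
}

# count backbone N...O hydrogen-bond-like contacts between two strands
strand_pairing_contacts <- function(model, res_a, res_b, max_distance) {
  na <- atom_coords(model, "N", res_a); oa <- atom_coords(model, "O", res_a)
  nb <- atom_coords(model, "N", res_b); ob <- atom_coords(model, "O", res_b)
  cnt <- 0L
  pd <- function(x, y) {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
    sum(d2 < max_distance^2)
  }
  pd(na, ob) + pd(oa, nb)
}

# residue index range of each element for a blueprint
blueprint_ranges <- function(bp) {
  lens <- vapply(bp$segments, function(s) s$length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  ids <- vapply(bp$segments, function(s) s$element_id, character(1))
  stats::setNames(Map(function(s, e) s:e, starts, ends), ids)
}

#' Assemble backbones for a blueprint in three stages
#'
#' Each stage draws torsions for its segments, grows the chain and applies
#' the stage filters (clash everywhere; E1/E2 strand pairing at stage 2;
#' compactness and cavity on the full-length chain at stage 3).  A lineage
#' that fails all its attempts at a stage is dropped, so surviving counts
#' can only decrease stage over stage.  When a motif is supplied its
#' interior torsions are used verbatim for the L1 slot (and its anchor
#' torsions constrain the flanking E1/H1 residues), which reproduces the
#' motif backbone exactly inside the scaffold.
#'
#' @param bp a `blueprint` (see [as_blueprint()])
#' @param motif optional [motif_definition()]; interior length must equal the
#'   L1 loop length
#' @param n_tries_per_stage sampling attempts per stage (per lineage after
#'   stage 1)
#' @param rng_seed integer seed; identical seeds give identical output
#' @param filters see [assembly_filters()]
#' @param max_keep cap on lineages carried out of stage 1
#' @return list with `candidates` (list of `backbone_model`) and `reports`
#'   (three `stage_report` lists with `stage`, `elements`, `generated`,
#'   `passed` and per-filter failure tallies)
#' @export
assemble_stagewise <- function(bp, motif = NULL, n_tries_per_stage = 50,
                               rng_seed = 0, filters = assembly_filters(),
                               max_keep = 8) {
  stopifnot(inherits(bp, "blueprint"))
  segs <- stats::setNames(bp$segments,
                          vapply(bp$segments, function(s) s$element_id, character(1)))
  ranges <- blueprint_ranges(bp)
  if (!is.null(motif)) {
    interior <- motif_interior_length(motif)
    if (interior != segs$L1$length) {
      stop("motif interior length (", interior,
           ") must equal the L1 loop length (", segs$L1$length, ")", call. = FALSE)
    }
  }
  seq_letters <- unlist(lapply(bp$segments, function(s)
    rep(placeholder_letter[[s$ss_type]], s$length)))
  if (!is.null(motif)) {
    seq_letters[ranges$L1] <- motif$sequence[seq(2, length(motif$sequence) - 1L)]
  }

  with_seed(rng_seed, {
    sdk <- filters$sd_scale
    reports <- list()
    # ---- stage 1: E1 + L1 + H1 -------------------------------------------
    el1 <- STAGE_ELEMENTS[[1]]
    gen1 <- 0L; clash1 <- 0L
    lineages <- list()
    mt <- if (!is.null(motif)) measure_torsions(motif_model(motif))
    for (t in seq_len(n_tries_per_stage)) {
      if (length(lineages) >= max_keep) break
      gen1 <- gen1 + 1L
      tor <- do.call(rbind, lapply(el1, function(el) {
        if (el == "L1" && !is.null(motif)) {
          mt[seq(2, nrow(mt) - 1L), , drop = FALSE]
        } else sample_segment_torsions_raw(segs[[el]], sd_scale = sdk)
      }))
      if (!is.null(motif)) {
        i_pre <- segs$E1$length            # last E1 residue = anchor_pre
        i_post <- i_pre + segs$L1$length + 1L  # first H1 residue = anchor_post
        tor[i_pre, c("psi", "omega")] <- mt[1, c("psi", "omega")]
        tor[i_post, "phi"] <- mt[nrow(mt), "phi"]
      }
      m <- build_chain_from_torsions(tor)
      if (check_clashes(m, filters$clash_min_distance) == 0) {
        lineages[[length(lineages) + 1L]] <- tor
      } else clash1 <- clash1 + 1L
    }
    reports[[1]] <- stage_report(1, el1, gen1, length(lineages),
                                 list(clash = clash1))

    # ---- stage 2: + L2 + E2 + L3 + E3, E1/E2 pairing ---------------------
    el2 <- STAGE_ELEMENTS[[2]]
    gen2 <- 0L; clash2 <- 0L; pair2 <- 0L
    lineages2 <- list()
    for (tor0 in lineages) {
      for (t in seq_len(n_tries_per_stage)) {
        gen2 <- gen2 + 1L
        ext <- do.call(rbind, lapply(el2, function(el)
          sample_segment_torsions_raw(segs[[el]], sd_scale = sdk)))
        tor <- rbind(tor0, ext)
        m <- build_chain_from_torsions(tor)
        if (check_clashes(m, filters$clash_min_distance) > 0) {
          clash2 <- clash2 + 1L; next
        }
        npair <- strand_pairing_contacts(m, ranges$E1, ranges$E2,
                                         filters$pairing_max_distance)
        if (npair < filters$pairing_min_pairs) { pair2 <- pair2 + 1L; next }
        lineages2[[length(lineages2) + 1L]] <- tor
        break
      }
    }
    reports[[2]] <- stage_report(2, el2, gen2, length(lineages2),
                                 list(clash = clash2, pairing = pair2))

    # ---- stage 3: + L4 + H2 + L5 + E4, global filters --------------------
    el3 <- STAGE_ELEMENTS[[3]]
    gen3 <- 0L; clash3 <- 0L; comp3 <- 0L; cav3 <- 0L
    out <- list()
    for (tor0 in lineages2) {
      for (t in seq_len(n_tries_per_stage)) {
        gen3 <- gen3 + 1L
        ext <- do.call(rbind, lapply(el3, function(el)
          sample_segment_torsions_raw(segs[[el]], sd_scale = sdk)))
        tor <- rbind(tor0, ext)
        m <- build_chain_from_torsions(tor, sequence = seq_letters)
        if (check_clashes(m, filters$clash_min_distance) > 0) {
          clash3 <- clash3 + 1L; next
        }
        # compactness is cheap, the voxel scan is not: check Rg first
        rgmax <- if (is.null(filters$rg_max)) default_rg_max(n_residues(m))
                 else filters$rg_max
        rg <- radius_of_gyration(m)
        if (rg >= rgmax) { comp3 <- comp3 + 1L; next }
        cav <- cavity_volume(m)
        if (cav >= filters$cavity_volume_max) { cav3 <- cav3 + 1L; next }
        m$provenance <- list(blueprint = bp$segment_string, seed = rng_seed,
                             lineage = length(out) + 1L,
                             radius_of_gyration = rg,
                             cavity_volume = cav)
        attr(m, "torsions") <- tor
        attr(m, "ranges") <- ranges
        out[[length(out) + 1L]] <- m
        break
      }
    }
    reports[[3]] <- stage_report(3, el3, gen3, length(out),
                                 list(clash = clash3, compactness = comp3,
                                      cavity = cav3))
    list(candidates = out, reports = reports)
  })
}

stage_report <- function(stage, elements, generated, passed, tallies) {
  stopifnot(passed <= generated)
  structure(list(stage = as.integer(stage), elements = elements,
                 generated = generated,
                 passed = passed, filter_tallies = tallies),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("stage %d [%s]: generated %d, passed %d (%s)\n", x$stage,
              paste(x$elements, collapse = "+"), x$generated, x$passed,
              paste(names(x$filter_tallies), unlist(x$filter_tallies),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
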