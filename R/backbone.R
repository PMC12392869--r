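#' Backbone models and torsion-space chain growth
#'
#' A `backbone_model` holds the four backbone heavy atoms (N, CA, C, O) of
#' every residue of a single chain.  Chains are grown in internal
#' coordinates (NeRF-style sequential placement) from per-residue torsion
#' triples under ideal covalent geometry, and measured back to torsions for
#' round-trip validation and ABEGO classification.
#'
#' @name backbone
NULL

#' Ideal backbone covalent geometry
#'
#' Bond lengths (Angstrom) and angles (degrees) used by the chain builder:
#' N-CA 1.458, CA-C 1.525, C-N 1.329; N-CA-C 111.2, CA-C-N 116.2,
#' C-N-CA 121.7; carbonyl C-O 1.231 at CA-C-O 120.8, O placed trans to the
#' next amide nitrogen (terminal O along the same rule using torsion 180 to
#' the own N).
#'
#' @return named list of geometry parameters
#' @export
geometry_params <- function() {
  list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
       a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8)
}

#' Construct a backbone model from atom coordinates
#'
#' @param xyz numeric matrix `(4n) x 3`, atoms ordered N, CA, C, O within each
#'   residue
#' @param sequence per-residue one-letter amino-acid codes (default all "G")
#' @param provenance free-form list recording how the model was built
#' @return object of class `backbone_model`
#' @export
backbone_model <- function(xyz, sequence = NULL, provenance = list()) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) %% 4 == 0, nrow(xyz) >= 4)
  n <- nrow(xyz) / 4
  if (is.null(sequence)) sequence <- rep("G", n)
  stopifnot(length(sequence) == n)
  structure(list(xyz = unname(xyz),
                 atom = rep(c("N", "CA", "C", "O"), n),
                 resno = rep(seq_len(n), each = 4),
                 sequence = sequence,
                 provenance = provenance),
            class = "backbone_model")
}

#' Number of residues in a backbone model
#' @param model a `backbone_model`
#' @return integer
#' @export
n_residues <- function(model) length(model$sequence)

#' Extract coordinates of one atom type per residue
#' @param model a `backbone_model`
#' @param atom one of "N", "CA", "C", "O"
#' @param resno optional residue subset
#' @return `n x 3` matrix
#' @export
atom_coords <- function(model, atom = "CA", resno = NULL) {
  keep <- model$atom == atom
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  model$xyz[keep, , drop = FALSE]
}

#' @export
print.backbone_model <- function(x, ...) {
  cat("backbone_model:", n_residues(x), "residues,", nrow(x$xyz), "atoms\n")
  invisible(x)
}

# normalize torsion input to an n x 3 numeric matrix (phi, psi, omega)
as_torsion_matrix <- function(torsions) {
  if (is.matrix(torsions)) {
    stopifnot(ncol(torsions) == 3)
    m <- torsions
  } else if (is.data.frame(torsions)) {
    m <- as.matrix(torsions[, c("phi", "psi", "omega")])
  } else if (is.list(torsions)) {
    m <- do.call(rbind, lapply(torsions, function(t) t[c("phi", "psi", "omega")]))
  } else stop("invalid input: unrecognized torsion container", call. = FALSE)
  colnames(m) <- c("phi", "psi", "omega")
  m
}

#' Build a backbone chain from torsions
#'
#' Sequential internal-coordinate construction: residue `i+1` is placed from
#' residue `i` using `psi_i`, `omega_i` and `phi_{i+1}` under the ideal
#' geometry of [geometry_params()].  `phi_1`, `psi_n` and `omega_n` are not
#' consumed.  [measure_torsions()] on the result reproduces the interior
#' inputs to well below 1e-6 degrees.
#'
#' @param torsions `n x 3` matrix (columns phi, psi, omega, degrees), a
#'   data.frame with those columns, or a list of [torsion_triple]s
#' @param geometry geometry parameters, see [geometry_params()]
#' @param sequence optional per-residue letters passed to [backbone_model()]
#' @return a `backbone_model` of `n` residues
#' @examples
#' helix <- build_chain_from_torsions(
#'   matrix(rep(c(-57, -47, 180), 8), ncol = 3, byrow = TRUE))
#' @export
build_chain_from_torsions <- function(torsions, geometry = geometry_params(),
                                      sequence = NULL) {
  tm <- as_torsion_matrix(torsions)
  n <- nrow(tm)
  if (n < 1) stop("invalid input: need at least one residue", call. = FALSE)
  if (!all(is.finite(tm))) stop("invalid input: non-finite torsion", call. = FALSE)
  g <- geometry
  Nc <- matrix(0, n, 3); CAc <- matrix(0, n, 3); Cc <- matrix(0, n, 3)
  Nc[1, ] <- c(0, 0, 0)
  CAc[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * DEG
  Cc[1, ] <- CAc[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1L)) {
    Nc[i + 1, ] <- place_atom(Nc[i, ], CAc[i, ], Cc[i, ],
                              g$b_c_n, g$a_ca_c_n, tm[i, "psi"])
    CAc[i + 1, ] <- place_atom(CAc[i, ], Cc[i, ], Nc[i + 1, ],
                               g$b_n_ca, g$a_c_n_ca, tm[i, "omega"])
    Cc[i + 1, ] <- place_atom(Cc[i, ], Nc[i + 1, ], CAc[i + 1, ],
                              g$b_ca_c, g$a_n_ca_c, tm[i + 1, "phi"])
  }
  Oc <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ref <- if (i < n) Nc[i + 1, ] else Nc[i, ]
    Oc[i, ] <- place_atom(ref, CAc[i, ], Cc[i, ], g$b_c_o, g$a_ca_c_o, 180)
  }
  xyz <- matrix(0, 4 * n, 3)
  xyz[seq(1, 4 * n, 4), ] <- Nc
  xyz[seq(2, 4 * n, 4), ] <- CAc
  xyz[seq(3, 4 * n, 4), ] <- Cc
  xyz[seq(4, 4 * n, 4), ] <- Oc
  backbone_model(xyz, sequence = sequence,
                 provenance = list(builder = "torsion_chain"))
}

#' Measure backbone torsions of a model
#'
#' Standard definitions: `phi_i = C(i-1)-N(i)-CA(i)-C(i)`,
#' `psi_i = N(i)-CA(i)-C(i)-N(i+1)`, `omega_i = CA(i)-C(i)-N(i+1)-CA(i+1)`.
#' Undefined terminal angles (`phi_1`, `psi_n`, `omega_n`) are reported as
#' `NA`.
#'
#' @param model a `backbone_model` with >= 2 residues
#' @return `n x 3` matrix (phi, psi, omega) in degrees
#' @export
measure_torsions <- function(model) {
  n <- n_residues(model)
  if (n < 2) stop("invalid input: need >= 2 residues", call. = FALSE)
  Nc <- atom_coords(model, "N"); CAc <- atom_coords(model, "CA")
  Cc <- atom_coords(model, "C")
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    if (i > 1) out[i, "phi"] <- dihedral_angle(Cc[i - 1, ], Nc[i, ], CAc[i, ], Cc[i, ])
    if (i < n) {
      out[i, "psi"] <- dihedral_angle(Nc[i, ], CAc[i, ], Cc[i, ], Nc[i + 1, ])
      out[i, "omega"] <- dihedral_angle(CAc[i, ], Cc[i, ], Nc[i + 1, ], CAc[i + 1, ])
    }
  }
  out
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# per-ABEGO-class torsion sampling parameters (mean phi, mean psi, sd)
ABEGO_SAMPLER <- list(
  A = c(-63, -42, 8), B = c(-120, 130, 15),
  G = c(60, 35, 10), E = c(120, -130, 15)
)

# one rejection-sampled (phi, psi) draw guaranteed to classify as `letter`
draw_torsion_for_class <- function(letter, allow_cis = FALSE, sd_scale = 1) {
  if (letter == "O") {
    if (!allow_cis) {
      stop("configuration error: ABEGO letter O requires cis support (allow_cis)",
           call. = FALSE)
    }
    repeat {
      phi <- stats::rnorm(1, -75, 15); psi <- stats::rnorm(1, 160, 15)
      omega <- stats::rnorm(1, 0, 5)
      if (classify_abego(phi, psi, omega) == "O") return(c(phi, psi, omega))
    }
  }
  p <- ABEGO_SAMPLER[[letter]]
  repeat {
    phi <- stats::rnorm(1, p[1], p[3] * sd_scale)
    psi <- stats::rnorm(1, p[2], p[3] * sd_scale)
    if (classify_abego(phi, psi, 180) == letter) return(c(phi, psi, 180))
  }
}

# segment sampler drawing from the current RNG stream (no seed handling)
sample_segment_torsions_raw <- function(seg, allow_cis = FALSE, sd_scale = 1) {
  draw_h <- function() {
    repeat {
      phi <- stats::rnorm(1, -57, 8 * sd_scale)
      psi <- stats::rnorm(1, -47, 8 * sd_scale)
      if (classify_abego(phi, psi) == "A") return(c(phi, psi, 180))
    }
  }
  rows <- switch(seg$ss_type,
    H = t(vapply(seq_len(seg$length), function(i) draw_h(), numeric(3))),
    E = t(vapply(seq_len(seg$length),
                 function(i) draw_torsion_for_class("B", sd_scale = sd_scale),
                 numeric(3))),
    L = t(vapply(strsplit(seg$abego, "")[[1]],
                 function(a) draw_torsion_for_class(a, allow_cis, sd_scale),
                 numeric(3)))
  )
  rows <- matrix(rows, ncol = 3)
  colnames(rows) <- c("phi", "psi", "omega")
  rows
}

#' Sample torsions for one blueprint segment
#'
#' Helices draw near ideal alpha torsions (-57, -47), strands near ideal
#' beta torsions (-120, 130); loop residues draw from a per-class Gaussian
#' matched to each ABEGO letter, with rejection so that every draw
#' re-classifies to the requested letter.  Deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param seg a [segment_spec]
#' @param rng_seed integer seed
#' @param allow_cis permit ABEGO letter "O" (cis omega) in loops
#' @return `length x 3` torsion matrix
#' @export
sample_torsions_for_segment <- function(seg, rng_seed = 0, allow_cis = FALSE) {
  stopifnot(inherits(seg, "segment_spec"))
  with_seed(rng_seed, sample_segment_torsions_raw(seg, allow_cis))
}

#' Count steric clashes among non-bonded backbone atoms
#'
#' Atom pairs separated by at least two residues in sequence and closer than
#' `min_distance` count as clashes; bonded and next-neighbour (1-3) contacts
#' are excluded by the residue-separation rule.
#'
#' @param model a `backbone_model`
#' @param min_distance clash threshold in Angstrom (default 2.8)
#' @return integer clash count
#' @export
check_clashes <- function(model, min_distance = 2.8) {
  stopifnot(inherits(model, "backbone_model"))
  d <- as.matrix(stats::dist(model$xyz))
  sep <- abs(outer(model$resno, model$resno, "-"))
  sum(d < min_distance & sep >= 2 & upper.tri(d))
}

#' Radius of gyration over CA atoms
#' @param model a `backbone_model`
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(model) {
  ca <- atom_coords(model, "CA")
  ctr <- colMeans(ca)
  sqrt(mean(rowSums(sweep(ca, 2, ctr)^2)))
}

# rotate coordinates into a canonical principal-axes frame so that the
# voxel-grid cavity scan is invariant under rigid motion of the input
canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  if (nrow(x) < 3) return(x)
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  r <- ev$vectors
  if (det(r) < 0) r[, 3] <- -r[, 3]
  y <- x %*% r
  # fix axis signs by third moments (break near-zero ties robustly)
  s <- sign(colSums(y^3) + 1e-9)
  y <- sweep(y, 2, s, "*")
  if (prod(s) < 0) y[, 3] <- -y[, 3]  # keep a proper rotation overall
  y
}

#' Cavity volume by voxel-grid scan
#'
#' Coordinates are first rotated to a canonical principal-axes frame (making
#' the result invariant under rigid motion), then a cubic grid at `grid`
#' Angstrom spacing is scanned.  A voxel is occupied when its centre lies
#' within `atom_radius + probe` of any atom; an empty voxel counts as cavity
#' when occupied voxels block it along at least 5 of the 6 axis directions.
#'
#' @param xyz atom coordinate matrix (or a `backbone_model`)
#' @param grid voxel spacing, Angstrom (default 1.0)
#' @param probe probe radius, Angstrom (default 1.4)
#' @param atom_radius uniform heavy-atom radius, Angstrom (default 1.7)
#' @return cavity volume in Angstrom^3
#' @export
cavity_volume <- function(xyz, grid = 1.0, probe = 1.4, atom_radius = 1.7) {
  if (inherits(xyz, "backbone_model")) xyz <- xyz$xyz
  xyz <- canonical_frame(xyz)
  pad <- atom_radius + probe + grid
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = grid))
  dims <- vapply(ax, length, integer(1))
  centers <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  thr2 <- (atom_radius + probe)^2
  occ_flat <- rep(FALSE, nrow(centers))
  chunk <- 20000L
  for (s in seq(1, nrow(centers), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(centers))
    cc <- centers[s:e, , drop = FALSE]
    d2 <- outer(rowSums(cc^2), rowSums(xyz^2), "+") - 2 * cc %*% t(xyz)
    occ_flat[s:e] <- rowSums(d2 <= thr2) > 0
  }
  # expand.grid varies the first factor fastest -> dim order matches dims
  occ <- array(occ_flat, dim = dims)
  dirany <- function(a, margin, forward) {
    # out[i] = any occupied strictly beyond i along `margin` in given direction
    out <- array(FALSE, dim = dim(a))
    n <- dim(a)[margin]
    idx <- function(k) switch(margin,
      list(k, TRUE, TRUE), list(TRUE, k, TRUE), list(TRUE, TRUE, k))
    seqk <- if (forward) (n - 1):1 else 2:n
    prev <- if (forward) function(k) k + 1 else function(k) k - 1
    for (k in seqk) {
      i <- idx(k); j <- idx(prev(k))
      out[i[[1]], i[[2]], i[[3]]] <-
        out[j[[1]], j[[2]], j[[3]]] | a[j[[1]], j[[2]], j[[3]]]
    }
    out
  }
  enclosed <- (dirany(occ, 1, TRUE) + dirany(occ, 1, FALSE) +
               dirany(occ, 2, TRUE) + dirany(occ, 2, FALSE) +
               dirany(occ, 3, TRUE) + dirany(occ, 3, FALSE))
  sum(!occ & enclosed >= 5) * grid^3
}

#' Default compactness threshold
#'
#' Upper bound on the CA radius of gyration for an `n`-residue chain:
#' 1.3 x 2.2 n^0.38 Angstrom, i.e. 30% above the empirical scaling of
#' compact folded domains, so only clearly non-compact chains fail.
#'
#' @param n residue count
#' @return Rg bound in Angstrom
#' @export
default_rg_max <- function(n) 1.3 * 2.2 * n^0.38

#' Compactness and cavity filter
#'
#' Full-length models pass when the CA radius of gyration is below `rg_max`
#' and the voxel-scan cavity volume is below `cavity_volume_max`.
#'
#' @param model a `backbone_model`
#' @param rg_max Rg bound, Angstrom; default [default_rg_max()] of the length
#' @param cavity_volume_max cavity bound, Angstrom^3 (default 20)
#' @param grid,probe voxel-scan parameters, see [cavity_volume()]
#' @return list with `pass`, `radius_of_gyration`, `cavity_volume`
#' @export
compactness_and_cavity_filter <- function(model, rg_max = NULL,
                                          cavity_volume_max = 20,
                                          grid = 1.0, probe = 1.4) {
  if (is.null(rg_max)) rg_max <- default_rg_max(n_residues(model))
  rg <- radius_of_gyration(model)
  cav <- cavity_volume(model, grid = grid, probe = probe)
  list(pass = rg < rg_max && cav < cavity_volume_max,
       radius_of_gyration = rg, cavity_volume = cav)
}
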