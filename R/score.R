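#' Geometric interface scoring
#'
#' Desk-scale proxies for the metrics used to rank binder designs against a
#' target: Shrake-Rupley solvent-accessible surface area (SASA), buried
#' interface area, a class-weighted contact energy standing in for an
#' interface binding-energy score, and a tight-contact surface standing in
#' for the molecular contact surface.
#'
#' @name interface-scoring
NULL

#' SASA atomic radii
#'
#' Default heavy-atom radii (Angstrom): N 1.55, C 1.70, O 1.52, S 1.80;
#' anything else 1.70.
#'
#' @param elements character vector of element symbols
#' @return numeric radii
#' @export
sasa_radii <- function(elements) {
  r <- c(N = 1.55, C = 1.70, O = 1.52, S = 1.80)
  out <- r[toupper(substr(elements, 1, 1))]
  out[is.na(out)] <- 1.70
  unname(out)
}

# deterministic quasi-uniform unit-sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere is inflated by the probe radius and sampled with a
#' deterministic quasi-uniform point set; a point is accessible when it lies
#' outside every other inflated sphere.
#'
#' @param xyz `n x 3` atom coordinates, Angstrom
#' @param radii per-atom radii, Angstrom (recycled)
#' @param probe probe radius, Angstrom (default 1.4)
#' @param n_points sample points per atom (>= 92; default 960)
#' @return numeric vector of per-atom accessible areas, Angstrom^2
#' @details Coordinates are rotated to a canonical principal-axes frame
#'   before sampling, so the sampled areas are exactly invariant under rigid
#'   motion of the input.
#' @examples
#' sasa(matrix(0, 1, 3), 1.7)  # isolated sphere, ~ 4*pi*3.1^2
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (nrow(xyz) >= 3) xyz <- canonical_frame(xyz)
  n <- nrow(xyz)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("invalid input: radii must be positive", call. = FALSE)
  if (n_points < 92) stop("invalid input: n_points must be >= 92", call. = FALSE)
  sp <- sphere_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  # neighbour lists keep the point-in-sphere test local
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- sweep(sp * rr[i], 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj <- sweep(pts, 2, xyz[j, ])
        buried <- buried | rowSums(dj^2) < rr[j]^2
      }
      acc <- sum(!buried)
    }
    out[i] <- 4 * pi * rr[i]^2 * acc / n_points
  }
  out
}

#' Interface buried area
#'
#' Per-atom SASA lost on complex formation, summed over both parts:
#' `sum(sasa(A)) + sum(sasa(B)) - sum(sasa(A u B))`, clamped at zero.
#'
#' @param xyz_a,xyz_b coordinate matrices of the two parts
#' @param radii_a,radii_b per-atom radii
#' @param probe probe radius, Angstrom
#' @param n_points sample points per atom
#' @return buried area in Angstrom^2
#' @export
interface_buried_area <- function(xyz_a, xyz_b, radii_a, radii_b,
                                  probe = 1.4, n_points = 960) {
  a <- sum(sasa(xyz_a, radii_a, probe, n_points))
  b <- sum(sasa(xyz_b, radii_b, probe, n_points))
  ab <- sum(sasa(rbind(xyz_a, xyz_b), c(rep_len(radii_a, nrow(xyz_a)),
                                        rep_len(radii_b, nrow(xyz_b))),
                 probe, n_points))
  max(0, a + b - ab)
}

#' Construct a pseudo-target
#'
#' A minimal stand-in for a receptor binding site: point atoms with a
#' radius and a chemical class, plus free-form pocket annotations.
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `radius` (1.0-2.5 A)
#'   and `class` (one of hydrophobic, donor, acceptor, positive, negative)
#' @param annotations named list of pocket annotations
#' @return object of class `pseudo_target`
#' @export
pseudo_target <- function(atoms, annotations = list()) {
  need <- c("x", "y", "z", "radius", "class")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)), nrow(atoms) >= 1)
  if (any(atoms$radius < 1.0 | atoms$radius > 2.5)) {
    stop("invalid input: pseudo-target radii must lie in [1.0, 2.5] A",
         call. = FALSE)
  }
  cls <- c("hydrophobic", "donor", "acceptor", "positive", "negative")
  stopifnot(all(atoms$class %in% cls))
  structure(list(atoms = atoms, annotations = annotations),
            class = "pseudo_target")
}

#' Chemical class of a residue letter
#'
#' Coarse per-residue classes used for backbone-only designs: K/R positive,
#' D/E negative, S/T/N/Q/H/Y donor, everything else hydrophobic.
#'
#' @param letters one-letter amino-acid codes
#' @return character vector of classes
#' @export
residue_class <- function(letters) {
  out <- rep("hydrophobic", length(letters))
  out[letters %in% c("K", "R")] <- "positive"
  out[letters %in% c("D", "E")] <- "negative"
  out[letters %in% c("S", "T", "N", "Q", "H", "Y")] <- "donor"
  out
}

# pairwise class-compatibility weights for the contact energy
class_pair_weight <- function(a, b) {
  w <- 0
  if (a == "hydrophobic" && b == "hydrophobic") w <- -1
  else if ((a == "donor" && b == "acceptor") || (a == "acceptor" && b == "donor")) w <- -1.5
  else if (a %in% c("positive", "negative") && b %in% c("positive", "negative")) {
    w <- if (a == b) 2 else -2
  }
  w
}

# distance kernel: 1 up to 3.5 A, linear to 0 at 5 A
contact_kernel <- function(d) pmax(0, pmin(1, (5 - d) / 1.5))

# per-residue pseudo-atoms (CA position, class from the sequence letter)
design_pseudo_atoms <- function(design, radius = 1.7) {
  ca <- atom_coords(design, "CA")
  data.frame(x = ca[, 1], y = ca[, 2], z = ca[, 3], radius = radius,
             class = residue_class(design$sequence))
}

#' Score a design pose against a target
#'
#' Computes the interface metrics used for ranking: a class-weighted contact
#' energy (`ddg_proxy`; negative is favourable), total SASA of the complex,
#' buried interface area, the tight-contact surface (buried area restricted
#' to atoms in contacts with surface gap <= 1.5 A) and the cross-interface
#' clash count.
#'
#' @param design a `backbone_model` posed in the target frame
#' @param target a [pseudo_target()] (or a parsed structure with an `atoms`
#'   data.frame carrying `x y z` plus either `class`/`radius` or `elety`)
#' @param design_id identifier recorded on the card
#' @param probe,n_points SASA parameters
#' @param clash_distance cross-interface clash threshold, Angstrom
#' @return object of class `score_card`
#' @export
contact_and_ddg_proxy <- function(design, target, design_id = "design",
                                  probe = 1.4, n_points = 960,
                                  clash_distance = 2.8) {
  stopifnot(inherits(design, "backbone_model"))
  ta <- if (inherits(target, "pseudo_target")) target$atoms else target$atoms
  if (is.null(ta$class)) ta$class <- "hydrophobic"
  if (is.null(ta$radius)) ta$radius <- sasa_radii(ta$elety %||% "C")
  da <- design_pseudo_atoms(design)
  dxyz <- as.matrix(da[, c("x", "y", "z")])
  txyz <- as.matrix(ta[, c("x", "y", "z")])
  d <- sqrt(pmax(0, outer(rowSums(dxyz^2), rowSums(txyz^2), "+") -
                    2 * dxyz %*% t(txyz)))
  wmat <- outer(da$class, ta$class, Vectorize(class_pair_weight))
  ddg <- sum(wmat * contact_kernel(d) * (d <= 5))
  clash_count <- sum(d < clash_distance)

  # SASA over backbone atoms of the design + target spheres
  bxyz <- design$xyz
  bradii <- sasa_radii(design$atom)
  tradii <- ta$radius
  sasa_a <- sasa(bxyz, bradii, probe, n_points)
  sasa_b <- sasa(txyz, tradii, probe, n_points)
  sasa_ab <- sasa(rbind(bxyz, txyz), c(bradii, tradii), probe, n_points)
  na <- nrow(bxyz)
  buried_per_atom <- pmax(0, c(sasa_a, sasa_b) - sasa_ab)
  buried <- sum(buried_per_atom)
  # tight contacts: surface gap <= 1.5 A between backbone and target atoms
  db <- sqrt(pmax(0, outer(rowSums(bxyz^2), rowSums(txyz^2), "+") -
                     2 * bxyz %*% t(txyz)))
  gap <- db - outer(bradii, tradii, "+")
  tight_a <- apply(gap <= 1.5, 1, any)
  tight_b <- apply(gap <= 1.5, 2, any)
  contact_surface <- sum(buried_per_atom[c(tight_a, tight_b)])
  structure(list(design_id = design_id, ddg_proxy = ddg,
                 sasa_total = sum(sasa_ab),
                 interface_buried_area = buried,
                 contact_surface = contact_surface,
                 clash_count = clash_count,
                 pass = clash_count == 0L),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf(paste0("score_card %s: ddg %.2f, SASA %.1f A^2, buried %.1f A^2, ",
                     "contact %.1f A^2, clashes %d, %s\n"),
              x$design_id, x$ddg_proxy, x$sasa_total, x$interface_buried_area,
              x$contact_surface, x$clash_count,
              if (x$pass) "pass" else "fail"))
  invisible(x)
}

#' Collect score cards into a data.frame
#' @param cards list of `score_card`s
#' @return data.frame, one row per card
#' @export
score_cards_df <- function(cards) {
  do.call(rbind, lapply(cards, function(c)
    data.frame(design_id = c$design_id, ddg_proxy = c$ddg_proxy,
               sasa_total = c$sasa_total,
               interface_buried_area = c$interface_buried_area,
               contact_surface = c$contact_surface,
               clash_count = c$clash_count, pass = c$pass)))
}

#' Rank scored designs
#'
#' Filters by the configured thresholds (defaults accept everything that is
#' clash free) and sorts by contact energy ascending, breaking ties by
#' contact surface descending and then design id.  Deterministic under input
#' permutation.
#'
#' @param cards list of `score_card`s or the data.frame from
#'   [score_cards_df()]
#' @param thresholds list with any of `max_ddg`, `min_buried`, `min_contact`,
#'   `require_pass`
#' @return data.frame of accepted designs in rank order
#' @export
rank_designs <- function(cards, thresholds = list()) {
  df <- if (is.data.frame(cards)) cards else score_cards_df(cards)
  if (nrow(df) == 0) stop("invalid input: no score cards", call. = FALSE)
  th <- utils::modifyList(list(max_ddg = Inf, min_buried = 0, min_contact = 0,
                               require_pass = TRUE), thresholds)
  keep <- df$ddg_proxy <= th$max_ddg &
    df$interface_buried_area >= th$min_buried &
    df$contact_surface >= th$min_contact &
    (!th$require_pass | df$pass)
  out <- df[keep, , drop = FALSE]
  ord <- order(out$ddg_proxy, -out$contact_surface, out$design_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
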