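#' Backbone torsion triples and ABEGO classification
#'
#' The ABEGO alphabet partitions backbone torsion space into five regions:
#' `A` (alpha/helical), `B` (beta/extended), `G` and `E` (their left-handed
#' mirrors, positive phi), and `O` (cis omega).  Loop conformations are
#' summarized as strings over this alphabet; the blueprint machinery counts
#' and enumerates such strings.
#'
#' @name abego
NULL

ABEGO_LABELS <- c("A", "B", "E", "G", "O")

#' Construct a torsion triple
#'
#' @param phi,psi backbone dihedrals in degrees; normalized to `[-180, 180)`
#' @param omega peptide-bond dihedral in degrees, default 180 (trans)
#' @return an object of class `torsion_triple` (named numeric vector)
#' @examples
#' torsion_triple(-57, -47)
#' @export
torsion_triple <- function(phi, psi, omega = 180) {
  if (!all(is.finite(c(phi, psi, omega)))) {
    stop("invalid input: torsion angles must be finite", call. = FALSE)
  }
  structure(c(phi = wrap180(phi), psi = wrap180(psi), omega = wrap180(omega)),
            class = "torsion_triple")
}

#' Classify backbone torsions into the ABEGO alphabet
#'
#' Community-standard binning: `O` when |omega| < 90 (cis); otherwise
#' `A` when phi < 0 and -75 <= psi < 50; `B` for the remaining phi < 0;
#' `G` when phi >= 0 and -100 < psi <= 100; `E` for the remaining phi >= 0.
#' The function is total: every finite (phi, psi, omega) maps to exactly one
#' label.
#'
#' @param phi,psi,omega torsions in degrees (vectorized); alternatively pass a
#'   `torsion_triple` as `phi`
#' @return character vector of labels in `A B E G O`
#' @examples
#' classify_abego(-57, -47)   # "A"
#' classify_abego(-120, 130)  # "B"
#' classify_abego(-57, -47, 10)  # "O"
#' @export
classify_abego <- function(phi, psi = NULL, omega = 180) {
  if (inherits(phi, "torsion_triple")) {
    psi <- phi[["psi"]]; omega <- phi[["omega"]]; phi <- phi[["phi"]]
  }
  if (!all(is.finite(c(phi, psi, omega)))) {
    stop("invalid input: torsion angles must be finite", call. = FALSE)
  }
  n <- max(length(phi), length(psi), length(omega))
  phi <- wrap180(rep_len(phi, n)); psi <- wrap180(rep_len(psi, n))
  omega <- wrap180(rep_len(omega, n))
  out <- character(n)
  cis <- abs(omega) < 90
  out[cis] <- "O"
  neg <- !cis & phi < 0
  out[neg & psi >= -75 & psi < 50] <- "A"
  out[neg & !(psi >= -75 & psi < 50)] <- "B"
  pos <- !cis & phi >= 0
  out[pos & psi > -100 & psi <= 100] <- "G"
  out[pos & !(psi > -100 & psi <= 100)] <- "E"
  out
}
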