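#' RGD-motif extraction and grafting
#'
#' The binding epitope is carried by a short hotspot loop (for the designs
#' here, the fibronectin-derived RGD loop).  A `motif_definition` stores the
#' loop backbone with one flanking anchor residue on each side; grafting
#' superposes the anchor frames onto the flanks of a scaffold loop by
#' least-squares (Kabsch) superposition and swaps the loop interior for the
#' motif interior.
#'
#' @name graft
NULL

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' Construct a motif definition
#'
#' @param model a `backbone_model` of >= 3 residues; the first and last
#'   residues are the pre/post anchors, the rest is the grafted interior
#' @param source provenance list, e.g. `list(kind = "fixture")` or
#'   `list(kind = "extracted", structure = ..., chain = ..., range = ...)`
#' @return object of class `motif_definition`
#' @export
motif_definition <- function(model, source = list(kind = "fixture")) {
  stopifnot(inherits(model, "backbone_model"), n_residues(model) >= 3)
  structure(list(model = model, sequence = model$sequence, source = source),
            class = "motif_definition")
}

#' @rdname motif_definition
#' @param motif a `motif_definition`
#' @export
motif_model <- function(motif) motif$model

#' @rdname motif_definition
#' @export
motif_interior_length <- function(motif) n_residues(motif$model) - 2L

# N, CA, C coordinates of given residues as a stacked matrix
anchor_atoms <- function(model, resno) {
  do.call(rbind, lapply(resno, function(r)
    rbind(atom_coords(model, "N", r), atom_coords(model, "CA", r),
          atom_coords(model, "C", r))))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `rotation %*% moving + translation` onto `fixed`.  Reflections are never
#' returned: the determinant of the rotation is +1 even for mirrored inputs
#' (where the optimum RMSD is then strictly positive).
#'
#' @param moving,fixed `n x 3` coordinate matrices, `n >= 3`
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3) {
    stop("invalid input: coordinate sets must share an n x 3 shape", call. = FALSE)
  }
  if (nrow(moving) < 3) {
    stop("degenerate geometry: need at least 3 points", call. = FALSE)
  }
  cm <- colMeans(moving); cf <- colMeans(fixed)
  p <- sweep(moving, 2, cm); q <- sweep(fixed, 2, cf)
  s <- svd(t(p) %*% q)
  if (s$d[2] < 1e-10 * max(s$d[1], 1)) {
    stop("degenerate geometry: rank-deficient point set", call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cf - as.vector(rot %*% cm)
  moved <- sweep(moving %*% t(rot), 2, -trans)
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

#' Extract a motif from a parsed structure
#'
#' Copies the backbone of `residue_range` (first and last residues become
#' the anchors) verbatim from a parsed PDB structure.  A missing carbonyl
#' oxygen is rebuilt from ideal geometry; a missing N, CA or C is an error
#' naming the residue.
#'
#' @param structure a parsed structure from [read_pdb()]
#' @param chain chain identifier
#' @param residue_range integer vector of residue numbers (closed interval,
#'   in author numbering)
#' @return a [motif_definition()]
#' @export
extract_motif_from_complex <- function(structure, chain, residue_range) {
  at <- structure$atoms
  at <- at[at$chain == chain & at$resno %in% residue_range, , drop = FALSE]
  g <- geometry_params()
  res <- sort(unique(residue_range))
  coords <- vector("list", length(res))
  seqs <- character(length(res))
  get1 <- function(sub, elety, r) {
    row <- sub[sub$elety == elety, , drop = FALSE]
    if (nrow(row) < 1) {
      stop("extraction error: residue ", r, " chain ", chain,
           " is missing backbone atom ", elety, call. = FALSE)
    }
    as.numeric(row[1, c("x", "y", "z")])
  }
  for (k in seq_along(res)) {
    sub <- at[at$resno == res[k], , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("extraction error: residue ", res[k], " not found in chain ", chain,
           call. = FALSE)
    }
    n <- get1(sub, "N", res[k]); ca <- get1(sub, "CA", res[k])
    cc <- get1(sub, "C", res[k])
    o <- if (any(sub$elety == "O")) get1(sub, "O", res[k]) else
      place_atom(n, ca, cc, g$b_c_o, g$a_ca_c_o, 180)
    coords[[k]] <- rbind(n, ca, cc, o)
    r3 <- toupper(sub$resid[1])
    seqs[k] <- if (r3 %in% names(AA3TO1)) AA3TO1[[r3]] else "X"
  }
  model <- backbone_model(do.call(rbind, coords), sequence = seqs,
                          provenance = list(builder = "extracted"))
  motif_definition(model, source = list(kind = "extracted",
                                        structure = structure$id %||% "pdb",
                                        chain = chain, range = range(res)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a motif straight out of a backbone model
#'
#' Convenience sibling of [extract_motif_from_complex()] for models already
#' in memory: `residue_range` must include the two anchor residues.
#'
#' @param model a `backbone_model`
#' @param residue_range residue indices, anchors included (length >= 3)
#' @return a [motif_definition()]
#' @export
extract_motif_from_model <- function(model, residue_range) {
  residue_range <- sort(residue_range)
  stopifnot(length(residue_range) >= 3,
            min(residue_range) >= 1, max(residue_range) <= n_residues(model))
  keep <- model$resno %in% residue_range
  sub <- backbone_model(model$xyz[keep, , drop = FALSE],
                        sequence = model$sequence[residue_range],
                        provenance = list(builder = "extracted_from_model"))
  motif_definition(sub, source = list(kind = "extracted",
                                      range = range(residue_range)))
}

#' Graft a motif into a scaffold loop
#'
#' The motif anchor frames (N, CA, C of its first and last residues) are
#' superposed onto the scaffold residues flanking the target loop; the loop
#' interior is replaced by the transformed motif interior.  The reported
#' `closure_rmsd` is the post-fit RMSD over the 6 anchor atoms; the graft is
#' accepted when it is at or below `closure_threshold` and the grafted model
#' is clash free.
#'
#' @param scaffold a `backbone_model`; models from [assemble_stagewise()]
#'   carry their element ranges, otherwise pass `loop_range`
#' @param motif a [motif_definition()]; interior length may differ from the
#'   loop length by at most 2 residues
#' @param target_loop loop element id (default "L1"), resolved through the
#'   scaffold's stored blueprint ranges
#' @param loop_range explicit residue indices of the loop interior
#'   (overrides `target_loop`)
#' @param closure_threshold acceptance bound on the closure RMSD, Angstrom
#' @param clash_min_distance clash threshold for the grafted model
#' @return object of class `graft_result`: `model`, `closure_rmsd`,
#'   `replaced`, `accepted`, `clash_count`
#' @export
graft_motif_into_scaffold <- function(scaffold, motif, target_loop = "L1",
                                      loop_range = NULL,
                                      closure_threshold = 0.75,
                                      clash_min_distance = 2.8) {
  stopifnot(inherits(scaffold, "backbone_model"),
            inherits(motif, "motif_definition"))
  if (is.null(loop_range)) {
    ranges <- attr(scaffold, "ranges")
    if (is.null(ranges) || is.null(ranges[[target_loop]])) {
      stop("lookup error: scaffold has no loop named ", target_loop,
           "; supply loop_range explicitly", call. = FALSE)
    }
    loop_range <- ranges[[target_loop]]
  }
  loop_range <- sort(loop_range)
  n <- n_residues(scaffold)
  pre <- min(loop_range) - 1L; post <- max(loop_range) + 1L
  if (pre < 1 || post > n) {
    stop("lookup error: loop must have a flanking residue on both sides",
         call. = FALSE)
  }
  mi <- motif_interior_length(motif)
  if (abs(mi - length(loop_range)) > 2) {
    stop("motif interior length (", mi, ") differs from loop length (",
         length(loop_range), ") by more than 2 residues", call. = FALSE)
  }
  mm <- motif_model(motif)
  fit <- kabsch_superpose(anchor_atoms(mm, c(1L, n_residues(mm))),
                          anchor_atoms(scaffold, c(pre, post)))
  moved <- transform_coords(mm$xyz, fit$rotation, fit$translation)
  interior <- seq(2L, n_residues(mm) - 1L)
  motif_rows <- as.vector(vapply(interior, function(r) (r - 1L) * 4L + 1:4,
                                 integer(4)))
  keep_head <- scaffold$resno <= pre
  keep_tail <- scaffold$resno >= post
  xyz <- rbind(scaffold$xyz[keep_head, , drop = FALSE],
               moved[motif_rows, , drop = FALSE],
               scaffold$xyz[keep_tail, , drop = FALSE])
  seqs <- c(scaffold$sequence[seq_len(pre)],
            motif$sequence[interior],
            scaffold$sequence[seq(post, n)])
  seqs[pre] <- motif$sequence[1]
  seqs[pre + mi + 1L] <- motif$sequence[length(motif$sequence)]
  grafted <- backbone_model(xyz, sequence = seqs,
                            provenance = c(scaffold$provenance,
                                           list(graft = target_loop)))
  # carry element ranges forward, shifted by any length change
  ranges <- attr(scaffold, "ranges")
  if (!is.null(ranges)) {
    shift <- mi - length(loop_range)
    attr(grafted, "ranges") <- lapply(stats::setNames(names(ranges), names(ranges)),
      function(el) {
        r <- ranges[[el]]
        if (max(r) <= pre) r
        else if (min(r) >= post) r + shift
        else seq(pre + 1L, pre + mi)
      })
  }
  clashes <- check_clashes(grafted, clash_min_distance)
  structure(list(model = grafted, closure_rmsd = fit$rmsd,
                 replaced = target_loop, clash_count = clashes,
                 accepted = fit$rmsd <= closure_threshold && clashes == 0L),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  cat(sprintf("graft_result: loop %s, closure RMSD %.3f A, clashes %d, %s\n",
              x$replaced, x$closure_rmsd, x$clash_count,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}
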