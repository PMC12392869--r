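#' File formats and configuration
#'
#' Readers and writers for the formats the pipeline exchanges: fixed-column
#' PDB (single chain "A", 1-based contiguous numbering on write), FASTA,
#' sort-seq count tables (long CSV plus a JSON gate manifest), tidy binding
#' curves, pseudo-targets (JSON) and JSON run configuration.  Intervals in
#' CSV manifests are closed and 1-based.  Logs go to stderr, results to
#' files, keeping shell pipelines composable.
#'
#' @name cli-io
NULL

#' Write a backbone model as PDB
#'
#' Standard fixed-column ATOM records: chain "A", contiguous 1-based residue
#' numbers, occupancy 1.00, B-factor 0.00.  Output is byte-identical across
#' runs for identical models.
#'
#' @param model a `backbone_model`
#' @param path output path
#' @return the path, invisibly
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "backbone_model"))
  res3 <- AA1TO3[model$sequence]
  res3[is.na(res3)] <- "GLY"
  lines <- character(nrow(model$xyz))
  for (i in seq_len(nrow(model$xyz))) {
    r <- model$resno[i]
    el <- substr(model$atom[i], 1, 1)
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, sprintf(" %-3s", model$atom[i]), res3[r], r,
      model$xyz[i, 1], model$xyz[i, 2], model$xyz[i, 3], 1, 0, el)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Parse a PDB file
#'
#' Backed by `bio3d::read.pdb`; returns the ATOM records as a plain atom
#' table (`chain`, `resno`, `insert`, `elety`, `resid`, `x`, `y`, `z`).
#' HETATM records (ligands, glycans, waters) are dropped with a warning when
#' present.  Malformed files surface as a parse error naming the file.
#'
#' @param path PDB file path
#' @return object of class `pdb_structure` with elements `atoms` and `id`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("parse error in ", path, ": no ATOM records", call. = FALSE)
  }
  het <- at$type != "ATOM"
  if (any(het)) {
    warning("ignoring ", sum(het), " HETATM record(s) in ", basename(path))
    at <- at[!het, , drop = FALSE]
  }
  structure(list(atoms = data.frame(chain = at$chain, resno = at$resno,
                                    insert = at$insert, elety = at$elety,
                                    resid = at$resid,
                                    x = at$x, y = at$y, z = at$z,
                                    stringsAsFactors = FALSE),
                 id = basename(path)),
            class = "pdb_structure")
}

#' Convert a parsed structure to a backbone model
#'
#' Keeps the N, CA, C, O backbone of one chain; a residue missing N, CA or C
#' is recorded as a gap (dropped with a warning), a missing O is rebuilt
#' from ideal geometry.
#'
#' @param structure a `pdb_structure` from [read_pdb()]
#' @param chain chain id (default "A")
#' @return a `backbone_model`
#' @export
as_backbone_model <- function(structure, chain = "A") {
  at <- structure$atoms
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain ", chain, call. = FALSE)
  g <- geometry_params()
  res <- unique(at$resno)
  coords <- list(); seqs <- character(0); gaps <- integer(0)
  for (r in res) {
    sub <- at[at$resno == r, , drop = FALSE]
    have <- function(e) any(sub$elety == e)
    if (!have("N") || !have("CA") || !have("C")) { gaps <- c(gaps, r); next }
    pick <- function(e) as.numeric(sub[sub$elety == e, c("x", "y", "z")][1, ])
    n <- pick("N"); ca <- pick("CA"); cc <- pick("C")
    o <- if (have("O")) pick("O") else
      place_atom(n, ca, cc, g$b_c_o, g$a_ca_c_o, 180)
    coords[[length(coords) + 1L]] <- rbind(n, ca, cc, o)
    r3 <- toupper(sub$resid[1])
    seqs <- c(seqs, if (r3 %in% names(AA3TO1)) AA3TO1[[r3]] else "X")
  }
  if (length(gaps) > 0) {
    warning("residue(s) ", paste(gaps, collapse = ", "),
            " missing backbone atoms; recorded as gap")
  }
  if (length(coords) == 0) stop("no complete backbone residues", call. = FALSE)
  backbone_model(do.call(rbind, coords), sequence = seqs,
                 provenance = list(builder = "pdb", source = structure$id))
}

#' FASTA round trip
#'
#' Thin wrappers over `seqinr`; duplicate sequence ids are rejected on read.
#'
#' @param sequences named character vector of sequences
#' @param path file path
#' @return `read_fasta` returns a named character vector
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  seqinr::write.fasta(as.list(strsplit(sequences, "")),
                      names = names(sequences), file.out = path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  ids <- names(fa)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(toupper(vapply(fa, as.character, character(1))), ids)
}

require_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Sort-seq counts CSV + gate manifest round trip
#'
#' Counts travel as a long CSV (`variant`, `gate_id`, `reads`, optional
#' `sequence`) with the pre-sort pool stored under `gate_id = "reference"`;
#' gate metadata travels as a JSON array of objects with `gate_id`, `round`,
#' `target`, `concentration_nM`, `fraction_collected`.
#'
#' @param data a [sortseq_counts()]
#' @param counts_path,gates_path file paths
#' @return `read_sortseq_counts` returns a [sortseq_counts()]
#' @export
write_sortseq_counts <- function(data, counts_path, gates_path) {
  long <- data.frame(
    variant = rep(rownames(data$counts), ncol(data$counts) + 1L),
    gate_id = rep(c(colnames(data$counts), "reference"),
                  each = nrow(data$counts)),
    reads = c(as.vector(data$counts), unname(data$reference)))
  utils::write.csv(long, counts_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(data$gates, gates_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(counts_path)
}

#' @rdname write_sortseq_counts
#' @export
read_sortseq_counts <- function(counts_path, gates_path) {
  long <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  require_columns(long, c("variant", "gate_id", "reads"), counts_path)
  if (any(long$reads < 0)) {
    stop("schema error in ", counts_path, ": negative read counts", call. = FALSE)
  }
  gates <- jsonlite::fromJSON(gates_path)
  require_columns(gates, c("gate_id", "concentration_nM"), gates_path)
  ref <- long[long$gate_id == "reference", ]
  cnt <- long[long$gate_id != "reference", ]
  variants <- unique(long$variant)
  m <- matrix(0, length(variants), nrow(gates),
              dimnames = list(variants, gates$gate_id))
  m[cbind(match(cnt$variant, variants), match(cnt$gate_id, gates$gate_id))] <-
    cnt$reads
  rv <- stats::setNames(rep(0, length(variants)), variants)
  rv[ref$variant] <- ref$reads
  sortseq_counts(m, rv, gates)
}

#' Read tidy binding curves
#'
#' Kinetic traces need columns `series_id`, `phase`, `time_s`, `response`
#' (plus `conc_nM`); dose/competition curves need `series_id`, `conc_nM`,
#' `response`.
#'
#' @param path CSV path
#' @param kind "kinetic" or "dose"
#' @return data.frame validated against the schema
#' @export
read_curves_csv <- function(path, kind = c("kinetic", "dose")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (kind == "kinetic") c("series_id", "phase", "time_s", "response",
                                   "conc_nM")
          else c("series_id", "conc_nM", "response")
  require_columns(df, need, path)
  df
}

# kinetic curves data.frame -> list of kinetic_trace
curves_to_traces <- function(df) {
  out <- list()
  for (sid in unique(df$series_id)) {
    for (ph in unique(df$phase[df$series_id == sid])) {
      sub <- df[df$series_id == sid & df$phase == ph, ]
      out[[length(out) + 1L]] <- kinetic_trace(sub$time_s, sub$response, ph,
                                               sub$conc_nM[1], series_id = sid)
    }
  }
  out
}

#' Pseudo-target JSON round trip
#' @param target a [pseudo_target()]
#' @param path file path
#' @return `read_pseudo_target` returns a [pseudo_target()]
#' @export
write_pseudo_target <- function(target, path) {
  jsonlite::write_json(list(atoms = target$atoms,
                            annotations = target$annotations),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pseudo_target
#' @export
read_pseudo_target <- function(path) {
  obj <- jsonlite::fromJSON(path)
  pseudo_target(obj$atoms, as.list(obj$annotations))
}

#' Read a JSON run configuration
#'
#' Known keys override the supplied defaults; unknown keys are ignored with
#' a warning.
#'
#' @param path JSON file
#' @param defaults named list of known keys and default values
#' @return merged configuration list
#' @export
read_config <- function(path, defaults = list()) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0 && length(defaults) > 0) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- cfg[intersect(names(cfg), names(defaults))]
  }
  utils::modifyList(defaults, cfg)
}

#' Write a machine-readable run log
#'
#' Records the subcommand, seed, parameters and md5 checksums of the input
#' files as JSON next to the results.
#'
#' @param path output JSON path
#' @param subcommand name of the operation
#' @param seed RNG seed used
#' @param params parameter list
#' @param inputs character vector of input file paths
#' @export
write_run_log <- function(path, subcommand, seed = 0, params = list(),
                          inputs = character(0)) {
  existing <- inputs[file.exists(inputs)]
  jsonlite::write_json(list(subcommand = subcommand, seed = seed,
                            params = params,
                            input_checksums = as.list(tools::md5sum(existing)),
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
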