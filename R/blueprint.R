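#' Ferredoxin blueprints from topology occurrence statistics
#'
#' A blueprint specifies, segment by segment, the secondary structure of a
#' ferredoxin-fold (EHEEHE) backbone: four strands (E1..E4), two helices
#' (H1, H2) and the five connecting loops (L1..L5), each loop carrying an
#' ABEGO torsion-pattern string.  Blueprints are enumerated as the Cartesian
#' product of the most frequently observed options per degree of freedom
#' (loop ABEGO string, helix length, strand-pairing combination) and ranked
#' by a joint log-frequency score.
#'
#' @name blueprint
NULL

#' Segment order of the ferredoxin fold
#' @format character vector of element ids in sequence order
#' @export
FERREDOXIN_ELEMENTS <- c("E1", "L1", "H1", "L2", "E2", "L3", "E3",
                         "L4", "H2", "L5", "E4")

FERREDOXIN_SS <- c(E1 = "E", L1 = "L", H1 = "H", L2 = "L", E2 = "E",
                   L3 = "L", E3 = "E", L4 = "L", H2 = "H", L5 = "L", E4 = "E")

LOOP_IDS <- c("L1", "L2", "L3", "L4", "L5")
HELIX_IDS <- c("H1", "H2")
STRAND_IDS <- c("E1", "E2", "E3", "E4")

#' Construct a segment specification
#'
#' @param element_id one of `E1 L1 H1 L2 E2 L3 E3 L4 H2 L5 E4`
#' @param length residue count (>= 1); for loops inferred from `abego`
#' @param abego ABEGO string, loops only; length must equal `length`
#' @return object of class `segment_spec`
#' @export
segment_spec <- function(element_id, length = NULL, abego = NULL) {
  element_id <- match.arg(element_id, FERREDOXIN_ELEMENTS)
  ss_type <- FERREDOXIN_SS[[element_id]]
  if (ss_type == "L") {
    if (is.null(abego) || !nzchar(abego)) {
      stop("loop segment ", element_id, " requires an abego string", call. = FALSE)
    }
    letters_ok <- strsplit(abego, "")[[1]] %in% ABEGO_LABELS
    if (!all(letters_ok)) stop("invalid abego letters in ", abego, call. = FALSE)
    if (is.null(length)) length <- nchar(abego)
    if (length != nchar(abego)) {
      stop("abego string length must equal loop length", call. = FALSE)
    }
  } else {
    if (!is.null(abego)) stop("strand/helix segments carry no abego string", call. = FALSE)
    if (is.null(length) || length < 1) stop("segment length must be >= 1", call. = FALSE)
    abego <- NA_character_
  }
  structure(list(element_id = element_id, ss_type = ss_type,
                 length = as.integer(length), abego = abego),
            class = "segment_spec")
}

#' Construct topology occurrence statistics
#'
#' @param loop_abego_counts named list (`L1`..`L5`), each a named numeric
#'   vector mapping ABEGO string to occurrence count
#' @param helix_length_counts named list (`H1`, `H2`), each a named numeric
#'   vector mapping length (as name) to occurrence count
#' @param sheet_combination_counts named numeric vector mapping
#'   strand-pairing combination id to occurrence count
#' @param strand_lengths named integer vector (`E1`..`E4`) of fixed strand
#'   lengths used by every blueprint
#' @return object of class `topology_stats`
#' @export
topology_stats <- function(loop_abego_counts, helix_length_counts,
                           sheet_combination_counts, strand_lengths) {
  stopifnot(all(LOOP_IDS %in% names(loop_abego_counts)),
            all(HELIX_IDS %in% names(helix_length_counts)),
            all(STRAND_IDS %in% names(strand_lengths)))
  chk <- function(x, what) {
    if (any(x < 0) || !any(x > 0)) {
      stop("counts for ", what, " must be >= 0 with at least one positive",
           call. = FALSE)
    }
  }
  for (l in LOOP_IDS) chk(loop_abego_counts[[l]], l)
  for (h in HELIX_IDS) chk(helix_length_counts[[h]], h)
  chk(sheet_combination_counts, "sheet combinations")
  structure(list(loop_abego_counts = loop_abego_counts[LOOP_IDS],
                 helix_length_counts = helix_length_counts[HELIX_IDS],
                 sheet_combination_counts = sheet_combination_counts,
                 strand_lengths = as.integer(strand_lengths[STRAND_IDS]) |>
                   stats::setNames(STRAND_IDS)),
            class = "topology_stats")
}

# options sorted by count desc then lexicographic; returns the top n names
top_options <- function(counts, n, what) {
  if (length(counts) < n) {
    stop("configuration error: only ", length(counts), " options available for ",
         what, ", ", n, " requested", call. = FALSE)
  }
  ord <- order(-counts, names(counts), method = "radix")
  names(counts)[ord][seq_len(n)]
}

# log relative frequency of the chosen option within its full table
log_freq <- function(counts, option) {
  log(counts[[option]] / sum(counts))
}

#' Enumerate ferredoxin blueprints
#'
#' Forms the full Cartesian product of the top `n_abego_per_loop` ABEGO
#' strings per loop, the top `n_lengths_per_helix` lengths per helix and the
#' top `n_sheet_combos` strand-pairing combinations, scored by the sum of
#' log occurrence frequencies of the chosen options (factors treated as
#' independent) and ordered by score (descending) with a lexicographic
#' tie-break on the segment string.
#'
#' @param stats a [topology_stats] object
#' @param n_abego_per_loop,n_lengths_per_helix,n_sheet_combos how many of the
#'   most frequent options to combine (defaults 5, 4, 5)
#' @return a `blueprint_set`: a data.frame with one row per blueprint
#'   (columns `L1`..`L5`, `H1`, `H2`, `sheet`, `score`, `segment_string`) and
#'   the generating `stats` attached as an attribute
#' @examples
#' st <- make_topology_stats(seed = 1)
#' nrow(enumerate_blueprints(st, 1, 1, 1))  # 1
#' @export
enumerate_blueprints <- function(stats, n_abego_per_loop = 5,
                                 n_lengths_per_helix = 4, n_sheet_combos = 5) {
  stopifnot(inherits(stats, "topology_stats"))
  opts <- c(
    lapply(stats::setNames(LOOP_IDS, LOOP_IDS), function(l)
      top_options(stats$loop_abego_counts[[l]], n_abego_per_loop, l)),
    lapply(stats::setNames(HELIX_IDS, HELIX_IDS), function(h)
      top_options(stats$helix_length_counts[[h]], n_lengths_per_helix, h)),
    list(sheet = top_options(stats$sheet_combination_counts, n_sheet_combos,
                             "sheet combinations"))
  )
  grid <- expand.grid(opts, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  score <- rep(0, nrow(grid))
  for (l in LOOP_IDS) {
    lf <- vapply(opts[[l]], function(o) log_freq(stats$loop_abego_counts[[l]], o),
                 numeric(1))
    score <- score + lf[grid[[l]]]
  }
  for (h in HELIX_IDS) {
    lf <- vapply(opts[[h]], function(o) log_freq(stats$helix_length_counts[[h]], o),
                 numeric(1))
    score <- score + lf[grid[[h]]]
  }
  lf <- vapply(opts$sheet, function(o) log_freq(stats$sheet_combination_counts, o),
               numeric(1))
  score <- score + lf[grid$sheet]
  grid$score <- unname(score)
  grid$segment_string <- blueprint_segment_string(grid, stats)
  ord <- order(-grid$score, grid$segment_string, method = "radix")
  grid <- grid[ord, , drop = FALSE]
  rownames(grid) <- NULL
  structure(grid, stats = stats, class = c("blueprint_set", "data.frame"))
}

# canonical one-line serialization of each blueprint row, used for
# deterministic tie-breaking and as a compact id
blueprint_segment_string <- function(grid, stats) {
  sl <- stats$strand_lengths
  paste0("E1:", sl[["E1"]],
         "|L1:", grid$L1, "|H1:", grid$H1,
         "|L2:", grid$L2, "|E2:", sl[["E2"]],
         "|L3:", grid$L3, "|E3:", sl[["E3"]],
         "|L4:", grid$L4, "|H2:", grid$H2,
         "|L5:", grid$L5, "|E4:", sl[["E4"]],
         "|S:", grid$sheet)
}

#' Select the top-scoring blueprints
#'
#' Deterministic selection: sort by score descending, break ties
#' lexicographically on the segment string, return exactly `top_k` rows.
#' Idempotent: re-selecting the top k of an already selected set returns it
#' unchanged.
#'
#' @param blueprints a `blueprint_set` from [enumerate_blueprints()]
#' @param top_k number of blueprints to retain (defaults to 100)
#' @return a `blueprint_set` of `top_k` rows
#' @export
rank_and_select_blueprints <- function(blueprints, top_k = 100) {
  stopifnot(inherits(blueprints, "blueprint_set"))
  if (top_k > nrow(blueprints)) {
    stop("bounds error: top_k (", top_k, ") exceeds available blueprints (",
         nrow(blueprints), ")", call. = FALSE)
  }
  ord <- order(-blueprints$score, blueprints$segment_string, method = "radix")
  out <- blueprints[ord[seq_len(top_k)], , drop = FALSE]
  rownames(out) <- NULL
  structure(out, stats = attr(blueprints, "stats"),
            class = c("blueprint_set", "data.frame"))
}

#' Materialize one blueprint from a blueprint set
#'
#' @param set a `blueprint_set`
#' @param i row index
#' @return object of class `blueprint`: ordered `segments` (list of
#'   [segment_spec]), `sheet_combination_id`, `score`
#' @export
as_blueprint <- function(set, i = 1) {
  stopifnot(inherits(set, "blueprint_set"), i >= 1, i <= nrow(set))
  stats <- attr(set, "stats")
  row <- set[i, , drop = FALSE]
  segs <- lapply(FERREDOXIN_ELEMENTS, function(el) {
    ss <- FERREDOXIN_SS[[el]]
    if (ss == "L") segment_spec(el, abego = row[[el]])
    else if (ss == "H") segment_spec(el, length = as.integer(row[[el]]))
    else segment_spec(el, length = stats$strand_lengths[[el]])
  })
  structure(list(segments = segs, sheet_combination_id = row$sheet,
                 score = row$score, segment_string = row$segment_string),
            class = "blueprint")
}

#' @export
print.blueprint <- function(x, ...) {
  cat("ferredoxin blueprint (score ", format(x$score, digits = 4), ", sheet ",
      x$sheet_combination_id, ")\n", sep = "")
  for (s in x$segments) {
    cat(sprintf("  %-3s %s %3d %s\n", s$element_id, s$ss_type, s$length,
                if (is.na(s$abego)) "" else s$abego))
  }
  invisible(x)
}

#' Total residue length of a blueprint
#' @param bp a `blueprint`
#' @return integer residue count
#' @export
blueprint_length <- function(bp) {
  sum(vapply(bp$segments, function(s) s$length, integer(1)))
}

#' Write / read a blueprint in the plain-text blueprint dialect
#'
#' One line per segment: `element_id ss_type length abego` (loops) or
#' `element_id ss_type length .` (strands/helices); a trailing `# sheet <id>`
#' comment records the strand combination.  The round trip is lossless up to
#' the enumeration score.
#'
#' @param bp a `blueprint`
#' @param path file path
#' @return `read_blueprint` returns a `blueprint` (score `NA`)
#' @export
write_blueprint <- function(bp, path) {
  lines <- vapply(bp$segments, function(s)
    sprintf("%s %s %d %s", s$element_id, s$ss_type, s$length,
            if (is.na(s$abego)) "." else s$abego), character(1))
  lines <- c(lines, paste("# sheet", bp$sheet_combination_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  lines <- readLines(path)
  sheet <- sub("^# sheet ", "", grep("^# sheet ", lines, value = TRUE)[1])
  lines <- grep("^#", lines, invert = TRUE, value = TRUE)
  segs <- lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    if (length(f) != 4) stop("malformed blueprint line: ", paste(f, collapse = " "),
                             call. = FALSE)
    segment_spec(f[1], length = as.integer(f[3]),
                 abego = if (f[4] == ".") NULL else f[4])
  })
  structure(list(segments = segs, sheet_combination_id = sheet, score = NA_real_,
                 segment_string = NA_character_),
            class = "blueprint")
}

#' Topology statistics CSV / JSON round trip
#'
#' CSV layout: columns `element`, `option`, `count`; strand rows carry the
#' fixed strand length in `option` and `NA` count.
#'
#' @param stats a `topology_stats`
#' @param path file path
#' @return `read_topology_stats` returns a `topology_stats`
#' @export
write_topology_stats <- function(stats, path) {
  rows <- list()
  for (l in LOOP_IDS) {
    cnt <- stats$loop_abego_counts[[l]]
    rows[[l]] <- data.frame(element = l, option = names(cnt), count = unname(cnt))
  }
  for (h in HELIX_IDS) {
    cnt <- stats$helix_length_counts[[h]]
    rows[[h]] <- data.frame(element = h, option = names(cnt), count = unname(cnt))
  }
  rows$sheet <- data.frame(element = "sheet",
                           option = names(stats$sheet_combination_counts),
                           count = unname(stats$sheet_combination_counts))
  rows$strand <- data.frame(element = STRAND_IDS,
                            option = as.character(stats$strand_lengths),
                            count = NA_real_)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology_stats
#' @export
read_topology_stats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(element = "character", option = "character"))
  need <- c("element", "option", "count")
  if (!all(need %in% names(df))) {
    stop("schema error: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  pick <- function(el) {
    sub <- df[df$element == el & !is.na(df$count), ]
    stats::setNames(sub$count, sub$option)
  }
  strands <- df[df$element %in% STRAND_IDS, ]
  topology_stats(
    loop_abego_counts = lapply(stats::setNames(LOOP_IDS, LOOP_IDS), pick),
    helix_length_counts = lapply(stats::setNames(HELIX_IDS, HELIX_IDS), pick),
    sheet_combination_counts = pick("sheet"),
    strand_lengths = stats::setNames(as.integer(strands$option), strands$element)
  )
}

#' Write a blueprint set as JSON lines
#'
#' One JSON object per line with the per-loop ABEGO strings, helix lengths,
#' sheet combination, score and segment string.
#'
#' @param set a `blueprint_set`
#' @param path output path
#' @export
write_blueprints_jsonl <- function(set, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(set))) {
    writeLines(jsonlite::toJSON(as.list(set[i, , drop = FALSE][1, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
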