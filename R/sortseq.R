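#' Sort-seq screening analytics
#'
#' A displayed variant library is sorted by FACS at several ligand
#' concentrations and deep-sequenced before and after each sort.  Frequency
#' changes across gates carry the binding signal: the fraction of cells
#' carrying variant v collected at concentration c is modelled as
#' proportional to the receptor occupancy `c / (c + K_D(v))`, and per-variant
#' dissociation constants are recovered by multinomial maximum likelihood
#' jointly over all variants (the per-gate normalization couples them).
#'
#' @name sortseq
NULL

#' Construct a sort-seq count container
#'
#' @param counts integer matrix, variants x gates (rownames = variant ids,
#'   colnames = gate ids)
#' @param reference integer vector of pre-sort reads per variant
#' @param gates data.frame with columns `gate_id`, `round`, `target`,
#'   `concentration_nM`, `fraction_collected`
#' @param sequences optional named character vector of variant sequences
#' @return object of class `sortseq_counts`
#' @export
sortseq_counts <- function(counts, reference, gates, sequences = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(reference >= 0),
            nrow(counts) == length(reference),
            ncol(counts) == nrow(gates),
            all(c("gate_id", "concentration_nM") %in% names(gates)))
  if (any(colSums(counts) <= 0)) {
    stop("invalid input: every gate needs positive total reads", call. = FALSE)
  }
  if (sum(reference) <= 0) {
    stop("invalid input: reference totals must be positive", call. = FALSE)
  }
  if (is.null(rownames(counts))) rownames(counts) <- paste0("v", seq_len(nrow(counts)))
  colnames(counts) <- gates$gate_id
  structure(list(counts = counts, reference = stats::setNames(reference, rownames(counts)),
                 gates = gates, sequences = sequences),
            class = "sortseq_counts")
}

#' @export
print.sortseq_counts <- function(x, ...) {
  cat("sortseq_counts:", nrow(x$counts), "variants x", ncol(x$counts), "gates\n")
  invisible(x)
}

#' Pseudocounted variant frequencies per gate
#' @param data a `sortseq_counts`
#' @param pseudocount additive pseudocount alpha (default 1)
#' @return matrix of frequencies; each column sums to 1
#' @export
gate_frequencies <- function(data, pseudocount = 1) {
  v <- nrow(data$counts)
  f <- sweep(data$counts + pseudocount, 2,
             colSums(data$counts) + pseudocount * v, "/")
  f
}

#' Log2 enrichment of each variant in each gate
#'
#' `log2 f_vg - log2 f_v0` with pseudocounted frequencies
#' `f = (c + a) / (T + a V)`; the reference column is the pre-sort pool.
#'
#' @param data a `sortseq_counts`
#' @param pseudocount additive pseudocount alpha (default 1); with 0, every
#'   variant must be present in the reference pool
#' @return matrix (variants x gates) of log2 enrichment values
#' @export
enrichment_ratios <- function(data, pseudocount = 1) {
  stopifnot(inherits(data, "sortseq_counts"))
  if (pseudocount == 0 && any(data$reference == 0)) {
    stop("undefined ratio: variant absent from the reference pool with ",
         "pseudocount 0", call. = FALSE)
  }
  v <- nrow(data$counts)
  f0 <- (data$reference + pseudocount) / (sum(data$reference) + pseudocount * v)
  fg <- gate_frequencies(data, pseudocount)
  log2(fg) - log2(f0)
}

# joint multinomial log-likelihood of log10-KD vector x given the data
sortseq_loglik <- function(x, counts, f0, conc) {
  occ <- outer(10^x, conc, function(k, c) c / (c + k))
  fo <- f0 * occ
  z <- colSums(fo)
  sum(counts * log(sweep(fo, 2, z, "/")))
}

#' Estimate per-variant dissociation constants from sort-seq counts
#'
#' Occupancy model: the chance a displayed cell is collected in the gate at
#' concentration `c` is proportional to `c / (c + K_D)` (with the per-gate
#' selection stringency absorbed into the gate normalization).  Log10 K_D
#' values are fit by coordinate-wise maximization of the joint multinomial
#' likelihood; estimates at the edge of the probed concentration range are
#' flagged `below-range` / `above-range` rather than reported as converged
#' point values.  Variants with identical count profiles receive identical
#' estimates.
#'
#' @param data a `sortseq_counts` with >= 2 distinct concentrations
#' @param pseudocount additive pseudocount on read counts (default 1)
#' @param n_sweeps coordinate-ascent sweeps (default 40)
#' @param bound_pad log10 decades beyond the concentration range searched
#'   (default 2)
#' @return data.frame with `variant`, `kd_nM`, `kd_molar`, `log10_kd_nM`,
#'   `se_log10`, `kd_lo_nM`, `kd_hi_nM`, `status`
#' @export
estimate_kd_from_sorts <- function(data, pseudocount = 1, n_sweeps = 40,
                                   bound_pad = 2) {
  stopifnot(inherits(data, "sortseq_counts"))
  conc <- data$gates$concentration_nM
  if (length(unique(conc)) < 2) {
    stop("identifiability error: need >= 2 distinct concentrations", call. = FALSE)
  }
  v <- nrow(data$counts)
  f0 <- (data$reference + pseudocount) / (sum(data$reference) + pseudocount * v)
  cnt <- data$counts + pseudocount
  lo <- log10(min(conc)) - bound_pad
  hi <- log10(max(conc)) + bound_pad

  # identical count profiles share one estimate exactly
  key <- apply(cbind(data$counts, data$reference), 1, paste, collapse = ",")
  groups <- split(seq_len(v), key)
  rep_idx <- vapply(groups, `[`, integer(1), 1L)
  cnt_u <- do.call(rbind, lapply(groups, function(g)
    colSums(cnt[g, , drop = FALSE])))
  f0_u <- f0[rep_idx] * vapply(groups, length, integer(1))
  vu <- length(rep_idx)

  x <- rep(log10(stats::median(conc)), vu)
  for (s in seq_len(n_sweeps)) {
    x_old <- x
    for (i in seq_len(vu)) {
      obj <- function(xi) {
        xx <- x; xx[i] <- xi
        -sortseq_loglik(xx, cnt_u, f0_u, conc)
      }
      x[i] <- stats::optimize(obj, c(lo, hi), tol = 1e-7)$minimum
    }
    if (max(abs(x - x_old)) < 1e-7) break
  }

  # curvature-based standard error on log10 KD
  se <- vapply(seq_len(vu), function(i) {
    h <- 1e-3
    f <- function(xi) { xx <- x; xx[i] <- xi; sortseq_loglik(xx, cnt_u, f0_u, conc) }
    d2 <- (f(x[i] + h) - 2 * f(x[i]) + f(x[i] - h)) / h^2
    if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }, numeric(1))

  status <- ifelse(x <= lo + 0.01, "below-range",
                   ifelse(x >= hi - 0.01, "above-range", "converged"))
  sorted_reads <- rowSums(data$counts)[rep_idx]
  status[sorted_reads == 0] <- "above-range"

  # expand group estimates back to all variants
  xi <- numeric(v); sei <- numeric(v); sti <- character(v)
  for (k in seq_along(groups)) {
    xi[groups[[k]]] <- x[k]; sei[groups[[k]]] <- se[k]; sti[groups[[k]]] <- status[k]
  }
  data.frame(variant = rownames(data$counts),
             kd_nM = 10^xi, kd_molar = 10^xi * 1e-9, log10_kd_nM = xi,
             se_log10 = sei,
             kd_lo_nM = 10^(xi - 1.96 * sei), kd_hi_nM = 10^(xi + 1.96 * sei),
             status = sti, row.names = NULL)
}

#' Construct a site-saturation-mutagenesis matrix
#'
#' @param delta_log_kd numeric matrix, positions x 20 amino acids (columns
#'   named by one-letter code), holding log10 K_D change relative to the
#'   parent; `NA` marks unobserved substitutions
#' @param parent parent sequence (length = number of rows); parent cells are
#'   forced to 0
#' @return object of class `ssm_matrix`
#' @export
ssm_matrix <- function(delta_log_kd, parent) {
  delta_log_kd <- as.matrix(delta_log_kd)
  stopifnot(ncol(delta_log_kd) == 20, nrow(delta_log_kd) == length(parent))
  if (is.null(colnames(delta_log_kd))) colnames(delta_log_kd) <- sort(names(AA1TO3))
  for (i in seq_along(parent)) delta_log_kd[i, parent[i]] <- 0
  structure(list(delta = delta_log_kd, parent = parent), class = "ssm_matrix")
}

#' Positional Shannon entropy of an SSM matrix
#'
#' Substitution tolerances are turned into per-position amino-acid weights
#' `p_a` proportional to `exp(-delta_log_kd / temperature)`; the entropy is
#' `-sum p_a log2 p_a` in bits (0 = fully conserved, log2 20 ~ 4.32 = fully
#' tolerant).  Positions with no observed substitution are returned as `NA`.
#'
#' @param ssm an [ssm_matrix()]
#' @param temperature softmax temperature (dimensionless, default 1)
#' @return numeric vector of per-position entropies, bits
#' @export
ssm_entropy_profile <- function(ssm, temperature = 1) {
  stopifnot(inherits(ssm, "ssm_matrix"), temperature > 0)
  apply(ssm$delta, 1, function(row) {
    obs <- row[!is.na(row)]
    if (length(obs) == 0) return(NA_real_)
    w <- exp(-(obs - min(obs)) / temperature)
    p <- w / sum(w)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Classify variant specificity between two targets
#'
#' A variant is `specific_a5b1` when it binds the primary target tightly
#' (K_D <= `k_max_nM`) and the off-target affinity is at least
#' `fold_threshold`-fold weaker (or off-target binding is out of range);
#' `nonbinder` when neither target is bound within range; `cross_reactive`
#' otherwise.
#'
#' @param affinities_a5b1,affinities_avb3 data.frames from
#'   [estimate_kd_from_sorts()] (columns `variant`, `kd_nM`, `status`)
#' @param fold_threshold selectivity fold change required (default 100)
#' @param k_max_nM maximum on-target K_D called a binder (default 100)
#' @return data.frame with `variant`, `kd_a5b1_nM`, `kd_avb3_nM`, `label`
#' @export
classify_specificity <- function(affinities_a5b1, affinities_avb3,
                                 fold_threshold = 100, k_max_nM = 100) {
  miss <- c(setdiff(affinities_a5b1$variant, affinities_avb3$variant),
            setdiff(affinities_avb3$variant, affinities_a5b1$variant))
  if (length(miss) > 0) {
    stop("join error: unmatched variant ids: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- merge(affinities_a5b1, affinities_avb3, by = "variant",
             suffixes = c("_a", "_b"))
  binds_a <- m$status_a == "converged" & m$kd_nM_a <= k_max_nM
  binds_b <- m$status_b == "converged" & m$kd_nM_b <= k_max_nM
  fold <- m$kd_nM_b / m$kd_nM_a
  label <- ifelse(!binds_a & !binds_b, "nonbinder",
           ifelse(binds_a & (!binds_b | fold >= fold_threshold),
                  "specific_a5b1", "cross_reactive"))
  data.frame(variant = m$variant, kd_a5b1_nM = m$kd_nM_a,
             kd_avb3_nM = m$kd_nM_b, label = label)
}

#' Enumerate a combination library
#'
#' Full Cartesian product of `{parent residue, substitution(s)}` at every
#' listed position; the parent sequence is always included.  Substitutions
#' identical to the parent residue are dropped with a warning.  With `k`
#' single-option positions the library has `2^k` members.
#'
#' @param beneficial_substitutions data.frame with columns `position`
#'   (1-based) and `aa` (one-letter); several rows may share a position
#' @param parent parent amino-acid sequence (single string)
#' @return character vector of sequences (parent first, then by position
#'   order), deduplicated
#' @export
build_combination_library <- function(beneficial_substitutions, parent) {
  pl <- strsplit(parent, "")[[1]]
  subs <- beneficial_substitutions
  if (nrow(subs) > 0) {
    stopifnot(all(subs$position >= 1), all(subs$position <= length(pl)))
    same <- subs$aa == pl[subs$position]
    if (any(same)) {
      warning("dropping substitutions identical to the parent residue at ",
              "position(s) ", paste(subs$position[same], collapse = ", "))
      subs <- subs[!same, , drop = FALSE]
    }
  }
  if (nrow(subs) == 0) return(parent)
  opts <- lapply(split(subs$aa, subs$position), function(a) unique(a))
  pos <- as.integer(names(opts))
  choices <- lapply(seq_along(pos), function(i) c(pl[pos[i]], opts[[i]]))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  seqs <- apply(grid, 1, function(row) {
    s <- pl; s[pos] <- row; paste(s, collapse = "")
  })
  unique(c(parent, seqs))
}
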