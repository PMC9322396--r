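#' Build a position-specific scoring matrix from an ungapped seed alignment
#'
#' Columns are log-odds (bits) of observing each residue versus a uniform
#' background, with one background pseudocount per column. An `X` column with
#' score 0 makes unknown residues neutral.
#'
#' @param seqs Character vector of equal-length ungapped aligned sequences.
#' @param kind Domain kind label.
#' @param accession Profile accession recorded as metadata.
#' @param threshold_frac Detection threshold as a fraction of the consensus
#'   (maximum attainable) score.
#' @return A list with `kind`, `accession`, `matrix` (L x 21), `threshold`,
#'   `consensus`, `length`.
#' @export
build_profile <- function(seqs, kind, accession = NA_character_,
                          threshold_frac = 0.35) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) abort("seed sequences must be aligned (equal length)")
  n <- length(seqs)
  bg <- 1 / 20
  mat <- matrix(0, nrow = L, ncol = 21, dimnames = list(NULL, c(AA20, "X")))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (a in seq_along(AA20)) {
    cnt <- colSums(chars == AA20[a])
    mat[, a] <- log2(((cnt + bg) / (n + 1)) / bg)
  }
  consensus <- paste(AA20[apply(mat[, 1:20, drop = FALSE], 1, which.max)],
                     collapse = "")
  max_score <- sum(apply(mat[, 1:20, drop = FALSE], 1, max))
  list(kind = kind, accession = accession, matrix = mat,
       threshold = round(threshold_frac * max_score, 2),
       consensus = consensus, length = L)
}

#' The bundled R-protein domain profile library
#'
#' Position-specific scoring matrices for the NB, TIR, Rx-type coiled-coil and
#' RPW8 domains, built from the small synthetic seed alignments shipped with
#' the package. Accession labels record the Pfam families the profiles stand
#' in for (NB: PF00931; CC/Rx-N: PF18052; TIR: PF01582); the RPW8 profile is
#' artifact-defined. These are self-contained substitutes for external
#' profile-HMM scanners, not calibrated Pfam models.
#'
#' @return A named list of profiles (see [build_profile()]).
#' @export
profile_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- system.file("extdata", "profiles", package = "hrpredict")
      read_seed <- function(f) read_fasta(file.path(dir, f), "protein")$seq
      cache <<- list(
        NB = build_profile(read_seed("nb_seed.faa"), "NB", "PF00931"),
        TIR = build_profile(read_seed("tir_seed.faa"), "TIR", "PF01582"),
        CC_RXN = build_profile(read_seed("cc_seed.faa"), "CC_RXN", "PF18052"),
        RPW8 = build_profile(read_seed("rpw8_seed.faa"), "RPW8", "artifact")
      )
    }
    cache
  }
})

aa_index <- function(protein) {
  idx <- match(strsplit(protein, "")[[1]], c(AA20, "X"))
  idx[is.na(idx)] <- 21L  # '*' and ambiguity codes score like X
  idx
}

empty_hits <- function() {
  tibble(kind = character(), start = integer(), end = integer(),
         score = numeric(), repeats = integer())
}

#' Scan a protein with a PSSM profile
#'
#' Ungapped sliding-window log-odds scan; every window scoring at or above the
#' threshold is reported after greedy resolution of overlapping windows into
#' maximal-scoring non-overlapping hits (higher score first, then smaller
#' start).
#'
#' @param protein Protein string.
#' @param profile A profile from [build_profile()].
#' @param threshold Bit-score threshold (default: the profile's own).
#' @return A hits tibble (`kind`, `start`, `end`, `score`, `repeats`),
#'   1-based inclusive protein coordinates. Proteins shorter than the profile
#'   yield an empty tibble.
#' @export
scan_profile <- function(protein, profile, threshold = profile$threshold) {
  L <- profile$length
  idx <- aa_index(protein)
  n <- length(idx)
  if (n < L) return(empty_hits())
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    sc <- sc + unname(profile$matrix[i, idx[seq.int(i, i + nw - 1L)]])
  }
  keep <- which(sc >= threshold)
  if (length(keep) == 0) return(empty_hits())
  cand <- tibble(kind = profile$kind, start = keep, end = keep + L - 1L,
                 score = sc[keep], repeats = NA_integer_)
  greedy_nonoverlap(cand)
}

greedy_nonoverlap <- function(hits) {
  hits <- hits[order(-hits$score, hits$start), ]
  sel <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(sel) == 0 ||
        all(hits$start[i] > hits$end[sel] | hits$end[i] < hits$start[sel])) {
      sel <- c(sel, i)
    }
  }
  out <- hits[sel, ]
  out[order(out$start), ]
}

LRR_CLASS <- c("L", "I", "V", "F")

#' Detect leucine-rich repeat regions
#'
#' Scores the degenerate repeat consensus `LxxLxLxx` (leucine-type residues
#' L/I/V/F at positions 1, 4, 6 and 8) in tiled 8-residue frames. A hit covers
#' at least `min_repeats` consecutive frames, each matching at least 3 of the
#' 4 consensus positions.
#'
#' @param protein Protein string.
#' @param min_repeats Minimum number of consecutive qualifying frames.
#' @return A hits tibble with `repeats` = frame count.
#' @export
detect_lrr <- function(protein, min_repeats = 3L) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < 8L * min_repeats) return(empty_hits())
  is_l <- aa %in% LRR_CLASS
  frame_ok <- function(s) sum(is_l[c(s, s + 3L, s + 5L, s + 7L)]) >= 3L
  hits <- empty_hits()
  for (off in 0:7) {
    starts <- seq.int(1L + off, n - 7L, by = 8L)
    if (length(starts) < min_repeats) next
    ok <- vapply(starts, frame_ok, logical(1))
    r <- rle(ok)
    ends_i <- cumsum(r$lengths)
    begs_i <- ends_i - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_repeats)) {
      s <- starts[begs_i[k]]
      reps <- r$lengths[k]
      hits <- bind_rows(hits, tibble(
        kind = "LRR", start = s, end = s + 8L * reps - 1L,
        score = as.numeric(reps), repeats = as.integer(reps)))
    }
  }
  if (nrow(hits) == 0) return(hits)
  greedy_nonoverlap(hits)
}

# Heptad propensity table for the coiled-coil heuristic: rows are residues,
# columns the heptad registers a-g. Hydrophobic residues are favoured at the
# core positions a/d, charged/polar residues at the flanking e/g positions;
# proline is a strong breaker everywhere.
coils_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- matrix(0.8, nrow = 20, ncol = 7,
                  dimnames = list(AA20, letters[1:7]))
      core <- c(L = 3.0, I = 2.5, M = 2.5, V = 2.0, A = 1.5, F = 1.5)
      flank <- c(E = 2.5, K = 2.2, Q = 2.0, R = 1.8, D = 1.2, A = 1.2)
      face <- c(E = 1.5, K = 1.5, Q = 1.5, R = 1.5, A = 1.5, S = 1.2,
                N = 1.2, D = 1.2, L = 1.2, T = 1.0)
      m[names(core), c("a", "d")] <- core
      m[names(flank), c("e", "g")] <- flank
      m[names(face), c("b", "c", "f")] <- face
      m["P", ] <- 0.05
      m["G", ] <- 0.3
      cache <<- m
    }
    cache
  }
})

#' Detect coiled-coil regions with a sliding heptad-propensity window
#'
#' Each window is scored, for each of the seven heptad registers, by the
#' geometric mean of the bundled residue propensities; the best register's
#' mean is mapped to a probability with a logistic curve. Contiguous windows
#' above `prob_threshold` are merged into one hit (kind `CC_COILS`).
#'
#' @param protein Protein string.
#' @param window Window width in residues (three heptads by default).
#' @param prob_threshold Probability cut-off.
#' @return A hits tibble; `score` is the peak window probability.
#' @export
detect_coiled_coil <- function(protein, window = 21L, prob_threshold = 0.5) {
  tab <- coils_table()
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  if (n < window) return(empty_hits())
  ai <- match(aa, AA20)
  logp <- matrix(log(0.3), nrow = n, ncol = 7)  # unknown residues: mild breaker
  known <- !is.na(ai)
  for (r in 1:7) logp[known, r] <- log(tab[ai[known], r])
  nw <- n - window + 1L
  best <- rep(-Inf, nw)
  for (reg in 0:6) {
    # register `reg`: position p occupies heptad slot (p + reg) mod 7
    slot <- ((seq_len(n) - 1L + reg) %% 7L) + 1L
    v <- logp[cbind(seq_len(n), slot)]
    cs <- c(0, cumsum(v))
    wmean <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
    best <- pmax(best, wmean)
  }
  prob <- plogis(6 * (best - log(1.5)))
  above <- prob > prob_threshold
  if (!any(above)) return(empty_hits())
  r <- rle(above)
  ends_i <- cumsum(r$lengths)
  begs_i <- ends_i - r$lengths + 1L
  out <- empty_hits()
  for (k in which(r$values)) {
    s <- begs_i[k]; e <- ends_i[k]
    out <- bind_rows(out, tibble(
      kind = "CC_COILS", start = s, end = e + window - 1L,
      score = max(prob[s:e]), repeats = NA_integer_))
  }
  out
}

#' Scan a protein with the full domain battery
#'
#' Runs all PSSM profiles, the LRR repeat detector and the coiled-coil
#' heuristic.
#'
#' @param protein Protein string.
#' @param lib Profile library (default: bundled).
#' @param min_repeats,cc_window,cc_threshold Detector parameters.
#' @return A hits tibble sorted by start.
#' @export
annotate_domains <- function(protein, lib = profile_library(),
                             min_repeats = 3L, cc_window = 21L,
                             cc_threshold = 0.5) {
  hits <- bind_rows(
    bind_rows(map(lib, ~ scan_profile(protein, .x))),
    detect_lrr(protein, min_repeats),
    detect_coiled_coil(protein, cc_window, cc_threshold)
  )
  hits[order(hits$start), ]
}

#' Assemble an ordered domain architecture from hits
#'
#' Overlapping hits of the same kind are merged (higher score kept, then
#' smaller start); `CC_RXN` and `CC_COILS` evidence collapses to a single `CC`
#' token positioned at the earliest CC evidence. Tokens are the distinct kinds
#' ordered by first start.
#'
#' @param hits A hits tibble for one protein.
#' @return List with `tokens` (ordered kinds), `class_label`, `full_length`
#'   and the merged `hits`.
#' @export
build_architecture <- function(hits) {
  if (nrow(hits) == 0) {
    return(list(tokens = character(), class_label = "none",
                full_length = FALSE, hits = hits))
  }
  # heuristic coiled-coil evidence contained inside another domain's hit is
  # not an independent N-terminal domain (helices inside NB/TIR/LRR folds)
  cc <- hits$kind == "CC_COILS"
  if (any(cc) && any(!cc)) {
    nested <- vapply(which(cc), function(i) {
      any(hits$start[!cc] <= hits$start[i] & hits$end[!cc] >= hits$end[i])
    }, logical(1))
    if (any(nested)) hits <- hits[-which(cc)[nested], , drop = FALSE]
    if (nrow(hits) == 0) {
      return(list(tokens = character(), class_label = "none",
                  full_length = FALSE, hits = hits))
    }
  }
  merged <- hits |>
    group_by(.data$kind) |>
    dplyr::group_modify(~ greedy_nonoverlap(.x)) |>
    ungroup()
  merged$kind[merged$kind %in% c("CC_RXN", "CC_COILS")] <- "CC"
  tok <- merged |>
    group_by(.data$kind) |>
    summarise(first = min(.data$start), .groups = "drop") |>
    arrange(.data$first)
  tokens <- tok$kind
  label <- classify_architecture(tokens)
  list(tokens = tokens, class_label = label,
       full_length = label %in% c("CNL", "TNL", "RNL", "NL"),
       hits = merged[order(merged$start), ])
}

#' Classify an ordered domain-kind list into NB-LRR classes
#'
#' Full-length architectures (NB present, LRR present, NB before LRR) are
#' labelled `CNL`, `TNL` or `RNL` according to the earliest of CC, TIR or RPW8
#' preceding the NB, or `NL` when no N-terminal domain is detected. Anything
#' else is a partial architecture labelled by its ordered kinds joined with
#' `-` (CC evidence kinds count as `CC`); an empty list is `"none"`.
#'
#' @param tokens Character vector of ordered domain kinds.
#' @return The class label string.
#' @export
classify_architecture <- function(tokens) {
  tokens[tokens %in% c("CC_RXN", "CC_COILS")] <- "CC"
  tokens <- unique(tokens)
  if (length(tokens) == 0) return("none")
  inb <- match("NB", tokens)
  ilrr <- match("LRR", tokens)
  if (!is.na(inb) && !is.na(ilrr) && inb < ilrr) {
    nterm <- tokens[seq_len(inb - 1L)]
    nterm <- nterm[nterm %in% c("CC", "TIR", "RPW8")]
    if (length(nterm) == 0) return("NL")
    return(switch(nterm[1], CC = "CNL", TIR = "TNL", RPW8 = "RNL"))
  }
  paste(tokens, collapse = "-")
}

#' Write domain hits to TSV
#' @param hits Hits tibble with a `protein_id` column.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
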