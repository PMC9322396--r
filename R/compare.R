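# Comparison of two gene-model sets (coding-base overlap, intron-exon
# structure identity) and of two proteomes (reciprocal best hits with a
# normalized confidence), mirroring how re-annotations are benchmarked
# against prior annotations.

exon_ranges <- function(model_row) {
  ex <- model_row$exons[[1]]
  IRanges::IRanges(start = ex[, "start"], end = ex[, "end"])
}

#' Match two gene-model sets by coding overlap
#'
#' Same-sequence, same-strand pairs with at least 1 bp of CDS overlap are
#' reported with the fraction of shared coding bases (intersection over union
#' of coding bases) and a flag for identical intron-exon structure (identical
#' exon boundary sets).
#'
#' @param set_a,set_b Gene-model tibbles on the same assembly coordinates.
#' @return List with `matches` (tibble: `id_a`, `id_b`, `overlap_bp`,
#'   `cds_overlap_fraction`, `structure_identical`), `unmatched_a`,
#'   `unmatched_b` (character ids), and `aggregate` (shared and union coding
#'   bases over all matched pairs and their percentage).
#' @export
match_models <- function(set_a, set_b) {
  matches <- tibble(id_a = character(), id_b = character(),
                    overlap_bp = integer(), cds_overlap_fraction = numeric(),
                    structure_identical = logical())
  sa <- if (nrow(set_a)) model_span(set_a) else tibble(start = integer(), end = integer())
  sb <- if (nrow(set_b)) model_span(set_b) else tibble(start = integer(), end = integer())
  for (i in seq_len(nrow(set_a))) {
    cand <- which(set_b$seqid == set_a$seqid[i] & set_b$strand == set_a$strand[i] &
                    sb$start <= sa$end[i] & sb$end >= sa$start[i])
    for (j in cand) {
      ra <- exon_ranges(set_a[i, ]); rb <- exon_ranges(set_b[j, ])
      shared <- sum(IRanges::width(IRanges::intersect(ra, rb)))
      if (shared < 1) next
      uni <- sum(IRanges::width(IRanges::union(ra, rb)))
      ident <- nrow(set_a$exons[[i]]) == nrow(set_b$exons[[j]]) &&
        all(set_a$exons[[i]][, c("start", "end")] ==
              set_b$exons[[j]][, c("start", "end")])
      matches <- bind_rows(matches, tibble(
        id_a = set_a$id[i], id_b = set_b$id[j],
        overlap_bp = shared, cds_overlap_fraction = shared / uni,
        structure_identical = ident))
    }
  }
  shared_tot <- sum(matches$overlap_bp)
  union_tot <- if (nrow(matches)) {
    sum(map_dbl(seq_len(nrow(matches)), function(k) {
      i <- match(matches$id_a[k], set_a$id); j <- match(matches$id_b[k], set_b$id)
      sum(IRanges::width(IRanges::union(exon_ranges(set_a[i, ]),
                                        exon_ranges(set_b[j, ]))))
    }))
  } else 0
  list(
    matches = matches,
    unmatched_a = setdiff(set_a$id, matches$id_a),
    unmatched_b = setdiff(set_b$id, matches$id_b),
    aggregate = list(
      shared_bases = shared_tot, union_bases = union_tot,
      shared_cds_percent = if (union_tot > 0) 100 * shared_tot / union_tot else NA_real_,
      structure_identical_pairs = sum(matches$structure_identical))
  )
}

self_score <- function(protein) {
  B <- blosum62()
  aa <- strsplit(protein, "")[[1]]
  aa[!aa %in% rownames(B)] <- "X"
  sum(B[cbind(aa, aa)])
}

#' Reciprocal-best-hit ortholog pairing between two proteomes
#'
#' All-vs-all best ungapped BLOSUM62 local scores (the HSP machinery applied
#' protein-vs-protein) define mutual best hits; a pair is emitted when its
#' normalized confidence (score divided by the self-score of the smaller
#' protein) reaches `base_cutoff * confidence_threshold`. The confidence is a
#' package-defined normalization and is not numerically comparable to
#' external orthology tools' internal scores.
#'
#' @param proteome_a,proteome_b Sequence tibbles (`id`, `seq`).
#' @param confidence_threshold Scaling of the confidence cut-off (default 1).
#' @param base_cutoff Base confidence cut-off (default 0.3).
#' @param k,xdrop Seeding parameters.
#' @return Tibble of pairs (`id_a`, `id_b`, `score`, `confidence`).
#' @export
rbh_pairs <- function(proteome_a, proteome_b, confidence_threshold = 1,
                      base_cutoff = 0.3, k = 4L, xdrop = 20L) {
  if (nrow(proteome_a) == 0 || nrow(proteome_b) == 0)
    abort("both proteomes must be non-empty")
  na <- nrow(proteome_a); nb <- nrow(proteome_b)
  S <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    h <- cpp_seed_extend(proteome_a$seq[i], proteome_b$seq[j], blosum62(),
                         k, xdrop, 1L)
    if (nrow(h)) S[i, j] <- max(h$score)
  }
  best_b_for_a <- apply(S, 1, which.max)
  best_a_for_b <- apply(S, 2, which.max)
  out <- tibble(id_a = character(), id_b = character(),
                score = numeric(), confidence = numeric())
  cutoff <- base_cutoff * confidence_threshold
  for (i in seq_len(na)) {
    j <- best_b_for_a[i]
    if (S[i, j] <= 0 || best_a_for_b[j] != i) next
    smaller <- if (nchar(proteome_a$seq[i]) <= nchar(proteome_b$seq[j]))
      proteome_a$seq[i] else proteome_b$seq[j]
    conf <- S[i, j] / self_score(smaller)
    if (conf >= cutoff) {
      out <- bind_rows(out, tibble(id_a = proteome_a$id[i],
                                   id_b = proteome_b$id[j],
                                   score = S[i, j], confidence = conf))
    }
  }
  out
}
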