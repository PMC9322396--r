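# Full-length homology gene prediction on genomic DNA: translated k-mer
# seeding with X-drop extension (HSPs), colinear chaining, splice-aware codon
# alignment and Karlin-Altschul E-values.

#' Karlin-Altschul parameters for ungapped BLOSUM62 scoring
#'
#' Bundled defaults (`lambda` in nats per half-bit score unit, `K`
#' dimensionless). They are validated empirically in the test suite against
#' the score distribution of shuffled sequences rather than asserted exactly.
#'
#' @return List with `lambda` and `K`.
#' @export
karlin_params <- function() list(lambda = 0.3176, K = 0.134)

#' E-value of an alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}}; strictly decreasing in `S` for fixed
#' search-space size.
#'
#' @param S Alignment score (BLOSUM62 half-bit units).
#' @param m Query length (residues).
#' @param n Search-space size (nucleotides; both strands for genome searches).
#' @param params Karlin parameters, see [karlin_params()].
#' @return Numeric E-value.
#' @export
hsp_evalue <- function(S, m, n, params = karlin_params()) {
  params$K * m * n * exp(-params$lambda * S)
}

translate_frames <- function(dna) {
  n <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else revcomp(dna)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      aa <- if (ncod > 0) {
        as.character(Biostrings::translate(
          Biostrings::DNAString(substring(s, off + 1L, off + 3L * ncod)),
          if.fuzzy.codon = "X", no.init.codon = TRUE))
      } else ""
      out[[paste0(strand, off)]] <- list(strand = strand, off = off, aa = aa)
    }
  }
  out
}

empty_hsps <- function() {
  tibble(qstart = integer(), qend = integer(), tstart = integer(),
         tend = integer(), gstart = integer(), gend = integer(),
         strand = character(), frame = integer(), score = integer())
}

#' Seed and extend a protein query against all six frames of a DNA sequence
#'
#' Exact amino-acid k-mer matches between the query and the six translated
#' frames seed ungapped extensions under BLOSUM62 with X-drop termination.
#' HSPs below `min_score` are discarded; duplicate seeds on an already
#' extended diagonal are merged.
#'
#' @param query Protein string.
#' @param dna Genomic DNA string.
#' @param k Seed word size (amino acids).
#' @param xdrop X-drop threshold (score units).
#' @param min_score Minimum HSP score.
#' @return HSP tibble: query coords (`qstart`,`qend`, residues), subject
#'   coords both transcript-oriented (`tstart`,`tend`) and genome-forward
#'   (`gstart`,`gend`, nucleotides), `strand`, `frame`, `score`.
#' @export
seed_and_extend <- function(query, dna, k = 4L, xdrop = 20L, min_score = 50L) {
  n <- nchar(dna)
  frames <- translate_frames(dna)
  out <- list()
  for (f in frames) {
    if (nchar(f$aa) < k) next
    h <- cpp_seed_extend(query, f$aa, blosum62(), k, xdrop, min_score)
    if (nrow(h) == 0) next
    tstart <- f$off + 3L * (h$sstart - 1L) + 1L
    tend <- f$off + 3L * h$send
    if (f$strand == "+") {
      gstart <- tstart; gend <- tend
    } else {
      gstart <- n - tend + 1L; gend <- n - tstart + 1L
    }
    out[[length(out) + 1L]] <- tibble(
      qstart = h$qstart, qend = h$qend, tstart = tstart, tend = tend,
      gstart = gstart, gend = gend, strand = f$strand, frame = f$off,
      score = as.integer(h$score))
  }
  if (length(out) == 0) return(empty_hsps())
  arrange(bind_rows(out), .data$strand, .data$tstart)
}

#' Chain colinear HSPs into gene-locus candidates
#'
#' Per strand, maximum-score colinear chains by dynamic programming over HSPs
#' sorted by transcript-oriented subject start. Joins require query and
#' subject order consistency, a subject gap of at most `max_intron`, and a
#' chain footprint of at most `max_span`. Chains are extracted greedily (best
#' first, members removed) and returned sorted by score, descending.
#'
#' @param hsps HSP tibble from [seed_and_extend()] for one query/sequence pair.
#' @param max_span Maximum genomic footprint of a chain (bp).
#' @param max_intron Maximum subject gap between chained HSPs (bp).
#' @param min_chain_score Minimum chain score to report.
#' @return Tibble of chains with `strand`, `score`, `tstart`, `tend`,
#'   `gstart`, `gend` and the member HSPs as a list-column `hsps`.
#' @export
chain_hsps <- function(hsps, max_span = 20000L, max_intron = 10000L,
                       min_chain_score = 50L) {
  chains <- list()
  for (st in unique(hsps$strand)) {
    h <- hsps[hsps$strand == st, ]
    h <- h[order(h$tstart, h$qstart), ]
    active <- rep(TRUE, nrow(h))
    while (any(active)) {
      ai <- which(active)
      hh <- h[ai, ]
      nn <- nrow(hh)
      sc <- as.numeric(hh$score)
      par <- rep(NA_integer_, nn)
      cstart <- hh$tstart
      if (nn > 1) {
        for (j in 2:nn) {
          ok <- which(hh$qstart[1:(j - 1)] < hh$qstart[j] &
                      hh$qend[1:(j - 1)] < hh$qend[j] &
                      hh$tstart[1:(j - 1)] < hh$tstart[j] &
                      hh$tend[1:(j - 1)] < hh$tend[j] &
                      hh$tstart[j] - hh$tend[1:(j - 1)] - 1L <= max_intron &
                      hh$tend[j] - cstart[1:(j - 1)] + 1L <= max_span)
          if (length(ok)) {
            bi <- ok[which.max(sc[ok])]
            if (sc[bi] > 0) {
              sc[j] <- sc[j] + sc[bi]
              par[j] <- bi
              cstart[j] <- cstart[bi]
            }
          }
        }
      }
      bj <- which.max(sc)
      if (sc[bj] < min_chain_score) break
      members <- integer(0)
      cur <- bj
      while (!is.na(cur)) { members <- c(cur, members); cur <- par[cur] }
      mh <- hh[members, ]
      chains[[length(chains) + 1L]] <- tibble(
        strand = st, score = sc[bj],
        tstart = min(mh$tstart), tend = max(mh$tend),
        gstart = min(mh$gstart), gend = max(mh$gend),
        hsps = list(mh))
      active[ai[members]] <- FALSE
    }
  }
  if (length(chains) == 0) {
    return(tibble(strand = character(), score = numeric(), tstart = integer(),
                  tend = integer(), gstart = integer(), gend = integer(),
                  hsps = list()))
  }
  arrange(bind_rows(chains), desc(.data$score))
}

#' Splice-aware codon alignment of a query protein within a chain's window
#'
#' Codon-level local dynamic programming of the protein against the genomic
#' window covering the chain footprint plus flanks. Introns are permitted only
#' between codons (phase 0) at canonical `GT..AG` boundaries with lengths in
#' `[min_intron, max_intron]`; gaps cost `gap_open`/`gap_extend` and an intron
#' a flat, length-independent `intron_cost` (all in BLOSUM62 half-bit units).
#' The default intron cost (10 bits) is deliberately larger than a couple of
#' mismatches, so the aligner cannot skip mutation clusters or hop between
#' tandem paralogs through spurious mini-introns.
#'
#' @param query Protein string.
#' @param dna Genomic DNA string (forward orientation).
#' @param chain One row of the [chain_hsps()] output.
#' @param seqid Sequence name for the resulting model.
#' @param id Model identifier.
#' @param flank Window flank (bp) on each side of the chain footprint.
#' @param gap_open,gap_extend,intron_cost,min_intron,max_intron DP parameters.
#' @return A one-row gene-model tibble with `score`, `qstart`, `qend` and
#'   alignment `ops` carried as extra columns, or `NULL` when no
#'   positive-scoring alignment exists in the window.
#' @export
spliced_align <- function(query, dna, chain, seqid = "seq", id = "cand",
                          flank = 2000L, gap_open = 11L, gap_extend = 1L,
                          intron_cost = 20L, min_intron = 40L,
                          max_intron = 10000L) {
  n <- nchar(dna)
  ts <- max(1L, chain$tstart - flank)
  te <- min(n, chain$tend + flank)
  s <- if (chain$strand == "+") dna else revcomp(dna)
  win <- substring(s, ts, te)
  res <- cpp_spliced_align(query, win, blosum62(), gap_open, gap_extend,
                           intron_cost, min_intron, max_intron)
  if (res$score <= 0 || nrow(res$exons) == 0) return(NULL)
  ex_t <- res$exons + (ts - 1L)  # transcript-oriented coords
  # include a directly following stop codon in the CDS, as annotations do
  last_end <- ex_t[nrow(ex_t), "end"]
  if (last_end + 3L <= n &&
      substring(s, last_end + 1L, last_end + 3L) %in% c("TAA", "TAG", "TGA")) {
    ex_t[nrow(ex_t), "end"] <- last_end + 3L
  }
  if (chain$strand == "+") {
    ex <- cbind(start = ex_t[, "start"], end = ex_t[, "end"])
  } else {
    ex <- cbind(start = n - ex_t[, "end"] + 1L, end = n - ex_t[, "start"] + 1L)
  }
  model <- gene_models(id = id, seqid = seqid, strand = chain$strand,
                       exons = list(new_exon_matrix(ex[, "start"], ex[, "end"])),
                       score = res$score)
  model$qstart <- res$qstart
  model$qend <- res$qend
  model$ops <- list(res$ops)
  model
}

# Iterated alignment within one transcript-oriented window: align, accept the
# best model, then recurse into the sub-windows left and right of it, so that
# every member of a tandem gene cluster is modelled, not only the best copy.
# Sub-windows are only explored while they still contain HSP evidence.
carve_window <- function(query, s_oriented, ts, te, config, evidence,
                         max_models = 12L, min_width = 600L) {
  out <- list()
  stack <- list(c(ts, te))
  has_evidence <- function(a, b) {
    any(pmin(evidence[, 2], b) - pmax(evidence[, 1], a) + 1L >= 60L)
  }
  while (length(stack) && length(out) < max_models) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- iv[1]; b <- iv[2]
    if (b - a + 1L < min_width || !has_evidence(a, b)) next
    res <- cpp_spliced_align(query, substring(s_oriented, a, b), blosum62(),
                             config$gap_open, config$gap_extend,
                             config$intron_cost, config$min_intron,
                             config$max_intron_align)
    if (res$score < config$min_hsp_score || nrow(res$exons) == 0) next
    ex_t <- res$exons + (a - 1L)
    last_end <- ex_t[nrow(ex_t), "end"]
    if (last_end + 3L <= nchar(s_oriented) &&
        substring(s_oriented, last_end + 1L, last_end + 3L) %in%
          c("TAA", "TAG", "TGA")) {
      ex_t[nrow(ex_t), "end"] <- last_end + 3L
    }
    out[[length(out) + 1L]] <- list(score = res$score, qstart = res$qstart,
                                    qend = res$qend, exons = ex_t,
                                    ops = res$ops)
    stack[[length(stack) + 1L]] <- c(a, min(ex_t[, "start"]) - 30L)
    stack[[length(stack) + 1L]] <- c(max(ex_t[, "end"]) + 30L, b)
  }
  out
}

# Candidate gene models for a set of queries against one genome. Per strand,
# chain footprints of all queries are clustered into loci. Each locus is
# carved with the locus's best query; evidence left uncovered (a gene without
# homology to that query) is re-carved with its own best query; finally the
# next-best queries re-align inside each carved model window so that the
# overlap filter can choose the longest encoded protein among queries.
homology_candidates <- function(queries, genome, config) {
  genome <- as_genome(genome)
  n_total <- 2 * sum(vapply(genome, nchar, 0L))
  cands <- list()
  ccount <- 0L
  add_cand <- function(md, qn, seqid, strand, n) {
    ex_t <- md$exons
    ex <- if (strand == "+") {
      cbind(start = ex_t[, "start"], end = ex_t[, "end"])
    } else {
      cbind(start = n - ex_t[, "end"] + 1L, end = n - ex_t[, "start"] + 1L)
    }
    ccount <<- ccount + 1L
    cand <- gene_models(
      id = sprintf("%s|%s|c%03d", qn, seqid, ccount), seqid = seqid,
      strand = strand,
      exons = list(new_exon_matrix(ex[, "start"], ex[, "end"])),
      score = md$score)
    cand$query <- qn
    cand$qstart <- md$qstart; cand$qend <- md$qend
    cand$ops <- list(md$ops)
    cand$S <- md$score
    cand$evalue <- hsp_evalue(md$score, nchar(queries$seq[match(qn, queries$id)]),
                              n_total, config$karlin)
    cands[[length(cands) + 1L]] <<- cand
  }
  refine_one <- function(qseq, s_oriented, a, b, config) {
    res <- cpp_spliced_align(qseq, substring(s_oriented, a, b), blosum62(),
                             config$gap_open, config$gap_extend,
                             config$intron_cost, config$min_intron,
                             config$max_intron_align)
    if (res$score < config$min_hsp_score || nrow(res$exons) == 0) return(NULL)
    ex_t <- res$exons + (a - 1L)
    last_end <- ex_t[nrow(ex_t), "end"]
    if (last_end + 3L <= nchar(s_oriented) &&
        substring(s_oriented, last_end + 1L, last_end + 3L) %in%
          c("TAA", "TAG", "TGA")) {
      ex_t[nrow(ex_t), "end"] <- last_end + 3L
    }
    list(score = res$score, qstart = res$qstart, qend = res$qend,
         exons = ex_t, ops = res$ops)
  }
  for (seqid in names(genome)) {
    dna <- genome[[seqid]]
    n <- nchar(dna)
    chains <- list()
    for (qi in seq_len(nrow(queries))) {
      hsps <- seed_and_extend(queries$seq[qi], dna, k = config$seed_k,
                              xdrop = config$xdrop,
                              min_score = config$min_hsp_score)
      if (nrow(hsps) == 0) next
      ch <- chain_hsps(hsps, max_span = config$max_span_bp,
                       max_intron = config$max_intron,
                       min_chain_score = config$min_hsp_score)
      if (nrow(ch) == 0) next
      ch$query <- queries$id[qi]
      chains[[length(chains) + 1L]] <- ch
    }
    if (length(chains) == 0) next
    pooled <- bind_rows(chains) |>
      group_by(.data$strand) |>
      mutate(locus = cluster_intervals(.data$tstart, .data$tend)) |>
      ungroup()
    loci <- pooled |>
      group_by(.data$strand, .data$locus) |>
      summarise(ts = min(.data$tstart), te = max(.data$tend), .groups = "drop")
    for (li in seq_len(nrow(loci))) {
      lc <- loci[li, ]
      sub <- pooled[pooled$strand == lc$strand & pooled$locus == lc$locus, ]
      s_oriented <- if (lc$strand == "+") dna else revcomp(dna)
      ts <- max(1L, lc$ts - config$align_flank)
      te <- min(n, lc$te + config$align_flank)
      evidence <- cbind(sub$tstart, sub$tend)
      q_rank <- sub |>
        group_by(.data$query) |>
        summarise(best = max(.data$score), .groups = "drop") |>
        arrange(desc(.data$best))
      remaining <- sub
      locus_models <- list()
      for (round in seq_len(4L)) {
        if (nrow(remaining) == 0) break
        qn <- remaining |>
          group_by(.data$query) |>
          summarise(best = max(.data$score), .groups = "drop") |>
          arrange(desc(.data$best)) |>
          pull(.data$query) |>
          head(1)
        qseq <- queries$seq[match(qn, queries$id)]
        models <- carve_window(qseq, s_oriented, ts, te, config,
                               evidence = cbind(remaining$tstart, remaining$tend))
        if (length(models) == 0) break
        for (md in models) {
          add_cand(md, qn, seqid, lc$strand, n)
          locus_models[[length(locus_models) + 1L]] <- md
        }
        spans <- do.call(rbind, map(locus_models, function(md)
          c(min(md$exons[, "start"]), max(md$exons[, "end"]))))
        covered <- vapply(seq_len(nrow(remaining)), function(i) {
          ov <- pmin(spans[, 2], remaining$tend[i]) -
            pmax(spans[, 1], remaining$tstart[i]) + 1L
          any(ov >= 0.5 * (remaining$tend[i] - remaining$tstart[i] + 1L))
        }, logical(1))
        remaining <- remaining[!covered, ]
      }
      # next-best queries compete inside each carved model window
      if (length(locus_models) && config$max_queries_per_locus > 1L) {
        used_q <- unique(map_chr(cands[length(cands) - seq_along(locus_models) + 1L],
                                 ~ .x$query[1]))
        others <- setdiff(q_rank$query, used_q)
        others <- head(others, config$max_queries_per_locus - 1L)
        for (md in locus_models) {
          a <- max(1L, min(md$exons[, "start"]) - 300L)
          b <- min(n, max(md$exons[, "end"]) + 300L)
          for (qn2 in others) {
            qseq2 <- queries$seq[match(qn2, queries$id)]
            md2 <- refine_one(qseq2, s_oriented, a, b, config)
            if (!is.null(md2)) add_cand(md2, qn2, seqid, lc$strand, n)
          }
        }
      }
    }
  }
  if (length(cands) == 0) {
    out <- gene_models(character(), character(), character(), list())
    out$query <- character(); out$S <- numeric(); out$evalue <- numeric()
    return(out)
  }
  out <- bind_rows(cands)
  out[out$evalue <= config$evalue_cutoff, ]
}

cluster_intervals <- function(start, end) {
  # single-linkage clustering of intervals overlapping by >= 1 bp
  o <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L; cur_end <- -Inf
  for (i in o) {
    if (start[i] > cur_end) cur <- cur + 1L
    cl[i] <- cur
    cur_end <- max(cur_end, end[i])
  }
  cl
}

#' Predict homologous gene models of a query protein in a genome
#'
#' Seeds and chains HSPs, clusters chain footprints into loci, and runs
#' iterated splice-aware alignment in each locus window (align, accept, mask,
#' recurse into the flanks) so that every tandem copy is modelled. Candidates
#' are scored and filtered at the configured E-value cut-off (default 0.01)
#' with \eqn{E = K m n e^{-\lambda S}}, where `m` is the query length and
#' `n` the total genome length counted on both strands.
#'
#' @param query Named character scalar (protein) or a one-row sequence tibble.
#' @param genome Genome as a named character vector or [read_fasta()] tibble.
#' @param config Pipeline configuration, see [hrp_config()].
#' @return Gene-model tibble of candidates with `query`, `S` (alignment
#'   score), `evalue`, sorted by E-value ascending.
#' @export
predict_homologs <- function(query, genome, config = hrp_config()) {
  if (is.data.frame(query)) {
    queries <- query[, c("id", "seq")]
  } else {
    queries <- tibble(id = names(query) %||% "query", seq = unname(query))
  }
  out <- homology_candidates(queries, genome, config)
  out[order(out$evalue), ]
}
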