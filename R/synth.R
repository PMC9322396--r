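# Synthetic genomes, proteomes and deliberately defective annotations with
# known truth: clustered intron-containing NB-LRR genes, diverged paralogs,
# transposon-like decoy ORFs and the annotation failure modes (omitted,
# fused, split, weakened models) that full-length homology prediction is
# designed to overcome.

# Conserved NB anchors (P-loop, kinase-2, GLPL) are never mutated when a
# gene is "weakened": the weakening removes profile-level evidence while the
# short motifs that EM discovery finds stay intact.
nb_anchor_ranges <- function() {
  anchors <- c("GGIGKTT", "FLIVLDDVW", "CGGLPLA")
  map(anchors, function(a) {
    p <- regexpr(a, NB_CONSENSUS, fixed = TRUE)[1]
    c(p, p + nchar(a) - 1L)
  })
}

class_blocks <- function(class_label) {
  full <- list(CNL = c("CC", "NB", "LRR"), TNL = c("TIR", "NB", "LRR"),
               RNL = c("RPW8", "NB", "LRR"), NL = c("NB", "LRR"))
  if (class_label %in% names(full)) return(full[[class_label]])
  toks <- strsplit(class_label, "-", fixed = TRUE)[[1]]
  ok <- toks %in% c("CC", "TIR", "RPW8", "NB", "LRR")
  if (!all(ok) || length(toks) == 0)
    abort(sprintf("unknown class label '%s'", class_label))
  toks
}

mutate_positions <- function(aa, pos) {
  for (p in pos) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  aa
}

#' Generate an R-protein of a given class and identity
#'
#' Proteins are assembled from the bundled consensus blocks (CC/TIR/RPW8,
#' a 200-aa NB block and 12 LRR repeats) with random point substitutions down
#' to the target identity. The loop is closed against the domain scanner: the
#' generated protein is guaranteed to classify as `class_label`, otherwise
#' mutation sets are resampled and eventually an error is raised (identity
#' too low to preserve the class). Uses the current RNG state.
#'
#' @param class_label `"CNL"`, `"TNL"`, `"RNL"`, `"NL"` or a partial label
#'   such as `"NB"` or `"TIR-NB"`.
#' @param identity Target sequence identity to the consensus, in (0.5, 1].
#' @param lib Profile library used for the closed-loop check.
#' @param max_tries Resampling attempts before giving up.
#' @return List with `protein` and `domains` (tibble `kind`, `start`, `end`
#'   in protein coordinates).
#' @export
generate_rgene <- function(class_label, identity = 1, lib = profile_library(),
                           max_tries = 40L) {
  if (identity <= 0.5 || identity > 1)
    abort("identity must be in (0.5, 1]")
  blocks <- class_blocks(class_label)
  parts <- c(list(M = "M"), setNames(map(blocks, consensus_block), blocks))
  # linkers between consecutive domains
  assembled <- "M"
  domains <- tibble(kind = character(), start = integer(), end = integer())
  for (b in blocks) {
    if (b == "NB" && nchar(assembled) > 1) assembled <- paste0(assembled, LINKER_NT_NB)
    if (b == "LRR") assembled <- paste0(assembled, LINKER_NB_LRR)
    s <- nchar(assembled) + 1L
    assembled <- paste0(assembled, consensus_block(b))
    domains <- bind_rows(domains, tibble(kind = b, start = s,
                                         end = nchar(assembled)))
  }
  n <- nchar(assembled)
  n_mut <- round((1 - identity) * n)
  for (try in seq_len(max_tries)) {
    aa <- strsplit(assembled, "")[[1]]
    if (n_mut > 0) aa <- mutate_positions(aa, sample(n, n_mut))
    protein <- paste(aa, collapse = "")
    arch <- build_architecture(annotate_domains(protein, lib))
    if (arch$class_label == class_label)
      return(list(protein = protein, domains = domains))
  }
  abort(sprintf("identity %.2f too low to preserve class '%s'",
                identity, class_label))
}

#' Generate a transposon-like decoy protein
#'
#' A reverse-transcriptase-like ORF with a composition depleted in the
#' leucine-type and coiled-coil core residues, so that it never classifies as
#' a full-length R-protein. Uses the current RNG state.
#'
#' @param len Protein length.
#' @return Protein string.
#' @export
te_decoy_protein <- function(len = 250L) {
  w <- setNames(rep(1, 20), AA20)
  w[c("L", "I", "V", "F", "M", "A")] <- 0.05
  w[c("P", "G", "S", "T", "E", "D", "K", "R", "N", "Q")] <- 1.6
  paste(sample(AA20, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

#' Reverse-translate a protein with random synonymous codons
#'
#' Appends a TAA stop. Uses the current RNG state.
#'
#' @param protein Protein string (internal `*` become stop codons).
#' @return CDS string.
#' @export
reverse_translate <- function(protein) {
  tab <- codon_table()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) opts <- tab[["X"]] %||% "NNN"
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Split a CDS into exons with phase-0 GT..AG introns; returns the genomic
# (transcript-layout) gene sequence plus exon offsets within it.
build_gene_structure <- function(cds, n_introns, intron_range = c(40L, 2000L)) {
  ncod <- nchar(cds) %/% 3L
  stopifnot(nchar(cds) %% 3L == 0L, ncod > 22L)
  cuts <- sort(sample(seq.int(10L, ncod - 10L), n_introns))
  bounds <- c(0L, cuts, ncod) * 3L
  pieces <- substring(cds, bounds[-length(bounds)] + 1L, bounds[-1])
  introns <- map_chr(seq_len(n_introns), function(i) {
    len <- sample(seq.int(intron_range[1], intron_range[2]), 1L)
    paste0("GT", random_dna(len - 4L), "AG")
  })
  seq <- ""
  exons <- tibble(start = integer(), end = integer())
  for (i in seq_along(pieces)) {
    s <- nchar(seq) + 1L
    seq <- paste0(seq, pieces[i])
    exons <- bind_rows(exons, tibble(start = s, end = nchar(seq)))
    if (i <= length(introns)) seq <- paste0(seq, introns[i])
  }
  list(seq = seq, exons = exons)
}

local_to_genomic <- function(exons, g0, L, strand) {
  if (strand == "+") {
    cbind(start = g0 + exons$start - 1L, end = g0 + exons$end - 1L)
  } else {
    m <- cbind(start = g0 + (L - exons$end), end = g0 + (L - exons$start))
    m[order(m[, "start"]), , drop = FALSE]
  }
}

#' Specification for a synthetic genome
#'
#' @param genome_length Total length (bp).
#' @param n_genes Number of implanted R-genes.
#' @param class_probs Probabilities of CNL/TNL/RNL for implanted genes.
#' @param identity_range Identity of each gene to the consensus blocks.
#' @param cluster_sizes Candidate tandem-cluster sizes (sampled).
#' @param intra_gap_range Distance between genes within a cluster (bp).
#' @param intron_count_range,intron_length_range Intron structure.
#' @param n_te Number of transposon-like decoy ORFs (also annotated).
#' @param n_omitted,n_fused,n_split,n_weakened Annotation defects.
#' @param gc GC content of the background DNA.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(genome_length = 500000L, n_genes = 30L,
                       class_probs = c(CNL = 0.8, TNL = 0.15, RNL = 0.05),
                       identity_range = c(0.85, 0.95),
                       cluster_sizes = 1:5,
                       intra_gap_range = c(1000L, 5000L),
                       intron_count_range = 1:3,
                       intron_length_range = c(40L, 2000L),
                       n_te = 10L, n_omitted = 0L, n_fused = 0L,
                       n_split = 0L, n_weakened = 0L, gc = 0.5) {
  structure(as.list(environment()), class = c("synth_spec", "list"))
}

weaken_nb_region <- function(protein, nb_range, lib,
                             target_frac = c(0.80, 0.98)) {
  prof <- lib$NB
  anchors <- nb_anchor_ranges()
  protected <- unlist(map(anchors, ~ seq.int(.x[1], .x[2]))) + nb_range[1] - 1L
  nb_pos <- setdiff(seq.int(nb_range[1], nb_range[2]), protected)
  aa <- strsplit(protein, "")[[1]]
  best_nb_score <- function(p) {
    h <- scan_profile(p, prof, threshold = -Inf)
    if (nrow(h) == 0) -Inf else max(h$score)
  }
  thr <- prof$threshold
  for (iter in seq_len(400L)) {
    sc <- best_nb_score(paste(aa, collapse = ""))
    if (sc < thr * target_frac[2]) {
      if (sc >= thr * target_frac[1]) break
      # overshot: restart from a lighter mutation load is unnecessary in
      # practice; accept anything below threshold
      break
    }
    aa <- mutate_positions(aa, sample(nb_pos, 4L))
  }
  paste(aa, collapse = "")
}

#' Generate a synthetic genome with known truth and a defective annotation
#'
#' Implants clustered, intron-containing R-genes and transposon-like decoy
#' ORFs into random background DNA, then derives a deliberately defective
#' "automated" annotation from the truth by omitting, fusing, splitting and
#' weakening models as specified. Bit-identical output for identical seeds.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return List of class `synthetic_truth`: `genome` (named character),
#'   `truth` (gene-model tibble with proteins), `annotation` (defective
#'   model tibble), `proteome` (tibble from the defective annotation),
#'   `decoys` (model tibble), `defects` (tibble `id`, `defect`), `query`
#'   helpers and the `spec`/`seed`.
#' @export
generate_genome_with_truth <- function(spec = synth_spec(), seed = 1L) {
  withr::with_seed(seed, generate_genome_impl(spec, seed))
}

generate_genome_impl <- function(spec, seed) {
  lib <- profile_library()
  n <- spec$n_genes
  classes <- sample(names(spec$class_probs), n, replace = TRUE,
                    prob = spec$class_probs)
  idents <- runif(n, spec$identity_range[1], spec$identity_range[2])

  genes <- map(seq_len(n), function(i) {
    g <- generate_rgene(classes[i], idents[i], lib)
    cds <- reverse_translate(g$protein)
    st <- build_gene_structure(cds, sample(spec$intron_count_range, 1L),
                               spec$intron_length_range)
    list(id = sprintf("rg%03d", i), class = classes[i], protein = g$protein,
         struct = st, glen = nchar(st$seq))
  })
  decoy_prots <- map(seq_len(spec$n_te), function(i) {
    p <- paste0("M", te_decoy_protein())
    list(id = sprintf("te%03d", i), protein = p,
         seq = reverse_translate(p))
  })

  # group genes into tandem clusters, then lay clusters and decoys out with
  # wide random gaps
  sizes <- integer(0)
  left <- n
  while (left > 0) {
    s <- min(sample(spec$cluster_sizes, 1L), left)
    sizes <- c(sizes, s); left <- left - s
  }
  assign <- split(seq_len(n), rep(seq_along(sizes), sizes))
  units <- c(map(assign, ~ list(type = "cluster", genes = .x)),
             map(seq_len(spec$n_te), ~ list(type = "te", te = .x)))
  units <- units[sample(length(units))]

  placements <- list()
  pos <- sample.int(5000L, 1L) + 2000L
  chr <- "chr1"
  for (u in units) {
    if (u$type == "cluster") {
      strand <- sample(c("+", "-"), 1L)
      for (gi in u$genes) {
        g <- genes[[gi]]
        placements[[length(placements) + 1L]] <-
          list(type = "gene", gi = gi, start = pos, strand = strand,
               len = g$glen)
        pos <- pos + g$glen +
          sample(seq.int(spec$intra_gap_range[1], spec$intra_gap_range[2]), 1L)
      }
      pos <- pos + sample.int(10000L, 1L) + 8000L
    } else {
      d <- decoy_prots[[u$te]]
      placements[[length(placements) + 1L]] <-
        list(type = "te", te = u$te, start = pos, strand = "+",
             len = nchar(d$seq))
      pos <- pos + nchar(d$seq) + sample.int(10000L, 1L) + 8000L
    }
  }
  if (pos + 2000L > spec$genome_length)
    abort("spec infeasible: genes do not fit in genome_length")

  genome <- random_dna(spec$genome_length, spec$gc)

  implant <- function(genome, seq, start) {
    paste0(substring(genome, 1L, start - 1L), seq,
           substring(genome, start + nchar(seq), nchar(genome)))
  }

  truth_rows <- list()
  decoy_rows <- list()
  for (p in placements) {
    if (p$type == "gene") {
      g <- genes[[p$gi]]
      gseq <- if (p$strand == "+") g$struct$seq else revcomp(g$struct$seq)
      genome <- implant(genome, gseq, p$start)
      ex <- local_to_genomic(g$struct$exons, p$start, p$len, p$strand)
      truth_rows[[length(truth_rows) + 1L]] <- list(
        id = g$id, strand = p$strand, exons = ex, class = g$class,
        protein = g$protein)
    } else {
      d <- decoy_prots[[p$te]]
      genome <- implant(genome, d$seq, p$start)
      decoy_rows[[length(decoy_rows) + 1L]] <- list(
        id = d$id, start = p$start, end = p$start + nchar(d$seq) - 1L,
        protein = d$protein)
    }
  }

  truth <- gene_models(
    id = map_chr(truth_rows, "id"), seqid = chr,
    strand = map_chr(truth_rows, "strand"),
    exons = map(truth_rows, ~ new_exon_matrix(.x$exons[, "start"],
                                              .x$exons[, "end"])),
    source = "truth")
  truth$class <- map_chr(truth_rows, "class")
  truth$protein_truth <- map_chr(truth_rows, "protein")
  genome_v <- setNames(genome, chr)
  truth <- extract_and_translate(truth, genome_v)

  decoys <- gene_models(
    id = map_chr(decoy_rows, "id"), seqid = chr, strand = "+",
    exons = map(decoy_rows, ~ new_exon_matrix(.x$start, .x$end)),
    source = "truth")

  # ---- defective annotation --------------------------------------------
  defects <- tibble(id = character(), defect = character())
  ann <- truth
  ann$source <- "auto"

  # weakened: re-implant a weakened-NB version of the gene into the genome
  if (spec$n_weakened > 0) {
    cand <- sample(nrow(truth), spec$n_weakened)
    for (i in cand) {
      prot <- truth$protein_truth[i]
      g <- genes[[match(truth$id[i], map_chr(genes, "id"))]]
      arch <- build_architecture(annotate_domains(prot, lib))
      nbh <- arch$hits[arch$hits$kind == "NB", ]
      nb_range <- if (nrow(nbh)) c(nbh$start[1], nbh$end[1]) else c(1L, nchar(prot))
      weak <- weaken_nb_region(prot, nb_range, lib)
      # rebuild the gene in place with identical intron structure
      old_struct <- g$struct
      cds <- reverse_translate(weak)
      pieces_len <- old_struct$exons$end - old_struct$exons$start + 1L
      stopifnot(sum(pieces_len) == nchar(cds))
      newseq <- old_struct$seq
      off <- 0L
      for (e in seq_len(nrow(old_struct$exons))) {
        piece <- substring(cds, off + 1L, off + pieces_len[e])
        substr(newseq, old_struct$exons$start[e], old_struct$exons$end[e]) <- piece
        off <- off + pieces_len[e]
      }
      pl <- placements[map_lgl(placements, ~ .x$type == "gene" &&
                                 genes[[.x$gi]]$id == truth$id[i])][[1]]
      gseq <- if (truth$strand[i] == "+") newseq else revcomp(newseq)
      genome_v[[1]] <- implant(genome_v[[1]], gseq, pl$start)
      truth$protein_truth[i] <- weak
      defects <- bind_rows(defects, tibble(id = truth$id[i], defect = "weakened"))
    }
    truth <- extract_and_translate(truth, genome_v)
    ann <- truth
    ann$source <- "auto"
  }

  # omitted
  if (spec$n_omitted > 0) {
    weak_ids <- defects$id
    cand <- setdiff(ann$id, weak_ids)
    omit <- sample(cand, spec$n_omitted)
    defects <- bind_rows(defects, tibble(id = omit, defect = "omitted"))
    ann <- ann[!(ann$id %in% omit), ]
  }

  # fused: replace two adjacent same-strand models by one merged model
  if (spec$n_fused > 0) {
    for (f in seq_len(spec$n_fused)) {
      sp <- model_span(ann)
      o <- order(sp$start)
      pair <- NULL
      for (k in seq_len(length(o) - 1L)) {
        i1 <- o[k]; i2 <- o[k + 1L]
        if (ann$strand[i1] == ann$strand[i2] &&
            !(ann$id[i1] %in% defects$id) && !(ann$id[i2] %in% defects$id) &&
            sp$start[i2] - sp$end[i1] < 6000L) { pair <- c(i1, i2); break }
      }
      if (is.null(pair)) break
      ex <- rbind(ann$exons[[pair[1]]], ann$exons[[pair[2]]])
      fused <- gene_models(id = sprintf("fused%02d", f), seqid = chr,
                           strand = ann$strand[pair[1]],
                           exons = list(new_exon_matrix(ex[, "start"], ex[, "end"])),
                           source = "auto")
      defects <- bind_rows(defects, tibble(id = ann$id[pair], defect = "fused"))
      ann <- bind_rows(ann[-pair, ], fused)
    }
  }

  # split: replace one multi-exon model by two models partitioning its exons
  if (spec$n_split > 0) {
    for (f in seq_len(spec$n_split)) {
      cand <- which(map_int(ann$exons, nrow) >= 2L & !(ann$id %in% defects$id) &
                      !startsWith(ann$id, "fused"))
      if (length(cand) == 0) break
      i <- cand[sample.int(length(cand), 1L)]
      ex <- ann$exons[[i]]
      cut <- nrow(ex) %/% 2L
      parts <- gene_models(
        id = sprintf("split%02d%s", f, c("a", "b")), seqid = chr,
        strand = ann$strand[i],
        exons = list(new_exon_matrix(ex[1:cut, "start"], ex[1:cut, "end"]),
                     new_exon_matrix(ex[(cut + 1L):nrow(ex), "start"],
                                     ex[(cut + 1L):nrow(ex), "end"])),
        source = "auto")
      defects <- bind_rows(defects, tibble(id = ann$id[i], defect = "split"))
      ann <- bind_rows(ann[-i, ], parts)
    }
  }

  # decoy ORFs are part of the automated annotation
  dec_ann <- decoys
  dec_ann$source <- "auto"
  ann <- bind_rows(ann, dec_ann)
  ann$class <- NULL
  ann$protein_truth <- NULL
  ann <- extract_and_translate(ann, genome_v)
  sp <- model_span(ann)
  ann <- ann[order(sp$start), ]

  proteome <- tibble(id = ann$id, seq = gsub("\\*", "X", ann$protein))

  list(genome = genome_v, truth = truth, annotation = ann,
       proteome = proteome, decoys = decoys, defects = defects,
       spec = spec, seed = seed) |>
    structure(class = c("synthetic_truth", "list"))
}
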