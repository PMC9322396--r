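# Orchestration of the double-pass prediction procedure: domain-based pass on
# the proteome (PDS), motif discovery and rescue, genome-wide full-length
# homology pass, span/overlap filters, re-annotation and reporting.

#' Pipeline configuration
#'
#' Defaults follow the method's published settings where stated (19 motifs of
#' width 4-7, homology E-value cut-off 0.01, 20-kb span filter, reciprocal
#' best-hit confidence threshold 1); the remaining knobs are package defaults.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `hrp_config`.
#' @export
hrp_config <- function(...) {
  cfg <- list(
    # motif stage
    n_motifs = 19L, min_w = 4L, max_w = 7L,
    rescue_min_motifs = 3L, rescue_pvalue = 1e-4, rescue_evalue = 10,
    rescue_as_query = FALSE,
    # domain stage
    min_repeats = 3L, cc_window = 21L, cc_threshold = 0.5,
    # homology stage
    seed_k = 4L, xdrop = 20L, min_hsp_score = 50L,
    gap_open = 11L, gap_extend = 1L, intron_cost = 20L,
    min_intron = 40L, max_intron = 10000L, max_intron_align = 2000L,
    align_flank = 2000L,
    max_queries_per_locus = 3L, evalue_cutoff = 0.01,
    karlin = karlin_params(),
    # filters
    max_span_bp = 20000L,
    # comparison
    rbh_confidence = 1,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(sprintf("unknown config fields: %s", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = c("hrp_config", "list"))
}

classify_proteome <- function(proteome, lib, config) {
  map(seq_len(nrow(proteome)), function(i) {
    hits <- annotate_domains(proteome$seq[i], lib,
                             min_repeats = config$min_repeats,
                             cc_window = config$cc_window,
                             cc_threshold = config$cc_threshold)
    arch <- build_architecture(hits)
    list(id = proteome$id[i], seq = proteome$seq[i], arch = arch)
  })
}

#' First pass: protein motif/domain-based search over a proteome
#'
#' Every protein is scanned with the domain battery and classified. The
#' NB-domain subsequences of full-length proteins are returned for motif
#' discovery.
#'
#' @param proteome Sequence tibble (`id`, `seq`) or named character vector.
#' @param lib Profile library.
#' @param config Pipeline configuration.
#' @return List with `full_length` and `partial` tibbles (`id`, `seq`,
#'   `class`), and `nb_seqs`, a named character vector of NB-domain
#'   subsequences of the full-length set.
#' @export
pass1_pds <- function(proteome, lib = profile_library(), config = hrp_config()) {
  if (is.character(proteome)) proteome <- tibble(id = names(proteome), seq = unname(proteome))
  if (nrow(proteome) == 0) {
    e <- tibble(id = character(), seq = character(), class = character())
    return(list(full_length = e, partial = e, nb_seqs = character()))
  }
  ann <- classify_proteome(proteome, lib, config)
  cls <- map_chr(ann, ~ .x$arch$class_label)
  fl <- map_lgl(ann, ~ .x$arch$full_length)
  full_length <- tibble(id = proteome$id[fl], seq = proteome$seq[fl], class = cls[fl])
  partial <- tibble(id = proteome$id[!fl & cls != "none"],
                    seq = proteome$seq[!fl & cls != "none"],
                    class = cls[!fl & cls != "none"])
  nb_seqs <- character(0)
  for (a in ann[fl]) {
    nb <- a$arch$hits[a$arch$hits$kind == "NB", ]
    if (nrow(nb)) {
      best <- nb[which.max(nb$score), ]
      nb_seqs[a$id] <- substring(a$seq, best$start, best$end)
    }
  }
  list(full_length = full_length, partial = partial, nb_seqs = nb_seqs)
}

#' Rescue NB-LRR candidates by motif scanning
#'
#' Proteins absent from `already_found` are scanned with the discovered
#' motifs; a protein is rescued when at least `rescue_min_motifs` distinct
#' motifs have a best-hit p-value below `rescue_pvalue` and the QFAST combined
#' E-value over the proteome is at most `rescue_evalue`.
#'
#' @param proteome Sequence tibble (`id`, `seq`).
#' @param motifs Motif models from [discover_motifs()].
#' @param already_found Character vector of protein ids to exclude.
#' @param config Pipeline configuration.
#' @return Tibble of rescued proteins (`id`, `seq`, `n_sig`, `combined_e`).
#' @export
motif_rescue <- function(proteome, motifs, already_found = character(),
                         config = hrp_config()) {
  if (is.character(proteome)) proteome <- tibble(id = names(proteome), seq = unname(proteome))
  out <- tibble(id = character(), seq = character(),
                n_sig = integer(), combined_e = numeric())
  if (length(motifs) == 0) return(out)
  todo <- proteome[!(proteome$id %in% already_found), ]
  n_db <- nrow(proteome)
  for (i in seq_len(nrow(todo))) {
    bp <- map_dbl(motifs, function(m) {
      h <- motif_hit_pvalue(todo$seq[i], m)
      if (nrow(h) == 0) 1 else min(h$pvalue)
    })
    n_sig <- sum(bp < config$rescue_pvalue)
    ce <- combined_evalue(pmin(bp, 1), n_db)
    if (n_sig >= config$rescue_min_motifs && ce$evalue <= config$rescue_evalue) {
      out <- bind_rows(out, tibble(id = todo$id[i], seq = todo$seq[i],
                                   n_sig = as.integer(n_sig),
                                   combined_e = ce$evalue))
    }
  }
  out
}

#' Drop candidate models whose introns swallow another candidate's exons
#'
#' In tandem R-gene arrays, a spliced alignment can bridge two adjacent gene
#' copies with a spurious intron across the intergenic gap (a chimeric
#' model). Such models are recognisable because one of their introns covers a
#' substantial part of another candidate's coding exons, whereas genuine
#' introns do not contain neighbouring genes. Any candidate with an intron
#' overlapping at least `min_overlap` coding bases of another same-strand
#' candidate is removed before overlap resolution.
#'
#' @param candidates Gene-model tibble.
#' @param min_overlap Minimum intron-over-exon overlap (bp) that marks a
#'   bridge.
#' @return The filtered tibble.
#' @export
drop_bridging_models <- function(candidates, min_overlap = 300L) {
  if (nrow(candidates) < 2) return(candidates)
  sp <- model_span(candidates)
  introns <- map(candidates$exons, function(ex) {
    if (nrow(ex) < 2) return(NULL)
    cbind(start = ex[-nrow(ex), "end"] + 1L, end = ex[-1, "start"] - 1L)
  })
  bridging <- vapply(seq_len(nrow(candidates)), function(i) {
    ir <- introns[[i]]
    if (is.null(ir)) return(FALSE)
    js <- which(candidates$seqid == candidates$seqid[i] &
                  candidates$strand == candidates$strand[i] &
                  sp$start <= sp$end[i] & sp$end >= sp$start[i])
    js <- setdiff(js, i)
    for (j in js) {
      ex <- candidates$exons[[j]]
      ov <- sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(ir[, "start"], ir[, "end"]),
        IRanges::IRanges(ex[, "start"], ex[, "end"]))))
      if (ov >= min_overlap) return(TRUE)
    }
    FALSE
  }, logical(1))
  candidates[!bridging, ]
}

#' Apply the method's span and overlap filters to candidate models
#'
#' First, models whose genomic footprint is strictly greater than
#' `max_span_bp` are dropped. Second, same-strand models on the same sequence
#' overlapping by at least 1 bp are clustered by single linkage and only the
#' model encoding the longest protein is kept per cluster (ties: higher
#' alignment score `S`, then smaller start). Opposite-strand overlaps are
#' both kept.
#'
#' @param candidates Gene-model tibble with `protein` filled in (an `S` score
#'   column is used for tie-breaks when present).
#' @param config Pipeline configuration.
#' @return The filtered tibble.
#' @export
filter_models <- function(candidates, config = hrp_config()) {
  if (nrow(candidates) == 0) return(candidates)
  sp <- model_span(candidates)
  candidates <- candidates[sp$end - sp$start + 1L <= config$max_span_bp, ]
  if (nrow(candidates) == 0) return(candidates)
  sp <- model_span(candidates)
  candidates$.start <- sp$start
  candidates$.end <- sp$end
  candidates$.S <- if ("S" %in% names(candidates)) candidates$S else
    ifelse(is.na(candidates$score), 0, candidates$score)
  out <- candidates |>
    group_by(.data$seqid, .data$strand) |>
    mutate(.cluster = cluster_intervals(.data$.start, .data$.end)) |>
    group_by(.data$seqid, .data$strand, .data$.cluster) |>
    arrange(desc(nchar(.data$protein)), desc(.data$.S), .data$.start,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$seqid, .data$.start)
  out$.start <- out$.end <- out$.S <- out$.cluster <- NULL
  out
}

reannotate_models <- function(models, lib, config) {
  if (nrow(models) == 0) {
    models$class <- character()
    models$full_length <- logical()
    return(models)
  }
  archs <- map(models$protein, function(p) {
    build_architecture(annotate_domains(p, lib,
                                        min_repeats = config$min_repeats,
                                        cc_window = config$cc_window,
                                        cc_threshold = config$cc_threshold))
  })
  models$class <- map_chr(archs, "class_label")
  models$full_length <- map_lgl(archs, "full_length")
  models
}

overlaps_any <- function(models, others) {
  # for each row of `models`: any same-seqid same-strand span overlap in `others`
  if (nrow(others) == 0) return(rep(FALSE, nrow(models)))
  sa <- model_span(models); sb <- model_span(others)
  vapply(seq_len(nrow(models)), function(i) {
    any(others$seqid == models$seqid[i] & others$strand == models$strand[i] &
          sb$start <= sa$end[i] & sb$end >= sa$start[i])
  }, logical(1))
}

build_report <- function(genes) {
  fl_order <- c("CNL", "TNL", "RNL", "NL")
  fl <- genes[genes$full_length, ]
  pt <- genes[!genes$full_length, ]
  counts <- bind_rows(
    tibble(block = "full_length",
           class = fl_order,
           n = unname(vapply(fl_order, function(k) sum(fl$class == k), 0L))),
    tibble(block = "full_length", class = "Total full-length", n = nrow(fl)),
    if (nrow(pt)) {
      tb <- sort(table(pt$class), decreasing = TRUE)
      tibble(block = "partial", class = names(tb), n = as.integer(tb))
    },
    tibble(block = "partial", class = "Total partial", n = nrow(pt)),
    tibble(block = "total", class = "Total", n = nrow(genes)),
    tibble(block = "total", class = "Pseudogenes", n = sum(genes$pseudogene))
  )
  counts
}

#' Run the full two-pass prediction pipeline
#'
#' Pass 1 classifies the automatically annotated proteome by domain content
#' (PDS) and extracts NB-domain sequences; motifs discovered in them rescue
#' weakly scoring proteins. Pass 2 uses every full-length pass-1 protein as a
#' query for genome-wide splice-aware homology prediction; candidates are
#' filtered (20-kb span, strand-aware overlap with longest-protein choice),
#' re-annotated by domain content, classified and flagged as pseudogenes when
#' they contain internal stops or a frameshift. Pass-1 full-length loci with
#' no surviving pass-2 model at the locus are appended, so no pass-1 locus is
#' ever dropped.
#'
#' @param genome Genome as a named character vector or [read_fasta()] tibble.
#' @param proteome Proteome tibble (`id`, `seq`); ids must match the mRNA ids
#'   of `annotation`.
#' @param annotation Gene-model tibble of the automated annotation
#'   ([read_gff3()]).
#' @param config Pipeline configuration.
#' @param lib Profile library.
#' @return An object of class `hrp_result`: per-gene records (`genes`), the
#'   output `models`, the class-count `report`, discovered `motifs`, the
#'   `rescued` set, the `pass1` result and the `config`.
#' @export
run_hrp <- function(genome, proteome, annotation, config = hrp_config(),
                    lib = profile_library()) {
  genome <- as_genome(genome)
  if (is.character(proteome)) proteome <- tibble(id = names(proteome), seq = unname(proteome))

  p1 <- pass1_pds(proteome, lib, config)

  motifs <- if (length(p1$nb_seqs) >= 2) {
    discover_motifs(p1$nb_seqs, n_motifs = config$n_motifs,
                    min_w = config$min_w, max_w = config$max_w,
                    seed = config$seed)
  } else list()
  rescued <- motif_rescue(proteome, motifs,
                          already_found = p1$full_length$id,
                          config = config)

  queries <- p1$full_length
  # queries must be clean full-length proteins: models whose CDS carries
  # internal stops or a frameshift (defective fusions, pseudogenes) would
  # seed chimeric multi-gene alignments
  ann_q <- annotation[annotation$id %in% queries$id, ]
  if (nrow(ann_q)) {
    ann_q <- extract_and_translate(ann_q, genome)
    bad <- ann_q$id[ann_q$pseudogene]
    queries <- queries[!(queries$id %in% bad), ]
  }
  if (isTRUE(config$rescue_as_query) && nrow(rescued)) {
    resc_fl <- rescued[rescued$id %in% p1$full_length$id, ]
    queries <- distinct(bind_rows(queries,
                                  tibble(id = resc_fl$id, seq = resc_fl$seq,
                                         class = NA_character_)))
  }

  # pass 2: genome-wide homology search with every clean full-length query;
  # iterated per-locus alignment carves out each member of a tandem cluster
  candidates <- homology_candidates(queries, genome, config)

  if (nrow(candidates)) {
    candidates <- extract_and_translate(candidates, genome)
    candidates <- drop_bridging_models(candidates)
    candidates <- filter_models(candidates, config)
    candidates <- reannotate_models(candidates, lib, config)
    candidates <- candidates[candidates$class != "none", ]
    candidates$provenance <- "homology-pass"
  } else {
    candidates$class <- character(); candidates$full_length <- logical()
    candidates$provenance <- character()
  }

  # reconcile pass-1 loci: pass-2 models take precedence at a locus; pass-1
  # loci without a surviving pass-2 model are appended unchanged
  ann_extra <- gene_models(character(), character(), character(), list())
  ann_extra$class <- character(); ann_extra$full_length <- logical()
  ann_extra$provenance <- character()
  append_from_annotation <- function(ids, provenance) {
    keep <- annotation[annotation$id %in% ids, ]
    if (nrow(keep) == 0) return(NULL)
    keep <- keep[!overlaps_any(keep, candidates), ]
    if (nrow(keep) == 0) return(NULL)
    keep <- extract_and_translate(keep, genome)
    keep <- reannotate_models(keep, lib, config)
    keep$provenance <- provenance
    keep$query <- NA_character_; keep$S <- NA_real_; keep$evalue <- NA_real_
    keep
  }
  extra_pds <- append_from_annotation(p1$full_length$id, "PDS")
  extra_resc <- append_from_annotation(setdiff(rescued$id, p1$full_length$id),
                                       "motif-rescue")
  genes_models <- bind_rows(candidates, extra_pds, extra_resc)

  sp <- if (nrow(genes_models)) model_span(genes_models) else
    tibble(start = integer(), end = integer())
  genes <- tibble(
    id = genes_models$id, seqid = genes_models$seqid,
    start = sp$start, end = sp$end, strand = genes_models$strand,
    class = genes_models$class, full_length = genes_models$full_length,
    pseudogene = genes_models$pseudogene,
    provenance = genes_models$provenance,
    protein_length = nchar(genes_models$protein)
  )

  structure(list(
    genes = genes, models = genes_models, report = build_report(genes),
    motifs = motifs, rescued = rescued, pass1 = p1,
    annotation = annotation, config = config
  ), class = "hrp_result")
}

#' @export
print.hrp_result <- function(x, ...) {
  cat("Full-length homology-based R-gene prediction\n")
  cat(sprintf("  %d gene models (%d full-length, %d partial, %d pseudogenes)\n",
              nrow(x$genes), sum(x$genes$full_length),
              sum(!x$genes$full_length), sum(x$genes$pseudogene)))
  print(x$report, n = Inf)
  invisible(x)
}

#' Check the pass-1 conservation property of a pipeline result
#'
#' Every pass-1 full-length locus of the input annotation must be represented
#' in the final output by at least one overlapping same-strand model (pass 2
#' may re-model a locus but never silently drops it).
#'
#' @param result An `hrp_result`.
#' @return Logical vector, one entry per pass-1 full-length locus.
#' @export
check_conservation <- function(result) {
  ids <- result$pass1$full_length$id
  loci <- result$annotation[result$annotation$id %in% ids, ]
  if (nrow(loci) == 0) return(logical(0))
  setNames(overlaps_any(loci, result$models), loci$id)
}

#' Allele mining: homologs of a single query protein in a genome
#'
#' Runs the homology pass with one query, applies the span/overlap filters,
#' re-annotates the predicted models and flags loci absent from an (optional)
#' automated annotation as novel.
#'
#' @param query Named character scalar (protein) or one-row sequence tibble.
#' @param genome Genome as a named character vector or [read_fasta()] tibble.
#' @param annotation Optional gene-model tibble to define novelty.
#' @param config Pipeline configuration.
#' @param lib Profile library.
#' @return An `hrp_result` whose `genes` carry a `novel` column.
#' @export
mine_alleles <- function(query, genome, annotation = NULL,
                         config = hrp_config(), lib = profile_library()) {
  genome <- as_genome(genome)
  cands <- predict_homologs(query, genome, config)
  if (nrow(cands)) {
    cands <- extract_and_translate(cands, genome)
    cands <- drop_bridging_models(cands)
    cands <- filter_models(cands, config)
    cands <- reannotate_models(cands, lib, config)
    cands <- cands[cands$class != "none", ]
    cands$provenance <- "homology-pass"
  } else {
    cands$class <- character(); cands$full_length <- logical()
    cands$provenance <- character()
  }
  sp <- if (nrow(cands)) model_span(cands) else tibble(start = integer(), end = integer())
  genes <- tibble(
    id = cands$id, seqid = cands$seqid, start = sp$start, end = sp$end,
    strand = cands$strand, class = cands$class,
    full_length = cands$full_length, pseudogene = cands$pseudogene,
    provenance = cands$provenance, protein_length = nchar(cands$protein)
  )
  genes$novel <- if (!is.null(annotation)) !overlaps_any(cands, annotation) else NA
  structure(list(genes = genes, models = cands, report = build_report(genes),
                 motifs = list(), rescued = tibble(),
                 pass1 = list(full_length = tibble(id = character())),
                 annotation = annotation %||%
                   gene_models(character(), character(), character(), list()),
                 config = config), class = "hrp_result")
}

#' Write the pipeline outputs to a directory
#'
#' Emits `hrp.gff3` (gene models), `hrp_proteins.faa` (predicted proteins),
#' `report.tsv` (per-gene records) and `report.json` (class counts).
#'
#' @param result An `hrp_result`.
#' @param dir Output directory (created if needed).
#' @export
write_hrp_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(result$models, file.path(dir, "hrp.gff3"))
  prot <- result$models$protein
  names(prot) <- result$models$id
  write_fasta(prot[!is.na(prot)], file.path(dir, "hrp_proteins.faa"))
  write.table(result$genes, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = result$report,
         totals = list(genes = nrow(result$genes),
                       full_length = sum(result$genes$full_length),
                       pseudogenes = sum(result$genes$pseudogene))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
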