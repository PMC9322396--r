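#' Read a FASTA file into a sequence tibble
#'
#' Sequences are folded to upper case and wrapped lines are joined. The
#' declared alphabet is enforced: DNA allows `ACGTN`, protein allows the 20
#' standard residues plus `X` and `*` (pseudoprotein stops).
#'
#' @param path Path to a FASTA file.
#' @param kind `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `seq`, `kind`, in file order.
#' @export
read_fasta <- function(path, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  set <- if (kind == "dna") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("duplicate sequence id '%s' in %s", dup, path))
  }
  seqs <- toupper(as.character(set))
  allowed <- if (kind == "dna") "ACGTN" else paste0(paste(AA20, collapse = ""), "X*")
  bad <- stringr::str_locate(seqs, sprintf("[^%s]", gsub("\\*", "\\\\*", allowed)))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("illegal %s character '%s' at position %d of sequence '%s'",
                  kind, substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  if (any(nchar(seqs) == 0)) abort("empty sequence in FASTA")
  tibble(id = unname(ids), seq = unname(seqs), kind = kind)
}

#' Write a sequence tibble (or named character vector) as FASTA
#'
#' @param x Tibble with `id` and `seq` columns, or a named character vector.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- tibble(id = names(x), seq = unname(x))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param dna A DNA character string.
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

new_exon_matrix <- function(start, end, phase = rep(0L, length(start))) {
  m <- cbind(start = as.integer(start), end = as.integer(end),
             phase = as.integer(phase))
  m[order(m[, "start"]), , drop = FALSE]
}

#' Construct a gene-model tibble
#'
#' One row per gene model. Exons are 1-based inclusive genomic intervals,
#' stored in ascending order regardless of strand; transcript order is applied
#' only at translation time.
#'
#' @param id,seqid,strand Character/character/`"+"` or `"-"` vectors.
#' @param exons List of integer matrices with columns `start`, `end`, `phase`.
#' @param source Annotation source tag.
#' @param score Numeric score or `NA`.
#' @param protein Protein string or `NA`.
#' @param internal_stops Integer count of internal stop codons.
#' @param frameshift Logical: CDS length not a codon multiple.
#' @return A tibble of class `hrp_models`.
#' @export
gene_models <- function(id, seqid, strand, exons, source = "HRP",
                        score = NA_real_, protein = NA_character_,
                        internal_stops = 0L, frameshift = FALSE) {
  stopifnot(all(strand %in% c("+", "-")))
  out <- tibble(
    id = as.character(id), seqid = as.character(seqid), strand = strand,
    exons = exons,
    source = source, score = as.numeric(score),
    protein = as.character(protein),
    internal_stops = as.integer(internal_stops),
    frameshift = as.logical(frameshift)
  )
  out$pseudogene <- out$internal_stops > 0L | out$frameshift
  for (e in out$exons) {
    if (any(e[, "start"] > e[, "end"])) abort("exon start > end")
    if (nrow(e) > 1 && any(e[-1, "start"] <= e[-nrow(e), "end"]))
      abort("exons overlap or are unsorted")
  }
  class(out) <- c("hrp_models", class(out))
  out
}

model_span <- function(models) {
  tibble(
    start = map_int(models$exons, ~ min(.x[, "start"])),
    end = map_int(models$exons, ~ max(.x[, "end"]))
  )
}

cds_length <- function(models) {
  map_int(models$exons, ~ sum(.x[, "end"] - .x[, "start"] + 1L))
}

#' Read gene models from GFF3
#'
#' Expects a gene/mRNA/CDS hierarchy with `ID`/`Parent` attributes. GFF3
#' coordinates (1-based inclusive) are kept as-is internally. For genes with
#' several mRNAs, the mRNA with the longest total CDS is kept.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (see [gene_models()]); `protein` is `NA` until
#'   [extract_and_translate()] is applied with a genome.
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    seqid = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    type = as.character(g$type),
    source = as.character(g$source),
    score = if (is.null(g$score)) NA_real_ else as.numeric(g$score),
    phase = if (is.null(g$phase)) NA_integer_ else as.integer(g$phase),
    ID = if (is.null(g$ID)) NA_character_ else as.character(g$ID),
    Parent = map_chr(as.list(g$Parent %||% vector("list", length(g))),
                     ~ if (length(.x)) .x[[1]] else NA_character_),
    pseudo_attr = if (is.null(g$pseudogene)) NA_character_ else as.character(g$pseudogene),
    fs_attr = if (is.null(g$frameshift)) NA_character_ else as.character(g$frameshift)
  )
  if (any(df$end < df$start)) abort("GFF3 record with end < start")
  cds <- df[df$type == "CDS", ]
  if (nrow(cds) == 0) abort("no CDS features in GFF3")
  if (any(is.na(cds$Parent))) abort("CDS feature without Parent attribute")
  mrna <- df[df$type == "mRNA", ]
  cds_by_parent <- split(cds, cds$Parent)
  rows <- map(seq_len(nrow(mrna)), function(i) {
    m <- mrna[i, ]
    cc <- cds_by_parent[[m$ID]]
    if (is.null(cc)) return(NULL)
    ex <- new_exon_matrix(cc$start, cc$end,
                          ifelse(is.na(cc$phase), 0L, cc$phase))
    tibble(id = m$ID, gene = m$Parent, seqid = m$seqid, strand = m$strand,
           source = m$source, score = m$score, exons = list(ex),
           pseudo_attr = m$pseudo_attr, fs_attr = m$fs_attr,
           clen = sum(ex[, "end"] - ex[, "start"] + 1L), order = i)
  })
  rows <- bind_rows(rows)
  if (nrow(rows) == 0) abort("no mRNA with CDS children in GFF3")
  # longest-CDS mRNA per gene; keep file order between genes
  rows <- rows |>
    group_by(.data$gene) |>
    arrange(desc(.data$clen), .data$order, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$order)
  out <- gene_models(rows$id, rows$seqid, rows$strand, rows$exons,
                     source = rows$source, score = rows$score)
  out$frameshift <- !is.na(rows$fs_attr) & rows$fs_attr == "true"
  out$pseudogene <- out$frameshift |
    (!is.na(rows$pseudo_attr) & rows$pseudo_attr == "true")
  out
}

fmt_score <- function(s) ifelse(is.na(s), ".", sprintf("%.10g", s))

#' Write gene models as GFF3
#'
#' Emits a gene/mRNA/CDS hierarchy with `ID`/`Parent` attributes;
#' `pseudogene=true` and `frameshift=true` attributes are carried on the mRNA.
#'
#' @param models A gene-model tibble.
#' @param path Output path.
#' @param source Value for the GFF3 source column (default `"HRP"`).
#' @export
write_gff3 <- function(models, path, source = NULL) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    src <- source %||% m$source
    ex <- m$exons[[1]]
    gs <- min(ex[, "start"]); ge <- max(ex[, "end"])
    gid <- paste0(m$id, ".gene")
    extra <- ""
    if (isTRUE(m$pseudogene)) extra <- paste0(extra, ";pseudogene=true")
    if (isTRUE(m$frameshift)) extra <- paste0(extra, ";frameshift=true")
    sc <- fmt_score(m$score)
    lines <- c(lines,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s", m$seqid, src, gs, ge, m$strand, gid),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t%s\t%s\t.\tID=%s;Parent=%s%s",
              m$seqid, src, gs, ge, sc, m$strand, m$id, gid, extra),
      sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
              m$seqid, src, ex[, "start"], ex[, "end"], m$strand, ex[, "phase"],
              m$id, seq_len(nrow(ex)), m$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export gene-model spans as BED6
#'
#' @param models A gene-model tibble.
#' @param path Output path. Coordinates follow BED's 0-based half-open
#'   convention.
#' @export
write_bed <- function(models, path) {
  sp <- model_span(models)
  df <- data.frame(models$seqid, sp$start - 1L, sp$end, models$id,
                   ifelse(is.na(models$score), 0, models$score), models$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the CDS of a model and translate it
#'
#' Exons are concatenated in ascending genomic order; on the minus strand the
#' concatenation is reverse-complemented to transcript orientation. The phase
#' of the transcript-first exon is applied, the standard genetic code is used,
#' a trailing stop is dropped, and internal stops are rendered `*` and
#' counted. A CDS whose length is not a codon multiple is flagged as a
#' frameshift (and hence pseudogene) but still translated in frame 0.
#'
#' @param models A gene-model tibble.
#' @param genome Named character vector of chromosome sequences (or a
#'   `read_fasta()` tibble of kind dna).
#' @return `models` with `protein`, `internal_stops`, `frameshift`,
#'   `pseudogene` filled in.
#' @export
extract_and_translate <- function(models, genome) {
  genome <- as_genome(genome)
  res <- map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    chr <- genome[[m$seqid]]
    ex <- m$exons[[1]]
    if (min(ex[, "start"]) < 1 || max(ex[, "end"]) > nchar(chr))
      abort(sprintf("exons of model '%s' outside genome bounds", m$id))
    cds <- paste0(substring(chr, ex[, "start"], ex[, "end"]), collapse = "")
    first_phase <- if (m$strand == "+") ex[1, "phase"] else ex[nrow(ex), "phase"]
    if (m$strand == "-") cds <- revcomp(cds)
    if (first_phase > 0) cds <- substring(cds, first_phase + 1L)
    translate_cds(cds)
  })
  models$protein <- map_chr(res, "protein")
  models$internal_stops <- map_int(res, "internal_stops")
  models$frameshift <- map_lgl(res, "frameshift")
  models$pseudogene <- models$internal_stops > 0L | models$frameshift
  models
}

#' Translate a coding sequence (transcript orientation)
#'
#' @param cds DNA string in transcript orientation.
#' @return List with `protein` (trailing stop dropped, internal stops as `*`),
#'   `internal_stops` and `frameshift`.
#' @export
translate_cds <- function(cds) {
  frameshift <- (nchar(cds) %% 3L) != 0L
  ncod <- nchar(cds) %/% 3L
  if (ncod == 0) return(list(protein = "", internal_stops = 0L, frameshift = frameshift))
  cds <- substring(cds, 1L, ncod * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  # drop a single trailing stop
  if (substring(aa, nchar(aa)) == "*") aa <- substring(aa, 1L, nchar(aa) - 1L)
  nstop <- stringr::str_count(aa, "\\*")
  list(protein = aa, internal_stops = as.integer(nstop), frameshift = frameshift)
}

as_genome <- function(genome) {
  if (is.data.frame(genome)) {
    as.list(setNames(genome$seq, genome$id))
  } else if (is.character(genome)) {
    as.list(genome)
  } else if (is.list(genome)) {
    genome
  } else {
    abort("genome must be a named character vector or read_fasta() tibble")
  }
}

#' Stop-codon counts in all six reading frames
#'
#' Counts occurrences of TAA, TAG and TGA codons in the three forward frames
#' and the three frames of the reverse complement.
#'
#' @param dna A DNA string (ACGTN), length >= 3. Frames shorter than one codon
#'   report 0.
#' @return Named integer vector `f1,f2,f3,r1,r2,r3`.
#' @export
six_frame_stop_profile <- function(dna) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna)) abort("non-DNA character in six_frame_stop_profile input")
  if (nchar(dna) < 3) abort("input shorter than one codon")
  count_frame <- function(s, off) {
    s <- substring(s, off)
    n <- nchar(s) %/% 3L
    if (n == 0) return(0L)
    starts <- seq(1L, by = 3L, length.out = n)
    codons <- substring(s, starts, starts + 2L)
    sum(codons %in% c("TAA", "TAG", "TGA"))
  }
  rc <- revcomp(dna)
  c(f1 = count_frame(dna, 1L), f2 = count_frame(dna, 2L), f3 = count_frame(dna, 3L),
    r1 = count_frame(rc, 1L), r2 = count_frame(rc, 2L), r3 = count_frame(rc, 3L))
}
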