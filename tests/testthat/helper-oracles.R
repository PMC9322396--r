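# Independent brute-force oracles. These are deliberately written as plain
# loops against the stated definitions, separate from the package's
# vectorised / compiled implementations.

AA20h <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20h, n, replace = TRUE), collapse = "")
random_dna_str <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

# every-window PSSM scores by explicit double loop
oracle_window_scores <- function(protein, profile) {
  aa <- strsplit(protein, "")[[1]]
  L <- profile$length
  n <- length(aa)
  if (n < L) return(numeric(0))
  out <- numeric(n - L + 1)
  for (p in seq_len(n - L + 1)) {
    s <- 0
    for (i in seq_len(L)) {
      a <- aa[p + i - 1]
      col <- if (a %in% AA20h) a else "X"
      s <- s + profile$matrix[i, col]
    }
    out[p] <- s
  }
  out
}

# greedy best-first resolution of overlapping windows (independent rewrite)
oracle_merge_hits <- function(scores, L, threshold) {
  cand <- which(scores >= threshold)
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(), score = numeric()))
  }
  cand <- cand[order(-scores[cand], cand)]
  keep <- integer(0)
  for (p in cand) {
    clash <- FALSE
    for (q in keep) if (abs(p - q) < L) { clash <- TRUE; break }
    if (!clash) keep <- c(keep, p)
  }
  keep <- sort(keep)
  data.frame(start = keep, end = keep + L - 1L, score = scores[keep])
}

# stop-codon counts per frame by explicit codon enumeration
oracle_six_frame <- function(dna) {
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
  count1 <- function(s, off) {
    cnt <- 0L
    i <- off
    while (i + 2 <= nchar(s)) {
      if (substr(s, i, i + 2) %in% c("TAA", "TAG", "TGA")) cnt <- cnt + 1L
      i <- i + 3L
    }
    cnt
  }
  c(count1(dna, 1), count1(dna, 2), count1(dna, 3),
    count1(rc, 1), count1(rc, 2), count1(rc, 3))
}

# translation by explicit codon lookup
oracle_translate <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3
  aa <- character(n)
  for (i in seq_len(n)) aa[i] <- gc[[substr(cds, 3 * i - 2, 3 * i)]]
  paste(aa, collapse = "")
}

# best chain by enumeration over all HSP subsets (<= 10 HSPs)
oracle_best_chain <- function(h, max_intron = 10000, max_span = 20000) {
  n <- nrow(h)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) == 0) next
    idx <- idx[order(h$tstart[idx])]
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        i <- idx[k - 1]; j <- idx[k]
        if (!(h$qstart[i] < h$qstart[j] && h$qend[i] < h$qend[j] &&
              h$tstart[i] < h$tstart[j] && h$tend[i] < h$tend[j] &&
              h$tstart[j] - h$tend[i] - 1 <= max_intron)) { ok <- FALSE; break }
      }
    }
    if (ok && max(h$tend[idx]) - min(h$tstart[idx]) + 1 > max_span) ok <- FALSE
    if (ok) best <- max(best, sum(h$score[idx]))
  }
  best
}

# ungapped seeded X-drop extension re-implemented in plain R, following the
# same stated algorithm (seeds inside an already-extended diagonal region are
# skipped)
oracle_seed_extend <- function(query, subject, k = 4, xdrop = 20, min_score = 50) {
  B <- hrpredict::blosum62()
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  q[!q %in% rownames(B)] <- "X"
  s[!s %in% rownames(B)] <- "X"
  m <- length(q); n <- length(s)
  res <- list()
  covered <- new.env()
  if (m < k || n < k) {
    return(data.frame(qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), score = integer()))
  }
  for (j in seq_len(n - k + 1)) {
    for (i in seq_len(m - k + 1)) {
      if (!all(q[i:(i + k - 1)] == s[j:(j + k - 1)])) next
      if (any(!q[i:(i + k - 1)] %in% AA20h)) next
      d <- as.character(j - i)
      cov <- covered[[d]]
      if (!is.null(cov) && j <= cov) next
      seed <- sum(B[cbind(q[i:(i + k - 1)], s[j:(j + k - 1)])])
      cur <- seed; best_r <- 0; ext_r <- 0; t <- 1
      while (i + k - 1 + t <= m && j + k - 1 + t <= n) {
        cur <- cur + B[q[i + k - 1 + t], s[j + k - 1 + t]]
        if (cur - seed > best_r) { best_r <- cur - seed; ext_r <- t }
        if (best_r - (cur - seed) > xdrop) break
        t <- t + 1
      }
      cur <- 0; best_l <- 0; ext_l <- 0; t <- 1
      while (i - t >= 1 && j - t >= 1) {
        cur <- cur + B[q[i - t], s[j - t]]
        if (cur > best_l) { best_l <- cur; ext_l <- t }
        if (best_l - cur > xdrop) break
        t <- t + 1
      }
      total <- seed + best_r + best_l
      if (total >= min_score) {
        res[[length(res) + 1]] <- data.frame(
          qstart = i - ext_l, qend = i + k - 1 + ext_r,
          sstart = j - ext_l, send = j + k - 1 + ext_r, score = total)
      }
      send <- j + k - 1 + ext_r
      if (is.null(cov) || send > cov) covered[[d]] <- send
    }
  }
  if (length(res) == 0) {
    return(data.frame(qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), score = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$sstart, out$qstart), , drop = FALSE]
}

# exact motif p-values by full enumeration over all w-mers of a reduced
# alphabet: returns P(integer score >= s) for a query score s
oracle_motif_tail <- function(motif, s_int, alphabet_idx, precision = 100) {
  si <- round(motif$logodds * precision)
  bg <- motif$background
  w <- motif$width
  words <- expand.grid(rep(list(alphabet_idx), w))
  tot <- 0
  for (r in seq_len(nrow(words))) {
    idx <- as.integer(words[r, ])
    sc <- sum(si[cbind(seq_len(w), idx)])
    pr <- prod(bg[idx] / sum(bg[alphabet_idx]))
    if (sc >= s_int) tot <- tot + pr
  }
  tot
}

# base-by-base shared/union coding fraction
oracle_cds_fraction <- function(ex_a, ex_b) {
  ba <- unlist(lapply(seq_len(nrow(ex_a)), function(i) ex_a[i, "start"]:ex_a[i, "end"]))
  bb <- unlist(lapply(seq_len(nrow(ex_b)), function(i) ex_b[i, "start"]:ex_b[i, "end"]))
  length(intersect(ba, bb)) / length(union(ba, bb))
}

# score an alignment from its op list (codon matches, gaps, introns)
score_from_ops <- function(ops, query, cds, qstart, gap_open = 11, gap_extend = 1,
                           intron_cost = 20) {
  B <- hrpredict::blosum62()
  qi <- qstart; ci <- 1L
  total <- 0; prev <- ""
  qaa <- strsplit(query, "")[[1]]
  for (op in ops) {
    if (op == "M") {
      codon <- substr(cds, ci, ci + 2)
      aa <- oracle_translate(codon)
      a <- if (aa %in% rownames(B)) aa else "X"
      b <- if (qaa[qi] %in% rownames(B)) qaa[qi] else "X"
      total <- total + B[b, a]
      qi <- qi + 1L; ci <- ci + 3L
    } else if (op == "I") {
      total <- total - if (prev == "I") gap_extend else gap_open
      ci <- ci + 3L
    } else if (op == "D") {
      total <- total - if (prev == "D") gap_extend else gap_open
      qi <- qi + 1L
    } else if (startsWith(op, "N")) {
      total <- total - intron_cost
    }
    prev <- substr(op, 1, 1)
  }
  total
}

# small synthetic gene fixture shared by several tests
make_gene_fixture <- function(seed = 5, n_introns = 1, class_label = "CNL",
                              identity = 1, flank = 2500) {
  withr::with_seed(seed, {
    q <- generate_rgene(class_label, identity)$protein
    cds <- reverse_translate(q)
    st <- hrpredict:::build_gene_structure(cds, n_introns)
    genome <- paste0(hrpredict:::random_dna(flank), st$seq,
                     hrpredict:::random_dna(flank))
    list(query = q, cds = cds, struct = st, genome = genome, offset = flank)
  })
}

# exhaustive gapless <=1-intron local alignment enumeration for tiny instances
oracle_spliced_best <- function(query, dna, intron_cost = 20,
                                min_intron = 40, max_intron = 2000) {
  B <- blosum62()
  q <- strsplit(query, "")[[1]]
  m <- length(q); n <- nchar(dna)
  codon_score <- function(qi, s) {
    if (s + 2 > n) return(NA_real_)
    aa <- oracle_translate(substr(dna, s, s + 2))
    B[q[qi], if (aa %in% rownames(B)) aa else "X"]
  }
  donors <- which(vapply(seq_len(n - 1), function(j)
    substr(dna, j, j + 1) == "GT", TRUE))
  best <- 0
  for (q0 in seq_len(m)) {
    for (s0 in seq_len(n - 2)) {
      # gapless, no intron
      cum <- 0; k <- 0
      prefix <- numeric(0)
      while (q0 + k <= m && s0 + 3 * k + 2 <= n) {
        cum <- cum + codon_score(q0 + k, s0 + 3 * k)
        k <- k + 1
        prefix[k] <- cum
        if (cum > best) best <- cum
      }
      # one intron after c codons
      for (cc in seq_len(length(prefix))) {
        d <- s0 + 3 * cc            # first intron base
        if (!(d %in% donors)) next
        for (L in seq(min_intron, min(max_intron, n - d + 1))) {
          p <- d + L - 1            # last intron base
          if (p + 3 > n) break
          if (substr(dna, p - 1, p) != "AG") next
          cum2 <- prefix[cc] - intron_cost
          k2 <- 0
          while (q0 + cc + k2 <= m && p + 1 + 3 * k2 + 2 <= n) {
            cum2 <- cum2 + codon_score(q0 + cc + k2, p + 1 + 3 * k2)
            k2 <- k2 + 1
            if (cum2 > best) best <- cum2
          }
        }
      }
    }
  }
  best
}

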