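test_that("an exact in-frame copy yields one HSP with the query self-score", {
  fx <- make_gene_fixture(seed = 5, n_introns = 0)
  # intron-less: genome contains the CDS verbatim
  genome <- paste0(substring(fx$genome, 1, fx$offset), fx$cds,
                   substring(fx$genome, fx$offset + nchar(fx$struct$seq) + 1))
  h <- seed_and_extend(fx$query, genome)
  top <- h[which.max(h$score), ]
  B <- blosum62(); aa <- strsplit(fx$query, "")[[1]]
  expect_equal(top$qstart, 1L)
  expect_equal(top$qend, nchar(fx$query))
  expect_equal(top$score, sum(B[cbind(aa, aa)]))
  expect_equal(top$gstart, fx$offset + 1L)
})

test_that("a genome sharing no seed word yields no HSP", {
  withr::local_seed(3)   # fixture pre-checked: no WWWW word in any frame
  q <- strrep("W", 20)
  g <- random_dna_str(2000)
  expect_equal(nrow(seed_and_extend(q, g)), 0L)
})

test_that("HSP generation equals the brute-force diagonal oracle on 50 fixtures", {
  withr::local_seed(91)
  for (i in 1:50) {
    q <- random_protein(sample(25:50, 1))
    s <- random_protein(sample(80:150, 1))
    if (i %% 2 == 0) {
      # implant a mutated copy of part of the query
      frag <- substring(q, 5, 24)
      fa <- strsplit(frag, "")[[1]]
      fa[sample(20, 3)] <- sample(AA20h, 3, replace = TRUE)
      pos <- sample(nchar(s) - 20, 1)
      s <- paste0(substring(s, 1, pos), paste(fa, collapse = ""),
                  substring(s, pos + 21))
    }
    got <- hrpredict:::cpp_seed_extend(q, s, blosum62(), 4L, 20L, 30L)
    want <- oracle_seed_extend(q, s, k = 4, xdrop = 20, min_score = 30)
    got <- got[order(got$sstart, got$qstart), , drop = FALSE]
    expect_equal(nrow(got), nrow(want), info = i)
    if (nrow(got)) {
      expect_equal(got$qstart, want$qstart, info = i)
      expect_equal(got$qend, want$qend, info = i)
      expect_equal(got$sstart, want$sstart, info = i)
      expect_equal(got$send, want$send, info = i)
      expect_equal(got$score, want$score, info = i)
    }
  }
})

make_hsp_tbl <- function(qstart, qend, tstart, tend, score) {
  tibble::tibble(qstart = qstart, qend = qend, tstart = tstart, tend = tend,
                 gstart = tstart, gend = tend, strand = "+", frame = 0L,
                 score = as.integer(score))
}

test_that("three colinear non-overlapping HSPs chain into one chain with summed score", {
  h <- make_hsp_tbl(c(1, 40, 80), c(30, 70, 120), c(1, 500, 1200),
                    c(90, 590, 1320), c(100, 120, 140))
  ch <- chain_hsps(h)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$score, 360)
  expect_equal(nrow(ch$hsps[[1]]), 3L)
})

test_that("chaining equals subset enumeration on <= 10-HSP instances", {
  withr::local_seed(17)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    ts <- sort(sample(1:5000, n))
    h <- make_hsp_tbl(
      qstart = sample(1:300, n), qend = 0L, tstart = ts, tend = ts + sample(60:300, n),
      score = sample(50:200, n))
    h$qend <- h$qstart + sample(20:80, n)
    got <- chain_hsps(h, max_span = 1e6, max_intron = 2000)
    want <- oracle_best_chain(h, max_intron = 2000, max_span = 1e6)
    expect_equal(max(got$score), want, info = i)
  }
})

test_that("two HSP groups 50 kb apart split into two chains by the span rule", {
  h <- make_hsp_tbl(c(1, 40, 200, 240), c(30, 70, 230, 270),
                    c(1, 500, 50001, 50500), c(90, 590, 50090, 50590),
                    c(100, 100, 100, 100))
  ch <- chain_hsps(h, max_span = 20000L, max_intron = 1e6L)
  expect_equal(nrow(ch), 2L)
  expect_equal(sort(ch$score), c(200, 200))
})

test_that("a generator-made two-exon gene is recovered with exact exon boundaries", {
  fx <- make_gene_fixture(seed = 5, n_introns = 1)
  h <- seed_and_extend(fx$query, fx$genome)
  ch <- chain_hsps(h)
  m <- spliced_align(fx$query, fx$genome, ch[1, ], intron_cost = 20L,
                     max_intron = 2000L)
  got <- m$exons[[1]][, c("start", "end")] - fx$offset
  expect_equal(unname(got), unname(as.matrix(fx$struct$exons)))
  m <- extract_and_translate(m, c(seq = fx$genome))
  expect_equal(m$protein, fx$query)
})

test_that("an intron-less copy reduces to the single-HSP projection plus the stop codon", {
  fx <- make_gene_fixture(seed = 8, n_introns = 0)
  genome <- paste0(substring(fx$genome, 1, fx$offset), fx$cds,
                   substring(fx$genome, fx$offset + nchar(fx$struct$seq) + 1))
  h <- seed_and_extend(fx$query, genome)
  top <- h[which.max(h$score), ]
  ch <- chain_hsps(h)
  m <- spliced_align(fx$query, genome, ch[1, ])
  ex <- m$exons[[1]]
  expect_equal(nrow(ex), 1L)
  expect_equal(ex[1, "start"], top$gstart, ignore_attr = TRUE)
  expect_equal(ex[1, "end"], top$gend + 3L, ignore_attr = TRUE)  # stop codon
  expect_equal(m$score, top$score)
})

test_that("DP equals exhaustive enumeration on tiny spliced instances", {
  withr::local_seed(29)
  for (i in 1:12) {
    q <- random_protein(8)
    cds <- reverse_translate(q)
    cds <- substring(cds, 1, 24)  # 8 codons, no stop
    c1 <- substring(cds, 1, 12); c2 <- substring(cds, 13, 24)
    intron <- paste0("GT", random_dna_str(38), "AG")  # length 42
    dna <- paste0(random_dna_str(20), c1, intron, c2, random_dna_str(20))
    got <- hrpredict:::cpp_spliced_align(q, dna, blosum62(), 11L, 1L, 20L,
                                         40L, 2000L)
    want <- oracle_spliced_best(q, dna)
    expect_equal(got$score, want, info = i)
  }
  # random tiny instances: the DP explores a superset (gaps), so it can only
  # match or beat the gapless enumeration
  for (i in 1:8) {
    q <- random_protein(10)
    dna <- random_dna_str(120)
    got <- hrpredict:::cpp_spliced_align(q, dna, blosum62(), 11L, 1L, 20L,
                                         40L, 2000L)
    expect_gte(got$score, oracle_spliced_best(q, dna))
  }
})

test_that("candidate scores re-derive from the alignment operations", {
  fx <- make_gene_fixture(seed = 41, n_introns = 2, identity = 0.9)
  cands <- predict_homologs(c(q = fx$query), c(chr = fx$genome))
  expect_gte(nrow(cands), 1L)
  cand <- cands[1, ]
  ex <- cand$exons[[1]]
  cds <- paste0(substring(fx$genome, ex[, "start"], ex[, "end"]), collapse = "")
  ops <- cand$ops[[1]]
  ncod_ops <- sum(ops %in% c("M", "I"))
  if (nchar(cds) == 3 * ncod_ops + 3) cds <- substring(cds, 1, nchar(cds) - 3)
  expect_equal(score_from_ops(ops, fx$query, cds, cand$qstart), cand$S)
})

test_that("every returned model re-translates consistently with its protein", {
  fx <- make_gene_fixture(seed = 43, n_introns = 1, identity = 0.85)
  cands <- predict_homologs(c(q = fx$query), c(chr = fx$genome))
  cands <- extract_and_translate(cands, c(chr = fx$genome))
  expect_true(all(nchar(cands$protein) > 0))
  expect_true(all(!cands$frameshift))  # DP emits codon-multiple models
})

test_that("strand symmetry: the reverse-complemented genome gives mirror models with equal scores", {
  fx <- make_gene_fixture(seed = 47, n_introns = 1)
  n <- nchar(fx$genome)
  a <- predict_homologs(c(q = fx$query), c(chr = fx$genome))
  b <- predict_homologs(c(q = fx$query), c(chr = revcomp(fx$genome)))
  expect_equal(sort(a$S), sort(b$S))
  sa <- hrpredict:::model_span(a[which.max(a$S), ])
  sb <- hrpredict:::model_span(b[which.max(b$S), ])
  expect_equal(sb$start, n - sa$end + 1L)
  expect_equal(sb$end, n - sa$start + 1L)
  expect_true(all(a$strand[which.max(a$S)] != b$strand[which.max(b$S)]))
})

test_that("E-values are strictly decreasing in the score", {
  S <- seq(50, 500, by = 10)
  E <- hsp_evalue(S, m = 500, n = 1e6)
  expect_true(all(diff(E) < 0))
})

test_that("an implanted full-length homolog passes E <= 0.01 with truth-identical CDS", {
  fx <- make_gene_fixture(seed = 53, n_introns = 2)
  cands <- predict_homologs(c(q = fx$query), c(chr = fx$genome))
  top <- cands[1, ]
  expect_lt(top$evalue, 0.01)
  got <- top$exons[[1]][, c("start", "end")] - fx$offset
  expect_equal(unname(got), unname(as.matrix(fx$struct$exons)))
})

test_that("random genomes almost never produce E <= 0.01 candidates (stochastic null)", {
  withr::local_seed(71)
  q <- generate_rgene("CNL", 1)$protein
  clean <- 0L
  for (i in 1:20) {
    g <- random_dna_str(100000)
    cands <- predict_homologs(c(q = q), c(chr = g))
    if (nrow(cands) == 0) clean <- clean + 1L
  }
  expect_gte(clean, 19L)
})

test_that("bundled Karlin parameters are consistent with shuffled-score statistics", {
  withr::local_seed(83)
  q <- random_protein(150)
  evals <- vapply(1:8, function(i) {
    g <- random_dna_str(30000)
    h <- seed_and_extend(q, g, min_score = 30L)
    smax <- if (nrow(h)) max(h$score) else 30
    hsp_evalue(smax, 150, 2 * 30000)
  }, 0)
  # the E-value at the per-run maximum should be of order 1 under the null
  expect_gt(median(evals), 0.05)
  expect_lt(median(evals), 50)
})
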