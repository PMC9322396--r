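implant_fixture <- function(n = 50, len = 60, motif = "WNDKAR", seed = 7) {
  withr::with_seed(seed, {
    pos <- integer(n)
    seqs <- vapply(seq_len(n), function(i) {
      bg <- random_protein(len)
      p <- sample(seq_len(len - nchar(motif) + 1), 1)
      pos[i] <<- p
      paste0(substring(bg, 1, p - 1), motif,
             substring(bg, p + nchar(motif), len))
    }, "")
    list(seqs = seqs, pos = pos)
  })
}

test_that("an implanted 6-mer is recovered within Hamming distance 1 at >= 45/50 sites", {
  fx <- implant_fixture()
  mo <- discover_motifs(fx$seqs, n_motifs = 3)
  m1 <- mo[[1]]
  expect_equal(m1$width, 6L)
  hamming <- sum(strsplit(m1$consensus, "")[[1]] != strsplit("WNDKAR", "")[[1]])
  expect_lte(hamming, 1L)
  hit <- sum(m1$sites$pos == fx$pos[m1$sites$seq])
  expect_gte(hit, 45L)
})

test_that("default discovery respects the width bounds and motif count", {
  fx <- implant_fixture(n = 12, len = 40, seed = 3)
  mo <- discover_motifs(fx$seqs)
  expect_lte(length(mo), 19L)
  ws <- vapply(mo, `[[`, 0L, "width")
  expect_true(all(ws >= 4L & ws <= 7L))
})

test_that("identical input copies give a maximal-information exact substring as motif 1", {
  withr::local_seed(9)
  s <- random_protein(40)
  mo <- discover_motifs(rep(s, 10), n_motifs = 1)
  m1 <- mo[[1]]
  expect_true(grepl(m1$consensus, s, fixed = TRUE))
  # information content (sum of -log bg over letters) is maximal among
  # substrings of the same width
  bg <- m1$background
  ic <- function(word) sum(-log(bg[strsplit(word, "")[[1]]]))
  subs <- substring(s, 1:(40 - m1$width + 1), m1$width:(40))
  expect_equal(ic(m1$consensus), max(vapply(subs, ic, 0)))
})

test_that("discovery input contracts are enforced", {
  expect_error(discover_motifs("AAAA"), "at least 2")
  expect_error(discover_motifs(c("ACD", "ACD")), "max_w")
  expect_error(discover_motifs(c(strrep("A", 10), strrep("A", 10))),
               "degenerate")
})

test_that("discovery is bit-identical across repeated runs", {
  fx <- implant_fixture(n = 20, len = 50, seed = 21)
  a <- discover_motifs(fx$seqs, n_motifs = 5, seed = 1)
  b <- discover_motifs(fx$seqs, n_motifs = 5, seed = 1)
  expect_identical(a, b)
})

test_that("width-1 single-residue motif has analytic p-value = background frequency", {
  bg <- setNames(rep(0.05, 20), AA20h)
  lo <- matrix(-10, nrow = 1, ncol = 20, dimnames = list(NULL, AA20h))
  lo[1, "L"] <- 2
  motif <- list(id = 1L, width = 1L, logodds = lo, background = bg)
  h <- motif_hit_pvalue("LA", motif)
  expect_equal(h$pvalue[h$pos == 1], 0.05)   # score 2 only from L
  expect_equal(h$pvalue[h$pos == 2], 1)      # minimum of the distribution
})

test_that("staged-convolution p-values equal full enumeration on a 4-letter alphabet", {
  withr::local_seed(5)
  idx4 <- match(c("A", "C", "G", "L"), AA20h)
  bg <- setNames(rep(1e-9, 20), AA20h)
  bg[idx4] <- c(0.4, 0.3, 0.2, 0.1)
  bg <- bg / sum(bg)
  lo <- matrix(round(rnorm(60), 2), nrow = 3, ncol = 20,
               dimnames = list(NULL, AA20h))
  motif <- list(id = 1L, width = 3L, logodds = lo, background = bg)
  # proteins drawn from the reduced alphabet: every window's p-value must
  # match exhaustive enumeration over the 4^3 = 64 words
  p <- paste(sample(c("A", "C", "G", "L"), 30, replace = TRUE), collapse = "")
  h <- motif_hit_pvalue(p, motif)
  for (r in seq_len(nrow(h))) {
    want <- unname(oracle_motif_tail(motif, round(h$score[r] * 100), idx4))
    expect_equal(h$pvalue[r], want, tolerance = 1e-6)
  }
})

test_that("the distribution minimum scores have p-value 1", {
  bg <- setNames(rep(0.05, 20), AA20h)
  lo <- matrix(0, nrow = 2, ncol = 20, dimnames = list(NULL, AA20h))
  lo[, "A"] <- 3
  motif <- list(id = 1L, width = 2L, logodds = lo, background = bg)
  h <- motif_hit_pvalue("CCC", motif)   # scores 0 = distribution minimum
  expect_equal(h$pvalue, c(1, 1))
})

test_that("QFAST combination: closed form, boundaries, monotonicity", {
  expect_equal(combined_evalue(0.05, 100),
               list(combined_p = 0.05, evalue = 5))
  # n = 2 with p1*p2 = 0.01: q(1 - ln q) = 0.01 * (1 + ln 100)
  r <- combined_evalue(c(0.1, 0.1), 1)
  expect_equal(r$combined_p, 0.01 * (1 + log(100)), tolerance = 1e-12)
  expect_equal(combined_evalue(c(1, 1), 50),
               list(combined_p = 1, evalue = 50))
  expect_error(combined_evalue(c(0.5, 0), 10), "> 0")
  # monotone nondecreasing in each argument, always in (0, 1]
  withr::local_seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1))
    r1 <- combined_evalue(p, 1)$combined_p
    expect_gt(r1, 0); expect_lte(r1, 1)
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(combined_evalue(p2, 1)$combined_p, r1 - 1e-12)
  }
})

test_that("Monte-Carlo check of the two-uniform product formula", {
  withr::local_seed(77)
  n <- 2e5
  q0 <- 0.01
  emp <- mean(runif(n) * runif(n) <= q0)
  expect_equal(emp, combined_evalue(c(0.1, 0.1), 1)$combined_p,
               tolerance = 0.05)
})

test_that("null best-hit p-values are stochastically >= uniform at rescaling resolution", {
  fx <- implant_fixture(n = 30, len = 60, seed = 15)
  mo <- discover_motifs(fx$seqs, n_motifs = 2)
  m1 <- mo[[1]]
  withr::local_seed(99)
  # 10,000 independent null windows drawn from the motif's background
  words <- vapply(1:10000, function(i)
    paste(sample(AA20h, m1$width, replace = TRUE, prob = m1$background),
          collapse = ""), "")
  pv <- vapply(words, function(w) motif_hit_pvalue(w, m1)$pvalue[1], 0)
  for (t in c(0.01, 0.05, 0.2, 0.5)) {
    expect_lte(mean(pv <= t), t + 0.02)
  }
})

test_that("MEME minimal format serialization is well-formed", {
  fx <- implant_fixture(n = 10, len = 40, seed = 31)
  mo <- discover_motifs(fx$seqs, n_motifs = 2)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_meme(mo, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "MEME version 4")
  expect_equal(sum(grepl("^MOTIF ", lines)), length(mo))
  probs <- as.numeric(strsplit(lines[grep("^MOTIF ", lines)[1] + 2], " +")[[1]])
  expect_equal(sum(probs), 1, tolerance = 1e-4)
})
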