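test_that("FASTA reading folds case, joins wrapped lines, keeps file order", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s2 description text", "ac", "gt"), tf)
  x <- read_fasta(tf, "dna")
  expect_equal(x$id, c("s1", "s2"))
  expect_equal(x$seq, c("ACGT", "ACGT"))
  expect_equal(nchar(x$seq[1]), 4L)
})

test_that("FASTA contract errors: duplicate ids and illegal characters", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GT"), tf)
  expect_error(read_fasta(tf, "dna"), "duplicate.*'a'")
  tf2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU"), tf2)
  expect_error(read_fasta(tf2, "dna"), "illegal dna character 'U' at position 4")
})

test_that("FASTA write/read round trip is identity and wraps at 60 columns", {
  withr::local_seed(1)
  x <- tibble::tibble(id = c("a", "b"),
                      seq = c(random_dna_str(150), random_dna_str(59)),
                      kind = "dna")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(x, tf)
  lines <- readLines(tf)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  expect_equal(read_fasta(tf, "dna"), x)
})

test_that("GFF3 coordinates are 1-based inclusive and minus-strand exons stay ascending", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tID=c1;Parent=m1"), tf)
  m <- read_gff3(tf)
  expect_equal(m$exons[[1]][, "start"], 101L, ignore_attr = TRUE)
  expect_equal(m$exons[[1]][, "end"], 200L, ignore_attr = TRUE)
  expect_equal(hrpredict:::cds_length(m), 100L)
})

test_that("two-exon minus-strand translation matches a manual oracle on a 60-nt fixture", {
  # transcript = revcomp(exon2) + revcomp(exon1); hand-build it
  withr::local_seed(42)
  prot <- "MKLVDEAHRS"                      # 10 aa
  cds <- reverse_translate(prot)            # 33 nt with TAA
  # place on minus strand: genome holds revcomp(cds) split by a 27-nt spacer
  rc <- revcomp(cds)
  ex1 <- substring(rc, 1, 15); ex2 <- substring(rc, 16, 33)
  genome <- paste0("GGGG", ex1, strrep("C", 27), ex2, "GGG")
  m <- gene_models("m1", "chr", "-",
                   list(hrpredict:::new_exon_matrix(c(5, 47), c(19, 64))))
  m <- extract_and_translate(m, c(chr = genome))
  expect_equal(m$protein, prot)
  expect_equal(paste0(m$protein, "*"), oracle_translate(cds))
  expect_equal(m$internal_stops, 0L)
})

test_that("GFF3 write/read round trip preserves models, scores and flags", {
  withr::local_seed(7)
  ex1 <- hrpredict:::new_exon_matrix(c(11, 301), c(100, 402), c(0, 0))
  ex2 <- hrpredict:::new_exon_matrix(c(550), c(720))
  m <- gene_models(c("m1", "m2"), "chr1", c("+", "-"), list(ex1, ex2),
                   score = c(12.5, NA), internal_stops = c(0L, 2L))
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(m, tf)
  m2 <- read_gff3(tf)
  expect_equal(m2$id, m$id)
  expect_equal(m2$exons, m$exons)
  expect_equal(m2$score, m$score)
  expect_equal(m2$strand, m$strand)
  expect_equal(m2$pseudogene, m$pseudogene)
  # second round trip is byte-identical
  tf2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(m2, tf2)
  expect_equal(readLines(tf), readLines(tf2))
})

test_that("GFF3 contract errors and longest-CDS mRNA selection", {
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=m2;Parent=g1",
    "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=c2;Parent=m2"), tf)
  m <- read_gff3(tf)
  expect_equal(m$id, "m2")  # longest CDS kept per gene
  tf2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tCDS\t1\t90\t.\t+\t0\tID=c1"), tf2)
  expect_error(read_gff3(tf2), "Parent")
})

test_that("translation follows the standard code, drops the trailing stop, counts internal stops", {
  expect_equal(translate_cds("ATGGCATAA"),
               list(protein = "MA", internal_stops = 0L, frameshift = FALSE))
  m <- gene_models("m", "c", "-", list(hrpredict:::new_exon_matrix(1, 9)))
  m <- extract_and_translate(m, c(c = "TTACGCCAT"))  # revcomp = ATGGCGTAA
  expect_equal(m$protein, "MA")
  expect_equal(translate_cds("ATGTAAGCATAA")$protein, "M*A")
  expect_equal(translate_cds("ATGTAAGCATAA")$internal_stops, 1L)
})

test_that("frameshifted CDS is flagged pseudogene but still translated in frame 0", {
  r <- translate_cds("ATGGCATA")  # 8 nt
  expect_true(r$frameshift)
  expect_equal(r$protein, "MA")
  m <- gene_models("m", "c", "+", list(hrpredict:::new_exon_matrix(1, 8)))
  m <- extract_and_translate(m, c(c = "ATGGCATAG"))
  expect_true(m$pseudogene)
})

test_that("gene-model exon invariants are enforced", {
  expect_error(gene_models("m", "c", "+",
                           list(cbind(start = 10L, end = 5L, phase = 0L))),
               "start > end")
  expect_error(gene_models("m", "c", "+",
                           list(cbind(start = c(1L, 5L), end = c(10L, 20L),
                                      phase = c(0L, 0L)))),
               "overlap")
})

test_that("six-frame stop profile matches the exhaustive codon-scan oracle", {
  expect_equal(unname(six_frame_stop_profile("TAA")), c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(six_frame_stop_profile("ATGTAGATGTGAATGTAAGGG")),
               oracle_six_frame("ATGTAGATGTGAATGTAAGGG"))
  # 4-nt edge: frames 2/3 hold at most one codon
  expect_equal(unname(six_frame_stop_profile("TTAA")), oracle_six_frame("TTAA"))
  withr::local_seed(33)
  for (i in 1:20) {
    d <- random_dna_str(sample(3:200, 1))
    expect_equal(unname(six_frame_stop_profile(d)), oracle_six_frame(d))
  }
  expect_error(six_frame_stop_profile("ACGU"), "non-DNA")
})

test_that("six-frame profile of the reverse complement is the frame-swapped profile", {
  withr::local_seed(11)
  for (i in 1:10) {
    d <- random_dna_str(sample(6:120, 1))
    p <- six_frame_stop_profile(d)
    pr <- six_frame_stop_profile(revcomp(d))
    expect_equal(unname(pr), unname(p[c(4:6, 1:3)]))
  }
})

test_that("CDS length identity: exon lengths equal 3*protein+3 for stop-bearing models", {
  fx <- make_gene_fixture(seed = 21, n_introns = 2)
  m <- gene_models("m", "chr", "+",
                   list(hrpredict:::new_exon_matrix(
                     fx$struct$exons$start + fx$offset,
                     fx$struct$exons$end + fx$offset)))
  m <- extract_and_translate(m, c(chr = fx$genome))
  expect_false(m$frameshift)
  expect_equal(hrpredict:::cds_length(m), 3L * nchar(m$protein) + 3L)
})

test_that("BED6 export uses 0-based half-open spans", {
  m <- gene_models("m1", "chr1", "+",
                   list(hrpredict:::new_exon_matrix(c(101, 301), c(200, 400))))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(m, tf)
  f <- strsplit(readLines(tf), "\t")[[1]]
  expect_equal(f[2], "100")
  expect_equal(f[3], "400")
})
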