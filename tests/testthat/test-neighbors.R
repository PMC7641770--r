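# Shared toy sequences: a Class I toxin, an antitoxin, and an inert gene.
TOX_SEQ <- "MRAAAAHAYKLLM"            # carries RX4HXY
ANTI_SEQ <- "MGSAAAAAAAAAADADKL"      # carries GSX10DXD
BG_SEQ <- "MKLVTTAEE"

toy_three_genes <- function(dir) {
  genes <- data.frame(
    contig = "c1", start1 = c(100, 500, 900), end1 = c(300, 700, 1100),
    strand = "+", protein_id = c("pA", "pB", "pC"), genome_id = "G1")
  prots <- c(pA = ANTI_SEQ, pB = TOX_SEQ, pC = BG_SEQ)
  write_toy_genome(dir, genes, prots)
}

test_that("annotation loads with 0-based coordinates and ranks by start", {
  d <- withr::local_tempdir()
  paths <- toy_three_genes(d)
  gm <- read_annotation(paths$gff3, paths$fasta)
  expect_equal(gm$genes$locus_rank, c(0, 1, 2))
  expect_equal(gm$genes$start, c(99, 499, 899))
  expect_equal(gm$genes$end, c(300, 700, 1100))

  # a 1..300 feature becomes the half-open interval (0, 300)
  expect_equal(gm$genes$start[1] + 1, 100)
})

test_that("locus ranks are invariant to GFF3 record order", {
  d <- withr::local_tempdir()
  paths <- toy_three_genes(d)
  lines <- readLines(paths$gff3)
  shuffled <- c(lines[1], lines[c(4, 2, 3) ])
  writeLines(shuffled, paths$gff3)
  gm <- read_annotation(paths$gff3, paths$fasta)
  expect_equal(gm$genes$protein_id[order(gm$genes$locus_rank)],
               c("pA", "pB", "pC"))
})

test_that("annotation errors name the problem", {
  d <- withr::local_tempdir()
  paths <- toy_three_genes(d)
  # id mismatch
  writeLines(c(">pA", ANTI_SEQ), paths$fasta)
  expect_error(read_annotation(paths$gff3, paths$fasta), "absent from FASTA")
  # malformed line (8 fields) reported with its line number
  paths2 <- toy_three_genes(d)
  lines <- readLines(paths2$gff3)
  lines[3] <- sub("\t0\tID=", "\tID=", lines[3])
  writeLines(lines, paths2$gff3)
  expect_error(read_annotation(paths2$gff3, paths2$fasta),
               "malformed GFF3 line 3")
})

test_that("an adjacent antitoxin-toxin arrangement forms exactly one pair", {
  d <- withr::local_tempdir()
  paths <- toy_three_genes(d)
  gm <- read_annotation(paths$gff3, paths$fasta)
  tox <- scan_proteins(gm$proteins, "RX4HXY")
  anti <- scan_proteins(gm$proteins, "GSX10DXD")
  pairs <- find_candidate_pairs(gm, tox, anti)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$toxin_id, "pB")
  expect_equal(pairs$antitoxin_id, "pA")
  expect_equal(pairs$rank_distance, 1)
  expect_equal(pairs$intergenic_bp, 199)  # 500-based gap: 499 - 300
  expect_equal(pairs$strand_relation, "same")
})

test_that("a lone toxin hit with no motif-bearing neighbor yields no pair", {
  d <- withr::local_tempdir()
  genes <- data.frame(
    contig = "c1", start1 = c(100, 500), end1 = c(300, 700), strand = "+",
    protein_id = c("pT", "pBg"), genome_id = "G1")
  paths <- write_toy_genome(d, genes, c(pT = TOX_SEQ, pBg = BG_SEQ))
  gm <- read_annotation(paths$gff3, paths$fasta)
  pairs <- find_candidate_pairs(gm, scan_proteins(gm$proteins, "RX4HXY"),
                                scan_proteins(gm$proteins, "GSX10DXD"))
  expect_equal(nrow(pairs), 0)
})

test_that("two toxins flanking one antitoxin pair greedily, upstream first", {
  d <- withr::local_tempdir()
  genes <- data.frame(
    contig = "c1", start1 = c(100, 500, 900), end1 = c(300, 700, 1100),
    strand = "+", protein_id = c("pT1", "pA", "pT2"), genome_id = "G1")
  paths <- write_toy_genome(
    d, genes, c(pT1 = TOX_SEQ, pA = ANTI_SEQ, pT2 = TOX_SEQ))
  gm <- read_annotation(paths$gff3, paths$fasta)
  pairs <- find_candidate_pairs(gm, scan_proteins(gm$proteins, "RX4HXY"),
                                scan_proteins(gm$proteins, "GSX10DXD"))
  expect_equal(nrow(pairs), 1)
  # the antitoxin is upstream of pT2, so that pairing is preferred
  expect_equal(pairs$toxin_id, "pT2")
})

test_that("greedy pairing matches the brute-force maximum on random toys", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    roles <- sample(c("T", "A", "B"), n, replace = TRUE)
    # gaps stay below the 500 bp intergenic limit so adjacency is
    # governed by rank distance alone, as in the reference greedy
    starts <- cumsum(sample(seq(100, 400, by = 10), n, replace = TRUE)) + 100
    starts <- as.integer(starts + (seq_len(n) - 1) * 50)
    d <- withr::local_tempdir()
    prots <- setNames(ifelse(roles == "T", TOX_SEQ,
                             ifelse(roles == "A", ANTI_SEQ, BG_SEQ)),
                      paste0("p", seq_len(n)))
    genes <- data.frame(contig = "c1", start1 = starts,
                        end1 = starts + 50, strand = "+",
                        protein_id = names(prots), genome_id = "G1")
    paths <- write_toy_genome(d, genes, prots)
    gm <- read_annotation(paths$gff3, paths$fasta)
    tox <- scan_proteins(gm$proteins, "RX4HXY")
    anti <- scan_proteins(gm$proteins, "GSX10DXD")
    pairs <- find_candidate_pairs(gm, tox, anti)
    # no gene in two pairs
    expect_false(anyDuplicated(c(pairs$toxin_id, pairs$antitoxin_id)) > 0)
    # every feasible adjacent edge set: the result must be a maximal
    # matching (no adjacent toxin/antitoxin both left unpaired) and
    # agree with an independent re-implementation of the greedy rules
    edges <- expand.grid(toxin_id = names(prots)[roles == "T"],
                         antitoxin_id = names(prots)[roles == "A"],
                         stringsAsFactors = FALSE)
    rk <- setNames(gm$genes$locus_rank, gm$genes$protein_id)
    if (nrow(edges)) {
      edges <- edges[abs(rk[edges$toxin_id] - rk[edges$antitoxin_id]) == 1, ,
                     drop = FALSE]
    }
    used <- c(pairs$toxin_id, pairs$antitoxin_id)
    open <- edges[!(edges$toxin_id %in% used) &
                    !(edges$antitoxin_id %in% used), , drop = FALSE]
    expect_equal(nrow(open), 0)
    ref <- reference_greedy_pairs(edges, rk)
    expect_equal(paste(pairs$toxin_id, pairs$antitoxin_id),
                 paste(ref$toxin_id, ref$antitoxin_id))
    # shuffled hit order never changes the pair set
    pairs2 <- find_candidate_pairs(
      gm, tox[sample(nrow(tox)), , drop = FALSE],
      anti[sample(nrow(anti)), , drop = FALSE])
    expect_equal(pairs2, pairs)
  }
})

test_that("pairs never span contigs", {
  d <- withr::local_tempdir()
  genes <- data.frame(
    contig = c("c1", "c2"), start1 = c(100, 100), end1 = c(300, 300),
    strand = "+", protein_id = c("pT", "pA"), genome_id = "G1")
  paths <- write_toy_genome(d, genes, c(pT = TOX_SEQ, pA = ANTI_SEQ))
  gm <- read_annotation(paths$gff3, paths$fasta)
  pairs <- find_candidate_pairs(gm, scan_proteins(gm$proteins, "RX4HXY"),
                                scan_proteins(gm$proteins, "GSX10DXD"))
  expect_equal(nrow(pairs), 0)
})

test_that("class rules assign Class I, Class II, and flag the exclusion", {
  base_pair <- data.frame(
    genome_id = "G1", contig_id = "c1", toxin_id = "pT",
    antitoxin_id = "pA", toxin_rank = 1L, antitoxin_rank = 0L,
    rank_distance = 1L, intergenic_bp = 100L, strand_relation = "same",
    toxin_motif_hits = 1L, antitoxin_motif_hits = 1L,
    class_label = "unclassified", stringsAsFactors = FALSE)

  dom1 <- data.frame(protein_id = c("pT", "pA"),
                     family = c("PF01934", "PF01909"),
                     clan = c("CL0291", "CL0260"))
  expect_equal(classify_pairs(base_pair, dom1)$class_label, "ClassI")

  p2 <- base_pair; p2$toxin_motif_hits <- 0L
  dom2 <- data.frame(protein_id = c("pT", "pA"),
                     family = c("PF05168", "PF01909"),
                     clan = c("CL0291", "CL0260"))
  expect_equal(classify_pairs(p2, dom2)$class_label, "ClassII")

  # PF05168 toxin that nevertheless carries the motif: excluded + flagged
  p3 <- classify_pairs(base_pair, dom2)
  expect_equal(p3$class_label, "unclassified")
  expect_true(p3$flag_pf05168_with_motif)

  # missing antitoxin motif blocks Class I
  p4 <- base_pair; p4$antitoxin_motif_hits <- 0L
  expect_equal(classify_pairs(p4, dom1)$class_label, "unclassified")
})

test_that("the census counts pairs, means and percentages per taxon", {
  pairs <- data.frame(
    genome_id = c("A", "A"), class_label = "ClassI",
    toxin_id = c("t1", "t2"), antitoxin_id = c("a1", "a2"))
  taxa <- data.frame(genome_id = c("A", "B"), taxon = "Proteobacteria")
  cs <- census(pairs, taxa)
  row1 <- cs[cs$class_label == "ClassI", ]
  expect_equal(row1$n_genomes, 2)
  expect_equal(row1$total_pairs, 2)
  expect_equal(row1$mean_per_genome, 1.0)
  expect_equal(row1$pct_genomes_with_pair, 50.0)
  # a class with no pairs anywhere reports zeros
  row2 <- cs[cs$class_label == "ClassII", ]
  expect_equal(row2$total_pairs, 0)
  expect_equal(row2$mean_per_genome, 0)
  expect_equal(row2$pct_genomes_with_pair, 0)
  # census totals = number of classified pairs
  expect_equal(sum(cs$total_pairs), nrow(pairs))

  expect_error(census(pairs, data.frame(genome_id = "B", taxon = "x")),
               "missing from taxa table: A")
})
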