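vtab <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  d[, c("gene_id", "pos", "ref", "alt", "gt")]
}

test_that("diagnostic sites require differing fixed alleles", {
  vR <- vtab(gene_id = "g1", pos = 100L, ref = "A", alt = "G", gt = "0/0")
  vS <- vtab(gene_id = "g1", pos = 100L, ref = "A", alt = "G", gt = "1/1")
  s <- findDiagnosticSites(vR, vS)
  expect_equal(nrow(s), 1L)
  expect_equal(s$allele_R, "A")
  expect_equal(s$allele_S, "G")

  # identical fixed alleles: excluded
  vS2 <- vtab(gene_id = "g1", pos = 100L, ref = "A", alt = "G", gt = "0/0")
  expect_equal(nrow(findDiagnosticSites(vR, vS2)), 0L)

  # heterozygous in R: excluded regardless of S
  vRhet <- vtab(gene_id = "g1", pos = 100L, ref = "A", alt = "G", gt = "0/1")
  expect_equal(nrow(findDiagnosticSites(vRhet, vS)), 0L)

  # species absent from the table carries the reference allele
  empty <- vtab(gene_id = character(), pos = integer(), ref = character(),
                alt = character(), gt = character())
  s2 <- findDiagnosticSites(empty, vS)
  expect_equal(s2$allele_R, "A")
  expect_equal(s2$allele_S, "G")

  # unknown contig rejected when a gene universe is given
  expect_error(findDiagnosticSites(vR, vS, genes = "other_gene"),
               "unknown contigs")

  # multiallelic ALT with hom-alt call: excluded
  vSm <- vtab(gene_id = "g1", pos = 100L, ref = "A", alt = "G,T", gt = "1/1")
  expect_equal(nrow(findDiagnosticSites(vR, vSm)), 0L)

  # output sorted by gene then position
  vSx <- vtab(gene_id = c("g2", "g1", "g1"), pos = c(5L, 200L, 50L),
              ref = c("C", "T", "G"), alt = c("G", "A", "C"),
              gt = "1/1")
  sx <- findDiagnosticSites(empty, vSx)
  expect_equal(sx$gene_id, c("g1", "g1", "g2"))
  expect_equal(sx$pos, c(50L, 200L, 5L))
})

sites2 <- S4Vectors::DataFrame(gene_id = c("g1", "g1"), pos = c(10L, 20L),
                               allele_R = c("A", "A"), allele_S = c("G", "G"))
read1 <- function(seq, pos = 1L, id = "r1")
  data.frame(qname = id, rname = "g1", pos = pos, seq = seq,
             stringsAsFactors = FALSE)

test_that("read assignment categories follow the diagnostic-site rules", {
  # 25-base read covering both sites (positions 10 and 20)
  base <- strrep("C", 25)
  at <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  rr <- at(at(base, 10, "A"), 20, "A")   # matches R at both
  ss <- at(at(base, 10, "G"), 20, "G")   # matches S at both
  rs <- at(at(base, 10, "A"), 20, "G")   # one each: "from two parents"
  rn <- at(at(base, 10, "A"), 20, "T")   # R + neither: still parent_R
  nn <- at(at(base, 10, "T"), 20, "T")   # neither at all covered sites

  a <- assignReads(rbind(read1(rr, id = "r1"), read1(ss, id = "r2"),
                         read1(rs, id = "r3"), read1(rn, id = "r4"),
                         read1(nn, id = "r5"), read1("CCC", 100L, "r6")),
                   sites2)
  expect_equal(a$category,
               c("parent_R", "parent_S", "conflict", "parent_R",
                 "uninformative", "uninformative"))
  expect_equal(a$n_sites_covered, c(2L, 2L, 2L, 2L, 2L, 0L))
  # partition invariant: counts add up
  expect_true(all(a$n_match_R + a$n_match_S + a$n_match_neither ==
                    a$n_sites_covered))
  # duplicated qname (multi-gene read) rejected
  expect_error(assignReads(rbind(read1(rr), read1(ss)), sites2),
               "pre-split")
})

test_that("allele counting tallies categories and keeps empty genes", {
  asg <- S4Vectors::DataFrame(
    read_id = sprintf("r%d", 1:4), sample = "s1",
    gene_id = "g1", n_sites_covered = 1L,
    n_match_R = c(1L, 1L, 1L, 0L), n_match_S = c(0L, 0L, 0L, 1L),
    n_match_neither = 0L,
    category = c("parent_R", "parent_R", "parent_R", "parent_S"))
  ac <- countAlleles(asg, genes = c("g1", "g2"))
  d <- as.data.frame(ac)
  g1 <- d[d$gene_id == "g1", ]
  expect_equal(g1$count_R, 3L)
  expect_equal(g1$count_S, 1L)
  expect_equal(g1$count_total, 4L)
  g2 <- d[d$gene_id == "g2", ]
  expect_equal(g2$count_total, 0L)

  empty <- countAlleles(asg[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("counts are invariant to read order and match simulator truth", {
  cfg <- simulationConfig(nGenes = 15, seed = 41, errorRate = 0,
                          transcriptLength = 500L, readLength = 100L)
  tr <- simulateTruth(cfg)
  rd <- simulateReads(tr, cfg, nReads = 3000)
  asg <- assignReads(rd$alignments, rd$sites)
  ac <- as.data.frame(countAlleles(asg))

  # exact recovery: per gene/sample assigned counts equal true-origin tallies
  covered <- asg$n_sites_covered > 0
  truthTab <- table(rd$reads$gene_id[covered], rd$reads$sample[covered],
                    rd$reads$origin[covered])
  for (i in seq_len(nrow(ac))) {
    g <- ac$gene_id[i]; s <- ac$sample[i]
    inTab <- g %in% rownames(truthTab) && s %in% colnames(truthTab)
    expect_equal(ac$count_R[i], if (inTab) truthTab[g, s, "R"] else 0L)
    expect_equal(ac$count_S[i], if (inTab) truthTab[g, s, "S"] else 0L)
  }
  expect_true(all(ac$count_conflict == 0L))

  # permutation invariance
  perm <- sample(nrow(rd$alignments))
  ac2 <- as.data.frame(countAlleles(assignReads(rd$alignments[perm, ],
                                                rd$sites)))
  expect_identical(ac[order(ac$gene_id, ac$sample), ],
                   ac2[order(ac2$gene_id, ac2$sample), ])
})

test_that("assignment summary reports rates and parental bias", {
  ac <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2"), sample = "s1",
    count_R = c(10L, 30L), count_S = c(10L, 30L),
    count_conflict = c(0L, 0L), count_uninformative = c(5L, 15L),
    count_total = c(25L, 75L))
  s <- assignmentSummary(ac)
  expect_equal(s$perSample$bias_R, 0.5)
  expect_equal(s$perSample$fraction_assigned, 0.8)

  acR <- S4Vectors::DataFrame(gene_id = "g1", sample = "s1",
                              count_R = 40L, count_S = 0L,
                              count_conflict = 0L,
                              count_uninformative = 0L, count_total = 40L)
  sR <- assignmentSummary(acR)
  expect_equal(sR$perSample$bias_R, 1)
  expect_equal(sR$perSample$fraction_assigned, 1)
  expect_lt(sR$perGene$p, 0.001)   # 40:0 against fair split

  # zero-total sample reported as missing, not an error
  ac0 <- S4Vectors::DataFrame(gene_id = "g1", sample = "s2",
                              count_R = 0L, count_S = 0L,
                              count_conflict = 0L,
                              count_uninformative = 0L, count_total = 0L)
  expect_true(is.na(assignmentSummary(ac0)$perSample$fraction_assigned))
})
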