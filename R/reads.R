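.BASES <- c("A", "C", "G", "T")

## deterministic site placement: one site every round(1000/snpPerKb) bases,
## starting at half the spacing; density 0 => no sites
.sitePositions <- function(len, snpPerKb) {
  if (snpPerKb <= 0) return(integer())
  spacing <- max(1L, as.integer(round(1000 / snpPerKb)))
  seq.int(from = max(1L, spacing %/% 2L), to = len, by = spacing)
}

#' Simulate hybrid reads carrying diagnostic alleles
#'
#' For every gene a transcript template is drawn (the species-R sequence is
#' the reference); diagnostic sites are placed at density `snpPerKb`
#' (regular spacing, so coverage of sites is predictable), and the species-S
#' haplotype differs from R at exactly those sites. Reads of length
#' `readLength` are sampled uniformly along the transcript of the allele
#' implied by their (recorded) origin; allocation of reads over genes and
#' origins is proportional to the expected hybrid allele means. The base at
#' a covered diagnostic site is flipped to a uniformly random different base
#' with probability `errorRate`.
#'
#' @param truth truth table from [simulateTruth()].
#' @param config a \linkS4class{SimulationConfig}; its seed (offset by 2)
#'   governs this stage.
#' @param nReads total number of reads to simulate.
#' @return A list:
#'   \item{reads}{DataFrame: read_id, sample, gene_id, origin ("R"/"S"),
#'     start (1-based), seq, qual.}
#'   \item{sites}{diagnostic-site DataFrame: gene_id, pos (1-based),
#'     allele_R, allele_S.}
#'   \item{reference}{named character vector of species-R transcript
#'     sequences.}
#'   \item{alignments}{DataFrame ready for [writeSam()]: qname, rname, pos,
#'     seq (all reads fully aligned, CIGAR `<readLength>M`).}
#' @export
simulateReads <- function(truth, config, nReads = 100L * nrow(truth)) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@readLength >= config@transcriptLength + 1L)
    stop("readLength must not exceed transcriptLength")
  set.seed(config@seed + 2L)
  n <- nrow(truth)
  len <- config@transcriptLength
  rl <- config@readLength
  genes <- truth$gene_id

  ## templates and diagnostic sites
  tmplR <- vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE), collapse = ""), "")
  names(tmplR) <- genes
  sitePos <- .sitePositions(len, config@snpPerKb)
  siteTab <- DataFrame(
    gene_id = rep(genes, each = length(sitePos)),
    pos = rep(sitePos, times = n))
  if (nrow(siteTab)) {
    aR <- unname(substring(tmplR[siteTab$gene_id], siteTab$pos, siteTab$pos))
    shift <- sample(1:3, nrow(siteTab), replace = TRUE)
    aS <- .BASES[(match(aR, .BASES) - 1L + shift) %% 4L + 1L]
    siteTab$allele_R <- aR
    siteTab$allele_S <- aS
  } else {
    siteTab$allele_R <- character()
    siteTab$allele_S <- character()
  }
  tmplS <- tmplR
  if (length(sitePos)) {
    for (i in seq_len(n)) {
      s <- tmplS[i]
      rows <- which(siteTab$gene_id == genes[i])
      for (r in rows)
        substr(s, siteTab$pos[r], siteTab$pos[r]) <- siteTab$allele_S[r]
      tmplS[i] <- s
    }
  }

  ## allocate reads over gene x origin proportional to expected allele means
  wR <- expectedMeans(truth, "hybrid_allele_R")
  wS <- expectedMeans(truth, "hybrid_allele_S")
  w <- c(wR, wS) / sum(wR, wS)
  pick <- sample.int(2L * n, nReads, replace = TRUE, prob = w)
  gidx <- ifelse(pick > n, pick - n, pick)
  origin <- ifelse(pick > n, "S", "R")
  start <- sample.int(len - rl + 1L, nReads, replace = TRUE)
  tmpl <- ifelse(origin == "R", tmplR[gidx], tmplS[gidx])
  seqs <- substring(tmpl, start, start + rl - 1L)

  ## sequencing errors at covered diagnostic sites only
  if (length(sitePos) && config@errorRate > 0) {
    for (p in sitePos) {
      cov <- which(start <= p & p + 0L <= start + rl - 1L)
      err <- cov[stats::runif(length(cov)) < config@errorRate]
      if (!length(err)) next
      off <- p - start[err] + 1L
      for (k in seq_along(err)) {
        i <- err[k]
        old <- substr(seqs[i], off[k], off[k])
        substr(seqs[i], off[k], off[k]) <-
          sample(setdiff(.BASES, old), 1L)
      }
    }
  }

  samp <- paste0("hybrid_", sample.int(config@nReplicates, nReads,
                                       replace = TRUE))
  reads <- DataFrame(
    read_id = sprintf("read%07d", seq_len(nReads)),
    sample = samp,
    gene_id = genes[gidx],
    origin = origin,
    start = start,
    seq = seqs,
    qual = strrep("I", rl))
  list(reads = reads,
       sites = siteTab,
       reference = tmplR,
       alignments = DataFrame(qname = reads$read_id,
                              rname = reads$gene_id,
                              pos = reads$start,
                              seq = reads$seq,
                              sample = samp))
}
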