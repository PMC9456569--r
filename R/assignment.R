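#' Identify species-diagnostic sites from two parental variant tables
#'
#' A site is diagnostic when each species is represented by a single fixed
#' allele there and the two alleles differ. Heterozygous (`0/1`),
#' multiallelic and missing (`./.`) genotype calls exclude a site. When a
#' position appears in only one species' table, the other species is taken
#' to carry the reference allele recorded at that row (the common case when
#' one species' transcriptome is the mapping reference).
#'
#' Variant tables are data.frames with columns `gene_id`, `pos` (1-based),
#' `ref`, `alt`, `gt` (a diploid genotype string such as `"0/0"`, `"1/1"`,
#' `"0/1"` or `"./."`); [readVariants()] produces them from VCF.
#'
#' @param variantsR,variantsS variant tables for species R and S.
#' @param genes optional character vector restricting/validating the gene
#'   universe; positions on unknown genes raise an error.
#' @return DataFrame with columns `gene_id`, `pos`, `allele_R`, `allele_S`,
#'   sorted by gene then position.
#' @examples
#' vR <- data.frame(gene_id = "g1", pos = 100, ref = "A", alt = "G",
#'                  gt = "0/0")
#' vS <- data.frame(gene_id = "g1", pos = 100, ref = "A", alt = "G",
#'                  gt = "1/1")
#' findDiagnosticSites(vR, vS)
#' @export
findDiagnosticSites <- function(variantsR, variantsS, genes = NULL) {
  fixedAllele <- function(v) {
    gt <- gsub("\\|", "/", as.character(v$gt))
    alt1 <- vapply(strsplit(as.character(v$alt), ","),
                   function(a) if (length(a) == 1L) a else NA_character_, "")
    allele <- rep(NA_character_, nrow(v))
    allele[gt == "0/0"] <- as.character(v$ref)[gt == "0/0"]
    allele[gt == "1/1"] <- alt1[gt == "1/1"]
    ## heterozygous, missing or multiallelic calls stay NA (excluded)
    allele[!allele %in% .BASES] <- NA_character_
    data.frame(gene_id = as.character(v$gene_id), pos = as.integer(v$pos),
               ref = as.character(v$ref), allele = allele,
               stringsAsFactors = FALSE)
  }
  fR <- fixedAllele(variantsR)
  fS <- fixedAllele(variantsS)
  if (!is.null(genes)) {
    bad <- setdiff(unique(c(fR$gene_id, fS$gene_id)), genes)
    if (length(bad))
      stop("variant table references unknown contigs: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- function(d) paste(d$gene_id, d$pos)
  m <- merge(fR, fS, by = c("gene_id", "pos"), all = TRUE,
             suffixes = c("_R", "_S"))
  ## a species absent at a position carries that row's reference allele;
  ## a species present but unresolved (NA allele, e.g. het) excludes the site
  presentR <- key(m) %in% key(fR)
  presentS <- key(m) %in% key(fS)
  ref <- ifelse(is.na(m$ref_R), m$ref_S, m$ref_R)
  alleleR <- ifelse(presentR, m$allele_R, ref)
  alleleS <- ifelse(presentS, m$allele_S, ref)
  keep <- !is.na(alleleR) & !is.na(alleleS) & alleleR != alleleS &
    alleleR %in% .BASES & alleleS %in% .BASES
  out <- DataFrame(gene_id = m$gene_id[keep], pos = m$pos[keep],
                   allele_R = alleleR[keep], allele_S = alleleS[keep])
  out[order(out$gene_id, out$pos), , drop = FALSE]
}

#' Assign hybrid reads to parental origin via diagnostic sites
#'
#' Each aligned read is compared with its covered diagnostic sites:
#' reads whose covered bases match only species-R alleles are `parent_R`,
#' only species-S alleles `parent_S`, at least one match to each parent
#' `conflict` ("from two parents"), and reads covering no diagnostic site or
#' matching neither allele at every covered site are `uninformative`
#' ("unknown"). Bases matching neither allele (sequencing error / residual
#' polymorphism) never veto an otherwise unanimous read.
#'
#' @param alignments data.frame of single-gene alignments: `qname`, `rname`
#'   (gene), `pos` (1-based leftmost), `seq`; an optional `sample` column is
#'   carried through ([readSam()] and [simulateReads()] provide it).
#' @param sites diagnostic-site table from [findDiagnosticSites()] (or the
#'   simulator).
#' @return DataFrame: `read_id`, `sample`, `gene_id`, `n_sites_covered`,
#'   `n_match_R`, `n_match_S`, `n_match_neither`, `category`.
#' @export
assignReads <- function(alignments, sites) {
  aln <- as.data.frame(alignments)
  if (anyDuplicated(aln$qname))
    stop("reads spanning multiple genes/alignments must be pre-split: ",
         "duplicated qname in input")
  if (is.null(aln$sample)) aln$sample <- "sample_1"
  n <- nrow(aln)
  nR <- nS <- nN <- integer(n)
  st <- as.data.frame(sites)
  if (nrow(st) && n) {
    width <- nchar(aln$seq)
    pr <- merge(
      data.frame(idx = seq_len(n), gene_id = as.character(aln$rname),
                 start = aln$pos, end = aln$pos + width - 1L,
                 stringsAsFactors = FALSE),
      st, by = "gene_id")
    pr <- pr[pr$pos >= pr$start & pr$pos <= pr$end, , drop = FALSE]
    if (nrow(pr)) {
      base <- substring(aln$seq[pr$idx], pr$pos - pr$start + 1L,
                        pr$pos - pr$start + 1L)
      mR <- base == pr$allele_R
      mS <- base == pr$allele_S
      add <- function(w) {
        z <- integer(n)
        if (any(w)) {
          t <- rowsum(rep(1L, sum(w)), pr$idx[w])
          z[as.integer(rownames(t))] <- t[, 1L]
        }
        z
      }
      nR <- add(mR); nS <- add(mS); nN <- add(!mR & !mS)
    }
  }
  category <- rep("uninformative", n)
  category[nR > 0L & nS == 0L] <- "parent_R"
  category[nS > 0L & nR == 0L] <- "parent_S"
  category[nR > 0L & nS > 0L] <- "conflict"
  DataFrame(read_id = aln$qname, sample = aln$sample,
            gene_id = as.character(aln$rname),
            n_sites_covered = nR + nS + nN,
            n_match_R = nR, n_match_S = nS, n_match_neither = nN,
            category = category)
}

#' Tally read assignments into an allele count matrix
#'
#' @param assignments DataFrame from [assignReads()].
#' @param genes,samples optional universes; genes/samples without reads get
#'   all-zero rows.
#' @return DataFrame (long form): `gene_id`, `sample`, `count_R`, `count_S`,
#'   `count_conflict`, `count_uninformative`, `count_total`.
#' @export
countAlleles <- function(assignments, genes = NULL, samples = NULL) {
  a <- as.data.frame(assignments)
  genes <- sort(unique(c(genes, a$gene_id)))
  samples <- sort(unique(c(samples, a$sample)))
  grid <- expand.grid(gene_id = genes, sample = samples,
                      stringsAsFactors = FALSE)
  cats <- c(parent_R = "count_R", parent_S = "count_S",
            conflict = "count_conflict", uninformative = "count_uninformative")
  for (nm in cats) grid[[nm]] <- rep(0L, nrow(grid))
  if (nrow(a)) {
    tab <- table(paste(a$gene_id, a$sample, sep = "\r"), a$category)
    idx <- match(paste(grid$gene_id, grid$sample, sep = "\r"), rownames(tab))
    for (cat in names(cats)) {
      if (cat %in% colnames(tab)) {
        v <- tab[, cat][idx]
        v[is.na(v)] <- 0L
        grid[[cats[[cat]]]] <- as.integer(v)
      }
    }
  }
  grid$count_total <- grid$count_R + grid$count_S + grid$count_conflict +
    grid$count_uninformative
  DataFrame(grid)
}

#' Summarize assignment rates and parental bias
#'
#' Per sample: the fraction of reads assigned to either parent,
#' `(R + S) / total`, and the parental bias `R / (R + S)` aggregated over
#' genes. Per gene (aggregated over samples): the bias with a two-sided
#' exact binomial test against 0.5, BH-adjusted across genes.
#'
#' @param alleleCounts DataFrame from [countAlleles()].
#' @return list with elements `perSample` and `perGene` (DataFrames).
#' @export
assignmentSummary <- function(alleleCounts) {
  ac <- as.data.frame(alleleCounts)
  agg <- function(d) {
    tot <- sum(d$count_total); rs <- sum(d$count_R) + sum(d$count_S)
    c(assigned = if (tot > 0) rs / tot else NA_real_,
      bias = if (rs > 0) sum(d$count_R) / rs else NA_real_)
  }
  per_sample <- do.call(rbind, lapply(split(ac, ac$sample), agg))
  perSample <- DataFrame(sample = rownames(per_sample),
                         fraction_assigned = per_sample[, "assigned"],
                         bias_R = per_sample[, "bias"])
  g <- rowsum(ac[, c("count_R", "count_S")], ac$gene_id)
  nRS <- g$count_R + g$count_S
  p <- vapply(seq_len(nrow(g)), function(i) {
    if (nRS[i] == 0L) return(NA_real_)
    stats::binom.test(g$count_R[i], nRS[i], p = 0.5)$p.value
  }, 0)
  perGene <- DataFrame(gene_id = rownames(g),
                       count_R = g$count_R, count_S = g$count_S,
                       bias_R = ifelse(nRS > 0, g$count_R / nRS, NA_real_),
                       p = p, padj = adjustPvalues(p))
  list(perSample = perSample, perGene = perGene)
}
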