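#' Read / write gene-by-sample count tables
#'
#' Tab-separated, sample IDs in the header, gene IDs in the first column
#' (`gene_id`). Reading enforces integer counts and unique gene IDs;
#' write-then-read is an identity.
#'
#' @param path TSV file path.
#' @return `readCounts`: integer matrix with gene rownames.
#' @export
readCounts <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("count table needs a gene column plus samples: ",
                         path)
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene IDs in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  m <- as.matrix(d[, -1L, drop = FALSE])
  bad <- which(!is.finite(m) | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at row %d (gene %s), column '%s' in %s",
                 bad[1L, 1L], ids[bad[1L, 1L]],
                 colnames(m)[bad[1L, 2L]], path))
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname readCounts
#' @param counts matrix (genes x samples) or
#'   \linkS4class{HybridExpressionSet}.
#' @export
writeCounts <- function(counts, path) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ (Sanger qualities)
#'
#' @param reads `reads` DataFrame from [simulateReads()].
#' @param path output FASTQ path.
#' @export
writeFastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$read_id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname writeFastq
#' @return `readFastq`: a named `DNAStringSet`.
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write a diagnostic-site table as VCF v4.2
#'
#' One record per site with the species-R allele as REF and the species-S
#' allele as ALT, a single sample ("S") genotyped `1/1` (R's genome is the
#' reference, so its own VCF would be empty). Positions are 1-based.
#'
#' @param sites site table (`gene_id`, `pos`, `allele_R`, `allele_S`).
#' @param path output VCF path.
#' @param contigLengths named contig lengths for the header (defaults to
#'   max position per gene).
#' @export
writeDiagnosticVcf <- function(sites, path, contigLengths = NULL) {
  st <- as.data.frame(sites)
  if (is.null(contigLengths)) {
    contigLengths <- tapply(st$pos, st$gene_id, max)
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                   as.integer(contigLengths)),
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S"), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1/1",
                  st$gene_id, st$pos, st$allele_R, st$allele_S)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Thin wrapper over `VariantAnnotation::readVcf` producing the variant
#' table consumed by [findDiagnosticSites()]: one row per biallelic record
#' with `gene_id` (contig), `pos` (1-based), `ref`, `alt` and the `gt` of
#' the given sample (`"1/1"` assumed when the VCF has no genotypes).
#'
#' @param path VCF path.
#' @param sample sample column to take genotypes from (default: first).
#' @return data.frame variant table.
#' @export
readVariants <- function(path, sample = 1L) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- vapply(VariantAnnotation::alt(v), function(a)
    if (length(a) == 1L) as.character(a) else
      paste(as.character(a), collapse = ","), "")
  gt <- if ("GT" %in% names(VariantAnnotation::geno(v)) &&
            ncol(VariantAnnotation::geno(v)$GT) >= 1L)
    VariantAnnotation::geno(v)$GT[, sample]
  else rep("1/1", length(v))
  data.frame(gene_id = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(v)),
             alt = alt, gt = as.character(gt),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write alignments as SAM
#'
#' Minimal valid SAM: @HD/@SQ headers, one line per read, flag 0, MAPQ 60,
#' full-length match CIGAR, 1-based leftmost positions. Sample of origin is
#' preserved in a `RG:Z:` tag.
#'
#' @param alignments DataFrame (`qname`, `rname`, `pos`, `seq`, optional
#'   `sample`) as produced by [simulateReads()].
#' @param path output SAM path.
#' @param refLengths named vector of reference (transcript) lengths.
#' @export
writeSam <- function(alignments, path, refLengths) {
  a <- as.data.frame(alignments)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                   as.integer(refLengths)))
  rg <- if (is.null(a$sample)) "sample_1" else a$sample
  body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                  a$qname, a$rname, a$pos, nchar(a$seq), a$seq,
                  strrep("I", nchar(a$seq)), rg)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read single-gene alignments from SAM
#'
#' Converts with `Rsamtools::asBam` and extracts `qname`, `rname`, `pos`,
#' `seq` plus the read-group tag as `sample`. Unmapped reads are dropped.
#'
#' @param path SAM path.
#' @return data.frame of alignments for [assignReads()].
#' @export
readSam <- function(path) {
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, dest)), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname", "pos", "seq"),
                               tag = "RG")
  r <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(r$pos)
  rg <- r$tag$RG
  if (is.null(rg)) rg <- rep("sample_1", length(r$qname))
  data.frame(qname = r$qname[keep], rname = as.character(r$rname)[keep],
             pos = r$pos[keep], seq = as.character(r$seq)[keep],
             sample = rg[keep], stringsAsFactors = FALSE)
}

#' Read / write generic result tables
#'
#' Plain TSV with a header; used for contrast results, classifications,
#' allele counts and divergence tables.
#'
#' @param x data.frame-like.
#' @param path TSV path.
#' @export
writeTable <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror the arguments of [simulationConfig()]; unknown keys
#' are rejected.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown simulation config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$categoryFractions))
    cfg$categoryFractions <- unlist(cfg$categoryFractions)
  do.call(simulationConfig, cfg)
}
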