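## serialize a config to canonical JSON for hashing in the manifest
.configDigest <- function(...) {
  x <- list(...)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

.simConfigAsList <- function(config) {
  nm <- slotNames(class(config))
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Run the full simulate-assign-test-classify-stats pipeline
#'
#' Executes the enabled stages in order on a seeded synthetic dataset,
#' writing every artifact as plain text under `outDir`:
#' counts.tsv, truth.tsv, (reads.fastq, sites.vcf, alignments.sam,
#' allele_counts.tsv, assignment_summary.tsv when `reads = TRUE`),
#' contrast_*.tsv, classification.tsv, category_proportions.json,
#' divergence.tsv, category_comparisons.tsv, pca_scores.tsv, and finally
#' manifest.json with the seed, config hash and md5 checksum of every
#' artifact. Re-running with an identical config reproduces identical
#' checksums.
#'
#' @param simConfig a \linkS4class{SimulationConfig}.
#' @param config a [testConfig()].
#' @param outDir output directory (created).
#' @param stages subset of
#'   `c("simulate", "assign", "test", "classify", "stats")`.
#' @param reads simulate and process read-level data (enables "assign").
#' @param nReads total reads when `reads = TRUE`.
#' @return (invisibly) the manifest as a list.
#' @examples
#' \donttest{
#' out <- tempfile()
#' m <- runPipeline(simulationConfig(nGenes = 100, seed = 1), outDir = out)
#' names(m$checksums)
#' }
#' @export
runPipeline <- function(simConfig = simulationConfig(),
                        config = testConfig(),
                        outDir,
                        stages = c("simulate", "assign", "test",
                                   "classify", "stats"),
                        reads = FALSE,
                        nReads = 50L * simConfig@nGenes) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- character()
  put <- function(x, name, writer = writeTable) {
    p <- file.path(outDir, name)
    writer(x, p)
    art <<- c(art, p)
    p
  }
  message("[pipeline] seed = ", simConfig@seed)

  sim <- NULL; rd <- NULL
  if ("simulate" %in% stages) {
    message("[simulate] ", simConfig@nGenes, " genes")
    sim <- simulateDataset(simConfig, reads = reads)
    put(sim$counts, "counts.tsv", writeCounts)
    put(as.data.frame(sim$truth), "truth.tsv")
    if (reads) {
      rd <- sim$reads
      put(rd$reads, "reads.fastq", writeFastq)
      put(rd$sites, "sites.vcf", function(x, p)
        writeDiagnosticVcf(x, p, contigLengths = stats::setNames(
          rep(simConfig@transcriptLength, length(rd$reference)),
          names(rd$reference))))
      put(rd$alignments, "alignments.sam", function(x, p)
        writeSam(x, p, refLengths = stats::setNames(
          rep(simConfig@transcriptLength, length(rd$reference)),
          names(rd$reference))))
    }
  } else {
    cpath <- file.path(outDir, "counts.tsv")
    if (!file.exists(cpath))
      stop("stage 'simulate' disabled and counts file missing: ", cpath)
  }

  if ("assign" %in% stages && reads && !is.null(rd)) {
    message("[assign] ", nrow(rd$alignments), " alignments")
    sites <- findDiagnosticSites(
      data.frame(gene_id = character(), pos = integer(), ref = character(),
                 alt = character(), gt = character()),
      readVariants(file.path(outDir, "sites.vcf")))
    asg <- assignReads(rd$alignments, sites)
    ac <- countAlleles(asg, genes = names(rd$reference))
    put(ac, "allele_counts.tsv")
    put(assignmentSummary(ac)$perSample, "assignment_summary.tsv")
  }

  contrasts <- NULL
  if ("test" %in% stages) {
    message("[test] five contrasts")
    se <- if (!is.null(sim)) sim$counts else {
      k <- readCounts(file.path(outDir, "counts.tsv"))
      grp <- sub("_[0-9]+$", "", colnames(k))
      HybridExpressionSet(k, grp, as.integer(sub(".*_", "", colnames(k))))
    }
    contrasts <- runContrasts(se, config)
    for (nm in c("P", "H", "T", "FR", "FS"))
      put(contrasts[[nm]], sprintf("contrast_%s.tsv", nm))
  }

  cls <- NULL
  if ("classify" %in% stages) {
    if (is.null(contrasts)) stop("stage 'classify' requires stage 'test'")
    message("[classify] decision tables")
    cls <- classifyDataset(contrasts, config)
    put(cls, "classification.tsv")
    prop <- categoryProportions(cls)
    p <- file.path(outDir, "category_proportions.json")
    jsonlite::write_json(lapply(prop, as.list), p, auto_unbox = TRUE,
                         digits = NA)
    art <- c(art, p)
  }

  if ("stats" %in% stages) {
    if (is.null(cls)) stop("stage 'stats' requires stage 'classify'")
    message("[stats] divergence + PCA")
    div <- divergenceMagnitude(contrasts$P, cls)
    put(div, "divergence.tsv")
    cc <- tryCatch(compareCategories(div),
                   error = function(e) NULL)
    if (!is.null(cc)) {
      put(cc$categories, "category_medians.tsv")
      put(cc$pairs, "category_comparisons.tsv")
    }
    se <- if (!is.null(sim)) sim$counts else NULL
    if (!is.null(se)) {
      vst <- vstTransform(se, contrasts$sizeFactors)
      pca <- runPCA(vst, nComponents = min(4L, ncol(vst) - 1L))
      put(data.frame(sample = rownames(pca$scores), pca$scores,
                     check.names = FALSE), "pca_scores.tsv")
    }
  }

  manifest <- list(
    seed = simConfig@seed,
    configHash = .configDigest(sim = .simConfigAsList(simConfig),
                               test = unclass(config)),
    stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(art)))
  names(manifest$checksums) <- basename(art)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
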