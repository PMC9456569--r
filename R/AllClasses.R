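#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Controlled vocabularies used throughout the package. Order matters: it is
## the display/factor order in every summary table.
.REG_CATEGORIES <- c("conserved", "all_cis", "all_trans", "cis_plus_trans",
                     "cis_times_trans", "compensatory", "ambiguous",
                     "uninformative")
.INH_MODES <- c("conserved", "additive", "RR_dominant", "SS_dominant",
                "overdominant", "underdominant", "ambiguous", "uninformative")
.SIM_CATEGORIES <- c("conserved", "all_cis", "all_trans", "cis_plus_trans",
                     "cis_times_trans", "compensatory")
.SAMPLE_GROUPS <- c("parent_R", "parent_S", "hybrid_total",
                    "hybrid_allele_R", "hybrid_allele_S")

#' Regulatory-pattern and inheritance-mode vocabularies
#'
#' Category labels used by the classifiers, in canonical order.
#'
#' @return Character vector of category labels.
#' @export
regulatoryCategories <- function() .REG_CATEGORIES

#' @rdname regulatoryCategories
#' @export
inheritanceModes <- function() .INH_MODES

#' @rdname regulatoryCategories
#' @export
sampleGroupLevels <- function() .SAMPLE_GROUPS

#' Simulation configuration for two-species + F1 hybrid datasets
#'
#' An S4 container holding every tunable of the synthetic-data generator:
#' the number of genes and replicates, the log-normal baseline expression
#' distribution, the mixture of true regulatory categories, cis/trans effect
#' magnitude, hybrid misexpression parameters, negative-binomial dispersion,
#' per-library size factors, the read-level parameters (transcript length,
#' read length, diagnostic-site density, sequencing error rate) and the seed
#' that fixes all downstream randomness.
#'
#' @slot nGenes number of genes.
#' @slot nReplicates replicate libraries per sample group.
#' @slot baselineLog2Mean,baselineLog2Sd parameters of the log2-normal
#'   baseline expression \eqn{\mu_g} (counts scale).
#' @slot categoryFractions named proportions over the six true regulatory
#'   categories; must sum to 1.
#' @slot effectSizeLog2 magnitude e of cis (c) and trans (t) effects in log2
#'   units; signs are drawn at random unless the category constrains them.
#' @slot misexpressionFraction,misexpressionShiftLog2 fraction of genes given
#'   a hybrid-specific shift m, and |m| in log2 units.
#' @slot dispersion global NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 degenerates to Poisson.
#' @slot librarySizeFactors per-sample scaling (recycled across samples).
#' @slot assignmentRate expected fraction of hybrid reads assignable to a
#'   parental allele (the remainder is "unassigned").
#' @slot transcriptLength,readLength,snpPerKb,errorRate read-level simulation
#'   parameters.
#' @slot seed integer seed fixing all randomness.
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    nReplicates = "integer",
    baselineLog2Mean = "numeric",
    baselineLog2Sd = "numeric",
    categoryFractions = "numeric",
    effectSizeLog2 = "numeric",
    misexpressionFraction = "numeric",
    misexpressionShiftLog2 = "numeric",
    dispersion = "numeric",
    librarySizeFactors = "numeric",
    assignmentRate = "numeric",
    transcriptLength = "integer",
    readLength = "integer",
    snpPerKb = "numeric",
    errorRate = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@baselineLog2Sd < 0) msg <- c(msg, "baselineLog2Sd must be >= 0")
  cf <- object@categoryFractions
  if (!all(sort(names(cf)) == sort(.SIM_CATEGORIES)))
    msg <- c(msg, sprintf("categoryFractions must be named by: %s",
                          paste(.SIM_CATEGORIES, collapse = ", ")))
  else {
    if (any(cf < 0)) msg <- c(msg, "categoryFractions must be non-negative")
    if (abs(sum(cf) - 1) > 1e-9)
      msg <- c(msg, "categoryFractions must sum to 1 (tolerance 1e-9)")
  }
  if (object@effectSizeLog2 < 0) msg <- c(msg, "effectSizeLog2 must be >= 0")
  if (object@misexpressionFraction < 0 || object@misexpressionFraction > 1)
    msg <- c(msg, "misexpressionFraction must be in [0, 1]")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (any(object@librarySizeFactors <= 0))
    msg <- c(msg, "librarySizeFactors must be > 0")
  if (object@assignmentRate < 0 || object@assignmentRate > 1)
    msg <- c(msg, "assignmentRate must be in [0, 1]")
  if (object@errorRate < 0 || object@errorRate > 1)
    msg <- c(msg, "errorRate must be in [0, 1]")
  if (object@snpPerKb < 0) msg <- c(msg, "snpPerKb must be >= 0")
  if (object@readLength > object@transcriptLength)
    msg <- c(msg, "readLength must be <= transcriptLength")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe the package's reference study conditions: 2000 genes,
#' 3 replicates per group, log2-normal baselines centred on ~500 counts,
#' an even mixture of divergent regulatory categories over a conserved
#' background, unit cis/trans effects, NB dispersion 0.05, a 55% hybrid
#' read-assignment rate, and 150 bp reads on 1500 bp transcripts carrying
#' 5 diagnostic sites per kb.
#'
#' @param nGenes,nReplicates problem size.
#' @param baselineLog2Mean,baselineLog2Sd log2-normal baseline expression.
#' @param categoryFractions named numeric over the six true categories.
#' @param effectSizeLog2 effect magnitude e (log2).
#' @param misexpressionFraction,misexpressionShiftLog2 hybrid shift m.
#' @param dispersion global NB dispersion alpha.
#' @param librarySizeFactors per-sample scaling (recycled).
#' @param assignmentRate fraction of hybrid reads assignable to an allele.
#' @param transcriptLength,readLength,snpPerKb,errorRate read simulation.
#' @param seed integer seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, seed = 7)
#' @export
simulationConfig <- function(nGenes = 2000L,
                             nReplicates = 3L,
                             baselineLog2Mean = log2(500),
                             baselineLog2Sd = 1.5,
                             categoryFractions = c(conserved = 0.25,
                                                   all_cis = 0.15,
                                                   all_trans = 0.15,
                                                   cis_plus_trans = 0.15,
                                                   cis_times_trans = 0.15,
                                                   compensatory = 0.15),
                             effectSizeLog2 = 1,
                             misexpressionFraction = 0,
                             misexpressionShiftLog2 = 2,
                             dispersion = 0.05,
                             librarySizeFactors = 1,
                             assignmentRate = 0.55,
                             transcriptLength = 1500L,
                             readLength = 150L,
                             snpPerKb = 5,
                             errorRate = 0.005,
                             seed = 1L) {
  cf <- stats::setNames(numeric(length(.SIM_CATEGORIES)), .SIM_CATEGORIES)
  bad <- setdiff(names(categoryFractions), .SIM_CATEGORIES)
  if (length(bad))
    stop("unknown category in categoryFractions: ",
         paste(bad, collapse = ", "))
  cf[names(categoryFractions)] <- categoryFractions
  new("SimulationConfig",
      nGenes = as.integer(nGenes), nReplicates = as.integer(nReplicates),
      baselineLog2Mean = baselineLog2Mean, baselineLog2Sd = baselineLog2Sd,
      categoryFractions = cf,
      effectSizeLog2 = effectSizeLog2,
      misexpressionFraction = misexpressionFraction,
      misexpressionShiftLog2 = misexpressionShiftLog2,
      dispersion = dispersion,
      librarySizeFactors = librarySizeFactors,
      assignmentRate = assignmentRate,
      transcriptLength = as.integer(transcriptLength),
      readLength = as.integer(readLength),
      snpPerKb = snpPerKb, errorRate = errorRate,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes x",
      object@nReplicates, "replicates/group\n")
  cat("  baseline log2 ~ N(", round(object@baselineLog2Mean, 2), ",",
      object@baselineLog2Sd, "); effect e =", object@effectSizeLog2,
      "; dispersion =", object@dispersion, "\n")
  cf <- object@categoryFractions
  cat("  categories:", paste(sprintf("%s=%.2f", names(cf), cf),
                             collapse = " "), "\n")
  cat("  misexpression:", object@misexpressionFraction, "of genes, |m| =",
      object@misexpressionShiftLog2, "; seed =", object@seed, "\n")
})

#' Container for parental + hybrid expression data
#'
#' A \linkS4class{SummarizedExperiment} with one `counts` assay whose columns
#' are parental replicate libraries, hybrid total libraries, and hybrid
#' allele-level pseudo-libraries (R-allele and S-allele counts from read
#' assignment). `colData` carries `group` (one of
#' `sampleGroupLevels()`) and `replicate`; when the object comes from the
#' simulator, per-gene ground truth lives in `rowData` (columns `mu`, `c`,
#' `t`, `m`, `trueRegulatoryCategory`, `trueInheritanceMode`).
#'
#' @export
setClass("HybridExpressionSet", contains = "SummarizedExperiment")

setValidity("HybridExpressionSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  k <- SummarizedExperiment::assay(object, "counts")
  if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(k != round(k))) msg <- c(msg, "counts must be integers")
  cd <- colData(object)
  if (!all(c("group", "replicate") %in% colnames(cd)))
    return("colData must contain 'group' and 'replicate'")
  if (!all(cd$group %in% .SAMPLE_GROUPS))
    msg <- c(msg, sprintf("group labels must be among: %s",
                          paste(.SAMPLE_GROUPS, collapse = ", ")))
  ## allele counts cannot exceed the matching hybrid total library
  gr <- as.character(cd$group)
  for (r in unique(cd$replicate[gr == "hybrid_total"])) {
    tot <- k[, gr == "hybrid_total" & cd$replicate == r, drop = FALSE]
    aR <- k[, gr == "hybrid_allele_R" & cd$replicate == r, drop = FALSE]
    aS <- k[, gr == "hybrid_allele_S" & cd$replicate == r, drop = FALSE]
    if (ncol(tot) == 1L && ncol(aR) == 1L && ncol(aS) == 1L &&
        any(aR + aS > tot))
      msg <- c(msg, sprintf(
        "allele counts exceed hybrid total in replicate %s", r))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HybridExpressionSet
#'
#' @param counts integer matrix, genes x samples.
#' @param group character vector of `sampleGroupLevels()` labels per column.
#' @param replicate replicate index per column (links a hybrid total library
#'   to its two allele columns).
#' @param truth optional per-gene truth table (`DataFrame`/`data.frame`) to
#'   store in `rowData`.
#' @return A \linkS4class{HybridExpressionSet}.
#' @export
HybridExpressionSet <- function(counts, group, replicate, truth = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  cd <- DataFrame(group = as.character(group),
                  replicate = as.integer(replicate),
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  if (!is.null(truth)) rowData(se) <- DataFrame(truth)
  new("HybridExpressionSet", se)
}

#' @importFrom SummarizedExperiment assayNames rowData rowData<-
NULL

#' Accessors for HybridExpressionSet
#'
#' `hybridCounts` returns the counts assay, optionally restricted to a sample
#' group; `sampleGroups` the per-column group labels; `geneTruth` the
#' simulator's per-gene truth table (NULL if absent).
#'
#' @param x a \linkS4class{HybridExpressionSet}.
#' @param group optional group label to subset columns.
#' @return matrix, character vector, or DataFrame respectively.
#' @export
hybridCounts <- function(x, group = NULL) {
  k <- SummarizedExperiment::assay(x, "counts")
  if (is.null(group)) return(k)
  stopifnot(group %in% .SAMPLE_GROUPS)
  k[, colData(x)$group == group, drop = FALSE]
}

#' @rdname hybridCounts
#' @export
sampleGroups <- function(x) as.character(colData(x)$group)

#' @rdname hybridCounts
#' @export
geneTruth <- function(x) {
  rd <- rowData(x)
  if (!ncol(rd)) return(NULL)
  rd
}

setMethod("show", "HybridExpressionSet", function(object) {
  cat("HybridExpressionSet:", nrow(object), "genes x", ncol(object),
      "samples\n")
  tab <- table(factor(sampleGroups(object), levels = .SAMPLE_GROUPS))
  cat("  columns:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = " "), "\n")
  if (!is.null(geneTruth(object)))
    cat("  simulator truth attached (rowData)\n")
})
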