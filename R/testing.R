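#' Test configuration
#'
#' @param alpha significance level applied to (adjusted) p-values when
#'   deriving the classifier's significance flags.
#' @param minMeanCount informativeness threshold: a gene is informative for a
#'   contrast only when its mean normalized count is at least this in both
#'   groups.
#' @param dispersionMode `"trend"` (default; gene-wise moment estimates
#'   moderated by a mean-dispersion trend fit, stable at few replicates) or
#'   `"gene"` (raw per-gene moment estimates).
#' @param dispersionFloor lower bound on the working dispersion.
#' @param pseudocount added to a group mean only when that mean is zero.
#' @param useAdjusted derive significance flags from BH-adjusted p-values
#'   (`TRUE`, default) or raw p-values.
#' @param signConvention for the regulatory classifier's cis+trans vs
#'   cis-x-trans split: `"parental_allelic"` (sign of L_P vs sign of L_H,
#'   default) or `"allelic_trans"` (sign of L_H vs sign of L_T).
#' @return A list of class `ase_test_config`.
#' @export
testConfig <- function(alpha = 0.05, minMeanCount = 10,
                       dispersionMode = c("trend", "gene"),
                       dispersionFloor = 1e-4, pseudocount = 0.5,
                       useAdjusted = TRUE,
                       signConvention = c("parental_allelic",
                                          "allelic_trans")) {
  stopifnot(alpha > 0, alpha < 1, minMeanCount >= 0, dispersionFloor >= 0,
            pseudocount >= 0)
  structure(list(alpha = alpha, minMeanCount = minMeanCount,
                 dispersionMode = match.arg(dispersionMode),
                 dispersionFloor = dispersionFloor,
                 pseudocount = pseudocount, useAdjusted = useAdjusted,
                 signConvention = match.arg(signConvention)),
            class = "ase_test_config")
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the factor for sample j is the median over
#' genes of `counts[g, j] / geometric-mean(counts[g, ])`, computed over
#' genes with strictly positive counts in every sample.
#'
#' @param counts integer matrix, genes x samples, or a
#'   \linkS4class{HybridExpressionSet}.
#' @return named numeric vector of positive size factors.
#' @examples
#' computeSizeFactors(matrix(c(10, 30, 20, 60), 2,
#'                    dimnames = list(NULL, c("a", "b"))))
#' @export
computeSizeFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("cannot estimate size factors: no gene has nonzero counts in ",
         "every sample; filter samples or provide factors manually")
  lgm <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2L,
              function(k) exp(stats::median(log(k) - lgm)))
  names(sf) <- colnames(counts)
  sf
}

#' Per-gene NB dispersion by moments, with optional trend moderation
#'
#' For each replicate group the method-of-moments estimate
#' `(s^2 - mbar) / mbar^2` is formed on normalized counts and pooled across
#' groups (weights: within-group degrees of freedom). In `"trend"` mode a
#' mean-dispersion curve `alpha(mu) = a0 + a1 / mu` is fit across genes and
#' its fitted values (floored) are used as the working dispersions --
#' gene-wise moment estimates at 2-3 replicates are far too noisy to plug
#' into a Wald test directly. `"gene"` mode floors the raw pooled estimates.
#'
#' @param counts matrix or \linkS4class{HybridExpressionSet}.
#' @param sizeFactors from [computeSizeFactors()].
#' @param groups character vector of per-column replicate-group labels
#'   (taken from `colData` for a HybridExpressionSet).
#' @param mode `"trend"` or `"gene"`.
#' @param floor lower bound for the working dispersion.
#' @return DataFrame: `gene_id`, `mean` (normalized), `alphaMoment`,
#'   `alphaTrend`, `alpha` (the working value).
#' @export
estimateDispersion <- function(counts, sizeFactors, groups = NULL,
                               mode = c("trend", "gene"), floor = 1e-4) {
  mode <- match.arg(mode)
  if (is(counts, "SummarizedExperiment")) {
    if (is.null(groups)) groups <- sampleGroups(counts)
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  norm <- sweep(counts, 2L, sizeFactors, "/")
  num <- den <- numeric(nrow(counts))
  singles <- TRUE
  for (g in unique(groups)) {
    k <- norm[, groups == g, drop = FALSE]
    if (ncol(k) < 2L) next
    singles <- FALSE
    m <- rowMeans(k)
    s2 <- apply(k, 1L, stats::var)
    w <- ncol(k) - 1L
    a <- ifelse(m > 0, (s2 - m) / m^2, NA_real_)
    ok <- !is.na(a)
    num[ok] <- num[ok] + w * a[ok]
    den[ok] <- den[ok] + w
  }
  if (singles) {
    warning("no group has >= 2 replicates; using global prior dispersion")
    amom <- rep(NA_real_, nrow(counts))
  } else {
    amom <- ifelse(den > 0, num / den, NA_real_)
  }
  mu <- rowMeans(norm)
  atrend <- rep(NA_real_, nrow(counts))
  ok <- !is.na(amom) & mu > 0
  if (sum(ok) >= 10L) {
    fit <- stats::lm(amom[ok] ~ I(1 / mu[ok]))
    atrend[mu > 0] <- stats::coef(fit)[1L] + stats::coef(fit)[2L] / mu[mu > 0]
  } else if (any(ok)) {
    atrend[] <- mean(amom[ok])
  }
  prior <- 0.05  # fallback when moments are unavailable (single replicate)
  alpha <- switch(mode,
                  gene = pmax(floor, ifelse(is.na(amom), prior, amom)),
                  trend = pmax(floor, ifelse(is.na(atrend), prior, atrend)))
  DataFrame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
            mean = mu, alphaMoment = amom, alphaTrend = atrend, alpha = alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## core NB Wald machinery on two column sets of a normalized matrix;
## paired = TRUE switches to the within-library allelic variance (binomial)
.nbWald <- function(counts, sfA, sfB, colsA, colsB, alpha, config,
                    paired = FALSE) {
  kA <- counts[, colsA, drop = FALSE]
  kB <- counts[, colsB, drop = FALSE]
  nA <- ncol(kA); nB <- ncol(kB)
  mA <- rowMeans(sweep(kA, 2L, sfA, "/"))
  mB <- rowMeans(sweep(kB, 2L, sfB, "/"))
  informative <- mA >= config$minMeanCount & mB >= config$minMeanCount
  ps <- config$pseudocount
  mAp <- ifelse(mA == 0, ps, mA)
  mBp <- ifelse(mB == 0, ps, mB)
  L <- log2(mAp / mBp)
  if (paired) {
    ## the two column sets are allele counts carved out of the same
    ## libraries: their library-depth fluctuations cancel in the ratio and
    ## the split is binomial given the assigned total, so the variance of
    ## the log2 allelic ratio is the binomial (1/sumA + 1/sumB) / ln(2)^2
    sA <- pmax(rowSums(kA), ps)
    sB <- pmax(rowSums(kB), ps)
    se <- sqrt(1 / sA + 1 / sB) / log(2)
  } else {
    ## var of the mean of normalized NB counts:
    ## (1/n^2) sum_j (m/sf_j + a m^2)
    vA <- (mAp * sum(1 / sfA) + alpha * mAp^2 * nA) / nA^2
    vB <- (mBp * sum(1 / sfB) + alpha * mBp^2 * nB) / nB^2
    se <- sqrt(vA / (mAp * log(2))^2 + vB / (mBp * log(2))^2)
  }
  stat <- ifelse(se > 0, L / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(L = L, se = se, stat = stat, p = p,
             meanA = mA, meanB = mB, informative = informative)
}

#' Negative-binomial Wald test for one contrast
#'
#' Tests, per gene, the log2 ratio of mean normalized counts between two
#' sample groups. The log2 fold change is `L = log2(mA / mB)` (pseudocount
#' applied only to zero means); its standard error comes from the NB
#' variance of the group means on the log2 scale (delta method); the Wald
#' statistic `L / se` is referred to a standard normal, two-sided. A gene is
#' flagged uninformative when its mean normalized count falls below
#' `minMeanCount` in either group.
#'
#' @param x \linkS4class{HybridExpressionSet} (or counts matrix with
#'   `groups` supplied).
#' @param groupA,groupB group labels (for a matrix: values of `groups`).
#' @param sizeFactors optional; computed on the full matrix when missing.
#' @param dispersion optional DataFrame from [estimateDispersion()] or a
#'   numeric vector of working dispersions; estimated when missing.
#' @param config a [testConfig()].
#' @param groups per-column labels when `x` is a plain matrix.
#' @param paired treat the two groups as allele counts carved out of the
#'   same libraries (the hybrid allelic contrast): the standard error then
#'   uses the within-library binomial variance of the allelic split, which
#'   the unpaired NB variance would overstate several-fold.
#' @param name contrast name stored in the result (defaults to
#'   `"groupA_vs_groupB"`).
#' @return data.frame: `gene_id`, `contrast`, `L`, `se`, `stat`, `p`,
#'   `padj` (BH within this contrast), `informative`, `meanA`, `meanB`.
#' @export
testContrast <- function(x, groupA, groupB, sizeFactors = NULL,
                         dispersion = NULL, config = testConfig(),
                         groups = NULL, paired = FALSE, name = NULL) {
  if (is(x, "SummarizedExperiment")) {
    groups <- sampleGroups(x)
    counts <- SummarizedExperiment::assay(x, "counts")
  } else counts <- as.matrix(x)
  if (is.null(groups)) stop("'groups' must be supplied for a plain matrix")
  if (!groupA %in% groups) stop("unknown group label: ", groupA)
  if (!groupB %in% groups) stop("unknown group label: ", groupB)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (is.null(dispersion))
    dispersion <- estimateDispersion(counts, sizeFactors, groups,
                                     mode = config$dispersionMode,
                                     floor = config$dispersionFloor)
  alpha <- if (is(dispersion, "DataFrame") || is.data.frame(dispersion))
    dispersion$alpha else dispersion
  colsA <- which(groups == groupA)
  colsB <- which(groups == groupB)
  res <- .nbWald(counts, sizeFactors[colsA], sizeFactors[colsB],
                 colsA, colsB, alpha, config, paired = paired)
  data.frame(gene_id = rownames(counts) %||%
               as.character(seq_len(nrow(counts))),
             contrast = name %||% paste0(groupA, "_vs_", groupB),
             L = res$L, se = res$se, stat = res$stat, p = res$p,
             padj = adjustPvalues(res$p),
             informative = res$informative,
             meanA = res$meanA, meanB = res$meanB,
             row.names = NULL)
}

#' Trans test: difference between parental and allelic log2 ratios
#'
#' `L_T = L_P - L_H` with `se_T = sqrt(se_P^2 + se_H^2)`; Wald statistic
#' against a standard normal, two-sided. A significant L_T indicates a trans
#' component (parental divergence not explained by allelic imbalance).
#'
#' @param resultP,resultH contrast results from [testContrast()] for the
#'   parental and hybrid-allelic contrasts, same gene universe and order.
#' @param name contrast name for the output.
#' @return data.frame with the same columns as [testContrast()].
#' @export
testRatioDifference <- function(resultP, resultH, name = "trans") {
  if (!identical(as.character(resultP$gene_id),
                 as.character(resultH$gene_id)))
    stop("gene mismatch between parental and allelic contrast results")
  L <- resultP$L - resultH$L
  se <- sqrt(resultP$se^2 + resultH$se^2)
  stat <- ifelse(se > 0, L / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(gene_id = resultP$gene_id, contrast = name,
             L = L, se = se, stat = stat, p = p,
             padj = adjustPvalues(p),
             informative = resultP$informative & resultH$informative,
             meanA = resultP$meanA, meanB = resultH$meanA,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment with validation and NA passthrough
#'
#' @param p numeric p-values in [0, 1]; NAs pass through.
#' @return BH-adjusted p-values.
#' @export
adjustPvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the five standard contrasts of the hybrid design
#'
#' Size factors and dispersions are estimated once on the full matrix, then
#' the contrasts are: `P` parent_R vs parent_S (parental divergence, L_P),
#' `H` hybrid_allele_R vs hybrid_allele_S (allelic imbalance, L_H; a paired
#' test, see the `paired` argument of [testContrast()]),
#' `T` the ratio difference L_P - L_H (trans component),
#' `FR` hybrid_total vs parent_R and `FS` hybrid_total vs parent_S
#' (inheritance-mode comparisons).
#'
#' @param x a \linkS4class{HybridExpressionSet}.
#' @param config a [testConfig()].
#' @return named list of contrast data.frames (`P`, `H`, `T`, `FR`, `FS`)
#'   plus `sizeFactors` and `dispersion`.
#' @export
runContrasts <- function(x, config = testConfig()) {
  sf <- computeSizeFactors(x)
  disp <- estimateDispersion(x, sf, mode = config$dispersionMode,
                             floor = config$dispersionFloor)
  tc <- function(a, b, nm, paired = FALSE)
    testContrast(x, a, b, sizeFactors = sf, dispersion = disp,
                 config = config, paired = paired, name = nm)
  P <- tc("parent_R", "parent_S", "parental")
  H <- tc("hybrid_allele_R", "hybrid_allele_S", "allelic", paired = TRUE)
  list(P = P, H = H,
       T = testRatioDifference(P, H),
       FR = tc("hybrid_total", "parent_R", "hybrid_vs_R"),
       FS = tc("hybrid_total", "parent_S", "hybrid_vs_S"),
       sizeFactors = sf, dispersion = disp)
}
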