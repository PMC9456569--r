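#' Expression-divergence magnitude by regulatory category
#'
#' The magnitude of parental expression divergence is `|L_P|`, the absolute
#' log2 ratio of the two parental species' expression, reported per
#' informative gene alongside its regulatory category.
#'
#' @param resultP parental contrast result from [testContrast()] /
#'   [runContrasts()].
#' @param classification data.frame from [classifyDataset()].
#' @return data.frame: `gene_id`, `magnitude`, `category`.
#' @export
divergenceMagnitude <- function(resultP, classification) {
  idx <- match(classification$gene_id, resultP$gene_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " classified genes missing from the parental ",
            "contrast were dropped")
  keep <- !is.na(idx) & classification$informative_regulation
  data.frame(gene_id = classification$gene_id[keep],
             magnitude = abs(resultP$L[idx[keep]]),
             category = as.character(classification$regulation[keep]),
             row.names = NULL)
}

#' Pairwise comparison of divergence magnitudes between categories
#'
#' Shapiro-Wilk normality is recorded per category (the magnitudes of real
#' data are typically non-normal, which motivates rank tests), then all
#' category pairs are compared with two-sided Wilcoxon rank-sum tests on
#' the magnitudes, BH-adjusted across pairs. Categories with fewer than
#' `minGenes` genes are skipped with a warning.
#'
#' @param divergence data.frame from [divergenceMagnitude()].
#' @param minGenes minimum genes per category (default 3).
#' @return list: `categories` (per-category n, median, Shapiro-Wilk p) and
#'   `pairs` (per-pair Wilcoxon W, p, padj, median difference).
#' @export
compareCategories <- function(divergence, minGenes = 3L) {
  sp <- split(divergence$magnitude, divergence$category)
  small <- names(sp)[lengths(sp) < minGenes]
  if (length(small))
    warning("categories skipped (fewer than ", minGenes, " genes): ",
            paste(small, collapse = ", "))
  sp <- sp[lengths(sp) >= minGenes]
  if (length(sp) < 2L)
    stop("need at least two categories with >= ", minGenes, " genes")
  catTab <- data.frame(
    category = names(sp),
    n = lengths(sp),
    median = vapply(sp, stats::median, 0),
    shapiro_p = vapply(sp, function(x) {
      x <- x[seq_len(min(length(x), 5000L))]
      if (length(unique(x)) < 3L) return(NA_real_)
      stats::shapiro.test(x)$p.value
    }, 0),
    row.names = NULL)
  cmb <- utils::combn(names(sp), 2L)
  pairs <- data.frame(
    category1 = cmb[1L, ], category2 = cmb[2L, ],
    W = NA_real_, p = NA_real_, median_diff = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    x <- sp[[cmb[1L, i]]]; y <- sp[[cmb[2L, i]]]
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    pairs$W[i] <- unname(wt$statistic)
    pairs$p[i] <- wt$p.value
    pairs$median_diff[i] <- stats::median(x) - stats::median(y)
  }
  pairs$padj <- adjustPvalues(pairs$p)
  list(categories = catTab, pairs = pairs)
}

#' Simple variance-stabilizing transformation
#'
#' `log2(normalized count + 1)` per cell: a documented shifted-log VST,
#' monotone in counts and deterministic, adequate for sample-level
#' diagnostics such as PCA.
#'
#' @param counts matrix or \linkS4class{HybridExpressionSet}.
#' @param sizeFactors from [computeSizeFactors()] (computed when missing).
#' @return transformed numeric matrix, genes x samples.
#' @export
vstTransform <- function(counts, sizeFactors = NULL) {
  if (is(counts, "SummarizedExperiment"))
    counts <- SummarizedExperiment::assay(counts, "counts")
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  log2(sweep(counts, 2L, sizeFactors, "/") + 1)
}

#' PCA of samples over the most variable genes
#'
#' Genes are ranked by variance, the top `nTopGenes` retained and centred,
#' and the sample scores obtained by SVD (equivalently, `prcomp` without
#' re-centering). Variance explained is reported per component.
#'
#' @param mat numeric matrix, genes x samples (typically [vstTransform()]
#'   output).
#' @param nComponents number of components (reduced with a warning when it
#'   exceeds what the data support).
#' @param nTopGenes number of most-variable genes to use (`Inf` for all).
#' @return list: `scores` (samples x k), `loadings` (genes x k,
#'   orthonormal columns), `varianceExplained` (length k, non-increasing,
#'   sums to <= 1), `genes` (the genes used).
#' @export
runPCA <- function(mat, nComponents = 2L, nTopGenes = 500L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("PCA needs at least two samples")
  v <- apply(mat, 1L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(nTopGenes, nrow(mat)))]
  x <- mat[keep, , drop = FALSE]
  x <- x - rowMeans(x)
  kmax <- min(dim(x)) - 0L
  if (nComponents > kmax) {
    warning("reducing nComponents to ", kmax)
    nComponents <- kmax
  }
  sv <- svd(t(x), nu = nComponents, nv = nComponents)
  scores <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  dimnames(scores) <- list(colnames(mat),
                           paste0("PC", seq_len(nComponents)))
  loadings <- sv$v
  dimnames(loadings) <- list(rownames(x), colnames(scores))
  ve <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings,
       varianceExplained = ve[seq_len(nComponents)],
       genes = rownames(x) %||% keep)
}

#' Spearman correlation between expression and a phenotype
#'
#' Per gene, Spearman's rho (average ranks for ties) between the expression
#' levels across groups and a per-group phenotype value. For fewer than 10
#' groups the p-value is exact (null permutation distribution of rho;
#' tie-free cases use the exact method of `cor.test`, tied cases a full
#' enumeration up to n = 7 and Monte-Carlo permutation beyond); otherwise
#' the asymptotic approximation is used. Constant vectors give NA.
#'
#' @param expression numeric matrix, genes x groups (or a vector).
#' @param phenotype numeric vector, one value per group.
#' @param nPerm Monte-Carlo permutations for tied, non-enumerable cases.
#' @return data.frame: `gene_id`, `rho`, `p`.
#' @export
correlateExpressionPhenotype <- function(expression, phenotype,
                                         nPerm = 10000L) {
  if (is.null(dim(expression)))
    expression <- matrix(expression, nrow = 1L,
                         dimnames = list("gene1", NULL))
  expression <- as.matrix(expression)
  n <- length(phenotype)
  if (ncol(expression) != n)
    stop("expression columns must match phenotype length")
  if (n < 3L) stop("need at least 3 paired groups")
  rho_p <- function(x) {
    if (length(unique(x)) < 2L || length(unique(phenotype)) < 2L)
      return(c(NA_real_, NA_real_))
    rho <- stats::cor(x, phenotype, method = "spearman")
    ties <- anyDuplicated(x) > 0L || anyDuplicated(phenotype) > 0L
    if (n >= 10L) {
      p <- stats::cor.test(x, phenotype, method = "spearman",
                           exact = FALSE)$p.value
    } else if (!ties) {
      p <- stats::cor.test(x, phenotype, method = "spearman",
                           exact = TRUE)$p.value
    } else if (n <= 7L) {
      perms <- .permutations(n)
      null <- apply(perms, 1L, function(ix)
        stats::cor(x, phenotype[ix], method = "spearman"))
      p <- mean(abs(null) >= abs(rho) - 1e-12)
    } else {
      null <- replicate(nPerm,
        stats::cor(x, sample(phenotype), method = "spearman"))
      p <- (sum(abs(null) >= abs(rho) - 1e-12) + 1) / (nPerm + 1)
    }
    c(rho, p)
  }
  res <- t(apply(expression, 1L, rho_p))
  data.frame(gene_id = rownames(expression) %||%
               as.character(seq_len(nrow(expression))),
             rho = res[, 1L], p = res[, 2L], row.names = NULL)
}

## all permutations of seq_len(n), rows = n! permutations
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}
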