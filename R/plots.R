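#' Bar plot of regulatory-pattern or inheritance-mode proportions
#'
#' @param classification data.frame from [classifyDataset()].
#' @param which `"regulation"` or `"inheritance"`.
#' @param ... passed to [graphics::barplot()].
#' @return (invisibly) the proportions plotted.
#' @export
plotCategoryProportions <- function(classification,
                                    which = c("regulation", "inheritance"),
                                    ...) {
  which <- match.arg(which)
  pr <- categoryProportions(classification)[[which]]
  graphics::barplot(pr, las = 2, ylab = "proportion of genes",
                    main = which, ...)
  invisible(pr)
}

#' Box plot of divergence magnitude by regulatory category
#'
#' @param divergence data.frame from [divergenceMagnitude()].
#' @param ... passed to [graphics::boxplot()].
#' @export
plotDivergenceByCategory <- function(divergence, ...) {
  cats <- intersect(.REG_CATEGORIES, unique(divergence$category))
  graphics::boxplot(magnitude ~ factor(category, levels = cats),
                    data = divergence, las = 2,
                    xlab = "", ylab = "|log2(R/S)|", ...)
  invisible(NULL)
}

#' Scatter plot of parental vs allelic log2 ratios, coloured by pattern
#'
#' The classic cis/trans diagnostic: genes on the diagonal are all-cis,
#' genes on the horizontal axis all-trans, off-diagonal genes mix effects.
#'
#' @param classification data.frame from [classifyDataset()].
#' @param ... passed to [graphics::plot()].
#' @export
plotRegulationScatter <- function(classification, ...) {
  cl <- classification[classification$informative_regulation, ]
  cols <- stats::setNames(
    c("grey60", "#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e",
      "grey85", "white"), .REG_CATEGORIES)
  graphics::plot(cl$L_P, cl$L_H, col = cols[as.character(cl$regulation)],
                 pch = 16, cex = 0.6,
                 xlab = "parental log2(R/S)",
                 ylab = "hybrid allelic log2(R/S)", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::abline(0, 1, col = "grey80", lty = 2)
  invisible(NULL)
}

#' PCA score plot
#'
#' @param pca result of [runPCA()].
#' @param groups optional per-sample labels used for colour.
#' @param components which two components to show.
#' @param ... passed to [graphics::plot()].
#' @export
plotPCA <- function(pca, groups = NULL, components = c(1L, 2L), ...) {
  sc <- pca$scores[, components, drop = FALSE]
  ve <- round(100 * pca$varianceExplained[components], 1)
  col <- if (is.null(groups)) "black" else as.integer(factor(groups))
  graphics::plot(sc[, 1L], sc[, 2L], col = col, pch = 16,
                 xlab = sprintf("PC%d (%.1f%%)", components[1L], ve[1L]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2L], ve[2L]),
                 ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 16,
                     cex = 0.7)
  invisible(NULL)
}
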