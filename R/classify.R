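#' Classify cis/trans regulatory pattern from three test outcomes
#'
#' Decision table on the significance flags of the parental contrast
#' (sig_P), the hybrid allelic contrast (sig_H) and the trans
#' ratio-difference test (sig_T):
#' \tabular{llll}{
#'   sig_P \tab sig_H \tab sig_T \tab pattern \cr
#'   F \tab F \tab F \tab conserved \cr
#'   T \tab T \tab F \tab all_cis \cr
#'   T \tab F \tab T \tab all_trans \cr
#'   T \tab T \tab T \tab cis_plus_trans if the parental and allelic ratios
#'     share sign, else cis_times_trans \cr
#'   F \tab T \tab T \tab compensatory \cr
#'   other \tab \tab \tab ambiguous
#' }
#' Any gene uninformative in a required contrast is `uninformative`. A log2
#' ratio of exactly 0 with a significant flag (contrived input) yields
#' `ambiguous`.
#'
#' @param sigP,sigH,sigT logical significance flags.
#' @param LP,LH,LT log2 ratios (LT used only under the `"allelic_trans"`
#'   sign convention).
#' @param informative logical; FALSE forces `uninformative`.
#' @param convention `"parental_allelic"` (default: compare sign(L_P) with
#'   sign(L_H)) or `"allelic_trans"` (compare sign(L_H) with sign(L_T)).
#' @return character vector of regulatory-pattern labels.
#' @export
classifyRegulation <- function(sigP, sigH, sigT, LP, LH, LT = NULL,
                               informative = TRUE,
                               convention = c("parental_allelic",
                                              "allelic_trans")) {
  convention <- match.arg(convention)
  n <- max(length(sigP), length(sigH), length(sigT))
  sigP <- rep_len(sigP, n); sigH <- rep_len(sigH, n); sigT <- rep_len(sigT, n)
  LP <- rep_len(LP, n); LH <- rep_len(LH, n)
  informative <- rep_len(informative, n)
  if (convention == "allelic_trans") {
    if (is.null(LT)) stop("LT is required under the allelic_trans convention")
    LT <- rep_len(LT, n)
  }
  out <- rep("ambiguous", n)
  out[!sigP & !sigH & !sigT] <- "conserved"
  out[sigP & sigH & !sigT] <- "all_cis"
  out[sigP & !sigH & sigT] <- "all_trans"
  out[!sigP & sigH & sigT] <- "compensatory"
  ttt <- sigP & sigH & sigT
  agree <- if (convention == "parental_allelic")
    sign(LP) == sign(LH) & LP != 0 & LH != 0
  else
    sign(LH) == sign(LT) & LH != 0 & LT != 0
  tie <- if (convention == "parental_allelic") LP == 0 | LH == 0
         else LH == 0 | LT == 0
  out[ttt & agree] <- "cis_plus_trans"
  out[ttt & !agree & !tie] <- "cis_times_trans"
  out[ttt & tie] <- "ambiguous"
  out[!informative] <- "uninformative"
  out
}

#' Classify inheritance mode from three test outcomes
#'
#' Compares hybrid total expression with each parent (FR: hybrid vs parent
#' R; FS: hybrid vs parent S) and the parents with each other (P):
#' no significant difference anywhere is `conserved`; hybrid significantly
#' above both parents `overdominant`, below both `underdominant`
#' (misexpression); hybrid significantly different from both parents in
#' opposite directions, with the parents diverged, `additive`
#' (intermediate); hybrid indistinguishable from one diverged parent,
#' `RR_dominant` / `SS_dominant`; anything else `ambiguous`. Over- and
#' underdominance do not require parental divergence (a hybrid can escape
#' two equal parents); additivity does.
#'
#' @param sigP,sigFR,sigFS logical significance flags.
#' @param LP,LFR,LFS log2 ratios; LFR = log2(hybrid/parent_R),
#'   LFS = log2(hybrid/parent_S).
#' @param informative logical; FALSE forces `uninformative`.
#' @return character vector of inheritance-mode labels.
#' @export
classifyInheritance <- function(sigP, sigFR, sigFS, LP, LFR, LFS,
                                informative = TRUE) {
  n <- max(length(sigP), length(sigFR), length(sigFS))
  sigP <- rep_len(sigP, n); sigFR <- rep_len(sigFR, n)
  sigFS <- rep_len(sigFS, n)
  LP <- rep_len(LP, n); LFR <- rep_len(LFR, n); LFS <- rep_len(LFS, n)
  informative <- rep_len(informative, n)
  out <- rep("ambiguous", n)
  out[!sigP & !sigFR & !sigFS] <- "conserved"
  out[sigFR & sigFS & LFR > 0 & LFS > 0] <- "overdominant"
  out[sigFR & sigFS & LFR < 0 & LFS < 0] <- "underdominant"
  out[sigP & sigFR & sigFS & sign(LFR) != sign(LFS) &
        LFR != 0 & LFS != 0] <- "additive"
  out[sigP & !sigFR & sigFS] <- "RR_dominant"
  out[sigP & sigFR & !sigFS] <- "SS_dominant"
  out[!informative] <- "uninformative"
  out
}

#' Classify every gene of a dataset
#'
#' Applies both decision tables to the five contrasts from
#' [runContrasts()]. Significance flags are `padj < alpha` (or raw
#' `p < alpha` when `config$useAdjusted` is FALSE). A gene uninformative in
#' any of P/H/T is regulatory-uninformative; in any of P/FR/FS
#' inheritance-uninformative.
#'
#' @param contrasts named list with elements `P`, `H`, `T`, `FR`, `FS`
#'   (from [runContrasts()]).
#' @param config a [testConfig()].
#' @return data.frame: gene_id, the five L's, the five sig flags, the two
#'   informativeness flags, `regulation` and `inheritance` (factors in
#'   canonical category order).
#' @export
classifyDataset <- function(contrasts, config = testConfig()) {
  need <- c("P", "H", "T", "FR", "FS")
  if (!all(need %in% names(contrasts)))
    stop("missing contrast families: ",
         paste(setdiff(need, names(contrasts)), collapse = ", "))
  g <- as.character(contrasts$P$gene_id)
  for (nm in need)
    if (!identical(as.character(contrasts[[nm]]$gene_id), g))
      stop("gene universe mismatch in contrast family ", nm)
  sig <- function(r) {
    v <- if (isTRUE(config$useAdjusted)) r$padj else r$p
    v < config$alpha
  }
  sigP <- sig(contrasts$P); sigH <- sig(contrasts$H)
  sigT <- sig(contrasts$T)
  sigFR <- sig(contrasts$FR); sigFS <- sig(contrasts$FS)
  infReg <- contrasts$P$informative & contrasts$H$informative &
    contrasts$T$informative
  infInh <- contrasts$P$informative & contrasts$FR$informative &
    contrasts$FS$informative
  regulation <- classifyRegulation(sigP, sigH, sigT,
                                   contrasts$P$L, contrasts$H$L,
                                   contrasts$T$L, infReg,
                                   convention = config$signConvention)
  inheritance <- classifyInheritance(sigP, sigFR, sigFS,
                                     contrasts$P$L, contrasts$FR$L,
                                     contrasts$FS$L, infInh)
  data.frame(gene_id = g,
             L_P = contrasts$P$L, L_H = contrasts$H$L, L_T = contrasts$T$L,
             L_FR = contrasts$FR$L, L_FS = contrasts$FS$L,
             sig_P = sigP, sig_H = sigH, sig_T = sigT,
             sig_FR = sigFR, sig_FS = sigFS,
             informative_regulation = infReg,
             informative_inheritance = infInh,
             regulation = factor(regulation, levels = .REG_CATEGORIES),
             inheritance = factor(inheritance, levels = .INH_MODES),
             row.names = NULL)
}

#' Category proportions of a classified dataset
#'
#' @param classification data.frame from [classifyDataset()].
#' @return list with `regulation` and `inheritance` proportion tables
#'   (each sums to 1 over all genes, uninformative included).
#' @export
categoryProportions <- function(classification) {
  list(regulation = proportions(table(classification$regulation)),
       inheritance = proportions(table(classification$inheritance)))
}

#' Proportion of misexpressed genes
#'
#' Misexpression in F1 hybrids is over- or underdominant inheritance:
#' hybrid expression outside the parental range. Reported as the fraction
#' of informative genes, with the per-direction breakdown.
#'
#' @param classification data.frame from [classifyDataset()].
#' @return list: `proportion`, `overdominant`, `underdominant` (fractions of
#'   informative genes; NA when no gene is informative), `nInformative`.
#' @export
misexpressionProportion <- function(classification) {
  stopifnot(nrow(classification) > 0)
  inf <- classification$informative_inheritance
  nInf <- sum(inf)
  if (nInf == 0L)
    return(list(proportion = NA_real_, overdominant = NA_real_,
                underdominant = NA_real_, nInformative = 0L))
  inh <- as.character(classification$inheritance[inf])
  over <- mean(inh == "overdominant")
  under <- mean(inh == "underdominant")
  list(proportion = over + under, overdominant = over,
       underdominant = under, nInformative = nInf)
}
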