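#' Draw per-gene ground truth for a simulated two-species + hybrid dataset
#'
#' Assigns each gene a true regulatory category (multinomial over
#' `categoryFractions`), then cis (c), trans (t) and misexpression (m)
#' effects in log2 units consistent with that category:
#' \itemize{
#'   \item conserved: c = t = 0
#'   \item all_cis: c = s e, t = 0
#'   \item all_trans: c = 0, t = s e
#'   \item cis_plus_trans: c = s e, t = s e (same sign, reinforcing)
#'   \item cis_times_trans: c = s e, t = -2 s e (opposing, trans dominates,
#'     so the parental and allelic ratios have opposite signs)
#'   \item compensatory: c = s e, t = -s e (exact cancellation)
#' }
#' with s a random sign and e = `effectSizeLog2`. A fraction
#' `misexpressionFraction` of genes additionally receives a hybrid-specific
#' shift m = +/- `misexpressionShiftLog2`. Baselines mu_g are log2-normal.
#'
#' The derived columns `trueRegulatoryCategory` and `trueInheritanceMode`
#' are the categories an ideal classifier would recover; the inheritance
#' mode is computed from the expected group means (hybrid above both parents
#' = overdominant, below both = underdominant, at the mid-parent with
#' diverged parents = additive, etc.).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A `DataFrame` with one row per gene: `gene_id`, `mu`, `c`, `t`,
#'   `m`, `trueRegulatoryCategory`, `trueInheritanceMode`.
#' @examples
#' truth <- simulateTruth(simulationConfig(nGenes = 50, seed = 1))
#' table(truth$trueRegulatoryCategory)
#' @export
simulateTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nGenes
  e <- config@effectSizeLog2
  cat_draw <- sample(.SIM_CATEGORIES, n, replace = TRUE,
                     prob = config@categoryFractions)
  s <- sample(c(-1, 1), n, replace = TRUE)
  c_eff <- numeric(n)
  t_eff <- numeric(n)
  c_eff[cat_draw == "all_cis"] <- (s * e)[cat_draw == "all_cis"]
  t_eff[cat_draw == "all_trans"] <- (s * e)[cat_draw == "all_trans"]
  i <- cat_draw == "cis_plus_trans"
  c_eff[i] <- (s * e)[i]; t_eff[i] <- (s * e)[i]
  i <- cat_draw == "cis_times_trans"
  c_eff[i] <- (s * e)[i]; t_eff[i] <- (-2 * s * e)[i]
  i <- cat_draw == "compensatory"
  c_eff[i] <- (s * e)[i]; t_eff[i] <- (-s * e)[i]
  m_eff <- numeric(n)
  mis <- runif(n) < config@misexpressionFraction
  m_eff[mis] <- sample(c(-1, 1), sum(mis), replace = TRUE) *
    config@misexpressionShiftLog2
  mu <- 2^stats::rnorm(n, config@baselineLog2Mean, config@baselineLog2Sd)
  truth <- DataFrame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    mu = mu, c = c_eff, t = t_eff, m = m_eff,
    trueRegulatoryCategory = trueRegulatoryCategory(c_eff, t_eff),
    trueInheritanceMode = trueInheritanceMode(c_eff, t_eff, m_eff))
  rownames(truth) <- truth$gene_id
  truth
}

#' True regulatory category implied by (c, t)
#'
#' Recomputes the category label from the cis and trans effects alone;
#' used both by the generator and by truth-consistency tests.
#'
#' @param c,t cis and trans effects (log2).
#' @param tol numeric tolerance for "zero" and for exact cancellation.
#' @return character vector of category labels.
#' @export
trueRegulatoryCategory <- function(c, t, tol = 1e-12) {
  cz <- abs(c) < tol
  tz <- abs(t) < tol
  out <- character(length(c))
  out[cz & tz] <- "conserved"
  out[!cz & tz] <- "all_cis"
  out[cz & !tz] <- "all_trans"
  both <- !cz & !tz
  cancel <- both & abs(c + t) < tol
  same <- both & !cancel & sign(c) == sign(t)
  out[same] <- "cis_plus_trans"
  out[cancel] <- "compensatory"
  ## opposing signs without cancellation: cis x trans when the net parental
  ## ratio flips sign relative to the allelic (cis) ratio, ambiguous-by-
  ## construction otherwise (net still cis-directed; not generated here)
  opp <- both & !cancel & sign(c) != sign(t)
  out[opp & sign(c + t) != sign(c)] <- "cis_times_trans"
  out[opp & sign(c + t) == sign(c)] <- "cis_plus_trans"
  out
}

#' True inheritance mode implied by (c, t, m)
#'
#' @param c,t,m per-gene effects (log2).
#' @param tol relative tolerance for comparing expected means.
#' @return character vector of mode labels.
#' @export
trueInheritanceMode <- function(c, t, m, tol = 1e-9) {
  pR <- 2^(+(c + t) / 2)
  pS <- 2^(-(c + t) / 2)
  fT <- 2^m * (pR + pS) / 2
  hi <- pmax(pR, pS); lo <- pmin(pR, pS)
  eq <- function(a, b) abs(a - b) <= tol * pmax(a, b)
  out <- rep("ambiguous", length(c))
  out[eq(pR, pS) & eq(fT, pR)] <- "conserved"
  out[fT > hi * (1 + tol)] <- "overdominant"
  out[fT < lo * (1 - tol)] <- "underdominant"
  mid <- !eq(pR, pS) & fT < hi * (1 - tol) & fT > lo * (1 + tol)
  out[mid & !eq(fT, pR) & !eq(fT, pS)] <- "additive"
  out[mid & eq(fT, pR)] <- "RR_dominant"
  out[mid & eq(fT, pS)] <- "SS_dominant"
  out
}

#' Expected group means under the generative model
#'
#' Parental divergence is c + t and hybrid allelic divergence is c alone,
#' split symmetrically around the baseline so mu is the geometric mid-parent:
#' \deqn{E[R] = \mu 2^{+(c+t)/2}, \quad E[S] = \mu 2^{-(c+t)/2}}
#' \deqn{\mu_F = 2^m (E[R] + E[S]) / 2}
#' \deqn{E[F_R] = (\mu_F/2) 2^{+c/2}, \quad E[F_S] = (\mu_F/2) 2^{-c/2}}
#'
#' @param truth truth table from [simulateTruth()].
#' @param group one of `"parent_R"`, `"parent_S"`, `"hybrid_total"`,
#'   `"hybrid_allele_R"`, `"hybrid_allele_S"`.
#' @return numeric vector of expected means (counts scale), one per gene.
#' @examples
#' tr <- DataFrame(mu = 100, c = 2, t = 0, m = 0)
#' expectedMeans(tr, "hybrid_allele_R") / expectedMeans(tr, "hybrid_allele_S")
#' @export
expectedMeans <- function(truth, group) {
  group <- match.arg(group, .SAMPLE_GROUPS)
  mu <- truth$mu; c <- truth$c; t <- truth$t; m <- truth$m
  pR <- mu * 2^(+(c + t) / 2)
  pS <- mu * 2^(-(c + t) / 2)
  muF <- 2^m * (pR + pS) / 2
  switch(group,
         parent_R = pR,
         parent_S = pS,
         hybrid_total = muF,
         hybrid_allele_R = (muF / 2) * 2^(+c / 2),
         hybrid_allele_S = (muF / 2) * 2^(-c / 2))
}

## NB draw that degenerates to Poisson at alpha = 0
.rnb <- function(n, mu, alpha) {
  if (alpha == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Sample a count dataset from a truth table
#'
#' Draws parental and hybrid-total counts from a negative binomial with the
#' model's expected means (scaled by per-library size factors) and dispersion
#' alpha. Hybrid allele counts are obtained by binomial thinning of each
#' hybrid total: `assigned ~ Binomial(total, assignmentRate)` reads are
#' assignable, split R vs S with probability \eqn{2^c/(2^c + 1)} for R, so
#' that R + S + unassigned = total exactly, per gene per library.
#'
#' @param truth truth table from [simulateTruth()].
#' @param config the \linkS4class{SimulationConfig} (its seed, offset by 1,
#'   governs this stage's randomness).
#' @return A \linkS4class{HybridExpressionSet} with the truth in `rowData`.
#' @export
sampleCounts <- function(truth, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 1L)
  n <- nrow(truth)
  reps <- config@nReplicates
  alpha <- config@dispersion
  nsamp <- 5L * reps
  sf <- rep_len(config@librarySizeFactors, nsamp)
  means <- list(parent_R = expectedMeans(truth, "parent_R"),
                parent_S = expectedMeans(truth, "parent_S"),
                hybrid_total = expectedMeans(truth, "hybrid_total"))
  draw <- function(mu, f) .rnb(n, mu * f, alpha)
  cols <- list(); grp <- character(); repl <- integer()
  j <- 0L
  for (g in c("parent_R", "parent_S")) {
    for (r in seq_len(reps)) {
      j <- j + 1L
      cols[[length(cols) + 1L]] <- draw(means[[g]], sf[j])
      grp <- c(grp, g); repl <- c(repl, r)
    }
  }
  pRallele <- 2^truth$c / (2^truth$c + 1)
  for (r in seq_len(reps)) {
    j <- j + 1L
    tot <- draw(means$hybrid_total, sf[j])
    assigned <- stats::rbinom(n, tot, config@assignmentRate)
    aR <- stats::rbinom(n, assigned, pRallele)
    aS <- assigned - aR
    cols[[length(cols) + 1L]] <- tot
    cols[[length(cols) + 1L]] <- aR
    cols[[length(cols) + 1L]] <- aS
    grp <- c(grp, "hybrid_total", "hybrid_allele_R", "hybrid_allele_S")
    repl <- c(repl, r, r, r)
  }
  k <- do.call(cbind, cols)
  rownames(k) <- truth$gene_id
  colnames(k) <- paste0(grp, "_", repl)
  HybridExpressionSet(k, group = grp, replicate = repl, truth = truth)
}

#' Simulate a complete dataset (truth + counts, optionally reads)
#'
#' Convenience wrapper: [simulateTruth()] then [sampleCounts()], and when
#' `reads = TRUE` also [simulateReads()].
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param reads also simulate read-level data (FASTQ/sites/alignments)?
#' @return A list with elements `counts` (\linkS4class{HybridExpressionSet}),
#'   `truth`, and when requested `reads` (see [simulateReads()]).
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 20, seed = 3))
#' sim$counts
#' @export
simulateDataset <- function(config, reads = FALSE) {
  truth <- simulateTruth(config)
  se <- sampleCounts(truth, config)
  out <- list(counts = se, truth = truth)
  if (reads) out$reads <- simulateReads(truth, config)
  out
}
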