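# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles are deliberately written as literal
# rule-by-rule transcriptions, independent of the vectorized implementations
# they check.

# Regulatory pattern, one gene at a time, rules spelled out longhand.
oracleRegulation <- function(sigP, sigH, sigT, LP, LH, informative = TRUE) {
  if (!informative) return("uninformative")
  if (!sigP && !sigH && !sigT) return("conserved")
  if (sigP && sigH && !sigT) return("all_cis")
  if (sigP && !sigH && sigT) return("all_trans")
  if (!sigP && sigH && sigT) return("compensatory")
  if (sigP && sigH && sigT) {
    if (LP == 0 || LH == 0) return("ambiguous")
    if ((LP > 0) == (LH > 0)) return("cis_plus_trans")
    return("cis_times_trans")
  }
  "ambiguous"
}

# Inheritance mode, one gene at a time.
oracleInheritance <- function(sigP, sigFR, sigFS, LP, LFR, LFS,
                              informative = TRUE) {
  if (!informative) return("uninformative")
  if (!sigP && !sigFR && !sigFS) return("conserved")
  if (sigFR && sigFS && LFR > 0 && LFS > 0) return("overdominant")
  if (sigFR && sigFS && LFR < 0 && LFS < 0) return("underdominant")
  if (sigP && sigFR && sigFS && LFR != 0 && LFS != 0 &&
      (LFR > 0) != (LFS > 0)) return("additive")
  if (sigP && !sigFR && sigFS) return("RR_dominant")
  if (sigP && sigFR && !sigFS) return("SS_dominant")
  "ambiguous"
}

# All combinations of three significance flags x sign patterns of the log2
# ratios x informativeness, as a data.frame for exhaustive enumeration.
enumerateCases <- function() {
  expand.grid(s1 = c(FALSE, TRUE), s2 = c(FALSE, TRUE), s3 = c(FALSE, TRUE),
              L1 = c(-1.5, 0, 1.5), L2 = c(-0.5, 0, 0.5),
              L3 = c(-1, 0, 1),
              informative = c(FALSE, TRUE))
}

# Minimal hybrid count matrix with known group means, Poisson noise.
# Allele columns are binomial thins of the matching hybrid totals so the
# container's allele-sum invariant holds.
makeCountSet <- function(nGenes = 50, reps = 3, mean = 500, seed = 42) {
  set.seed(seed)
  grp <- rep(sampleGroupLevels(), each = reps)
  repl <- rep(seq_len(reps), times = 5)
  k <- matrix(rpois(nGenes * length(grp), mean), nGenes)
  colnames(k) <- paste0(grp, "_", repl)
  rownames(k) <- sprintf("g%03d", seq_len(nGenes))
  for (r in seq_len(reps)) {
    tot <- k[, grp == "hybrid_total" & repl == r]
    aR <- rbinom(nGenes, tot, 0.5)
    k[, grp == "hybrid_allele_R" & repl == r] <- aR
    k[, grp == "hybrid_allele_S" & repl == r] <- tot - aR
  }
  HybridExpressionSet(k, grp, repl)
}

# Contrast-result stub for classifier-level tests.
makeResult <- function(gene_id, L, se = 0.1, p = 0.5, informative = TRUE,
                       contrast = "stub") {
  data.frame(gene_id = gene_id, contrast = contrast, L = L, se = se,
             stat = L / se, p = p, padj = p, informative = informative,
             meanA = 100, meanB = 100)
}
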