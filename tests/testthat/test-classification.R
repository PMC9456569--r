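test_that("regulatory decision table matches the brute-force oracle", {
  cases <- enumerateCases()
  got <- classifyRegulation(cases$s1, cases$s2, cases$s3,
                            cases$L1, cases$L2, cases$L3,
                            informative = cases$informative)
  want <- vapply(seq_len(nrow(cases)), function(i)
    oracleRegulation(cases$s1[i], cases$s2[i], cases$s3[i],
                     cases$L1[i], cases$L2[i], cases$informative[i]), "")
  expect_identical(got, want)
  # total and single-valued: every case got exactly one known label
  expect_true(all(got %in% regulatoryCategories()))
})

test_that("named sign cases split cis+trans from cis x trans", {
  expect_equal(classifyRegulation(TRUE, TRUE, TRUE, LP = 2, LH = 1),
               "cis_plus_trans")
  expect_equal(classifyRegulation(TRUE, TRUE, TRUE, LP = 1, LH = -1),
               "cis_times_trans")
  expect_equal(classifyRegulation(FALSE, TRUE, TRUE, LP = 0, LH = 1),
               "compensatory")
  expect_equal(classifyRegulation(TRUE, TRUE, TRUE, LP = 0, LH = 1),
               "ambiguous")  # tie at exactly 0 with a significant flag
  # alternative sign convention: agreement of L_H with L_T
  expect_equal(classifyRegulation(TRUE, TRUE, TRUE, LP = 2, LH = 1, LT = 1,
                                  convention = "allelic_trans"),
               "cis_plus_trans")
  expect_equal(classifyRegulation(TRUE, TRUE, TRUE, LP = 2, LH = 1, LT = -1,
                                  convention = "allelic_trans"),
               "cis_times_trans")
})

test_that("inheritance decision table matches the brute-force oracle", {
  cases <- enumerateCases()
  got <- classifyInheritance(cases$s1, cases$s2, cases$s3,
                             cases$L1, cases$L2, cases$L3,
                             informative = cases$informative)
  want <- vapply(seq_len(nrow(cases)), function(i)
    oracleInheritance(cases$s1[i], cases$s2[i], cases$s3[i],
                      cases$L1[i], cases$L2[i], cases$L3[i],
                      cases$informative[i]), "")
  expect_identical(got, want)
  expect_true(all(got %in% inheritanceModes()))
})

test_that("misexpression is hybrid expression outside the parental range", {
  # hybrid above both parents
  expect_equal(classifyInheritance(FALSE, TRUE, TRUE, 0, 1, 1),
               "overdominant")
  expect_equal(classifyInheritance(FALSE, TRUE, TRUE, 0, -1, -1),
               "underdominant")
  # intermediate between diverged parents
  expect_equal(classifyInheritance(TRUE, TRUE, TRUE, 2, -1, 1), "additive")
  # additive requires parental divergence
  expect_equal(classifyInheritance(FALSE, TRUE, TRUE, 0, -1, 1), "ambiguous")
  # hybrid tracks one parent
  expect_equal(classifyInheritance(TRUE, FALSE, TRUE, 2, 0, 2),
               "RR_dominant")
  expect_equal(classifyInheritance(TRUE, TRUE, FALSE, 2, -2, 0),
               "SS_dominant")
})

test_that("species relabelling R<->S maps categories symmetrically", {
  cases <- enumerateCases()
  reg1 <- classifyRegulation(cases$s1, cases$s2, cases$s3,
                             cases$L1, cases$L2, cases$L3,
                             informative = cases$informative)
  # swapping species negates every log2 ratio; flags unchanged
  reg2 <- classifyRegulation(cases$s1, cases$s2, cases$s3,
                             -cases$L1, -cases$L2, -cases$L3,
                             informative = cases$informative)
  expect_identical(reg1, reg2)  # regulatory patterns are direction-free

  inh1 <- classifyInheritance(cases$s1, cases$s2, cases$s3,
                              cases$L1, cases$L2, cases$L3,
                              informative = cases$informative)
  # under the swap the parental ratio negates, while the hybrid-vs-parent
  # contrasts exchange roles keeping the hybrid in the numerator
  inh2 <- classifyInheritance(cases$s1, cases$s3, cases$s2,
                              -cases$L1, cases$L3, cases$L2,
                              informative = cases$informative)
  map <- c(conserved = "conserved", additive = "additive",
           RR_dominant = "SS_dominant", SS_dominant = "RR_dominant",
           overdominant = "overdominant", underdominant = "underdominant",
           ambiguous = "ambiguous", uninformative = "uninformative")
  expect_identical(unname(map[inh1]), inh2)
})

test_that("classifyDataset joins the five families and summarizes", {
  sim <- simulateDataset(simulationConfig(nGenes = 80, seed = 16,
                                          effectSizeLog2 = 2))
  ct <- runContrasts(sim$counts)
  cls <- classifyDataset(ct)
  expect_equal(nrow(cls), 80L)
  pr <- categoryProportions(cls)
  expect_equal(sum(pr$regulation), 1)
  expect_equal(sum(pr$inheritance), 1)
  expect_error(classifyDataset(ct[c("P", "H")]), "missing contrast")

  # empty gene set passes through
  ct0 <- lapply(ct[c("P", "H", "T", "FR", "FS")], function(d) d[0, ])
  expect_equal(nrow(classifyDataset(ct0)), 0L)
})

test_that("misexpressionProportion counts over/under among informative", {
  cls <- data.frame(
    gene_id = sprintf("g%d", 1:12),
    informative_inheritance = c(rep(TRUE, 10), FALSE, FALSE),
    inheritance = c("overdominant", "underdominant", rep("conserved", 8),
                    "overdominant", "ambiguous"))
  m <- misexpressionProportion(cls)
  expect_equal(m$proportion, 0.2)
  expect_equal(m$overdominant, 0.1)
  expect_equal(m$nInformative, 10L)

  cls0 <- data.frame(gene_id = "g1", informative_inheritance = FALSE,
                     inheritance = "uninformative")
  expect_true(is.na(misexpressionProportion(cls0)$proportion))
})
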