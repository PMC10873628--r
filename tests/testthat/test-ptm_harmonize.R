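test_that("probability strings parse to positions in the stripped peptide", {
  p <- parse_probability_string("AAS(0.98)PT(0.02)K")
  expect_equal(p$peptide, "AASPTK")
  expect_equal(p$annotations$position_in_peptide, c(3L, 5L))
  expect_equal(p$annotations$residue, c("S", "T"))
  expect_equal(p$annotations$probability, c(0.98, 0.02))

  plain <- parse_probability_string("PEPTIDE")
  expect_equal(plain$peptide, "PEPTIDE")
  expect_equal(nrow(plain$annotations), 0L)

  one <- parse_probability_string("S(1)")
  expect_equal(one$annotations$probability, 1)
  expect_equal(one$annotations$position_in_peptide, 1L)

  # Spectronaut-style underscore anchors are normalized away
  expect_equal(parse_probability_string("_GPLS(0.97)R_")$peptide, "GPLSR")

  expect_error(parse_probability_string("AS(0.5K"), "parenthes",
               class = "volcanaut_data_error")
  expect_error(parse_probability_string("AS(1.5)K"), "\\[0, 1\\]",
               class = "volcanaut_data_error")
})

test_that("each dialect converter reproduces the generated ground truth", {
  sim <- gen_ptm(ptm_sim_params(seed = 101))
  converted <- list(
    maxquant = convert_maxquant(sim$files$maxquant,
                                sequences = sim$sequences_exp),
    msfragger = convert_msfragger(sim$files$msfragger, sim$sequences_exp),
    spectronaut = convert_spectronaut(sim$files$spectronaut,
                                      sim$sequences_exp),
    diann = convert_diann(sim$files$diann_quant, sim$files$diann_prob,
                          sequences = sim$sequences_exp))
  for (engine in names(converted)) {
    sites <- converted[[engine]]
    expect_equal(sites$accession, sim$truth$accession, label = engine)
    expect_equal(sites$position_in_peptide, sim$truth$position_in_peptide,
                 label = engine)
    expect_equal(sites$position_in_protein, sim$truth$position_in_protein,
                 label = engine)
    expect_equal(sites$residue, sim$truth$residue, label = engine)
    expect_equal(sites$localization_probability, sim$truth$probability,
                 label = engine)
    expect_true(all(sites$valid), label = engine)
    # residue cross-check invariant: protein[pos] == residue
    seqs <- unclass(sim$sequences_exp)[sites$accession]
    expect_equal(substr(seqs, sites$position_in_protein,
                        sites$position_in_protein),
                 stats::setNames(sites$residue, sites$accession),
                 label = engine)
  }
})

test_that("maxquant multiplicity selects the matching intensity columns", {
  sim <- gen_ptm(ptm_sim_params(seed = 5))
  m1 <- convert_maxquant(sim$files$maxquant, multiplicity = 1)
  m2 <- convert_maxquant(sim$files$maxquant, multiplicity = 2)
  expect_equal(m2$quant, m1$quant * 2)  # generator writes x2 for ___2
  expect_equal(colnames(m1$quant), sim$samples)
})

test_that("msfragger peptides that mismatch the protein are flagged invalid", {
  seqs <- sequence_set(c(P1 = "MKSASKLLQ"))
  p <- write_tmp_tsv(data.frame(
    `Protein ID` = c("P1", "P1"),
    `Modified Peptide` = c("SAS(0.9)K", "WWS(0.9)W"),
    `Peptide Start` = c(3, 3),
    `Intensity A` = c(10, 10), check.names = FALSE))
  sites <- convert_msfragger(p, seqs)
  expect_equal(sites$position_in_protein[1], 5L)  # 3 + 3 - 1
  expect_equal(sites$residue[1], "S")
  expect_true(sites$valid[1])
  expect_false(sites$valid[2])
  expect_equal(attr(sites, "run_report")$n_invalid, 1L)
})

test_that("spectronaut locates peptides and flags ambiguous placements", {
  seqs <- sequence_set(c(P1 = "MAGPLSRK", P2 = "AGTKAGTK"))
  p <- write_tmp_tsv(data.frame(
    PG.ProteinAccessions = c("P1", "P2", "P1"),
    EG.ModifiedPeptide = c("_GPLS(0.97)R_", "_AGT(0.8)K_", "_QQQS(0.9)Q_"),
    EG.PTMType = c("Phospho (STY)", "Phospho (STY)", "GlyGly (K)"),
    `Intensity A` = c(1, 2, 3), check.names = FALSE))
  sites <- convert_spectronaut(p, seqs)
  expect_equal(sites$position_in_protein[1], 6L)
  expect_false(sites$ambiguous[1])
  # peptide occurs twice in P2: first occurrence, flagged ambiguous
  expect_equal(sites$position_in_protein[2], 3L)
  expect_true(sites$ambiguous[2])
  # peptide absent from protein: invalid
  expect_false(sites$valid[3])
  # combined file splits into per-modification tables
  by_mod <- split_by_modification(sites)
  expect_setequal(names(by_mod), c("Phospho (STY)", "GlyGly (K)"))
  expect_equal(nrow(by_mod[["Phospho (STY)"]]), 2L)
})

test_that("diann merge is an inner join with unmatched keys reported", {
  q <- data.frame(Precursor.Id = c("k1", "k2", "k3", "only_q"),
                  Protein.Group = "P1",
                  `Intensity A` = c(1, 2, 3, 4), check.names = FALSE)
  pr <- data.frame(Precursor.Id = c("k1", "k2", "k3", "only_p"),
                   Protein.Group = "P1",
                   Modified.Sequence = "SAS(0.9)K",
                   Peptide.Start = 3, Modification = "Phospho (STY)",
                   check.names = FALSE)
  sites <- convert_diann(write_tmp_tsv(q), write_tmp_tsv(pr))
  expect_equal(nrow(sites), 3L)
  rep <- attr(sites, "run_report")
  expect_equal(rep$unmatched_quant_keys, "only_q")
  expect_equal(rep$unmatched_prob_keys, "only_p")

  # zero key overlap is a merge error
  q2 <- q; q2$Precursor.Id <- paste0("x", q2$Precursor.Id)
  expect_error(convert_diann(write_tmp_tsv(q2), write_tmp_tsv(pr)),
               "overlapping", class = "volcanaut_data_error")

  # conflicting accession for a shared key is an error
  pr2 <- pr; pr2$Protein.Group[1] <- "P2"
  expect_error(convert_diann(write_tmp_tsv(q), write_tmp_tsv(pr2)),
               "conflicting accession", class = "volcanaut_data_error")
})

test_that("class-I filtering is strictly greater than the threshold", {
  sites <- ptm_sites(accession = c("P1", "P1", "P1"),
                     peptide = c("ASK", "ASK", "ASK"),
                     position_in_peptide = 2L, position_in_protein = 5L,
                     residue = "S",
                     localization_probability = c(0.99, 0.75, 0.74),
                     modification = "Phospho (STY)")
  kept <- filter_class1(sites)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$localization_probability, 0.99)
  expect_equal(nrow(filter_class1(sites, threshold = 0)), 3L)
  expect_equal(nrow(filter_class1(sites[0, ])), 0L)
})

test_that("class-I filter equals a brute-force recount across thresholds", {
  set.seed(9)
  probs <- round(stats::runif(300), 3)
  sites <- ptm_sites(accession = "P1", peptide = "ASK",
                     position_in_peptide = 2L,
                     position_in_protein = seq_along(probs),
                     residue = "S", localization_probability = probs,
                     modification = "m")
  sites$valid <- TRUE  # positions are synthetic, skip sequence checks
  for (thr in c(0, 0.5, 0.75, 0.999)) {
    expect_equal(nrow(filter_class1(sites, thr)), sum(probs > thr))
  }
})
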