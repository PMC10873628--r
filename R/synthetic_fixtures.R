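# Synthetic-data generators: every supported input dialect rendered from a
# known ground truth, so all importers, converters and downstream analyses
# are testable without any download. The dialect renderings implement
# exactly the column presets the converters expect — generator and parser
# are co-specified.

#' Simulation parameters for a label-free proteome experiment
#'
#' @param n_features Number of quantified features (protein groups).
#' @param n_conditions Number of conditions (>= 2; the differential
#'   comparison is condition 2 vs condition 1).
#' @param n_replicates Replicates per condition (>= 2).
#' @param de_fraction Fraction of features truly differential, in \[0, 1\].
#' @param effect_size True log2 fold change of differential features.
#' @param noise_sd Gaussian replicate noise on the log2 scale.
#' @param missing_rate Probability any single intensity is missing.
#' @param seed Integer seed; fully determines the output.
#' @return A `proteome_sim_params` list.
#' @export
proteome_sim_params <- function(n_features = 500, n_conditions = 2,
                                n_replicates = 4, de_fraction = 0.1,
                                effect_size = 3, noise_sd = 0.2,
                                missing_rate = 0.02, seed = 1) {
  if (n_replicates < 2) vn_config_error("n_replicates must be >= 2")
  if (n_conditions < 2) vn_config_error("n_conditions must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) {
    vn_config_error("de_fraction must lie in [0, 1]")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    vn_config_error("missing_rate must lie in [0, 1]")
  }
  structure(list(n_features = as.integer(n_features),
                 n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates),
                 de_fraction = de_fraction, effect_size = effect_size,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "proteome_sim_params")
}

#' Generate a synthetic proteome experiment with known truth
#'
#' Log2 intensities are a per-feature baseline plus, for the truly
#' differential features, a condition effect of `effect_size` (random sign)
#' in condition 2, plus Gaussian noise. The accompanying differential table
#' is computed per feature by a plain two-sample t-test (condition 2 vs
#' condition 1) on the generated log2 replicates — generator plumbing that
#' stands in for the external statistics program whose output the importer
#' normally consumes. Missing values are dropped per feature; features with
#' fewer than two non-missing replicates in either compared condition are
#' omitted from the differential table.
#'
#' @param params A [proteome_sim_params()].
#' @return List with `raw` (a `raw_quant`), `diff` (a `diff_table`),
#'   `truth` (data frame feature_id/gene/is_de/direction), and `colmap`
#'   (the [column_map()] matching [write_proteome_files()] output).
#' @export
gen_proteome <- function(params) {
  stopifnot(inherits(params, "proteome_sim_params"))
  set.seed(params$seed)
  n <- params$n_features
  ids <- sprintf("PROT%04d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(n))
  conds <- if (params$n_conditions == 2) c("control", "treatment") else
    sprintf("cond%d", seq_len(params$n_conditions))
  ann <- sample_annotation(
    sample_name = as.vector(t(outer(conds, seq_len(params$n_replicates),
                                    function(a, b) sprintf("%s_R%d", a, b)))),
    condition = rep(conds, each = params$n_replicates),
    replicate = rep(seq_len(params$n_replicates), times = length(conds)))

  n_de <- floor(params$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  direction <- integer(n)
  direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)

  baseline <- stats::rnorm(n, mean = 26, sd = 2)
  effect <- outer(direction * params$effect_size,
                  as.integer(ann$condition == conds[2]))
  log2_int <- baseline + effect +
    matrix(stats::rnorm(n * nrow(ann), 0, params$noise_sd), n, nrow(ann))
  miss <- matrix(stats::runif(n * nrow(ann)) < params$missing_rate,
                 n, nrow(ann))
  log2_int[miss] <- NA_real_
  intens <- 2 ^ log2_int
  dimnames(intens) <- list(ids, ann$sample_name)
  raw <- new_raw_quant(ids, ann, intens)

  i1 <- which(ann$condition == conds[1])
  i2 <- which(ann$condition == conds[2])
  stats_list <- lapply(seq_len(n), function(f) {
    x <- log2_int[f, i2]; y <- log2_int[f, i1]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA_real_))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    c(mean(x) - mean(y), tt$p.value)
  })
  fc <- vapply(stats_list, `[`, numeric(1), 1)
  pv <- vapply(stats_list, `[`, numeric(1), 2)
  keep <- is.finite(fc) & is.finite(pv) & pv > 0
  diff <- data.frame(primary_id = ids[keep], gene = genes[keep],
                     log2_fc = fc[keep], neglog10_sig = -log10(pv[keep]),
                     comparison = sprintf("%s vs %s", conds[2], conds[1]),
                     stringsAsFactors = FALSE)
  class(diff) <- c("diff_table", "data.frame")

  truth <- data.frame(feature_id = ids, gene = genes,
                      is_de = seq_len(n) %in% de_idx,
                      direction = direction, stringsAsFactors = FALSE)
  cm <- column_map("Protein IDs", "log2FC", "pvalue", fc_scale = "log2",
                   sig_scale = "raw_p", gene_col = "Gene names",
                   comparison_label = diff$comparison[1] %||%
                     sprintf("%s vs %s", conds[2], conds[1]))
  list(raw = raw, diff = diff, truth = truth, colmap = cm,
       annotation = ann)
}

#' Write a simulated proteome to importable files
#'
#' Renders [gen_proteome()] output as the two tab-delimited files the import
#' path consumes: a search-output-style raw intensity table (missing values
#' written as 0, the MaxQuant convention) and a differential-analysis table
#' (log2 fold change plus raw p-values, matching the colmap the generator
#' returns).
#'
#' @param sim A [gen_proteome()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`raw`, `diff`).
#' @export
write_proteome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw_path <- file.path(dir, "raw_intensities.tsv")
  m <- sim$raw$intensities
  m[is.na(m)] <- 0
  raw_df <- data.frame(sim$raw$feature_ids, sim$truth$gene,
                       m, check.names = FALSE, stringsAsFactors = FALSE)
  names(raw_df) <- c("Protein IDs", "Gene names",
                     sim$raw$samples$sample_name)
  write_tsv_file(raw_df, raw_path)

  diff_path <- file.path(dir, "differential.tsv")
  diff_df <- data.frame(sim$diff$primary_id, sim$diff$gene,
                        sim$diff$log2_fc, 10 ^ (-sim$diff$neglog10_sig),
                        check.names = FALSE, stringsAsFactors = FALSE)
  names(diff_df) <- c("Protein IDs", "Gene names", "log2FC", "pvalue")
  write_tsv_file(diff_df, diff_path)
  list(raw = raw_path, diff = diff_path)
}

#' Simulation parameters for a synthetic PTM experiment
#'
#' @param n_proteins Number of simulated proteins.
#' @param sites_per_protein Modified sites per protein.
#' @param seq_length Length range (min, max) of the experimental sequences.
#' @param prob_range Localization probabilities are drawn uniformly from
#'   this range (and rounded to 4 decimals so text renderings are exact).
#' @param offset_choices Isoform offsets sampled per protein: the canonical
#'   sequence gains (positive) or loses (negative) that many N-terminal
#'   residues relative to the experimental sequence.
#' @param n_samples Number of quantified samples.
#' @param seed Integer seed; fully determines the output.
#' @return A `ptm_sim_params` list.
#' @export
ptm_sim_params <- function(n_proteins = 6, sites_per_protein = 3,
                           seq_length = c(60, 120),
                           prob_range = c(0.3, 1),
                           offset_choices = c(0, 0, 5, 11, -3),
                           n_samples = 4, seed = 1) {
  if (any(prob_range < 0) || any(prob_range > 1)) {
    vn_config_error("prob_range must lie within [0, 1]")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 sites_per_protein = as.integer(sites_per_protein),
                 seq_length = as.integer(seq_length),
                 prob_range = prob_range,
                 offset_choices = as.integer(offset_choices),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "ptm_sim_params")
}

#' Generate a synthetic PTM experiment in all four dialects
#'
#' One underlying set of modified sites — with known protein, residue,
#' position and localization probability — is rendered into the four
#' supported report dialects (MaxQuant site table, MS-Fragger report,
#' Spectronaut report, DIA-NN quantification + probability pair) plus a
#' FASTA pair: the experimental sequences and canonical isoforms that
#' differ from them by known N-terminal extensions or deletions, so that
#' residue remapping has closed-form expected answers
#' (`canonical = experimental + offset`).
#'
#' @param params A [ptm_sim_params()].
#' @param dir Output directory for the rendered files.
#' @return List with `truth` (one row per site: accession, gene, peptide,
#'   position_in_peptide, position_in_protein, canonical_position, residue,
#'   probability, modification, offset), `sequences_exp` and
#'   `sequences_canonical` (`sequence_set`s), `samples`, and `files`
#'   (named paths: maxquant, msfragger, spectronaut, diann_quant,
#'   diann_prob, fasta_exp, fasta_canonical).
#' @export
gen_ptm <- function(params, dir = tempfile("ptm_fixture")) {
  stopifnot(inherits(params, "ptm_sim_params"))
  set.seed(params$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  np <- params$n_proteins
  acc <- sprintf("PTMP%02d", seq_len(np))
  genes <- sprintf("PGENE%02d", seq_len(np))
  offsets <- sample(params$offset_choices, np, replace = TRUE)
  lens <- sample(seq(params$seq_length[1], params$seq_length[2]), np,
                 replace = TRUE)
  margin <- max(8L, max(abs(params$offset_choices)) + 1L)

  exp_seqs <- character(np)
  canon_seqs <- character(np)
  rows <- list()
  for (i in seq_len(np)) {
    s <- sample(AA_STANDARD, lens[i], replace = TRUE)
    pos <- sort(sample(seq(margin, lens[i] - margin),
                       params$sites_per_protein))
    res <- sample(c("S", "T", "Y"), length(pos), replace = TRUE)
    s[pos] <- res
    exp_seqs[i] <- paste(s, collapse = "")
    canon_seqs[i] <- if (offsets[i] >= 0) {
      paste0(paste(sample(AA_STANDARD, offsets[i], replace = TRUE),
                   collapse = ""), exp_seqs[i])
    } else {
      substring(exp_seqs[i], 1 - offsets[i])
    }
    prob <- round(stats::runif(length(pos), params$prob_range[1],
                               params$prob_range[2]), 4)
    pep_start <- pmax(1L, pos - 5L)
    pep_end <- pmin(lens[i], pos + 5L)
    rows[[i]] <- data.frame(
      accession = acc[i], gene = genes[i],
      peptide = substring(exp_seqs[i], pep_start, pep_end),
      peptide_start = pep_start,
      position_in_peptide = pos - pep_start + 1L,
      position_in_protein = pos,
      canonical_position = pos + offsets[i],
      residue = res, probability = prob,
      modification = "Phospho (STY)", offset = offsets[i],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  seqs_exp <- sequence_set(stats::setNames(exp_seqs, acc))
  seqs_canon <- sequence_set(stats::setNames(canon_seqs, acc))

  samples <- sprintf("Sample_%d", seq_len(params$n_samples))
  n_sites <- nrow(truth)
  quant <- matrix(round(2 ^ stats::rnorm(n_sites * params$n_samples, 20, 2)),
                  n_sites, params$n_samples)

  annotate_peptide <- function(pep, pos_in_pep, prob) {
    paste0(substring(pep, 1, pos_in_pep),
           sprintf("(%s)", format(prob, trim = TRUE, scientific = FALSE)),
           substring(pep, pos_in_pep + 1))
  }
  annotated <- mapply(annotate_peptide, truth$peptide,
                      truth$position_in_peptide, truth$probability)

  int_named <- function(prefix, m) {
    df <- as.data.frame(m)
    names(df) <- paste0(INTENSITY_PREFIX, samples, prefix)
    df
  }

  files <- list()
  # MaxQuant site table: one row per site, protein-level numbering resolved
  mq <- data.frame(Protein = truth$accession, `Gene names` = truth$gene,
                   Position = truth$position_in_protein,
                   `Amino acid` = truth$residue,
                   `Localization prob` = truth$probability,
                   Probabilities = annotated,
                   `Position in peptide` = truth$position_in_peptide,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mq <- cbind(mq, int_named("___1", quant), int_named("___2", quant * 2),
              int_named("___3", quant * 3))
  files$maxquant <- file.path(dir, "maxquant_sites.tsv")
  write_tsv_file(mq, files$maxquant)

  # MS-Fragger: modified peptide + peptide start, no protein-level position
  mf <- data.frame(`Protein ID` = truth$accession, Gene = truth$gene,
                   `Modified Peptide` = annotated,
                   `Peptide Start` = truth$peptide_start,
                   check.names = FALSE, stringsAsFactors = FALSE)
  mf <- cbind(mf, int_named("", quant))
  files$msfragger <- file.path(dir, "msfragger_sites.tsv")
  write_tsv_file(mf, files$msfragger)

  # Spectronaut: modified peptide only, all modifications in one file
  sn <- data.frame(PG.ProteinAccessions = truth$accession,
                   PG.Genes = truth$gene,
                   EG.ModifiedPeptide = paste0("_", annotated, "_"),
                   EG.PTMType = truth$modification,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sn <- cbind(sn, int_named("", quant))
  files$spectronaut <- file.path(dir, "spectronaut_report.tsv")
  write_tsv_file(sn, files$spectronaut)

  # DIA-NN: quantification and probabilities in separate files, shared key
  key <- sprintf("%s_%d", truth$accession, truth$position_in_protein)
  dq <- data.frame(Precursor.Id = key, Protein.Group = truth$accession,
                   Genes = truth$gene, check.names = FALSE,
                   stringsAsFactors = FALSE)
  dq <- cbind(dq, int_named("", quant))
  files$diann_quant <- file.path(dir, "diann_quant.tsv")
  write_tsv_file(dq, files$diann_quant)
  dp <- data.frame(Precursor.Id = key, Protein.Group = truth$accession,
                   Modified.Sequence = annotated,
                   `Peptide.Start` = truth$peptide_start,
                   Modification = truth$modification,
                   check.names = FALSE, stringsAsFactors = FALSE)
  files$diann_prob <- file.path(dir, "diann_prob.tsv")
  write_tsv_file(dp, files$diann_prob)

  files$fasta_exp <- file.path(dir, "experimental.fasta")
  write_fasta(seqs_exp, files$fasta_exp)
  files$fasta_canonical <- file.path(dir, "canonical.fasta")
  write_fasta(seqs_canon, files$fasta_canonical)

  list(truth = truth, sequences_exp = seqs_exp,
       sequences_canonical = seqs_canon, samples = samples,
       quant = quant, files = files, params = params)
}
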