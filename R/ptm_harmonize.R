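# Harmonization of PTM site reports from four search-engine dialects into
# one canonical site table. MaxQuant site tables already carry protein-level
# residue numbers; MS-Fragger, Spectronaut and DIA-NN exports need the
# in-peptide annotation resolved against the protein sequence first.
#
# Each converter reads one representative column layout per engine (export
# headers drift across versions; the layouts here are presets, adjustable by
# renaming columns upstream). All converters emit the same `ptm_sites` table.

# Intensity columns are recognised by this header prefix in all dialects.
INTENSITY_PREFIX <- "Intensity "

#' Parse a probability-annotated peptide string
#'
#' Search engines report site localization as an annotated peptide in which
#' each candidate residue is followed by its localization probability in
#' parentheses, e.g. `"AAS(0.98)PT(0.02)K"`. This parses that grammar:
#' uppercase residue letters, each optionally followed by `(p)` with
#' p in \[0, 1\]. Leading/trailing `_` anchors (Spectronaut style) are
#' stripped before parsing.
#'
#' @param s Annotated peptide string.
#' @return List with `peptide` (the stripped sequence) and `annotations`
#'   (data frame `position_in_peptide`, `residue`, `probability`; positions
#'   1-based in the stripped peptide, strictly increasing).
#' @export
#' @examples
#' parse_probability_string("AAS(0.98)PT(0.02)K")
parse_probability_string <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s)) {
    vn_data_error("probability string must be a single character value")
  }
  s <- gsub("^_+|_+$", "", s)
  if (lengths(regmatches(s, gregexpr("(", s, fixed = TRUE))) !=
      lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))) {
    vn_data_error(sprintf("unbalanced parentheses in '%s'", s))
  }
  token_re <- "([A-Za-z])(\\(([0-9.eE+-]+)\\))?"
  m <- gregexpr(token_re, s, perl = TRUE)
  tokens <- regmatches(s, m)[[1]]
  if (length(tokens) == 0 ||
      sum(attr(m[[1]], "match.length")) != nchar(s)) {
    vn_data_error(sprintf("'%s' does not match the annotated-peptide grammar", s))
  }
  residues <- toupper(substr(tokens, 1, 1))
  has_prob <- nchar(tokens) > 1
  probs <- rep(NA_real_, length(tokens))
  probs[has_prob] <- suppressWarnings(
    as.numeric(sub("^.\\((.*)\\)$", "\\1", tokens[has_prob])))
  if (any(is.na(probs[has_prob]))) {
    vn_data_error(sprintf("unparseable probability in '%s'", s))
  }
  if (any(probs[has_prob] < 0 | probs[has_prob] > 1)) {
    vn_data_error(sprintf("probability outside [0, 1] in '%s'", s))
  }
  ann <- data.frame(position_in_peptide = which(has_prob),
                    residue = residues[has_prob],
                    probability = probs[has_prob],
                    stringsAsFactors = FALSE)
  list(peptide = paste(residues, collapse = ""), annotations = ann)
}

#' Construct a harmonized PTM site table
#'
#' @param accession,gene,peptide,position_in_peptide,position_in_protein,
#'   residue,localization_probability,modification Parallel site vectors;
#'   positions 1-based.
#' @param quant Numeric matrix (sites x samples) of intensities, or `NULL`.
#' @param ambiguous Logical: peptide placement in the protein was not unique.
#' @param valid Logical: record passed all residue cross-checks.
#' @return A `ptm_sites` data frame.
#' @export
ptm_sites <- function(accession, peptide, position_in_peptide,
                      position_in_protein, residue,
                      localization_probability, modification,
                      gene = NA_character_, quant = NULL,
                      ambiguous = FALSE, valid = TRUE) {
  n <- length(accession)
  df <- data.frame(accession = as.character(accession),
                   gene = rep_len(as.character(gene), n),
                   peptide = as.character(peptide),
                   position_in_peptide = as.integer(position_in_peptide),
                   position_in_protein = as.integer(position_in_protein),
                   residue = as.character(residue),
                   localization_probability = as.numeric(localization_probability),
                   modification = as.character(modification),
                   ambiguous = rep_len(as.logical(ambiguous), n),
                   valid = rep_len(as.logical(valid), n),
                   stringsAsFactors = FALSE)
  p <- df$localization_probability
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    vn_data_error("localization probabilities must lie in [0, 1]")
  }
  ok <- !is.na(df$position_in_peptide) & df$position_in_peptide >= 1 &
    df$position_in_peptide <= nchar(df$peptide)
  bad_pep <- ok & substr(df$peptide, df$position_in_peptide,
                         df$position_in_peptide) != df$residue
  df$valid[bad_pep | !ok] <- FALSE
  if (!is.null(quant)) {
    quant <- as.matrix(quant)
    storage.mode(quant) <- "double"
    stopifnot(nrow(quant) == n)
    df$quant <- quant
  }
  class(df) <- c("ptm_sites", "data.frame")
  df
}

#' @export
print.ptm_sites <- function(x, ...) {
  cat(sprintf("ptm_sites: %d site(s) on %d protein(s); %d invalid, %d ambiguous\n",
              nrow(x), length(unique(x$accession)),
              sum(!x$valid), sum(x$ambiguous)))
  invisible(x)
}

# Flag records whose protein-level residue disagrees with the sequence.
cross_check_residues <- function(sites, sequences) {
  if (is.null(sequences)) return(sites)
  rep_acc <- representative_accession(sites$accession)
  idx <- match(rep_acc, names(sequences))
  have <- !is.na(idx)
  seqs <- unclass(sequences)[idx[have]]
  pos <- sites$position_in_protein[have]
  in_range <- !is.na(pos) & pos >= 1 & pos <= nchar(seqs)
  agree <- in_range & substr(seqs, pos, pos) == sites$residue[have]
  sites$valid[have][!agree] <- FALSE
  sites
}

finish_sites <- function(sites, source) {
  attr(sites, "run_report") <- list(
    source = source, n_records = nrow(sites),
    n_invalid = sum(!sites$valid), n_ambiguous = sum(sites$ambiguous))
  sites
}

quant_matrix_from <- function(df, cols, sample_names) {
  if (length(cols) == 0) return(NULL)
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, sample_names)
  m
}

#' Convert a MaxQuant PTM site table
#'
#' MaxQuant site tables (e.g. a Phospho (STY) sites export) report one row
#' per site with the protein-level position, residue and localization
#' probability already resolved. Per-sample intensities carry a multiplicity
#' suffix (`___1`, `___2`, `___3` for singly/doubly/triply modified
#' peptides); one multiplicity is selected explicitly.
#'
#' Expected columns: `Protein`, `Position`, `Amino acid`,
#' `Localization prob`, `Probabilities`, `Position in peptide`, optional
#' `Gene names`, and `Intensity <sample>___<m>` intensity columns.
#'
#' @param path Tab-delimited site table.
#' @param multiplicity Which multiplicity's intensity columns to use (1-3).
#' @param modification Modification label attached to every record.
#' @param sequences Optional `sequence_set` for residue cross-checking.
#' @return A `ptm_sites` table.
#' @export
convert_maxquant <- function(path, multiplicity = 1,
                             modification = "Phospho (STY)",
                             sequences = NULL) {
  multiplicity <- as.integer(multiplicity)
  if (!multiplicity %in% 1:3) vn_config_error("multiplicity must be 1, 2 or 3")
  df <- read_tsv_file(path)
  require_columns(df, c("Protein", "Position", "Amino acid",
                        "Localization prob", "Probabilities",
                        "Position in peptide"), path)
  suffix <- sprintf("___%d", multiplicity)
  int_cols <- grep(sprintf("^%s.*%s$", INTENSITY_PREFIX, suffix), names(df),
                   value = TRUE)
  samples <- sub(sprintf("%s$", suffix), "",
                 sub(sprintf("^%s", INTENSITY_PREFIX), "", int_cols))
  parsed <- lapply(df$Probabilities, parse_probability_string)
  sites <- ptm_sites(
    accession = df$Protein,
    gene = if ("Gene names" %in% names(df)) df$`Gene names` else NA_character_,
    peptide = vapply(parsed, `[[`, character(1), "peptide"),
    position_in_peptide = df$`Position in peptide`,
    position_in_protein = df$Position,
    residue = toupper(df$`Amino acid`),
    localization_probability = df$`Localization prob`,
    modification = modification,
    quant = quant_matrix_from(df, int_cols, samples))
  sites <- cross_check_residues(sites, sequences)
  finish_sites(sites, "maxquant")
}

# Resolve annotated-peptide rows into one record per annotated site.
# `locate` returns, per row, the 1-based peptide start in the protein plus
# an ambiguity flag; position_in_protein = start + position_in_peptide - 1.
peptide_rows_to_sites <- function(df, accession, gene, annotated,
                                  modification, locate, quant) {
  parsed <- lapply(annotated, parse_probability_string)
  n_ann <- vapply(parsed, function(p) nrow(p$annotations), integer(1))
  row_idx <- rep(seq_along(parsed), n_ann)
  ann <- do.call(rbind, lapply(parsed, `[[`, "annotations"))
  if (is.null(ann) || nrow(ann) == 0) {
    return(ptm_sites(character(), character(), integer(), integer(),
                     character(), numeric(), character()))
  }
  peptide <- vapply(parsed, `[[`, character(1), "peptide")[row_idx]
  loc <- locate(row_idx)  # list(start, ambiguous, found) aligned to row_idx
  pos_prot <- ifelse(loc$found, loc$start + ann$position_in_peptide - 1L,
                     NA_integer_)
  sites <- ptm_sites(
    accession = accession[row_idx], gene = gene[row_idx],
    peptide = peptide,
    position_in_peptide = ann$position_in_peptide,
    position_in_protein = pos_prot,
    residue = ann$residue,
    localization_probability = ann$probability,
    modification = rep_len(modification, length(row_idx))[seq_along(row_idx)],
    quant = if (is.null(quant)) NULL else quant[row_idx, , drop = FALSE],
    ambiguous = loc$ambiguous)
  sites$valid[!loc$found] <- FALSE
  # records located only by in-peptide annotation keep NA protein position
  sites
}

#' Convert an MS-Fragger PTM report
#'
#' MS-Fragger PTM exports report the modified peptide and the peptide's
#' start position in the protein, but not the protein-level residue number;
#' that number is computed here as `peptide_start + position_in_peptide - 1`
#' and cross-checked against the protein sequence. Records whose peptide
#' does not match the protein at the stated start are flagged invalid.
#'
#' Expected columns: `Protein ID`, `Modified Peptide`, `Peptide Start`,
#' optional `Gene`, and `Intensity <sample>` columns.
#'
#' @param path Tab-delimited report.
#' @param sequences A `sequence_set` containing each report accession.
#' @param modification Modification label attached to every record.
#' @return A `ptm_sites` table.
#' @export
convert_msfragger <- function(path, sequences,
                              modification = "Phospho (STY)") {
  df <- read_tsv_file(path)
  require_columns(df, c("Protein ID", "Modified Peptide", "Peptide Start"),
                  path)
  int_cols <- grep(sprintf("^%s", INTENSITY_PREFIX), names(df), value = TRUE)
  samples <- sub(sprintf("^%s", INTENSITY_PREFIX), "", int_cols)
  acc <- as.character(df$`Protein ID`)
  starts <- as.integer(df$`Peptide Start`)
  stripped <- vapply(lapply(df$`Modified Peptide`, parse_probability_string),
                     `[[`, character(1), "peptide")
  seqs <- unclass(sequences)[representative_accession(acc)]
  found <- !is.na(seqs) & !is.na(starts) & starts >= 1 &
    substr(seqs, starts, starts + nchar(stripped) - 1L) == stripped
  locate <- function(row_idx) {
    list(start = starts[row_idx], ambiguous = rep(FALSE, length(row_idx)),
         found = found[row_idx])
  }
  sites <- peptide_rows_to_sites(
    df, acc, if ("Gene" %in% names(df)) as.character(df$Gene) else
      rep(NA_character_, nrow(df)),
    df$`Modified Peptide`, modification, locate,
    quant_matrix_from(df, int_cols, samples))
  sites <- cross_check_residues(sites, sequences)
  finish_sites(sites, "msfragger")
}

#' Convert a Spectronaut PTM report
#'
#' Spectronaut reports the modified peptide without any protein-level
#' residue number, and combines all modification types in one file. The
#' stripped peptide is located in the protein by exact substring search;
#' when it occurs more than once the first occurrence is used and the record
#' is flagged `ambiguous`. Rows carry their modification type in
#' `EG.PTMType`, so the output can be split per modification.
#'
#' Expected columns: `PG.ProteinAccessions`, `EG.ModifiedPeptide`,
#' `EG.PTMType`, optional `PG.Genes`, and `Intensity <sample>` columns.
#'
#' @param path Tab-delimited report.
#' @param sequences A `sequence_set` containing each report accession.
#' @return A `ptm_sites` table (all modifications; use
#'   [split_by_modification()] for per-modification lists).
#' @export
convert_spectronaut <- function(path, sequences) {
  df <- read_tsv_file(path)
  require_columns(df, c("PG.ProteinAccessions", "EG.ModifiedPeptide",
                        "EG.PTMType"), path)
  int_cols <- grep(sprintf("^%s", INTENSITY_PREFIX), names(df), value = TRUE)
  samples <- sub(sprintf("^%s", INTENSITY_PREFIX), "", int_cols)
  acc <- as.character(df$PG.ProteinAccessions)
  stripped <- vapply(lapply(df$EG.ModifiedPeptide, parse_probability_string),
                     `[[`, character(1), "peptide")
  seqs <- unclass(sequences)[representative_accession(acc)]
  starts <- integer(nrow(df)); n_occ <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (is.na(seqs[i])) { starts[i] <- NA_integer_; next }
    occ <- gregexpr(stripped[i], seqs[i], fixed = TRUE)[[1]]
    if (occ[1] == -1) { starts[i] <- NA_integer_; n_occ[i] <- 0L }
    else { starts[i] <- occ[1]; n_occ[i] <- length(occ) }
  }
  locate <- function(row_idx) {
    list(start = starts[row_idx], ambiguous = n_occ[row_idx] > 1,
         found = !is.na(starts[row_idx]))
  }
  sites <- peptide_rows_to_sites(
    df, acc, if ("PG.Genes" %in% names(df)) as.character(df$PG.Genes) else
      rep(NA_character_, nrow(df)),
    df$EG.ModifiedPeptide, rep(as.character(df$EG.PTMType), 1), locate,
    quant_matrix_from(df, int_cols, samples))
  # modification is per-row, not constant: rebuild from the row expansion
  parsed_n <- vapply(lapply(df$EG.ModifiedPeptide, parse_probability_string),
                     function(p) nrow(p$annotations), integer(1))
  sites$modification <- rep(as.character(df$EG.PTMType), parsed_n)
  sites <- cross_check_residues(sites, sequences)
  finish_sites(sites, "spectronaut")
}

#' Split a harmonized site table into per-modification tables
#' @param sites A `ptm_sites` table.
#' @return Named list of `ptm_sites`, one per modification type.
#' @export
split_by_modification <- function(sites) {
  out <- split(as.data.frame(sites), sites$modification)
  lapply(out, function(d) { class(d) <- c("ptm_sites", "data.frame"); d })
}

#' Convert a DIA-NN PTM report pair
#'
#' DIA-NN writes quantification and site-probability information to
#' different files sharing a precursor key; they are merged here by inner
#' join on `Precursor.Id`. Keys present in only one file are excluded and
#' reported, never imputed; a key whose accession differs between the two
#' files is an error.
#'
#' Quantification file columns: `Precursor.Id`, `Protein.Group`, optional
#' `Genes`, `Intensity <sample>` columns. Probability file columns:
#' `Precursor.Id`, `Protein.Group`, `Modified.Sequence` (probability
#' annotated), `Peptide.Start`, `Modification`.
#'
#' @param quant_path Quantification report path.
#' @param prob_path Site-probability report path.
#' @param sequences Optional `sequence_set` for residue cross-checking.
#' @return A `ptm_sites` table; attribute `run_report` lists unmatched keys.
#' @export
convert_diann <- function(quant_path, prob_path, sequences = NULL) {
  q <- read_tsv_file(quant_path)
  p <- read_tsv_file(prob_path)
  require_columns(q, c("Precursor.Id", "Protein.Group"), quant_path)
  require_columns(p, c("Precursor.Id", "Protein.Group", "Modified.Sequence",
                       "Peptide.Start", "Modification"), prob_path)
  shared <- intersect(q$Precursor.Id, p$Precursor.Id)
  if (length(shared) == 0) {
    vn_data_error("no overlapping Precursor.Id keys between quantification and probability files")
  }
  qi <- match(shared, q$Precursor.Id)
  pi <- match(shared, p$Precursor.Id)
  if (any(as.character(q$Protein.Group[qi]) !=
          as.character(p$Protein.Group[pi]))) {
    bad <- shared[as.character(q$Protein.Group[qi]) !=
                    as.character(p$Protein.Group[pi])]
    vn_data_error(sprintf("conflicting accession between files for key(s): %s",
                          paste(utils::head(bad, 5), collapse = ", ")))
  }
  int_cols <- grep(sprintf("^%s", INTENSITY_PREFIX), names(q), value = TRUE)
  samples <- sub(sprintf("^%s", INTENSITY_PREFIX), "", int_cols)
  acc <- as.character(p$Protein.Group[pi])
  starts <- as.integer(p$Peptide.Start[pi])
  locate <- function(row_idx) {
    list(start = starts[row_idx], ambiguous = rep(FALSE, length(row_idx)),
         found = !is.na(starts[row_idx]))
  }
  mods <- as.character(p$Modification[pi])
  sites <- peptide_rows_to_sites(
    p[pi, , drop = FALSE], acc,
    if ("Genes" %in% names(q)) as.character(q$Genes[qi]) else
      rep(NA_character_, length(shared)),
    p$Modified.Sequence[pi], "", locate,
    quant_matrix_from(q[qi, , drop = FALSE], int_cols, samples))
  parsed_n <- vapply(lapply(p$Modified.Sequence[pi], parse_probability_string),
                     function(x) nrow(x$annotations), integer(1))
  sites$modification <- rep(mods, parsed_n)
  sites <- cross_check_residues(sites, sequences)
  sites <- finish_sites(sites, "diann")
  rep_q <- setdiff(q$Precursor.Id, shared)
  rep_p <- setdiff(p$Precursor.Id, shared)
  attr(sites, "run_report")$unmatched_quant_keys <- rep_q
  attr(sites, "run_report")$unmatched_prob_keys <- rep_p
  sites
}

#' Filter to class-I (high-confidence) sites
#'
#' Class-I sites are those whose localization probability strictly exceeds
#' the threshold, 0.75 by convention. A site with probability exactly at the
#' threshold is excluded.
#'
#' @param records A `ptm_sites` table.
#' @param threshold Localization-probability threshold (default 0.75).
#' @return The retained subset, same class.
#' @export
filter_class1 <- function(records, threshold = 0.75) {
  keep <- !is.na(records$localization_probability) &
    records$localization_probability > threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
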