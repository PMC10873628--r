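# Reading and writing the external tables: differential-analysis files,
# raw quantification matrices, FASTA sequence sets, custom PTM databases.
# Every reader is driven by an explicit column map or annotation; nothing is
# guessed from headers.

#' Column map for a differential-analysis table
#'
#' Declares which columns of a tab-delimited differential-analysis file hold
#' the feature identifier, fold change and significance, and on what scale
#' each is reported. Scales are declared, never inferred: a file produced by
#' Perseus typically carries log2 fold change and -log10 p, while other
#' pipelines export linear ratios and raw p-values.
#'
#' @param primary_id_col Name of the unique feature-identifier column.
#' @param fc_col Name of the fold-change column.
#' @param sig_col Name of the significance column. Must differ from `fc_col`.
#' @param fc_scale Either `"log2"` (values already log2 fold change) or
#'   `"linear"` (ratios, transformed to log2 on read).
#' @param sig_scale Either `"neglog10"` (already -log10) or `"raw_p"`
#'   (p-values, transformed to -log10 on read).
#' @param gene_col Optional gene-symbol column name.
#' @param comparison_label Free-text label of the comparison the file encodes.
#' @return An object of class `colmap`.
#' @export
#' @examples
#' column_map("Protein IDs", "Ratio", "p-value",
#'            fc_scale = "linear", sig_scale = "raw_p")
column_map <- function(primary_id_col, fc_col, sig_col,
                       fc_scale = c("log2", "linear"),
                       sig_scale = c("neglog10", "raw_p"),
                       gene_col = NULL,
                       comparison_label = "comparison 1") {
  fc_scale <- match.arg(fc_scale)
  sig_scale <- match.arg(sig_scale)
  for (arg in list(primary_id_col, fc_col, sig_col)) {
    if (!is.character(arg) || length(arg) != 1 || is.na(arg) || !nzchar(arg)) {
      vn_config_error("column names must be single non-empty strings")
    }
  }
  if (identical(fc_col, sig_col)) {
    vn_config_error("fc_col and sig_col must name different columns")
  }
  structure(
    list(primary_id_col = primary_id_col, gene_col = gene_col,
         fc_col = fc_col, fc_scale = fc_scale,
         sig_col = sig_col, sig_scale = sig_scale,
         comparison_label = comparison_label),
    class = "colmap")
}

#' Per-sample annotation of a quantification matrix
#'
#' @param sample_name Column names of the quantified samples, as they appear
#'   in the search-output file.
#' @param condition Experimental condition of each sample.
#' @param replicate Positive integer replicate index within condition.
#' @param display_order Integer order in which samples are shown; defaults to
#'   input order.
#' @return A `sample_annotation` data frame, one row per sample.
#' @export
sample_annotation <- function(sample_name, condition, replicate,
                              display_order = seq_along(sample_name)) {
  n <- length(sample_name)
  if (length(condition) != n || length(replicate) != n ||
      length(display_order) != n) {
    vn_config_error("sample_name, condition, replicate, display_order must have equal length")
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    vn_config_error("replicate indices must be positive integers")
  }
  if (anyDuplicated(sample_name)) {
    vn_config_error("duplicate sample_name in annotation")
  }
  key <- paste(condition, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    vn_config_error("(condition, replicate) pairs must be unique")
  }
  structure(
    data.frame(sample_name = as.character(sample_name),
               condition = as.character(condition),
               replicate = replicate,
               display_order = as.integer(display_order),
               stringsAsFactors = FALSE),
    class = c("sample_annotation", "data.frame"))
}

#' Project metadata in PRIDE-style fields
#'
#' Free-text experiment description carried verbatim into the session
#' document, mirroring the fields a PRIDE submission asks for.
#'
#' @param title,description,sample_processing_protocol,
#'   data_processing_protocol,instrument,authors Free text.
#' @return An object of class `project_metadata`.
#' @export
project_metadata <- function(title = "", description = "",
                             sample_processing_protocol = "",
                             data_processing_protocol = "",
                             instrument = "", authors = "") {
  structure(
    list(title = title, description = description,
         sample_processing_protocol = sample_processing_protocol,
         data_processing_protocol = data_processing_protocol,
         instrument = instrument, authors = authors),
    class = "project_metadata")
}

#' Read a differential-analysis table into volcano space
#'
#' Reads a tab-delimited differential-analysis file (e.g. a Perseus or
#' MSstats export) and transforms it to plot space: fold change to log2 and
#' significance to -log10, according to the scales declared in the column
#' map. Rows whose transform input cannot produce a finite value — a
#' non-positive ratio under a linear scale, a p-value outside (0, 1] under a
#' raw-p scale, or an unparseable number — are dropped, not clamped, and
#' counted in the attached drop report.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param map A [column_map()] naming the id, fold-change and significance
#'   columns and their scales.
#' @return A `diff_table` data frame with columns `primary_id`, `gene`,
#'   `log2_fc`, `neglog10_sig`, `comparison`, and attribute `drop_report`
#'   (list with `n_source`, `n_kept`, `n_dropped`, `dropped_ids`).
#' @export
read_differential <- function(path, map) {
  if (!inherits(map, "colmap")) vn_config_error("map must be a column_map()")
  df <- read_tsv_file(path)
  needed <- c(map$primary_id_col, map$fc_col, map$sig_col, map$gene_col)
  require_columns(df, needed, path)

  id <- as.character(df[[map$primary_id_col]])
  gene <- if (is.null(map$gene_col)) rep(NA_character_, nrow(df)) else
    as.character(df[[map$gene_col]])
  fc <- suppressWarnings(as.numeric(df[[map$fc_col]]))
  sig <- suppressWarnings(as.numeric(df[[map$sig_col]]))

  log2_fc <- if (map$fc_scale == "linear") {
    out <- rep(NA_real_, length(fc))
    ok <- !is.na(fc) & fc > 0
    out[ok] <- log2(fc[ok])
    out
  } else fc
  neglog10_sig <- if (map$sig_scale == "raw_p") {
    out <- rep(NA_real_, length(sig))
    ok <- !is.na(sig) & sig > 0
    out[ok] <- -log10(sig[ok])
    out
  } else sig

  keep <- is.finite(log2_fc) & is.finite(neglog10_sig) & neglog10_sig >= 0 &
    !is.na(id) & nzchar(id)
  out <- data.frame(primary_id = id[keep], gene = gene[keep],
                    log2_fc = log2_fc[keep], neglog10_sig = neglog10_sig[keep],
                    comparison = map$comparison_label,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$primary_id)) {
    vn_data_error(sprintf("duplicate primary ids in '%s' within comparison '%s'",
                          path, map$comparison_label))
  }
  attr(out, "drop_report") <- list(
    n_source = nrow(df), n_kept = nrow(out),
    n_dropped = nrow(df) - nrow(out),
    dropped_ids = id[!keep])
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Read a raw quantification matrix
#'
#' Assembles the feature-by-sample intensity matrix from a search-output
#' table. Intensities of exactly zero are converted to missing — the
#' convention of MaxQuant-style outputs, where zero encodes "not detected",
#' and a necessary step before any log transform or correlation. Duplicate
#' feature ids keep the first occurrence with a warning.
#'
#' @param path Tab-delimited search-output file.
#' @param id_col Name of the feature-identifier column.
#' @param annotation A [sample_annotation()]; every `sample_name` must be a
#'   column of the file. Columns are ordered by `display_order`.
#' @return A `raw_quant` object: list with `feature_ids`, `samples`
#'   (the annotation, ordered), and `intensities` (numeric matrix,
#'   features x samples, `NA` for missing).
#' @export
read_raw <- function(path, id_col, annotation) {
  if (!inherits(annotation, "sample_annotation")) {
    vn_config_error("annotation must be a sample_annotation()")
  }
  df <- read_tsv_file(path)
  require_columns(df, c(id_col, annotation$sample_name), path)

  ids <- as.character(df[[id_col]])
  dup <- duplicated(ids)
  if (any(dup)) {
    warning(sprintf("%d duplicate feature id(s) in '%s'; keeping first occurrence (%s)",
                    sum(dup), path,
                    paste(utils::head(unique(ids[dup]), 5), collapse = ", ")))
    df <- df[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  ann <- annotation[order(annotation$display_order), , drop = FALSE]
  rownames(ann) <- NULL
  m <- as.matrix(df[, ann$sample_name, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) {
    vn_data_error(sprintf("negative intensities in '%s'", path))
  }
  m[!is.na(m) & m == 0] <- NA_real_
  dimnames(m) <- list(ids, ann$sample_name)
  new_raw_quant(ids, ann, m)
}

new_raw_quant <- function(feature_ids, samples, intensities) {
  stopifnot(nrow(intensities) == length(feature_ids),
            ncol(intensities) == nrow(samples))
  structure(list(feature_ids = feature_ids, samples = samples,
                 intensities = intensities),
            class = "raw_quant")
}

#' @export
print.raw_quant <- function(x, ...) {
  cat(sprintf("raw_quant: %d features x %d samples (%d conditions), %.1f%% missing\n",
              length(x$feature_ids), nrow(x$samples),
              length(unique(x$samples$condition)),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Write a raw quantification matrix to tab-delimited text
#'
#' Inverse of [read_raw()] for matrices without missing values; missing
#' entries are written as empty cells.
#'
#' @param x A `raw_quant` object.
#' @param path Output path.
#' @param id_col Header of the identifier column.
#' @return The path, invisibly.
#' @export
write_raw <- function(x, path, id_col = "Protein IDs") {
  df <- data.frame(x$feature_ids, x$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, x$samples$sample_name)
  write_tsv_file(df, path)
}

#' Read a FASTA file into a sequence set
#'
#' Accessions are the first whitespace-delimited token of each header, with
#' UniProt `db|ACC|name` headers reduced to the accession. Sequences are
#' uppercased and validated against the amino-acid alphabet (20 standard
#' residues plus X/U/B/Z).
#'
#' @param path FASTA file path.
#' @return A named character vector (accession -> sequence) of class
#'   `sequence_set`.
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) vn_data_error(
                     sprintf("cannot read FASTA '%s': %s", path,
                             conditionMessage(e))))
  if (length(seqs) == 0) vn_data_error(sprintf("no records in FASTA '%s'", path))
  acc <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, character(1), 1)
  bar <- grepl("^[A-Za-z]+\\|[^|]+\\|", acc)
  acc[bar] <- vapply(strsplit(acc[bar], "|", fixed = TRUE), `[[`,
                     character(1), 2)
  if (any(!nzchar(acc))) vn_data_error("malformed FASTA header (empty accession)")
  if (anyDuplicated(acc)) {
    vn_data_error(sprintf("duplicate accession(s) in '%s': %s", path,
                          paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  s <- toupper(as.character(seqs))
  if (any(!nzchar(s))) vn_data_error("empty sequence in FASTA")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALLOWED, collapse = "")), s)
  if (any(bad)) {
    vn_data_error(sprintf("sequence for %s contains non-amino-acid characters",
                          paste(acc[bad], collapse = ", ")))
  }
  names(s) <- acc
  class(s) <- "sequence_set"
  s
}

#' Construct a sequence set from named sequences
#'
#' @param x Named character vector of amino-acid sequences.
#' @return A `sequence_set`.
#' @export
sequence_set <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    vn_config_error("sequences must be named by accession")
  }
  if (anyDuplicated(names(x))) vn_config_error("duplicate accessions")
  s <- toupper(as.character(x))
  if (any(!nzchar(s))) vn_config_error("empty sequence")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALLOWED, collapse = "")), s)
  if (any(bad)) vn_config_error("sequence contains non-amino-acid characters")
  names(s) <- names(x)
  class(s) <- "sequence_set"
  s
}

#' Write a sequence set to FASTA
#' @param x A `sequence_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(c(paste0(">", names(x)[i]), unclass(x)[[i]]), con)
  }
  invisible(path)
}

#' Read a custom PTM database from tabulated text
#'
#' The expected dialect is a tab-delimited file with header columns
#' `accession`, `position`, `residue`, `modification`; positions are 1-based
#' residue numbers in the canonical sequence. This is the import path for
#' any reference PTM resource (PhosphoSitePlus exports, PLMD, a custom
#' citrullination table, ...) reduced to that four-column form.
#'
#' @param path Tab-delimited file path.
#' @param source_name Name under which the database is reported.
#' @return A `ptm_database`: list with `source_name` and `entries`
#'   (data frame accession/position/residue/modification).
#' @export
read_custom_ptm_db <- function(path, source_name) {
  df <- tryCatch(read_tsv_file(path), volcanaut_data_error = function(e) {
    # a headed but row-less file is a valid, empty database
    if (grepl("empty file", conditionMessage(e))) NULL else stop(e)
  })
  if (is.null(df)) vn_data_error(sprintf("empty file: '%s'", path))
  require_columns(df, c("accession", "position", "residue", "modification"),
                  path)
  ptm_database(source_name,
               accession = as.character(df$accession),
               position = df$position,
               residue = as.character(df$residue),
               modification = as.character(df$modification))
}

#' Construct a PTM database in code
#'
#' @param source_name Database name.
#' @param accession,position,residue,modification Parallel entry vectors;
#'   positions 1-based, residues single uppercase letters.
#' @return A `ptm_database`.
#' @export
ptm_database <- function(source_name, accession = character(),
                         position = integer(), residue = character(),
                         modification = character()) {
  pos_num <- suppressWarnings(as.numeric(position))
  if (any(is.na(pos_num)) && length(position) > 0) {
    vn_data_error("non-numeric PTM database position")
  }
  if (length(pos_num) > 0 && any(pos_num != floor(pos_num))) {
    vn_data_error("PTM database positions must be integers")
  }
  pos <- as.integer(pos_num)
  if (any(pos < 1)) vn_data_error("PTM database positions are 1-based (>= 1)")
  residue <- toupper(as.character(residue))
  if (length(residue) > 0 && any(!grepl("^[A-Z]$", residue))) {
    vn_data_error("PTM database residues must be single letters")
  }
  entries <- data.frame(accession = as.character(accession), position = pos,
                        residue = residue,
                        modification = as.character(modification),
                        stringsAsFactors = FALSE)
  structure(list(source_name = source_name, entries = entries),
            class = "ptm_database")
}

#' @export
print.ptm_database <- function(x, ...) {
  cat(sprintf("ptm_database '%s': %d entries on %d protein(s)\n",
              x$source_name, nrow(x$entries),
              length(unique(x$entries$accession))))
  invisible(x)
}
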