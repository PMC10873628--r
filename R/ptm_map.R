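# Remapping experimental PTM residue numbers onto canonical isoform
# numbering via global sequence alignment, comparison against reference PTM
# databases, and motif-window extraction.

# Substitution matrices are cached per session.
.align_env <- new.env(parent = emptyenv())

get_substitution_matrix <- function(substitution) {
  if (is.character(substitution) && length(substitution) == 1) {
    key <- substitution
    if (!is.null(.align_env[[key]])) return(.align_env[[key]])
    ok <- substitution %in% c("BLOSUM45", "BLOSUM50", "BLOSUM62",
                              "BLOSUM80", "BLOSUM100", "PAM30", "PAM40",
                              "PAM70", "PAM120", "PAM250")
    if (!ok) vn_config_error(sprintf("unknown substitution matrix '%s'",
                                     substitution))
    e <- new.env()
    utils::data(list = substitution, package = "Biostrings", envir = e)
    m <- e[[substitution]]
    .align_env[[key]] <- m
    return(m)
  }
  if (is.numeric(substitution) && all(c("match", "mismatch") %in%
                                      names(substitution))) {
    letters20 <- AA_ALLOWED
    m <- matrix(substitution[["mismatch"]], length(letters20),
                length(letters20), dimnames = list(letters20, letters20))
    diag(m) <- substitution[["match"]]
    return(m)
  }
  vn_config_error("substitution must be a matrix name or c(match=, mismatch=)")
}

#' Alignment parameters for isoform remapping
#'
#' Global (end-to-end) pairwise alignment is used to reconcile splice-variant
#' numbering: exactly two sequences — the experimental isoform and the
#' canonical isoform — are compared, so a pairwise global alignment is the
#' appropriate tool. Defaults are BLOSUM62 with affine gap penalties of -10
#' (open) and -0.5 (per extended residue); a gap of length L scores
#' `gap_open + L * gap_extend`.
#'
#' @param substitution A standard amino-acid matrix name (e.g. `"BLOSUM62"`)
#'   or `c(match = , mismatch = )` for a simple scheme.
#' @param gap_open,gap_extend Gap penalties, in score convention (<= 0).
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(substitution = "BLOSUM62", gap_open = -10,
                             gap_extend = -0.5) {
  if (gap_open > 0 || gap_extend > 0) {
    vn_config_error("gap penalties must be <= 0 in score convention")
  }
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend), mode = "global"),
            class = "alignment_params")
}

seq_to_indices <- function(s, sub) {
  letters_ <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(letters_, rownames(sub))
  # residues absent from the matrix (e.g. selenocysteine U) score as X
  idx[is.na(idx)] <- match("X", rownames(sub))
  idx - 1L
}

#' Globally align an experimental isoform to a canonical sequence
#'
#' Computes the optimal global (Needleman-Wunsch, affine-gap) alignment of
#' the experimental protein sequence against the canonical isoform and
#' returns the position-to-position correspondence used to renumber PTM
#' sites. Identical sequences short-circuit to the identity map. Traceback
#' ties are broken deterministically (diagonal over up over left), so the
#' same input always yields the same mapping.
#'
#' @param exp_seq Experimental (search-database) protein sequence.
#' @param canonical_seq Canonical isoform sequence.
#' @param params An [alignment_params()].
#' @return An `alignment_map`: list with `exp_to_canonical` (integer vector,
#'   one entry per experimental residue, `NA` where the residue aligns to a
#'   gap), `canonical_to_exp`, `aligned_exp`/`aligned_canonical` (gapped
#'   strings), `score`, and `identity` (identical aligned pairs / alignment
#'   length).
#' @export
align_isoforms <- function(exp_seq, canonical_seq,
                           params = alignment_params()) {
  exp_seq <- toupper(as.character(exp_seq))
  canonical_seq <- toupper(as.character(canonical_seq))
  if (!nzchar(exp_seq) || !nzchar(canonical_seq)) {
    vn_data_error("sequences must be non-empty")
  }
  n <- nchar(exp_seq); m <- nchar(canonical_seq)
  if (identical(exp_seq, canonical_seq)) {
    sub <- get_substitution_matrix(params$substitution)
    idx <- seq_to_indices(exp_seq, sub) + 1L
    return(structure(list(
      exp_to_canonical = seq_len(n), canonical_to_exp = seq_len(n),
      aligned_exp = exp_seq, aligned_canonical = canonical_seq,
      score = sum(sub[cbind(idx, idx)]), identity = 1.0, exp_seq = exp_seq,
      canonical_seq = canonical_seq, params = params),
      class = "alignment_map"))
  }
  sub <- get_substitution_matrix(params$substitution)
  res <- nw_align(seq_to_indices(exp_seq, sub),
                  seq_to_indices(canonical_seq, sub),
                  sub, params$gap_open, params$gap_extend)
  ai <- res$a_index; bi <- res$b_index
  e2c <- rep(NA_integer_, n)
  both <- ai > 0 & bi > 0
  e2c[ai[both]] <- bi[both]
  c2e <- rep(NA_integer_, m)
  c2e[bi[both]] <- ai[both]
  ea <- strsplit(exp_seq, "")[[1]]
  ca <- strsplit(canonical_seq, "")[[1]]
  col_e <- ifelse(ai > 0, ea[pmax(ai, 1)], "-")
  col_c <- ifelse(bi > 0, ca[pmax(bi, 1)], "-")
  identity <- sum(both & col_e == col_c) / length(ai)
  structure(list(
    exp_to_canonical = e2c, canonical_to_exp = c2e,
    aligned_exp = paste(col_e, collapse = ""),
    aligned_canonical = paste(col_c, collapse = ""),
    score = res$score, identity = identity,
    exp_seq = exp_seq, canonical_seq = canonical_seq, params = params),
    class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map: %d -> %d residues, %.1f%% identity, score %s\n",
              nchar(x$exp_seq), nchar(x$canonical_seq), 100 * x$identity,
              format(x$score)))
  invisible(x)
}

#' Remap an experimental residue position to canonical numbering
#'
#' @param map An `alignment_map` from [align_isoforms()].
#' @param exp_position 1-based position(s) in the experimental sequence.
#' @return Data frame with one row per queried position: `exp_position`,
#'   `canonical_position` (`NA` when the residue aligns to a gap, i.e.
#'   unaligned), `exp_residue`, `canonical_residue` (`NA` when unaligned),
#'   and `unaligned`.
#' @export
remap_site <- function(map, exp_position) {
  exp_position <- as.integer(exp_position)
  n <- nchar(map$exp_seq)
  if (any(is.na(exp_position)) || any(exp_position < 1) ||
      any(exp_position > n)) {
    vn_data_error(sprintf("position out of range 1..%d", n))
  }
  canon <- map$exp_to_canonical[exp_position]
  data.frame(
    exp_position = exp_position,
    canonical_position = canon,
    exp_residue = substring(map$exp_seq, exp_position, exp_position),
    canonical_residue = ifelse(is.na(canon), NA_character_,
                               substring(map$canonical_seq, canon, canon)),
    unaligned = is.na(canon),
    stringsAsFactors = FALSE)
}

SITE_CLASSES <- c("BOTH", "EXPERIMENT_ONLY", "DATABASE_ONLY", "SELECTED")

#' Compare experimental PTM sites with reference databases
#'
#' Classifies every canonical residue position carrying a PTM — either
#' observed experimentally (after remapping) or listed in a selected
#' reference database — into one of four display classes: `BOTH`
#' (experimental site coinciding in position and modification type with a
#' database entry), `EXPERIMENT_ONLY`, `DATABASE_ONLY`, or `SELECTED`
#' (the user's currently selected site, which overrides the other classes
#' while retaining the database-presence record). Sites whose differential
#' class is `S_C` carry `significant_flag`, independent of the display
#' class. A position matched in the database whose residue letter differs
#' from the experimental residue is demoted from `BOTH` to
#' `EXPERIMENT_ONLY` with `residue_conflict` set.
#'
#' @param experimental Data frame of remapped experimental sites with
#'   columns `accession`, `position` (canonical numbering), `residue`,
#'   `modification`, optional `experimental_position` (pre-remap numbering,
#'   retained in the output) and optional `sig_class` (a significance class
#'   as produced by [classify()]).
#' @param databases List of `ptm_database` objects.
#' @param selected Optional data frame `accession`/`position` of the
#'   currently selected site(s).
#' @return A `site_comparison` data frame: one row per (accession,
#'   canonical position) with `class`, `significant_flag`, `db_sources`,
#'   `experimental_position`, `residue_conflict`.
#' @export
compare_sites <- function(experimental, databases = list(), selected = NULL) {
  stopifnot(is.data.frame(experimental))
  need <- c("accession", "position", "residue", "modification")
  if (!all(need %in% names(experimental))) {
    vn_config_error(sprintf("experimental sites need columns: %s",
                            paste(need, collapse = ", ")))
  }
  exp_df <- experimental
  if (!"experimental_position" %in% names(exp_df)) {
    exp_df$experimental_position <- exp_df$position
  }
  if (!"sig_class" %in% names(exp_df)) exp_df$sig_class <- NA_character_

  db_all <- do.call(rbind, lapply(databases, function(d) {
    if (nrow(d$entries) == 0) return(NULL)
    cbind(d$entries, source = d$source_name, stringsAsFactors = FALSE)
  }))
  if (is.null(db_all)) {
    db_all <- data.frame(accession = character(), position = integer(),
                         residue = character(), modification = character(),
                         source = character(), stringsAsFactors = FALSE)
  }

  keys <- unique(rbind(
    exp_df[!is.na(exp_df$position), c("accession", "position")],
    db_all[, c("accession", "position")]))
  keys <- keys[order(keys$accession, keys$position), , drop = FALSE]
  rownames(keys) <- NULL

  out <- keys
  out$class <- NA_character_
  out$significant_flag <- FALSE
  out$db_sources <- ""
  out$experimental_position <- NA_integer_
  out$residue_conflict <- FALSE
  for (k in seq_len(nrow(keys))) {
    acc <- keys$accession[k]; pos <- keys$position[k]
    ei <- which(exp_df$accession == acc & !is.na(exp_df$position) &
                  exp_df$position == pos)
    di <- which(db_all$accession == acc & db_all$position == pos)
    in_exp <- length(ei) > 0
    coincide <- FALSE
    conflict <- FALSE
    srcs <- character()
    if (length(di) > 0) {
      srcs <- unique(db_all$source[di])
      if (in_exp) {
        mod_match <- db_all$modification[di] %in% exp_df$modification[ei]
        res_match <- db_all$residue[di] %in% exp_df$residue[ei]
        coincide <- any(mod_match & res_match)
        conflict <- any(mod_match) && !coincide
      }
    }
    out$class[k] <- if (in_exp && coincide) "BOTH"
      else if (in_exp) "EXPERIMENT_ONLY"
      else "DATABASE_ONLY"
    out$residue_conflict[k] <- conflict
    out$db_sources[k] <- paste(srcs, collapse = ";")
    if (in_exp) {
      out$experimental_position[k] <- exp_df$experimental_position[ei[1]]
      out$significant_flag[k] <- any(exp_df$sig_class[ei] %in% "S_C")
    }
  }
  if (!is.null(selected) && nrow(selected) > 0) {
    sel_key <- paste(selected$accession, selected$position)
    hit <- paste(out$accession, out$position) %in% sel_key
    out$class[hit] <- "SELECTED"
  }
  out$class <- factor(out$class, levels = SITE_CLASSES)
  class(out) <- c("site_comparison", "data.frame")
  out
}

#' Extract the sequence window around a site
#'
#' Returns the `2 * halfwidth + 1` residues centered on a site, padded with
#' `"_"` beyond the sequence ends — the 15-mer convention (halfwidth 7) of
#' kinase-substrate resources and sequence-logo tools.
#'
#' @param seq Protein sequence.
#' @param position 1-based site position(s).
#' @param halfwidth Residues on each side of the site.
#' @param pad Padding character for positions beyond the sequence ends.
#' @return Character vector of windows, each of length `2 * halfwidth + 1`.
#' @export
#' @examples
#' extract_window("ABCDEFG", 4, halfwidth = 2)
extract_window <- function(seq, position, halfwidth = 7, pad = "_") {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1) || any(position > n)) {
    vn_data_error(sprintf("position out of range 1..%d", n))
  }
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 0) vn_config_error("halfwidth must be >= 0")
  vapply(position, function(p) {
    lo <- p - halfwidth; hi <- p + halfwidth
    core <- substring(seq, max(lo, 1), min(hi, n))
    paste0(strrep(pad, max(0, 1 - lo)), core, strrep(pad, max(0, hi - n)))
  }, character(1))
}

#' Position frequency matrix of motif windows
#'
#' Counts residues per window column for sequence-logo rendering: a
#' 21-row matrix (the 20 standard residues plus the padding character) by
#' window-length columns, every column summing to the number of windows.
#'
#' @param windows Character vector of equal-length windows (e.g. from
#'   [extract_window()]).
#' @param pad Padding character counted in its own row.
#' @return Integer count matrix, 21 x window length.
#' @export
position_frequency_matrix <- function(windows, pad = "_") {
  if (length(windows) == 0) vn_config_error("no windows given")
  w <- unique(nchar(windows))
  if (length(w) != 1) vn_data_error("windows have mixed lengths")
  rows <- c(AA_STANDARD, pad)
  mat <- matrix(0L, nrow = length(rows), ncol = w,
                dimnames = list(rows, seq_len(w)))
  chars <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  chars[chars == toupper(pad)] <- pad
  unknown <- setdiff(unique(as.vector(chars)), rows)
  if (length(unknown) > 0) {
    vn_data_error(sprintf("windows contain non-standard residue(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, j], levels = rows))
    mat[, j] <- as.integer(tab)
  }
  mat
}
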