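# Persistence of the complete analysis state as a versioned JSON document.
# The contract is exact round-tripping: load(save(state)) reproduces the
# state value-for-value, and fields this version does not know about are
# carried through untouched.

SESSION_SCHEMA_VERSION <- "1.0"
SUPPORTED_SCHEMA_VERSIONS <- c("1.0")

# Top-level document fields owned by this schema version; anything else in
# a loaded document is preserved verbatim in state$extras.
SESSION_KNOWN_FIELDS <- c("schema_version", "session_id", "metadata",
                          "colmap", "annotations", "cutoffs", "selections",
                          "style", "data")

#' Assemble a full analysis state
#'
#' Bundles everything a shared analysis needs to be reopened: experiment
#' metadata, the column map used at import, sample annotations, cutoffs,
#' selection sets, plot style, and the data payloads themselves. Payloads
#' are embedded in the session document, so a saved session is fully
#' self-contained.
#'
#' @param metadata A [project_metadata()].
#' @param colmap A [column_map()] or `NULL`.
#' @param annotations A [sample_annotation()] or `NULL`.
#' @param cutoffs A [cutoff_config()].
#' @param selections List of [selection_set()] objects.
#' @param style A [style_options()].
#' @param diff A `diff_table` or `NULL`.
#' @param raw A `raw_quant` or `NULL`.
#' @param sites A `ptm_sites` table or `NULL`.
#' @param extras Named list of additional fields carried verbatim.
#' @return A `session_state`.
#' @export
session_state <- function(metadata = project_metadata(), colmap = NULL,
                          annotations = NULL, cutoffs = cutoff_config(),
                          selections = list(), style = style_options(),
                          diff = NULL, raw = NULL, sites = NULL,
                          extras = list()) {
  structure(list(metadata = metadata, colmap = colmap,
                 annotations = annotations, cutoffs = cutoffs,
                 selections = selections, style = style, diff = diff,
                 raw = raw, sites = sites, extras = extras),
            class = "session_state")
}

chr0 <- function(x) as.character(unlist(x) %||% character(0))
num0 <- function(x) as.numeric(unlist(x) %||% numeric(0))
int0 <- function(x) as.integer(unlist(x) %||% integer(0))
lgl0 <- function(x) as.logical(unlist(x) %||% logical(0))
`%||%` <- function(a, b) if (is.null(a)) b else a

matrix_to_doc <- function(m) {
  if (is.null(m)) return(NULL)
  list(dim = dim(m), values = as.numeric(t(m)),
       colnames = colnames(m) %||% character(0))
}

matrix_from_doc <- function(d, rownames_ = NULL) {
  if (is.null(d)) return(NULL)
  dm <- int0(d$dim)
  m <- matrix(num0(d$values), nrow = dm[1], ncol = dm[2], byrow = TRUE)
  cn <- chr0(d$colnames)
  dimnames(m) <- list(rownames_, if (length(cn)) cn else NULL)
  m
}

diff_to_doc <- function(d) {
  if (is.null(d)) return(NULL)
  rep <- attr(d, "drop_report")
  list(primary_id = d$primary_id, gene = d$gene, log2_fc = d$log2_fc,
       neglog10_sig = d$neglog10_sig, comparison = d$comparison,
       drop_report = if (is.null(rep)) NULL else
         list(n_source = rep$n_source, n_kept = rep$n_kept,
              n_dropped = rep$n_dropped,
              dropped_ids = as.character(rep$dropped_ids)))
}

diff_from_doc <- function(d) {
  if (is.null(d)) return(NULL)
  out <- data.frame(primary_id = chr0(d$primary_id), gene = chr0(d$gene),
                    log2_fc = num0(d$log2_fc),
                    neglog10_sig = num0(d$neglog10_sig),
                    comparison = chr0(d$comparison),
                    stringsAsFactors = FALSE)
  if (!is.null(d$drop_report)) {
    attr(out, "drop_report") <- list(
      n_source = int0(d$drop_report$n_source),
      n_kept = int0(d$drop_report$n_kept),
      n_dropped = int0(d$drop_report$n_dropped),
      dropped_ids = chr0(d$drop_report$dropped_ids))
  }
  class(out) <- c("diff_table", "data.frame")
  out
}

annotations_from_doc <- function(d) {
  if (is.null(d)) return(NULL)
  sample_annotation(chr0(d$sample_name), chr0(d$condition),
                    int0(d$replicate), int0(d$display_order))
}

raw_to_doc <- function(r) {
  if (is.null(r)) return(NULL)
  list(feature_ids = r$feature_ids,
       samples = as.list(as.data.frame(r$samples)),
       intensities = matrix_to_doc(r$intensities))
}

raw_from_doc <- function(d) {
  if (is.null(d)) return(NULL)
  ann <- annotations_from_doc(d$samples)
  ids <- chr0(d$feature_ids)
  m <- matrix_from_doc(d$intensities, rownames_ = ids)
  new_raw_quant(ids, ann, m)
}

sites_to_doc <- function(s) {
  if (is.null(s)) return(NULL)
  q <- if ("quant" %in% names(s)) s$quant else NULL
  rep <- attr(s, "run_report")
  list(accession = s$accession, gene = s$gene, peptide = s$peptide,
       position_in_peptide = s$position_in_peptide,
       position_in_protein = s$position_in_protein, residue = s$residue,
       localization_probability = s$localization_probability,
       modification = s$modification, ambiguous = s$ambiguous,
       valid = s$valid, quant = matrix_to_doc(q),
       run_report = if (is.null(rep)) NULL else list(
         source = rep$source, n_records = rep$n_records,
         n_invalid = rep$n_invalid, n_ambiguous = rep$n_ambiguous,
         unmatched_quant_keys = rep$unmatched_quant_keys,
         unmatched_prob_keys = rep$unmatched_prob_keys))
}

sites_from_doc <- function(d) {
  if (is.null(d)) return(NULL)
  out <- ptm_sites(
    accession = chr0(d$accession), gene = chr0(d$gene),
    peptide = chr0(d$peptide),
    position_in_peptide = int0(d$position_in_peptide),
    position_in_protein = int0(d$position_in_protein),
    residue = chr0(d$residue),
    localization_probability = num0(d$localization_probability),
    modification = chr0(d$modification),
    quant = matrix_from_doc(d$quant),
    ambiguous = lgl0(d$ambiguous), valid = lgl0(d$valid))
  out$valid <- lgl0(d$valid)  # constructor re-checks; stored flags win
  if (!is.null(d$run_report)) {
    rep <- list(source = chr0(d$run_report$source),
                n_records = int0(d$run_report$n_records),
                n_invalid = int0(d$run_report$n_invalid),
                n_ambiguous = int0(d$run_report$n_ambiguous))
    if (!is.null(d$run_report$unmatched_quant_keys)) {
      rep$unmatched_quant_keys <- chr0(d$run_report$unmatched_quant_keys)
      rep$unmatched_prob_keys <- chr0(d$run_report$unmatched_prob_keys)
    }
    attr(out, "run_report") <- rep
  }
  out
}

colmap_from_doc <- function(d) {
  if (is.null(d)) return(NULL)
  column_map(d$primary_id_col, d$fc_col, d$sig_col, d$fc_scale, d$sig_scale,
             gene_col = d$gene_col, comparison_label = d$comparison_label)
}

style_from_doc <- function(d) {
  style_options(palette = d$palette, fade_alpha = num0(d$fade_alpha),
                point_size = num0(d$point_size),
                font_size = num0(d$font_size),
                x_limits = if (is.null(d$x_limits)) NULL else num0(d$x_limits),
                y_limits = if (is.null(d$y_limits)) NULL else num0(d$y_limits))
}

#' Save an analysis state as a session document
#'
#' Serializes the full state into a versioned JSON document carrying a
#' freshly generated unique session id (UUID4). Field order is fixed, and no
#' clock-dependent values are written, so two saves of the same state yield
#' identical documents except for the session id — convenient for diffing
#' shared sessions. Numeric values are written at full precision so the
#' round trip is exact.
#'
#' @param state A [session_state()].
#' @param path Optional output path for the JSON file.
#' @return The session document (named list), invisibly if written to file.
#' @export
save_session <- function(state, path = NULL) {
  if (!inherits(state, "session_state")) {
    vn_config_error("state must be a session_state()")
  }
  doc <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    session_id = uuid4(),
    metadata = unclass(state$metadata),
    colmap = if (is.null(state$colmap)) NULL else unclass(state$colmap),
    annotations = if (is.null(state$annotations)) NULL else
      as.list(as.data.frame(state$annotations)),
    cutoffs = unclass(state$cutoffs),
    selections = lapply(state$selections, function(s)
      list(name = s$name, member_ids = as.character(s$member_ids),
           color = s$color)),
    style = unclass(state$style),
    data = list(differential = diff_to_doc(state$diff),
                raw = raw_to_doc(state$raw),
                ptm_sites = sites_to_doc(state$sites)))
  extras <- state$extras
  if (length(extras) > 0) {
    clash <- intersect(names(extras), names(doc))
    if (length(clash) > 0) {
      vn_config_error(sprintf("extras may not shadow schema fields: %s",
                              paste(clash, collapse = ", ")))
    }
    doc <- c(doc, extras)
  }
  if (!is.null(path)) {
    json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                             null = "null", na = "null", pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Load a session document back into an analysis state
#'
#' Refuses documents with an unsupported `schema_version` rather than
#' attempting a partial load: a silently half-loaded shared session is worse
#' than an explicit failure. Unknown top-level fields are kept in
#' `state$extras` and written back verbatim on the next save.
#'
#' @param x Path to a session JSON file, or an already-parsed document list.
#' @return A `session_state`.
#' @export
load_session <- function(x) {
  doc <- if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) vn_data_error(sprintf("file not found: '%s'", x))
    tryCatch(
      jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                         simplifyMatrix = FALSE),
      error = function(e) vn_data_error(
        sprintf("malformed session JSON '%s': %s", x, conditionMessage(e))))
  } else if (is.list(x)) x else {
    vn_config_error("x must be a file path or a parsed document")
  }
  ver <- doc$schema_version
  if (is.null(ver)) vn_data_error("document has no schema_version")
  if (!ver %in% SUPPORTED_SCHEMA_VERSIONS) {
    vn_data_error(sprintf(
      "unsupported session schema version '%s' (supported: %s); refusing to load",
      ver, paste(SUPPORTED_SCHEMA_VERSIONS, collapse = ", ")))
  }
  md <- doc$metadata
  state <- session_state(
    metadata = project_metadata(
      title = md$title %||% "", description = md$description %||% "",
      sample_processing_protocol = md$sample_processing_protocol %||% "",
      data_processing_protocol = md$data_processing_protocol %||% "",
      instrument = md$instrument %||% "", authors = md$authors %||% ""),
    colmap = colmap_from_doc(doc$colmap),
    annotations = annotations_from_doc(doc$annotations),
    cutoffs = cutoff_config(num0(doc$cutoffs$fc_cutoff),
                            num0(doc$cutoffs$sig_cutoff)),
    selections = lapply(doc$selections, function(s)
      selection_set(s$name, chr0(s$member_ids), s$color)),
    style = style_from_doc(doc$style),
    diff = diff_from_doc(doc$data$differential),
    raw = raw_from_doc(doc$data$raw),
    sites = sites_from_doc(doc$data$ptm_sites),
    extras = {
      ex <- doc[setdiff(names(doc), SESSION_KNOWN_FIELDS)]
      if (length(ex) == 0) list() else ex
    })
  attr(state, "session_id") <- doc$session_id
  state
}
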