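# Offline-first annotation providers. Protein metadata (gene, names,
# function, localization, domains, interactors) is consumed through a
# pluggable provider interface; the shipped implementation reads a local
# TSV, so the whole toolchain runs without network access. A live web
# provider is an extension point, not a dependency.

#' Create an annotation provider backed by a local TSV file
#'
#' The TSV dialect: header columns `accession`, `gene`, `protein_name`,
#' `function`, `subcellular_location`, `domains` (semicolon-separated
#' `name:start-end` spans, 1-based inclusive), `interactors`
#' (semicolon-separated accessions). A small synthetic fixture ships with
#' the package (`system.file("extdata", "annotations_synthetic.tsv",
#' package = "volcanaut")`).
#'
#' @param path TSV file path.
#' @param name Provider name recorded on every returned record.
#' @return An `annotation_provider`.
#' @export
annotation_provider_tsv <- function(path, name = "local-tsv") {
  df <- read_tsv_file(path)
  require_columns(df, c("accession", "gene", "protein_name", "function",
                        "subcellular_location", "domains", "interactors"),
                  path)
  structure(list(name = name, table = df), class = "annotation_provider")
}

parse_domains <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(name = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) vn_data_error(sprintf("malformed domain span '%s'",
                                      parts[bad][1]))
  data.frame(name = vapply(m, `[[`, character(1), 2),
             start = as.integer(vapply(m, `[[`, character(1), 3)),
             end = as.integer(vapply(m, `[[`, character(1), 4)),
             stringsAsFactors = FALSE)
}

#' Annotate accessions through a provider
#'
#' Looks up each unique id once; protein-group ids (`"P1;P2"`) are looked
#' up by their first accession. Missing ids are reported, never fabricated.
#'
#' @param ids Character vector of accessions or protein-group ids.
#' @param provider An `annotation_provider`.
#' @return List with `records` (named list of `annotation_record`s) and
#'   `missing` (ids with no annotation).
#' @export
annotate <- function(ids, provider) {
  if (!inherits(provider, "annotation_provider")) {
    vn_config_error("provider must be an annotation_provider")
  }
  ids <- unique(as.character(ids))
  records <- list()
  missing <- character()
  for (id in ids) {
    acc <- representative_accession(id)
    i <- match(acc, provider$table$accession)
    if (is.na(i)) { missing <- c(missing, id); next }
    row <- provider$table[i, ]
    inter <- if (is.na(row$interactors) || !nzchar(row$interactors))
      character() else strsplit(row$interactors, ";", fixed = TRUE)[[1]]
    records[[id]] <- structure(list(
      accession = acc, gene = row$gene, protein_name = row$protein_name,
      function_text = row[["function"]],
      subcellular_location = row$subcellular_location,
      domains = parse_domains(row$domains),
      interactors = inter, provider = provider$name),
      class = "annotation_record")
  }
  list(records = records, missing = missing)
}

INTERACTOR_CLASSES <- c("up", "down", "present_unchanged", "absent")

#' Classify a protein's interactors against the differential table
#'
#' Each known interactor of an annotated protein is assigned exactly one
#' display class: `absent` when not in the differential table, `up` or
#' `down` when it falls in the significant-and-changed (`S_C`) volcano
#' class with positive or negative log2 fold change, and
#' `present_unchanged` otherwise.
#'
#' @param record An `annotation_record`.
#' @param table A `diff_table`.
#' @param cutoffs A [cutoff_config()].
#' @return An `interactor_overlay` data frame: `interactor`, `class`.
#' @export
interactor_overlay <- function(record, table, cutoffs = cutoff_config()) {
  inter <- record$interactors
  cls <- character(length(inter))
  idx <- match(inter, representative_accession(table$primary_id))
  for (k in seq_along(inter)) {
    i <- idx[k]
    if (is.na(i)) { cls[k] <- "absent"; next }
    sc <- as.character(classify(table$log2_fc[i], table$neglog10_sig[i],
                                cutoffs))
    cls[k] <- if (sc == "S_C") {
      if (table$log2_fc[i] > 0) "up" else "down"
    } else "present_unchanged"
  }
  out <- data.frame(interactor = inter,
                    class = factor(cls, levels = INTERACTOR_CLASSES),
                    stringsAsFactors = FALSE)
  class(out) <- c("interactor_overlay", "data.frame")
  out
}
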