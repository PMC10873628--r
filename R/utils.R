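# Internal helpers shared across modules.

#' @useDynLib volcanaut, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

utils::globalVariables(c("log2_fc", "neglog10_sig", "class", "alpha",
                         "rank", "log2_intensity", "sample_name"))

# Condition constructors: configuration errors (bad column maps, bad
# arguments) are distinguished from data/format errors (unreadable or
# inconsistent input) so the command-line wrapper can map them to exit codes.
vn_config_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("volcanaut_config_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

vn_data_error <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("volcanaut_data_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Read a tab-delimited text table (UTF-8, '.' decimal). check.names is off:
# search-engine headers contain spaces and parentheses that must survive.
read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    vn_data_error(sprintf("file not found: '%s'", path))
  }
  if (file.size(path) == 0) {
    vn_data_error(sprintf("empty file: '%s'", path))
  }
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "",
                      na.strings = c("NA", ""), fileEncoding = "UTF-8"),
    error = function(e) vn_data_error(sprintf("cannot parse '%s': %s", path,
                                              conditionMessage(e)))
  )
  df
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

require_columns <- function(df, cols, path = "<table>") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    vn_config_error(sprintf(
      "column%s %s not found in '%s' (available: %s)",
      if (length(missing) > 1) "s" else "",
      paste(sQuote(missing), collapse = ", "), path,
      paste(sQuote(utils::head(names(df), 12)), collapse = ", ")))
  }
  invisible(df)
}

# RFC-4122 version-4 identifier drawn from the session RNG.
uuid4 <- function() {
  hex <- c(0:9, letters[1:6])
  d <- sample(hex, 32, replace = TRUE)
  d[13] <- "4"
  d[17] <- sample(c("8", "9", "a", "b"), 1)
  paste0(
    paste(d[1:8], collapse = ""), "-", paste(d[9:12], collapse = ""), "-",
    paste(d[13:16], collapse = ""), "-", paste(d[17:20], collapse = ""), "-",
    paste(d[21:32], collapse = ""))
}

# Amino-acid alphabet accepted in sequence sets: the 20 standard residues
# plus X (unknown), U (selenocysteine), B and Z (ambiguity codes).
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALLOWED <- c(AA_STANDARD, "X", "U", "B", "Z")

# First accession of a protein-group string "P1;P2;P3" represents the group
# for any sequence or annotation lookup; the full string stays the id.
representative_accession <- function(id) {
  vapply(strsplit(as.character(id), ";", fixed = TRUE),
         function(x) if (length(x) == 0) NA_character_ else trimws(x[[1]]),
         character(1))
}
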