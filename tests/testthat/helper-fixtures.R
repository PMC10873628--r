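# Shared fixture builders and independent oracles.

write_tmp_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# Independent re-derivation of the four-class volcano partition, written as
# explicit branch logic so it shares no code with classify().
oracle_classify <- function(fc, sig, fc_cut, sig_cut) {
  out <- character(length(fc))
  for (i in seq_along(fc)) {
    s <- sig[i] > sig_cut
    cpos <- fc[i] > fc_cut
    cneg <- fc[i] < -fc_cut
    if (s && (cpos || cneg)) out[i] <- "S_C"
    else if (s) out[i] <- "S_NC"
    else if (cpos || cneg) out[i] <- "NS_C"
    else out[i] <- "NS_NC"
  }
  out
}

# Brute-force global-alignment score by recursive enumeration of all
# alignment paths with affine gap costs (gap of length L costs
# open + L * extend). Exponential; for short sequences only.
oracle_align_score <- function(s1, s2, sub, open = -10, extend = -0.5) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(a)) {
      cost <- if (state == "U") extend else open + extend
      best <- max(best, cost + rec(i + 1, j, "U"))
    }
    if (j <= length(b)) {
      cost <- if (state == "L") extend else open + extend
      best <- max(best, cost + rec(i, j + 1, "L"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_aa_string <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len,
               replace = TRUE), collapse = "")
}

# Small fully populated analysis state for round-trip tests.
random_session_state <- function() {
  sim <- gen_proteome(proteome_sim_params(
    n_features = sample(10:40, 1), n_replicates = sample(2:4, 1),
    missing_rate = stats::runif(1, 0, 0.2), seed = sample.int(1e6, 1)))
  nsel <- sample(0:3, 1)
  sels <- lapply(seq_len(nsel), function(k) {
    selection_set(sprintf("set%d", k),
                  sample(sim$diff$primary_id, min(3, nrow(sim$diff))),
                  sprintf("#%06x", sample.int(16^6, 1) - 1))
  })
  session_state(
    metadata = project_metadata(title = paste0("t", sample.int(100, 1)),
                                authors = "A; B"),
    colmap = sim$colmap, annotations = sim$raw$samples,
    cutoffs = cutoff_config(stats::runif(1, 0, 2), stats::runif(1, 0, 3)),
    selections = sels,
    style = style_options(sample(c("default", "colorblind"), 1)),
    diff = sim$diff, raw = sim$raw,
    extras = if (stats::runif(1) < 0.5) list(custom_note = "kept") else list())
}
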