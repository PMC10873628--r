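# Data-quality views: ranked per-sample profile series and the global
# sample-sample correlation matrix.

#' Ranked per-sample intensity profiles
#'
#' For each sample, the non-missing intensities are log2-transformed and
#' sorted descending; plotting log2 intensity against rank gives the
#' profile plot used to judge whether all samples share the same abundance
#' distribution. Features of interest can be highlighted with their rank
#' and level marked in every sample where they were detected.
#'
#' @param matrix A `raw_quant` object.
#' @param highlight_ids Feature ids to annotate on the profiles.
#' @return A `profile_series`: list with `series` (named list per sample of
#'   data frames rank/log2_intensity/feature_id), `highlights` (data frame
#'   sample_name/feature_id/rank/log2_intensity), and
#'   `missing_highlight_ids` (ids found in no sample).
#' @export
profile_data <- function(matrix, highlight_ids = character()) {
  if (length(matrix$feature_ids) == 0) vn_data_error("empty matrix")
  series <- list()
  hl <- list()
  for (s in matrix$samples$sample_name) {
    v <- matrix$intensities[, s]
    ok <- !is.na(v)
    if (!any(ok)) {
      warning(sprintf("sample '%s' has no quantified features", s))
      series[[s]] <- data.frame(rank = integer(), log2_intensity = numeric(),
                                feature_id = character(),
                                stringsAsFactors = FALSE)
      next
    }
    lv <- log2(v[ok])
    ord <- order(lv, decreasing = TRUE)
    series[[s]] <- data.frame(rank = seq_along(ord),
                              log2_intensity = lv[ord],
                              feature_id = matrix$feature_ids[ok][ord],
                              stringsAsFactors = FALSE)
    pres <- highlight_ids[highlight_ids %in% series[[s]]$feature_id]
    if (length(pres) > 0) {
      idx <- match(pres, series[[s]]$feature_id)
      hl[[s]] <- data.frame(sample_name = s, feature_id = pres,
                            rank = series[[s]]$rank[idx],
                            log2_intensity = series[[s]]$log2_intensity[idx],
                            stringsAsFactors = FALSE)
    }
  }
  highlights <- if (length(hl)) do.call(rbind, hl) else
    data.frame(sample_name = character(), feature_id = character(),
               rank = integer(), log2_intensity = numeric(),
               stringsAsFactors = FALSE)
  rownames(highlights) <- NULL
  found <- unique(highlights$feature_id)
  structure(list(series = series, highlights = highlights,
                 missing_highlight_ids = setdiff(highlight_ids, found)),
            class = "profile_series")
}

#' Global sample-sample correlation matrix
#'
#' Pairwise correlation of per-sample intensity profiles, the standard
#' replicate-quality check: technical/biological replicates of the same
#' condition are expected to correlate very highly. Correlations are
#' computed on log2 intensities (configurable) over the features
#' non-missing in both samples of each pair. Pairs sharing fewer than
#' 3 features get an undefined coefficient, reported as `NA`, never as 0.
#'
#' @param matrix A `raw_quant` object with at least 2 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param log2 Correlate log2-transformed intensities (default) or raw.
#' @return A `corr_matrix`: symmetric numeric matrix (samples x samples,
#'   unit diagonal) with attributes `method` and `n_shared` (pairwise
#'   feature counts).
#' @export
correlation_matrix <- function(matrix, method = c("pearson", "spearman"),
                               log2 = TRUE) {
  method <- match.arg(method)
  if (nrow(matrix$samples) < 2) vn_data_error("need at least 2 samples")
  m <- matrix$intensities
  if (log2) m <- base::log2(m)
  cc <- stats::cor(m, method = method, use = "pairwise.complete.obs")
  n_shared <- crossprod(!is.na(m))
  cc[n_shared < 3] <- NA_real_
  diag(cc) <- 1
  cc[] <- (cc + t(cc)) / 2  # enforce exact symmetry against fp asymmetry
  structure(cc, method = method, log2 = log2, n_shared = n_shared,
            class = c("corr_matrix", class(cc)))
}
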