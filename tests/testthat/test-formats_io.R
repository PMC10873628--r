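test_that("read_differential transforms declared scales into plot space", {
  p <- write_tmp_tsv(data.frame(id = c("P1", "P2", "P3"),
                                FC = c(4, 0.5, 1), pval = c(0.001, 0.05, 1)))
  cm <- column_map("id", "FC", "pval", fc_scale = "linear",
                   sig_scale = "raw_p")
  d <- read_differential(p, cm)
  expect_equal(d$log2_fc, c(2, -1, 0))
  expect_equal(d$neglog10_sig, c(3, -log10(0.05), 0))

  cm2 <- column_map("id", "FC", "pval", fc_scale = "log2",
                    sig_scale = "raw_p")
  d2 <- read_differential(p, cm2)
  expect_equal(d2$log2_fc, c(4, 0.5, 1))  # identity transform
})

test_that("linear fold changes round-trip through log2 to 1e-9 relative", {
  set.seed(11)
  fc <- stats::runif(50, 0.01, 100)
  p <- write_tmp_tsv(data.frame(id = sprintf("P%02d", 1:50), FC = fc,
                                pval = stats::runif(50, 1e-8, 1)))
  d <- read_differential(p, column_map("id", "FC", "pval",
                                       fc_scale = "linear",
                                       sig_scale = "raw_p"))
  expect_equal(2 ^ d$log2_fc, fc, tolerance = 1e-9)
})

test_that("untransformable rows are dropped, not clamped, and counted", {
  p <- write_tmp_tsv(data.frame(id = c("P1", "P2", "P3", "P4"),
                                FC = c(2, -1, 2, 2),
                                pval = c(0.01, 0.01, 0, "oops")))
  d <- read_differential(p, column_map("id", "FC", "pval",
                                       fc_scale = "linear",
                                       sig_scale = "raw_p"))
  expect_equal(d$primary_id, "P1")
  rep <- attr(d, "drop_report")
  expect_equal(rep$n_dropped, 3)
  expect_equal(rep$n_kept + rep$n_dropped, rep$n_source)
  expect_setequal(rep$dropped_ids, c("P2", "P3", "P4"))
})

test_that("missing mapped columns raise a configuration error naming them", {
  p <- write_tmp_tsv(data.frame(id = "P1", FC = 1, pval = 0.5))
  expect_error(
    read_differential(p, column_map("id", "logFC", "pval")),
    "logFC", class = "volcanaut_config_error")
  expect_error(column_map("id", "x", "x"), class = "volcanaut_config_error")
})

test_that("read_raw assembles matrix in display order with zeros missing", {
  df <- data.frame(pid = c("A", "B"), s1 = c(1, 0), s2 = c(2, 5),
                   s3 = c(3, 6), s4 = c(4, 7))
  p <- write_tmp_tsv(df)
  ann <- sample_annotation(c("s1", "s2", "s3", "s4"),
                           rep(c("ctl", "trt"), each = 2), c(1, 2, 1, 2),
                           display_order = c(4, 3, 2, 1))
  r <- read_raw(p, "pid", ann)
  expect_equal(colnames(r$intensities), c("s4", "s3", "s2", "s1"))
  expect_equal(dim(r$intensities), c(2L, 4L))
  expect_true(is.na(r$intensities["B", "s1"]))  # zero -> missing
  expect_equal(r$intensities["A", "s4"], 4)
})

test_that("duplicate feature ids keep the first occurrence with a warning", {
  p <- write_tmp_tsv(data.frame(pid = c("A", "A"), s1 = c(1, 9),
                                s2 = c(2, 8)))
  ann <- sample_annotation(c("s1", "s2"), c("c", "t"), c(1, 1))
  expect_warning(r <- read_raw(p, "pid", ann), "duplicate")
  expect_equal(length(r$feature_ids), 1L)
  expect_equal(unname(r$intensities["A", "s1"]), 1)
})

test_that("read_raw round-trips write_raw on complete matrices", {
  sim <- gen_proteome(proteome_sim_params(n_features = 15,
                                          missing_rate = 0, seed = 2))
  p <- tempfile(fileext = ".tsv")
  write_raw(sim$raw, p, id_col = "pid")
  back <- read_raw(p, "pid", sim$raw$samples)
  expect_equal(back$intensities, sim$raw$intensities)
  expect_equal(back$feature_ids, sim$raw$feature_ids)
})

test_that("read_fasta reduces UniProt headers and validates records", {
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|Q86Y82|STX12_HUMAN some description", "msyGPL",
               ">P99999", "ACDEF"), p)
  s <- read_fasta(p)
  expect_equal(unclass(s)[["Q86Y82"]], "MSYGPL")  # uppercased
  expect_equal(names(s), c("Q86Y82", "P99999"))

  writeLines(c(">sp|P1|A", "MA", ">tr|P1|B", "MK"), p)
  expect_error(read_fasta(p), "duplicate", class = "volcanaut_data_error")
})

test_that("custom PTM databases enforce 1-based integer positions", {
  p <- write_tmp_tsv(data.frame(accession = "P12345", position = 139,
                                residue = "S", modification = "Phospho"))
  db <- read_custom_ptm_db(p, "custom")
  expect_equal(db$entries$position, 139L)
  expect_equal(db$source_name, "custom")

  p0 <- write_tmp_tsv(data.frame(accession = "P1", position = 0,
                                 residue = "S", modification = "Phospho"))
  expect_error(read_custom_ptm_db(p0, "x"), "1-based",
               class = "volcanaut_data_error")

  pe <- write_tmp_tsv(data.frame(accession = character(),
                                 position = integer(),
                                 residue = character(),
                                 modification = character()))
  db0 <- read_custom_ptm_db(pe, "empty")
  expect_equal(nrow(db0$entries), 0L)
})

test_that("sample annotations reject duplicate condition/replicate pairs", {
  expect_error(sample_annotation(c("a", "b"), c("c", "c"), c(1, 1)),
               class = "volcanaut_config_error")
  expect_error(sample_annotation(c("a", "a"), c("c", "c"), c(1, 2)),
               class = "volcanaut_config_error")
})
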