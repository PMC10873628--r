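test_that("classify applies strict cutoffs with boundary points less extreme", {
  cut <- cutoff_config(1.0, 1.301)
  expect_equal(as.character(classify(2.0, 3.0, cut)), "S_C")
  expect_equal(as.character(classify(0.0, 0.0, cut)), "NS_NC")
  # exactly on the fold-change line: not changed
  expect_equal(as.character(classify(1.0, 3.0, cut)), "S_NC")
  # exactly on the significance line: not significant
  expect_equal(as.character(classify(2.0, 1.301, cut)), "NS_C")
})

test_that("classification partitions, is sign-symmetric and matches oracle", {
  set.seed(21)
  n <- 5000
  fc <- stats::runif(n, -4, 4)
  sig <- stats::runif(n, 0, 6)
  for (cut in list(cutoff_config(0.6, 1.301), cutoff_config(0, 0),
                   cutoff_config(2, 3))) {
    cls <- classify(fc, sig, cut)
    expect_false(anyNA(cls))
    expect_equal(sum(table(cls)), n)  # exact partition
    expect_equal(as.character(cls),
                 oracle_classify(fc, sig, cut$fc_cutoff, cut$sig_cutoff))
    expect_equal(classify(-fc, sig, cut), cls)  # sign symmetry
  }
})

test_that("raising a cutoff never promotes a point to a more extreme class", {
  set.seed(22)
  fc <- stats::runif(2000, -4, 4)
  sig <- stats::runif(2000, 0, 6)
  base <- classify(fc, sig, cutoff_config(0.5, 1))
  higher_sig <- classify(fc, sig, cutoff_config(0.5, 2))
  higher_fc <- classify(fc, sig, cutoff_config(1.5, 1))
  sig_of <- function(cls) cls %in% c("S_NC", "S_C")
  chg_of <- function(cls) cls %in% c("NS_C", "S_C")
  expect_true(all(!sig_of(higher_sig) | sig_of(base)))
  expect_true(all(!chg_of(higher_fc) | chg_of(base)))
})

test_that("volcano figure data splits classes and overlays selections", {
  tab <- data.frame(
    primary_id = c("a", "b", "c", "d"), gene = c("GA", "GB", "GC", "GD"),
    log2_fc = c(2, 0, 2, 0), neglog10_sig = c(3, 3, 0, 0),
    comparison = "x", stringsAsFactors = FALSE)
  class(tab) <- c("diff_table", "data.frame")
  cut <- cutoff_config(1, 1.301)
  vd <- build_volcano(tab, cut)
  expect_equal(vapply(vd$series, nrow, integer(1)),
               c(NS_NC = 1L, S_NC = 1L, NS_C = 1L, S_C = 1L))
  expect_equal(vd$cutoff_lines$vertical, c(-1, 1))
  expect_false(any(vd$points$faded))

  sel <- selection_set("pick", c("a", "zzz"), "#123456")
  vd2 <- build_volcano(tab, cut, selections = list(sel), fade = TRUE)
  expect_equal(nrow(vd2$overlays$pick$points), 1L)
  expect_equal(vd2$missing_selection_ids$pick, "zzz")
  expect_equal(sum(vd2$points$faded), 3L)
  # overlays duplicate points: base series still carry all rows
  expect_equal(sum(vapply(vd2$series, nrow, integer(1))), nrow(tab))
})

test_that("batch selection matches genes case-insensitively and exactly", {
  tab <- data.frame(primary_id = c("p1", "p2", "p3"),
                    gene = c("Rab10", "RAB10B", "LRRK2"),
                    log2_fc = 0, neglog10_sig = 0, comparison = "x",
                    stringsAsFactors = FALSE)
  class(tab) <- c("diff_table", "data.frame")
  sel <- batch_select(tab, c("RAB10", "MISSING", "RAB10"), "batch")
  expect_equal(sel$member_ids, "p1")  # no substring match on RAB10B
  expect_equal(attr(sel, "unmatched_genes"), "MISSING")
})

test_that("feature summaries report per-condition mean, SD and SEM", {
  ann <- sample_annotation(c("c1", "c2", "c3", "t1"),
                           c("ctl", "ctl", "ctl", "trt"), c(1, 2, 3, 1))
  m <- matrix(c(1, 2, 3, 5), nrow = 1,
              dimnames = list("F1", ann$sample_name))
  raw <- volcanaut:::new_raw_quant("F1", ann, m)
  fs <- summarize_feature(raw, "F1")
  ctl <- fs$conditions[fs$conditions$condition == "ctl", ]
  expect_equal(ctl$mean, 2)
  expect_equal(ctl$sd, 1)
  expect_equal(ctl$sem, 0.5774, tolerance = 1e-4)
  # single replicate: SD/SEM reported 0 and flagged, not an error
  trt <- fs$conditions[fs$conditions$condition == "trt", ]
  expect_equal(trt$sd, 0)
  expect_true(trt$insufficient_replicates)
  expect_equal(attr(fs$conditions, "values")$ctl, c(c1 = 1, c2 = 2, c3 = 3))
  expect_error(summarize_feature(raw, "nope"),
               class = "volcanaut_data_error")
})

test_that("missing replicate values are excluded from summaries", {
  ann <- sample_annotation(c("c1", "c2", "c3"), rep("ctl", 3), 1:3)
  m <- matrix(c(4, NA, 6), nrow = 1,
              dimnames = list("F1", ann$sample_name))
  raw <- volcanaut:::new_raw_quant("F1", ann, m)
  fs <- summarize_feature(raw, "F1")
  expect_equal(fs$conditions$n, 2L)
  expect_equal(fs$conditions$mean, 5)
})
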