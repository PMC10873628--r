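test_that("identical sequences short-circuit to the identity map", {
  s <- random_aa_string(40)
  m <- align_isoforms(s, s)
  expect_equal(m$exp_to_canonical, seq_len(40))
  expect_equal(m$identity, 1.0)
  expect_equal(remap_site(m, 17)$canonical_position, 17L)
})

test_that("N-terminal extensions shift every mapped position by the offset", {
  set.seed(41)
  for (d in c(3, 5, 11)) {
    core <- random_aa_string(30)
    canonical <- paste0(random_aa_string(d), core)
    m <- align_isoforms(core, canonical)
    expect_equal(m$exp_to_canonical, seq_len(30) + d)
    r <- remap_site(m, 12)
    expect_equal(r$canonical_position, 12L + d)
    expect_equal(r$exp_residue, r$canonical_residue)
  }
})

test_that("internal deletions shift downstream positions and unmap the gap", {
  set.seed(42)
  left <- random_aa_string(15)
  del <- random_aa_string(2)
  right <- random_aa_string(15)
  exp_seq <- paste0(left, right)
  canonical <- paste0(left, del, right)
  m <- align_isoforms(exp_seq, canonical)
  expect_equal(m$exp_to_canonical[1:15], 1:15)
  expect_equal(m$exp_to_canonical[16:30], 18:32)  # +2 after the deletion
  expect_equal(setdiff(seq_len(32), m$exp_to_canonical), c(16L, 17L))
  # a position inside an experimental insertion is unaligned
  m2 <- align_isoforms(canonical, exp_seq)
  expect_true(all(is.na(m2$exp_to_canonical[16:17])))
  expect_true(remap_site(m2, 16)$unaligned)
})

test_that("alignment scores match brute-force enumeration on short pairs", {
  set.seed(43)
  for (k in 1:40) {
    s1 <- random_aa_string(sample(1:6, 1))
    s2 <- random_aa_string(sample(1:6, 1))
    got <- align_isoforms(s1, s2)$score
    want <- oracle_align_score(s1, s2, blosum62)
    expect_equal(got, want, info = paste(s1, s2))
  }
})

test_that("mapped positions are strictly monotone increasing", {
  set.seed(44)
  for (k in 1:25) {
    s1 <- random_aa_string(sample(5:25, 1))
    s2 <- random_aa_string(sample(5:25, 1))
    m <- align_isoforms(s1, s2)
    mapped <- m$exp_to_canonical[!is.na(m$exp_to_canonical)]
    if (length(mapped) > 1) expect_true(all(diff(mapped) > 0))
  }
})

test_that("traceback is deterministic and prefers the diagonal", {
  m1 <- align_isoforms("AR", "AR", alignment_params(c(match = 1,
                                                      mismatch = -1),
                                                    gap_open = 0,
                                                    gap_extend = 0))
  expect_equal(m1$exp_to_canonical, c(1L, 2L))
  # repeated runs agree exactly
  a <- align_isoforms("MKSASK", "MKSK")
  b <- align_isoforms("MKSASK", "MKSK")
  expect_identical(a$exp_to_canonical, b$exp_to_canonical)
  expect_identical(a$aligned_exp, b$aligned_exp)
})

test_that("out-of-range remap positions raise an error", {
  m <- align_isoforms("MKSA", "MKSA")
  expect_error(remap_site(m, 5), "range", class = "volcanaut_data_error")
  expect_error(remap_site(m, 0), "range", class = "volcanaut_data_error")
})

test_that("site comparison assigns the four display classes", {
  exp_sites <- data.frame(accession = "P1", position = 139, residue = "S",
                          modification = "Phospho",
                          experimental_position = 128,
                          sig_class = "S_C", stringsAsFactors = FALSE)
  db <- ptm_database("ref", "P1", 139, "S", "Phospho")
  comp <- compare_sites(exp_sites, list(db))
  expect_equal(as.character(comp$class), "BOTH")
  expect_true(comp$significant_flag)
  expect_equal(comp$experimental_position, 128L)
  expect_equal(comp$db_sources, "ref")

  db2 <- ptm_database("ref", "P1", 140, "S", "Phospho")
  comp2 <- compare_sites(exp_sites, list(db2))
  expect_equal(as.character(comp2$class[comp2$position == 139]),
               "EXPERIMENT_ONLY")
  expect_equal(as.character(comp2$class[comp2$position == 140]),
               "DATABASE_ONLY")

  comp3 <- compare_sites(exp_sites, list(db),
                         selected = data.frame(accession = "P1",
                                               position = 139))
  expect_equal(as.character(comp3$class), "SELECTED")
  expect_equal(comp3$db_sources, "ref")  # presence retained under override
})

test_that("site comparison classes partition all positions", {
  set.seed(45)
  exp_pos <- sample(1:60, 12)
  db_pos <- sample(1:60, 12)
  exp_sites <- data.frame(accession = "P1", position = exp_pos,
                          residue = "S", modification = "Phospho",
                          stringsAsFactors = FALSE)
  db <- ptm_database("ref", rep("P1", 12), db_pos, rep("S", 12),
                     rep("Phospho", 12))
  comp <- compare_sites(exp_sites, list(db))
  expect_setequal(comp$position, union(exp_pos, db_pos))
  expect_false(anyNA(comp$class))
  expect_equal(sort(comp$position[comp$class == "BOTH"]),
               sort(intersect(exp_pos, db_pos)))
})

test_that("a residue mismatch against the database is reported as conflict", {
  exp_sites <- data.frame(accession = "P1", position = 10, residue = "T",
                          modification = "Phospho", stringsAsFactors = FALSE)
  db <- ptm_database("ref", "P1", 10, "S", "Phospho")
  comp <- compare_sites(exp_sites, list(db))
  expect_equal(as.character(comp$class), "EXPERIMENT_ONLY")
  expect_true(comp$residue_conflict)
})

test_that("motif windows are centered, padded and exact length", {
  expect_equal(extract_window("ABCDEFG", 4, halfwidth = 2), "BCDEF")
  expect_equal(extract_window("ABCDEFG", 1, halfwidth = 3), "___ABCD")
  expect_equal(extract_window("ABCDEFG", 7, halfwidth = 3), "DEFG___")
  expect_equal(extract_window("ABCDEFG", 4, halfwidth = 0), "D")
  w <- extract_window("ACDEFGHIKLMNPQRSTVWY", 10, halfwidth = 7)
  expect_equal(nchar(w), 15L)
  expect_equal(substr(w, 8, 8), "L")  # center is the site residue
  expect_error(extract_window("ABC", 4), class = "volcanaut_data_error")
})

test_that("position frequency matrices conserve the window count per column", {
  w2 <- c("ASK", "ASK")
  pfm <- position_frequency_matrix(w2)
  expect_equal(dim(pfm), c(21L, 3L))
  expect_equal(pfm["S", 2], 2L)
  expect_true(all(colSums(pfm) == 2))

  set.seed(46)
  seqs <- vapply(1:100, function(i) random_aa_string(50), character(1))
  wins <- vapply(seqs, extract_window, character(1), position = 25,
                 halfwidth = 7)
  pfm2 <- position_frequency_matrix(wins)
  expect_true(all(colSums(pfm2) == 100))
  expect_error(position_frequency_matrix(c("ASK", "AS")),
               "mixed", class = "volcanaut_data_error")
})
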