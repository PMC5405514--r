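# Motif transfer, conservation profiles and conserved-block mining.

make_defs <- function() {
  motif_definitions(c("GQ", "QFP", "T"), c(0L, 10L, 20L), c(6L, 16L, 26L),
                    "ref")
}

test_that("motif configs validate intervals and ship with the package", {
  expect_error(motif_definitions("GQ", 5, 5, "r"), "start < end")
  expect_error(motif_definitions(c("A", "B"), c(0, 3), c(5, 8), "r"),
               "overlap")
  d <- motif_definitions(c("GQ", "DAT"), c(0, 2), c(10, 6), "r")
  expect_equal(nrow(d), 2L)
  expect_error(motif_definitions(c("GQ", "DAT"), c(0, 8), c(10, 14), "r"),
               "inside GQ")

  cfgs <- c("hTERT_motifs.json", "celegans_TERT_motifs.json")
  for (cfg in cfgs) {
    p <- system.file("extdata", "motifs", cfg, package = "tertarch")
    d <- read_motif_config(p)
    expect_s3_class(d, "motif_definitions")
    expect_true(all(c("QFP", "T") %in% d$name))
  }
})

test_that("a reference aligned to itself carries every motif at coverage 1", {
  ref <- paste(rep(c("M", "K", "V", "L", "Q", "A"), 5), collapse = "")
  aln <- new_alignment(c("ref", "copy"), c(ref, ref))
  calls <- transfer_motifs(aln, make_defs())
  expect_true(all(calls$status == "present"))
  expect_true(all(calls$coverage == 1))
  expect_equal(calls$target_start, c(0L, 10L, 20L))
  expect_equal(calls$target_end, c(6L, 16L, 26L))
})

test_that("deleting a motif region before alignment makes it absent", {
  set.seed(41)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  ref <- paste(sample(aas, 30, TRUE), collapse = "")
  target <- paste0(substr(ref, 7, 30))  # GQ region [0,6) removed
  aln <- global_align(target, ref, ids = c("target", "ref"))
  calls <- transfer_motifs(aln, make_defs())
  expect_equal(calls$status[calls$motif == "GQ"], "absent")
  expect_true(all(calls$status[calls$motif != "GQ"] == "present"))
})

test_that("status thresholds partition calls by coverage", {
  ref <- strrep("K", 20)
  defs <- motif_definitions("M1", 0L, 20L, "ref")
  for (kept in c(0L, 3L, 10L, 15L, 20L)) {
    target_row <- paste0(strrep("K", kept), strrep("-", 20L - kept))
    aln <- new_alignment(c("ref", "t"), c(ref, target_row))
    call <- transfer_motifs(aln, defs)
    cov <- kept / 20
    expect_equal(call$coverage, cov)
    expect_equal(call$status,
                 if (cov >= 0.7) "present" else if (cov >= 0.2) "partial"
                 else "absent")
    if (kept == 0L) expect_true(is.na(call$target_start))
  }
})

test_that("motif transfer is invariant under all-gap column insertion", {
  set.seed(42)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  ref <- paste(sample(aas, 30, TRUE), collapse = "")
  tgt <- paste0(substr(ref, 1, 12), substr(ref, 19, 30))
  aln <- global_align(tgt, ref, ids = c("t", "ref"))
  calls <- transfer_motifs(aln, make_defs())
  # splice three all-gap columns into the middle of both rows
  pad <- function(s) paste0(substr(s, 1, 8), "---",
                            substr(s, 9, nchar(s)))
  aln2 <- new_alignment(aln$ids, vapply(aln$seqs, pad, character(1)))
  calls2 <- transfer_motifs(aln2, make_defs())
  expect_equal(calls2$status, calls$status)
  expect_equal(calls2$coverage, calls$coverage)
})

test_that("conservation profile computes modal residues and frequencies", {
  aln <- new_alignment(
    letters[1:5],
    c("AAG", "AAG", "AAC", "A-C", "A-C")
  )
  p <- conservation_profile(aln)
  expect_equal(p$consensus, c("A", "A", "C"))
  expect_equal(p$frequency, c(1, 1, 3 / 5))
  expect_equal(p$n_nongap, c(5L, 3L, 5L))
  # 'all' denominator divides by row count
  p2 <- conservation_profile(aln, denominator = "all")
  expect_equal(p2$frequency[2], 3 / 5)
  # modal ties break alphabetically
  tie <- new_alignment(c("a", "b"), c("G", "A"))
  expect_equal(conservation_profile(tie)$consensus, "A")
})

test_that("profile drops all-gap columns and ignores row order", {
  aln <- new_alignment(c("a", "b"), c("A-G", "A-C"))
  p <- conservation_profile(aln)
  expect_equal(p$column, c(1L, 3L))
  perm <- new_alignment(c("b", "a"), c("A-C", "A-G"))
  expect_equal(conservation_profile(perm)$frequency, p$frequency)
  expect_equal(conservation_profile(perm)$consensus, p$consensus)
})

test_that("mean profile frequency tracks the substitution probability", {
  # Monte-Carlo: 20 rows from a consensus with per-site substitution
  # probability p; expected modal frequency ~ 1 - p * 19/20
  set.seed(43)
  p_sub <- 0.1
  n_rows <- 20L; n_cols <- 40L; n_rep <- 200L
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  means <- replicate(n_rep, {
    cons <- sample(aas, n_cols, TRUE)
    rows <- vapply(seq_len(n_rows), function(i) {
      r <- cons
      mut <- runif(n_cols) < p_sub
      r[mut] <- sample(aas, sum(mut), TRUE)
      paste(r, collapse = "")
    }, character(1))
    mean(conservation_profile(new_alignment(as.character(seq_len(n_rows)),
                                            rows))$frequency)
  })
  expected <- 1 - p_sub * 19 / 20
  se <- sd(means) / sqrt(n_rep)
  expect_lt(abs(mean(means) - expected), max(2 * se, 0.01))
})

test_that("an identical clade hexapeptide is recovered as one block", {
  set.seed(44)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  width <- 6L
  clade_rows <- replicate(4, "QQRVLF")
  bg_rows <- replicate(8, paste(sample(aas, width, TRUE), collapse = ""))
  aln <- new_alignment(
    c(paste0("c", 1:4), paste0("b", 1:8)),
    c(clade_rows, bg_rows)
  )
  labels <- setNames(c(rep("kin", 4), rep("out", 8)), aln$ids)
  blocks <- find_conserved_blocks(aln, labels, "kin")
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$consensus, "QQRVLF")
  expect_equal(c(blocks$col_start, blocks$col_end), c(1L, 6L))
  expect_equal(blocks$mean_frequency, 1)
})

test_that("a 50/50 two-state column renders as (A/B) and failures as x", {
  # clade of 4: one column split I/I/V/V, one column all different
  clade <- c("IQQRVALQF",
             "IQQRVCLQF",
             "VQQRVDLQF",
             "VQQRVELQF")
  # maximally diverse background: every column holds 6 distinct residues
  aas14 <- c("A", "C", "D", "E", "F", "G", "H", "K", "L", "M", "N", "P",
             "S", "W")
  bg <- vapply(1:6, function(i) {
    paste(aas14[((seq_len(9) * 2 + i) %% 14) + 1], collapse = "")
  }, character(1))
  aln <- new_alignment(c(paste0("c", 1:4), paste0("b", 1:6)), c(clade, bg))
  labels <- setNames(c(rep("kin", 4), rep("out", 6)), aln$ids)
  blocks <- find_conserved_blocks(aln, labels, "kin")
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$consensus, "(I/V)QQRVxLQF")
})

test_that("blocks are deterministic, non-overlapping and sorted", {
  set.seed(46)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  n_col <- 60L
  clade_core <- paste(sample(aas, n_col, TRUE), collapse = "")
  clade_rows <- replicate(5, {
    r <- strsplit(clade_core, "")[[1]]
    mut <- runif(n_col) < 0.3
    r[mut] <- sample(aas, sum(mut), TRUE)
    paste(r, collapse = "")
  })
  bg_rows <- replicate(8, paste(sample(aas, n_col, TRUE), collapse = ""))
  aln <- new_alignment(c(paste0("c", 1:5), paste0("b", 1:8)),
                       c(clade_rows, bg_rows))
  labels <- setNames(c(rep("kin", 5), rep("out", 8)), aln$ids)
  b1 <- find_conserved_blocks(aln, labels, "kin")
  b2 <- find_conserved_blocks(aln, labels, "kin")
  expect_identical(b1, b2)
  if (nrow(b1) > 1L) {
    expect_true(all(diff(b1$col_start) > 0))
    expect_true(all(b1$col_start[-1] > b1$col_end[-nrow(b1)]))
  }
  expect_error(find_conserved_blocks(aln, labels, "nosuch"), "fewer than 3")
})

test_that("simulated clade-specific insertions are recovered with exact bounds", {
  set.seed(47)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    n_col <- 50L
    motif <- paste(sample(aas, 9, TRUE), collapse = "")
    at <- sample(10:35, 1)
    clade_rows <- replicate(5, {
      row <- sample(aas, n_col, TRUE)
      paste(c(row[1:(at - 1)], strsplit(motif, "")[[1]],
              row[at:n_col]), collapse = "")
    })
    bg_rows <- replicate(8, {
      row <- sample(aas, n_col, TRUE)
      paste(c(row[1:(at - 1)], rep("-", 9), row[at:n_col]), collapse = "")
    })
    aln <- new_alignment(c(paste0("c", 1:5), paste0("b", 1:8)),
                         c(clade_rows, bg_rows))
    labels <- setNames(c(rep("kin", 5), rep("out", 8)), aln$ids)
    blocks <- find_conserved_blocks(aln, labels, "kin",
                                    min_block_length = 5L)
    ok <- nrow(blocks) >= 1L &&
      any(blocks$col_start == at & blocks$col_end == at + 8L &
            blocks$consensus == motif)
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
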