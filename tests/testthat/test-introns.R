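# Intron projection arithmetic and conservation classification.

test_that("projection arithmetic: boundary offset -> residue and phase", {
  t <- transcript_model("t", strrep("ATGAAA", 10), exon_boundaries_nt = 9L)
  p <- project_introns(t)
  expect_equal(p$transcript_nt, 9L)
  expect_equal(p$residue_index, 3L)
  expect_equal(p$phase, 0L)

  t2 <- transcript_model("t", strrep("ATGAAA", 10), exon_boundaries_nt = 10L)
  p2 <- project_introns(t2)
  expect_equal(p2$residue_index, 3L)
  expect_equal(p2$phase, 1L)
})

test_that("projection agrees with explicit codon-layout enumeration", {
  set.seed(31)
  for (rep in 1:50) {
    len <- 3L * sample(10:40, 1)
    cds_start <- sample(0:6, 1)
    cdna_len <- cds_start + len + sample(0:6, 1)
    b <- sort(sample(seq_len(cdna_len - 1L), sample(1:5, 1)))
    t <- transcript_model("t", strrep("A", cdna_len), b,
                          cds_start_nt = cds_start,
                          cds_end_nt = cds_start + len)
    p <- project_introns(t)
    # enumeration oracle: lay out codon positions one by one
    inside <- b[b >= cds_start & b < cds_start + len]
    codon_of <- rep(seq_len(len %/% 3L) - 1L, each = 3L)
    expect_equal(p$transcript_nt, inside)
    expect_equal(p$residue_index, codon_of[inside - cds_start + 1L])
    expect_equal(p$phase, (inside - cds_start) %% 3L)
    expect_equal(attr(p, "n_utr"), length(b) - length(inside))
  }
})

test_that("UTR boundaries are excluded from projection", {
  t <- transcript_model("t", strrep("A", 60), c(3L, 30L, 57L),
                        cds_start_nt = 6L, cds_end_nt = 54L)
  p <- project_introns(t)
  expect_equal(p$transcript_nt, 30L)
  expect_equal(attr(p, "n_utr"), 2L)
})

test_that("a protein against itself conserves every intron", {
  prot <- "MKVLLQAGHIWK"
  introns <- data.frame(residue_index = c(2L, 7L), phase = c(0L, 1L))
  cmp <- classify_introns(prot, introns, prot, introns)
  expect_true(all(cmp$status == "conserved"))
  expect_equal(cmp$matched_ref_rank, 1:2)
})

test_that("a one-column shift is species-specific at tolerance 0, conserved at 1", {
  # fixture: query has an extra residue so its intron column shifts by one
  q <- "MKAVLQ"
  r <- "MKVLQ"
  aln <- new_alignment(c("q", "r"), c("MKAVLQ", "MK-VLQ"))
  qi <- data.frame(residue_index = 2L, phase = 0L)   # 'A', column 3
  ri <- data.frame(residue_index = 2L, phase = 0L)   # 'V', column 4
  cmp0 <- classify_introns(q, qi, r, ri, aln = aln, tolerance = 0L)
  expect_equal(cmp0$status, "species_specific")
  cmp1 <- classify_introns(q, qi, r, ri, aln = aln, tolerance = 1L)
  expect_equal(cmp1$status, "conserved")
  expect_equal(cmp1$matched_ref_rank, 1L)
})

test_that("phase matching is enforced only when requested", {
  prot <- "MKVLLQ"
  qi <- data.frame(residue_index = 2L, phase = 1L)
  ri <- data.frame(residue_index = 2L, phase = 2L)
  expect_equal(classify_introns(prot, qi, prot, ri)$status, "conserved")
  expect_equal(
    classify_introns(prot, qi, prot, ri, require_phase = TRUE)$status,
    "species_specific"
  )
})

test_that("each reference intron matches at most one query intron", {
  prot <- "MKVLLQ"
  qi <- data.frame(residue_index = c(2L, 3L), phase = c(0L, 0L))
  ri <- data.frame(residue_index = 3L, phase = 0L)
  cmp <- classify_introns(prot, qi, prot, ri, tolerance = 1L)
  expect_equal(sum(cmp$status == "conserved"), 1L)
  # nearest wins: the query intron at residue 3 (exact column match)
  expect_equal(cmp$status, c("species_specific", "conserved"))
})

test_that("conservation counts are consistent and monotone in tolerance", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(30:60, 1)
    aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
    qp <- paste(sample(aas, n, TRUE), collapse = "")
    rp <- paste(sample(aas, n + sample(-5:5, 1), TRUE), collapse = "")
    qpos <- sort(sample(0:(nchar(qp) - 1L), sample(0:6, 1)))
    qi <- data.frame(residue_index = qpos,
                     phase = sample(0:2, length(qpos), TRUE))
    rpos <- sort(sample(0:(nchar(rp) - 1L), sample(0:6, 1)))
    ri <- data.frame(residue_index = rpos,
                     phase = sample(0:2, length(rpos), TRUE))
    aln <- global_align(qp, rp, ids = c("q", "r"))
    prev <- -1L
    for (tol in c(0L, 1L, 2L, 4L)) {
      cmp <- classify_introns(qp, qi, rp, ri, aln = aln, tolerance = tol)
      n_cons <- sum(cmp$status == "conserved")
      expect_equal(n_cons + sum(cmp$status == "species_specific"), nrow(qi))
      expect_lte(n_cons, min(nrow(qi), nrow(ri)))
      expect_gte(n_cons, prev)
      prev <- n_cons
    }
  }
})

test_that("conservation_table counts the reference against itself in full", {
  prot <- "MKVLLQAGHIWK"
  introns <- data.frame(residue_index = c(2L, 5L, 9L), phase = c(0L, 1L, 2L))
  ref <- list(protein = prot, introns = introns)
  tab <- conservation_table(list(refsp = ref), ref)
  expect_equal(tab$n_introns, 3L)
  expect_equal(tab$n_conserved, 3L)
  expect_equal(tab$n_specific, 0L)
  expect_equal(tab$matched_ref_ranks, "1,2,3")
})

test_that("conservation_table matches simulator truth with substitutions only", {
  fam <- simulate_family(sim_config(
    tree = "((a:0.3,b:0.3):0.1,(c:0.3,d:0.3):0.1);",
    substitution_rate = 0.3, indel_rate = 0, intron_loss_prob = 0.25,
    intron_gain_rate = 0.5, motif_loss_prob = 0, n_variants = 0L,
    seed = 33
  ))
  ref_sp <- names(fam$leaves)[1]
  entries <- lapply(fam$leaves, function(l) {
    list(protein = l$protein, introns = project_introns(l$model))
  })
  tab <- conservation_table(entries, entries[[ref_sp]])
  for (sp in names(fam$leaves)) {
    truth_sp <- fam$truth$leaves[[sp]]
    truth_ref <- fam$truth$leaves[[ref_sp]]
    # substitution-only evolution: proteins keep their length, so an
    # intron is conserved exactly when its hosting residue index occurs
    # among the reference's intron positions
    shared <- length(intersect(truth_sp$intron_positions$residue_index,
                               truth_ref$intron_positions$residue_index))
    row <- tab[tab$species == sp, ]
    expect_equal(row$n_conserved, shared)
    expect_equal(row$n_introns, nrow(truth_sp$intron_positions))
    expect_equal(row$n_conserved + row$n_specific, row$n_introns)
  }
})
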