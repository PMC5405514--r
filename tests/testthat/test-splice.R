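# Variant mapping, event classification, frame/domain annotation.

test_that("a variant identical to the reference yields no segments", {
  ref <- fixture_reference()
  seg <- map_variant(ref$cdna, ref)
  expect_equal(nrow(seg), 0L)
  expect_equal(attr(seg, "identity"), 1)
})

test_that("removing exon 5 gives one deletion segment spanning exon 5", {
  ref <- fixture_reference(n_exons = 6, exon_len = 30)
  b <- c(0L, ref$exon_boundaries_nt, nchar(ref$cdna))
  v <- paste0(substr(ref$cdna, 1, b[5]),
              substr(ref$cdna, b[6] + 1, nchar(ref$cdna)))
  seg <- map_variant(v, ref)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$type, "deletion")
  expect_equal(c(seg$ref_start, seg$ref_end), c(b[5], b[6]))
  ev <- classify_events(seg, ref)
  expect_equal(ev$type, "exon_skip")
  expect_equal(ev$exons, "5")
})

test_that("a 47-nt insertion is recovered with its length and sequence", {
  set.seed(51)
  ref <- fixture_reference()
  ins <- paste(sample(c("A", "C", "G", "T"), 47, TRUE), collapse = "")
  at <- 71L
  v <- paste0(substr(ref$cdna, 1, at), ins,
              substr(ref$cdna, at + 1, nchar(ref$cdna)))
  seg <- map_variant(v, ref)
  ins_seg <- seg[seg$type == "insertion", ]
  expect_equal(nrow(ins_seg), 1L)
  expect_equal(ins_seg$length, 47L)
  expect_equal(nchar(ins_seg$seq), 47L)
})

test_that("unrelated sequences fail the identity gate", {
  set.seed(52)
  ref <- fixture_reference()
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(ref$cdna), TRUE),
                collapse = "")
  expect_error(map_variant(junk, ref), "not a variant")
})

test_that("deletions spanning several exons report the full skipped run", {
  ref <- fixture_reference(n_exons = 12, exon_len = 30)
  b <- c(0L, ref$exon_boundaries_nt, nchar(ref$cdna))
  # deletion of exons 8-10
  v <- paste0(substr(ref$cdna, 1, b[8]),
              substr(ref$cdna, b[11] + 1, nchar(ref$cdna)))
  ev <- classify_events(map_variant(v, ref), ref)
  expect_equal(ev$type, "exon_skip")
  expect_equal(ev$exons, "8-10")
})

test_that("an insertion matching a genomic intron is intron retention", {
  set.seed(53)
  ref <- fixture_reference(n_exons = 5, exon_len = 30)
  intron_seqs <- replicate(4, paste0(
    "GT", paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""), "AG"
  ))
  b4 <- ref$exon_boundaries_nt[4]
  v <- paste0(substr(ref$cdna, 1, b4), intron_seqs[4],
              substr(ref$cdna, b4 + 1, nchar(ref$cdna)))
  ev <- classify_events(map_variant(v, ref), ref, intron_seqs = intron_seqs)
  expect_equal(ev$type, "intron_retention")
  expect_equal(ev$intron, 4L)
  # without genomic introns the same insertion is a flagged mutation
  ev2 <- classify_events(map_variant(v, ref), ref)
  expect_equal(ev2$type, "splice_site_mutation")
  expect_equal(ev2$note, "possible retention")
})

test_that("an interior 7-nt deletion is a splice-site mutation", {
  ref <- fixture_reference(n_exons = 4, exon_len = 30)
  v <- paste0(substr(ref$cdna, 1, 40), substr(ref$cdna, 48, nchar(ref$cdna)))
  ev <- classify_events(map_variant(v, ref), ref)
  expect_equal(ev$type, "splice_site_mutation")
  expect_equal(ev$length, 7L)
})

test_that("indel length bookkeeping balances the cDNA lengths", {
  set.seed(54)
  fam <- simulate_family(sim_config(tree = "(a:0.1,b:0.1);", seed = 54,
                                    n_variants = 6L))
  for (sp in names(fam$leaves)) {
    ref <- fam$leaves[[sp]]$model
    v <- fam$variants[[sp]]$variants
    for (i in seq_len(nrow(v))) {
      seg <- map_variant(v$cdna[i], ref)
      del <- sum(seg$length[seg$type == "deletion"])
      ins <- sum(seg$length[seg$type == "insertion"])
      expect_equal(del - ins, nchar(ref$cdna) - nchar(v$cdna[i]))
      ev <- classify_events(seg, ref,
                            intron_seqs = fam$leaves[[sp]]$intron_seqs)
      expect_equal(nrow(ev), nrow(seg))  # every segment yields one event
    }
  }
})

test_that("frame-preserving skips shorten the protein by the skipped codons", {
  ref <- fixture_reference(n_exons = 6, exon_len = 30)
  b <- c(0L, ref$exon_boundaries_nt, nchar(ref$cdna))
  ref_prot <- translate_cds(ref)$protein
  v <- paste0(substr(ref$cdna, 1, b[3]),
              substr(ref$cdna, b[4] + 1, nchar(ref$cdna)))  # skip exon 3
  orf <- translate_cds(transcript_model("v", v, integer(0)))
  if (orf$orf_retained) {
    expect_equal(nchar(orf$protein), nchar(ref_prot) - 30 / 3)
  }
})

test_that("boundary projection onto the donor itself returns its boundaries", {
  ref <- fixture_reference()
  prot <- translate_cds(ref)$protein
  proj <- infer_boundaries_by_projection(
    list(cdna = ref$cdna, protein = prot, cds_start_nt = 0L),
    list(model = ref, protein = prot)
  )
  expect_equal(proj$exon_boundaries_nt, ref$exon_boundaries_nt)
  expect_equal(attr(proj, "unplaced"), integer(0))
})

test_that("boundaries project exactly onto substitution-only orthologs", {
  fam <- simulate_family(sim_config(
    tree = "(a:0.4,b:0.4);", substitution_rate = 0.3, indel_rate = 0,
    intron_loss_prob = 0, intron_gain_rate = 0, motif_loss_prob = 0,
    n_variants = 0L, seed = 55
  ))
  a <- fam$leaves$a; b <- fam$leaves$b
  proj <- infer_boundaries_by_projection(
    list(cdna = b$model$cdna, protein = b$protein, cds_start_nt = 0L),
    list(model = a$model, protein = a$protein)
  )
  expect_equal(proj$exon_boundaries_nt, b$model$exon_boundaries_nt)
})

test_that("domain status is a pure function of motif statuses", {
  motifs9 <- c("QFP", "T", "1", "2", "A", "Bprime", "C", "D", "E")
  states <- c("present", "partial", "absent")
  grid <- expand.grid(rep(list(states), 9), stringsAsFactors = FALSE)
  trbd_m <- c("QFP", "T")  # CP absent from this reference schema
  rt_m <- c("1", "2", "A", "Bprime", "C", "D", "E")
  for (i in seq_len(nrow(grid))) {
    st <- setNames(unlist(grid[i, ]), motifs9)
    d <- domain_status_from_motifs(st)
    oracle <- function(ms) {
      s <- st[ms]
      if (all(s == "present")) "intact"
      else if (all(s == "absent")) "missing" else "truncated"
    }
    if (d["TRBD"] != oracle(trbd_m) || d["RT"] != oracle(rt_m)) {
      fail(sprintf("mismatch at row %d", i))
    }
  }
  succeed()
})

test_that("annotate_variant calls domains on engineered variants", {
  ref <- fixture_reference(n_exons = 10, exon_len = 30)
  prot <- translate_cds(ref)$protein  # 100 residues
  defs <- motif_definitions(
    c("CP", "QFP", "T", "1", "2", "A", "Bprime", "C", "D", "E"),
    c(5L, 15L, 25L, 40L, 46L, 52L, 58L, 64L, 70L, 76L),
    c(12L, 22L, 32L, 45L, 51L, 57L, 63L, 69L, 75L, 81L),
    "ref1"
  )
  # identity variant: everything intact
  ann <- annotate_variant("v0", ref$cdna, ref, defs, ref_protein = prot)
  expect_equal(unname(ann$domain_status), c("intact", "intact"))
  expect_true(ann$orf$orf_retained)
  expect_equal(nrow(ann$events), 0L)

  # skip the RT-encoding exons 5-9 (residues 40-90): RT missing/truncated,
  # TRBD intact, frame preserved (multiple of 3 by construction)
  b <- c(0L, ref$exon_boundaries_nt, nchar(ref$cdna))
  v <- paste0(substr(ref$cdna, 1, b[5]),
              substr(ref$cdna, b[10] + 1, nchar(ref$cdna)))
  ann2 <- annotate_variant("v1", v, ref, defs, ref_protein = prot)
  expect_equal(ann2$events$type, "exon_skip")
  expect_equal(unname(ann2$domain_status["TRBD"]), "intact")
  expect_equal(unname(ann2$domain_status["RT"]), "missing")
})

test_that("summaries aggregate event, frame and domain counts faithfully", {
  set.seed(56)
  fam <- simulate_family(sim_config(tree = "(a:0.05,b:0.05);", seed = 56,
                                    n_variants = 8L,
                                    frame_preserving_fraction = 1))
  sp <- "a"
  leaf <- fam$leaves[[sp]]
  hm <- leaf$state$motifs
  defs <- motif_definitions(hm$name, hm$start, hm$end, "ref")
  anns <- lapply(seq_len(nrow(fam$variants[[sp]]$variants)), function(i) {
    annotate_variant(fam$variants[[sp]]$variants$id[i],
                     fam$variants[[sp]]$variants$cdna[i],
                     leaf$model, defs, ref_protein = leaf$protein,
                     intron_seqs = leaf$intron_seqs)
  })
  s <- summarize_variants(anns, species = rep(sp, length(anns)))
  expect_equal(nrow(s$per_variant), 8L)
  expect_equal(sum(s$aggregate$n), 8L)  # categories partition the total
  # frame_preserving_fraction 1 => every variant keeps its ORF
  truth_orf <- vapply(fam$variants[[sp]]$truth, `[[`, logical(1),
                      "orf_retained")
  expect_true(all(truth_orf))
  expect_equal(sum(s$orf$n_orf_retained), sum(s$per_variant$orf_retained))
})

test_that("a single intact variant aggregates to one intact/intact cell", {
  ref <- fixture_reference(n_exons = 4, exon_len = 30)
  prot <- translate_cds(ref)$protein
  defs <- motif_definitions(c("QFP", "T", "1"), c(2L, 10L, 20L),
                            c(8L, 16L, 26L), "ref1")
  ann <- annotate_variant("only", ref$cdna, ref, defs, ref_protein = prot)
  s <- summarize_variants(list(ann))
  expect_equal(nrow(s$aggregate), 1L)
  expect_equal(s$aggregate$n, 1L)
  expect_equal(s$aggregate$TRBD, "intact")
  expect_equal(s$aggregate$RT, "intact")
})
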