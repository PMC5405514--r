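# Independent oracles and fixture builders used across the suite.

# Brute-force optimal global affine-gap alignment score by recursive
# enumeration over all alignments (no dynamic programming): a gap of
# length L costs open + L * extend. Feasible for sequences up to ~6.
brute_affine_score <- function(a, b, submat, open, extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) {
      cost <- if (last == 1L) extend else open + extend
      best <- max(best, rec(i + 1L, j, 1L) - cost)
    }
    if (j <= nb) {
      cost <- if (last == 2L) extend else open + extend
      best <- max(best, rec(i, j + 1L, 2L) - cost)
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Score an explicit pairwise alignment under the same affine convention.
score_alignment_rows <- function(x, y, submat, open, extend) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  s <- 0
  last <- 0L
  for (k in seq_along(cx)) {
    gx <- cx[k] %in% c("-", ".")
    gy <- cy[k] %in% c("-", ".")
    if (!gx && !gy) {
      s <- s + submat[cx[k], cy[k]]
      last <- 0L
    } else if (gx) {
      s <- s - extend - if (last == 2L) 0 else open
      last <- 2L
    } else {
      s <- s - extend - if (last == 1L) 0 else open
      last <- 1L
    }
  }
  s
}

# Linear-scan residue<->column map oracle.
scan_map <- function(row) {
  cs <- strsplit(row, "")[[1]]
  col_of_res <- integer(0)
  res_of_col <- rep(NA_integer_, length(cs))
  r <- 0L
  for (cc in seq_along(cs)) {
    if (!cs[cc] %in% c("-", ".")) {
      r <- r + 1L
      col_of_res[r] <- cc
      res_of_col[cc] <- r
    }
  }
  list(col_of_res = col_of_res, res_of_col = res_of_col)
}

# Random gene model on a random genome; returns list(gene, genome).
random_gene_model <- function(n_exons = NULL, strand = NULL) {
  n_exons <- n_exons %||% sample(1:6, 1)
  strand <- strand %||% sample(c("+", "-"), 1)
  exon_lens <- sample(6:60, n_exons, replace = TRUE)
  intron_lens <- if (n_exons > 1) sample(10:50, n_exons - 1, replace = TRUE) else integer(0)
  gstart <- sample(0:20, 1)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- gstart
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i]
    pos <- ends[i] + if (i < n_exons) intron_lens[i] else 0L
  }
  glen <- pos + sample(0:20, 1)
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  gene <- gene_model("g", "chr", strand, cbind(starts, ends),
                     cbind(starts, ends))
  list(gene = gene, genome = genome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small deterministic two-exon reference transcript for splice tests:
# clean ORF, known boundaries.
fixture_reference <- function(n_exons = 6, exon_len = 30, seed = 99) {
  set.seed(seed)
  tab <- Biostrings::GENETIC_CODE
  sense <- names(tab)[tab != "*"]
  n_codons <- n_exons * exon_len / 3
  cdna <- paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
                collapse = "")
  bounds <- seq(exon_len, by = exon_len, length.out = n_exons - 1)
  transcript_model("ref1", cdna, as.integer(bounds))
}
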