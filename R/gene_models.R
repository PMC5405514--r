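# Gene models and transcript-space coordinates.
#
# Coordinate convention: GFF3 input is 1-based inclusive; every internal
# coordinate is a 0-based half-open offset. A transcript exon boundary is
# stored as the offset of the first nucleotide of the downstream exon, i.e.
# the cumulative length of the exons 5' of the intron. Ordinal ranks of
# exons/introns in reports are 1-based.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param seq_region Name of the genomic sequence the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (start, end) of exon intervals,
#'   0-based half-open, in genomic coordinates.
#' @param cds Two-column integer matrix of CDS intervals, same convention;
#'   every CDS interval must be contained in an exon.
#' @param transcript_id Transcript identifier.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_region, strand, exons, cds,
                       transcript_id = gene_id) {
  exons <- as_interval_matrix(exons, "exons")
  cds <- as_interval_matrix(cds, "cds")
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  check_disjoint_sorted(exons, "exons")
  check_disjoint_sorted(cds, "cds")
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    if (!inside) stopf("cds interval [%d,%d) not contained in any exon",
                       cds[i, 1], cds[i, 2])
  }
  if (sum(cds[, 2] - cds[, 1]) < 3L) stopf("total CDS length must be >= 3")
  structure(
    list(gene_id = gene_id, seq_region = seq_region, strand = strand,
         exons = exons, cds = cds, transcript_id = transcript_id),
    class = "gene_model"
  )
}

as_interval_matrix <- function(x, what) {
  m <- matrix(as.integer(as.matrix(x)), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(is.na(m)) || any(m[, 2] <= m[, 1]) || any(m < 0)) {
    stopf("%s must be non-negative intervals with end > start", what)
  }
  m[order(m[, 1]), , drop = FALSE]
}

check_disjoint_sorted <- function(m, what) {
  if (nrow(m) > 1L && any(m[-1, 1] < m[-nrow(m), 2])) {
    stopf("%s intervals overlap", what)
  }
}

#' Read gene models from a GFF3 file
#'
#' Exon and CDS features are collected per `Parent` transcript. GFF3
#' coordinates (1-based inclusive) are converted to the package's 0-based
#' half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param transcript_id Optional transcript to select; required when the
#'   file annotates more than one transcript.
#' @return A named list of `gene_model` objects (all transcripts), or a
#'   single `gene_model` when `transcript_id` is given.
#' @export
read_gene_models <- function(path, transcript_id = NULL) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  gff <- tryCatch(
    as.data.frame(rtracklayer::readGFF(
      path, columns = c("seqid", "type", "start", "end", "strand"),
      tags = c("ID", "Parent", "gene_id")
    )),
    error = function(e) stopf("failed to parse GFF3 '%s': %s", path,
                              conditionMessage(e))
  )
  gff$Parent <- vapply(gff$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  feats <- gff[gff$type %in% c("exon", "CDS") & !is.na(gff$Parent), ,
               drop = FALSE]
  if (nrow(feats) == 0L) stopf("no exon/CDS features with Parent in %s", path)
  tx_ids <- unique(feats$Parent)
  models <- lapply(tx_ids, function(tx) {
    f <- feats[feats$Parent == tx, , drop = FALSE]
    ex <- f[f$type == "exon", c("start", "end"), drop = FALSE]
    cd <- f[f$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0L) stopf("transcript '%s' has no exon features", tx)
    if (nrow(cd) == 0L) stopf("transcript '%s' has no CDS features", tx)
    strand <- unique(as.character(f$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stopf("transcript '%s' has inconsistent or missing strand", tx)
    }
    gid <- f$gene_id[!is.na(f$gene_id)]
    gene_model(
      gene_id = if (length(gid)) gid[1] else tx,
      seq_region = as.character(f$seqid[1]), strand = strand,
      exons = cbind(ex$start - 1L, ex$end),
      cds = cbind(cd$start - 1L, cd$end),
      transcript_id = tx
    )
  })
  names(models) <- tx_ids
  if (!is.null(transcript_id)) {
    if (!transcript_id %in% tx_ids) {
      stopf("transcript '%s' not found in %s (has: %s)", transcript_id,
            path, paste(tx_ids, collapse = ", "))
    }
    return(models[[transcript_id]])
  }
  if (length(models) == 1L) models[[1]] else models
}

#' Write gene models as GFF3
#'
#' @param models A `gene_model` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
    writeLines(sprintf(
      "%s\ttertarch\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
      g$seq_region, span[1] + 1L, span[2], g$strand, g$transcript_id,
      g$gene_id
    ), con)
    emit <- function(type, m, phase = ".") {
      for (i in seq_len(nrow(m))) {
        writeLines(sprintf(
          "%s\ttertarch\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
          g$seq_region, type, m[i, 1] + 1L, m[i, 2], g$strand, phase,
          g$transcript_id
        ), con)
      }
    }
    emit("exon", g$exons)
    emit("CDS", g$cds)
  }
  invisible(path)
}

#' Build a transcript model from a gene model and its genomic sequence
#'
#' Concatenates the exon sequence in transcript orientation (minus-strand
#' genes are reverse-complemented and boundaries recomputed), records each
#' exon boundary as the transcript offset of the first nucleotide of the
#' downstream exon, and locates the CDS in transcript coordinates. A CDS
#' whose joined length is not a multiple of three is kept, flagged with
#' `partial_codon = TRUE`; translation later drops the trailing 1-2 nt.
#'
#' @param gene A `gene_model`.
#' @param genome_seq The genomic sequence of `gene$seq_region` (character).
#' @return An object of class `transcript_model` with fields
#'   `transcript_id`, `cdna`, `exon_boundaries_nt` (0-based offsets),
#'   `cds_start_nt`, `cds_end_nt`, `partial_codon`.
#' @export
build_transcript_model <- function(gene, genome_seq) {
  stopifnot(inherits(gene, "gene_model"))
  genome_seq <- toupper(as.character(genome_seq))
  L <- nchar(genome_seq)
  if (max(gene$exons[, 2]) > L) {
    stopf("gene '%s' extends past end of genomic sequence (%d > %d)",
          gene$gene_id, max(gene$exons[, 2]), L)
  }
  minus <- gene$strand == "-"
  # order exons 5'->3' in transcript orientation
  ord <- order(gene$exons[, 1], decreasing = minus)
  exons <- gene$exons[ord, , drop = FALSE]
  pieces <- substring(genome_seq, exons[, 1] + 1L, exons[, 2])
  if (minus) pieces <- vapply(pieces, revcomp, character(1), USE.NAMES = FALSE)
  cdna <- paste(pieces, collapse = "")
  lens <- exons[, 2] - exons[, 1]
  boundaries <- if (nrow(exons) > 1L) cumsum(lens)[-nrow(exons)] else integer(0)

  # genomic -> transcript offset for a position inside an exon
  g2t <- function(gpos) {
    for (i in seq_len(nrow(exons))) {
      if (gpos >= exons[i, 1] && gpos <= exons[i, 2]) {
        before <- if (i > 1L) sum(lens[seq_len(i - 1L)]) else 0L
        return(if (minus) before + (exons[i, 2] - gpos) else
                 before + (gpos - exons[i, 1]))
      }
    }
    stopf("position %d not inside any exon of '%s'", gpos, gene$gene_id)
  }
  # 5'-most and 3'-most CDS genomic endpoints in transcript orientation
  if (minus) {
    cds_start_nt <- g2t(max(gene$cds[, 2]))
    cds_end_nt <- g2t(min(gene$cds[, 1]))
  } else {
    cds_start_nt <- g2t(min(gene$cds[, 1]))
    cds_end_nt <- g2t(max(gene$cds[, 2]))
  }
  cds_len_genomic <- sum(gene$cds[, 2] - gene$cds[, 1])
  partial <- (cds_len_genomic %% 3L) != 0L
  if (partial) {
    warnf("transcript '%s': CDS length %d is not a multiple of 3; trailing nucleotides will be dropped at translation",
          gene$transcript_id, cds_len_genomic)
  }
  transcript_model(
    transcript_id = gene$transcript_id, cdna = cdna,
    exon_boundaries_nt = as.integer(boundaries),
    cds_start_nt = as.integer(cds_start_nt),
    cds_end_nt = as.integer(cds_end_nt),
    partial_codon = partial
  )
}

#' Construct a transcript model directly
#'
#' @param transcript_id Identifier.
#' @param cdna Spliced transcript sequence (nucleotides).
#' @param exon_boundaries_nt Sorted 0-based transcript offsets of intron
#'   sites: each value is the offset of the first nucleotide of the
#'   downstream exon, so there are `n_exons - 1` of them.
#' @param cds_start_nt,cds_end_nt 0-based half-open CDS span on the cDNA.
#' @param partial_codon Logical flag: CDS length not a multiple of 3.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, cdna, exon_boundaries_nt,
                             cds_start_nt = 0L,
                             cds_end_nt = nchar(cdna),
                             partial_codon = FALSE) {
  cdna <- toupper(cdna)
  b <- as.integer(exon_boundaries_nt)
  n <- nchar(cdna)
  if (length(b) && (any(b <= 0L) || any(b >= n))) {
    stopf("exon boundaries must satisfy 0 < boundary < length(cdna)")
  }
  if (is.unsorted(b, strictly = TRUE) && length(b) > 1L) {
    stopf("exon boundaries must be strictly increasing")
  }
  if (!(cds_start_nt >= 0L && cds_start_nt < cds_end_nt && cds_end_nt <= n)) {
    stopf("need 0 <= cds_start < cds_end <= length(cdna)")
  }
  structure(
    list(transcript_id = transcript_id, cdna = cdna,
         exon_boundaries_nt = b, cds_start_nt = as.integer(cds_start_nt),
         cds_end_nt = as.integer(cds_end_nt),
         partial_codon = isTRUE(partial_codon)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s: %d nt, %d exon(s), CDS [%d,%d)%s\n",
    x$transcript_id, nchar(x$cdna), length(x$exon_boundaries_nt) + 1L,
    x$cds_start_nt, x$cds_end_nt,
    if (x$partial_codon) " [partial trailing codon]" else ""
  ))
  invisible(x)
}

#' Split a cDNA back into exon sequences
#'
#' @param t A `transcript_model`.
#' @return Character vector of exon sequences in transcript order.
#' @export
exon_sequences <- function(t) {
  starts <- c(0L, t$exon_boundaries_nt)
  ends <- c(t$exon_boundaries_nt, nchar(t$cdna))
  substring(t$cdna, starts + 1L, ends)
}

#' Translate the CDS of a transcript model
#'
#' Standard genetic code; translation runs codon by codon from
#' `cds_start_nt`, dropping any trailing partial codon. A stop codon
#' before the final codon is a premature termination codon (PTC); the
#' protein is truncated there and `orf_retained` is `FALSE`. Codons
#' containing ambiguity codes translate to `X`.
#'
#' @param t A `transcript_model`.
#' @return An `orf_report`: list with `protein` (no stops), `ptc_residue_index`
#'   (0-based codon index of the PTC, or `NA`), `orf_retained`.
#' @examples
#' t <- transcript_model("t1", "ATGAAATAA", integer(0))
#' translate_cds(t)
#' @export
translate_cds <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  cds <- substr(t$cdna, t$cds_start_nt + 1L, t$cds_end_nt)
  n_codons <- nchar(cds) %/% 3L
  if (n_codons < 1L) stopf("CDS shorter than one codon")
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  stops <- which(aa == "*")
  if (length(stops) == 0L) {
    prot <- paste(aa, collapse = "")
    ptc <- NA_integer_
  } else {
    first <- stops[1]
    prot <- paste(aa[seq_len(first - 1L)], collapse = "")
    ptc <- if (first < n_codons) first - 1L else NA_integer_
  }
  structure(
    list(protein = prot, ptc_residue_index = ptc,
         orf_retained = is.na(ptc)),
    class = "orf_report"
  )
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf(
    "<orf_report> %d aa; ORF %s%s\n", nchar(x$protein),
    if (x$orf_retained) "retained" else "lost",
    if (!is.na(x$ptc_residue_index))
      sprintf(" (PTC at residue %d)", x$ptc_residue_index) else ""
  ))
  invisible(x)
}
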