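# Intron-position conservation: project exon boundaries into protein
# coordinates, map them through a pairwise alignment with a reference,
# and classify each intron as conserved or species-specific.
#
# An intron position is the triple (transcript_nt offset, 0-based residue
# index of the hosting residue, codon phase). The hosting residue is the
# residue whose codon contains the boundary, or, for a phase-0 boundary,
# the residue immediately after it: residue_index = floor((nt - cds_start)/3),
# phase = (nt - cds_start) mod 3.

#' Project intron positions onto protein coordinates
#'
#' One row per exon boundary lying within the CDS; boundaries in the 5' or
#' 3' UTR are excluded from the result and counted in the `n_utr`
#' attribute.
#'
#' @param t A `transcript_model`.
#' @return A data frame of class `intron_positions` with columns
#'   `transcript_nt`, `residue_index` (0-based), `phase` (0/1/2), plus an
#'   attribute `n_utr`.
#' @examples
#' t <- transcript_model("t", strrep("ATG", 6), exon_boundaries_nt = 9L)
#' project_introns(t)
#' @export
project_introns <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  b <- t$exon_boundaries_nt
  in_cds <- b >= t$cds_start_nt & b < t$cds_end_nt
  bc <- b[in_cds]
  off <- bc - t$cds_start_nt
  out <- data.frame(
    transcript_nt = bc,
    residue_index = off %/% 3L,
    phase = off %% 3L
  )
  attr(out, "n_utr") <- sum(!in_cds)
  class(out) <- c("intron_positions", "data.frame")
  out
}

#' Classify query introns as conserved or species-specific
#'
#' Maps each intron's hosting residue to its alignment column and calls a
#' query intron conserved when some reference intron's column lies within
#' `tolerance` columns (and, optionally, the codon phases match). Each
#' reference intron matches at most one query intron; assignment is
#' greedy by column distance with ties going to the 5'-most intron.
#'
#' @param query_protein,ref_protein Ungapped protein sequences.
#' @param query_introns,ref_introns `intron_positions` data frames (or any
#'   data frame with `residue_index` and `phase`).
#' @param aln Optional `seq_alignment` of the two proteins (query row
#'   first); computed with [global_align()] when `NULL`.
#' @param tolerance Maximum column offset still called conserved
#'   (default 0: exact shared column).
#' @param require_phase Require matching codon phase as well.
#' @return Data frame of class `intron_comparison`: one row per query
#'   intron with `query_rank`, `residue_index`, `phase`, `query_column`,
#'   `matched_ref_rank`, `ref_column`, `status`
#'   (`"conserved"`/`"species_specific"`).
#' @export
classify_introns <- function(query_protein, query_introns,
                             ref_protein, ref_introns, aln = NULL,
                             tolerance = 0L, require_phase = FALSE) {
  stopifnot(tolerance >= 0L)
  if (is.null(aln)) {
    aln <- global_align(query_protein, ref_protein, ids = c("query", "ref"))
  }
  if (degap(aln$seqs[1]) != toupper(query_protein) ||
      degap(aln$seqs[2]) != toupper(ref_protein)) {
    stopf("alignment rows do not degap to the query/reference proteins")
  }
  maps <- build_alignment_map(aln)
  qcol <- intron_columns(query_introns, maps[[1]], nchar(query_protein))
  rcol <- intron_columns(ref_introns, maps[[2]], nchar(ref_protein))

  nq <- nrow(query_introns)
  matched_ref <- rep(NA_integer_, nq)
  if (nq > 0L && nrow(ref_introns) > 0L) {
    cand <- expand.grid(q = seq_len(nq), r = seq_len(nrow(ref_introns)))
    cand$dist <- abs(qcol[cand$q] - rcol[cand$r])
    cand <- cand[cand$dist <= tolerance, , drop = FALSE]
    if (require_phase && nrow(cand) > 0L) {
      cand <- cand[query_introns$phase[cand$q] == ref_introns$phase[cand$r], ,
                   drop = FALSE]
    }
    cand <- cand[order(cand$dist, cand$q, cand$r), , drop = FALSE]
    ref_used <- logical(nrow(ref_introns))
    for (k in seq_len(nrow(cand))) {
      q <- cand$q[k]; r <- cand$r[k]
      if (is.na(matched_ref[q]) && !ref_used[r]) {
        matched_ref[q] <- r
        ref_used[r] <- TRUE
      }
    }
  }
  out <- data.frame(
    query_rank = seq_len(nq),
    residue_index = query_introns$residue_index,
    phase = query_introns$phase,
    query_column = qcol,
    matched_ref_rank = matched_ref,
    ref_column = ifelse(is.na(matched_ref), NA_integer_, rcol[matched_ref]),
    status = ifelse(is.na(matched_ref), "species_specific", "conserved")
  )
  class(out) <- c("intron_comparison", "data.frame")
  out
}

# Column of each intron's hosting residue. A hosting residue index equal
# to the protein length (boundary right at the final codon edge) is
# clamped to the last residue.
intron_columns <- function(introns, map, protein_len) {
  if (nrow(introns) == 0L) return(integer(0))
  r1 <- pmin(introns$residue_index + 1L, protein_len)  # 0-based -> 1-based
  if (any(r1 < 1L | r1 > length(map$col_of_res))) {
    stopf("intron residue index outside the protein")
  }
  map$col_of_res[r1]
}

#' Cross-species intron conservation table
#'
#' Runs [classify_introns()] for every species against a common reference
#' and tabulates the counts, mirroring a conserved/species-specific intron
#' map relative to a reference gene.
#'
#' @param species_set Named list; each element a list with `protein`,
#'   `introns` and optionally `aln` (a precomputed `seq_alignment` with
#'   the species row first).
#' @param reference List with `protein` and `introns`.
#' @param tolerance,require_phase Passed to [classify_introns()].
#' @return Data frame with one row per species: `species`, `n_introns`,
#'   `n_conserved`, `n_specific`, `matched_ref_ranks` (comma-separated
#'   1-based ranks of the matched reference introns).
#' @export
conservation_table <- function(species_set, reference, tolerance = 0L,
                               require_phase = FALSE) {
  stopifnot(length(species_set) >= 1L, !is.null(names(species_set)))
  rows <- lapply(names(species_set), function(sp) {
    s <- species_set[[sp]]
    cmp <- tryCatch(
      classify_introns(s$protein, s$introns, reference$protein,
                       reference$introns, aln = s$aln %||% NULL,
                       tolerance = tolerance,
                       require_phase = require_phase),
      error = function(e) {
        warnf("species '%s' skipped: %s", sp, conditionMessage(e))
        NULL
      }
    )
    if (is.null(cmp)) return(NULL)
    ranks <- sort(cmp$matched_ref_rank[!is.na(cmp$matched_ref_rank)])
    data.frame(
      species = sp,
      n_introns = nrow(cmp),
      n_conserved = sum(cmp$status == "conserved"),
      n_specific = sum(cmp$status == "species_specific"),
      matched_ref_ranks = paste(ranks, collapse = ",")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
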