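# Alternative-splice variant analysis: map a variant cDNA onto the
# full-length isoform (isoform 1), classify structural events (exon
# skipping, intron retention, splice-site mutation), check reading
# frame / premature termination, and call domain truncation from motif
# presence.

#' Map a splice variant onto its full-length reference
#'
#' Globally aligns the variant cDNA to the reference cDNA (nucleotide
#' scores: match 2, mismatch -3, gap open 10, extend 0.5) and extracts
#' maximal gap runs as deletion segments (gap in the variant) or
#' insertion segments (gap in the reference), in reference coordinates.
#'
#' @param variant_cdna Variant cDNA (character).
#' @param ref A `transcript_model` for isoform 1.
#' @param min_identity Minimum identity over aligned non-gap positions;
#'   below this the sequence is rejected as not a variant of this
#'   reference (default 0.8).
#' @param ... Passed to [global_align()] (nucleotide mode).
#' @return Data frame of class `variant_segments`: `type`
#'   (`"deletion"`/`"insertion"`), `ref_start`, `ref_end` (0-based
#'   half-open; equal for insertions, giving the anchor point),
#'   `var_start`, `var_end`, `length`, `seq` (inserted sequence, `""` for
#'   deletions). Attribute `identity` records the aligned identity.
#' @export
map_variant <- function(variant_cdna, ref, min_identity = 0.8, ...) {
  stopifnot(inherits(ref, "transcript_model"))
  aln <- global_align(toupper(variant_cdna), ref$cdna, moltype = "nt",
                      ids = c("variant", "ref"), ...)
  cv <- chars(aln$seqs[1]); cr <- chars(aln$seqs[2])
  gv <- is_gap(cv); gr <- is_gap(cr)
  both <- !gv & !gr
  ident <- sum(both & cv == cr) / sum(both)
  if (ident < min_identity) {
    stopf("not a variant of this reference: aligned identity %.1f%% < %.1f%%",
          100 * ident, 100 * min_identity)
  }
  # cumulative residue counts give coordinates at each column
  ref_off <- cumsum(!gr)   # ref residues consumed up to and incl. column
  var_off <- cumsum(!gv)
  seg <- function(runs, type) {
    if (length(runs) == 0L) return(NULL)
    do.call(rbind, lapply(runs, function(rn) {
      s <- rn[1]; e <- rn[2]
      data.frame(
        type = type,
        ref_start = if (s > 1L) ref_off[s - 1L] else 0L,
        ref_end = ref_off[e],
        var_start = if (s > 1L) var_off[s - 1L] else 0L,
        var_end = var_off[e],
        length = e - s + 1L,
        seq = if (type == "insertion")
          paste(cv[s:e], collapse = "") else ""
      )
    }))
  }
  out <- rbind(
    seg(gap_runs(gv), "deletion"),
    seg(gap_runs(gr), "insertion")
  )
  if (is.null(out)) {
    out <- data.frame(type = character(0), ref_start = integer(0),
                      ref_end = integer(0), var_start = integer(0),
                      var_end = integer(0), length = integer(0),
                      seq = character(0))
  }
  out <- out[order(out$ref_start, out$type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "identity") <- ident
  class(out) <- c("variant_segments", "data.frame")
  out
}

gap_runs <- function(g) {
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i], ends[i]))
}

#' Classify indel segments as splice events
#'
#' A deletion whose both ends lie within `tol_nt` of annotated exon
#' boundaries is an exon-skipping event (with the 1-based ranks of the
#' skipped exons). An insertion whose sequence matches a genomic intron
#' adjacent to its anchor (>= 90% aligned identity) is an intron
#' retention. Everything else is a splice-site mutation; insertions at a
#' boundary with no genomic intron sequence available are additionally
#' flagged `"possible retention"`.
#'
#' @param segments A `variant_segments` data frame from [map_variant()].
#' @param ref A `transcript_model`.
#' @param intron_seqs Optional character vector of genomic intron
#'   sequences, one per exon boundary (in order).
#' @param tol_nt Boundary-matching tolerance in nucleotides (default 3).
#' @return Data frame of class `splice_events`: `type` (`"exon_skip"`,
#'   `"intron_retention"`, `"splice_site_mutation"`), `exons`
#'   (e.g. `"8-10"`), `intron` (rank, retention only), `ref_start`,
#'   `ref_end`, `length`, `note`.
#' @export
classify_events <- function(segments, ref, intron_seqs = NULL, tol_nt = 3L) {
  stopifnot(inherits(ref, "transcript_model"))
  bounds <- c(0L, ref$exon_boundaries_nt, nchar(ref$cdna))
  n_exons <- length(bounds) - 1L
  cs <- chars(ref$cdna)
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    if (s$type == "deletion") {
      # a gap bordered by repeated sequence can slide without changing
      # the variant; scan its equivalence class for a placement whose
      # ends both sit at exon boundaries, nearest placement first
      for (d in slide_offsets(cs, s$ref_start, s$ref_end)) {
        i1 <- nearest_boundary(s$ref_start + d, bounds, tol_nt)
        i2 <- nearest_boundary(s$ref_end + d, bounds, tol_nt)
        if (!is.na(i1) && !is.na(i2) && i2 > i1) {
          return(data.frame(
            type = "exon_skip",
            exons = format_ranks(i1:(i2 - 1L)),
            intron = NA_integer_, ref_start = s$ref_start + d,
            ref_end = s$ref_end + d, length = s$length, note = ""
          ))
        }
      }
      return(data.frame(
        type = "splice_site_mutation", exons = "", intron = NA_integer_,
        ref_start = s$ref_start, ref_end = s$ref_end, length = s$length,
        note = "deletion"
      ))
    }
    # insertion: slide its anchor the same way, preferring a placement
    # at an exon boundary
    q <- chars(s$seq)
    anchors <- insertion_slides(cs, q, s$ref_start)
    pick <- NULL
    for (k in seq_along(anchors)) {
      ib <- nearest_boundary(anchors[[k]]$at, bounds, tol_nt)
      if (!is.na(ib) && ib > 1L && ib <= n_exons) {
        pick <- c(anchors[[k]], list(rank = ib - 1L))
        break
      }
    }
    if (!is.null(pick) && !is.null(intron_seqs)) {
      iseq <- intron_seqs[pick$rank]
      if (!is.na(iseq) && nzchar(iseq) &&
          insertion_matches_intron(pick$seq, iseq)) {
        return(data.frame(
          type = "intron_retention", exons = "", intron = pick$rank,
          ref_start = pick$at, ref_end = pick$at,
          length = s$length, note = ""
        ))
      }
    }
    data.frame(
      type = "splice_site_mutation", exons = "", intron = NA_integer_,
      ref_start = s$ref_start, ref_end = s$ref_end, length = s$length,
      note = if (!is.null(pick) && is.null(intron_seqs))
        "possible retention" else "insertion"
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), exons = character(0),
               intron = integer(0), ref_start = integer(0),
               ref_end = integer(0), length = integer(0),
               note = character(0))
  rownames(out) <- NULL
  class(out) <- c("splice_events", "data.frame")
  out
}

# Shifts d (0, -1, +1, -2, ...) under which a deletion [s,e) of the
# reference can be moved without changing the spliced product: shifting
# left by k is valid when cs[s-j+1] == cs[e-j+1] for j=1..k, and
# symmetrically to the right. Offsets are 0-based half-open; cs is the
# reference split into characters.
slide_offsets <- function(cs, s, e, max_shift = 60L) {
  left <- 0L
  while (left < max_shift && s - left >= 1L &&
         cs[s - left] == cs[e - left]) {
    left <- left + 1L
  }
  right <- 0L
  while (right < max_shift && e + right + 1L <= length(cs) &&
         cs[s + right + 1L] == cs[e + right + 1L]) {
    right <- right + 1L
  }
  d <- seq(-left, right)
  d[order(abs(d), d)]
}

# All equivalent placements of an insertion (anchor + rotated sequence),
# ordered by distance from the aligned anchor.
insertion_slides <- function(cs, q, at, max_shift = 60L) {
  m <- length(q)
  out <- list(list(at = at, seq = paste(q, collapse = "")))
  ql <- q; al <- at
  for (k in seq_len(max_shift)) {
    if (al >= 1L && ql[m] == cs[al]) {
      ql <- c(cs[al], ql[-m])
      al <- al - 1L
      out[[length(out) + 1L]] <- list(at = al,
                                      seq = paste(ql, collapse = ""))
    } else break
  }
  qr <- q; ar <- at
  for (k in seq_len(max_shift)) {
    if (ar + 1L <= length(cs) && qr[1] == cs[ar + 1L]) {
      qr <- c(qr[-1], cs[ar + 1L])
      ar <- ar + 1L
      out[[length(out) + 1L]] <- list(at = ar,
                                      seq = paste(qr, collapse = ""))
    } else break
  }
  out[order(vapply(out, function(x) abs(x$at - at), numeric(1)))]
}

nearest_boundary <- function(pos, bounds, tol) {
  d <- abs(bounds - pos)
  i <- which.min(d)
  if (d[i] <= tol) i else NA_integer_
}

format_ranks <- function(r) {
  if (length(r) == 1L) as.character(r) else
    paste0(min(r), "-", max(r))
}

insertion_matches_intron <- function(ins, intron, min_identity = 0.9) {
  if (abs(nchar(ins) - nchar(intron)) > 0.2 * nchar(intron)) return(FALSE)
  aln <- global_align(ins, intron, moltype = "nt", ids = c("ins", "intron"))
  pair_identity(aln$seqs[1], aln$seqs[2], "ungapped") >= 100 * min_identity
}

#' Project exon-intron boundaries from a donor species
#'
#' Transfers each donor intron through a protein alignment onto a target
#' isoform-1 sequence lacking genomic data, producing putative
#' transcript-space boundaries: the donor intron's hosting residue is
#' mapped to its target residue and converted back to a cDNA offset using
#' the donor codon phase. Boundaries whose hosting residue aligns to a
#' gap in the target row are flagged unplaced.
#'
#' @param target List with `cdna`, `protein` and `cds_start_nt`
#'   (0-based offset of the start codon on the target cDNA; default 0).
#' @param donor List with `model` (a `transcript_model`) and `protein`.
#' @param aln Optional `seq_alignment` (donor row first); computed when
#'   `NULL`.
#' @param max_unplaced_frac Error when more than this fraction of donor
#'   boundaries cannot be placed (default 0.5).
#' @return A `transcript_model` for the target with putative boundaries;
#'   attribute `unplaced` lists donor intron ranks that could not be
#'   transferred.
#' @export
infer_boundaries_by_projection <- function(target, donor, aln = NULL,
                                           max_unplaced_frac = 0.5) {
  stopifnot(inherits(donor$model, "transcript_model"))
  if (is.null(aln)) {
    aln <- global_align(donor$protein, target$protein,
                        ids = c("donor", "target"))
  }
  if (degap(aln$seqs[1]) != toupper(donor$protein) ||
      degap(aln$seqs[2]) != toupper(target$protein)) {
    stopf("alignment rows do not degap to the donor/target proteins")
  }
  maps <- build_alignment_map(aln)
  dintrons <- project_introns(donor$model)
  cds_start <- as.integer(target$cds_start_nt %||% 0L)
  placed <- integer(0)
  unplaced <- integer(0)
  for (k in seq_len(nrow(dintrons))) {
    r1 <- dintrons$residue_index[k] + 1L
    col <- maps[[1]]$col_of_res[min(r1, length(maps[[1]]$col_of_res))]
    tres <- maps[[2]]$res_of_col[col]
    if (is.na(tres)) {
      unplaced <- c(unplaced, k)
      next
    }
    b <- cds_start + 3L * (tres - 1L) + dintrons$phase[k]
    if (b <= 0L || b >= nchar(target$cdna)) {
      unplaced <- c(unplaced, k)
      next
    }
    placed <- c(placed, b)
  }
  if (nrow(dintrons) > 0L &&
      length(unplaced) / nrow(dintrons) > max_unplaced_frac) {
    stopf("projection unreliable: %d of %d boundaries unplaced",
          length(unplaced), nrow(dintrons))
  }
  out <- transcript_model(
    transcript_id = target$transcript_id %||% "projected",
    cdna = target$cdna,
    exon_boundaries_nt = sort(unique(placed)),
    cds_start_nt = cds_start,
    cds_end_nt = as.integer(target$cds_end_nt %||% nchar(target$cdna))
  )
  attr(out, "unplaced") <- unplaced
  out
}

#' Domain status from motif presence
#'
#' Pure derivation of domain status from the statuses of the motifs a
#' domain comprises: `intact` iff all present, `missing` iff all absent,
#' `truncated` otherwise. By default TRBD = {CP, QFP, T} and
#' RT = {1, 2, A, Bprime, C, D, E}, restricted to motifs actually
#' annotated on the reference (e.g. TRBD = {QFP, T} where the reference
#' lacks CP).
#'
#' @param motif_status Named character vector of
#'   `present`/`partial`/`absent` per motif.
#' @param domains Named list of motif-name vectors (default TRBD/RT).
#' @return Named character vector of `intact`/`truncated`/`missing` per
#'   domain.
#' @export
domain_status_from_motifs <- function(motif_status,
                                      domains = list(
                                        TRBD = c("CP", "QFP", "T"),
                                        RT = c("1", "2", "A", "Bprime",
                                               "C", "D", "E")
                                      )) {
  vapply(domains, function(ms) {
    ms <- ms[ms %in% names(motif_status)]
    if (length(ms) == 0L) return(NA_character_)
    st <- motif_status[ms]
    if (all(st == "present")) "intact"
    else if (all(st == "absent")) "missing"
    else "truncated"
  }, character(1))
}

#' Annotate a splice variant
#'
#' Full structural annotation of one variant against isoform 1: indel
#' segments, splice-event classes, translation in the reference reading
#' frame (from the image of the reference start codon), motif presence on
#' the variant protein (via protein alignment to the reference), and
#' TRBD/RT domain status.
#'
#' @param variant_id Identifier for reports.
#' @param variant_cdna Variant cDNA; `NULL` when only a protein is
#'   available (nt-level event typing is then skipped).
#' @param variant_protein Optional variant protein (required when
#'   `variant_cdna` is `NULL`).
#' @param ref A `transcript_model` for isoform 1.
#' @param ref_protein Reference protein (default: translated from `ref`).
#' @param defs `motif_definitions` on the reference protein.
#' @param intron_seqs,tol_nt Passed to [classify_events()].
#' @param thresholds Passed to [transfer_motifs()].
#' @param domains Passed to [domain_status_from_motifs()].
#' @return Object of class `variant_annotation`: list with `variant_id`,
#'   `events`, `segments`, `orf` (an `orf_report` or `NULL`),
#'   `motif_status`, `domain_status`, `level` (`"nt"` or `"aa"`).
#' @export
annotate_variant <- function(variant_id, variant_cdna, ref,
                             defs, variant_protein = NULL,
                             ref_protein = NULL,
                             intron_seqs = NULL, tol_nt = 3L,
                             thresholds = c(present = 0.70, partial = 0.20),
                             domains = list(
                               TRBD = c("CP", "QFP", "T"),
                               RT = c("1", "2", "A", "Bprime", "C", "D", "E")
                             )) {
  stopifnot(inherits(ref, "transcript_model"),
    inherits(defs, "motif_definitions"))
  ref_protein <- ref_protein %||% translate_cds(ref)$protein
  level <- if (is.null(variant_cdna)) "aa" else "nt"
  segments <- NULL; events <- NULL; orf <- NULL
  if (level == "nt") {
    segments <- map_variant(variant_cdna, ref)
    events <- classify_events(segments, ref, intron_seqs = intron_seqs,
                              tol_nt = tol_nt)
    orf <- translate_variant_in_ref_frame(variant_cdna, ref)
    variant_protein <- orf$protein
  } else if (is.null(variant_protein)) {
    stopf("need variant_cdna or variant_protein")
  }
  if (is.null(variant_protein) || !nzchar(variant_protein)) {
    motif_status <- stats::setNames(rep("absent", nrow(defs)), defs$name)
  } else {
    paln <- global_align(variant_protein, ref_protein,
                         ids = c(variant_id, defs$reference_id[1]))
    calls <- transfer_motifs(paln, defs, thresholds = thresholds)
    motif_status <- stats::setNames(calls$status, calls$motif)
  }
  structure(
    list(variant_id = variant_id, level = level, segments = segments,
         events = events, orf = orf, motif_status = motif_status,
         domain_status = domain_status_from_motifs(motif_status, domains)),
    class = "variant_annotation"
  )
}

# Translate a variant cDNA in the reference reading frame: locate the
# image of the reference CDS start on the variant via the nt alignment,
# then translate from there to the first stop.
translate_variant_in_ref_frame <- function(variant_cdna, ref) {
  aln <- global_align(toupper(variant_cdna), ref$cdna, moltype = "nt",
                      ids = c("variant", "ref"))
  maps <- build_alignment_map(aln)
  ref_map <- maps[[2]]; var_map <- maps[[1]]
  start_res <- ref$cds_start_nt + 1L  # 1-based ref nt of start codon
  if (start_res > length(ref_map$col_of_res)) {
    stopf("reference CDS start outside reference")
  }
  # first variant nt aligned at or after the ref start position
  col <- ref_map$col_of_res[start_res]
  vres <- var_map$res_of_col[col]
  if (is.na(vres)) {
    later <- var_map$res_of_col[seq(col, alignment_width(aln))]
    later <- later[!is.na(later)]
    if (length(later) == 0L) {
      return(structure(
        list(protein = "", ptc_residue_index = NA_integer_,
             orf_retained = FALSE, reason = "no start"),
        class = "orf_report"
      ))
    }
    vres <- later[1]
  }
  vstart <- vres - 1L  # 0-based offset on variant
  if (nchar(variant_cdna) - vstart < 3L) {
    return(structure(
      list(protein = "", ptc_residue_index = NA_integer_,
           orf_retained = FALSE, reason = "no start"),
      class = "orf_report"
    ))
  }
  t <- transcript_model("variant_frame", variant_cdna, integer(0),
                        cds_start_nt = vstart,
                        cds_end_nt = nchar(variant_cdna))
  translate_cds(t)
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat(sprintf("<variant_annotation> %s (%s level)\n", x$variant_id, x$level))
  if (!is.null(x$events) && nrow(x$events)) {
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s[%s]", x$events$type,
                              ifelse(nzchar(x$events$exons), x$events$exons,
                                     x$events$length)),
                      collapse = ", ")))
  }
  if (!is.null(x$orf)) {
    cat(sprintf("  ORF %s\n",
                if (x$orf$orf_retained) "retained" else "lost"))
  }
  cat(sprintf("  domains: %s\n",
              paste(names(x$domain_status), x$domain_status, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Summarize a set of variant annotations
#'
#' @param annotations List of `variant_annotation` objects.
#' @param species Optional character vector (one per annotation) for
#'   per-species aggregation.
#' @return List with `per_variant` (one row per variant: events, frame,
#'   PTC, TRBD, RT) and `aggregate` (counts per domain-status
#'   combination, plus ORF retention; counts over categories sum to the
#'   total).
#' @export
summarize_variants <- function(annotations, species = NULL) {
  stopifnot(length(annotations) >= 1L)
  species <- species %||% rep("all", length(annotations))
  per <- do.call(rbind, lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    ev <- if (!is.null(a$events) && nrow(a$events)) {
      paste(sprintf("%s(%s)", a$events$type,
                    ifelse(nzchar(a$events$exons), a$events$exons,
                           a$events$length)), collapse = ";")
    } else ""
    data.frame(
      variant_id = a$variant_id, species = species[i], level = a$level,
      events = ev,
      n_events = if (is.null(a$events)) NA_integer_ else nrow(a$events),
      orf_retained = if (is.null(a$orf)) NA else a$orf$orf_retained,
      ptc = if (is.null(a$orf)) NA_integer_ else a$orf$ptc_residue_index,
      TRBD = unname(a$domain_status["TRBD"]),
      RT = unname(a$domain_status["RT"])
    )
  }))
  rownames(per) <- NULL
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(per))) ~ species + TRBD + RT, data = per, FUN = sum
  )
  orf_agg <- data.frame(
    species = unique(per$species),
    n_variants = as.vector(table(per$species)[unique(per$species)]),
    n_orf_retained = vapply(unique(per$species), function(sp) {
      sum(per$orf_retained[per$species == sp], na.rm = TRUE)
    }, integer(1))
  )
  rownames(orf_agg) <- NULL
  list(per_variant = per, aggregate = agg, orf = orf_agg)
}
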