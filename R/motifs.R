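# Motif annotation transfer, conservation-frequency profiles and
# lineage-restricted conserved-block mining.
#
# Reference motif intervals (e.g. the canonical TERT motifs GQ, CP, QFP,
# T, 1, 2, A, B', C, D, E plus the DAT sub-region, the N-terminal linker
# and the CTE) are given as 0-based half-open residue ranges on a named
# reference sequence and transferred to the other rows of a multiple
# alignment containing that reference.

CANONICAL_MOTIFS <- c("GQ", "CP", "QFP", "T", "1", "2", "A", "Bprime",
                      "C", "D", "E", "DAT", "linker", "CTE")

#' Construct a motif definition set
#'
#' @param name Motif names (e.g. `"GQ"`, `"CP"`, `"QFP"`, `"T"`, `"1"`,
#'   `"2"`, `"A"`, `"Bprime"`, `"C"`, `"D"`, `"E"`, `"DAT"`, `"linker"`,
#'   `"CTE"`, or user-defined).
#' @param start,end 0-based half-open residue intervals on the reference.
#' @param reference_id Id of the reference sequence carrying the
#'   coordinates.
#' @return Data frame of class `motif_definitions`.
#' @details Intervals on one reference must be non-overlapping, with two
#'   exceptions mirroring TERT domain nomenclature: `DAT` may lie inside
#'   `GQ`, and the derived regions `linker` (between GQ and CP) and `CTE`
#'   (after motif E) are exempt from the overlap check.
#' @export
motif_definitions <- function(name, start, end, reference_id) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  d <- data.frame(
    name = as.character(name), start = as.integer(start),
    end = as.integer(end), reference_id = reference_id,
    stringsAsFactors = FALSE
  )
  if (any(d$end <= d$start) || any(d$start < 0L)) {
    stopf("motif intervals must satisfy 0 <= start < end")
  }
  if (anyDuplicated(d$name)) stopf("duplicate motif names")
  core <- d[!d$name %in% c("DAT", "linker", "CTE"), , drop = FALSE]
  if (nrow(core) > 1L) {
    o <- core[order(core$start), ]
    if (any(o$start[-1] < o$end[-nrow(o)])) {
      stopf("motif intervals overlap on the reference")
    }
  }
  if ("DAT" %in% d$name && "GQ" %in% d$name) {
    dat <- d[d$name == "DAT", ]; gq <- d[d$name == "GQ", ]
    if (dat$start < gq$start || dat$end > gq$end) {
      stopf("DAT must lie inside GQ")
    }
  }
  class(d) <- c("motif_definitions", "data.frame")
  d
}

#' Read motif definitions from a JSON config
#'
#' The JSON holds `reference_id` and a `motifs` array of
#' `{name, start, end}` with 0-based half-open residue coordinates.
#' Two packaged reference annotations ship with the package (approximate
#' literature-based coordinates, intended to be overridden with exact
#' ones where available):
#' `system.file("extdata/motifs/hTERT_motifs.json", package = "tertarch")`
#' and `.../celegans_TERT_motifs.json`.
#'
#' @param path Path to the JSON file.
#' @return A `motif_definitions` data frame.
#' @export
read_motif_config <- function(path) {
  if (!file.exists(path)) stopf("motif config not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$motifs) || is.null(cfg$reference_id)) {
    stopf("motif config must contain 'reference_id' and 'motifs'")
  }
  motif_definitions(cfg$motifs$name, cfg$motifs$start, cfg$motifs$end,
                    cfg$reference_id)
}

#' Transfer reference motif annotations through an alignment
#'
#' For every non-reference row and every motif, computes coverage = the
#' fraction of reference motif columns aligned to a residue (not a gap)
#' in the target row, and calls status `present` (coverage >= present
#' threshold), `partial` (>= partial threshold) or `absent`. The target
#' interval is the smallest 0-based half-open residue range spanning the
#' aligned positions.
#'
#' @param aln A `seq_alignment` containing the reference row.
#' @param defs A `motif_definitions` whose `reference_id` matches a row id.
#' @param thresholds Named numeric: `present` and `partial` coverage
#'   cut-offs (defaults 0.70 / 0.20).
#' @return Data frame of class `motif_calls`: `target_id`, `motif`,
#'   `coverage`, `status`, `target_start`, `target_end` (NA when absent
#'   with zero coverage).
#' @export
transfer_motifs <- function(aln, defs,
                            thresholds = c(present = 0.70, partial = 0.20)) {
  stopifnot(inherits(aln, "seq_alignment"),
    inherits(defs, "motif_definitions"))
  ref_id <- defs$reference_id[1]
  ri <- match(ref_id, aln$ids)
  if (is.na(ri)) stopf("reference row '%s' absent from alignment", ref_id)
  maps <- build_alignment_map(aln)
  ref_map <- maps[[ri]]
  ref_len <- length(ref_map$col_of_res)
  if (any(defs$end > ref_len)) {
    stopf("motif interval extends past the reference length (%d)", ref_len)
  }
  targets <- setdiff(seq_along(aln$ids), ri)
  out <- list()
  for (ti in targets) {
    tmap <- maps[[ti]]
    for (k in seq_len(nrow(defs))) {
      cols <- ref_map$col_of_res[(defs$start[k] + 1L):defs$end[k]]
      tres <- tmap$res_of_col[cols]
      cov <- mean(!is.na(tres))
      status <- if (cov >= thresholds[["present"]]) "present"
        else if (cov >= thresholds[["partial"]]) "partial" else "absent"
      hit <- tres[!is.na(tres)]
      out[[length(out) + 1L]] <- data.frame(
        target_id = aln$ids[ti], motif = defs$name[k], coverage = cov,
        status = status,
        target_start = if (length(hit)) min(hit) - 1L else NA_integer_,
        target_end = if (length(hit)) max(hit) else NA_integer_
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("motif_calls", "data.frame")
  res
}

#' Per-column conservation-frequency profile
#'
#' For each alignment column, the modal (most frequent) non-gap residue
#' and its frequency among non-gap residues — a frequency of 1.0 means
#' every sequence with a residue at that column agrees. Columns that are
#' all gaps are dropped. Ties between residues break alphabetically.
#'
#' @param aln A `seq_alignment` with >= 2 rows.
#' @param columns Optional integer range of columns (default: all).
#' @param denominator `"nongap"` (default) divides by the number of
#'   non-gap residues in the column; `"all"` divides by the number of
#'   rows.
#' @return Data frame of class `conservation_profile`: `column`,
#'   `consensus`, `frequency`, `n_nongap`.
#' @export
conservation_profile <- function(aln, columns = NULL,
                                 denominator = c("nongap", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "seq_alignment"))
  if (length(aln$ids) < 2L) stopf("profile needs >= 2 rows")
  columns <- columns %||% seq_len(alignment_width(aln))
  if (length(columns) == 0L) stopf("empty column range")
  mat <- alignment_matrix(aln)
  rows <- lapply(columns, function(cc) {
    col <- mat[, cc]
    col <- col[!is_gap(col)]
    if (length(col) == 0L) return(NULL)
    tab <- table(col)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    denom <- if (denominator == "nongap") length(col) else nrow(mat)
    data.frame(column = cc, consensus = modal,
               frequency = as.numeric(max(tab)) / denom,
               n_nongap = length(col))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conservation_profile", "data.frame")
  out
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

#' Mine clade-restricted conserved blocks
#'
#' Scans the alignment for maximal runs of columns where, within a clade
#' of interest, at most `max_states` residues cover at least `f_within`
#' of the clade members (gaps count against coverage) while the modal
#' residue frequency outside the clade stays below `f_background_max`.
#' A failing column inside a run is rendered `x` when flanked by at least
#' two passing columns on each side. Runs shorter than
#' `min_block_length` are discarded. The consensus uses one letter where
#' a single state suffices and `(A/B)` where two states are needed —
#' the notation used for degenerate lineage-specific motifs such as
#' `(I/V)QQRVxLQF`.
#'
#' @param aln A `seq_alignment`.
#' @param clade_labels Named character vector mapping every row id to a
#'   clade label.
#' @param clade Label of the clade of interest (>= 3 members required).
#' @param f_within Minimum within-clade coverage per column (default 0.8).
#' @param max_states Maximum residues in a degenerate position (default 2).
#' @param min_block_length Minimum run length in columns (default 4).
#' @param f_background_max Maximum outside-clade modal frequency
#'   (default 0.5); ignored when the clade covers all rows.
#' @return Data frame of class `conserved_blocks`: `clade`, `col_start`,
#'   `col_end` (1-based inclusive), `consensus`, `mean_frequency`.
#' @export
find_conserved_blocks <- function(aln, clade_labels, clade,
                                  f_within = 0.8, max_states = 2L,
                                  min_block_length = 4L,
                                  f_background_max = 0.5) {
  stopifnot(inherits(aln, "seq_alignment"))
  if (!all(aln$ids %in% names(clade_labels))) {
    stopf("every alignment row must have a clade label")
  }
  lab <- clade_labels[aln$ids]
  in_clade <- lab == clade
  if (sum(in_clade) < 3L) stopf("clade '%s' has fewer than 3 members", clade)
  mat <- alignment_matrix(aln)
  w <- ncol(mat)
  n_clade <- sum(in_clade)

  col_call <- function(cc) {
    col <- mat[in_clade, cc]
    res <- col[!is_gap(col)]
    if (length(res) == 0L) {
      return(list(pass = FALSE))
    }
    tab <- sort(table(res), decreasing = TRUE)
    # deterministic order among equal counts: alphabetical
    tab <- tab[order(-as.numeric(tab), names(tab))]
    k <- min(max_states, length(tab))
    states <- names(tab)[seq_len(k)]
    need <- which(cumsum(as.numeric(tab[seq_len(k)])) / n_clade >= f_within)
    if (length(need) == 0L) {
      return(list(pass = FALSE))
    }
    used <- states[seq_len(need[1])]
    covg <- sum(as.numeric(tab[used])) / n_clade
    if (any(!in_clade)) {
      bg <- mat[!in_clade, cc]
      bg <- bg[!is_gap(bg)]
      if (length(bg) > 0L) {
        if (max(table(bg)) / length(bg) >= f_background_max) {
          return(list(pass = FALSE))
        }
      }
    }
    cons <- if (length(used) == 1L) used else
      paste0("(", paste(sort(used), collapse = "/"), ")")
    list(pass = TRUE, consensus = cons, frequency = covg)
  }

  calls <- lapply(seq_len(w), col_call)
  pass <- vapply(calls, `[[`, logical(1), "pass")
  # bridge single failing columns flanked by >= 2 passing columns each side
  bridge <- rep(FALSE, w)
  for (cc in seq_len(w)) {
    if (!pass[cc] && cc > 2L && cc < w - 1L &&
        all(pass[c(cc - 2L, cc - 1L, cc + 1L, cc + 2L)])) {
      bridge[cc] <- TRUE
    }
  }
  keep <- pass | bridge
  blocks <- list()
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    # trim to passing columns at the edges
    while (s <= e && !pass[s]) s <- s + 1L
    while (e >= s && !pass[e]) e <- e - 1L
    if (e - s + 1L < min_block_length) next
    cons <- vapply(s:e, function(cc) {
      if (pass[cc]) calls[[cc]]$consensus else "x"
    }, character(1))
    freqs <- vapply((s:e)[pass[s:e]], function(cc) calls[[cc]]$frequency,
                    numeric(1))
    blocks[[length(blocks) + 1L]] <- data.frame(
      clade = clade, col_start = s, col_end = e,
      consensus = paste(cons, collapse = ""),
      mean_frequency = mean(freqs)
    )
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(clade = character(0), col_start = integer(0),
               col_end = integer(0), consensus = character(0),
               mean_frequency = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("conserved_blocks", "data.frame")
  out
}
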