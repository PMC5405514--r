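# Pairwise global alignment, alignment coordinate maps and percent
# identity. Multiple alignments are imported (aligned FASTA); only
# pairwise alignment is computed here, as a standard affine-gap
# Needleman-Wunsch (via Biostrings), with a gap of length L costing
# gap_open + L * gap_extend.

#' Construct an alignment object from gapped rows
#'
#' @param ids Character vector of row ids.
#' @param seqs Character vector of gapped sequences (gap = `-` or `.`),
#'   all the same length.
#' @param score Optional alignment score.
#' @return An object of class `seq_alignment`.
#' @export
new_alignment <- function(ids, seqs, score = NA_real_) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stopf("alignment rows have unequal lengths")
  if (w == 0L) stopf("alignment has zero columns")
  if (anyDuplicated(ids)) stopf("duplicate alignment row ids")
  structure(
    list(ids = as.character(ids), seqs = toupper(as.character(seqs)),
         score = score),
    class = "seq_alignment"
  )
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d row(s) x %d column(s)%s\n",
              length(x$ids), nchar(x$seqs[1]),
              if (!is.na(x$score)) sprintf(", score %.1f", x$score) else ""))
  show <- function(s) if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  for (i in seq_along(x$ids)) {
    cat(sprintf("  %-12s %s\n", x$ids[i], show(x$seqs[i])))
  }
  invisible(x)
}

#' Number of columns in an alignment
#' @param aln A `seq_alignment`.
#' @export
alignment_width <- function(aln) nchar(aln$seqs[1])

#' Read an aligned FASTA file
#'
#' @inheritParams read_fasta
#' @return A `seq_alignment`.
#' @export
read_alignment <- function(path) {
  rec <- read_fasta_allow_gaps(path)
  new_alignment(rec$id, rec$seq)
}

read_fasta_allow_gaps <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA file is empty: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate FASTA ids in %s", path)
  data.frame(id = ids, seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A `seq_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(data.frame(id = aln$ids, seq = aln$seqs), path)
}

#' Load a substitution matrix
#'
#' Returns a built-in Biostrings matrix by name, or parses an NCBI-format
#' matrix file (comment lines starting `#`, a header row of residues, one
#' labelled row per residue).
#'
#' @param name_or_path `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`, ... or a
#'   file path.
#' @return A numeric substitution matrix.
#' @export
load_substitution_matrix <- function(name_or_path = "BLOSUM62") {
  builtins <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (name_or_path %in% builtins) {
    e <- new.env()
    utils::data(list = name_or_path, package = "Biostrings", envir = e)
    return(get(name_or_path, envir = e))
  }
  if (!file.exists(name_or_path)) {
    stopf("substitution matrix '%s' is neither a built-in nor a file",
          name_or_path)
  }
  lines <- readLines(name_or_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  m <- matrix(NA_real_, length(lines) - 1L, length(cols))
  rn <- character(length(lines) - 1L)
  for (i in seq_along(rn)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    rn[i] <- f[1]
    m[i, ] <- as.numeric(f[-1])
  }
  dimnames(m) <- list(rn, cols)
  m
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment. A gap of length L costs
#' `gap_open + L * gap_extend`. Protein mode (default) scores with
#' BLOSUM62 and allows the 20 amino acids plus `X`; nucleotide mode uses
#' a match/mismatch matrix.
#'
#' @param a,b Sequences to align (character).
#' @param moltype `"aa"` or `"nt"`.
#' @param matrix Substitution matrix or name (protein mode); see
#'   [load_substitution_matrix()].
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @param match,mismatch Nucleotide-mode scores.
#' @param ids Row ids for the result.
#' @return A `seq_alignment` with two rows and a `score`.
#' @examples
#' global_align("MKVLL", "MKLL")
#' @export
global_align <- function(a, b, moltype = c("aa", "nt"),
                         matrix = "BLOSUM62",
                         gap_open = if (moltype == "aa") 11 else 10,
                         gap_extend = if (moltype == "aa") 1 else 0.5,
                         match = 2, mismatch = -3,
                         ids = c("a", "b")) {
  moltype <- match.arg(moltype)
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stopf("cannot align an empty sequence")
  if (moltype == "aa") {
    ok <- c(AA_ALPHABET_STRICT, "X")
    bad <- unique(c(chars(a), chars(b)))
    bad <- bad[!bad %in% ok]
    if (length(bad)) {
      stopf("non-amino-acid characters in input: %s",
            paste(bad, collapse = ", "))
    }
    submat <- if (is.character(matrix)) load_substitution_matrix(matrix) else matrix
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global"
    )
  } else {
    check_alphabet(a, "nt", "a"); check_alphabet(b, "nt", "b")
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE
    )
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global"
    )
  }
  aln <- new_alignment(
    ids,
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa))),
    score = Biostrings::score(pa)
  )
  stopifnot(degap(aln$seqs[1]) == a, degap(aln$seqs[2]) == b)
  aln
}

#' Percent identity of an alignment
#'
#' For each pair of rows, identical non-gap column pairs are divided by a
#' denominator chosen by `mode`:
#' * `"aligned"` (default) — all columns between the first and last
#'   position where both rows have residues (terminal gap columns
#'   excluded, internal gaps counted against identity);
#' * `"ungapped"` — only columns where both rows have residues.
#' With more than two rows the mean over all pairs is returned.
#'
#' @param aln A `seq_alignment` with >= 2 rows.
#' @param mode Denominator mode, see above.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity(new_alignment(c("x", "y"), c("AAAA", "AAAG")))
#' @export
percent_identity <- function(aln, mode = c("aligned", "ungapped")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "seq_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stopf("percent identity needs at least 2 rows")
  pairs <- utils::combn(n, 2)
  vals <- apply(pairs, 2, function(ij) {
    pair_identity(aln$seqs[ij[1]], aln$seqs[ij[2]], mode)
  })
  mean(vals)
}

pair_identity <- function(x, y, mode) {
  cx <- chars(x); cy <- chars(y)
  gx <- is_gap(cx); gy <- is_gap(cy)
  core <- which(!gx & !gy)
  if (length(core) == 0L) stopf("zero-length overlap between aligned rows")
  span <- seq(min(core), max(core))
  both <- !gx[span] & !gy[span]
  ident <- sum(both & cx[span] == cy[span])
  denom <- switch(mode, aligned = length(span), ungapped = sum(both))
  100 * ident / denom
}

#' Bidirectional residue/column maps for an alignment
#'
#' For each row, `col_of_res[r]` is the alignment column (1-based) of the
#' row's r-th residue, and `res_of_col[c]` the residue rank at column c
#' (`NA` at gap columns). Both maps are strictly increasing.
#'
#' @param aln A `seq_alignment`.
#' @return Named list (by row id) of lists with `col_of_res`,
#'   `res_of_col`.
#' @export
build_alignment_map <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  maps <- lapply(aln$seqs, function(s) {
    g <- is_gap(chars(s))
    col_of_res <- which(!g)
    res_of_col <- rep(NA_integer_, length(g))
    res_of_col[!g] <- seq_along(col_of_res)
    list(col_of_res = col_of_res, res_of_col = res_of_col)
  })
  names(maps) <- aln$ids
  maps
}
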