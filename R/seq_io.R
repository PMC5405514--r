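# FASTA input/output and the sequence-record table.
#
# Records carry an id, an optional species tag and a moltype. Species
# metadata is read from a "[species=...]" bracket tag in the FASTA header,
# with an optional sidecar TSV (id, species, clade) as fallback.

#' Read sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a data frame of
#' sequence records. The first whitespace-delimited token of each header is
#' the record id; a `[species=...]` tag anywhere in the header sets the
#' species field, otherwise species is `""` (or is filled from `metadata`).
#'
#' @param path Path to a FASTA file.
#' @param moltype `"auto"` (default) guesses nucleotide vs amino acid from
#'   residue content; `"nt"` or `"aa"` force a type and validate the
#'   alphabet (IUPAC nucleotides incl. N, or the 20 amino acids plus X
#'   and `*`).
#' @param metadata Optional path to a sidecar TSV with columns `id`,
#'   `species` (and optionally `clade`) used for records lacking a
#'   bracket tag.
#' @return A data frame of class `seq_records` with columns `id`,
#'   `species`, `seq`, `moltype` (and `clade` when the sidecar provides it).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 [species=Homo sapiens]", "MKVL", ">s2", "MKII"), fa)
#' read_fasta(fa, moltype = "aa")
#' @export
read_fasta <- function(path, moltype = c("auto", "nt", "aa"),
                       metadata = NULL) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA file is empty: %s", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  }
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("\\[species=[^]]*\\]", h))
    if (length(m) == 0L) "" else sub("\\[species=([^]]*)\\]", "\\1", m)
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stopf("empty sequence for id(s): %s", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  mt <- if (moltype == "auto") guess_moltype(seqs) else rep(moltype, length(seqs))
  rec <- data.frame(
    id = ids, species = species, seq = unname(seqs), moltype = mt,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata)) {
    meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    if (!all(c("id", "species") %in% names(meta))) {
      stopf("metadata TSV must have columns 'id' and 'species'")
    }
    hit <- match(rec$id, meta$id)
    fill <- !nzchar(rec$species) & !is.na(hit)
    rec$species[fill] <- meta$species[hit[fill]]
    if ("clade" %in% names(meta)) rec$clade <- meta$clade[hit]
  }
  for (i in seq_len(nrow(rec))) {
    check_alphabet(rec$seq[i], rec$moltype[i], rec$id[i])
  }
  class(rec) <- c("seq_records", "data.frame")
  rec
}

guess_moltype <- function(seqs) {
  vapply(seqs, function(s) {
    cs <- chars(s)
    frac_nt <- mean(cs %in% c("A", "C", "G", "T", "U", "N"))
    if (frac_nt >= 0.9) "nt" else "aa"
  }, character(1), USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param rec A `seq_records` data frame (or any data frame with `id`,
#'   `seq` and optionally `species` columns).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(rec, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rec))) {
    hdr <- rec$id[i]
    sp <- if ("species" %in% names(rec)) rec$species[i] else ""
    if (nzchar(sp)) hdr <- paste0(hdr, " [species=", sp, "]")
    writeLines(paste0(">", hdr), con)
    s <- rec$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf(
    "<seq_records> %d record(s); moltype: %s\n", nrow(x),
    paste(unique(x$moltype), collapse = "/")
  ))
  utils::str(data.frame(id = x$id, species = x$species,
                        nchar = nchar(x$seq)), give.attr = FALSE)
  invisible(x)
}
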