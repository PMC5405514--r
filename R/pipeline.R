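# End-to-end orchestration with reproducible provenance. Every output
# TSV starts with comment headers carrying the package version, a config
# hash and input checksums; outputs are written atomically (temp file,
# then rename) so a failed run leaves no partial files.

pkg_version <- function() {
  as.character(utils::packageVersion("tertarch"))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(cfg, inputs = character(0)) {
  h <- c(
    sprintf("# tertarch %s", pkg_version()),
    sprintf("# config_hash %s", config_hash(cfg))
  )
  for (p in inputs) {
    if (file.exists(p)) {
      h <- c(h, sprintf("# input %s md5 %s", basename(p),
                        unname(tools::md5sum(p))))
    }
  }
  h
}

write_tsv_provenance <- function(df, path, cfg, inputs = character(0)) {
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, "w")
  writeLines(provenance_header(cfg, inputs), con)
  suppressWarnings(utils::write.table(
    df, con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  ))
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the intron-conservation pipeline
#'
#' For each species: read the gene model and genome, build the
#' transcript, project introns to protein coordinates, align to the
#' reference protein and classify introns, then tabulate.
#'
#' @param samples Data frame with columns `species`, `gff`, `genome`
#'   (FASTA of the genomic region, one record per species id matching
#'   the GFF seqid) and optionally `transcript_id`.
#' @param reference_species Value of `samples$species` used as the
#'   reference.
#' @param out Output TSV path (`NULL` to skip writing).
#' @param tolerance,require_phase Passed to [classify_introns()].
#' @return The conservation table (invisibly when `out` given).
#' @export
run_introns <- function(samples, reference_species, out = NULL,
                        tolerance = 0L, require_phase = FALSE) {
  stopifnot(all(c("species", "gff", "genome") %in% names(samples)))
  if (!reference_species %in% samples$species) {
    stopf("reference species '%s' not among samples", reference_species)
  }
  load_one <- function(i) {
    row <- samples[i, ]
    tid <- if ("transcript_id" %in% names(samples) &&
               !is.na(row$transcript_id) && nzchar(row$transcript_id)) {
      row$transcript_id
    } else NULL
    gm <- read_gene_models(row$gff, transcript_id = tid)
    if (is.list(gm) && !inherits(gm, "gene_model")) {
      stopf("GFF '%s' has several transcripts; set transcript_id", row$gff)
    }
    genome <- read_fasta(row$genome, moltype = "nt")
    hit <- match(gm$seq_region, genome$id)
    if (is.na(hit)) {
      stopf("seq_region '%s' not found in genome FASTA '%s'",
            gm$seq_region, row$genome)
    }
    t <- build_transcript_model(gm, genome$seq[hit])
    list(protein = translate_cds(t)$protein, introns = project_introns(t))
  }
  entries <- lapply(seq_len(nrow(samples)), load_one)
  names(entries) <- samples$species
  reference <- entries[[reference_species]]
  tab <- conservation_table(entries, reference, tolerance = tolerance,
                            require_phase = require_phase)
  if (!is.null(out)) {
    cfg <- list(command = "introns", reference = reference_species,
                tolerance = tolerance, require_phase = require_phase)
    write_tsv_provenance(tab, out, cfg,
                         inputs = c(samples$gff, samples$genome))
    return(invisible(tab))
  }
  tab
}

#' Run the motif-annotation pipeline
#'
#' Transfers reference motifs through an imported multiple alignment,
#' computes the per-column conservation profile, and (when clade labels
#' are given) mines clade-restricted conserved blocks.
#'
#' @param msa Path to an aligned FASTA, or a `seq_alignment`.
#' @param motif_config Path to a motif JSON config, or a
#'   `motif_definitions`.
#' @param out_dir Output directory for `motif_matrix.tsv`,
#'   `conservation_profile.tsv` and `conserved_blocks.tsv` (`NULL` to
#'   skip writing).
#' @param clade_labels Optional named vector (row id -> clade label).
#' @param clades Clades to scan for blocks (default: all labels with
#'   >= 3 members).
#' @param thresholds,f_within,min_block_length,f_background_max Tuning
#'   parameters, see [transfer_motifs()] and [find_conserved_blocks()].
#' @return List with `calls`, `matrix` (species x motif status),
#'   `profile`, `blocks`.
#' @export
run_motifs <- function(msa, motif_config, out_dir = NULL,
                       clade_labels = NULL, clades = NULL,
                       thresholds = c(present = 0.70, partial = 0.20),
                       f_within = 0.8, min_block_length = 4L,
                       f_background_max = 0.5) {
  inputs <- character(0)
  if (is.character(msa)) {
    inputs <- c(inputs, msa)
    msa <- read_alignment(msa)
  }
  if (is.character(motif_config)) {
    inputs <- c(inputs, motif_config)
    motif_config <- read_motif_config(motif_config)
  }
  calls <- transfer_motifs(msa, motif_config, thresholds = thresholds)
  mat <- stats::reshape(
    calls[, c("target_id", "motif", "status")],
    idvar = "target_id", timevar = "motif", direction = "wide"
  )
  names(mat) <- sub("^status\\.", "", names(mat))
  profile <- conservation_profile(msa)
  blocks <- NULL
  if (!is.null(clade_labels)) {
    if (is.null(clades)) {
      tab <- table(clade_labels[msa$ids])
      clades <- names(tab)[tab >= 3L]
    }
    blocks <- do.call(rbind, lapply(clades, function(cl) {
      find_conserved_blocks(msa, clade_labels, cl, f_within = f_within,
                            min_block_length = min_block_length,
                            f_background_max = f_background_max)
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(command = "motifs", thresholds = as.list(thresholds),
                f_within = f_within, min_block_length = min_block_length,
                f_background_max = f_background_max)
    write_tsv_provenance(mat, file.path(out_dir, "motif_matrix.tsv"),
                         cfg, inputs)
    write_tsv_provenance(profile,
                         file.path(out_dir, "conservation_profile.tsv"),
                         cfg, inputs)
    if (!is.null(blocks)) {
      write_tsv_provenance(blocks,
                           file.path(out_dir, "conserved_blocks.tsv"),
                           cfg, inputs)
    }
  }
  list(calls = calls, matrix = mat, profile = profile, blocks = blocks)
}

#' Run the splice-variant pipeline
#'
#' Annotates every variant in a FASTA against an isoform-1 reference.
#' Nucleotide records get full event typing; protein records get motif
#' and domain calls only. Variants failing the identity gate are
#' collected in a rejects table and the run continues.
#'
#' @param variants Path to a variant FASTA, or a `seq_records` data
#'   frame (column `moltype` decides the per-record path).
#' @param ref A `transcript_model` for isoform 1, or a list
#'   `list(gff=, genome=, transcript_id=)` to load one.
#' @param defs Motif config path or `motif_definitions`.
#' @param out_dir Output directory for `variant_report.tsv`,
#'   `variant_aggregate.tsv`, `rejects.tsv` (`NULL` to skip writing).
#' @param intron_seqs,tol_nt Passed to [classify_events()].
#' @return List with `annotations`, `summary`, `rejects`.
#' @export
run_splice <- function(variants, ref, defs, out_dir = NULL,
                       intron_seqs = NULL, tol_nt = 3L) {
  inputs <- character(0)
  if (is.character(variants)) {
    inputs <- c(inputs, variants)
    variants <- read_fasta(variants)
  }
  if (is.character(defs)) {
    inputs <- c(inputs, defs)
    defs <- read_motif_config(defs)
  }
  if (!inherits(ref, "transcript_model")) {
    gm <- read_gene_models(ref$gff, transcript_id = ref$transcript_id)
    genome <- read_fasta(ref$genome, moltype = "nt")
    hit <- match(gm$seq_region, genome$id)
    ref <- build_transcript_model(gm, genome$seq[hit])
  }
  ref_protein <- translate_cds(ref)$protein
  annotations <- list()
  rejects <- list()
  species <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ann <- tryCatch({
      if (v$moltype == "nt") {
        annotate_variant(v$id, v$seq, ref, defs, ref_protein = ref_protein,
                         intron_seqs = intron_seqs, tol_nt = tol_nt)
      } else {
        annotate_variant(v$id, NULL, ref, defs, variant_protein = v$seq,
                         ref_protein = ref_protein)
      }
    }, error = function(e) e)
    if (inherits(ann, "error")) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = v$id, reason = conditionMessage(ann)
      )
    } else {
      annotations[[length(annotations) + 1L]] <- ann
      species <- c(species,
                   if (nzchar(v$species)) v$species else "unknown")
    }
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(id = character(0), reason = character(0))
  summary <- if (length(annotations)) {
    summarize_variants(annotations, species = species)
  } else {
    list(per_variant = data.frame(
      variant_id = character(0), species = character(0),
      level = character(0), events = character(0),
      n_events = integer(0), orf_retained = logical(0),
      ptc = integer(0), TRBD = character(0), RT = character(0)
    ), aggregate = NULL, orf = NULL)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(command = "splice", tol_nt = tol_nt)
    write_tsv_provenance(summary$per_variant,
                         file.path(out_dir, "variant_report.tsv"),
                         cfg, inputs)
    if (!is.null(summary$aggregate)) {
      write_tsv_provenance(summary$aggregate,
                           file.path(out_dir, "variant_aggregate.tsv"),
                           cfg, inputs)
    }
    write_tsv_provenance(rejects, file.path(out_dir, "rejects.tsv"),
                         cfg, inputs)
  }
  list(annotations = annotations, summary = summary, rejects = rejects)
}

#' Run the simulator and write a bundle to disk
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The `sim_family`, invisibly; files per [write_sim_family()].
#' @export
run_simulate <- function(cfg, out_dir) {
  fam <- simulate_family(cfg)
  write_sim_family(fam, out_dir)
  invisible(fam)
}
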