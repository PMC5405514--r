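# Gene-family simulator with full ground truth.
#
# An ancestral multi-exon gene (codon-structured, stop-free CDS) evolves
# along a user-supplied tree: codon substitutions (uniform over
# alternative residues, then a uniform codon for the chosen residue),
# codon-level indels, intron loss/gain, and motif-region deletions.
# Splice variants are generated per leaf by exon skipping, intron
# retention and boundary-jittered deletions, with a configurable
# frame-preserving fraction. Every event is recorded so that replaying
# the truth log against the ancestor reproduces each leaf exactly.

#' Simulation configuration
#'
#' @param tree Newick string. Branch lengths scale substitution and indel
#'   probabilities; intron and motif event probabilities are per branch.
#' @param n_exons Number of exons in the ancestral gene (>= 2).
#' @param exon_length_range Min/max ancestral exon length in nt.
#' @param substitution_rate Per codon site per unit branch length.
#' @param indel_rate Per codon site per unit branch length.
#' @param indel_length_p Geometric parameter for indel length in codons
#'   (mean `1/p`).
#' @param intron_loss_prob Per intron per branch.
#' @param intron_gain_rate Expected gains per branch (Poisson).
#' @param motif_map Optional `motif_definitions` on the ancestral
#'   protein; `NULL` auto-places the canonical TERT motif series scaled
#'   to the ancestral protein length.
#' @param motif_loss_prob Per motif per branch (loss = in-frame deletion
#'   of the motif interval).
#' @param n_variants Splice variants generated per leaf.
#' @param variant_event_mix Probabilities for
#'   `c(exon_skip, intron_retention, boundary_jitter_deletion)`.
#' @param frame_preserving_fraction Fraction of variants required to
#'   preserve the reading frame (enforced by resampling).
#' @param allow_stops Permit substitutions to create stop codons
#'   (default `FALSE`: stop-creating substitutions are resampled so that
#'   frame logic, not ORF noise, is under test).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree = "((human:0.2,fish:0.3):0.1,(insect:0.4,planarian:0.5):0.2,sponge:0.6);",
                       n_exons = 16L,
                       exon_length_range = c(60L, 240L),
                       substitution_rate = 0.5,
                       indel_rate = 0.01,
                       indel_length_p = 0.5,
                       intron_loss_prob = 0.1,
                       intron_gain_rate = 0.5,
                       motif_map = NULL,
                       motif_loss_prob = 0.05,
                       n_variants = 5L,
                       variant_event_mix = c(exon_skip = 0.5,
                                             intron_retention = 0.3,
                                             boundary_jitter_deletion = 0.2),
                       frame_preserving_fraction = 0.5,
                       allow_stops = FALSE,
                       seed = 1L) {
  cfg <- list(
    tree = tree, n_exons = as.integer(n_exons),
    exon_length_range = as.integer(exon_length_range),
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    indel_length_p = indel_length_p,
    intron_loss_prob = intron_loss_prob,
    intron_gain_rate = intron_gain_rate, motif_map = motif_map,
    motif_loss_prob = motif_loss_prob, n_variants = as.integer(n_variants),
    variant_event_mix = variant_event_mix,
    frame_preserving_fraction = frame_preserving_fraction,
    allow_stops = isTRUE(allow_stops), seed = as.integer(seed)
  )
  probs <- c(cfg$intron_loss_prob, cfg$motif_loss_prob,
             cfg$frame_preserving_fraction, cfg$variant_event_mix)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  if (cfg$substitution_rate < 0 || cfg$indel_rate < 0 ||
      cfg$intron_gain_rate < 0) {
    stopf("rates must be >= 0")
  }
  if (cfg$n_exons < 2L) stopf("n_exons must be >= 2")
  class(cfg) <- "sim_config"
  cfg
}

sense_codons <- function() {
  tab <- codon_table()
  names(tab)[tab != "*"]
}

codons_for_residue <- function() {
  tab <- codon_table()
  split(names(tab), tab)
}

random_codons <- function(n) {
  sample(sense_codons(), n, replace = TRUE)
}

# Intron sequences carry canonical GT..AG ends. The body avoids T (and
# the first body base is C), so a retained intron can never introduce a
# stop codon in any reading frame: all stops start with T, and the only
# T (the donor GT) is always followed by C. This keeps frame-preserving
# intron-retention variants constructible.
make_intron_seq <- function() {
  len <- sample(60:150, 1)
  paste0("GTC", paste(sample(c("A", "C", "G"), len - 5, replace = TRUE),
                      collapse = ""), "AG")
}

# ---- lineage state and event application ---------------------------------

# state: codons (character vec), introns (df: id, host, phase),
#        motifs (df: name, start, end; 0-based half-open residues)
intron_offsets <- function(state) {
  3L * (state$introns$host - 1L) + state$introns$phase
}

apply_event <- function(state, ev) {
  switch(ev$kind,
    sub = {
      if (ev$site <= length(state$codons)) state$codons[ev$site] <- ev$codon
      state
    },
    del = apply_codon_deletion(state, ev$at, ev$len),
    ins = {
      at <- ev$at  # insert before codon index `at`
      n <- length(state$codons)
      k <- length(ev$codons)
      state$codons <- append(state$codons, ev$codons, after = at - 1L)
      shift <- state$introns$host >= at
      state$introns$host[shift] <- state$introns$host[shift] + k
      d0 <- at - 1L
      state$motifs$start <- ifelse(state$motifs$start >= d0,
                                   state$motifs$start + k,
                                   state$motifs$start)
      state$motifs$end <- ifelse(state$motifs$end > d0,
                                 state$motifs$end + k, state$motifs$end)
      state
    },
    intron_loss = {
      state$introns <- state$introns[state$introns$id != ev$id, ,
                                     drop = FALSE]
      state
    },
    intron_gain = {
      state$introns <- rbind(
        state$introns,
        data.frame(id = ev$id, host = ev$host, phase = ev$phase)
      )
      state
    },
    motif_loss = {
      state <- apply_codon_deletion(state, ev$at, ev$len)
      state$motifs <- state$motifs[state$motifs$name != ev$name, ,
                                   drop = FALSE]
      state
    },
    stopf("unknown event kind '%s'", ev$kind)
  )
}

apply_codon_deletion <- function(state, at, len) {
  n <- length(state$codons)
  keep <- setdiff(seq_len(n), at:(at + len - 1L))
  state$codons <- state$codons[keep]
  h <- state$introns$host
  lost <- h >= at & h < at + len
  state$introns <- state$introns[!lost, , drop = FALSE]
  h <- state$introns$host
  state$introns$host <- ifelse(h >= at + len, h - len, h)
  d0 <- at - 1L  # 0-based residue offset of deletion start
  shrink <- function(x) ifelse(x <= d0, x, pmax(d0, x - len))
  state$motifs$start <- shrink(state$motifs$start)
  state$motifs$end <- shrink(state$motifs$end)
  gone <- state$motifs$end - state$motifs$start <= 0L
  state$motifs <- state$motifs[!gone, , drop = FALSE]
  state
}

# ---- event sampling along a branch ---------------------------------------

sample_branch_events <- function(state, bl, cfg, id_counter) {
  events <- list()
  n <- length(state$codons)
  aa_codons <- codons_for_residue()
  tab <- codon_table()

  # substitutions
  p_sub <- min(1, cfg$substitution_rate * bl)
  sites <- which(stats::runif(n) < p_sub)
  for (s in sites) {
    cur <- tab[[state$codons[s]]]
    if (cfg$allow_stops) {
      new_codon <- sample(setdiff(names(tab), state$codons[s]), 1)
    } else {
      new_res <- sample(setdiff(AA_ALPHABET_STRICT, cur), 1)
      new_codon <- resample(aa_codons[[new_res]])
    }
    ev <- list(kind = "sub", site = s, codon = new_codon)
    state <- apply_event(state, ev)
    events[[length(events) + 1L]] <- ev
  }

  # codon indels
  p_indel <- min(1, cfg$indel_rate * bl)
  m <- stats::rbinom(1, length(state$codons), p_indel)
  for (i in seq_len(m)) {
    n_now <- length(state$codons)
    if (n_now < 20L) break
    len <- stats::rgeom(1, cfg$indel_length_p) + 1L
    if (stats::runif(1) < 0.5) {
      len <- min(len, n_now - 10L)
      at <- resample(2:(n_now - len))
      ev <- list(kind = "del", at = at, len = len)
    } else {
      at <- resample(2:(n_now + 1L))
      ev <- list(kind = "ins", at = at, codons = random_codons(len))
    }
    state <- apply_event(state, ev)
    events[[length(events) + 1L]] <- ev
  }

  # motif losses
  for (nm in state$motifs$name) {
    if (stats::runif(1) < cfg$motif_loss_prob) {
      row <- state$motifs[state$motifs$name == nm, ]
      ev <- list(kind = "motif_loss", name = nm, at = row$start + 1L,
                 len = row$end - row$start)
      state <- apply_event(state, ev)
      events[[length(events) + 1L]] <- ev
    }
  }

  # intron losses
  for (id in state$introns$id) {
    if (stats::runif(1) < cfg$intron_loss_prob) {
      ev <- list(kind = "intron_loss", id = id)
      state <- apply_event(state, ev)
      events[[length(events) + 1L]] <- ev
    }
  }

  # intron gains: uniform CDS positions, never within 3 nt of an
  # existing boundary (keeps the truth unambiguous)
  n_gain <- stats::rpois(1, cfg$intron_gain_rate)
  for (i in seq_len(n_gain)) {
    L <- 3L * length(state$codons)
    for (try in 1:50) {
      b <- resample(seq_len(L - 1L))
      if (all(abs(b - intron_offsets(state)) > 3L)) {
        id_counter <- id_counter + 1L
        ev <- list(kind = "intron_gain", id = id_counter,
                   host = b %/% 3L + 1L, phase = b %% 3L,
                   seq = make_intron_seq())
        state <- apply_event(state, ev)
        events[[length(events) + 1L]] <- ev
        break
      }
    }
  }
  list(state = state, events = events, id_counter = id_counter)
}

# ---- the main entry points ------------------------------------------------

#' Simulate a gene family with ground truth
#'
#' Builds a stop-free codon-structured ancestral gene with `n_exons`
#' exons and the configured motif map, evolves it depth-first along the
#' tree, and generates splice variants per leaf. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_family`: list with `cfg`, `ancestor`
#'   (state), `leaves` (per species: `state`, `model`
#'   (`transcript_model`), `protein`, `genome`, `gene`
#'   (`gene_model`), `intron_seqs`), `variants` (per species list from
#'   [generate_variants()]), and `truth` (ancestor codons, per-branch
#'   event logs, per-leaf surviving/gained introns and lost motifs).
#' @examples
#' fam <- simulate_family(sim_config(tree = "(a:0.1,b:0.1);", seed = 42))
#' names(fam$leaves)
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = cfg$tree)),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$tip.label)) {
    stopf("unparseable newick tree")
  }
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))

  anc <- build_ancestor(cfg)
  ancestor <- anc$state
  intron_seq_pool <- anc$intron_seqs  # named by intron id

  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  states <- list()
  branch_log <- list()
  id_counter <- max(ancestor$introns$id)

  walk <- function(node, state) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in kids) {
      bl <- phy$edge.length[which(phy$edge[, 1] == node &
                                    phy$edge[, 2] == child)]
      res <- sample_branch_events(state, bl, cfg, id_counter)
      id_counter <<- res$id_counter
      for (ev in res$events) {
        if (ev$kind == "intron_gain") {
          intron_seq_pool[[as.character(ev$id)]] <<- ev$seq
        }
      }
      label <- if (child <= n_tip) phy$tip.label[child] else
        paste0("node", child)
      branch_log[[label]] <<- res$events
      if (child <= n_tip) {
        states[[phy$tip.label[child]]] <<- res$state
      } else {
        walk(child, res$state)
      }
    }
  }
  walk(root, ancestor)

  leaves <- lapply(names(states), function(sp) {
    leaf_package(sp, states[[sp]], intron_seq_pool)
  })
  names(leaves) <- names(states)

  variants <- lapply(names(leaves), function(sp) {
    generate_variants(leaves[[sp]], cfg, species = sp)
  })
  names(variants) <- names(leaves)

  truth <- list(
    seed = cfg$seed, tree = cfg$tree,
    ancestor = list(
      codons = ancestor$codons,
      introns = ancestor$introns,
      motifs = ancestor$motifs
    ),
    intron_seqs = intron_seq_pool,
    branches = branch_log,
    leaves = lapply(names(leaves), function(sp) {
      st <- states[[sp]]
      anc_ids <- ancestor$introns$id
      list(
        species = sp,
        surviving_introns = intersect(st$introns$id, anc_ids),
        gained_introns = setdiff(st$introns$id, anc_ids),
        lost_motifs = setdiff(ancestor$motifs$name, st$motifs$name),
        intron_positions = data.frame(
          id = st$introns$id,
          transcript_nt = intron_offsets(st),
          residue_index = intron_offsets(st) %/% 3L,
          phase = intron_offsets(st) %% 3L
        )
      )
    })
  )
  names(truth$leaves) <- names(leaves)

  structure(
    list(cfg = cfg, ancestor = ancestor, leaves = leaves,
         variants = variants, truth = truth, tree = phy),
    class = "sim_family"
  )
}

build_ancestor <- function(cfg) {
  lens <- sample(seq(cfg$exon_length_range[1], cfg$exon_length_range[2]),
                 cfg$n_exons, replace = TRUE)
  total <- sum(lens)
  pad <- (3L - total %% 3L) %% 3L
  lens[cfg$n_exons] <- lens[cfg$n_exons] + pad
  n_codons <- sum(lens) %/% 3L
  codons <- c("ATG", random_codons(n_codons - 1L))
  bounds <- cumsum(lens)[-cfg$n_exons]
  introns <- data.frame(
    id = seq_along(bounds),
    host = bounds %/% 3L + 1L,
    phase = bounds %% 3L
  )
  intron_seqs <- stats::setNames(
    replicate(length(bounds), make_intron_seq()),
    as.character(introns$id)
  )
  motifs <- cfg$motif_map
  if (is.null(motifs)) {
    motifs <- default_motif_map(n_codons)
  } else {
    motifs <- data.frame(name = motifs$name, start = motifs$start,
                         end = motifs$end)
  }
  list(
    state = list(codons = codons, introns = introns, motifs = motifs),
    intron_seqs = as.list(intron_seqs)
  )
}

# Canonical TERT-style motif series scaled to the protein length:
# GQ, CP, QFP, T, then RT motifs 1..E, evenly spread with gaps between.
default_motif_map <- function(n_codons) {
  names <- c("GQ", "CP", "QFP", "T", "1", "2", "A", "Bprime", "C", "D", "E")
  k <- length(names)
  span <- floor(n_codons * 0.9)
  offset <- floor(n_codons * 0.05)
  width <- max(5L, floor(span / (2L * k)))
  starts <- offset + floor((seq_len(k) - 1L) * span / k)
  data.frame(name = names, start = starts, end = starts + width)
}

leaf_package <- function(sp, state, intron_seq_pool) {
  cdna <- paste(state$codons, collapse = "")
  off <- sort(intron_offsets(state))
  ord <- order(intron_offsets(state))
  model <- transcript_model(sp, cdna, off)
  protein <- translate_cds(model)$protein
  iseqs <- vapply(state$introns$id[ord], function(id) {
    intron_seq_pool[[as.character(id)]]
  }, character(1))
  # genomic sequence: exons interleaved with intron sequences
  exons <- exon_sequences(model)
  genome_parts <- character(0)
  gstart <- 0L
  exon_coords <- matrix(0L, nrow = length(exons), ncol = 2)
  for (i in seq_along(exons)) {
    exon_coords[i, ] <- c(gstart, gstart + nchar(exons[i]))
    genome_parts <- c(genome_parts, exons[i])
    gstart <- gstart + nchar(exons[i])
    if (i <= length(iseqs)) {
      genome_parts <- c(genome_parts, iseqs[i])
      gstart <- gstart + nchar(iseqs[i])
    }
  }
  genome <- paste(genome_parts, collapse = "")
  gene <- gene_model(
    gene_id = sp, seq_region = paste0(sp, "_scaffold"), strand = "+",
    exons = exon_coords, cds = exon_coords,
    transcript_id = paste0(sp, "_t1")
  )
  list(state = state, model = model, protein = protein, genome = genome,
       gene = gene, intron_seqs = iseqs)
}

#' Generate splice variants for one simulated species
#'
#' Event types: `exon_skip` removes a contiguous run of 1-3 interior
#' exons; `intron_retention` splices one intron's genomic sequence back
#' in; `boundary_jitter_deletion` is an exon-skip deletion with one
#' endpoint shifted by 1-2 nt. The configured frame-preserving fraction
#' is enforced by resampling, and frame-preserving variants are
#' additionally required to translate without a premature stop.
#'
#' @param leaf One element of `sim_family$leaves` (needs `model` and
#'   `intron_seqs`).
#' @param cfg A `sim_config`.
#' @param species Species label for variant ids.
#' @return List with `variants` (data frame: `id`, `species`, `cdna`) and
#'   `truth` (per variant: event type, segment in reference coordinates,
#'   skipped exon ranks or retained intron rank, `frame_preserving`,
#'   `orf_retained`).
#' @export
generate_variants <- function(leaf, cfg, species = "sp") {
  model <- leaf$model
  bounds <- c(0L, model$exon_boundaries_nt, nchar(model$cdna))
  n_exons <- length(bounds) - 1L
  mix <- cfg$variant_event_mix / sum(cfg$variant_event_mix)
  types <- names(mix)
  out <- list(); truth <- list()
  for (v in seq_len(cfg$n_variants)) {
    want_fp <- stats::runif(1) < cfg$frame_preserving_fraction
    type <- sample(types, 1, prob = mix)
    if (type != "intron_retention" && n_exons < 3L) type <- "intron_retention"
    if (type == "intron_retention" && n_exons < 2L) {
      stopf("cannot generate variants for an intronless gene")
    }
    res <- NULL
    for (try in 1:200) {
      cand <- switch(type,
        exon_skip = make_skip_variant(model, bounds, n_exons, jitter = 0L),
        boundary_jitter_deletion =
          make_skip_variant(model, bounds, n_exons, jitter = resample(1:2)),
        intron_retention = make_retention_variant(model, bounds, leaf)
      )
      fp <- cand$delta %% 3L == 0L
      if (fp != want_fp) next
      orf <- translate_cds(transcript_model("v", cand$cdna, integer(0)))
      if (want_fp && !orf$orf_retained) next
      res <- c(cand, list(frame_preserving = fp,
                          orf_retained = orf$orf_retained))
      break
    }
    if (is.null(res)) {
      # fall back: accept the last candidate regardless of frame
      orf <- translate_cds(transcript_model("v", cand$cdna, integer(0)))
      res <- c(cand, list(frame_preserving = cand$delta %% 3L == 0L,
                          orf_retained = orf$orf_retained))
    }
    vid <- sprintf("%s_%s_ev%d", species, model$transcript_id, v)
    out[[v]] <- data.frame(id = vid, species = species, cdna = res$cdna)
    truth[[v]] <- list(
      id = vid, type = type, ref_start = res$ref_start,
      ref_end = res$ref_end, exons = res$exons, intron = res$intron,
      frame_preserving = res$frame_preserving,
      orf_retained = res$orf_retained
    )
  }
  list(variants = do.call(rbind, out), truth = truth)
}

make_skip_variant <- function(model, bounds, n_exons, jitter = 0L) {
  run_len <- resample(seq_len(min(3L, n_exons - 2L)))
  e1 <- resample(2:(n_exons - run_len))
  e2 <- e1 + run_len - 1L
  s <- bounds[e1]; e <- bounds[e2 + 1L]
  if (jitter > 0L) {
    side <- sample(c("s", "e"), 1)
    dir <- sample(c(-1L, 1L), 1)
    if (side == "s") s <- max(1L, s + dir * jitter) else
      e <- min(nchar(model$cdna) - 1L, e + dir * jitter)
  }
  cdna <- paste0(substr(model$cdna, 1, s), substr(model$cdna, e + 1L,
                                                  nchar(model$cdna)))
  list(cdna = cdna, ref_start = s, ref_end = e, delta = e - s,
       exons = if (jitter == 0L) e1:e2 else integer(0),
       intron = NA_integer_)
}

make_retention_variant <- function(model, bounds, leaf) {
  r <- resample(seq_along(model$exon_boundaries_nt))
  b <- model$exon_boundaries_nt[r]
  iseq <- leaf$intron_seqs[r]
  cdna <- paste0(substr(model$cdna, 1, b), iseq,
                 substr(model$cdna, b + 1L, nchar(model$cdna)))
  list(cdna = cdna, ref_start = b, ref_end = b, delta = nchar(iseq),
       exons = integer(0), intron = r)
}

#' Replay a simulation truth log
#'
#' Re-applies the recorded per-branch events to the recorded ancestor
#' along the tree and returns the reconstructed leaf cDNAs — an
#' independent closure check that the truth log fully determines every
#' leaf.
#'
#' @param truth The `truth` element of a `sim_family` (possibly after a
#'   JSON round trip).
#' @return Named character vector of reconstructed leaf cDNAs.
#' @export
replay_truth <- function(truth) {
  phy <- ape::read.tree(text = truth$tree)
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  anc <- list(
    codons = as.character(truth$ancestor$codons),
    introns = as.data.frame(truth$ancestor$introns),
    motifs = as.data.frame(truth$ancestor$motifs)
  )
  out <- character(0)
  walk <- function(node, state) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    for (child in kids) {
      label <- if (child <= n_tip) phy$tip.label[child] else
        paste0("node", child)
      st <- state
      evs <- truth$branches[[label]]
      # a JSON round trip may have collapsed the event list to a frame
      if (is.data.frame(evs)) {
        evs <- lapply(seq_len(nrow(evs)), function(i) as.list(evs[i, ]))
      }
      for (ev in evs) {
        st <- apply_event(st, normalize_event(ev))
      }
      if (child <= n_tip) {
        out[[phy$tip.label[child]]] <<- paste(st$codons, collapse = "")
      } else {
        walk(child, st)
      }
    }
  }
  walk(root, anc)
  out
}

# events that have been through a JSON round trip lose their types
normalize_event <- function(ev) {
  ev <- as.list(ev)
  for (f in c("site", "at", "len", "id", "host", "phase")) {
    if (!is.null(ev[[f]])) ev[[f]] <- as.integer(ev[[f]])
  }
  if (!is.null(ev$codons)) ev$codons <- as.character(unlist(ev$codons))
  ev
}

#' Write a simulated family to disk
#'
#' Emits per-species genome FASTA, gene-model GFF3, protein FASTA,
#' variant FASTA and a truth JSON into `dir`.
#'
#' @param fam A `sim_family`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_sim_family <- function(fam, dir) {
  stopifnot(inherits(fam, "sim_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genomes = file.path(dir, "genomes.fa"),
    gff = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fa"),
    variants = file.path(dir, "variants.fa"),
    truth = file.path(dir, "truth.json")
  )
  sps <- names(fam$leaves)
  write_fasta(data.frame(
    id = vapply(sps, function(s) fam$leaves[[s]]$gene$seq_region,
                character(1)),
    species = sps,
    seq = vapply(sps, function(s) fam$leaves[[s]]$genome, character(1))
  ), paths$genomes)
  write_gene_models(lapply(sps, function(s) fam$leaves[[s]]$gene),
                    paths$gff)
  write_fasta(data.frame(
    id = vapply(sps, function(s) fam$leaves[[s]]$model$transcript_id,
                character(1)),
    species = sps,
    seq = vapply(sps, function(s) fam$leaves[[s]]$protein, character(1))
  ), paths$proteins)
  vtab <- do.call(rbind, lapply(sps, function(s) {
    v <- fam$variants[[s]]$variants
    data.frame(id = v$id, species = v$species, seq = v$cdna)
  }))
  write_fasta(vtab, paths$variants)
  jsonlite::write_json(fam$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf(
    "<sim_family> %d leaves, ancestor: %d codons, %d introns, %d motifs\n",
    length(x$leaves), length(x$ancestor$codons),
    nrow(x$ancestor$introns), nrow(x$ancestor$motifs)
  ))
  invisible(x)
}
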