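# Pipeline driver: configuration with provenance flags, the four-phase
# flow (set-up -> patch -> assemble -> consensus) and standard-format
# outputs so every stage is independently inspectable.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default and a provenance flag:
#' `"paper"` marks values taken from the published assembly protocol
#' this tool follows (4-kb minimum read length, >=10-read coverage
#' masking, the 8-kb/>=3-chain chimera rule, 4-14-kb circular chain
#' bounds with 1,500 unaligned bases, 1,500-bp split overlap);
#' `"chosen"` marks values set by this implementation.
#'
#' @param genome_size_estimate expected genome size in bases (required
#'   for coverage masking).
#' @param ... overrides for any listed parameter.
#' @return a `pipeline_config` list.
#' @export
default_config <- function(genome_size_estimate = NULL, ...) {
  cfg <- list(
    min_length = 4000L,
    genome_size_estimate = genome_size_estimate,
    mask_threshold = 10L,
    dust_window = 64L, dust_threshold = 2.0,
    tandem_period = 500L, tandem_span = 100L,
    k = 14L, band_width = 256L, min_seeds = 3L,
    max_divergence = 0.30, min_alignment_length = 600L,
    end_slack = 25L, max_gap = 1500L, mask_extension_limit = 500L,
    span_slack = 100L, min_flank_support = 3L, min_patch_length = 400L,
    max_repeat_length = 8000L, min_spanning_chains = 3L, span_flank = 500L,
    fuzz = 200L, segment_width = 100L,
    mito_min_chain = 4000L, mito_max_chain = 14000L,
    mito_max_unaligned = 1500L, mito_split_overlap = 1500L,
    seed = 1L)
  prov <- c(min_length = "paper", genome_size_estimate = "chosen",
            mask_threshold = "paper", dust_window = "chosen",
            dust_threshold = "chosen", tandem_period = "chosen",
            tandem_span = "chosen", k = "chosen", band_width = "chosen",
            min_seeds = "chosen", max_divergence = "chosen",
            min_alignment_length = "chosen", end_slack = "chosen",
            max_gap = "chosen", mask_extension_limit = "chosen",
            span_slack = "chosen",
            min_flank_support = "chosen", min_patch_length = "chosen",
            max_repeat_length = "paper", min_spanning_chains = "paper",
            span_flank = "chosen", fuzz = "chosen", segment_width = "chosen",
            mito_min_chain = "paper", mito_max_chain = "paper",
            mito_max_unaligned = "paper", mito_split_overlap = "paper",
            seed = "chosen")
  up <- list(...)
  bad <- setdiff(names(up), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(up)] <- up
  structure(list(values = cfg, provenance = prov),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x$values)) {
    cat(sprintf("  %-22s %-10s [%s]\n", k,
                format(x$values[[k]]), x$provenance[[k]]))
  }
  invisible(x)
}

#' Serialize / parse a pipeline configuration (YAML)
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `write_config` returns `path`; `read_config` the parsed
#'   `pipeline_config` (round-trip safe).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(values = config$values,
                        provenance = as.list(config$provenance)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_config()
  vals <- raw$values
  # restore types against the defaults
  for (k in names(vals)) {
    if (!is.null(base$values[[k]]) && is.integer(base$values[[k]]) &&
        !is.null(vals[[k]]))
      vals[[k]] <- as.integer(vals[[k]])
  }
  structure(list(values = vals, provenance = unlist(raw$provenance)),
            class = "pipeline_config")
}

config_align_params <- function(cfg, segment_diffs = FALSE) {
  v <- cfg$values
  align_params(k = v$k, band_width = v$band_width, min_seeds = v$min_seeds,
               max_divergence = v$max_divergence,
               min_alignment_length = v$min_alignment_length,
               end_slack = v$end_slack, max_gap = v$max_gap,
               mask_extension_limit = v$mask_extension_limit,
               segment_width = v$segment_width,
               segment_diffs = segment_diffs)
}

config_patch_params <- function(cfg) {
  v <- cfg$values
  patch_params(span_slack = v$span_slack,
               min_flank_support = v$min_flank_support,
               min_patch_length = v$min_patch_length,
               min_length = v$min_length,
               max_repeat_length = v$max_repeat_length,
               min_spanning_chains = v$min_spanning_chains,
               span_flank = v$span_flank)
}

config_layout_params <- function(cfg) {
  v <- cfg$values
  layout_params(end_slack = v$end_slack, fuzz = v$fuzz,
                segment_width = v$segment_width)
}

#' Run the full assembly pipeline
#'
#' Set-up (database build with longest-subread selection and the
#' minimum-length filter), three-tier repeat masking, masked all-vs-all
#' alignment with mask-free re-alignment of chains ending prematurely in
#' repeats, read patching (including the spanning-chain chimera rule on
#' the patched reads), all-vs-all alignment of patched reads, pile
#' filtering, string graph, transitive reduction, touring and consensus.
#' Deterministic given config and inputs.
#'
#' @param reads FASTA/FASTQ path, or a subread data.frame.
#' @param config a `pipeline_config`; `genome_size_estimate` must be set.
#' @param outdir optional output directory; when given, all intermediate
#'   and final artifacts (FASTA/BED/PAF/GFA/JSON) are written there.
#' @param verbose log stage progress.
#' @return list: `db`, `patched_db`, `contigs`, `graph`, `stats`,
#'   `events`, `excluded`.
#' @export
run_pipeline <- function(reads, config, outdir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  v <- config$values
  if (is.null(v$genome_size_estimate))
    stop("config$values$genome_size_estimate is required")
  if (is.character(reads)) reads <- read_seqs(reads)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)

  say("[setup] %d subreads", nrow(reads))
  db <- build_db(reads, v$min_length)
  if (nrow(db$reads) == 0) {
    warning("no reads pass the set-up filters; empty assembly")
    empty <- data.frame(contig_id = character(), length = integer(),
                        circular = logical(), n_reads = integer(),
                        sequence = character())
    return(list(db = db, patched_db = db, contigs = empty,
                graph = NULL, stats = assembly_stats(integer()),
                events = NULL, excluded = character()))
  }
  aparams <- config_align_params(config, segment_diffs = TRUE)
  pparams <- config_patch_params(config)
  lparams <- config_layout_params(config)

  say("[mask] three-tier repeat masking")
  db <- mask_reads(db, v$genome_size_estimate, v$mask_threshold, aparams,
                   v$dust_window, v$dust_threshold,
                   v$tandem_period, v$tandem_span)
  if (!is.null(outdir)) {
    for (tr in c("dust", "tandem", "coverage", "repeat"))
      write_track_bed(db$tracks[[tr]],
                      file.path(outdir, paste0("mask_", tr, ".bed")), tr)
  }

  say("[patch] masked all-vs-all alignment of raw reads")
  aln <- all_vs_all(db, "repeat", aparams)
  say("[patch] %d alignments; re-aligning premature chains", nrow(aln))
  aln <- realign_premature(aln, db, aparams)
  say("[patch] artefact detection and correction")
  pr <- patch_reads(db, aln, db$tracks[["repeat"]], pparams, aparams)
  pdb <- pr$db
  say("[patch] %d patched reads (%d events)", nrow(pdb$reads),
      nrow(pr$events))

  if (identical(pdb$reads$sequence, db$reads$sequence) &&
      identical(pdb$reads$read_id, db$reads$read_id)) {
    # nothing was patched: the patch-phase masks and alignments are
    # already the assembly-phase ones
    say("[assemble] no reads changed; reusing patch-phase alignments")
    pdb$tracks <- db$tracks
    paln <- aln
  } else {
    say("[assemble] masking and aligning patched reads")
    pdb <- mask_reads(pdb, v$genome_size_estimate, v$mask_threshold, aparams,
                      v$dust_window, v$dust_threshold,
                      v$tandem_period, v$tandem_span)
    paln <- all_vs_all(pdb, "repeat", aparams)
    paln <- realign_premature(paln, pdb, aparams)
  }

  say("[assemble] spanning-chain chimera rule")
  excluded <- chimera_rule_exclusions(pdb, paln, pparams, aparams)
  excluded_names <- pdb$reads$read_id[excluded]
  if (length(excluded)) {
    say("[assemble] excluding %d reads with unspanned repeats",
        length(excluded))
    keep_ids <- setdiff(seq_len(nrow(pdb$reads)), excluded)
    paln <- paln[paln$a_id %in% keep_ids & paln$b_id %in% keep_ids, ,
                 drop = FALSE]
    # re-index reads and alignments
    remap <- match(seq_len(nrow(pdb$reads)), keep_ids)
    paln$a_id <- remap[paln$a_id]; paln$b_id <- remap[paln$b_id]
    keep_names <- pdb$reads$read_id[keep_ids]
    pdb$reads <- pdb$reads[keep_ids, , drop = FALSE]
    pdb$reads$id <- seq_len(nrow(pdb$reads))
    rownames(pdb$reads) <- NULL
    pdb$tracks <- lapply(pdb$tracks, function(tr) {
      tr2 <- tr[intersect(names(tr), keep_names)]
      class(tr2) <- "interval_track"
      tr2
    })
  }

  say("[assemble] quality track, layout and consensus")
  qtracks <- quality_tracks(pdb, paln, v$segment_width)
  asm <- assemble(pdb, paln, pdb$tracks[["repeat"]], qtracks,
                  lparams, aparams)
  say("[done] %d contigs, %.0f bases, N50 %.0f (%.1f s)",
      asm$stats$contig_count, asm$stats$total_length, asm$stats$n50,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(outdir)) {
    write_fasta(setNames(pdb$reads$sequence, pdb$reads$read_id),
                file.path(outdir, "patched_reads.fasta"))
    write_patch_report(pr$events, file.path(outdir, "patch_events.tsv"))
    write_paf(paln, pdb, file.path(outdir, "overlaps.paf"))
    write_gfa(asm$graph, pdb, asm$contigs,
              file.path(outdir, "assembly.gfa"))
    if (nrow(asm$contigs))
      write_fasta(setNames(asm$contigs$sequence, asm$contigs$contig_id),
                  file.path(outdir, "contigs.fasta"))
    jsonlite::write_json(
      list(contig_count = asm$stats$contig_count,
           total_length = asm$stats$total_length,
           n50 = asm$stats$n50,
           n_curve = as.list(asm$stats$n_curve)),
      file.path(outdir, "stats.json"), auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(outdir, "config.yaml"))
  }
  list(db = db, patched_db = pdb, contigs = asm$contigs, graph = asm$graph,
       stats = asm$stats, events = pr$events, excluded = excluded_names,
       quality = qtracks)
}

# find pairs with premature_in_repeat chains and re-align them mask-free
realign_premature <- function(aln, db, aparams) {
  if (nrow(aln) == 0) return(aln)
  rt <- db$tracks[["repeat"]]
  prem <- list()
  for (p in piles(aln)) {
    for (ch in pile_chains(p, db, rt, aparams)) {
      if (identical(attr(ch, "status"), "premature_in_repeat"))
        prem[[length(prem) + 1]] <- c(ch$a_id[1], ch$b_id[1])
    }
  }
  if (!length(prem)) return(aln)
  pp <- unique(do.call(rbind, prem))
  realign_unmasked(aln, pp, db, aparams)
}

# apply the spanning-chain rule to every read; returns excluded indices
chimera_rule_exclusions <- function(db, aln, pparams, aparams) {
  rt <- db$tracks[["repeat"]]
  if (is.null(rt)) return(integer())
  pl <- piles(aln)
  excluded <- integer()
  for (i in seq_len(nrow(db$reads))) {
    id <- db$reads$read_id[i]
    rep_iv <- rt[[id]]
    if (is.null(rep_iv) || nrow(rep_iv) == 0) next
    p <- pl[[as.character(i)]]
    chains <- if (is.null(p)) list() else pile_chains(p, db, rt, aparams)
    if (apply_chimera_repeat_rule(id, chains, rep_iv,
                                  db$reads$length[i], pparams) == "exclude")
      excluded <- c(excluded, i)
  }
  excluded
}
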