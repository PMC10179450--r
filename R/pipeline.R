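#' Run the full synthetic-to-summary analysis pipeline
#'
#' Chains the package's stages into one deterministic run: simulate a
#' repeat-bearing circular mitogenome, derive its isomers, simulate long
#' reads, count junction-spanning reads and call recombination activity, and
#' run the SSR and dispersed-repeat finders on the master genome. When a
#' GenBank annotation and/or a plastid genome are supplied the codon-usage
#' and MTPT stages run as well. All outputs are TSV/FASTA/FASTQ/BED files in
#' `outdir`, together with a `manifest.yaml` of every parameter used; a fixed
#' seed in `config` makes the run byte-identical.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param min_identity,max_end_slack Passed to [count_spanning_reads()].
#' @param genbank Optional GenBank flat file for the codon-usage stage.
#' @param plastid Optional plastid FASTA for the MTPT stage.
#' @return Invisibly, a list with the pipeline's main objects (`sim`,
#'   `isomers`, `reads`, `support`, `recombination`, `ssrs`, `dispersed`,
#'   `summary`).
#' @export
run_full_pipeline <- function(config = sim_config(), outdir,
                              min_identity = 0.8, max_end_slack = 0L,
                              genbank = NULL, plastid = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  sim <- generate_master_genome(config)
  write_fasta(sim$genome, p("master.fasta"))
  write_bed(tibble(
    chrom = sim$genome$id,
    start = sim$repeats$start - 1L,
    end = sim$repeats$end,
    name = paste0(sim$repeats$repeat_id, "_copy", sim$repeats$copy)
  ), p("repeats.bed"))

  isomers <- derive_isomers(sim)
  iso_tbl <- tidy(isomers)
  write_report_tsv(iso_tbl, p("isomers.tsv"))
  graph <- attr(isomers, "graph")
  fasta <- purrr::imap(isomers, function(iso, nm) {
    isomer_to_fasta(iso, graph, prefix = paste0("isomer_", nm))
  }) |> list_rbind()
  write_fasta(fasta, p("isomers.fasta"))
  write_gfa(graph, p("graph.gfa"))

  reads <- simulate_reads(sim, config, isomers)
  write_fastq(reads, p("reads.fastq"))
  write_report_tsv(select(reads, -"seq"), p("truth.tsv"))

  support <- NULL; recomb <- NULL
  if (nrow(sim$repeats)) {
    refs <- build_path_references(sim$genome, sim$repeats,
                                  flank_len = config$flank_len)
    support <- count_spanning_reads(reads, refs, min_identity = min_identity,
                                    max_end_slack = max_end_slack)
    write_report_tsv(support, p("junction_support.tsv"))
    recomb <- summarize_recombination(support)
    write_report_tsv(tidy(recomb), p("recombination.tsv"))
  }

  ssrs <- find_ssrs(sim$genome)
  write_report_tsv(ssrs, p("ssr.tsv"))
  dispersed <- find_dispersed_repeats(sim$genome)
  write_report_tsv(dispersed, p("dispersed_repeats.tsv"))
  rep_sum <- summarize_repeats(ssrs, dispersed, seq_len_bp(sim$genome))

  rscu <- NULL
  if (!is.null(genbank)) {
    cds <- extract_cds(genbank, genome = sim$genome)
    if (nrow(cds)) {
      rscu <- compute_rscu(cds)
      write_report_tsv(rscu, p("rscu.tsv"))
    }
  }
  mtpt <- NULL
  if (!is.null(plastid)) {
    pt <- read_fasta(plastid, circular = TRUE)
    mtpt <- find_homologous_fragments(
      sim$genome, circ_seq(pt$seq[1], id = pt$id[1], circular = TRUE))
    write_report_tsv(mtpt, p("mtpt.tsv"))
  }

  summary <- tibble(
    metric = c("genome_length", "gc_percent", "n_repeat_pairs", "n_isomers",
               "n_master_circles", "n_junction_paths", "n_reads",
               "n_ssr", "n_dispersed_pairs"),
    value = c(seq_len_bp(sim$genome), round(gc_content(sim$genome), 2),
              length(unique(sim$repeats$repeat_id)), length(isomers),
              sum(iso_tbl$classification == "master" & iso_tbl$circle == 1L),
              if (is.null(support)) 0L else nrow(support), nrow(reads),
              nrow(ssrs), nrow(dispersed))
  )
  write_report_tsv(summary, p("summary.tsv"))
  cfg <- config
  cfg$isomer_weights <- as.list(cfg$isomer_weights)
  yaml::write_yaml(
    list(parameters = cfg[!vapply(cfg, is.null, logical(1))],
         min_identity = min_identity, max_end_slack = max_end_slack),
    p("manifest.yaml"))

  invisible(list(sim = sim, isomers = isomers, reads = reads,
                 support = support, recombination = recomb, ssrs = ssrs,
                 dispersed = dispersed, rscu = rscu, mtpt = mtpt,
                 repeat_summary = rep_sum, summary = summary))
}
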