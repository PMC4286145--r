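# Pipeline entry points wiring the stages together, one per subcommand of
# the command-line wrapper (inst/cli/codonscreen.R). Every run writes its
# artifacts into one output directory plus a provenance JSON (parameters,
# seed, input checksums, package version) sufficient to re-run seeded
# stages bit-identically.

.write_provenance <- function(out_dir, subcommand, params, inputs = character()) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  checksums <- if (length(inputs) > 0L)
    as.list(tools::md5sum(unlist(inputs))) else list()
  prov <- list(subcommand = subcommand,
               package = "codonscreen",
               version = as.character(utils::packageVersion("codonscreen")),
               parameters = params,
               input_md5 = checksums,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the HGT scan pipeline
#'
#' Reads contigs and CDS annotations, extracts in-frame coding sequences,
#' screens every gene (or a subset) against the pooled background, merges
#' optional best-hit taxonomy, and writes `screen_report.tsv`,
#' `screen_summary.json` and `provenance.json` into `out_dir`.
#'
#' @param genome FASTA path.
#' @param annotations GFF3 or 6-column TSV path.
#' @param hits Optional hit-table TSV path.
#' @param subset Optional path to a file of gene ids (one per line) to
#'   report.
#' @param fold,fraction,gc_delta Screen thresholds (see [screen_params()]).
#' @param out_dir Output directory (created if needed).
#' @param code A [genetic_code()].
#' @return The screen report data.frame, invisibly.
#' @export
run_scan <- function(genome = NULL, annotations = NULL, hits = NULL, subset = NULL,
                     fold = 2, fraction = 0.25, gc_delta = 5,
                     out_dir = ".", code = genetic_code()) {
  if (is.null(genome) || is.null(annotations))
    stop("run_scan requires --genome and --annotations")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(genome)
  ann <- read_annotations(annotations)
  genes <- extract_cds(seqs, ann)
  hit_tab <- if (!is.null(hits)) read_hit_table(hits) else NULL
  subset_ids <- if (!is.null(subset)) readLines(subset) else NULL
  params <- screen_params(fold_threshold = fold,
                          fraction_threshold = fraction,
                          gc_delta_threshold = gc_delta)
  report <- screen_genome(genes, hits = hit_tab, subset = subset_ids,
                          params = params, code = code)
  .write_tsv(report, file.path(out_dir, "screen_report.tsv"))
  jsonlite::write_json(attr(report, "summary"),
                       file.path(out_dir, "screen_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .write_provenance(out_dir, "scan",
                    list(fold = fold, fraction = fraction,
                         gc_delta = gc_delta),
                    list(genome = genome, annotations = annotations,
                         hits = hits, subset = subset))
  invisible(report)
}

#' Run the genome-statistics pipeline
#'
#' Writes `genome_summary.tsv`, `genome_summary.json` and, when a COG
#' assignment table is given (TSV with columns gene_id, categories),
#' `cog_table.tsv`.
#'
#' @param genome FASTA path.
#' @param annotations Annotation path (GFF3 or TSV).
#' @param cog Optional COG assignment TSV path.
#' @param out_dir Output directory.
#' @return The [genome_summary()] object, invisibly.
#' @export
run_stats <- function(genome = NULL, annotations = NULL, cog = NULL, out_dir = ".") {
  if (is.null(genome) || is.null(annotations))
    stop("run_stats requires --genome and --annotations")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_fasta(genome)
  ann <- read_annotations(annotations)
  gs <- genome_summary(seqs, ann)
  df <- data.frame(attribute = names(unclass(gs)),
                   value = unlist(unclass(gs), use.names = FALSE))
  .write_tsv(df, file.path(out_dir, "genome_summary.tsv"))
  jsonlite::write_json(unclass(gs), file.path(out_dir, "genome_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cog)) {
    cog_df <- utils::read.delim(cog, colClasses = "character")
    ct <- cog_percentages(cog_df, total_genes = gs$total_genes)
    .write_tsv(ct$table, file.path(out_dir, "cog_table.tsv"))
  }
  .write_provenance(out_dir, "stats", list(),
                    list(genome = genome, annotations = annotations,
                         cog = cog))
  invisible(gs)
}

#' Run the phylogenetic-placement pipeline
#'
#' K2P distances and a neighbor-joining tree with bootstrap support from a
#' pre-aligned FASTA; writes `distances.tsv`, `tree.nwk` and
#' `provenance.json`.
#'
#' @param alignment Aligned FASTA path.
#' @param bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for resampling.
#' @param out_dir Output directory.
#' @return The supported `phylo` tree, invisibly.
#' @export
run_phylo <- function(alignment = NULL, bootstrap = 1000L, seed = 42L,
                      out_dir = ".") {
  if (is.null(alignment)) stop("run_phylo requires --alignment")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- read_alignment(alignment)
  dm <- k2p_matrix(aln)
  .write_tsv(data.frame(taxon = rownames(dm), dm, check.names = FALSE),
             file.path(out_dir, "distances.tsv"))
  tree <- bootstrap_nj(aln, replicates = bootstrap, seed = seed)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  .write_provenance(out_dir, "phylo",
                    list(bootstrap = bootstrap, seed = seed),
                    list(alignment = alignment))
  invisible(tree)
}

#' Run the synthetic-genome pipeline
#'
#' Writes genes.fasta, annotations.tsv, truth.tsv, hits.tsv and
#' provenance.json for a simulated genome of background plus alien genes.
#'
#' @param n_bg,n_alien Gene counts.
#' @param gc3_bg,gc3_alien Synonymous-GC3 targets of the two profiles.
#' @param len Length-2 codon-length range.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return The `synthetic_genome` object, invisibly.
#' @export
run_simulate <- function(n_bg = 200L, n_alien = 10L, gc3_bg = 0.85,
                         gc3_alien = 0.25, len = c(300L, 600L), seed = 42L,
                         out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(
    n_background = n_bg, n_alien = n_alien, len_codons_range = len,
    bg_profile = make_profile(gc3_bg, label = "background"),
    alien_profile = make_profile(gc3_alien, label = "alien"),
    seed = seed, out_dir = out_dir)
  hits <- simulate_hit_table(sim$truth, seed = seed)
  .write_tsv(hits, file.path(out_dir, "hits.tsv"))
  .write_provenance(out_dir, "simulate",
                    list(n_bg = n_bg, n_alien = n_alien, gc3_bg = gc3_bg,
                         gc3_alien = gc3_alien, len = len, seed = seed))
  invisible(sim)
}

#' Dispatch a pipeline run from a config list
#'
#' @param config List with `subcommand` (one of scan, stats, phylo,
#'   simulate) and that subcommand's arguments.
#' @return The subcommand's return value, invisibly.
#' @export
run <- function(config) {
  sub <- config$subcommand
  if (is.null(sub) || !sub %in% c("scan", "stats", "phylo", "simulate"))
    stop("unknown subcommand: ", if (is.null(sub)) "<missing>" else sub)
  config$subcommand <- NULL
  fn <- switch(sub, scan = run_scan, stats = run_stats,
               phylo = run_phylo, simulate = run_simulate)
  keep <- intersect(names(config), names(formals(fn)))
  do.call(fn, config[keep])
}
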