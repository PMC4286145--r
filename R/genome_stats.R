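# Genome-report statistics: assembly N50, nucleotide/gene count summary with
# the percentage conventions of standard genome-announcement tables, and the
# COG functional-category table with its two denominators.

#' Round half away from zero
#'
#' Genome-report tables round 2.5 -> 2.51-style halves upward, unlike R's
#' banker's rounding; this helper matches the printed convention.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # epsilon guard: 2.675 * 100 is 267.4999... in binary floating point
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage with report rounding
#'
#' @param num,den Numerator and denominator.
#' @param digits Decimal places (default 2).
#' @return `100 * num / den`, rounded half-up.
#' @export
percent_of <- function(num, den, digits = 2L) {
  round_half_up(100 * num / den, digits)
}

#' Contig N50
#'
#' The smallest contig length L such that contigs of length >= L together
#' cover at least half the assembly (sort descending, accumulate, first
#' length crossing total/2).
#'
#' @param contig_lengths Positive integer vector.
#' @return The N50 length.
#' @export
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("empty contig-length list")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  s <- sort(contig_lengths, decreasing = TRUE)
  unname(s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]])
}

#' Assembly size and N50 from contig lengths
#'
#' @param contig_lengths Positive integer vector.
#' @return List with `total_bp`, `n_contigs`, `n50_bp`.
#' @export
assembly_stats <- function(contig_lengths) {
  list(total_bp = sum(as.numeric(contig_lengths)),
       n_contigs = length(contig_lengths),
       n50_bp = n50(contig_lengths))
}

#' Genome summary statistics
#'
#' Reproduces the nucleotide-content and gene-count rows of a genome report:
#' genome size (sum of contig lengths), DNA coding (the union footprint of
#' CDS features — overlapping genes are counted once), genomic G+C, and gene
#' counts split into protein-coding and RNA genes. All percentages are
#' recomputed from the counts (of genome size for base-pair rows, of total
#' genes for gene rows), rounded to 2 decimals half-up.
#'
#' @param seqs Named character vector of contigs (from [read_fasta()]).
#' @param ann Annotation data.frame (from [read_annotations()]); an optional
#'   `type` column with values "protein"/"rna" splits the gene counts
#'   (missing column = all protein-coding).
#' @return List of class `genome_summary`.
#' @export
genome_summary <- function(seqs, ann) {
  genome_size <- sum(nchar(seqs))
  type <- if ("type" %in% names(ann)) ann$type else
    rep("protein", nrow(ann))
  stopifnot(all(type %in% c("protein", "rna")))
  coding_bp <- 0L
  cds <- ann[type == "protein", , drop = FALSE]
  if (nrow(cds) > 0L) {
    missing_contig <- setdiff(unique(cds$contig_id), names(seqs))
    if (length(missing_contig) > 0L)
      stop("annotation references unknown contig(s): ",
           paste(missing_contig, collapse = ", "))
    for (ctg in unique(cds$contig_id)) {
      rows <- cds[cds$contig_id == ctg, , drop = FALSE]
      if (any(rows$end > nchar(seqs[[ctg]])))
        stop("gene coordinates beyond contig ", ctg)
      ir <- IRanges::reduce(IRanges::IRanges(rows$start, rows$end))
      coding_bp <- coding_bp + sum(IRanges::width(ir))
    }
  }
  gc_bp <- sum(vapply(seqs, function(s)
    nchar(gsub("[^GCgc]", "", s)), 0L))
  n_protein <- sum(type == "protein")
  n_rna <- sum(type == "rna")
  total_genes <- n_protein + n_rna
  structure(list(
    genome_size_bp = genome_size,
    n_contigs = length(seqs),
    n50_bp = n50(nchar(seqs)),
    dna_coding_bp = coding_bp,
    dna_coding_percent = percent_of(coding_bp, genome_size),
    gc_bp = gc_bp,
    gc_percent = percent_of(gc_bp, genome_size),
    total_genes = total_genes,
    protein_coding_genes = n_protein,
    protein_coding_percent = if (total_genes > 0)
      percent_of(n_protein, total_genes) else 0,
    rna_genes = n_rna,
    rna_percent = if (total_genes > 0) percent_of(n_rna, total_genes) else 0
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("Genome: %s bp in %d contig(s), N50 %s bp\n",
              format(x$genome_size_bp, big.mark = ","), x$n_contigs,
              format(x$n50_bp, big.mark = ",")))
  cat(sprintf("DNA coding: %s bp (%.2f%%); G+C: %s bp (%.2f%%)\n",
              format(x$dna_coding_bp, big.mark = ","), x$dna_coding_percent,
              format(x$gc_bp, big.mark = ","), x$gc_percent))
  cat(sprintf("Genes: %d total; %d protein-coding (%.2f%%), %d RNA (%.2f%%)\n",
              x$total_genes, x$protein_coding_genes,
              x$protein_coding_percent, x$rna_genes, x$rna_percent))
  invisible(x)
}

COG_CATEGORIES <- c(
  J = "Translation",
  A = "RNA processing and modification",
  K = "Transcription",
  L = "Replication, recombination and repair",
  B = "Chromatin structure and dynamics",
  D = "Cell cycle control, mitosis and meiosis",
  Y = "Nuclear structure",
  V = "Defense mechanisms",
  T = "Signal transduction mechanisms",
  M = "Cell wall/membrane biogenesis",
  N = "Cell motility",
  Z = "Cytoskeleton",
  W = "Extracellular structures",
  U = "Intracellular trafficking and secretion",
  O = "Posttranslational modification, protein turnover, chaperones",
  C = "Energy production and conversion",
  G = "Carbohydrate transport and metabolism",
  E = "Amino acid transport and metabolism",
  F = "Nucleotide transport and metabolism",
  H = "Coenzyme transport and metabolism",
  I = "Lipid transport and metabolism",
  P = "Inorganic ion transport and metabolism",
  Q = "Secondary metabolites biosynthesis, transport and catabolism",
  R = "General function prediction only",
  S = "Function unknown")

#' COG functional-category table
#'
#' Builds the 25-category COG table with the dual-denominator convention of
#' published genome reports: each category percentage divides by the total
#' number of category assignments (a gene carrying two categories contributes
#' twice), while the "Not in COGs" percentage divides by the total gene
#' count. A uniform mode divides every row by `total_genes` instead.
#'
#' @param assignments One of: a named list (gene_id -> character vector of
#'   category letters); a data.frame with columns gene_id and categories
#'   (letters, possibly concatenated as e.g. "EG"); or a named integer
#'   vector of pre-tabulated per-category counts (as a printed report table
#'   supplies), in which case `n_genes_in_cogs` must be given.
#' @param total_genes Total number of genes in the genome (denominator of
#'   the Not-in-COGs row).
#' @param denominator `"assignments"` (the published convention, default)
#'   or `"total_genes"`.
#' @param n_genes_in_cogs Number of genes with at least one COG assignment;
#'   required (and only used) when `assignments` is a count vector.
#' @return List of class `cog_table`: `table` (data.frame code, count,
#'   percent, description), `not_in_cogs` (count + percent), and the two
#'   denominators used.
#' @export
cog_percentages <- function(assignments, total_genes,
                            denominator = c("assignments", "total_genes"),
                            n_genes_in_cogs = NULL) {
  denominator <- match.arg(denominator)
  if (is.data.frame(assignments)) {
    stopifnot(all(c("gene_id", "categories") %in% names(assignments)))
    assignments <- stats::setNames(
      strsplit(gsub("[^A-Z]", "", toupper(assignments$categories)), ""),
      assignments$gene_id)
  }
  if (is.numeric(assignments)) {
    unknown <- setdiff(names(assignments), names(COG_CATEGORIES))
    if (length(unknown) > 0L)
      stop("unknown COG category letter(s): ", paste(unknown, collapse = ", "))
    if (is.null(n_genes_in_cogs))
      stop("n_genes_in_cogs is required when passing per-category counts")
    counts <- stats::setNames(integer(length(COG_CATEGORIES)),
                              names(COG_CATEGORIES))
    counts[names(assignments)] <- as.integer(assignments)
    counts <- as.table(counts)
    n_in_cogs <- n_genes_in_cogs
  } else {
    codes <- unlist(assignments, use.names = FALSE)
    unknown <- setdiff(codes, names(COG_CATEGORIES))
    if (length(unknown) > 0L)
      stop("unknown COG category letter(s): ", paste(unknown, collapse = ", "))
    counts <- table(factor(codes, levels = names(COG_CATEGORIES)))
    n_in_cogs <- sum(lengths(assignments) > 0L)
  }
  n_assignments <- sum(counts)
  if (n_in_cogs > total_genes)
    stop("more genes with COG assignments than total_genes")
  not_in <- total_genes - n_in_cogs
  den <- if (denominator == "assignments") n_assignments else total_genes
  tab <- data.frame(code = names(COG_CATEGORIES),
                    count = as.integer(counts),
                    percent = percent_of(as.integer(counts), den),
                    description = unname(COG_CATEGORIES),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 not_in_cogs = list(count = not_in,
                                    percent = percent_of(not_in, total_genes)),
                 denominator_categories = den,
                 denominator_not_in_cogs = total_genes),
            class = "cog_table")
}

#' @export
print.cog_table <- function(x, ...) {
  cat(sprintf("COG categories (category %% of %d assignments; not-in-COGs %% of %d genes)\n",
              x$denominator_categories, x$denominator_not_in_cogs))
  print(x$table, row.names = FALSE)
  cat(sprintf("  Not in COGs: %d (%.2f%%)\n",
              x$not_in_cogs$count, x$not_in_cogs$percent))
  invisible(x)
}
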