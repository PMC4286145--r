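# Codon-level composition statistics: codon counts, GC content overall and by
# codon position, synonymous third-position GC (GC3s), and relative
# synonymous codon usage (RSCU).
#
# RSCU for codon c of amino acid a with synonymous family syn(a) of size k_a:
#   RSCU_c = n_c / ((1/k_a) * sum_{c' in syn(a)} n_{c'})
# i.e. observed count over the count expected under uniform synonymous usage;
# 1 means unbiased. RSCU is undefined (NA) when the amino acid is absent from
# the counted sequence — deliberately distinct from 0, which means a present
# amino acid avoiding that codon.

# Accepts a gene set as a data.frame with gene_id/sequence columns (the
# extract_cds shape) or a named character vector; returns named character.
.gene_seqs <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene_id", "sequence") %in% names(genes)))
    return(stats::setNames(genes$sequence, genes$gene_id))
  }
  if (is.character(genes)) {
    if (length(genes) == 0L) stop("empty gene list")
    if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
    return(genes)
  }
  stop("genes must be a data.frame with gene_id/sequence or a named character vector")
}

#' Count codons in a coding sequence
#'
#' The sequence is read as consecutive non-overlapping triplets from position
#' 1 (a trailing partial codon is dropped). Triplets containing any character
#' other than A, C, G or T are excluded from the counts and tallied
#' separately, so ambiguity codes never distort codon statistics.
#'
#' @param sequence A single in-frame nucleotide string (coding strand).
#' @param code A [genetic_code()].
#' @return List of class `codon_counts`: `counts` (named integer over all 64
#'   codons), `n_codons` (sum of counts) and `n_excluded` (ambiguous
#'   triplets).
#' @export
count_codons <- function(sequence, code = genetic_code()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n3 <- nchar(sequence) %/% 3L
  if (n3 < 1L) stop("sequence shorter than one codon")
  starts <- 3L * (seq_len(n3) - 1L) + 1L
  trip <- substring(sequence, starts, starts + 2L)
  clean <- trip[!grepl("[^ACGT]", trip)]
  counts <- stats::setNames(integer(64L), code$codons)
  if (length(clean) > 0L) {
    tab <- table(factor(clean, levels = code$codons))
    counts <- stats::setNames(as.integer(tab), code$codons)
  }
  structure(list(counts = counts,
                 n_codons = length(clean),
                 n_excluded = n3 - length(clean)),
            class = "codon_counts")
}

#' Sum codon-count tables element-wise
#'
#' @param tables List of `codon_counts` objects.
#' @return A pooled `codon_counts`.
#' @export
sum_codon_counts <- function(tables) {
  stopifnot(length(tables) >= 1L)
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  structure(list(counts = counts,
                 n_codons = sum(vapply(tables, `[[`, 0L, "n_codons")),
                 n_excluded = sum(vapply(tables, `[[`, 0L, "n_excluded"))),
            class = "codon_counts")
}

#' GC content metrics from a codon-count table
#'
#' `gc` is the G+C fraction over all counted codon positions, `gc1`/`gc2`/
#' `gc3_all` the fractions at codon positions 1, 2, 3. `gc3_syn` (CodonW's
#' GC3s) restricts the third-position fraction to codons of the degenerate
#' universe — amino acids with synonymous alternatives — so it excludes Met,
#' Trp and stop codons. Stop codons do contribute to `gc`/`gc1`/`gc2`/
#' `gc3_all`.
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return Named numeric vector gc, gc1, gc2, gc3_all, gc3_syn (fractions in
#'   \[0, 1\]; `gc3_syn` is NA when no degenerate codon was counted).
#' @export
gc_metrics <- function(counts, code = genetic_code()) {
  n <- counts$counts
  total <- counts$n_codons
  if (total < 1L) stop("empty codon-count table")
  pos_gc <- function(p) {
    is_gc <- substring(names(n), p, p) %in% c("G", "C")
    sum(n[is_gc]) / total
  }
  gc1 <- pos_gc(1L); gc2 <- pos_gc(2L); gc3 <- pos_gc(3L)
  deg <- names(n) %in% code$degenerate_codons
  n_deg <- sum(n[deg])
  gc3s <- if (n_deg == 0L) NA_real_ else {
    sum(n[deg & substring(names(n), 3L, 3L) %in% c("G", "C")]) / n_deg
  }
  c(gc = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2,
    gc3_all = gc3, gc3_syn = gc3s)
}

#' Relative synonymous codon usage
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the 64 codons. Stop codons are always
#'   NA; sense codons of an amino acid with zero observations are NA
#'   (undefined); otherwise `RSCU = k_a * n_c / sum(family counts)`.
#' @export
rscu <- function(counts, code = genetic_code()) {
  n <- counts$counts
  aa <- code$codon_to_aa[names(n)]
  out <- stats::setNames(rep(NA_real_, length(n)), names(n))
  fam_tot <- tapply(n, aa, sum)
  sense <- aa != "*"
  defined <- sense & fam_tot[aa] > 0
  out[defined] <- n[defined] * code$family_size[aa[defined]] /
    fam_tot[aa[defined]]
  out
}

#' Full composition profile of a codon-count table
#'
#' @param counts A `codon_counts` object.
#' @param code A [genetic_code()].
#' @return List of class `composition_profile` with the GC metrics of
#'   [gc_metrics()], the [rscu()] vector, `n_codons` and `n_excluded`.
#' @export
composition_profile <- function(counts, code = genetic_code()) {
  gm <- gc_metrics(counts, code)
  structure(c(as.list(gm),
              list(rscu = rscu(counts, code),
                   n_codons = counts$n_codons,
                   n_excluded = counts$n_excluded)),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf(
    "Composition profile: %d codons (%d excluded); GC %.3f, GC3all %.3f, GC3s %s\n",
    x$n_codons, x$n_excluded, x$gc, x$gc3_all,
    ifelse(is.na(x$gc3_syn), "NA", sprintf("%.3f", x$gc3_syn))))
  invisible(x)
}

#' Pool genes into a background count table and profile
#'
#' The background is the pooled codon-count table of all supplied genes (the
#' element-wise sum), and the profile is computed from that pooled table —
#' not the mean of per-gene profiles — so long genes weigh in proportion to
#' their codon count, as a genome-wide background should.
#'
#' @param genes Gene set: data.frame with gene_id/sequence columns or a named
#'   character vector of sequences.
#' @param code A [genetic_code()].
#' @return List with elements `counts` (pooled `codon_counts`) and `profile`
#'   (`composition_profile`).
#' @export
pool_background <- function(genes, code = genetic_code()) {
  seqs <- .gene_seqs(genes)
  if (length(seqs) == 0L) stop("empty gene list")
  tables <- lapply(seqs, count_codons, code = code)
  pooled <- sum_codon_counts(tables)
  list(counts = pooled, profile = composition_profile(pooled, code))
}

#' Per-gene composition table
#'
#' One row per gene: codon totals, GC metrics and the 64 RSCU values
#' (undefined serialized as NA), suitable for writing as TSV.
#'
#' @param genes Gene set (see [pool_background()]).
#' @param code A [genetic_code()].
#' @return data.frame with columns gene_id, n_codons, n_excluded, gc, gc1,
#'   gc2, gc3_all, gc3_syn and one column per codon (RSCU).
#' @export
composition_table <- function(genes, code = genetic_code()) {
  seqs <- .gene_seqs(genes)
  rows <- lapply(seq_along(seqs), function(i) {
    ct <- count_codons(seqs[[i]], code)
    gm <- gc_metrics(ct, code)
    r <- rscu(ct, code)
    cbind(data.frame(gene_id = names(seqs)[i], n_codons = ct$n_codons,
                     n_excluded = ct$n_excluded, stringsAsFactors = FALSE),
          as.data.frame(as.list(gm)), as.data.frame(as.list(r)))
  })
  do.call(rbind, rows)
}
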