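# Compositional HGT-candidate screen.
#
# A gene is compositionally atypical when the RSCU of more than a threshold
# fraction (default 25%) of the degenerate codons it actually uses changes by
# more than a fold threshold (default 2) relative to the pooled all-gene
# background. GC and synonymous third-position GC deviations from the
# background are reported alongside, and a best-hit taxonomy table (closest
# database relative per gene) supplies the independent line of evidence: a
# closest relative outside the genome's own family. The two lines are
# combined into an evidence class, never forced into a single boolean,
# because composition and similarity can disagree for recent vs ameliorated
# transfers.

#' Screen parameters
#'
#' @param fold_threshold RSCU fold-change threshold; a codon counts as
#'   changed when its symmetric fold change exceeds this (strictly, by
#'   default). Default 2.
#' @param fraction_threshold Fraction of used degenerate codons that must be
#'   changed for the gene-level RSCU flag (strict inequality by default).
#'   Default 0.25.
#' @param gc_delta_threshold GC/GC3s deviation threshold in percentage
#'   points for the GC flag. Default 5.
#' @param self_family Taxon family counted as "self" when classifying
#'   closest-relative hits. Default "Halomonadaceae".
#' @param strict Use strict inequalities (">") for the fold and fraction
#'   rules. Default TRUE.
#' @return List of class `screen_params`.
#' @export
screen_params <- function(fold_threshold = 2, fraction_threshold = 0.25,
                          gc_delta_threshold = 5,
                          self_family = "Halomonadaceae", strict = TRUE) {
  stopifnot(fold_threshold > 1, fraction_threshold > 0,
            fraction_threshold < 1, gc_delta_threshold > 0)
  structure(list(fold_threshold = fold_threshold,
                 fraction_threshold = fraction_threshold,
                 gc_delta_threshold = gc_delta_threshold,
                 self_family = self_family,
                 strict = strict),
            class = "screen_params")
}

#' Symmetric RSCU fold change
#'
#' Direction-agnostic: over- and under-representation are treated alike, so
#' the fold change of gene value g against background value b is
#' `max(g/b, b/g)`. A codon the gene uses but the background never does gives
#' +Inf; a codon the gene does not use, or whose background RSCU is undefined
#' (amino acid absent from the background), gives NA — such codons are
#' excluded from the screen's denominator.
#'
#' @param rscu_gene,rscu_bg Numeric vectors of RSCU values (NA = undefined).
#' @return Numeric vector of fold changes (may contain Inf and NA).
#' @export
fold_change <- function(rscu_gene, rscu_bg) {
  stopifnot(length(rscu_gene) == length(rscu_bg))
  out <- rep(NA_real_, length(rscu_gene))
  usable <- !is.na(rscu_gene) & rscu_gene > 0 & !is.na(rscu_bg)
  pos_bg <- usable & rscu_bg > 0
  out[pos_bg] <- pmax(rscu_gene[pos_bg] / rscu_bg[pos_bg],
                      rscu_bg[pos_bg] / rscu_gene[pos_bg])
  out[usable & rscu_bg == 0] <- Inf
  out
}

#' Screen one gene against a background profile
#'
#' Counts, over the degenerate-codon universe, the codons this gene uses
#' (`n_used`: gene count > 0 and background RSCU defined) and those whose
#' symmetric RSCU fold change exceeds the fold threshold (`n_changed`). The
#' gene is RSCU-flagged when `n_changed / n_used` exceeds the fraction
#' threshold; the fraction with the fixed universe size as denominator is
#' reported alongside. GC and GC3s deviations (gene minus background, in
#' percentage points) raise the GC flag when either exceeds the GC delta
#' threshold in absolute value.
#'
#' @param gene_counts `codon_counts` of the gene (from [count_codons()]).
#' @param bg_profile `composition_profile` of the pooled background.
#' @param code A [genetic_code()].
#' @param params A [screen_params()].
#' @param gene_id Optional identifier carried into the result.
#' @return One-row data.frame: gene_id, n_used, n_changed, fraction_changed,
#'   fraction_changed_universe, rscu_flag, gc_delta, gc3_delta, gc_flag.
#' @export
screen_gene <- function(gene_counts, bg_profile, code = genetic_code(),
                        params = screen_params(), gene_id = NA_character_) {
  deg <- code$degenerate_codons
  g_rscu <- rscu(gene_counts, code)[deg]
  b_rscu <- bg_profile$rscu[deg]
  used <- gene_counts$counts[deg] > 0L & !is.na(b_rscu)
  if (!any(gene_counts$counts[deg] > 0L))
    stop("gene uses no degenerate codon; cannot screen")
  fc <- fold_change(g_rscu, b_rscu)
  exceeds <- if (params$strict) fc > params$fold_threshold else
    fc >= params$fold_threshold
  changed <- used & !is.na(fc) & exceeds
  n_used <- sum(used)
  n_changed <- sum(changed)
  frac <- n_changed / n_used
  rscu_flag <- if (params$strict) frac > params$fraction_threshold else
    frac >= params$fraction_threshold
  g_gc <- gc_metrics(gene_counts, code)
  gc_delta <- 100 * (g_gc[["gc"]] - bg_profile$gc)
  gc3_delta <- 100 * (g_gc[["gc3_syn"]] - bg_profile$gc3_syn)
  gc_flag <- isTRUE(abs(gc_delta) > params$gc_delta_threshold) ||
    isTRUE(abs(gc3_delta) > params$gc_delta_threshold)
  data.frame(gene_id = gene_id, n_used = n_used, n_changed = n_changed,
             fraction_changed = frac,
             fraction_changed_universe = n_changed / length(deg),
             rscu_flag = rscu_flag, gc_delta = gc_delta,
             gc3_delta = gc3_delta, gc_flag = gc_flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genus-to-family taxonomy lookup
#'
#' The packaged default covers the Halomonadaceae genera plus the foreign
#' genera that typically appear as closest relatives of halophile
#' metal-resistance genes. Unknown genera resolve to "unknown", never
#' silently to self.
#'
#' @param extra Optional named character vector of additional genus = family
#'   pairs; entries override the defaults.
#' @return Named character vector, genus -> family.
#' @export
default_taxonomy <- function(extra = NULL) {
  tax <- c(
    # family Halomonadaceae
    Halomonas = "Halomonadaceae", Chromohalobacter = "Halomonadaceae",
    Cobetia = "Halomonadaceae", Kushneria = "Halomonadaceae",
    Modicisalibacter = "Halomonadaceae", Salinicola = "Halomonadaceae",
    Zymobacter = "Halomonadaceae", Carnimonas = "Halomonadaceae",
    Halotalea = "Halomonadaceae", Aidingimonas = "Halomonadaceae",
    # common foreign closest-relative genera
    Idiomarina = "Idiomarinaceae", Gracilimonas = "Balneolaceae",
    Burkholderia = "Burkholderiaceae", Pseudomonas = "Pseudomonadaceae",
    Paraglaciecola = "Alteromonadaceae", Glaciecola = "Alteromonadaceae",
    Stenotrophomonas = "Xanthomonadaceae",
    Pseudoxanthomonas = "Xanthomonadaceae",
    Sphingopyxis = "Sphingomonadaceae", Hyphomonas = "Hyphomonadaceae",
    Thialkalivibrio = "Ectothiorhodospiraceae",
    Thioalkalivibrio = "Ectothiorhodospiraceae")
  if (!is.null(extra)) tax[names(extra)] <- extra
  tax
}

#' Classify a closest-relative hit as self-family or foreign
#'
#' The genus is the first whitespace token of the organism name (so
#' "Halomonas sp." resolves by genus). A genus missing from the lookup yields
#' family "unknown" and `foreign_hit = NA`: unknowns are excluded from
#' foreign tallies rather than silently counted either way.
#'
#' @param organism Character vector of organism names.
#' @param taxmap Genus-to-family lookup (see [default_taxonomy()]).
#' @param params A [screen_params()] (supplies `self_family`).
#' @return data.frame with columns organism, genus, family, foreign_hit
#'   (logical, NA for unknown genus).
#' @export
classify_hit <- function(organism, taxmap = default_taxonomy(),
                         params = screen_params()) {
  stopifnot(is.character(organism), all(nzchar(organism)))
  genus <- vapply(strsplit(trimws(organism), "\\s+"), `[[`, "", 1L)
  family <- unname(taxmap[genus])
  family[is.na(family)] <- "unknown"
  foreign <- family != params$self_family
  foreign[family == "unknown"] <- NA
  data.frame(organism = organism, genus = genus, family = family,
             foreign_hit = foreign, stringsAsFactors = FALSE)
}

.evidence_class <- function(comp_flag, foreign_hit) {
  ifelse(comp_flag & !is.na(foreign_hit) & foreign_hit, "both",
    ifelse(comp_flag, "composition_only",
      ifelse(!is.na(foreign_hit) & foreign_hit, "taxonomy_only", "none")))
}

#' Screen a genome's genes for HGT candidates
#'
#' The background is always the pooled codon-count table of all supplied
#' genes, even when `subset` restricts which genes are reported (the genome
#' background must not shrink with the report). Each reported gene receives
#' the per-gene screen of [screen_gene()], the taxonomy verdict of
#' [classify_hit()] when a hit table is given, and a combined evidence class
#' in \{both, composition_only, taxonomy_only, none\}.
#'
#' @param genes Gene set: data.frame with gene_id/sequence columns (the
#'   [extract_cds()] shape) or a named character vector of CDS sequences.
#' @param hits Optional hit table (from [read_hit_table()]).
#' @param subset Optional character vector of gene ids to report.
#' @param params A [screen_params()].
#' @param code A [genetic_code()].
#' @param taxmap Genus-to-family lookup for [classify_hit()].
#' @return data.frame, one row per reported gene, with the screen columns
#'   plus hit_organism, hit_family, foreign_hit, evidence_class. A `summary`
#'   attribute holds per-class counts and the foreign tally as "x_of_n".
#' @export
screen_genome <- function(genes, hits = NULL, subset = NULL,
                          params = screen_params(), code = genetic_code(),
                          taxmap = default_taxonomy()) {
  seqs <- .gene_seqs(genes)
  if (length(seqs) == 0L) stop("empty gene list")
  if (!is.null(subset)) {
    absent <- setdiff(subset, names(seqs))
    if (length(absent) > 0L)
      stop("subset gene(s) absent from gene set: ",
           paste(absent, collapse = ", "))
  }
  tables <- lapply(seqs, count_codons, code = code)
  bg <- composition_profile(sum_codon_counts(tables), code)
  report_ids <- if (is.null(subset)) names(seqs) else subset
  rows <- lapply(report_ids, function(id)
    screen_gene(tables[[id]], bg, code, params, gene_id = id))
  res <- do.call(rbind, rows)
  res$hit_organism <- NA_character_
  res$hit_family <- NA_character_
  res$foreign_hit <- NA
  if (!is.null(hits) && nrow(hits) > 0L) {
    cls <- classify_hit(hits$organism, taxmap, params)
    idx <- match(res$gene_id, hits$gene_id)
    res$hit_organism <- hits$organism[idx]
    res$hit_family <- cls$family[idx]
    res$foreign_hit <- cls$foreign_hit[idx]
    if (any(!is.na(idx) & cls$family[idx] == "unknown"))
      message("genus not in taxonomy map for: ",
              paste(unique(cls$genus[idx][cls$family[idx] == "unknown"]),
                    collapse = ", "))
  }
  comp_flag <- res$rscu_flag | res$gc_flag
  res$evidence_class <- .evidence_class(comp_flag, res$foreign_hit)
  n_with_hit <- sum(!is.na(res$foreign_hit))
  attr(res, "summary") <- list(
    n_genes = length(seqs),
    n_reported = nrow(res),
    n_rscu_flag = sum(res$rscu_flag),
    n_gc_flag = sum(res$gc_flag),
    foreign_of_classified = sprintf("%d of %d",
                                    sum(res$foreign_hit, na.rm = TRUE),
                                    n_with_hit),
    by_class = as.list(table(res$evidence_class)))
  res
}
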