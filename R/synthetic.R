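# Synthetic coding-sequence sets with controlled codon-usage structure.
#
# The generator emulates the compositional situation a codon-usage HGT
# screen faces: a large population of "native" genes drawn from one codon
# profile (typically GC3-rich, as in a high-GC halophile genome) and a small
# number of planted "alien" genes drawn from a divergent profile (typically
# AT3-rich, resembling a recent low-GC donor). Truth labels make recovery
# measurable. All randomness flows from one integer seed through per-gene
# substreams, so adding genes never changes the sequences of earlier genes.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

# deterministic substream seed for gene i under master seed
# (double arithmetic avoids 32-bit overflow; result fits in an R integer)
.substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1009) %% 2147483 + i)
}

#' Build a codon-usage profile with a target synonymous GC3
#'
#' Within each synonymous family, probability mass `gc3_bias` is spread
#' uniformly over the G/C-ending codons and `1 - gc3_bias` over the
#' A/T-ending codons (a family lacking one class puts all mass on the
#' other). `alpha > 0` perturbs each family with Dirichlet-style jitter
#' (seeded), modelling gene-to-gene idiosyncrasy around the target; small
#' alpha means strong jitter. Long genes simulated from the profile have
#' expected synonymous GC3 close to `gc3_bias`.
#'
#' @param gc3_bias Target synonymous third-position GC, in \[0, 1\].
#' @param alpha Jitter concentration; 0 (default) disables jitter.
#' @param seed Seed for the jitter (only used when `alpha > 0`).
#' @param code A [genetic_code()].
#' @param aa_frequencies Optional named probability vector over the amino
#'   acids (default uniform over the 20 sense amino acids).
#' @param label Profile label carried through to outputs.
#' @return List of class `codon_profile`: `families` (per amino acid, named
#'   probability vector over its synonymous codons), `aa_frequencies`,
#'   `gc3_bias`, `label`.
#' @export
make_profile <- function(gc3_bias, alpha = 0, seed = 1L,
                         code = genetic_code(), aa_frequencies = NULL,
                         label = sprintf("gc3_%0.2f", gc3_bias)) {
  stopifnot(gc3_bias >= 0, gc3_bias <= 1, alpha >= 0)
  aas <- sort(unique(unname(code$codon_to_aa[code$codon_to_aa != "*"])))
  if (is.null(aa_frequencies)) {
    aa_frequencies <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  stopifnot(abs(sum(aa_frequencies) - 1) < 1e-8,
            all(aas %in% names(aa_frequencies)))
  families <- .with_seed(seed, lapply(aas, function(a) {
    syn <- synonymous_codons(code, a)
    ends_gc <- substring(syn, 3L, 3L) %in% c("G", "C")
    p <- numeric(length(syn))
    if (all(ends_gc)) p[] <- 1 / length(syn)
    else if (!any(ends_gc)) p[] <- 1 / length(syn)
    else {
      p[ends_gc] <- gc3_bias / sum(ends_gc)
      p[!ends_gc] <- (1 - gc3_bias) / sum(!ends_gc)
    }
    if (alpha > 0 && length(syn) > 1L) {
      # Dirichlet(alpha * p) jitter via gamma draws
      g <- stats::rgamma(length(syn), shape = pmax(alpha * p, 1e-6))
      if (sum(g) > 0) p <- g / sum(g)
    }
    stats::setNames(p, syn)
  }))
  names(families) <- aas
  structure(list(families = families,
                 aa_frequencies = aa_frequencies[aas],
                 gc3_bias = gc3_bias, alpha = alpha, label = label),
            class = "codon_profile")
}

# one gene: start codon + len_codons iid amino acids drawn through the
# profile + one stop codon
.simulate_gene <- function(profile, len_codons, code, seed) {
  .with_seed(seed, {
    aas <- sample(names(profile$aa_frequencies), len_codons, replace = TRUE,
                  prob = profile$aa_frequencies)
    body <- vapply(aas, function(a) {
      fam <- profile$families[[a]]
      if (length(fam) == 1L) names(fam) else
        sample(names(fam), 1L, prob = fam)
    }, "")
    stop_codon <- sample(code$stop_codons, 1L)
    paste0("ATG", paste(body, collapse = ""), stop_codon)
  })
}

#' Simulate a synthetic genome of background and alien genes
#'
#' Each gene is an ATG start, `len` iid amino acids (uniform length in
#' `len_codons_range`) encoded through its population's codon profile, and
#' a stop codon. Gene order is background genes first, then alien genes;
#' per-gene seed substreams make the output byte-identical under the same
#' seed and keep early genes stable when more are appended.
#'
#' @param n_background,n_alien Gene counts (at least one total).
#' @param len_codons_range Length-2 integer range of body lengths in codons
#'   (default c(300, 600)).
#' @param bg_profile,alien_profile [make_profile()] objects (defaults:
#'   GC3-rich background 0.85, AT3-rich alien 0.25).
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, writes genes.fasta,
#'   annotations.tsv, truth.tsv.
#' @param code A [genetic_code()].
#' @return List of class `synthetic_genome`: `genes` (data.frame gene_id,
#'   sequence, length_nt), `truth` (data.frame gene_id, origin in
#'   \{background, alien\}), `seed`, `params`.
#' @export
simulate_genome <- function(n_background = 200L, n_alien = 10L,
                            len_codons_range = c(300L, 600L),
                            bg_profile = make_profile(0.85, label = "background"),
                            alien_profile = make_profile(0.25, label = "alien"),
                            seed = 1L, out_dir = NULL,
                            code = genetic_code()) {
  stopifnot(n_background >= 0L, n_alien >= 0L,
            length(len_codons_range) == 2L,
            len_codons_range[1] >= 10L,
            len_codons_range[2] >= len_codons_range[1])
  n <- n_background + n_alien
  if (n == 0L) stop("need at least one gene")
  origin <- c(rep("background", n_background), rep("alien", n_alien))
  ids <- sprintf("%s_%04d", ifelse(origin == "alien", "ALIEN", "BG"),
                 seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    sub <- .substream(seed, i)
    len <- .with_seed(sub, sample(len_codons_range[1]:len_codons_range[2], 1L))
    prof <- if (origin[i] == "alien") alien_profile else bg_profile
    seqs[i] <- .simulate_gene(prof, len, code, seed = sub + 1L)
  }
  genes <- data.frame(gene_id = ids, sequence = seqs,
                      length_nt = nchar(seqs), stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = ids, origin = origin,
                      stringsAsFactors = FALSE)
  out <- structure(list(genes = genes, truth = truth, seed = seed,
                        params = list(n_background = n_background,
                                      n_alien = n_alien,
                                      len_codons_range = len_codons_range,
                                      bg_label = bg_profile$label,
                                      alien_label = alien_profile$label,
                                      bg_gc3 = bg_profile$gc3_bias,
                                      alien_gc3 = alien_profile$gc3_bias)),
                   class = "synthetic_genome")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(genes$sequence, genes$gene_id),
                file.path(out_dir, "genes.fasta"))
    # each gene is its own FASTA record, so annotations address the record
    ann <- data.frame(genes$gene_id, genes$gene_id, 1L, genes$length_nt, "+",
                      paste0("simulated ", origin, " gene"))
    utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "Synthetic genome: %d background + %d alien genes (seed %d)\n",
    x$params$n_background, x$params$n_alien, x$seed))
  invisible(x)
}

#' Simulate a best-hit taxonomy table matching truth labels
#'
#' Background genes draw their closest relative from `self_organisms`,
#' alien genes from `foreign_organisms`; identities are drawn uniformly in
#' \[40, 99\]. Deterministic under `seed`.
#'
#' @param truth Truth data.frame (gene_id, origin) from [simulate_genome()].
#' @param self_organisms,foreign_organisms Non-empty character vectors of
#'   organism names.
#' @param seed Integer seed.
#' @return Hit-table data.frame (gene_id, organism, class, identity,
#'   accession), the [read_hit_table()] shape.
#' @export
simulate_hit_table <- function(truth,
                               self_organisms = c("Halomonas lutea",
                                                  "Halomonas sp.",
                                                  "Chromohalobacter salexigens"),
                               foreign_organisms = c("Burkholderia cepacia",
                                                     "Pseudomonas putida",
                                                     "Paraglaciecola polaris",
                                                     "Stenotrophomonas maltophilia"),
                               seed = 1L) {
  stopifnot(length(self_organisms) > 0L, length(foreign_organisms) > 0L,
            all(c("gene_id", "origin") %in% names(truth)))
  .with_seed(seed, {
    n <- nrow(truth)
    org <- character(n)
    alien <- truth$origin == "alien"
    org[alien] <- sample(foreign_organisms, sum(alien), replace = TRUE)
    org[!alien] <- sample(self_organisms, sum(!alien), replace = TRUE)
    data.frame(gene_id = truth$gene_id, organism = org,
               class = "Gammaproteobacteria",
               identity = round(stats::runif(n, 40, 99), 1),
               accession = sprintf("SYN_%06d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}
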