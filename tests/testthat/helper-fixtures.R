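# Shared fixtures: random in-frame coding sequences and tiny on-disk files.

SENSE_CODONS <- local({
  code <- genetic_code()
  setdiff(code$codons, code$stop_codons)
})

# random in-frame CDS (no stops in body) of n codons
random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

random_gene_set <- function(n_genes, len_range = c(30, 120)) {
  lens <- sample(len_range[1]:len_range[2], n_genes, replace = TRUE)
  setNames(vapply(lens, random_cds, ""), sprintf("g%03d", seq_len(n_genes)))
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# character-level brute-force composition oracle, independent of the
# codon-count path: positional GC by direct string indexing
oracle_gc <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n3 <- length(chars) %/% 3
  chars <- chars[seq_len(3 * n3)]
  pos <- rep(1:3, n3)
  keep_codon <- colSums(matrix(chars %in% c("A", "C", "G", "T"), nrow = 3)) == 3
  used <- rep(keep_codon, each = 3)
  gc <- chars %in% c("G", "C")
  c(gc = mean(gc[used]),
    gc1 = mean(gc[used & pos == 1]),
    gc2 = mean(gc[used & pos == 2]),
    gc3_all = mean(gc[used & pos == 3]))
}

# 4-taxon alignment with two clean clades (AB vs CD): within-clade
# divergence ~2%, between-clade ~20% — far from K2P saturation
make_two_clade_alignment <- function(len = 400, seed = 1) {
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  anc <- sample(nt, len, replace = TRUE)
  mutate <- function(v, rate) {
    idx <- sample(len, round(rate * len))
    v[idx] <- sample(nt, length(idx), replace = TRUE)
    v
  }
  clade2 <- mutate(anc, 0.2)
  aln <- list(A = mutate(anc, 0.02), B = mutate(anc, 0.02),
              C = mutate(clade2, 0.02), D = mutate(clade2, 0.02))
  vapply(aln, paste, "", collapse = "")
}

# brute-force N50: try every length as candidate L per the definition
oracle_n50 <- function(lens) {
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= total / 2) return(L)
}
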