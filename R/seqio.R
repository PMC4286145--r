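# Sequence and table input/output: FASTA contigs, CDS annotations (GFF3 or
# 6-column TSV), in-frame CDS extraction, and the best-hit taxonomy table.
# Coordinates are 1-based inclusive throughout, matching GFF3 and the way
# bacterial genome reports print gene positions.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-")

#' Read a nucleotide FASTA file
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet; identifiers (the header token before the first whitespace) must
#' be unique and sequences non-empty. The remainder of each header line is
#' kept in the `descriptions` attribute.
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @return Named character vector of uppercase sequences, one per record, in
#'   file order, with a `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad_pat <- sprintf("[^%s]", paste(IUPAC_NT, collapse = ""))
  bad <- grepl(bad_pat, seqs)
  if (any(bad)) {
    stop("non-IUPAC nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(desc, ids)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read CDS annotations
#'
#' Two dialects are supported: GFF3 (only `CDS` features are retained; the
#' gene identifier is taken from the `ID=` attribute) and a headerless or
#' headered 6-column TSV with columns gene_id, contig_id, start, end, strand,
#' product. Coordinates are 1-based inclusive. Annotation rows written
#' high-to-low (as minus-strand genes often are in genome reports) are
#' normalized so that start <= end; strand alone conveys orientation.
#'
#' @param path Annotation file path.
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"tsv"`.
#' @return data.frame with columns gene_id, contig_id, start, end, strand,
#'   product.
#' @export
read_annotations <- function(path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.|$)", tolower(path))) "gff3" else "tsv"
  }
  ann <- if (dialect == "gff3") .read_ann_gff3(path) else .read_ann_tsv(path)
  .validate_annotations(ann)
}

.read_ann_gff3 <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[!is.na(g$type) & g$type == "CDS", , drop = FALSE]
  ids <- sub(";.*$", "", sub("^.*?ID=", "", g$attributes))
  ids[!grepl("ID=", g$attributes)] <- NA_character_
  if (anyNA(ids)) stop("GFF3 CDS feature without an ID= attribute")
  prod <- rep("", nrow(g))
  has_prod <- grepl("product=", g$attributes)
  prod[has_prod] <- sub(";.*$", "", sub("^.*?product=", "", g$attributes[has_prod]))
  data.frame(gene_id = ids, contig_id = as.character(g$seqid),
             start = g$start, end = g$end, strand = as.character(g$strand),
             product = prod, stringsAsFactors = FALSE)
}

.read_ann_tsv <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 6L)
    stop("TSV annotation dialect requires 6 columns, found ", ncol(raw))
  # tolerate a header row: both coordinate fields of row 1 non-numeric
  if (nrow(raw) > 0L &&
      is.na(suppressWarnings(as.numeric(raw[1L, 3L]))) &&
      is.na(suppressWarnings(as.numeric(raw[1L, 4L])))) {
    raw <- raw[-1L, , drop = FALSE]
  }
  if (nrow(raw) == 0L)
    return(data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), product = character(),
                      stringsAsFactors = FALSE))
  start <- suppressWarnings(as.integer(raw[[3L]]))
  end <- suppressWarnings(as.integer(raw[[4L]]))
  if (anyNA(start) || anyNA(end)) {
    bad <- raw[[1L]][is.na(start) | is.na(end)]
    stop("non-integer coordinates for gene(s): ", paste(bad, collapse = ", "))
  }
  data.frame(gene_id = raw[[1L]], contig_id = raw[[2L]],
             start = start, end = end, strand = raw[[5L]],
             product = raw[[6L]], stringsAsFactors = FALSE)
}

.validate_annotations <- function(ann) {
  if (nrow(ann) == 0L) return(ann)
  bad_strand <- !ann$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("unknown strand symbol for gene(s): ",
         paste(ann$gene_id[bad_strand], collapse = ", "))
  if (any(ann$start <= 0L | ann$end <= 0L)) {
    bad <- ann$gene_id[ann$start <= 0L | ann$end <= 0L]
    stop("non-positive coordinates for gene(s): ", paste(bad, collapse = ", "))
  }
  # descending pairs mean minus-strand written high-to-low: normalize
  desc <- ann$start > ann$end
  if (any(desc)) {
    tmp <- ann$start[desc]
    ann$start[desc] <- ann$end[desc]
    ann$end[desc] <- tmp
    ann$strand[desc] <- "-"
  }
  rownames(ann) <- NULL
  ann
}

#' Extract in-frame CDS sequences from contigs
#'
#' Plus-strand genes are the inclusive contig slice `[start, end]`;
#' minus-strand genes are its reverse complement, so every returned sequence
#' reads 5' to 3' on the coding strand. A CDS whose length is not a multiple
#' of three is kept whole with a warning; the trailing partial codon is
#' dropped later, at codon-counting time.
#'
#' @param seqs Named character vector of contigs (from [read_fasta()]).
#' @param ann Annotation data.frame (from [read_annotations()]).
#' @return data.frame with columns gene_id, sequence, length_nt, contig_id,
#'   start, end, strand — one row per annotation, in annotation order.
#' @export
extract_cds <- function(seqs, ann) {
  missing_contig <- !ann$contig_id %in% names(seqs)
  if (any(missing_contig))
    stop("contig not found for gene(s): ",
         paste(ann$gene_id[missing_contig], collapse = ", "))
  clen <- nchar(seqs)[ann$contig_id]
  oob <- ann$start < 1L | ann$end > clen
  if (any(oob))
    stop("coordinates beyond contig for gene(s): ",
         paste(ann$gene_id[oob], collapse = ", "))
  seq <- substring(seqs[ann$contig_id], ann$start, ann$end)
  minus <- ann$strand == "-"
  if (any(minus)) seq[minus] <- reverse_complement(seq[minus])
  len <- ann$end - ann$start + 1L
  off <- len %% 3L != 0L
  if (any(off))
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(ann$gene_id[off], collapse = ", "),
            "; trailing partial codon will be dropped in codon counts")
  data.frame(gene_id = ann$gene_id, sequence = unname(seq), length_nt = len,
             contig_id = ann$contig_id, start = ann$start, end = ann$end,
             strand = ann$strand, stringsAsFactors = FALSE)
}

#' Reverse complement of nucleotide strings
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. R to Y); gaps are
#' preserved.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Read a best-hit taxonomy table
#'
#' A TSV with a header containing at least the columns gene_id, organism,
#' class, identity, accession. Identities written with a percent sign
#' ("44%") are parsed to numbers.
#'
#' @param path TSV path.
#' @return data.frame with columns gene_id, organism, class, identity
#'   (numeric percent in \[0, 100\]), accession.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           quote = "", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("gene_id", "organism", "class", "identity", "accession")
  missing_col <- setdiff(need, names(tab))
  if (length(missing_col) > 0L)
    stop("hit table missing column(s): ", paste(missing_col, collapse = ", "))
  if (nrow(tab) == 0L) {
    out <- tab[, need]
    out$identity <- numeric()
    return(out)
  }
  ident <- suppressWarnings(as.numeric(sub("%$", "", trimws(tab$identity))))
  if (anyNA(ident))
    stop("unparseable identity for gene(s): ",
         paste(tab$gene_id[is.na(ident)], collapse = ", "))
  if (any(ident < 0 | ident > 100))
    stop("identity outside [0, 100] for gene(s): ",
         paste(tab$gene_id[ident < 0 | ident > 100], collapse = ", "))
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup) > 0L)
    stop("duplicate gene_id(s) in hit table: ",
         paste(unique(dup), collapse = ", "))
  data.frame(gene_id = tab$gene_id, organism = tab$organism,
             class = tab$class, identity = ident,
             accession = tab$accession, stringsAsFactors = FALSE)
}
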