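# Distance-based phylogenetic placement on pre-aligned sequences: pairwise
# identity, Kimura 2-parameter (K2P) distances, Saitou-Nei neighbor-joining,
# and nonparametric bootstrap support over internal bipartitions. Trees are
# ape "phylo" objects, so newick I/O and plotting come for free.
#
# K2P separates transitions (A<->G, C<->T; proportion P over comparable
# sites) from transversions (proportion Q):
#   d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)
# The distance diverges as either log argument approaches zero; such
# saturated pairs are reported as errors naming the pair rather than
# returned as numbers.

#' Read a pre-aligned FASTA file
#'
#' @param path FASTA path; all sequences must have equal length and there
#'   must be at least two.
#' @return Named character vector (an alignment), uppercase.
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  if (length(aln) < 2L) stop("alignment needs at least 2 taxa")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have the same length")
  aln
}

# Sites comparable between two rows: both unambiguous A/C/G/T
# (pairwise deletion of gaps, Ns and other ambiguity codes).
.comparable <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  list(a = av[keep], b = bv[keep], n = sum(keep))
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or ambiguity code are excluded
#' (pairwise deletion).
#'
#' @param row_i,row_j Aligned sequences (equal-length strings).
#' @param labels Length-2 character vector used in error messages.
#' @return The K2P distance (non-negative scalar).
#' @export
k2p_distance <- function(row_i, row_j, labels = c("seq_i", "seq_j")) {
  if (nchar(row_i) != nchar(row_j)) stop("aligned sequences differ in length")
  cmp <- .comparable(toupper(row_i), toupper(row_j))
  if (cmp$n == 0L)
    stop("no comparable sites between ", labels[1], " and ", labels[2])
  purine <- c("A", "G")
  diff <- cmp$a != cmp$b
  transition <- diff & ((cmp$a %in% purine) == (cmp$b %in% purine))
  P <- sum(transition) / cmp$n
  Q <- sum(diff & !transition) / cmp$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated between ", labels[1], " and ", labels[2],
         sprintf(" (P = %.3f, Q = %.3f)", P, Q))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Pairwise identity between two aligned sequences
#'
#' Matches over comparable sites (pairwise deletion of gaps/ambiguity),
#' as a percentage.
#'
#' @inheritParams k2p_distance
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(row_i, row_j, labels = c("seq_i", "seq_j")) {
  if (nchar(row_i) != nchar(row_j)) stop("aligned sequences differ in length")
  cmp <- .comparable(toupper(row_i), toupper(row_j))
  if (cmp$n == 0L)
    stop("no comparable sites between ", labels[1], " and ", labels[2])
  100 * sum(cmp$a == cmp$b) / cmp$n
}

#' K2P distance matrix of an alignment
#'
#' @param aln Alignment (named character vector of equal-length strings).
#' @param deletion `"pairwise"` (default) excludes gap/ambiguous sites per
#'   pair; `"complete"` drops such columns once, alignment-wide.
#' @return Symmetric matrix with zero diagonal, dimnames = taxa.
#' @export
k2p_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(aln) >= 2L, length(unique(nchar(aln))) == 1L)
  aln <- toupper(aln)
  if (deletion == "complete") {
    rows <- strsplit(aln, "")
    ok <- Reduce(`&`, lapply(rows, function(v) v %in% c("A", "C", "G", "T")))
    if (!any(ok)) stop("no alignment column free of gaps/ambiguity")
    aln <- vapply(rows, function(v) paste(v[ok], collapse = ""), "")
  }
  n <- length(aln)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        k2p_distance(aln[[i]], aln[[j]], labels = names(aln)[c(i, j)])
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion
#' `Q_ij = (n - 2) d_ij - r_i - r_j` with the standard branch-length
#' formulas. Ties on the minimal Q are broken deterministically by the
#' lowest (row, column) index pair in the current taxa ordering. Negative
#' estimated branch lengths are clamped to zero; the total clamped deficit
#' is recorded in the `negative_branch_deficit` attribute.
#'
#' @param dm Symmetric numeric matrix with dimnames (or a `dist`).
#' @return Unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(dm)
  if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries its newick subtree string
  node <- labels
  d <- dm
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + (-x); 0 } else x
  }
  while (length(node) > 3L) {
    m <- length(node)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (i, j) among minimal Q: column-major which.min with i < j
    q[lower.tri(q)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    vi <- clamp(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", node[i], vi, node[j], vj)
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    node <- c(node[keep], new_node)
    dimnames(d2) <- list(NULL, NULL)
    d <- d2
  }
  # terminal star: three branches solve the three-point equations exactly
  va <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  vb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  vc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    node[1], va, node[2], vb, node[3], vc)
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data K2P + NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilding the tree each time; the
#' support of each internal edge of the full tree is the percentage of
#' successful replicates containing that bipartition. Replicates whose
#' resampled alignment saturates the K2P distance are skipped, counted and
#' reported via warning. The same seed always yields the same tree.
#'
#' @param aln Alignment (named character vector).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for column resampling.
#' @param deletion Gap handling, as in [k2p_matrix()].
#' @return `phylo` tree whose `node.label` holds integer support
#'   percentages (NA on the root of the unrooted basal trifurcation); the
#'   `n_skipped` attribute counts skipped replicates.
#' @export
bootstrap_nj <- function(aln, replicates = 1000L, seed = 1L,
                         deletion = "pairwise") {
  stopifnot(replicates >= 1L)
  tree <- nj_tree(k2p_matrix(aln, deletion))
  len <- nchar(aln[[1]])
  rows <- strsplit(toupper(aln), "")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  boot_trees <- vector("list", replicates)
  n_skipped <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(len, len, replace = TRUE)
    rep_aln <- vapply(rows, function(v) paste(v[cols], collapse = ""), "")
    names(rep_aln) <- names(aln)
    t_b <- tryCatch(nj_tree(k2p_matrix(rep_aln, deletion)),
                    error = function(e) NULL)
    if (is.null(t_b)) n_skipped <- n_skipped + 1L else boot_trees[[b]] <- t_b
  }
  boot_trees <- Filter(Negate(is.null), boot_trees)
  if (n_skipped > 0L)
    warning(n_skipped, " bootstrap replicate(s) skipped (saturated distances)")
  n_ok <- length(boot_trees)
  if (n_ok == 0L) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  support <- round(100 * counts / n_ok)
  support[1L] <- NA  # basal node of the unrooted tree: trivial bipartition
  tree$node.label <- support
  attr(tree, "n_skipped") <- n_skipped
  attr(tree, "n_replicates") <- replicates
  tree
}

#' Format bootstrap supports for display
#'
#' Published trees often print only supports above a cutoff (commonly 60);
#' this returns the node labels with low values blanked while the tree
#' object keeps every value.
#'
#' @param tree A `phylo` with numeric `node.label`.
#' @param min_support Cutoff below which labels are blanked (default 60).
#' @return Character vector of display labels.
#' @export
display_supports <- function(tree, min_support = 60) {
  s <- suppressWarnings(as.numeric(tree$node.label))
  ifelse(!is.na(s) & s >= min_support, as.character(round(s)), "")
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
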