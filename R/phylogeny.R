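# Neighbor-joining phylogeny from concatenated ortholog alignments, with
# column-resampling bootstrap support. Distances are Jukes-Cantor; the
# minimal model is stated rather than guessed at, and branch lengths are
# not expected to match trees built under richer models.

#' Concatenate per-gene alignment blocks
#'
#' @param blocks list of named character vectors (taxon -> aligned
#'   sequence, gaps as `-`); every block must contain every taxon.
#' @return Named character vector of concatenated sequences with
#'   attributes `block_widths` and `total_columns`.
#' @export
concat_alignment <- function(blocks) {
  stopifnot(length(blocks) >= 1L)
  taxa <- sort(names(blocks[[1]]))
  for (b in blocks) {
    if (!setequal(names(b), taxa))
      stop("every taxon must be present in every block")
    if (length(unique(nchar(b))) != 1L)
      stop("unequal sequence lengths within a block")
  }
  out <- vapply(taxa, function(tx)
    paste(vapply(blocks, function(b) b[[tx]], ""), collapse = ""), "")
  attr(out, "block_widths") <- vapply(blocks, function(b) nchar(b[[1]]), 0)
  attr(out, "total_columns") <- nchar(out[[1]])
  out
}

aln_to_DNAbin <- function(alignment) {
  m <- do.call(rbind, strsplit(tolower(alignment), ""))
  rownames(m) <- names(alignment)
  ape::as.DNAbin(m)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' Distances are computed over the ungapped columns shared by each pair
#' (pairwise deletion); a pair sharing fewer than `min_shared` columns is
#' an error.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @param min_shared minimum shared ungapped columns per pair.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
build_distance_matrix <- function(alignment, min_shared = 100L) {
  stopifnot(length(alignment) >= 3L)
  bin <- aln_to_DNAbin(alignment)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (sum(ok[i, ] & ok[j, ]) < min_shared)
      stop("pair ", names(alignment)[i], "/", names(alignment)[j],
           " shares fewer than ", min_shared, " ungapped columns")
  d <- as.matrix(ape::dist.dna(bin, model = "JC69",
                               pairwise.deletion = TRUE))
  d[names(alignment), names(alignment)]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister edge so path
#' lengths are preserved. When `outgroup` is given the tree is rooted with
#' the outgroup sister to all ingroup taxa.
#'
#' @param d symmetric distance matrix (>= 3 taxa).
#' @param outgroup optional taxon label to root on.
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(d, outgroup = NULL) {
  stopifnot(nrow(d) >= 3L, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  tr <- ape::nj(as.dist(d))
  tr <- clamp_negative_edges(tr)
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- which(tr$edge[, 1] == parent)
    sisters <- setdiff(sisters, e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Column-resampling bootstrap: alignment columns are resampled with
#' replacement `n_reps` times, a JC + NJ tree built from each replicate,
#' and support for each internal edge of the original tree is the
#' percentage of replicates containing the same bipartition. Seeded, so
#' identical seeds give identical supports.
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @param outgroup optional rooting taxon for the returned tree.
#' @param min_shared forwarded to [build_distance_matrix()].
#' @return List with `tree` (original NJ tree, node labels set to support
#'   percentages) and `support` (numeric vector over internal nodes).
#' @export
bootstrap_support <- function(alignment, n_reps, seed = 1L,
                              outgroup = NULL, min_shared = 100L) {
  stopifnot(n_reps >= 1L)
  d0 <- build_distance_matrix(alignment, min_shared)
  tr0 <- neighbor_joining(d0)
  cols <- do.call(rbind, strsplit(alignment, ""))
  nc <- ncol(cols)
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(i) {
    idx <- sample.int(nc, nc, replace = TRUE)
    res <- apply(cols[, idx, drop = FALSE], 1, paste, collapse = "")
    names(res) <- names(alignment)
    neighbor_joining(build_distance_matrix(res, min_shared = 1L))
  }))
  counts <- ape::prop.clades(tr0, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  tr0$node.label <- support
  if (!is.null(outgroup)) {
    tr0 <- ape::root(tr0, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE)
  }
  list(tree = tr0, support = support)
}

#' Simulate an alignment on a known tree under Jukes-Cantor
#'
#' A uniform-random root sequence evolves along each branch with change
#' probability 3/4 (1 - exp(-4 d / 3)); changed sites pick uniformly among
#' the three alternatives. Intended for recovery tests of the NJ pipeline.
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/site).
#' @param n_columns alignment length.
#' @param seed RNG seed.
#' @return Named character vector (tip label -> sequence).
#' @export
simulate_jc_alignment <- function(tree, n_columns, seed = 1L) {
  stopifnot(!is.null(tree$edge.length))
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(DNA_BASES, n_columns, replace = TRUE)
    # parents precede children in a preorder edge walk
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      p_change <- 0.75 * (1 - exp(-4 * ord$edge.length[e] / 3))
      s <- seqs[[par]]
      hit <- which(runif(n_columns) < p_change)
      for (k in hit) s[k] <- sample(setdiff(DNA_BASES, s[k]), 1L)
      seqs[[child]] <- s
    }
    setNames(vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), ""), tree$tip.label)
  })
}

#' Write a tree in newick format
#'
#' @param tree `ape::phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
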