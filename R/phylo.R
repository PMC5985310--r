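# Distance phylogenetics for isotype assignment.
#
# The pipeline takes an existing multiple alignment (protein-guided nucleotide
# alignment, computed upstream by any aligner), removes columns below a site
# coverage threshold, computes p-distances with pairwise deletion, builds a
# neighbor-joining tree, attaches column-bootstrap supports, and assigns query
# sequences to isotypes by the smallest supported clade shared with reference
# panel sequences.
#
# NJ is implemented here because the pipeline fixes deterministic tie-breaking
# (smallest index pair) and negative-branch-length redistribution; ape::nj is
# used as an independent cross-check in the test suite.

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- toupper(aln)
  } else {
    if (is(aln, "XStringSet") || is(aln, "DNAMultipleAlignment"))
      aln <- as.character(aln)
    stopifnot(is.character(aln))
    if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
    L <- unique(nchar(aln))
    if (length(L) != 1L) stop("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  m
}

.GAP_CHARS <- c("-", ".", "N", "X", "?")

#' Remove alignment columns below a site-coverage threshold
#'
#' @param aln alignment: named character vector of equal-length gapped
#'   sequences, a character matrix (rows = taxa), or a `DNAStringSet`.
#' @param minCoverage minimum fraction of non-gap residues per retained
#'   column (default 0.95).
#' @return Character matrix of the retained columns, order preserved, with a
#'   `kept` attribute giving the original column indices.
#' @export
filterColumns <- function(aln, minCoverage = 0.95) {
  m <- .aln_matrix(aln)
  cov <- colMeans(!matrix(m %in% .GAP_CHARS, nrow = nrow(m)))
  keep <- which(cov >= minCoverage)
  if (!length(keep)) stop("all columns removed by the coverage filter")
  out <- m[, keep, drop = FALSE]
  attr(out, "kept") <- keep
  out
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair, with pairwise deletion of residual
#' gap/ambiguous positions.
#'
#' @inheritParams filterColumns
#' @return Symmetric numeric matrix with zero diagonal, entries in \[0, 1\].
#' @export
pDistance <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  ok <- !matrix(m %in% .GAP_CHARS, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L)
        stop("pair ", rownames(m)[i], "/", rownames(m)[j],
             " has zero compared sites")
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (the Q-minimal
#' pair with the smallest indices is joined) and non-negative branch lengths:
#' a negative pendant length is clamped to zero with the deficit moved to its
#' sister branch.
#'
#' @param d symmetric distance matrix with row/column names (or a `dist`).
#' @return An unrooted `phylo` object (ape).
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # node bookkeeping in ape convention: tips 1..n, internals n+1, n+2, ...
  n_tip <- n
  next_node <- n_tip + 2L          # n_tip+1 reserved for the final root node
  active <- seq_len(n)             # node ids of active cluster representatives
  D <- d
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)

  while (length(active) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest Q; ties by smallest (i, j) index pair in row-major order
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]

    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }

    new_id <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new_id, active[i]), c(new_id, active[j]))
    lens <- c(lens, vi, vj)

    others <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newd),
               c(newd, 0))
    active <- c(active[others], new_id)
    rownames(D) <- colnames(D) <- as.character(active)
  }

  # final three nodes joined at the (unrooted) root trifurcation
  root <- n_tip + 1L
  if (length(active) == 3L) {
    va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    v <- pmax(c(va, vb, vc), 0)
    edges <- rbind(edges, c(root, active[1]), c(root, active[2]),
                   c(root, active[3]))
    lens <- c(lens, v)
  } else stop("internal error: NJ terminated with != 3 nodes")

  # renumber internal nodes to ape's preorder-free convention (root = n+1)
  all_nodes <- sort(unique(as.vector(edges)))
  internal <- all_nodes[all_nodes > n_tip]
  map <- integer(max(all_nodes))
  map[seq_len(n_tip)] <- seq_len(n_tip)
  map[root] <- n_tip + 1L
  rest <- setdiff(internal, root)
  map[rest] <- n_tip + 1L + seq_along(rest)
  edges <- matrix(map[edges], ncol = 2)

  tr <- list(edge = edges, edge.length = lens,
             tip.label = labels, Nnode = length(internal))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

.tip_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tip_descendants, tree = tree))
}

# canonical bipartition keys for an unrooted tree: for each internal node
# (except the root), the smaller side of the split, normalized to exclude
# tip 1 (so each split has a unique key)
.bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  nodes <- setdiff(unique(tree$edge[, 1]), root)
  keys <- character(0)
  labs <- sort(tree$tip.label)
  for (nd in nodes) {
    tips <- sort(tree$tip.label[.tip_descendants(tree, nd)])
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    if (labs[1L] %in% tips) tips <- setdiff(labs, tips)
    keys <- c(keys, paste(tips, collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with column-bootstrap supports
#'
#' Builds the NJ tree from the coverage-filtered alignment, then resamples
#' alignment columns with replacement `bootstrapReps` times, rebuilds the tree
#' for each replicate, and reports for every internal edge of the full-data
#' tree the percentage of replicate trees containing the same bipartition.
#' Supports are stored in `$node.label` (empty for the root).
#'
#' @inheritParams filterColumns
#' @param bootstrapReps number of bootstrap replicates (default 500).
#' @param seed integer seed for the resampling (mandatory for
#'   reproducibility).
#' @param minCoverage site-coverage filter applied before tree building.
#' @return A `phylo` object whose `node.label` holds bootstrap percentages.
#' @export
bootstrapSupport <- function(aln, bootstrapReps = 500L, seed = 1L,
                             minCoverage = 0.95) {
  m <- filterColumns(aln, minCoverage)
  tree <- njTree(pDistance(m))
  n_tip <- length(tree$tip.label)
  target <- .bipartitions(tree)
  counts <- setNames(integer(length(target)), target)
  set.seed(seed)
  L <- ncol(m)
  for (b in seq_len(bootstrapReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    db <- tryCatch(pDistance(m[, cols, drop = FALSE]), error = function(e) NULL)
    if (is.null(db)) next
    bt <- njTree(db)
    hit <- intersect(.bipartitions(bt), target)
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / bootstrapReps, 1)
  # attach as node labels in internal-node order (root first, unlabeled)
  root <- n_tip + 1L
  node_ids <- root + seq_len(tree$Nnode) - 1L
  labs <- character(tree$Nnode)
  for (k in seq_along(node_ids)) {
    nd <- node_ids[k]
    if (nd == root) { labs[k] <- ""; next }
    tips <- sort(tree$tip.label[.tip_descendants(tree, nd)])
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) { labs[k] <- ""; next }
    all_labs <- sort(tree$tip.label)
    if (all_labs[1L] %in% tips) tips <- setdiff(all_labs, tips)
    key <- paste(tips, collapse = "|")
    labs[k] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  tree$node.label <- labs
  tree
}

#' Assign query leaves to isotypes by supported clades
#'
#' For each query leaf, walks rootward and calls the isotype of the smallest
#' clade that contains the query, contains at least one panel leaf, has
#' bootstrap support at or above `supportThreshold`, and whose panel members
#' carry a single isotype label. Queries for which no such clade exists are
#' `"unresolved"`.
#'
#' @param tree `phylo` with bootstrap percentages in `node.label` (from
#'   [bootstrapSupport()]); nodes with empty labels are treated as
#'   unsupported except the root, which is treated as resolved context.
#' @param panelLabels named character vector: names are panel leaf labels,
#'   values their isotypes.
#' @param queries character vector of query leaf labels present in the tree.
#' @param supportThreshold minimum bootstrap percentage (default 70).
#' @return Named character vector query -> isotype (or `"unresolved"`).
#' @export
assignIsotype <- function(tree, panelLabels, queries, supportThreshold = 70) {
  stopifnot(all(queries %in% tree$tip.label))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  node_support <- function(nd) {
    if (nd == root) return(100)
    lab <- tree$node.label[nd - n_tip]
    if (is.null(lab) || is.na(lab) || lab == "") return(-Inf)
    suppressWarnings(as.numeric(lab))
  }
  out <- setNames(rep("unresolved", length(queries)), queries)
  for (q in queries) {
    nd <- match(q, tree$tip.label)
    repeat {
      nd <- parent[nd]
      if (nd == 0L) break
      tips <- tree$tip.label[.tip_descendants(tree, nd)]
      panel_in <- intersect(tips, names(panelLabels))
      if (length(panel_in)) {
        labs <- unique(panelLabels[panel_in])
        # heterogeneity is monotone rootward: once mixed, always mixed
        if (length(labs) > 1L) break
        if (node_support(nd) >= supportThreshold) { out[q] <- labs; break }
        # supported ancestor may still qualify: keep climbing
      }
      if (nd == root) break
    }
  }
  out
}

#' Write a tree with supports as newick
#'
#' @param tree `phylo` (supports in `node.label` become internal node labels).
#' @param path output path.
#' @export
writeTreeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Thread nucleotide triplets through a protein alignment
#'
#' Produces the codon-space nucleotide alignment ("nucleotide sequences after
#' amino acid alignment"): each aligned residue expands to its source codon
#' and each protein gap to a 3-nt gap.
#'
#' @param proteinAln named character vector of equal-length gapped amino-acid
#'   sequences.
#' @param cds named character vector of the corresponding unaligned coding
#'   nucleotide sequences (length 3x the ungapped protein length).
#' @return Named character vector: the gapped nucleotide alignment.
#' @export
backThreadCodons <- function(proteinAln, cds) {
  stopifnot(all(names(proteinAln) %in% names(cds)))
  out <- vapply(names(proteinAln), function(nm) {
    aa <- strsplit(proteinAln[[nm]], "")[[1L]]
    nt <- cds[[nm]]
    need <- 3L * sum(aa != "-")
    if (nchar(nt) < need)
      stop("coding sequence for ", nm, " shorter than the aligned protein")
    pos <- 0L
    paste(vapply(aa, function(a) {
      if (a == "-") return("---")
      pos <<- pos + 3L
      substr(nt, pos - 2L, pos)
    }, character(1)), collapse = "")
  }, character(1))
  setNames(out, names(proteinAln))
}
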