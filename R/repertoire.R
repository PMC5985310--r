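# Amplicon repertoire processing: isotype pooling by CL match, open-reading-
# frame QC, unique-sequence collapsing with J-usage tabulation, V-subfamily
# clustering at the 75% nucleotide identity criterion, and allele/gene
# inference from variant-by-specimen presence tables.

.pid2 <- function(pa) {
  # percent identity over match+mismatch columns (gap columns excluded)
  Biostrings::pid(pa, type = "PID2")
}

#' Assign amplicons to isotype pools by best constant-region hit
#'
#' Each sequence is locally aligned against every CL reference; the label of
#' the best hit is assigned when its identity is at least `minIdentity` over
#' at least `minCoverage` of the CL reference; otherwise the sequence is
#' `"unassigned"`. Ties on identity are broken by higher score, then
#' lexicographic label, and flagged ambiguous.
#'
#' @param seqs `DNAStringSet` (or named character vector) of amplicons.
#' @param clRefs named `DNAStringSet` of CL references (names = isotype
#'   labels).
#' @param minIdentity minimum fractional identity (default 0.8).
#' @param minCoverage minimum fraction of the CL reference covered (default
#'   0.6).
#' @return `DataFrame` with `sequence_id`, `sequence`, `c_call`, `c_start`
#'   (start of the CL match in the read), `identity`, `ambiguous`.
#' @export
assignPool <- function(seqs, clRefs, minIdentity = 0.8, minCoverage = 0.6) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (is.character(clRefs)) clRefs <- DNAStringSet(clRefs)
  stopifnot(length(clRefs) >= 1L, !is.null(names(clRefs)))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  lab_order <- order(names(clRefs))
  scores <- idents <- covs <- matrix(NA_real_, n, length(clRefs))
  starts <- matrix(NA_integer_, n, length(clRefs))
  for (j in seq_along(clRefs)) {
    pa <- pairwiseAlignment(seqs, clRefs[[j]], type = "local",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
    scores[, j] <- score(pa)
    idents[, j] <- .pid2(pa) / 100
    sj <- subject(pa)
    covs[, j] <- (Biostrings::end(sj) - Biostrings::start(sj) + 1L) /
      length(clRefs[[j]])
    starts[, j] <- Biostrings::start(pattern(pa))
  }
  c_call <- character(n); c_start <- integer(n)
  ident <- numeric(n); ambiguous <- logical(n)
  for (i in seq_len(n)) {
    ok <- which(idents[i, ] >= minIdentity & covs[i, ] >= minCoverage)
    if (!length(ok)) {
      c_call[i] <- "unassigned"; c_start[i] <- NA_integer_
      ident[i] <- NA_real_
      next
    }
    best_sc <- max(scores[i, ok])
    top <- ok[scores[i, ok] == best_sc]
    ambiguous[i] <- length(top) > 1L
    top <- top[order(names(clRefs)[top])][1L]   # lexicographic tie-break
    c_call[i] <- names(clRefs)[top]
    c_start[i] <- starts[i, top]
    ident[i] <- idents[i, top]
  }
  DataFrame(sequence_id = ids, sequence = as.character(seqs),
            c_call = c_call, c_start = c_start, identity = ident,
            ambiguous = ambiguous)
}

#' Split pool assignments into AmpliconPool objects
#'
#' @param assigned `DataFrame` from [assignPool()].
#' @return Named list of [AmpliconPool-class] (unassigned sequences are
#'   dropped; their count is recorded in each pool's `n_unassigned`).
#' @export
splitPools <- function(assigned) {
  n_un <- sum(assigned$c_call == "unassigned")
  kept <- assigned[assigned$c_call != "unassigned", , drop = FALSE]
  out <- lapply(split(seq_len(nrow(kept)), kept$c_call), function(ix) {
    m <- kept[ix, , drop = FALSE]
    AmpliconPool(m$c_call[1L], m,
                 stats = list(n_input = nrow(m),
                              n_discarded_frameshift = 0L,
                              n_discarded_stop = 0L,
                              n_discarded_truncated = 0L,
                              n_unassigned = n_un))
  })
  out
}

#' ORF quality-control filter for an amplicon pool
#'
#' The reading frame is anchored on the CL match and extended 5'. Sequences
#' are discarded when (a) truncated: the pre-CL region covers less than
#' `truncatedFraction` of the pool's median pre-CL length, (b) frameshifted:
#' the pre-CL length is not congruent with the CL frame (amplicons are
#' expected to start at the leader/FR1 codon boundary, as 5'-RACE products
#' do), or (c) carrying an in-frame stop upstream of the CL. Survivors gain
#' `aa` (the CL-anchored translation) and `productive = TRUE`.
#'
#' @param pool an [AmpliconPool-class] with `c_start` from [assignPool()].
#' @param truncatedFraction minimum fraction of the pool median pre-CL length
#'   (default 0.95).
#' @return The filtered [AmpliconPool-class]; discard counts in
#'   [poolStats()].
#' @export
qcFilter <- function(pool, truncatedFraction = 0.95) {
  m <- members(pool)
  if (!nrow(m)) return(pool)
  pre_len <- m$c_start - 1L
  med <- median(pre_len)
  st <- poolStats(pool)
  aa <- .translate_many(substr(m$sequence, 1L, pmax(pre_len, 0L)))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (pre_len[i] < truncatedFraction * med) {
      st$n_discarded_truncated <- st$n_discarded_truncated + 1L
      next
    }
    if (pre_len[i] %% 3L != 0L) {
      st$n_discarded_frameshift <- st$n_discarded_frameshift + 1L
      next
    }
    if (grepl("*", aa[i], fixed = TRUE)) {
      st$n_discarded_stop <- st$n_discarded_stop + 1L
      next
    }
    keep[i] <- TRUE
  }
  m <- m[keep, , drop = FALSE]
  m$aa <- aa[keep]
  m$productive <- rep(TRUE, nrow(m))
  new("AmpliconPool", isotype = isotypeLabel(pool), members = m, stats = st)
}

#' Assign J segment calls by best alignment of the pre-CL tail
#'
#' @param pool an [AmpliconPool-class] (QC'd).
#' @param jRefs named `DNAStringSet` of germline J coding sequences.
#' @param tailWindow nt of pre-CL sequence searched (default 80).
#' @return The pool with a `j_call` members column.
#' @export
assignJCall <- function(pool, jRefs, tailWindow = 80L) {
  if (is.character(jRefs)) jRefs <- DNAStringSet(jRefs)
  m <- members(pool)
  if (!nrow(m)) return(pool)
  tails <- vapply(seq_len(nrow(m)), function(i) {
    endpos <- m$c_start[i] - 1L
    substr(m$sequence[i], max(1L, endpos - tailWindow + 1L), endpos)
  }, character(1))
  tl <- DNAStringSet(tails)
  sc <- matrix(-Inf, nrow(m), length(jRefs))
  for (j in seq_along(jRefs)) {
    pa <- pairwiseAlignment(tl, jRefs[[j]], type = "local",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
    sc[, j] <- score(pa)
  }
  m$j_call <- names(jRefs)[apply(sc, 1L, which.max)]
  new("AmpliconPool", isotype = isotypeLabel(pool), members = m,
      stats = poolStats(pool))
}

#' Assign V family calls by best local alignment to family exemplars
#'
#' @param pool an [AmpliconPool-class].
#' @param vRefs named `DNAStringSet` of V family exemplars.
#' @return The pool with a `v_family` members column.
#' @export
assignVFamily <- function(pool, vRefs) {
  if (is.character(vRefs)) vRefs <- DNAStringSet(vRefs)
  m <- members(pool)
  if (!nrow(m)) return(pool)
  seqs <- DNAStringSet(m$sequence)
  sc <- matrix(-Inf, nrow(m), length(vRefs))
  for (j in seq_along(vRefs)) {
    pa <- pairwiseAlignment(seqs, vRefs[[j]], type = "local",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
    sc[, j] <- score(pa)
  }
  m$v_family <- names(vRefs)[apply(sc, 1L, which.max)]
  new("AmpliconPool", isotype = isotypeLabel(pool), members = m,
      stats = poolStats(pool))
}

#' Collapse identical sequences and tabulate J usage
#'
#' Deduplication is exact nucleotide identity over the region from the
#' amplicon start (FR1/leader anchor) to the end of the J segment, i.e. the
#' pre-CL region; 5'-UTR/primer heterogeneity beyond that anchor is assumed
#' already removed. J usage fractions are computed over all (pre-dedup)
#' members.
#'
#' @param pool QC'd [AmpliconPool-class].
#' @return List with `unique` (`DataFrame` of unique sequences with
#'   `duplicate_count`), `n_unique`, `n_total` and `j_usage` (named fractions,
#'   when `j_call` is present).
#' @export
collapseUnique <- function(pool) {
  m <- members(pool)
  if (!nrow(m)) return(list(unique = m, n_unique = 0L, n_total = 0L,
                            j_usage = NULL))
  key <- vapply(seq_len(nrow(m)), function(i)
    substr(m$sequence[i], 1L, m$c_start[i] - 1L), character(1))
  grp <- split(seq_len(nrow(m)), key)
  first <- vapply(grp, `[`, integer(1), 1L)
  uni <- m[first, , drop = FALSE]
  uni$duplicate_count <- unname(vapply(grp, length, integer(1)))
  ord <- order(-uni$duplicate_count, uni$sequence_id)
  uni <- uni[ord, , drop = FALSE]
  j_usage <- NULL
  if (!is.null(m$j_call)) j_usage <- prop.table(table(m$j_call))
  list(unique = uni, n_unique = nrow(uni), n_total = nrow(m),
       j_usage = j_usage)
}

#' Pairwise percent-identity matrix (global alignment)
#'
#' @param seqs `DNAStringSet` or character vector.
#' @return Symmetric matrix of percent identities (diagonal 100).
#' @export
identityMatrix <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in 1:(n - 1L)) {
    pa <- pairwiseAlignment(seqs[(i + 1L):n], seqs[[i]], type = "global",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
    v <- .pid2(pa)
    m[i, (i + 1L):n] <- v
    m[(i + 1L):n, i] <- v
  }
  m
}

#' Cluster V genes into subfamilies by the percent-identity criterion
#'
#' Single-linkage agglomeration on pairwise global nucleotide identity; two
#' sequences end up in one family whenever a chain of pairs at or above the
#' threshold connects them. Family labels are ordered by size (descending),
#' ties by first-member input order.
#'
#' @param vSeqs `DNAStringSet` or character vector of V-region nucleotide
#'   sequences (leader excluded).
#' @param threshold identity fraction defining a family (default 0.75, the
#'   classical V subfamily criterion).
#' @return List of class `SubfamilyClustering`: `threshold`, `families`
#'   (integer membership vector named by sequence), `family_sizes`,
#'   `n_families`.
#' @export
clusterSubfamilies <- function(vSeqs, threshold = 0.75) {
  if (is.character(vSeqs)) vSeqs <- DNAStringSet(vSeqs)
  if (length(vSeqs) < 1L) stop("need at least one sequence")
  ids <- names(vSeqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(vSeqs))
  if (length(vSeqs) == 1L) {
    fam <- setNames(1L, ids)
    return(structure(list(threshold = threshold, families = fam,
                          family_sizes = c(`1` = 1L), n_families = 1L),
                     class = "SubfamilyClustering"))
  }
  idm <- identityMatrix(vSeqs)
  d <- as.dist(100 - idm)
  hc <- hclust(d, method = "single")
  raw <- cutree(hc, h = 100 * (1 - threshold))
  # relabel by decreasing size, ties by first appearance
  sizes <- table(raw)
  firsts <- vapply(names(sizes), function(g) min(which(raw == as.integer(g))),
                   integer(1))
  ord <- order(-as.integer(sizes), firsts)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  fam <- setNames(as.integer(relabel[as.character(raw)]), ids)
  structure(list(threshold = threshold, families = fam,
                 family_sizes = table(fam), n_families = length(sizes)),
            class = "SubfamilyClustering")
}

#' @export
print.SubfamilyClustering <- function(x, ...) {
  cat("SubfamilyClustering:", x$n_families, "families at",
      sprintf("%.0f%%", 100 * x$threshold), "identity\n")
  cat("  sizes:", paste(as.integer(x$family_sizes), collapse = "/"), "\n")
  invisible(x)
}

#' Infer genes and alleles from a variant-by-specimen presence table
#'
#' Variants are first grouped by nucleotide identity (candidate alleles of a
#' gene differ by a few substitutions; default threshold 97%), then variants
#' of each identity group are greedily packed into the minimum number of
#' genes such that no specimen carries more than two variants (alleles) per
#' gene, in decreasing order of prevalence.
#'
#' @param presence logical matrix, variants x specimens (`TRUE` = variant
#'   observed in that specimen); rownames are variant labels.
#' @param seqs optional named sequences of the variants, enabling the
#'   identity pre-grouping.
#' @param identityThreshold fraction for the allele-group pre-clustering
#'   (default 0.97).
#' @param maxAlleles alleles per gene per specimen (default 2; diploid).
#' @return List with `n_genes`, `genes` (list of variant-label vectors),
#'   `forced_splits` (number of genes added because more than `maxAlleles`
#'   close variants co-occurred in one specimen).
#' @export
inferAlleles <- function(presence, seqs = NULL, identityThreshold = 0.97,
                         maxAlleles = 2L) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            ncol(presence) >= 1L)
  variants <- rownames(presence)
  if (!is.null(seqs)) {
    stopifnot(all(variants %in% names(seqs)))
    cl <- clusterSubfamilies(seqs[variants], threshold = identityThreshold)
    groups <- split(variants, cl$families[variants])
  } else {
    groups <- list(variants)
  }
  genes <- list(); forced <- 0L
  for (grp in groups) {
    ord <- grp[order(-rowSums(presence[grp, , drop = FALSE]), grp)]
    bins <- .pack_variants(ord, presence, maxAlleles)
    if (length(bins) > 1L) {
      forced <- forced + (length(bins) - 1L)
      warning("identity group split across ", length(bins),
              " genes to respect the per-specimen allele limit")
    }
    genes <- c(genes, bins)
  }
  list(n_genes = length(genes), genes = genes, forced_splits = forced)
}

# minimum-bin packing of variants under the per-specimen allele cap:
# exact depth-first search for small groups, first-fit-decreasing beyond
.pack_variants <- function(vars, presence, maxAlleles, exactLimit = 10L) {
  first_fit <- function(vs) {
    bins <- list()
    for (v in vs) {
      placed <- FALSE
      for (b in seq_along(bins)) {
        load <- colSums(presence[c(bins[[b]], v), , drop = FALSE])
        if (all(load <= maxAlleles)) {
          bins[[b]] <- c(bins[[b]], v); placed <- TRUE; break
        }
      }
      if (!placed) bins[[length(bins) + 1L]] <- v
    }
    bins
  }
  best <- first_fit(vars)
  if (length(vars) > exactLimit || length(best) == 1L) return(best)
  # branch and bound on bin assignments
  n <- length(vars)
  assign_dfs <- function(i, bins) {
    if (length(bins) >= length(best)) return()
    if (i > n) { best <<- bins; return() }
    v <- vars[i]
    for (b in seq_along(bins)) {
      load <- colSums(presence[c(bins[[b]], v), , drop = FALSE])
      if (all(load <= maxAlleles)) {
        nb <- bins; nb[[b]] <- c(nb[[b]], v)
        assign_dfs(i + 1L, nb)
      }
    }
    assign_dfs(i + 1L, c(bins, list(v)))
  }
  assign_dfs(2L, list(vars[1L]))
  best
}

#' Write an AIRR-style rearrangement table
#'
#' @param pool QC'd, J/V-annotated [AmpliconPool-class] or the `unique`
#'   DataFrame from [collapseUnique()].
#' @param path output TSV path.
#' @export
writeRearrangementTSV <- function(pool, path) {
  m <- if (is(pool, "AmpliconPool")) members(pool) else pool
  cols <- intersect(c("sequence_id", "sequence", "c_call", "j_call",
                      "v_family", "productive", "duplicate_count"),
                    names(m))
  write.table(as.data.frame(m[, cols, drop = FALSE]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
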