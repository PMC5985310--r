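# Constant-region expression quantification from transcriptome reads:
# Genomecov-style mean read depth per nucleotide of each CL reference,
# normalized to percentages.

#' Per-reference per-position read depth
#'
#' Each read is locally aligned against every CL reference and assigned to
#' the best-scoring hit with identity at least `minIdentity`; reads tying
#' across k references contribute 1/k depth to each. Depth counts reads
#' (bases) covering each reference position.
#'
#' @param reads `DNAStringSet` or character vector of reads.
#' @param clRefs named `DNAStringSet` of CL references.
#' @param minIdentity minimum fractional identity of the aligned span
#'   (default 0.9).
#' @param minAlignedFraction minimum fraction of the read that must align
#'   (default 0.5; guards against spurious short perfect matches).
#' @return List with `depth` (named list of numeric per-position vectors),
#'   `assigned` (named weighted read counts), `n_multi` (reads split across
#'   references), `n_dropped`, `n_input`.
#' @export
coverageDepth <- function(reads, clRefs, minIdentity = 0.9,
                          minAlignedFraction = 0.5) {
  if (is.character(reads)) reads <- DNAStringSet(reads)
  if (is.character(clRefs)) clRefs <- DNAStringSet(clRefs)
  stopifnot(length(clRefs) >= 1L, !is.null(names(clRefs)))
  n <- length(reads)
  K <- length(clRefs)
  depth <- lapply(clRefs, function(r) numeric(length(r)))
  assigned <- setNames(numeric(K), names(clRefs))
  if (n == 0L)
    return(list(depth = depth, assigned = assigned, n_multi = 0L,
                n_dropped = 0L, n_input = 0L))
  sc <- ident <- matrix(-Inf, n, K)
  tstart <- tend <- matrix(NA_integer_, n, K)
  alen <- matrix(0L, n, K)
  for (j in seq_len(K)) {
    pa <- pairwiseAlignment(reads, clRefs[[j]], type = "local",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
    sc[, j] <- score(pa)
    ident[, j] <- Biostrings::pid(pa, type = "PID2") / 100
    sj <- subject(pa); pj <- pattern(pa)
    tstart[, j] <- Biostrings::start(sj)
    tend[, j] <- Biostrings::end(sj)
    alen[, j] <- Biostrings::end(pj) - Biostrings::start(pj) + 1L
  }
  rl <- Biostrings::width(reads)
  n_multi <- 0L; n_dropped <- 0L
  for (i in seq_len(n)) {
    ok <- which(ident[i, ] >= minIdentity & alen[i, ] >= minAlignedFraction * rl[i])
    if (!length(ok)) { n_dropped <- n_dropped + 1L; next }
    top <- ok[sc[i, ok] == max(sc[i, ok])]
    w <- 1 / length(top)
    if (length(top) > 1L) n_multi <- n_multi + 1L
    for (j in top) {
      span <- tstart[i, j]:tend[i, j]
      depth[[j]][span] <- depth[[j]][span] + w
      assigned[j] <- assigned[j] + w
    }
  }
  list(depth = depth, assigned = assigned, n_multi = n_multi,
       n_dropped = n_dropped, n_input = n)
}

#' Expression percentages from coverage depths
#'
#' Mean depth per nucleotide of each reference (averaged over the full
#' reference length, uncovered positions included), normalized so the
#' percentages sum to 100.
#'
#' @param cov result of [coverageDepth()].
#' @return `data.frame` with `reference`, `assigned_reads`,
#'   `mean_depth_per_nt`, `percent_of_total`.
#' @export
expressionProportions <- function(cov) {
  md <- vapply(cov$depth, mean, numeric(1))
  if (all(md == 0)) stop("all references have zero depth")
  data.frame(reference = names(cov$depth),
             assigned_reads = as.numeric(cov$assigned[names(cov$depth)]),
             mean_depth_per_nt = md,
             percent_of_total = 100 * md / sum(md),
             row.names = NULL)
}

#' Flag reference pairs too similar to resolve at a given read length
#'
#' Two references are resolvable by best-hit read assignment when every
#' read-length window of their pairwise alignment contains at least
#' `minMismatch` differing positions; pairs below that anywhere along the
#' alignment are flagged unresolvable.
#'
#' @param clRefs named `DNAStringSet`.
#' @param readLen read length (window size in alignment columns).
#' @param minMismatch minimum distinguishing mismatches per window
#'   (default 2).
#' @return `data.frame` with `ref_a`, `ref_b`, `min_window_mismatch`,
#'   `resolvable`.
#' @export
referenceResolvability <- function(clRefs, readLen, minMismatch = 2L) {
  if (is.character(clRefs)) clRefs <- DNAStringSet(clRefs)
  K <- length(clRefs)
  out <- list(); k <- 1L
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      al <- globalIdentity(as.character(clRefs[[i]]),
                           as.character(clRefs[[j]]))
      a <- strsplit(al$aligned_a, "")[[1L]]
      b <- strsplit(al$aligned_b, "")[[1L]]
      mism <- as.integer(a != b)
      L <- length(mism)
      win <- min(readLen, L)
      cs <- cumsum(c(0L, mism))
      wm <- min(cs[(win + 1L):(L + 1L)] - cs[1L:(L - win + 1L)])
      out[[k]] <- data.frame(ref_a = names(clRefs)[i],
                             ref_b = names(clRefs)[j],
                             min_window_mismatch = wm,
                             resolvable = wm >= minMismatch)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

#' Write a per-reference expression table
#'
#' @param tab result of [expressionProportions()].
#' @param path output TSV path.
#' @export
writeExpressionTSV <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
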