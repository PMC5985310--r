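# V-J junction decomposition.
#
# An observed junction window is partitioned into V-retained, P-, N-, and
# J-retained nucleotides. Germline assignment is maximal: the longest observed
# prefix matching the germline V 3' end and the longest suffix matching the
# germline J 5' start; a nucleotide explainable by both is assigned to V
# (convention; the ambiguous overlap is also reported so the J-first reading
# can be recomputed). P-nucleotides are palindromic extensions of an untrimmed
# coding end, at most `maxP` nt; anything left over is non-templated N
# (a signature of TdT activity).

.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- strsplit(substr(a, 1L, n), "")[[1L]]
  cb <- strsplit(substr(b, 1L, n), "")[[1L]]
  neq <- which(ca != cb)
  if (!length(neq)) n else neq[1L] - 1L
}

.rev_string <- function(x) {
  paste(rev(strsplit(x, "")[[1L]]), collapse = "")
}

#' Decompose an observed V-J junction
#'
#' @param vGerm3 germline V 3'-end sequence covering the junction window
#'   (coding strand, ending at the unrecombined V coding end).
#' @param jGerm5 germline J 5'-start sequence covering the junction window
#'   (coding strand, beginning at the unrecombined J coding start).
#' @param observed the observed sequence spanning the junction window: it must
#'   begin at the base of the rearranged sequence corresponding to the start
#'   of `vGerm3` and end at the base corresponding to the end of `jGerm5`.
#' @param maxP maximum P-nucleotide length considered (default 4).
#' @return A list with fields `v_retained`, `v_trim`, `p_v`, `n_region`,
#'   `p_j`, `j_trim`, `j_retained`, and `ambiguous_overlap` (number of middle
#'   nucleotides explainable by both germline ends, assigned to V). The
#'   concatenation `v_retained p_v n_region p_j j_retained` always equals
#'   `observed`.
#' @examples
#' decomposeJunction("ACGTCA", "GTTTGG", "ACGTCAGTTTGG")  # untrimmed join
#' @export
decomposeJunction <- function(vGerm3, jGerm5, observed, maxP = 4L) {
  v <- toupper(as.character(vGerm3))
  j <- toupper(as.character(jGerm5))
  o <- toupper(as.character(observed))
  if (nchar(o) < 1L || nchar(v) < 1L || nchar(j) < 1L)
    stop("junction window and germline flanks must be non-empty")

  v_len <- .common_prefix_len(o, v)
  j_len <- .common_prefix_len(.rev_string(o), .rev_string(j))
  ambiguous <- 0L
  if (v_len + j_len > nchar(o)) {
    # overlap: nucleotides explainable by both ends go to V
    ambiguous <- v_len + j_len - nchar(o)
    j_len <- nchar(o) - v_len
  }
  v_ret <- substr(o, 1L, v_len)
  j_ret <- if (j_len > 0L) substr(o, nchar(o) - j_len + 1L, nchar(o)) else ""
  middle <- substr(o, v_len + 1L, nchar(o) - j_len)
  v_trim <- nchar(v) - v_len
  j_trim <- nchar(j) - j_len

  p_v <- ""
  if (v_trim == 0L && nchar(middle) > 0L) {
    # P on the V side: revcomp of the last k bases of the V end
    for (k in min(maxP, nchar(middle)):1) {
      cand <- revComp(substr(v, nchar(v) - k + 1L, nchar(v)))
      if (substr(middle, 1L, k) == cand) { p_v <- cand; break }
    }
  }
  rest <- substr(middle, nchar(p_v) + 1L, nchar(middle))
  p_j <- ""
  if (j_trim == 0L && nchar(rest) > 0L) {
    # P on the J side: revcomp of the first k bases of the J start
    for (k in min(maxP, nchar(rest)):1) {
      cand <- revComp(substr(j, 1L, k))
      if (substr(rest, nchar(rest) - k + 1L, nchar(rest)) == cand) {
        p_j <- cand; break
      }
    }
  }
  n_region <- substr(rest, 1L, nchar(rest) - nchar(p_j))
  list(v_retained = v_ret, v_trim = v_trim, p_v = p_v, n_region = n_region,
       p_j = p_j, j_trim = j_trim, j_retained = j_ret,
       ambiguous_overlap = ambiguous)
}

#' Decompose many junctions at once
#'
#' @param vGerm3,jGerm5 germline flanks, either single strings (shared by all
#'   junctions) or vectors parallel to `observed`.
#' @param observed character vector of observed junction windows.
#' @inheritParams decomposeJunction
#' @return `data.frame` with one row per junction and the fields of
#'   [decomposeJunction()].
#' @export
decomposeJunctions <- function(vGerm3, jGerm5, observed, maxP = 4L) {
  n <- length(observed)
  if (length(vGerm3) == 1L) vGerm3 <- rep(vGerm3, n)
  if (length(jGerm5) == 1L) jGerm5 <- rep(jGerm5, n)
  stopifnot(length(vGerm3) == n, length(jGerm5) == n)
  rows <- lapply(seq_len(n), function(i)
    as.data.frame(decomposeJunction(vGerm3[i], jGerm5[i], observed[i], maxP),
                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarize junction diversity across a set of decompositions
#'
#' Reports the fractions of junctions carrying N- and P-nucleotides (an
#' all-germline repertoire, `frac_with_N == 0`, is the signature of absent
#' TdT), the distribution of the amino-acid residue encoded at the V-J
#' junction codon, and a deletion-class table keyed by net codon loss
#' (`(v_trim + j_trim - inserted) / 3`).
#'
#' @param junctions `data.frame` from [decomposeJunctions()].
#' @param junctionResidues optional character vector (parallel to rows) of the
#'   amino acid read at the V-J junction codon of each sequence.
#' @return List with `n_total`, `frac_with_N`, `frac_with_P`,
#'   `mean_v_trim`, `mean_j_trim`, `junction_residue_table` (fractions) and
#'   `deletion_class_table` (fractions keyed by codons lost; non-multiple-of-3
#'   nets are keyed `"frameshift"`).
#' @export
summarizeJunctions <- function(junctions, junctionResidues = NULL) {
  if (!nrow(junctions)) stop("empty junction set")
  ins <- nchar(junctions$p_v) + nchar(junctions$n_region) +
    nchar(junctions$p_j)
  net <- junctions$v_trim + junctions$j_trim - ins
  cls <- ifelse(net %% 3L == 0L, as.character(net %/% 3L), "frameshift")
  res <- list(
    n_total = nrow(junctions),
    frac_with_N = mean(nchar(junctions$n_region) > 0L),
    frac_with_P = mean(nchar(junctions$p_v) > 0L | nchar(junctions$p_j) > 0L),
    mean_v_trim = mean(junctions$v_trim),
    mean_j_trim = mean(junctions$j_trim),
    deletion_class_table = prop.table(table(cls))
  )
  if (!is.null(junctionResidues)) {
    stopifnot(length(junctionResidues) == nrow(junctions))
    res$junction_residue_table <- prop.table(table(junctionResidues))
  }
  res
}
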