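# Sequence primitives shared by all pipeline stages: translation, global and
# local pairwise alignment, percent identity. Alignment is delegated to
# Biostrings; this layer fixes the parameterization used throughout the
# package and the identity bookkeeping on top of it.

.NT_ALPHABET <- c("A", "C", "G", "T", "N")

.as_dna <- function(x, what = "sequence") {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- toupper(x)
    bad <- setdiff(unique(strsplit(x, "")[[1L]]), .NT_ALPHABET)
    if (length(bad))
      stop(what, " contains non-nucleotide characters: ",
           paste(bad, collapse = ", "))
    return(DNAString(x))
  }
  stop(what, " must be a character string or DNAString")
}

.as_aa <- function(x, what = "sequence") {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(AAString(toupper(x)))
  }
  stop(what, " must be a character string or AAString")
}

.is_protein <- function(x) {
  if (is(x, "AAString") || is(x, "AAStringSet")) return(TRUE)
  if (is(x, "DNAString") || is(x, "DNAStringSet")) return(FALSE)
  chars <- unique(strsplit(toupper(as.character(x)[1L]), "")[[1L]])
  length(setdiff(chars, .NT_ALPHABET)) > 0L
}

#' Reverse-complement a nucleotide sequence
#'
#' @param x character string, `DNAString` or `DNAStringSet`.
#' @return Object of the same flavour as the input (character in, character out).
#' @examples
#' revComp("ACGTT")
#' @export
revComp <- function(x) {
  if (is.character(x))
    return(as.character(reverseComplement(DNAStringSet(toupper(x)))))
  reverseComplement(x)
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; stop codons are rendered as `*`; a trailing partial
#' codon is dropped; codons containing `N` translate to `X`.
#'
#' @param x character string, `DNAString` or single-element `DNAStringSet`.
#' @param frame integer offset 0, 1 or 2 from the 5' end.
#' @return Character string of amino acids.
#' @examples
#' translateNT("ATGAAATAA")
#' @export
translateNT <- function(x, frame = 0L) {
  stopifnot(frame %in% 0:2)
  dna <- .as_dna(x, "translateNT() input")
  n <- length(dna) - frame
  n <- n - n %% 3L
  if (n <= 0L) return("")
  cds <- subseq(dna, start = frame + 1L, width = n)
  as.character(translate(cds, if.fuzzy.codon = "X"))
}

# vectorized frame-0 translation of many sequences in one Biostrings call
.translate_many <- function(x) {
  if (!length(x)) return(character(0))
  n <- nchar(x) - nchar(x) %% 3L
  dna <- DNAStringSet(substr(x, 1L, n))
  as.character(translate(dna, if.fuzzy.codon = "X"))
}

.nt_submat <- function() {
  nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = FALSE)
}

.aa_submat <- function() {
  # BLOSUM62 shipped with Biostrings; lazily loaded once
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

.identity_from_aligned <- function(a, b, gapMode) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  nongap <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & nongap)
  compared <- if (gapMode == "exclude_gap_columns") sum(nongap) else length(ca)
  list(identity_pct = if (compared > 0) 100 * ident / compared else NA_real_,
       compared_columns = compared, identical_columns = ident)
}

#' Global (Needleman-Wunsch) alignment with percent identity
#'
#' Aligns two sequences end to end and reports percent identity over compared
#' columns. Nucleotide scoring is match +2 / mismatch -3, gap open 5 / extend
#' 2; protein scoring is BLOSUM62, gap open 11 / extend 1.
#'
#' @param a,b sequences of the same alphabet (character, `DNAString` or
#'   `AAString`).
#' @param gapMode `"exclude_gap_columns"` (default: identity denominator is the
#'   number of columns where both sequences have a residue) or `"count_gaps"`
#'   (all alignment columns).
#' @param type passed to [Biostrings::pairwiseAlignment()]; `"global"` here,
#'   `"local"` via [localAlign()].
#' @return A list with elements `aligned_a`, `aligned_b`, `score`,
#'   `identity_pct`, `compared_columns`.
#' @examples
#' globalIdentity("ACGT", "ACGA")$identity_pct  # 75
#' @export
globalIdentity <- function(a, b,
                           gapMode = c("exclude_gap_columns", "count_gaps"),
                           type = "global") {
  gapMode <- match.arg(gapMode)
  protein <- .is_protein(a) || .is_protein(b)
  if (.is_protein(a) != .is_protein(b))
    stop("sequences must share an alphabet")
  if (!nchar(as.character(a)) || !nchar(as.character(b)))
    stop("empty sequence")
  if (protein) {
    pa <- pairwiseAlignment(.as_aa(a), .as_aa(b), type = type,
                            substitutionMatrix = .aa_submat(),
                            gapOpening = 11, gapExtension = 1)
  } else {
    pa <- pairwiseAlignment(.as_dna(a), .as_dna(b), type = type,
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
  }
  sa <- as.character(alignedPattern(pa))
  sb <- as.character(alignedSubject(pa))
  idn <- .identity_from_aligned(sa, sb, gapMode)
  list(aligned_a = sa, aligned_b = sb, score = score(pa),
       identity_pct = idn$identity_pct,
       compared_columns = idn$compared_columns)
}

#' Local (Smith-Waterman) alignment with percent identity
#'
#' Best-scoring local segment pair under the same scoring scheme as
#' [globalIdentity()]. Additionally reports the coordinates of the aligned
#' segments (1-based, inclusive) in query and target.
#'
#' @inheritParams globalIdentity
#' @param query,target sequences of the same alphabet.
#' @return List with `aligned_a`, `aligned_b`, `score`, `identity_pct`,
#'   `compared_columns`, `query_start`, `query_end`, `target_start`,
#'   `target_end`.
#' @export
localAlign <- function(query, target,
                       gapMode = c("exclude_gap_columns", "count_gaps")) {
  gapMode <- match.arg(gapMode)
  protein <- .is_protein(query) || .is_protein(target)
  if (.is_protein(query) != .is_protein(target))
    stop("sequences must share an alphabet")
  if (!nchar(as.character(query)) || !nchar(as.character(target)))
    stop("empty sequence")
  if (protein) {
    pa <- pairwiseAlignment(.as_aa(query), .as_aa(target), type = "local",
                            substitutionMatrix = .aa_submat(),
                            gapOpening = 11, gapExtension = 1)
  } else {
    pa <- pairwiseAlignment(.as_dna(query), .as_dna(target), type = "local",
                            substitutionMatrix = .nt_submat(),
                            gapOpening = 5, gapExtension = 2)
  }
  sa <- as.character(alignedPattern(pa))
  sb <- as.character(alignedSubject(pa))
  idn <- .identity_from_aligned(sa, sb, gapMode)
  p <- pattern(pa); s <- subject(pa)
  list(aligned_a = sa, aligned_b = sb, score = score(pa),
       identity_pct = idn$identity_pct,
       compared_columns = idn$compared_columns,
       query_start = Biostrings::start(p), query_end = Biostrings::end(p),
       target_start = Biostrings::start(s), target_end = Biostrings::end(s))
}

#' Read sequences from FASTA/FASTQ
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()]; FASTQ is Sanger
#' Phred+33 (qualities are discarded, the pipeline is substitution-aware via
#' identity thresholds, not quality-aware).
#'
#' @param path file path.
#' @return `DNAStringSet`.
#' @export
readFastaDNA <- function(path) readDNAStringSet(path, format = "fasta")

#' @rdname readFastaDNA
#' @export
readFastqDNA <- function(path) readDNAStringSet(path, format = "fastq")

#' Write sequences to FASTA (wrapped at 80 columns)
#'
#' @param x `DNAStringSet` or `AAStringSet` (or named character vector).
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    x <- if (.is_protein(x[1])) AAStringSet(x) else DNAStringSet(x)
  }
  writeXStringSet(x, filepath = path, width = 80L)
}

#' Write reads to FASTQ with uniform qualities
#'
#' @param x named `DNAStringSet` or named character vector.
#' @param path output path.
#' @param qual single quality character applied to every base (Phred+33).
#' @export
writeFastq <- function(x, path, qual = "I") {
  if (is.character(x)) x <- DNAStringSet(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("read", seq_along(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    s <- as.character(x[[i]])
    writeLines(c(paste0("@", ids[i]), s, "+",
                 strrep(qual, nchar(s))), con)
  }
  invisible(path)
}
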