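# Recombination signal sequence (RSS) detection and typing.
#
# An RSS is a conserved heptamer - spacer - nonamer motif flanking V and J
# coding segments. The spacer is ~12 or ~23 nt; kappa-type loci pair V-12 with
# J-23 ("12/23"), lambda-type loci pair V-23 with J-12 ("23/12"). Scoring is a
# simple match count against the canonical vertebrate consensus (0..16 over
# 7 heptamer + 9 nonamer positions).

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER  <- "ACAAAAACC"

#' RSS scanning configuration
#'
#' @param heptamer,nonamer consensus strings (7 and 9 nt).
#' @param spacerTolerance allowed deviation (nt) from the canonical 12/23
#'   spacer lengths.
#' @param minScore minimum combined match count (0..16) for a motif to be
#'   reported.
#' @param requireCAC if `TRUE` the first three heptamer positions must match
#'   `CAC` exactly (the functionally critical positions).
#' @return A list of class `RSSConfig`.
#' @examples
#' rssConfig(minScore = 12)
#' @export
rssConfig <- function(heptamer = RSS_HEPTAMER, nonamer = RSS_NONAMER,
                      spacerTolerance = 1L, minScore = 10L,
                      requireCAC = TRUE) {
  stopifnot(nchar(heptamer) == 7L, nchar(nonamer) == 9L, spacerTolerance >= 0L)
  structure(list(heptamer = toupper(heptamer), nonamer = toupper(nonamer),
                 spacerTolerance = as.integer(spacerTolerance),
                 minScore = as.integer(minScore),
                 requireCAC = isTRUE(requireCAC)),
            class = "RSSConfig")
}

.count_matches <- function(a, b) {
  sum(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
}

#' Scan a sequence for candidate recombination signal sequences
#'
#' Every window of the form heptamer + spacer + nonamer with spacer length
#' within tolerance of 12 or 23 nt and match score at least `cfg$minScore` is
#' reported, sorted by position. Position is the 0-based offset of the
#' heptamer start on the given strand.
#'
#' @param seq nucleotide sequence (character or `DNAString`).
#' @param cfg an [rssConfig()].
#' @return `data.frame` with columns `position`, `heptamer`, `spacer_len`,
#'   `spacer_class`, `nonamer`, `score`.
#' @export
scanRSS <- function(seq, cfg = rssConfig()) {
  s <- as.character(.as_dna(seq, "scanRSS() input"))
  n <- nchar(s)
  out <- list()
  if (n < 7L + 12L + 9L) return(.empty_rss_df())
  spacers <- sort(unique(c(
    (12L - cfg$spacerTolerance):(12L + cfg$spacerTolerance),
    (23L - cfg$spacerTolerance):(23L + cfg$spacerTolerance))))
  spacers <- spacers[spacers >= 0L]
  k <- 1L
  for (pos in 0:(n - (7L + min(spacers) + 9L))) {
    hept <- substr(s, pos + 1L, pos + 7L)
    if (cfg$requireCAC && substr(hept, 1L, 3L) != "CAC") next
    hscore <- .count_matches(hept, cfg$heptamer)
    for (sp in spacers) {
      nstart <- pos + 7L + sp
      if (nstart + 9L > n) next
      nona <- substr(s, nstart + 1L, nstart + 9L)
      sc <- hscore + .count_matches(nona, cfg$nonamer)
      if (sc < cfg$minScore) next
      cls <- if (abs(sp - 12L) <= cfg$spacerTolerance) 12L else 23L
      out[[k]] <- data.frame(position = pos, heptamer = hept,
                             spacer_len = sp, spacer_class = cls,
                             nonamer = nona, score = sc,
                             stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  if (!length(out)) return(.empty_rss_df())
  res <- do.call(rbind, out)
  res[order(res$position, res$spacer_len), , drop = FALSE]
}

.empty_rss_df <- function() {
  data.frame(position = integer(), heptamer = character(),
             spacer_len = integer(), spacer_class = integer(),
             nonamer = character(), score = integer(),
             stringsAsFactors = FALSE)
}

#' Classify the RSS of one segment flank
#'
#' Searches the flank immediately adjacent to a coding end for the
#' best-scoring RSS in the expected orientation. For a V segment the RSS lies
#' 3' of the coding end on the coding strand (heptamer first); for a J segment
#' it lies 5' of the coding start in reverse-complement orientation (heptamer
#' adjacent to the coding sequence). Returns `NULL` when no motif passes the
#' configured threshold ("disrupted RSS").
#'
#' @param flank flank sequence on the forward/coding strand. For
#'   `three_prime_of_V` the flank starts at the first base after the V coding
#'   end; for `five_prime_of_J` the flank ends at the last base before the J
#'   coding start.
#' @param side `"three_prime_of_V"` or `"five_prime_of_J"`.
#' @param cfg an [rssConfig()].
#' @return One-row `data.frame` as in [scanRSS()] (position is the 0-based
#'   heptamer offset in the scanned orientation; 0 means heptamer abuts the
#'   coding end), or `NULL`.
#' @export
classifySegmentRSS <- function(flank,
                               side = c("three_prime_of_V", "five_prime_of_J"),
                               cfg = rssConfig()) {
  side <- match.arg(side)
  s <- as.character(.as_dna(flank, "flank"))
  if (side == "five_prime_of_J") s <- revComp(s)
  hits <- scanRSS(s, cfg)
  if (!nrow(hits)) return(NULL)
  # best score; ties broken by proximity of the heptamer to the coding end
  hits <- hits[order(-hits$score, hits$position), , drop = FALSE]
  hits[1L, , drop = FALSE]
}

#' Classify locus rearrangement type from segment RSS spacer classes
#'
#' @param vClasses,jClasses integer vectors (possibly empty) of spacer classes
#'   (12 or 23) collected from the functional V and J segments of one locus.
#' @return `"kappa_type"` (V all 12, J all 23), `"lambda_type"` (V all 23,
#'   J all 12), `"non_rearranging"` (both empty) or `"inconsistent"`.
#' @examples
#' classifyLocusRSS(c(12, 12), 23)   # kappa_type
#' classifyLocusRSS(23, 12)          # lambda_type
#' classifyLocusRSS(integer(), integer())  # non_rearranging
#' @export
classifyLocusRSS <- function(vClasses, jClasses) {
  v <- as.integer(vClasses); j <- as.integer(jClasses)
  if (!length(v) && !length(j)) return("non_rearranging")
  if (length(v) && length(j) && all(v == 12L) && all(j == 23L))
    return("kappa_type")
  if (length(v) && length(j) && all(v == 23L) && all(j == 12L))
    return("lambda_type")
  "inconsistent"
}

#' Write an RSS report table
#'
#' @param hits data.frame of motifs (as from [scanRSS()]) with an added
#'   `segment_id` column.
#' @param path output TSV path.
#' @export
writeRSSReport <- function(hits, path) {
  cols <- c("segment_id", "position", "heptamer", "spacer_len", "nonamer",
            "score", "spacer_class")
  write.table(hits[, intersect(cols, names(hits)), drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
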