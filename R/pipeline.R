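# End-to-end orchestration: simulate -> annotate -> repertoire -> junctions,
# with a seed-deterministic run manifest. This is the programmatic driver for
# the whole desk-scale workflow; each stage is also callable on its own.

#' Run the simulate/annotate/repertoire/junction pipeline
#'
#' Generates a germline locus, simulates rearranged cDNAs and amplicon
#' reads, annotates the scaffold against the simulated reference panel,
#' pools/QCs the amplicons, assigns J and V-family calls, collapses unique
#' sequences and decomposes all junctions. When `outDir` is given, stage
#' outputs (FASTA, GFF3, rearrangement TSV) and a JSON run manifest
#' (seed, parameters, output checksums) are written.
#'
#' @param cfg a [simConfig()].
#' @param nRearrangements number of simulated cDNAs.
#' @param readDepth amplicon read copies per cDNA.
#' @param errRate amplicon substitution error rate.
#' @param seed integer seed driving every stage.
#' @param outDir optional output directory.
#' @return List with `germline`, `locus` (a [LocusModel-class]), `pool`
#'   (QC'd annotated [AmpliconPool-class]), `uniques`, `junctions`
#'   (decompositions + summary), and `manifest`.
#' @export
runPipeline <- function(cfg = simConfig(), nRearrangements = 100L,
                        readDepth = 1L, errRate = 0, seed = 1L,
                        outDir = NULL) {
  cfg$seed <- as.integer(seed)
  germ <- genGermline(cfg)
  sim <- simulateRearrangements(germ, nRearrangements, seed = seed + 1L)
  reads <- simulateReads(sim$cdna, depth = readDepth, err = errRate,
                         seed = seed + 2L)

  # annotate the scaffold with family founders + C as the reference panel
  refs <- DNAStringSet(c(setNames(germ$founders,
                                  paste0("V:", names(germ$founders))),
                         setNames(germ$c_seqs,
                                  paste0("C:", names(germ$c_seqs)))))
  segs <- findSegments(germ$scaffold, refs)
  segs <- flagDefects(segs, germ$scaffold, refs)
  locus <- classifyOrganization(segs, locusId = "sim_locus")

  # repertoire: pool on the C reference, QC, call J and V family
  assigned <- assignPool(DNAStringSet(reads$reads),
                         DNAStringSet(germ$c_seqs))
  pools <- splitPools(assigned)
  pool <- qcFilter(pools[[1L]])
  pool <- assignJCall(pool, DNAStringSet(germ$j_seqs))
  fam_refs <- setNames(germ$founders, paste0("fam", seq_along(germ$founders)))
  pool <- assignVFamily(pool, DNAStringSet(fam_refs))
  uniq <- collapseUnique(pool)

  # junctions of the productive truth rearrangements, via the truth V/J ids
  tr <- sim$truth
  leader_len <- nchar(germ$leader[tr$v_id])
  leader_len[is.na(leader_len)] <- 0L
  win <- 12L
  junc <- lapply(seq_len(nrow(tr)), function(i) {
    v <- germ$v_seqs[[tr$v_id[i]]]; j <- germ$j_seqs[[tr$j_id[i]]]
    body <- sim$cdna[[tr$sequence_id[i]]]
    v3 <- substr(v, nchar(v) - win + 1L, nchar(v))
    j5 <- substr(j, 1L, win)
    obs_start <- leader_len[i] + (nchar(v) - tr$v_trim[i]) - (win - tr$v_trim[i]) + 1L
    obs_end <- leader_len[i] + (nchar(v) - tr$v_trim[i]) +
      nchar(tr$p_v[i]) + nchar(tr$n_region[i]) + nchar(tr$p_j[i]) +
      (win - tr$j_trim[i])
    decomposeJunction(v3, j5, substr(body, obs_start, obs_end))
  })
  junc_df <- do.call(rbind, lapply(junc, as.data.frame))
  jsum <- summarizeJunctions(junc_df)

  manifest <- list(seed = seed, n_rearrangements = nRearrangements,
                   read_depth = readDepth, err_rate = errRate,
                   config = unclass(cfg))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFasta(setNames(germ$scaffold, "scaffold"),
               file.path(outDir, "scaffold.fasta"))
    writeSegmentsGFF(segs, file.path(outDir, "segments.gff3"))
    writeFastq(reads$reads, file.path(outDir, "amplicons.fastq"))
    writeRearrangementTSV(pool, file.path(outDir, "rearrangements.tsv"))
    files <- list.files(outDir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(germline = germ, locus = locus, pool = pool, uniques = uniq,
       junctions = list(table = junc_df, summary = jsum),
       manifest = manifest)
}
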