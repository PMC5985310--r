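# Central S4 containers.

#' LocusModel: an annotated immunoglobulin light-chain locus
#'
#' Holds the gene segments annotated on one scaffold/locus as a `GRanges`
#' (metadata columns `kind` in L/V/J/C, `segment_id`, `functionality`,
#' `defects`, `rss_spacer`, `frame`), the inferred locus organization
#' (`translocon`, `vjc_cluster`, `non_rearranging`) and the locus RSS type
#' (`kappa_type` 12/23, `lambda_type` 23/12, `non_rearranging`,
#' `inconsistent`).
#'
#' @slot locusId character scalar.
#' @slot segments `GRanges` of annotated segments.
#' @slot organization character scalar.
#' @slot rssType character scalar.
#' @export
setClass("LocusModel",
         representation(locusId = "character", segments = "GRanges",
                        organization = "character", rssType = "character"))

setValidity("LocusModel", function(object) {
  msg <- character()
  if (length(object@locusId) != 1L) msg <- c(msg, "locusId must be scalar")
  if (!object@organization %in%
      c("translocon", "vjc_cluster", "non_rearranging"))
    msg <- c(msg, "unknown organization")
  if (!object@rssType %in%
      c("kappa_type", "lambda_type", "non_rearranging", "inconsistent"))
    msg <- c(msg, "unknown rssType")
  need <- c("kind", "segment_id", "functionality")
  if (!all(need %in% names(mcols(object@segments))))
    msg <- c(msg, "segments must carry kind/segment_id/functionality")
  if (length(msg)) msg else TRUE
})

#' @describeIn LocusModel constructor.
#' @param locusId,segments,organization,rssType see slots.
#' @export
LocusModel <- function(locusId, segments, organization, rssType) {
  new("LocusModel", locusId = locusId, segments = segments,
      organization = organization, rssType = rssType)
}

#' @rdname LocusModel
#' @param object,x a `LocusModel`.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname LocusModel
#' @export
setMethod("segments", "LocusModel", function(x) x@segments)

#' @rdname LocusModel
#' @export
setGeneric("organization", function(x) standardGeneric("organization"))
#' @rdname LocusModel
#' @export
setMethod("organization", "LocusModel", function(x) x@organization)

#' @rdname LocusModel
#' @export
setGeneric("rssType", function(x) standardGeneric("rssType"))
#' @rdname LocusModel
#' @export
setMethod("rssType", "LocusModel", function(x) x@rssType)

setMethod("show", "LocusModel", function(object) {
  seg <- object@segments
  counts <- table(factor(mcols(seg)$kind, levels = c("L", "V", "J", "C")))
  fun <- sum(mcols(seg)$functionality == "functional")
  cat("LocusModel '", object@locusId, "': ", object@organization,
      " (", object@rssType, ")\n", sep = "")
  cat("  segments: ", paste(names(counts), counts, sep = "=",
                            collapse = " "), "\n", sep = "")
  cat("  functional: ", fun, "/", length(seg), "\n", sep = "")
})

#' AmpliconPool: QC'd amplicon sequences of one isotype
#'
#' @slot isotype character scalar (CL reference label of the pool).
#' @slot members `DataFrame` with at least `sequence_id`, `sequence`,
#'   `c_call`; QC and downstream steps add `j_call`, `v_family`, `productive`,
#'   `duplicate_count`.
#' @slot stats named list of counts: `n_input`, `n_discarded_frameshift`,
#'   `n_discarded_stop`, `n_discarded_truncated`, `n_unassigned`.
#' @export
setClass("AmpliconPool",
         representation(isotype = "character", members = "DataFrame",
                        stats = "list"))

setValidity("AmpliconPool", function(object) {
  msg <- character()
  if (length(object@isotype) != 1L) msg <- c(msg, "isotype must be scalar")
  if (!all(c("sequence_id", "sequence") %in% names(object@members)))
    msg <- c(msg, "members need sequence_id and sequence columns")
  if (length(msg)) msg else TRUE
})

#' @describeIn AmpliconPool constructor.
#' @param isotype,members,stats see slots.
#' @export
AmpliconPool <- function(isotype, members,
                         stats = list(n_input = nrow(members),
                                      n_discarded_frameshift = 0L,
                                      n_discarded_stop = 0L,
                                      n_discarded_truncated = 0L,
                                      n_unassigned = 0L)) {
  new("AmpliconPool", isotype = isotype, members = members, stats = stats)
}

#' @rdname AmpliconPool
#' @param x,object an `AmpliconPool`.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname AmpliconPool
#' @export
setMethod("members", "AmpliconPool", function(x) x@members)

#' @rdname AmpliconPool
#' @export
setGeneric("poolStats", function(x) standardGeneric("poolStats"))
#' @rdname AmpliconPool
#' @export
setMethod("poolStats", "AmpliconPool", function(x) x@stats)

#' @rdname AmpliconPool
#' @export
setGeneric("isotypeLabel", function(x) standardGeneric("isotypeLabel"))
#' @rdname AmpliconPool
#' @export
setMethod("isotypeLabel", "AmpliconPool", function(x) x@isotype)

setMethod("show", "AmpliconPool", function(object) {
  cat("AmpliconPool '", object@isotype, "': ", nrow(object@members),
      " sequences\n", sep = "")
  st <- object@stats
  cat("  input=", st$n_input,
      " discarded(frameshift/stop/truncated)=", st$n_discarded_frameshift,
      "/", st$n_discarded_stop, "/", st$n_discarded_truncated, "\n", sep = "")
})

setMethod("length", "AmpliconPool", function(x) nrow(x@members))
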