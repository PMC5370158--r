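# Accessor generics + show methods for the S4 containers.

#' @rdname CodingTranscript-class
#' @param object a `CodingTranscript` (or other object the generic applies to)
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))

#' @rdname CodingTranscript-class
#' @export
setMethod("transcriptId", "CodingTranscript", function(object) object@transcriptId)

#' @rdname CodonContext-class
#' @param object a `CodonContext`
#' @export
setMethod("transcriptId", "CodonContext", function(object) object@transcriptId)

#' @rdname CodingTranscript-class
#' @export
setGeneric("geneSymbol", function(object) standardGeneric("geneSymbol"))

#' @rdname CodingTranscript-class
#' @export
setMethod("geneSymbol", "CodingTranscript", function(object) object@gene)

#' @rdname CodingTranscript-class
#' @export
setGeneric("cdsSequence", function(object) standardGeneric("cdsSequence"))

#' @rdname CodingTranscript-class
#' @export
setMethod("cdsSequence", "CodingTranscript", function(object) object@cdsSequence)

#' @rdname CodingTranscript-class
#' @export
setGeneric("cdsSegments", function(object) standardGeneric("cdsSegments"))

#' @rdname CodingTranscript-class
#' @export
setMethod("cdsSegments", "CodingTranscript", function(object) object@cdsSegments)

#' @rdname CodonContext-class
#' @export
setGeneric("codonIndex", function(object) standardGeneric("codonIndex"))

#' @rdname CodonContext-class
#' @export
setMethod("codonIndex", "CodonContext", function(object) object@codonIndex)

#' @rdname CodonContext-class
#' @export
setGeneric("refCodon", function(object) standardGeneric("refCodon"))

#' @rdname CodonContext-class
#' @export
setMethod("refCodon", "CodonContext", function(object) object@refCodon)

#' @rdname CodonContext-class
#' @export
setGeneric("genomicPositions", function(object) standardGeneric("genomicPositions"))

#' @rdname CodonContext-class
#' @export
setMethod("genomicPositions", "CodonContext", function(object) object@genomicPositions)

#' @rdname PhaseCall-class
#' @param object a `PhaseCall`
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname PhaseCall-class
#' @export
setMethod("verdict", "PhaseCall", function(object) object@verdict)

#' @rdname PhaseCall-class
#' @export
setGeneric("phaseCounts", function(object) standardGeneric("phaseCounts"))

#' @rdname PhaseCall-class
#' @export
setMethod("phaseCounts", "PhaseCall", function(object)
    c(spanning = object@nReadsSpanning, cis = object@nReadsCis,
      trans = object@nReadsTrans))

#' @rdname NullModelResult-class
#' @param object a `NullModelResult`
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname NullModelResult-class
#' @export
setMethod("pValue", "NullModelResult", function(object) object@pValue)

#' @rdname NullModelResult-class
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname NullModelResult-class
#' @export
setMethod("modelName", "NullModelResult", function(object) object@modelName)

#' @rdname SyntheticCohort-class
#' @param object a `SyntheticCohort`
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

setMethod("show", "CodingTranscript", function(object) {
    cat(sprintf("CodingTranscript %s (%s) %s:%s strand %s\n",
                object@transcriptId, object@gene, object@chrom,
                paste(sprintf("%d-%d", start(object@cdsSegments),
                              end(object@cdsSegments)), collapse = ","),
                object@strand))
    cat(sprintf("  CDS: %d nt (%d codons)\n", length(object@cdsSequence),
                length(object@cdsSequence) %/% 3L))
})

setMethod("show", "CodonContext", function(object) {
    cat(sprintf("CodonContext %s codon %d [%s] %s (%s)\n",
                object@transcriptId, object@codonIndex,
                paste(object@genomicPositions, collapse = ","),
                object@refCodon, translateCodon(object@refCodon)))
})

setMethod("show", "PhaseCall", function(object) {
    cat(sprintf("PhaseCall: %s (spanning %d, cis %d, trans %d)\n",
                object@verdict, object@nReadsSpanning, object@nReadsCis,
                object@nReadsTrans))
})

setMethod("show", "Substitution", function(object) {
    cat(sprintf("Substitution %s/%s %s [%s]\n", object@gene,
                object@transcriptId, formatSubstitution(object),
                object@category))
})

setMethod("show", "NullModelResult", function(object) {
    cat(sprintf("NullModelResult '%s'\n  method: %s\n", object@modelName,
                object@method))
    cat(sprintf("  statistic = %.4g, p = %.4g, n = %d\n", object@statistic,
                object@pValue, object@n))
    if (!is.na(object@seed)) cat(sprintf("  seed = %d\n", object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf(paste0("SyntheticCohort: %d patients, %d transcripts, ",
                       "%d germline calls, %d somatic calls, %d planted events\n"),
                object@config@nPatients, length(object@transcripts),
                nrow(object@germline), nrow(object@somatic),
                nrow(object@truth)))
})
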