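# Candidate discovery (2-nt window, same-codon test), adjacent-codon
# controls, and read-backed cis/trans phasing.

#' Read phase evidence from a simple pileup TSV
#'
#' The simulator's read-evidence format: tab-separated `read_id, pos, base,
#' qual`, one row per read per covered position. A header line is optional.
#' Rows from the two mates of a pair share a `read_id` and therefore count as
#' one evidence unit.
#'
#' @param path TSV path.
#' @return data.frame with columns `read_id, pos, base, qual`.
#' @export
readPileup <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- length(first) && grepl("^read_id", first)
    df <- utils::read.table(path, sep = "\t", header = hasHeader,
                            stringsAsFactors = FALSE)
    if (!hasHeader) {
        if (ncol(df) < 4L) stop("pileup needs 4 columns: read_id, pos, base, qual")
        names(df)[1:4] <- c("read_id", "pos", "base", "qual")
    }
    df$pos <- as.integer(df$pos)
    df$qual <- as.numeric(df$qual)
    df
}

#' Extract phase evidence from a SAM file
#'
#' Converts the SAM to BAM in a temporary directory (via Rsamtools) and maps
#' the requested genomic positions into each overlapping alignment to recover
#' the base and base quality observed by every read, yielding the same
#' `read_id, pos, base, qual` table as [readPileup()]. Mates keep their query
#' name, so a fragment is naturally one evidence unit.
#'
#' @param samPath SAM file (coordinate-sorted or not; it is sorted during
#'   conversion).
#' @param chrom contig of interest.
#' @param positions integer vector of 1-based genomic positions.
#' @return data.frame with columns `read_id, pos, base, qual`.
#' @export
readSamEvidence <- function(samPath, chrom, positions) {
    bam <- Rsamtools::asBam(samPath, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    region <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(min(positions) - 1L, max(positions) + 1L))
    param <- Rsamtools::ScanBamParam(what = c("qname", "seq", "qual"),
                                     which = region)
    aln <- GenomicAlignments::readGAlignments(bam, param = param)
    empty <- data.frame(read_id = character(), pos = integer(),
                        base = character(), qual = numeric(),
                        stringsAsFactors = FALSE)
    if (length(aln) == 0L)
        return(empty)
    # lay read sequence and qualities into reference space: deletions become
    # '-' (position not covered), insertions are removed
    cig <- GenomicAlignments::cigar(aln)
    laidSeq <- GenomicAlignments::sequenceLayer(
        S4Vectors::mcols(aln)$seq, cig, from = "query", to = "reference")
    laidQual <- GenomicAlignments::sequenceLayer(
        methods::as(S4Vectors::mcols(aln)$qual, "BStringSet"), cig,
        from = "query", to = "reference")
    starts <- GenomicAlignments::start(aln)
    rows <- list()
    for (j in seq_along(aln)) {
        off <- positions - starts[j] + 1L
        ok <- off >= 1L & off <= Biostrings::width(laidSeq)[j]
        if (!any(ok)) next
        bases <- vapply(off[ok], function(o)
            as.character(Biostrings::subseq(laidSeq[[j]], o, o)), "")
        qchr <- vapply(off[ok], function(o)
            as.character(Biostrings::subseq(laidQual[[j]], o, o)), "")
        keep <- bases %in% c("A", "C", "G", "T")
        if (!any(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
            read_id = S4Vectors::mcols(aln)$qname[j],
            pos = positions[ok][keep], base = bases[keep],
            qual = as.numeric(vapply(qchr[keep], function(ch)
                as.integer(charToRaw(ch)) - 33L, 0L)),
            stringsAsFactors = FALSE)
    }
    if (!length(rows))
        return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Build one merged candidate from the qualifying (germline, somatic) pairs
# that share a codon. Variant pairs occupying the same genomic position are
# never eventized together; a germline variant colliding with a somatic
# position is dropped from the event.
mergeCandidate <- function(patient, chrom, contexts, gRows, sRows) {
    gRows <- unique(gRows)
    sRows <- unique(sRows)
    gRows <- gRows[!(gRows$pos %in% sRows$pos), , drop = FALSE]
    if (nrow(gRows) == 0L || nrow(sRows) == 0L)
        return(NULL)
    dist <- outer(gRows$pos, sRows$pos, function(a, b) abs(a - b))
    structure(list(
        patient_id = patient, chrom = chrom,
        transcripts = names(contexts),
        contexts = contexts,
        germline = gRows, somatic = sRows,
        nt_distance = min(dist),
        same_codon = TRUE), class = "CandidateEvent")
}

#' Find candidate same-codon co-occurrences
#'
#' For one or more patients, flags every (germline, somatic) SNV pair within
#' `window` nucleotides whose positions fall in the same codon of at least
#' one shared transcript. Pairs sharing a codon are merged into one candidate
#' per codon (so two germline plus one somatic variant in a codon is a
#' single event), and a codon shared by several transcripts yields one
#' candidate with all affected transcripts recorded. Codons whose reference
#' translation is a stop are never eventized.
#'
#' @param germline,somatic variant data.frames (see [readGermlineVcf()],
#'   [readSomaticVcf()]).
#' @param transcripts named list of [CodingTranscript].
#' @param window maximum germline-somatic distance in nucleotides.
#' @return list of `CandidateEvent` (each with `same_codon = TRUE`).
#' @export
findCandidates <- function(germline, somatic, transcripts, window = 2L) {
    out <- list()
    if (nrow(germline) == 0L || nrow(somatic) == 0L)
        return(out)
    byTx <- split(seq_along(transcripts),
                  vapply(transcripts, function(t) t@chrom, ""))
    for (patient in sort(unique(intersect(germline$patient_id,
                                          somatic$patient_id)))) {
        g <- germline[germline$patient_id == patient, , drop = FALSE]
        s <- somatic[somatic$patient_id == patient, , drop = FALSE]
        acc <- list()   # key -> list(contexts, g, s)
        for (chrom in unique(s$chrom)) {
            gi <- which(g$chrom == chrom)
            si <- which(s$chrom == chrom)
            txIdx <- byTx[[chrom]]
            if (!length(gi) || !length(si) || is.null(txIdx)) next
            for (j in si) for (i in gi) {
                d <- abs(g$pos[i] - s$pos[j])
                if (d < 1L || d > window) next
                for (t in txIdx) {
                    tx <- transcripts[[t]]
                    mg <- mapGenomicToCodon(tx, g$pos[i])
                    if (is.null(mg)) next
                    ms <- mapGenomicToCodon(tx, s$pos[j])
                    if (is.null(ms)) next
                    if (mg$context@codonIndex != ms$context@codonIndex) next
                    if (translateCodon(ms$context@refCodon) == "*") next
                    key <- paste(chrom,
                        paste(sort(ms$context@genomicPositions),
                              collapse = "-"), sep = ":")
                    slot <- acc[[key]]
                    if (is.null(slot))
                        slot <- list(contexts = list(), g = g[0, ], s = s[0, ])
                    slot$contexts[[tx@transcriptId]] <- ms$context
                    slot$g <- rbind(slot$g, g[i, , drop = FALSE])
                    slot$s <- rbind(slot$s, s[j, , drop = FALSE])
                    acc[[key]] <- slot
                }
            }
        }
        for (key in sort(names(acc))) {
            slot <- acc[[key]]
            cand <- mergeCandidate(patient, sub(":.*$", "", key),
                                   slot$contexts[sort(names(slot$contexts))],
                                   slot$g, slot$s)
            if (!is.null(cand)) out[[length(out) + 1L]] <- cand
        }
    }
    out
}

#' Find adjacent-codon control pairs
#'
#' The control set for the cis:trans selection comparison: (germline,
#' somatic) pairs at the same 1-2 nt distance that are coding in a shared
#' transcript but fall in *different* codons. One control event per variant
#' pair, with all transcripts supporting the different-codon verdict
#' recorded.
#'
#' @inheritParams findCandidates
#' @return list of `CandidateEvent` (each with `same_codon = FALSE`).
#' @export
findAdjacentControls <- function(germline, somatic, transcripts, window = 2L) {
    out <- list()
    if (nrow(germline) == 0L || nrow(somatic) == 0L)
        return(out)
    byTx <- split(seq_along(transcripts),
                  vapply(transcripts, function(t) t@chrom, ""))
    for (patient in sort(unique(intersect(germline$patient_id,
                                          somatic$patient_id)))) {
        g <- germline[germline$patient_id == patient, , drop = FALSE]
        s <- somatic[somatic$patient_id == patient, , drop = FALSE]
        acc <- list()
        for (chrom in unique(s$chrom)) {
            gi <- which(g$chrom == chrom)
            si <- which(s$chrom == chrom)
            txIdx <- byTx[[chrom]]
            if (!length(gi) || !length(si) || is.null(txIdx)) next
            for (j in si) for (i in gi) {
                d <- abs(g$pos[i] - s$pos[j])
                if (d < 1L || d > window) next
                for (t in txIdx) {
                    tx <- transcripts[[t]]
                    mg <- mapGenomicToCodon(tx, g$pos[i])
                    if (is.null(mg)) next
                    ms <- mapGenomicToCodon(tx, s$pos[j])
                    if (is.null(ms)) next
                    if (mg$context@codonIndex == ms$context@codonIndex) next
                    key <- paste(chrom, g$pos[i], s$pos[j], sep = ":")
                    slot <- acc[[key]]
                    if (is.null(slot))
                        slot <- list(contexts = list(), i = i, j = j)
                    slot$contexts[[tx@transcriptId]] <- ms$context
                    acc[[key]] <- slot
                }
            }
        }
        for (key in sort(names(acc))) {
            slot <- acc[[key]]
            contexts <- slot$contexts[sort(names(slot$contexts))]
            out[[length(out) + 1L]] <- structure(list(
                patient_id = patient, chrom = sub(":.*$", "", key),
                transcripts = names(contexts), contexts = contexts,
                germline = g[slot$i, , drop = FALSE],
                somatic = s[slot$j, , drop = FALSE],
                nt_distance = abs(g$pos[slot$i] - s$pos[slot$j]),
                same_codon = FALSE), class = "CandidateEvent")
        }
    }
    out
}

#' Phase a candidate event from read evidence
#'
#' An evidence unit (read or read pair, keyed by `read_id`) must cover every
#' variant position of the event with base quality at least `minBaseq` to be
#' counted. It is cis-supporting when it carries every alternate allele
#' (germline and somatic), and trans-supporting when it carries every somatic
#' alternate allele plus the germline *reference* base at one or more
#' germline positions. The verdict is cis when cis-supporting units reach
#' `minSupport` and outnumber trans-supporting units; symmetrically for
#' trans; anything else (including ties and uncovered events) is ambiguous.
#'
#' @param candidate a `CandidateEvent` from [findCandidates()].
#' @param evidence data.frame `read_id, pos, base, qual` (optionally with a
#'   `patient_id` column, filtered to the candidate's patient).
#' @param minSupport minimum supporting units for a cis/trans verdict.
#' @param minBaseq minimum base quality for a base to count as evidence.
#' @return a [PhaseCall].
#' @export
classifyPhase <- function(candidate, evidence, minSupport = 2L,
                          minBaseq = 20) {
    if ("patient_id" %in% names(evidence))
        evidence <- evidence[evidence$patient_id == candidate$patient_id, ,
                             drop = FALSE]
    gPos <- candidate$germline$pos
    gRef <- candidate$germline$ref
    gAlt <- candidate$germline$alt
    sPos <- candidate$somatic$pos
    sAlt <- candidate$somatic$alt
    allPos <- c(gPos, sPos)
    ev <- evidence[evidence$pos %in% allPos & evidence$qual >= minBaseq, ,
                   drop = FALSE]
    nSpan <- 0L; nCis <- 0L; nTrans <- 0L
    if (nrow(ev)) {
        ev <- ev[order(ev$read_id, ev$pos, -ev$qual), , drop = FALSE]
        ev <- ev[!duplicated(ev[, c("read_id", "pos")]), , drop = FALSE]
        for (unit in split(ev, ev$read_id)) {
            at <- stats::setNames(unit$base, unit$pos)
            if (!all(as.character(allPos) %in% names(at))) next
            nSpan <- nSpan + 1L
            somaticAlt <- all(at[as.character(sPos)] == sAlt)
            germAllAlt <- all(at[as.character(gPos)] == gAlt)
            germAnyRef <- any(at[as.character(gPos)] == gRef)
            if (somaticAlt && germAllAlt) nCis <- nCis + 1L
            else if (somaticAlt && germAnyRef) nTrans <- nTrans + 1L
        }
    }
    verdict <- if (nCis >= minSupport && nCis > nTrans) "cis"
        else if (nTrans >= minSupport && nTrans > nCis) "trans"
        else "ambiguous"
    new("PhaseCall", verdict = verdict, nReadsSpanning = nSpan,
        nReadsCis = nCis, nReadsTrans = nTrans)
}

#' Confirm candidates by phasing
#'
#' Phases every candidate and keeps only cis-confirmed events, the only ones
#' on which germline and somatic alleles combine within the codon. Counts are
#' conserved: `n_candidates = n_cis + n_trans + n_ambiguous`.
#'
#' @inheritParams classifyPhase
#' @param candidates list of `CandidateEvent`.
#' @return `list(events = <cis candidates, each with $phase>, counts =
#'   c(n_candidates, n_cis, n_trans, n_ambiguous), phases = <all PhaseCalls>)`
#' @export
confirmEvents <- function(candidates, evidence, minSupport = 2L,
                          minBaseq = 20) {
    phases <- lapply(candidates, classifyPhase, evidence = evidence,
                     minSupport = minSupport, minBaseq = minBaseq)
    verdicts <- vapply(phases, verdict, "")
    events <- mapply(function(cand, ph) { cand$phase <- ph; cand },
                     candidates[verdicts == "cis"],
                     phases[verdicts == "cis"], SIMPLIFY = FALSE)
    list(events = events,
         counts = c(n_candidates = length(candidates),
                    n_cis = sum(verdicts == "cis"),
                    n_trans = sum(verdicts == "trans"),
                    n_ambiguous = sum(verdicts == "ambiguous")),
         phases = phases)
}
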