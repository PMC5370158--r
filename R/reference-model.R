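# Coding-sequence model: annotation loading, genomic->codon mapping,
# translation, and the polarity-class scheme used to call substitutions
# conservative or not.

#' Amino-acid polarity classes
#'
#' The four-class scheme used to decide whether a missense substitution is
#' nonconservative: polar (G, S, T, C, Y, N, Q), nonpolar
#' (A, V, L, I, P, F, W, M), acidic (D, E) and basic (K, R, H).
#'
#' @return named character vector mapping each of the 20 amino-acid letters
#'   to its class.
#' @examples
#' aminoAcidClasses()[["P"]]
#' @export
aminoAcidClasses <- function() {
    c(G = "polar", S = "polar", T = "polar", C = "polar", Y = "polar",
      N = "polar", Q = "polar",
      A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
      P = "nonpolar", F = "nonpolar", W = "nonpolar", M = "nonpolar",
      D = "acidic", E = "acidic",
      K = "basic", R = "basic", H = "basic")
}

#' Translate one codon
#'
#' Standard genetic code (translation table 1); stop codons translate to
#' `"*"`.
#'
#' @param codon three-letter nucleotide string over A/C/G/T.
#' @return single amino-acid letter, or `"*"`.
#' @examples
#' translateCodon("ATG")
#' translateCodon("TAA")
#' @export
translateCodon <- function(codon) {
    if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
        stop("'codon' must be a single 3-letter string")
    codon <- toupper(codon)
    if (!all(strsplit(codon, "")[[1]] %in% c("A", "C", "G", "T")))
        stop("invalid codon '", codon, "': only A/C/G/T allowed")
    unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Is a substitution nonconservative?
#'
#' A substitution is nonconservative when it is a nonsense (stopgain) change,
#' or a missense change that crosses polarity classes. Silent changes are
#' conservative by definition.
#'
#' @param aaFrom reference amino acid (sense letter).
#' @param aaTo alternate amino acid, or `"*"` for a stopgain.
#' @param classes class table from [aminoAcidClasses()].
#' @return logical.
#' @examples
#' isNonconservative("L", "I")  # both nonpolar: conservative
#' isNonconservative("S", "A")  # polar -> nonpolar
#' isNonconservative("W", "*")  # stopgain
#' @export
isNonconservative <- function(aaFrom, aaTo, classes = aminoAcidClasses()) {
    if (aaFrom == "*")
        stop("'aaFrom' must be a sense amino acid, not a stop")
    if (!(aaFrom %in% names(classes)))
        stop("unknown amino acid '", aaFrom, "'")
    if (aaTo == "*")
        return(TRUE)
    if (!(aaTo %in% names(classes)))
        stop("unknown amino acid '", aaTo, "'")
    aaFrom != aaTo && classes[[aaFrom]] != classes[[aaTo]]
}

# Genomic positions of a transcript's CDS in coding order: ascending
# concatenation of segment positions for '+', descending for '-'.
codingPositions <- function(transcript) {
    seg <- cdsSegments(transcript)
    pos <- unlist(lapply(seq_along(seg), function(i)
        seq(IRanges::start(seg)[i], IRanges::end(seg)[i])), use.names = FALSE)
    if (transcript@strand == "-") pos <- rev(pos)
    as.integer(pos)
}

#' Map a genomic position to its codon
#'
#' Locates the codon of `transcript` covering `genomicPos` and returns its
#' [CodonContext] together with the within-codon position (1-3, counted in
#' coding direction). Positions outside the CDS yield `NULL` (a "not coding"
#' signal callers treat as no event).
#'
#' @param transcript a [CodingTranscript].
#' @param genomicPos 1-based genomic position.
#' @return `list(context = CodonContext, codonPos = integer)` or `NULL`.
#' @examples
#' tx <- new("CodingTranscript", transcriptId = "t1", gene = "g1",
#'           chrom = "chr1", strand = "+",
#'           cdsSegments = IRanges::IRanges(101, 109),
#'           cdsSequence = Biostrings::DNAString("ATGGTTAAA"))
#' mapGenomicToCodon(tx, 106)$codonPos  # codon 2, position 3
#' @export
mapGenomicToCodon <- function(transcript, genomicPos) {
    pos <- codingPositions(transcript)
    offset <- match(genomicPos, pos)
    if (is.na(offset))
        return(NULL)
    ci <- as.integer(ceiling(offset / 3))
    within <- as.integer((offset - 1L) %% 3L + 1L)
    idx <- (3L * (ci - 1L) + 1L):(3L * ci)
    ctx <- new("CodonContext",
               transcriptId = transcript@transcriptId,
               codonIndex = ci,
               genomicPositions = pos[idx],
               refCodon = as.character(
                   Biostrings::subseq(transcript@cdsSequence,
                                      start = idx[1L], end = idx[3L])))
    list(context = ctx, codonPos = within)
}

# Splice segment sequences out of the reference and orient them coding-wise.
spliceCds <- function(refSeq, segments, strand) {
    parts <- lapply(seq_along(segments), function(i)
        Biostrings::subseq(refSeq, IRanges::start(segments)[i],
                           IRanges::end(segments)[i]))
    seqs <- do.call(Biostrings::xscat, parts)
    if (strand == "-")
        seqs <- Biostrings::reverseComplement(seqs)
    Biostrings::DNAString(as.character(seqs))
}

readCdsBed <- function(path) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(bed) < 6L)
        stop("CDS BED dialect needs 6 columns ",
             "(chrom, start, end, transcript_id|gene, frame, strand)")
    names(bed)[1:6] <- c("chrom", "start", "end", "name", "frame", "strand")
    ids <- strsplit(bed$name, "|", fixed = TRUE)
    data.frame(chrom = bed$chrom,
               start = bed$start + 1L,   # BED is 0-based half-open
               end = bed$end,
               transcript_id = vapply(ids, `[`, "", 1L),
               gene = vapply(ids, function(x)
                   if (length(x) > 1L) x[2L] else x[1L], ""),
               strand = bed$strand,
               stringsAsFactors = FALSE)
}

readCdsGff <- function(path) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "cds"]
    if (length(gr) == 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), transcript_id = character(),
                          gene = character(), strand = character()))
    meta <- S4Vectors::mcols(gr)
    pick <- function(cands, default) {
        for (cand in cands) {
            if (cand %in% names(meta)) {
                v <- meta[[cand]]
                if (is(v, "List") || is.list(v))
                    v <- vapply(v, function(x)
                        if (length(x)) as.character(x[[1L]]) else NA_character_,
                        "")
                v <- as.character(v)
                if (any(!is.na(v))) return(v)
            }
        }
        rep(default, length(gr))
    }
    txid <- pick(c("transcript_id", "Parent", "ID"), NA_character_)
    gene <- pick(c("gene_name", "gene", "gene_id"), NA_character_)
    gene <- ifelse(is.na(gene), txid, gene)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               transcript_id = txid, gene = gene,
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
}

#' Load coding transcripts from reference + annotation
#'
#' Reads a FASTA reference and a CDS annotation (GFF3/GTF, or the 6-column
#' CDS BED dialect `chrom, start, end, transcript_id|gene, frame, strand`;
#' dialect chosen by file extension) and builds one [CodingTranscript] per
#' annotated CDS. Minus-strand sequences are reverse-complemented into coding
#' orientation. Transcripts whose CDS length is not divisible by 3 or whose
#' sequence contains ambiguity codes are skipped with a warning.
#'
#' @param fastaPath reference FASTA.
#' @param annotationPath GFF3/GTF or CDS BED file.
#' @return named list of [CodingTranscript] (names are transcript ids).
#' @export
loadTranscripts <- function(fastaPath, annotationPath) {
    ref <- Biostrings::readDNAStringSet(fastaPath)
    names(ref) <- sub("\\s.*$", "", names(ref))
    ext <- tolower(tools::file_ext(annotationPath))
    cds <- if (ext == "bed") readCdsBed(annotationPath)
           else readCdsGff(annotationPath)
    if (nrow(cds) == 0L) {
        warning("annotation '", annotationPath, "' contains no CDS features")
        return(structure(list(), names = character()))
    }
    missing <- setdiff(unique(cds$chrom), names(ref))
    if (length(missing))
        stop("annotation references contigs absent from FASTA: ",
             paste(missing, collapse = ", "))
    out <- list()
    for (tid in unique(cds$transcript_id)) {
        rows <- cds[cds$transcript_id == tid, , drop = FALSE]
        rows <- rows[order(rows$start), , drop = FALSE]
        strand <- rows$strand[1L]
        chrom <- rows$chrom[1L]
        seg <- IRanges::IRanges(start = rows$start, end = rows$end)
        seqs <- spliceCds(ref[[chrom]], seg, strand)
        tx <- try(new("CodingTranscript", transcriptId = tid,
                      gene = rows$gene[1L], chrom = chrom, strand = strand,
                      cdsSegments = seg, cdsSequence = seqs),
                  silent = TRUE)
        if (inherits(tx, "try-error")) {
            warning("skipping transcript '", tid, "': ",
                    attr(tx, "condition")$message, call. = FALSE)
            next
        }
        out[[tid]] <- tx
    }
    out
}
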