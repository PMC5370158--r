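#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet GENETIC_CODE reverseComplement
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors isSorted
NULL

#' Coding transcript model
#'
#' A `CodingTranscript` carries the CDS of one transcript: its genomic
#' footprint (possibly spliced) and its nucleotide sequence in coding
#' orientation. It is the frame carrier used to decide whether two variants
#' hit the same codon and to realize reference codons.
#'
#' @slot transcriptId single transcript identifier.
#' @slot gene gene symbol.
#' @slot chrom chromosome / contig name.
#' @slot strand `"+"` or `"-"`.
#' @slot cdsSegments [IRanges::IRanges] of the CDS segments in genomic
#'   coordinates (1-based, inclusive), sorted and non-overlapping.
#' @slot cdsSequence [Biostrings::DNAString] of the spliced CDS in coding
#'   orientation (reverse-complemented for minus-strand transcripts).
#'
#' @details The CDS length must be divisible by 3 and the sequence restricted
#' to `A`, `C`, `G`, `T`; transcripts violating either rule are rejected at
#' load time rather than patched, since no repair rule is defensible.
#'
#' @seealso [loadTranscripts()], [mapGenomicToCodon()]
#' @export
setClass("CodingTranscript",
    representation(
        transcriptId = "character",
        gene = "character",
        chrom = "character",
        strand = "character",
        cdsSegments = "IRanges",
        cdsSequence = "DNAString"
    )
)

setValidity("CodingTranscript", function(object) {
    msg <- character()
    if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
        msg <- c(msg, "'transcriptId' must be a single non-empty string")
    if (!(object@strand %in% c("+", "-")))
        msg <- c(msg, "'strand' must be '+' or '-'")
    seg <- object@cdsSegments
    if (length(seg) > 0L) {
        if (is.unsorted(start(seg)))
            msg <- c(msg, "CDS segments must be sorted by genomic start")
        if (length(seg) > 1L &&
            any(start(seg)[-1L] <= end(seg)[-length(seg)]))
            msg <- c(msg, "CDS segments must be non-overlapping")
    }
    len <- sum(width(seg))
    if (len != length(object@cdsSequence))
        msg <- c(msg, "cdsSequence length must equal total CDS segment width")
    if (len %% 3L != 0L)
        msg <- c(msg, "CDS length must be divisible by 3")
    if (!all(strsplit(as.character(object@cdsSequence), "")[[1]] %in%
             c("A", "C", "G", "T")) && len > 0L)
        msg <- c(msg, "cdsSequence must contain only A/C/G/T")
    if (length(msg)) msg else TRUE
})

#' Codon context at a genomic position
#'
#' Identifies one codon of one transcript: its index along the protein, the
#' three genomic positions it occupies (in codon order, i.e. coding
#' direction), and the reference codon read in coding orientation.
#'
#' @slot transcriptId transcript the codon belongs to.
#' @slot codonIndex 1-based codon (residue) index along the CDS.
#' @slot genomicPositions integer triple of 1-based genomic positions in
#'   codon order (descending for minus-strand transcripts).
#' @slot refCodon three-letter reference codon in coding orientation.
#'
#' @seealso [mapGenomicToCodon()]
#' @export
setClass("CodonContext",
    representation(
        transcriptId = "character",
        codonIndex = "integer",
        genomicPositions = "integer",
        refCodon = "character"
    )
)

setValidity("CodonContext", function(object) {
    msg <- character()
    if (length(object@genomicPositions) != 3L ||
        anyDuplicated(object@genomicPositions))
        msg <- c(msg, "'genomicPositions' must be 3 distinct positions")
    if (length(object@codonIndex) != 1L || object@codonIndex < 1L)
        msg <- c(msg, "'codonIndex' must be a single integer >= 1")
    if (length(object@refCodon) != 1L || nchar(object@refCodon) != 3L ||
        !all(strsplit(object@refCodon, "")[[1]] %in% c("A", "C", "G", "T")))
        msg <- c(msg, "'refCodon' must be a 3-letter A/C/G/T string")
    if (length(msg)) msg else TRUE
})

#' Cis/trans phase call for a candidate co-occurrence
#'
#' Result of read-backed phasing of a candidate event. A read (or read pair,
#' counted as one evidence unit) is cis-supporting when it covers every
#' variant position of the event and carries every alternate allele;
#' trans-supporting when it covers every position, carries every somatic
#' alternate allele, and the germline *reference* allele at one or more
#' germline positions.
#'
#' @slot verdict `"cis"`, `"trans"` or `"ambiguous"`.
#' @slot nReadsSpanning evidence units covering all event positions.
#' @slot nReadsCis cis-supporting units.
#' @slot nReadsTrans trans-supporting units.
#'
#' @seealso [classifyPhase()]
#' @export
setClass("PhaseCall",
    representation(
        verdict = "character",
        nReadsSpanning = "integer",
        nReadsCis = "integer",
        nReadsTrans = "integer"
    )
)

setValidity("PhaseCall", function(object) {
    msg <- character()
    if (!(object@verdict %in% c("cis", "trans", "ambiguous")))
        msg <- c(msg, "'verdict' must be cis, trans or ambiguous")
    if (object@nReadsCis + object@nReadsTrans > object@nReadsSpanning)
        msg <- c(msg, "cis + trans supporting reads cannot exceed spanning reads")
    if (any(c(object@nReadsSpanning, object@nReadsCis, object@nReadsTrans) < 0L))
        msg <- c(msg, "read counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Amino-acid substitution
#'
#' One substitution at one residue of one transcript. `aaAlt` may be `"*"`
#' for a stopgain. Category is determined by the alleles: `silent` iff
#' `aaRef == aaAlt`, `nonsense` iff `aaAlt == "*"`, otherwise `missense`.
#'
#' @slot gene gene symbol.
#' @slot transcriptId transcript identifier.
#' @slot residueIndex 1-based residue position.
#' @slot aaRef reference amino acid (single letter).
#' @slot aaAlt alternate amino acid or `"*"`.
#' @slot category `"silent"`, `"missense"` or `"nonsense"`.
#'
#' @seealso [reportedSubstitution()], [trueSubstitution()], [classifyChange()]
#' @export
setClass("Substitution",
    representation(
        gene = "character",
        transcriptId = "character",
        residueIndex = "integer",
        aaRef = "character",
        aaAlt = "character",
        category = "character"
    )
)

setValidity("Substitution", function(object) {
    msg <- character()
    expected <- if (object@aaAlt == "*") "nonsense"
        else if (object@aaRef == object@aaAlt) "silent" else "missense"
    if (object@category != expected)
        msg <- c(msg, sprintf("category '%s' inconsistent with alleles %s>%s",
                              object@category, object@aaRef, object@aaAlt))
    if (object@aaRef == "*")
        msg <- c(msg, "reference residue cannot be a stop")
    if (length(object@residueIndex) != 1L || object@residueIndex < 1L)
        msg <- c(msg, "'residueIndex' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Variant impact scorer
#'
#' Scores amino-acid substitutions on a 0-100 impact scale. Silent
#' substitutions score 0 and stopgains score 100 in every mode (heuristic
#' anchors of the scale). Missense substitutions are scored either by a
#' surrogate -- Grantham's physicochemical distance rescaled into (0, 100] --
#' or looked up in an external per-substitution score table (e.g. scores
#' produced by an external impact predictor).
#'
#' @slot mode `"surrogate"` or `"external"`.
#' @slot table data.frame with columns `gene`, `substitution` (e.g.
#'   `"T316I"`), `score` in \[0,100\]; used in external mode.
#' @slot isoformMode `"mean"` or `"max"`: how scores across multiple
#'   affected isoforms are aggregated.
#' @slot fallback when `TRUE`, external mode falls back to the surrogate for
#'   substitutions absent from the table; when `FALSE` a missing entry is an
#'   error.
#'
#' @seealso [impactScorer()], [scoreSubstitution()]
#' @export
setClass("ImpactScorer",
    representation(
        mode = "character",
        table = "data.frame",
        isoformMode = "character",
        fallback = "logical"
    )
)

setValidity("ImpactScorer", function(object) {
    msg <- character()
    if (!(object@mode %in% c("surrogate", "external")))
        msg <- c(msg, "'mode' must be 'surrogate' or 'external'")
    if (!(object@isoformMode %in% c("mean", "max")))
        msg <- c(msg, "'isoformMode' must be 'mean' or 'max'")
    if (object@mode == "external") {
        need <- c("gene", "substitution", "score")
        if (!all(need %in% names(object@table)))
            msg <- c(msg, "external table needs columns gene, substitution, score")
        else if (nrow(object@table) &&
                 (any(object@table$score < 0) || any(object@table$score > 100)))
            msg <- c(msg, "external scores must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' Null-model / hypothesis-test result
#'
#' A uniform container for the cohort-level statistics: an observed quantity,
#' the model expectation it is compared against, the test statistic and
#' p-value, and enough metadata (method, sample size, seed) to reproduce the
#' computation.
#'
#' @slot modelName short machine name of the model/test.
#' @slot observed observed counts or statistic (numeric, possibly named).
#' @slot expected expected counts or distribution (numeric, possibly named).
#' @slot statistic value of the test statistic.
#' @slot pValue p-value in \[0,1\] (may be `NA` for pure expectations).
#' @slot method human-readable description of the test.
#' @slot n problem size the statistic was computed on.
#' @slot seed RNG seed used, or `NA` for deterministic computations.
#' @slot extra list of auxiliary quantities (odds ratio, z-score, group
#'   means, ...).
#'
#' @export
setClass("NullModelResult",
    representation(
        modelName = "character",
        observed = "numeric",
        expected = "numeric",
        statistic = "numeric",
        pValue = "numeric",
        method = "character",
        n = "integer",
        seed = "integer",
        extra = "list"
    )
)

setValidity("NullModelResult", function(object) {
    msg <- character()
    p <- object@pValue
    if (length(p) == 1L && !is.na(p) && (p < 0 || p > 1))
        msg <- c(msg, "'pValue' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort simulation settings
#'
#' The stated world of the simulator: a toy exome, a population of common
#' coding SNPs biased toward the third codon position, per-patient somatic
#' mutation burdens with a configurable pyrimidine-biased spectrum, tumor
#' allele fractions peaked near 0.3, and a haplotype/read model that lets the
#' phasing stage be exercised end to end.
#'
#' @slot nPatients number of patients.
#' @slot nTranscripts number of toy transcripts.
#' @slot cdsCodons codons per transcript (including the terminal stop).
#' @slot snpDensity per-coding-site probability that a population SNP
#'   segregates there.
#' @slot mafShape1,mafShape2 Beta parameters of the population MAF
#'   distribution (defaults give mean 0.49, emulating the common-SNP
#'   character of co-occurring germline variants).
#' @slot thirdPosWeight relative weight of the third codon position when
#'   placing SNPs (first and second positions have weight 1).
#' @slot burdenMean mean somatic burden per patient (Poisson).
#' @slot ctBias probability that a somatic mutation is drawn from the
#'   C>T / G>A channel rather than uniformly.
#' @slot vafMean,vafConcentration Beta model of tumor variant allele
#'   fraction: `Beta(vafMean*k, (1-vafMean)*k)`; defaults peak at 0.3.
#' @slot cisProb probability that a somatic variant lands on the haplotype
#'   carrying a nearby heterozygous germline alternate allele (0.5 = neutral;
#'   homozygous sites are cis by construction).
#' @slot depth reads simulated over each candidate region.
#' @slot errorRate per-base sequencing error probability.
#' @slot seed mandatory RNG seed.
#'
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
    representation(
        nPatients = "integer",
        nTranscripts = "integer",
        cdsCodons = "integer",
        snpDensity = "numeric",
        mafShape1 = "numeric",
        mafShape2 = "numeric",
        thirdPosWeight = "numeric",
        burdenMean = "numeric",
        ctBias = "numeric",
        vafMean = "numeric",
        vafConcentration = "numeric",
        cisProb = "numeric",
        depth = "integer",
        errorRate = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    probs <- c(ctBias = object@ctBias, vafMean = object@vafMean,
               cisProb = object@cisProb, errorRate = object@errorRate,
               snpDensity = object@snpDensity)
    bad <- probs < 0 | probs > 1
    if (any(bad))
        msg <- c(msg, paste0("probabilities out of [0,1]: ",
                             paste(names(probs)[bad], collapse = ", ")))
    if (object@burdenMean < 0) msg <- c(msg, "'burdenMean' must be >= 0")
    if (is.na(object@seed)) msg <- c(msg, "'seed' is mandatory")
    if (object@cdsCodons < 3L) msg <- c(msg, "'cdsCodons' must be >= 3")
    if (object@depth < 1L) msg <- c(msg, "'depth' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Simulated cohort with ground truth
#'
#' Everything [simulateCohort()] emits, kept in memory: the toy reference and
#' transcript models, per-patient germline and somatic variant tables, read
#' evidence over candidate regions, and a truth table of planted codon-level
#' co-occurrences (with their cis/trans phase and expected reported/true
#' substitutions) against which the detection pipeline can be benchmarked.
#'
#' @slot reference [Biostrings::DNAStringSet] with the toy contig.
#' @slot transcripts named list of [CodingTranscript].
#' @slot germline data.frame: patient_id, chrom, pos, ref, alt, genotype, maf.
#' @slot somatic data.frame: patient_id, chrom, pos, ref, alt, vaf, filter.
#' @slot reads data.frame: patient_id, read_id, pos, base, qual.
#' @slot truth data.frame of planted co-occurrence events.
#' @slot config the [SimulationConfig] that generated the cohort.
#'
#' @seealso [simulateCohort()], [writeCohort()]
#' @export
setClass("SyntheticCohort",
    representation(
        reference = "DNAStringSet",
        transcripts = "list",
        germline = "data.frame",
        somatic = "data.frame",
        reads = "data.frame",
        truth = "data.frame",
        config = "SimulationConfig"
    )
)
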