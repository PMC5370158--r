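# Germline-aware re-annotation of amino-acid substitutions, impact scoring
# (heuristic anchors + Grantham surrogate or external table), and the
# codon-substitution enumeration behind the nonconservative-proportion table.

# ---- Grantham surrogate ---------------------------------------------------

# Physicochemical side-chain properties (composition, polarity, volume) and
# weights from Grantham (1974); distances scaled so the 190 pairs average 100.
granthamProperties <- function() {
    data.frame(
        aa = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
               "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
        c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
              0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
        p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
              6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
        v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
              136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
        stringsAsFactors = FALSE)
}

.codoncoocCache <- new.env(parent = emptyenv())

#' Grantham distance matrix
#'
#' The 20x20 physicochemical distance matrix of Grantham (1974), computed
#' from side-chain composition, polarity and volume with weights
#' alpha = 1.833, beta = 0.1018, gamma = 0.000399 and scaled so that the 190
#' unordered pairs average 100 (landmarks: Leu/Ile = 5, Cys/Trp = 215).
#'
#' @return symmetric numeric matrix with amino-acid letters as dimnames and
#'   zero diagonal.
#' @export
granthamMatrix <- function() {
    if (!is.null(.codoncoocCache$grantham))
        return(.codoncoocCache$grantham)
    pr <- granthamProperties()
    alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399
    d <- sqrt(alpha * outer(pr$c, pr$c, "-")^2 +
              beta * outer(pr$p, pr$p, "-")^2 +
              gamma * outer(pr$v, pr$v, "-")^2)
    rho <- 100 / mean(d[upper.tri(d)])
    d <- d * rho
    dimnames(d) <- list(pr$aa, pr$aa)
    d <- d[order(rownames(d)), order(colnames(d))]
    .codoncoocCache$grantham <- d
    d
}

# Missense surrogate: Grantham distance min-max rescaled onto (0, 100]
# (smallest pair -> 1, largest -> 100) so it shares the scale anchored by
# silent = 0 and stopgain = 100.
surrogateMissenseScore <- function(aaRef, aaAlt) {
    d <- granthamMatrix()
    off <- d[upper.tri(d)]
    1 + 99 * (d[aaRef, aaAlt] - min(off)) / (max(off) - min(off))
}

# ---- Substitutions --------------------------------------------------------

substitutionCategory <- function(aaRef, aaAlt) {
    if (aaAlt == "*") "nonsense" else if (aaRef == aaAlt) "silent"
    else "missense"
}

#' Construct a [Substitution]
#'
#' @param gene,transcriptId identifiers.
#' @param residueIndex 1-based residue position.
#' @param aaRef,aaAlt reference and alternate amino acids (`aaAlt` may be
#'   `"*"`).
#' @return a [Substitution]; its category is derived from the alleles.
#' @export
makeSubstitution <- function(gene, transcriptId, residueIndex, aaRef, aaAlt) {
    new("Substitution", gene = gene, transcriptId = transcriptId,
        residueIndex = as.integer(residueIndex), aaRef = aaRef, aaAlt = aaAlt,
        category = substitutionCategory(aaRef, aaAlt))
}

#' @rdname makeSubstitution
#' @param sub a [Substitution].
#' @export
formatSubstitution <- function(sub) {
    paste0(sub@aaRef, sub@residueIndex, sub@aaAlt)
}

#' @rdname makeSubstitution
#' @param string substitution in compact notation, e.g. `"T316I"` or
#'   `"W12*"`.
#' @export
parseSubstitution <- function(string, gene = "", transcriptId = "") {
    m <- regmatches(string, regexec("^([A-Z])([0-9]+)([A-Z*])$", string))[[1]]
    if (length(m) != 4L)
        stop("cannot parse substitution '", string, "'")
    makeSubstitution(gene, transcriptId, as.integer(m[3]), m[2], m[4])
}

# Orient a genomic-strand allele into coding orientation for `strand`.
codingAllele <- function(allele, strand) {
    if (strand == "+") allele
    else c(A = "T", C = "G", G = "C", T = "A")[[allele]]
}

# Apply variant alt alleles (genomic strand) to the reference codon of a
# context; returns the mutated codon string in coding orientation.
applyVariantsToCodon <- function(context, variants, strand) {
    codon <- strsplit(context@refCodon, "")[[1]]
    for (i in seq_len(nrow(variants))) {
        within <- match(variants$pos[i], context@genomicPositions)
        if (is.na(within))
            stop("variant at ", variants$pos[i], " is outside codon ",
                 context@codonIndex, " of ", context@transcriptId)
        refCoding <- codingAllele(variants$ref[i], strand)
        if (codon[within] != refCoding)
            warning("reference mismatch at ", variants$pos[i], ": codon has ",
                    codon[within], ", variant ref is ", refCoding,
                    call. = FALSE)
        codon[within] <- codingAllele(variants$alt[i], strand)
    }
    paste(codon, collapse = "")
}

#' Reported (somatic-only) substitution
#'
#' The substitution a traditional somatic caller reports: somatic alternate
#' alleles applied to the *reference* codon, ignoring any germline variant in
#' the same codon.
#'
#' @param context a [CodonContext].
#' @param somatic somatic variant rows falling in the codon.
#' @param transcript the [CodingTranscript] carrying the codon (supplies
#'   strand and gene).
#' @return a [Substitution] with `residueIndex = codonIndex`.
#' @export
reportedSubstitution <- function(context, somatic, transcript) {
    if (nrow(somatic) == 0L)
        stop("reported substitution requires at least one somatic variant")
    mut <- applyVariantsToCodon(context, somatic, transcript@strand)
    makeSubstitution(transcript@gene, transcript@transcriptId,
                     context@codonIndex,
                     translateCodon(context@refCodon), translateCodon(mut))
}

#' True (germline-aware) substitution
#'
#' The substitution actually present in the tumor: when the event is in cis,
#' germline then somatic alternate alleles are applied to the reference codon
#' (disjoint positions, so order is immaterial); in trans the alleles do not
#' combine and the true substitution equals the reported one. The reference
#' residue stays the reference-genome residue, so a codon where the germline
#' change alone is silent can still yield a missense substitution relative to
#' the reference.
#'
#' @inheritParams reportedSubstitution
#' @param germline germline variant rows in the codon.
#' @param phase a [PhaseCall].
#' @return a [Substitution].
#' @export
trueSubstitution <- function(context, germline, somatic, phase, transcript) {
    if (any(germline$pos %in% somatic$pos))
        stop("germline and somatic variants occupy the same position: ",
             "invalid event")
    if (verdict(phase) != "cis")
        return(reportedSubstitution(context, somatic, transcript))
    mut <- applyVariantsToCodon(context, rbind(
        germline[, c("pos", "ref", "alt")],
        somatic[, c("pos", "ref", "alt")]), transcript@strand)
    makeSubstitution(transcript@gene, transcript@transcriptId,
                     context@codonIndex,
                     translateCodon(context@refCodon), translateCodon(mut))
}

#' Classify how germline context changed the annotation
#'
#' Crosses the reported and true substitution categories. Two missense
#' substitutions with the same alternate residue are `no_change`; with
#' different residues, `missense_to_missense`. Reported-nonsense events that
#' change are lumped into `other` (the reference stop exclusion upstream
#' makes them unreachable in practice).
#'
#' @param reported,trueSub [Substitution] objects at the same residue.
#' @param strict when `TRUE` (default) a residue-index mismatch is an error;
#'   `FALSE` classifies on amino-acid letters only (used for printed tables
#'   whose isoform numbering differs between columns).
#' @return one of `no_change, silent_to_missense, silent_to_nonsense,
#'   missense_to_missense, missense_to_nonsense, missense_to_silent, other`.
#' @export
classifyChange <- function(reported, trueSub, strict = TRUE) {
    if (strict && reported@residueIndex != trueSub@residueIndex)
        stop("substitutions are at different residues (",
             reported@residueIndex, " vs ", trueSub@residueIndex, ")")
    r <- reported@category
    t <- trueSub@category
    if (r == "silent") {
        if (t == "silent") "no_change"
        else if (t == "missense") "silent_to_missense"
        else "silent_to_nonsense"
    } else if (r == "missense") {
        if (t == "nonsense") "missense_to_nonsense"
        else if (t == "silent") "missense_to_silent"
        else if (reported@aaAlt == trueSub@aaAlt) "no_change"
        else "missense_to_missense"
    } else {
        if (t == "nonsense") "no_change" else "other"
    }
}

# ---- Scoring --------------------------------------------------------------

#' Construct an [ImpactScorer]
#'
#' @param mode `"surrogate"` (rescaled Grantham distance for missense) or
#'   `"external"` (per-substitution score table).
#' @param table data.frame `gene, substitution, score` for external mode; a
#'   path to such a TSV is also accepted.
#' @param isoformMode `"mean"` (default) or `"max"` aggregation across
#'   isoforms.
#' @param fallback in external mode, fall back to the surrogate for missing
#'   entries instead of erroring.
#' @return an [ImpactScorer].
#' @export
impactScorer <- function(mode = c("surrogate", "external"), table = NULL,
                         isoformMode = c("mean", "max"), fallback = FALSE) {
    mode <- match.arg(mode)
    isoformMode <- match.arg(isoformMode)
    if (is.character(table) && length(table) == 1L)
        table <- utils::read.table(table, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
    if (is.null(table))
        table <- data.frame(gene = character(), substitution = character(),
                            score = numeric(), stringsAsFactors = FALSE)
    new("ImpactScorer", mode = mode, table = table,
        isoformMode = isoformMode, fallback = fallback)
}

#' Score a substitution on the 0-100 impact scale
#'
#' Silent substitutions score 0 and stopgains 100 in every mode. Missense
#' substitutions are scored by the external table (keyed on gene and compact
#' substitution notation) or by the Grantham surrogate. When a variant
#' affects multiple isoforms, pass the per-isoform scores via
#' `isoformScores`; they are aggregated by the scorer's isoform mode
#' (arithmetic mean by default).
#'
#' @param sub a [Substitution].
#' @param scorer an [ImpactScorer].
#' @param isoformScores optional numeric vector of per-isoform scores to
#'   aggregate instead of scoring `sub` itself.
#' @return score in \[0, 100\].
#' @export
scoreSubstitution <- function(sub, scorer = impactScorer(),
                              isoformScores = NULL) {
    if (!is.null(isoformScores)) {
        if (!length(isoformScores))
            stop("empty 'isoformScores'")
        return(if (scorer@isoformMode == "max") max(isoformScores)
               else mean(isoformScores))
    }
    switch(sub@category,
        silent = 0,
        nonsense = 100,
        missense = {
            if (scorer@mode == "external") {
                key <- scorer@table$gene == sub@gene &
                       scorer@table$substitution == formatSubstitution(sub)
                if (any(key))
                    return(scorer@table$score[which(key)[1L]])
                if (!scorer@fallback)
                    stop("no external score for ", sub@gene, " ",
                         formatSubstitution(sub))
            }
            surrogateMissenseScore(sub@aaRef, sub@aaAlt)
        })
}

# ---- Enumeration over the 61 sense codons ---------------------------------

senseCodons <- function() {
    code <- Biostrings::GENETIC_CODE
    sort(names(code)[code != "*"])
}

#' Proportion of nonconservative outcomes for a codon
#'
#' Enumerates every distinct outcome of changing exactly `nChanges` of the
#' codon's three positions (each changed position can take 3 alternate
#' bases: 9, 27 and 27 outcomes for 1, 2 and 3 changes) and reports the
#' proportion that are nonconservative relative to the original residue.
#' Outcomes are unweighted counts; no mutation-spectrum weighting.
#'
#' @param codon one of the 61 sense codons.
#' @param nChanges number of positions changed, 0-3 (0 returns 0 by
#'   convention).
#' @param classes polarity classes from [aminoAcidClasses()].
#' @return `list(proportion, nNonconservative, nOutcomes)`.
#' @export
enumerateNonconservative <- function(codon, nChanges,
                                     classes = aminoAcidClasses()) {
    aaFrom <- translateCodon(codon)
    if (aaFrom == "*")
        stop("'", codon, "' is a stop codon; only sense codons are enumerated")
    if (nChanges == 0L)
        return(list(proportion = 0, nNonconservative = 0L, nOutcomes = 1L))
    bases <- c("A", "C", "G", "T")
    orig <- strsplit(codon, "")[[1]]
    posSets <- utils::combn(3L, nChanges, simplify = FALSE)
    nNc <- 0L; nTot <- 0L
    for (posSet in posSets) {
        altChoices <- lapply(posSet, function(p) setdiff(bases, orig[p]))
        grid <- expand.grid(altChoices, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grid))) {
            mut <- orig
            mut[posSet] <- unlist(grid[r, ], use.names = FALSE)
            nTot <- nTot + 1L
            if (isNonconservative(aaFrom,
                                  translateCodon(paste(mut, collapse = "")),
                                  classes))
                nNc <- nNc + 1L
        }
    }
    list(proportion = nNc / nTot, nNonconservative = nNc, nOutcomes = nTot)
}

#' Nonconservative-proportion table over the 61 sense codons
#'
#' For every sense codon, the proportion of nonconservative outcomes under
#' one, two or three nucleotide changes, plus the unweighted average of each
#' column across the 61 codons. More changes to a codon make a
#' nonconservative (nonsense or polarity-crossing) outcome more likely, which
#' is why joint germline+somatic codon changes tend to be more radical than
#' either alone.
#'
#' @param classes polarity classes from [aminoAcidClasses()].
#' @return `list(table = <61-row data.frame: codon, aa, p1, p2, p3>,
#'   averages = <named numeric length 3>)`.
#' @export
fig1bSummary <- function(classes = aminoAcidClasses()) {
    codons <- senseCodons()
    tab <- data.frame(
        codon = codons,
        aa = vapply(codons, translateCodon, ""),
        p1 = vapply(codons, function(cd)
            enumerateNonconservative(cd, 1L, classes)$proportion, 0),
        p2 = vapply(codons, function(cd)
            enumerateNonconservative(cd, 2L, classes)$proportion, 0),
        p3 = vapply(codons, function(cd)
            enumerateNonconservative(cd, 3L, classes)$proportion, 0),
        stringsAsFactors = FALSE, row.names = NULL)
    list(table = tab,
         averages = c(p1 = mean(tab$p1), p2 = mean(tab$p2), p3 = mean(tab$p3)))
}

# ---- Event annotation -----------------------------------------------------

formatGermline <- function(g) {
    paste(sprintf("%s>%s(%s)", g$ref, g$alt, g$genotype), collapse = ";")
}

#' Annotate confirmed events
#'
#' Turns cis-confirmed candidates into the 16-column event table: reported
#' and true substitutions (computed on the first affected transcript, in
#' sorted order), the change category, and impact scores averaged (or
#' maximized) across all affected isoforms.
#'
#' @param events confirmed events from [confirmEvents()].
#' @param transcripts named list of [CodingTranscript].
#' @param scorer an [ImpactScorer].
#' @param cancerTypes optional named character vector mapping patient ids to
#'   cancer types.
#' @return data.frame with the stable 16-column schema of
#'   [writeEventTable()].
#' @export
annotateEvents <- function(events, transcripts, scorer = impactScorer(),
                           cancerTypes = NULL) {
    rows <- lapply(events, function(ev) {
        txIds <- ev$transcripts
        perIso <- lapply(txIds, function(tid) {
            tx <- transcripts[[tid]]
            ctx <- ev$contexts[[tid]]
            rep <- reportedSubstitution(ctx, ev$somatic, tx)
            tru <- trueSubstitution(ctx, ev$germline, ev$somatic, ev$phase, tx)
            list(rep = rep, tru = tru,
                 repScore = scoreSubstitution(rep, scorer),
                 truScore = scoreSubstitution(tru, scorer))
        })
        primary <- perIso[[1L]]
        repScore <- scoreSubstitution(primary$rep, scorer,
            isoformScores = vapply(perIso, `[[`, 0, "repScore"))
        truScore <- scoreSubstitution(primary$tru, scorer,
            isoformScores = vapply(perIso, `[[`, 0, "truScore"))
        cancer <- if (!is.null(cancerTypes) &&
                      ev$patient_id %in% names(cancerTypes))
            cancerTypes[[ev$patient_id]] else NA_character_
        data.frame(
            patient = ev$patient_id,
            cancer_type = cancer,
            gene = transcripts[[txIds[1L]]]@gene,
            transcript = paste(txIds, collapse = ","),
            codon_index = ev$contexts[[txIds[1L]]]@codonIndex,
            n_positions_changed = length(unique(c(ev$germline$pos,
                                                  ev$somatic$pos))),
            germline = formatGermline(ev$germline),
            somatic_alleles = paste(sprintf("%s>%s", ev$somatic$ref,
                                            ev$somatic$alt), collapse = ";"),
            somatic_vaf = paste(ifelse(is.na(ev$somatic$vaf), "NA",
                                       sprintf("%.4f", ev$somatic$vaf)),
                                collapse = ";"),
            reported_substitution = formatSubstitution(primary$rep),
            true_substitution = formatSubstitution(primary$tru),
            change_category = classifyChange(primary$rep, primary$tru),
            reported_score = repScore,
            true_score = truScore,
            delta_score = truScore - repScore,
            phase_support_reads = ev$phase@nReadsCis,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(
        stats::setNames(data.frame(matrix(ncol = 16L, nrow = 0L)),
                        eventTableColumns()))))
    rownames(out) <- NULL
    coerceEventTypes(out)
}
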