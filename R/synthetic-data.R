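# Synthetic cohort generation: a toy exome with common coding SNPs (third-
# position biased, Hardy-Weinberg genotypes), cancer-type-like somatic
# burdens with a pyrimidine-biased spectrum, Beta-distributed tumor VAFs
# peaked near 0.3, haplotype-aware allele placement, and read evidence over
# candidate regions -- everything the detection pipeline consumes, plus a
# ground-truth table of planted co-occurrences.

#' Construct a [SimulationConfig]
#'
#' Defaults encode the cohort structure the analysis assumes: common SNPs
#' (Beta MAF model with mean 0.49), third-codon-position bias (weight 3, so
#' 60 percent of SNPs sit in the third position), per-patient somatic burden
#' Poisson(30) with a C>T/G>A-heavy spectrum, tumor VAF Beta(6, 14) peaked
#' at 0.3, a neutral phase model (cis probability 0.5 for heterozygous
#' sites; homozygous sites are cis by construction), and a 30x error-free-ish
#' read model.
#'
#' @param nPatients,nTranscripts,cdsCodons cohort and toy-exome size
#'   (`cdsCodons` includes the terminal stop codon).
#' @param snpDensity per-coding-site probability of a segregating SNP.
#' @param mafShape1,mafShape2 Beta parameters of the population MAF model.
#' @param thirdPosWeight relative SNP weight of the third codon position.
#' @param burdenMean mean somatic burden per patient.
#' @param ctBias probability a somatic call comes from the C>T/G>A channel.
#' @param vafMean,vafConcentration Beta VAF model.
#' @param cisProb cis placement probability at heterozygous sites.
#' @param depth,errorRate read model.
#' @param genotypeModel `"hw"` (Hardy-Weinberg) or `"het_only"` (every
#'   carrier heterozygous; used for phase-model calibration).
#' @param cancerType optional preset (`"BRCA"`, `"COAD"`, `"HNSC"`,
#'   `"SKCM"`) overriding `burdenMean` and `ctBias` with desk-scale relative
#'   rates.
#' @param seed mandatory RNG seed.
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(nPatients = 50L, nTranscripts = 20L,
                             cdsCodons = 120L, snpDensity = 0.02,
                             mafShape1 = 2, mafShape2 = 2 * 0.51 / 0.49,
                             thirdPosWeight = 3, burdenMean = 30,
                             ctBias = 0.7, vafMean = 0.3,
                             vafConcentration = 20, cisProb = 0.5,
                             depth = 30L, errorRate = 0.001,
                             genotypeModel = c("hw", "het_only"),
                             cancerType = NULL, seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    genotypeModel <- match.arg(genotypeModel)
    if (!is.null(cancerType)) {
        preset <- cancerTypePreset(cancerType)
        burdenMean <- preset$burdenMean
        ctBias <- preset$ctBias
    }
    cfg <- new("SimulationConfig", nPatients = as.integer(nPatients),
               nTranscripts = as.integer(nTranscripts),
               cdsCodons = as.integer(cdsCodons),
               snpDensity = snpDensity, mafShape1 = mafShape1,
               mafShape2 = mafShape2, thirdPosWeight = thirdPosWeight,
               burdenMean = burdenMean, ctBias = ctBias, vafMean = vafMean,
               vafConcentration = vafConcentration, cisProb = cisProb,
               depth = as.integer(depth), errorRate = errorRate,
               seed = as.integer(seed))
    attr(cfg, "genotypeModel") <- genotypeModel
    if (burdenMean > nTranscripts * cdsCodons * 3L)
        stop("'burdenMean' exceeds the number of coding positions")
    cfg
}

#' @rdname simulationConfig
#' @param type cancer-type preset name.
#' @export
cancerTypePreset <- function(type) {
    presets <- list(
        BRCA = list(burdenMean = 10, ctBias = 0.5),
        COAD = list(burdenMean = 30, ctBias = 0.6),
        HNSC = list(burdenMean = 40, ctBias = 0.7),
        SKCM = list(burdenMean = 100, ctBias = 0.85))
    if (!(type %in% names(presets)))
        stop("unknown cancer-type preset '", type, "'")
    presets[[type]]
}

# Sample a random CDS in coding orientation: sense codons + terminal stop.
randomCds <- function(nCodons) {
    sense <- senseCodons()
    stops <- c("TAA", "TAG", "TGA")
    paste0(paste(sample(sense, nCodons - 1L, replace = TRUE), collapse = ""),
           sample(stops, 1L))
}

# Lay transcripts head-to-tail on one contig with intergenic gaps;
# alternating strands exercise coding-orientation handling downstream.
buildToyExome <- function(nTranscripts, cdsCodons, gap = 50L) {
    bases <- c("A", "C", "G", "T")
    segs <- list()
    chars <- character(0)
    cursor <- 0L
    for (i in seq_len(nTranscripts)) {
        chars <- c(chars, sample(bases, gap, replace = TRUE))
        cursor <- cursor + gap
        cds <- randomCds(cdsCodons)
        strand <- if (i %% 2L == 1L) "+" else "-"
        genomic <- if (strand == "+") cds else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cds)))
        chars <- c(chars, strsplit(genomic, "")[[1]])
        segs[[i]] <- list(id = sprintf("T%03d", i),
                          gene = sprintf("G%03d", i),
                          start = cursor + 1L,
                          end = cursor + nchar(cds), strand = strand)
        cursor <- cursor + nchar(cds)
    }
    chars <- c(chars, sample(bases, gap, replace = TRUE))
    contig <- paste(chars, collapse = "")
    transcripts <- lapply(segs, function(s)
        new("CodingTranscript", transcriptId = s$id, gene = s$gene,
            chrom = "chrSim", strand = s$strand,
            cdsSegments = IRanges::IRanges(s$start, s$end),
            cdsSequence = spliceCds(Biostrings::DNAString(contig),
                                    IRanges::IRanges(s$start, s$end),
                                    s$strand)))
    names(transcripts) <- vapply(segs, `[[`, "", "id")
    list(contigChars = chars, contig = contig, transcripts = transcripts)
}

# Population SNP sites with third-position bias and Beta MAFs.
drawPopulationSnps <- function(exome, config) {
    rows <- list()
    for (tx in exome$transcripts) {
        pos <- codingPositions(tx)
        L <- length(pos)
        codonPos <- rep(1:3, length.out = L)
        # exclude the terminal stop codon from SNP placement
        usable <- seq_len(L - 3L)
        nSites <- stats::rbinom(1L, length(usable), config@snpDensity)
        if (nSites == 0L) next
        w <- c(1, 1, config@thirdPosWeight)[codonPos[usable]]
        sel <- sample(usable, nSites, prob = w)
        gpos <- pos[sel]
        ref <- exome$contigChars[gpos]
        rows[[tx@transcriptId]] <- data.frame(
            transcript = tx@transcriptId, pos = gpos, ref = ref,
            alt = randomOtherBase(ref, length(gpos)),
            codon_pos = codonPos[sel],
            maf = stats::rbeta(length(gpos), config@mafShape1,
                               config@mafShape2),
            stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, rows)
    if (is.null(snps))
        snps <- data.frame(transcript = character(), pos = integer(),
                           ref = character(), alt = character(),
                           codon_pos = integer(), maf = numeric())
    # one population allele per site: drop duplicated positions (overlap-free
    # toy layout makes these rare)
    snps[!duplicated(snps$pos), , drop = FALSE]
}

# Germline genotypes per patient: Hardy-Weinberg from MAF (or het-only
# carriers), haplotype of the alternate allele tracked for phasing truth.
drawGermline <- function(snps, patients, config, genotypeModel) {
    rows <- list()
    for (p in patients) {
        if (nrow(snps) == 0L) break
        if (genotypeModel == "het_only") {
            q <- snps$maf
            carrier <- stats::rbinom(nrow(snps), 1L, 1 - (1 - q)^2) == 1L
            copies <- ifelse(carrier, 1L, 0L)
        } else {
            copies <- stats::rbinom(nrow(snps), 2L, snps$maf)
        }
        keep <- which(copies > 0L)
        if (!length(keep)) next
        hap <- ifelse(copies[keep] == 2L, 0L,
                      sample(1:2, length(keep), replace = TRUE))
        rows[[p]] <- data.frame(
            patient_id = p, chrom = "chrSim", pos = snps$pos[keep],
            ref = snps$ref[keep], alt = snps$alt[keep],
            genotype = ifelse(copies[keep] == 2L, "hom_alt", "het"),
            maf = snps$maf[keep], hap = hap, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, list(data.frame(
        patient_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), genotype = character(),
        maf = numeric(), hap = integer()))))
    rownames(out) <- NULL
    out
}

# Somatic SNVs per patient: Poisson burden, C>T/G>A-biased spectrum,
# Beta VAFs, haplotype placement honoring cisProb near het germline sites.
drawSomatic <- function(exome, germline, patients, config) {
    codingPos <- sort(unlist(lapply(exome$transcripts, codingPositions)))
    refAt <- exome$contigChars
    ctSites <- codingPos[refAt[codingPos] %in% c("C", "G")]
    rows <- list()
    for (p in patients) {
        m <- stats::rpois(1L, config@burdenMean)
        if (m == 0L) next
        g <- germline[germline$patient_id == p, , drop = FALSE]
        taken <- g$pos
        posSel <- integer(0)
        alts <- character(0)
        guard <- 0L
        while (length(posSel) < m && guard < 50L) {
            guard <- guard + 1L
            need <- m - length(posSel)
            fromCt <- stats::rbinom(1L, need, config@ctBias)
            cand <- c(if (fromCt > 0L && length(ctSites))
                          sample(ctSites, min(fromCt, length(ctSites))),
                      sample(codingPos, need - min(fromCt, length(ctSites))))
            cand <- setdiff(unique(cand), c(taken, posSel))
            posSel <- c(posSel, cand)
        }
        posSel <- posSel[seq_len(min(m, length(posSel)))]
        if (!length(posSel)) next
        ref <- refAt[posSel]
        alt <- ifelse(ref == "C", "T", ifelse(ref == "G", "A",
                      randomOtherBase(ref, length(ref))))
        # non-CT channel sites keep a uniformly random alternate
        uniformAlt <- randomOtherBase(ref, length(ref))
        useCt <- ref %in% c("C", "G") &
                 stats::runif(length(ref)) < config@ctBias
        alt <- ifelse(useCt, alt, uniformAlt)
        hap <- vapply(posSel, function(sp) {
            near <- g[abs(g$pos - sp) <= 2L, , drop = FALSE]
            if (nrow(near) == 0L)
                return(sample(1:2, 1L))
            near <- near[order(abs(near$pos - sp)), , drop = FALSE]
            if (near$genotype[1L] == "hom_alt")
                return(sample(1:2, 1L))
            if (stats::runif(1L) < config@cisProb) near$hap[1L]
            else 3L - near$hap[1L]
        }, 0L)
        rows[[p]] <- data.frame(
            patient_id = p, chrom = "chrSim", pos = posSel, ref = ref,
            alt = alt,
            vaf = stats::rbeta(length(posSel),
                               config@vafMean * config@vafConcentration,
                               (1 - config@vafMean) * config@vafConcentration),
            filter = "PASS", hap = hap, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(rows, list(data.frame(
        patient_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), vaf = numeric(),
        filter = character(), hap = integer()))))
    rownames(out) <- NULL
    out
}

# A haplotype's base at a position, given the patient's phased variants.
haplotypeBase <- function(refBase, pos, hap, g, s) {
    gi <- which(g$pos == pos)
    if (length(gi) && (g$hap[gi[1L]] == 0L || g$hap[gi[1L]] == hap))
        return(g$alt[gi[1L]])
    si <- which(s$pos == pos)
    if (length(si) && s$hap[si[1L]] == hap)
        return(s$alt[si[1L]])
    refBase
}

# Reads over candidate regions: windows +/-3 nt around each somatic variant
# with a germline neighbour within 2 nt, merged per patient. Haplotypes
# alternate across reads (balanced coverage of both alleles); somatic
# variants are clonal on their haplotype in the read model, the VAF model
# lives in the VCF.
simulateReads <- function(exome, germline, somatic, config) {
    rows <- list()
    contigLen <- length(exome$contigChars)
    for (p in unique(somatic$patient_id)) {
        g <- germline[germline$patient_id == p, , drop = FALSE]
        s <- somatic[somatic$patient_id == p, , drop = FALSE]
        if (nrow(g) == 0L || nrow(s) == 0L) next
        near <- vapply(s$pos, function(sp)
            any(abs(g$pos - sp) >= 1L & abs(g$pos - sp) <= 2L), TRUE)
        if (!any(near)) next
        win <- IRanges::reduce(IRanges::IRanges(
            pmax(1L, s$pos[near] - 3L), pmin(contigLen, s$pos[near] + 3L)))
        rid <- 0L
        for (w in seq_along(win)) {
            posRange <- IRanges::start(win)[w]:IRanges::end(win)[w]
            haps <- rep_len(1:2, config@depth)
            for (r in seq_len(config@depth)) {
                rid <- rid + 1L
                bases <- vapply(posRange, function(pp)
                    haplotypeBase(exome$contigChars[pp], pp, haps[r], g, s),
                    "")
                if (config@errorRate > 0) {
                    err <- stats::runif(length(bases)) < config@errorRate
                    if (any(err))
                        bases[err] <- vapply(bases[err], randomOtherBase, "")
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    patient_id = p,
                    read_id = sprintf("%s_w%03d_r%04d", p, w, rid),
                    pos = posRange, base = bases, qual = 30,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, c(rows, list(data.frame(
        patient_id = character(), read_id = character(), pos = integer(),
        base = character(), qual = numeric()))))
    rownames(out) <- NULL
    out
}

# Ground truth: candidates as the pipeline defines them, phased from the
# haplotype bookkeeping rather than from reads.
buildTruth <- function(transcripts, germline, somatic) {
    cands <- findCandidates(germline, somatic, transcripts)
    rows <- lapply(cands, function(cand) {
        cis <- any(vapply(1:2, function(h) {
            gOk <- all(cand$germline$hap %in% c(0L, h))
            sOk <- all(cand$somatic$hap == h)
            gOk && sOk
        }, TRUE))
        phase <- if (cis) "cis" else "trans"
        tid <- cand$transcripts[1L]
        tx <- transcripts[[tid]]
        ctx <- cand$contexts[[tid]]
        call <- new("PhaseCall", verdict = phase, nReadsSpanning = 0L,
                    nReadsCis = 0L, nReadsTrans = 0L)
        rep <- reportedSubstitution(ctx, cand$somatic, tx)
        tru <- trueSubstitution(ctx, cand$germline, cand$somatic, call, tx)
        data.frame(
            patient_id = cand$patient_id, chrom = cand$chrom,
            transcript = tid, codon_index = ctx@codonIndex,
            codon_key = paste(sort(ctx@genomicPositions), collapse = "-"),
            n_germline = nrow(cand$germline), n_somatic = nrow(cand$somatic),
            phase = phase,
            reported_substitution = formatSubstitution(rep),
            true_substitution = formatSubstitution(tru),
            change_category = classifyChange(rep, tru),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(data.frame(
        patient_id = character(), chrom = character(), transcript = character(),
        codon_index = integer(), codon_key = character(),
        n_germline = integer(), n_somatic = integer(), phase = character(),
        reported_substitution = character(), true_substitution = character(),
        change_category = character()))))
    rownames(out) <- NULL
    out
}

#' Simulate a cohort
#'
#' Generates the full stated world of the analysis -- toy exome, population
#' SNPs, Hardy-Weinberg germline genotypes, somatic variants with spectrum
#' and VAF models, haplotype-aware allele placement, and read evidence over
#' every candidate region -- together with a ground-truth table of the
#' codon-level co-occurrences that were planted. Deterministic given
#' `config@seed`.
#'
#' @param config a [SimulationConfig].
#' @return a [SyntheticCohort].
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    genotypeModel <- attr(config, "genotypeModel")
    if (is.null(genotypeModel)) genotypeModel <- "hw"
    withSeed(config@seed, {
        exome <- buildToyExome(config@nTranscripts, config@cdsCodons)
        patients <- sprintf("P%04d", seq_len(config@nPatients))
        snps <- drawPopulationSnps(exome, config)
        germline <- drawGermline(snps, patients, config, genotypeModel)
        somatic <- drawSomatic(exome, germline, patients, config)
        reads <- simulateReads(exome, germline, somatic, config)
        truth <- buildTruth(exome$transcripts, germline, somatic)
        ref <- Biostrings::DNAStringSet(exome$contig)
        names(ref) <- "chrSim"
        new("SyntheticCohort", reference = ref,
            transcripts = exome$transcripts, germline = germline,
            somatic = somatic, reads = reads, truth = truth, config = config)
    })
}

# ---- planted events -------------------------------------------------------

# Brute-force search of the genetic code for a codon + (germline, somatic)
# single-base change pair realizing a requested annotation-change category.
realizeChange <- function(category) {
    bases <- c("A", "C", "G", "T")
    for (codon in senseCodons()) {
        orig <- strsplit(codon, "")[[1]]
        for (sp in 1:3) for (salt in setdiff(bases, orig[sp])) {
            repCodon <- orig; repCodon[sp] <- salt
            aaRef <- translateCodon(codon)
            repAa <- translateCodon(paste(repCodon, collapse = ""))
            for (gp in setdiff(1:3, sp)) {
                for (galt in setdiff(bases, orig[gp])) {
                    truCodon <- repCodon; truCodon[gp] <- galt
                    truAa <- translateCodon(paste(truCodon, collapse = ""))
                    rep <- makeSubstitution("g", "t", 1L, aaRef, repAa)
                    tru <- makeSubstitution("g", "t", 1L, aaRef, truAa)
                    if (classifyChange(rep, tru) == category)
                        return(list(codon = codon, somaticPos = sp,
                                    somaticAlt = salt, germlinePos = gp,
                                    germlineAlt = galt, aaRef = aaRef,
                                    reportedAa = repAa, trueAa = truAa))
                }
            }
        }
    }
    stop("no realization exists for category '", category, "'")
}

#' Plant co-occurrence events with requested annotation changes
#'
#' Builds a minimal cohort in which each requested event is realized by a
#' genetic-code search (guaranteeing detectability): one 9-codon transcript
#' per event with the engineered codon at index 5, a heterozygous germline
#' variant, a somatic variant placed in cis (or trans, per `phases`), and
#' balanced error-free reads at `depth`.
#'
#' @param nEvents number of events to plant.
#' @param changeMix named weights over annotation-change categories
#'   (`no_change`, `silent_to_missense`, `missense_to_missense`,
#'   `missense_to_nonsense`, ...).
#' @param phases `"cis"`/`"trans"`, recycled over events.
#' @param depth read depth per event.
#' @param seed RNG seed.
#' @return a [SyntheticCohort] (single patient `PL01`).
#' @export
plantEvents <- function(nEvents, changeMix = c(missense_to_missense = 1),
                        phases = "cis", depth = 30L, seed = 1L) {
    w <- changeMix / sum(changeMix)
    counts <- diff(c(0L, roundHalfUp(cumsum(w) * nEvents)))
    categories <- rep(names(changeMix), counts)
    phases <- rep_len(phases, nEvents)
    realizations <- lapply(unique(categories), realizeChange)
    names(realizations) <- unique(categories)
    withSeed(seed, {
        gap <- 20L
        chars <- character(0)
        cursor <- 0L
        transcripts <- list()
        germline <- list(); somatic <- list()
        bases <- c("A", "C", "G", "T")
        for (i in seq_len(nEvents)) {
            rz <- realizations[[categories[i]]]
            cds <- paste0(strrep("GCT", 4L), rz$codon, strrep("GCT", 3L),
                          "TAA")
            chars <- c(chars, sample(bases, gap, replace = TRUE))
            cursor <- cursor + gap
            start <- cursor + 1L
            chars <- c(chars, strsplit(cds, "")[[1]])
            cursor <- cursor + nchar(cds)
            tid <- sprintf("PT%03d", i)
            transcripts[[tid]] <- new("CodingTranscript",
                transcriptId = tid, gene = sprintf("PG%03d", i),
                chrom = "chrSim", strand = "+",
                cdsSegments = IRanges::IRanges(start, cursor),
                cdsSequence = Biostrings::DNAString(cds))
            codonStart <- start + 12L
            orig <- strsplit(rz$codon, "")[[1]]
            germline[[i]] <- data.frame(
                patient_id = "PL01", chrom = "chrSim",
                pos = codonStart + rz$germlinePos - 1L,
                ref = orig[rz$germlinePos], alt = rz$germlineAlt,
                genotype = "het", maf = 0.5, hap = 1L,
                stringsAsFactors = FALSE)
            somatic[[i]] <- data.frame(
                patient_id = "PL01", chrom = "chrSim",
                pos = codonStart + rz$somaticPos - 1L,
                ref = orig[rz$somaticPos], alt = rz$somaticAlt, vaf = 0.3,
                filter = "PASS",
                hap = if (phases[i] == "cis") 1L else 2L,
                stringsAsFactors = FALSE)
        }
        chars <- c(chars, sample(bases, gap, replace = TRUE))
        exome <- list(contigChars = chars, contig = paste(chars, collapse = ""),
                      transcripts = transcripts)
        germline <- do.call(rbind, germline)
        somatic <- do.call(rbind, somatic)
        config <- simulationConfig(nPatients = 1L, nTranscripts = nEvents,
                                   cdsCodons = 9L, burdenMean = 1,
                                   depth = depth, errorRate = 0, seed = seed)
        reads <- simulateReads(exome, germline, somatic, config)
        truth <- buildTruth(transcripts, germline, somatic)
        ref <- Biostrings::DNAStringSet(exome$contig)
        names(ref) <- "chrSim"
        new("SyntheticCohort", reference = ref, transcripts = transcripts,
            germline = germline, somatic = somatic, reads = reads,
            truth = truth, config = config)
    })
}

# ---- cohort writer --------------------------------------------------------

#' Write a synthetic cohort to a pipeline-ready directory
#'
#' Emits exactly the formats the detection pipeline consumes: `ref.fa`,
#' `cds.bed` (6-column CDS dialect), and per patient
#' `<id>.germline.vcf`, `<id>.somatic.vcf`, `<id>.reads.tsv`, plus
#' `truth.tsv`.
#'
#' @param cohort a [SyntheticCohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(cohort@reference, file.path(dir, "ref.fa"))
    bed <- do.call(rbind, lapply(cohort@transcripts, function(tx)
        data.frame(chrom = tx@chrom,
                   start = IRanges::start(tx@cdsSegments) - 1L,
                   end = IRanges::end(tx@cdsSegments),
                   name = paste(tx@transcriptId, tx@gene, sep = "|"),
                   frame = 0L, strand = tx@strand,
                   stringsAsFactors = FALSE)))
    utils::write.table(bed, file.path(dir, "cds.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    patients <- sprintf("P%04d", seq_len(cohort@config@nPatients))
    if (nrow(cohort@germline))
        patients <- union(unique(cohort@germline$patient_id), patients)
    for (p in patients) {
        g <- cohort@germline[cohort@germline$patient_id == p, , drop = FALSE]
        s <- cohort@somatic[cohort@somatic$patient_id == p, , drop = FALSE]
        r <- cohort@reads[cohort@reads$patient_id == p, , drop = FALSE]
        writeGermlineVcf(g, file.path(dir, paste0(p, ".germline.vcf")))
        writeSomaticVcf(s, file.path(dir, paste0(p, ".somatic.vcf")))
        utils::write.table(
            r[, c("read_id", "pos", "base", "qual")],
            file.path(dir, paste0(p, ".reads.tsv")), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = TRUE)
    }
    utils::write.table(cohort@truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
    invisible(dir)
}

# ---- synthetic stand-in for the published event supplement ----------------

#' Synthetic stand-in event table for the published supplement
#'
#' The original per-event supplementary table is a controlled external
#' download and is not redistributable here. This generator builds a
#' SYNTHETIC 392-event table whose cohort-level marginals match the printed
#' summary figures: 56.4 percent of events with a changed substitution
#' (111 missense-to-missense, 82 silent-to-missense, 9 stopgains, 19
#' missense-to-silent), six events changing all three codon bases, and a
#' 53 percent homozygous germline genotype split. Every substitution pair is
#' realized from the genetic code, so re-annotation arithmetic on the table
#' is internally consistent. It validates the cohort summarizers; it is not
#' the original data.
#'
#' @param seed RNG seed for the incidental fields (genes, residues, VAFs).
#' @return event data.frame in the [writeEventTable()] schema.
#' @export
syntheticS1Table <- function(seed = 1L) {
    nEvents <- 392L
    changed <- c(missense_to_missense = 111L, silent_to_missense = 82L,
                 missense_to_nonsense = 9L, missense_to_silent = 19L)
    nNoChange <- nEvents - sum(changed)   # 171
    categories <- c(rep(names(changed), changed),
                    rep("no_change", nNoChange))
    nHom <- 209L   # of 394 germline variants -> 53%
    withSeed(seed, {
        categories <- sample(categories)
        rz <- lapply(stats::setNames(nm = unique(categories)), realizeChange)
        residue <- sample(2:800, nEvents, replace = TRUE)
        # six three-base events: four with two somatic variants, two with
        # two germline variants; assign them to missense_to_missense rows
        mmRows <- which(categories == "missense_to_missense")
        threeBase <- mmRows[1:6]
        twoGermline <- threeBase[5:6]
        genotypes <- sample(c(rep("hom_alt", nHom),
                              rep("het", 394L - nHom)))
        gIdx <- 0L
        cancers <- sample(c("SKCM", "HNSC", "COAD", "BRCA"), nEvents,
                          replace = TRUE, prob = c(0.45, 0.3, 0.2, 0.05))
        rows <- lapply(seq_len(nEvents), function(i) {
            r <- rz[[categories[i]]]
            nGerm <- if (i %in% twoGermline) 2L else 1L
            geno <- genotypes[gIdx + seq_len(nGerm)]
            gIdx <<- gIdx + nGerm
            orig <- strsplit(r$codon, "")[[1]]
            germStr <- paste(sprintf("%s>%s(%s)",
                                     orig[r$germlinePos], r$germlineAlt,
                                     geno), collapse = ";")
            nSom <- if (i %in% setdiff(threeBase, twoGermline)) 2L else 1L
            somStr <- paste(rep(sprintf("%s>%s", orig[r$somaticPos],
                                        r$somaticAlt), nSom), collapse = ";")
            nPos <- if (i %in% threeBase) 3L else 2L
            rep <- makeSubstitution("x", "x", residue[i], r$aaRef,
                                    r$reportedAa)
            tru <- makeSubstitution("x", "x", residue[i], r$aaRef, r$trueAa)
            repScore <- scoreSubstitution(rep)
            truScore <- scoreSubstitution(tru)
            data.frame(
                patient = sprintf("SP%04d", i),
                cancer_type = cancers[i],
                gene = sprintf("SG%04d", i),
                transcript = sprintf("ST%04d", i),
                codon_index = residue[i],
                n_positions_changed = nPos,
                germline = germStr,
                somatic_alleles = somStr,
                somatic_vaf = sprintf("%.4f", stats::rbeta(1L, 6, 14)),
                reported_substitution = formatSubstitution(rep),
                true_substitution = formatSubstitution(tru),
                change_category = categories[i],
                reported_score = repScore,
                true_score = truScore,
                delta_score = truScore - repScore,
                phase_support_reads = sample(4:40, 1L),
                stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        out
    })
}
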