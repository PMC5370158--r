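# End-to-end orchestration: detection over a per-patient file layout (or an
# in-memory cohort), cohort summaries, the stats battery, and report writers.

#' Detect and annotate co-occurrence events in memory
#'
#' The core detection pass: candidate discovery, read-backed phasing,
#' cis-confirmation and annotation, plus per-patient counts.
#'
#' @param transcripts named list of [CodingTranscript].
#' @param germline,somatic cohort variant data.frames.
#' @param reads phase evidence data.frame (`patient_id, read_id, pos, base,
#'   qual`).
#' @param minSupport,minBaseq,window detection parameters (defaults 2, 20, 2).
#' @param scorer an [ImpactScorer].
#' @param cancerTypes optional named vector patient -> cancer type.
#' @return list with `events` (annotated data.frame), `confirmed` (raw
#'   confirmed candidates), `candidates`, `controls`, `counts`, and
#'   `perPatient` (burden, candidate/cis/trans/ambiguous/event counts).
#' @export
detectEvents <- function(transcripts, germline, somatic, reads,
                         minSupport = 2L, minBaseq = 20, window = 2L,
                         scorer = impactScorer(), cancerTypes = NULL) {
    candidates <- findCandidates(germline, somatic, transcripts, window)
    controls <- findAdjacentControls(germline, somatic, transcripts, window)
    confirmed <- confirmEvents(candidates, reads, minSupport, minBaseq)
    events <- annotateEvents(confirmed$events, transcripts, scorer,
                             cancerTypes)
    patients <- sort(unique(c(germline$patient_id, somatic$patient_id)))
    verdicts <- vapply(confirmed$phases, verdict, "")
    candPatients <- vapply(candidates, `[[`, "", "patient_id")
    perPatient <- do.call(rbind, lapply(patients, function(p) {
        idx <- candPatients == p
        data.frame(
            patient = p,
            burden = sum(somatic$patient_id == p),
            n_candidates = sum(idx),
            n_cis = sum(idx & verdicts == "cis"),
            n_trans = sum(idx & verdicts == "trans"),
            n_ambiguous = sum(idx & verdicts == "ambiguous"),
            n_events = sum(events$patient == p),
            stringsAsFactors = FALSE)
    }))
    fractionPatients <- if (length(patients))
        mean(perPatient$n_events > 0) else NA_real_
    nSomaticInEvents <- sum(vapply(confirmed$events, function(ev)
        nrow(ev$somatic), 0L))
    list(events = events, confirmed = confirmed$events,
         candidates = candidates, controls = controls,
         counts = c(confirmed$counts,
                    fraction_patients_with_event = fractionPatients,
                    fraction_somatic_in_events =
                        if (nrow(somatic)) nSomaticInEvents / nrow(somatic)
                        else NA_real_),
         perPatient = perPatient)
}

#' Run detection over a per-patient directory
#'
#' Expects `ref.fa` plus a CDS annotation (`cds.bed`, `cds.gff3` or
#' `annotation` argument) and, per patient, `<id>.germline.vcf`,
#' `<id>.somatic.vcf` and `<id>.reads.tsv` (pileup) or `<id>.reads.sam`.
#' Patients with a germline file but no somatic file are skipped with a
#' warning. When `out` is given, the annotated event table is written there
#' with a provenance header.
#'
#' @param dir cohort directory.
#' @param annotation optional explicit annotation path.
#' @param out optional output TSV path for the event table.
#' @param seed recorded in output provenance.
#' @inheritParams detectEvents
#' @return as [detectEvents()].
#' @export
runDetect <- function(dir, annotation = NULL, minSupport = 2L, minBaseq = 20,
                      window = 2L, scorer = impactScorer(),
                      cancerTypes = NULL, out = NULL, seed = NA_integer_) {
    fasta <- file.path(dir, "ref.fa")
    if (!file.exists(fasta))
        stop("no reference 'ref.fa' in ", dir)
    if (is.null(annotation)) {
        for (cand in c("cds.bed", "cds.gff3", "cds.gtf")) {
            if (file.exists(file.path(dir, cand))) {
                annotation <- file.path(dir, cand)
                break
            }
        }
    }
    if (is.null(annotation))
        stop("no CDS annotation found in ", dir)
    transcripts <- loadTranscripts(fasta, annotation)
    gFiles <- list.files(dir, pattern = "\\.germline\\.vcf$")
    patients <- sub("\\.germline\\.vcf$", "", gFiles)
    germline <- list(); somatic <- list(); reads <- list()
    for (p in patients) {
        sFile <- file.path(dir, paste0(p, ".somatic.vcf"))
        if (!file.exists(sFile)) {
            warning("patient '", p, "' has germline but no somatic calls; ",
                    "skipped", call. = FALSE)
            next
        }
        germline[[p]] <- readGermlineVcf(
            file.path(dir, paste0(p, ".germline.vcf")), p)
        somatic[[p]] <- readSomaticVcf(sFile, p)
        pileup <- file.path(dir, paste0(p, ".reads.tsv"))
        sam <- file.path(dir, paste0(p, ".reads.sam"))
        if (file.exists(pileup)) {
            ev <- readPileup(pileup)
            if (nrow(ev)) {
                ev$patient_id <- p
                reads[[p]] <- ev
            }
        } else if (file.exists(sam)) {
            cand <- findCandidates(germline[[p]], somatic[[p]], transcripts,
                                   window)
            pos <- sort(unique(unlist(lapply(cand, function(cd)
                c(cd$germline$pos, cd$somatic$pos)))))
            if (length(pos)) {
                ev <- readSamEvidence(sam, cand[[1L]]$chrom, pos)
                ev$patient_id <- p
                reads[[p]] <- ev
            }
        }
    }
    bindOr <- function(lst, empty) if (length(lst)) do.call(rbind, c(lst,
        list(empty))) else empty
    germline <- bindOr(germline, emptyGermline(""))
    somatic <- bindOr(somatic, emptySomatic())
    reads <- bindOr(reads, data.frame(read_id = character(), pos = integer(),
                                      base = character(), qual = numeric(),
                                      patient_id = character()))
    res <- detectEvents(transcripts, germline, somatic, reads, minSupport,
                        minBaseq, window, scorer, cancerTypes)
    if (!is.null(out))
        writeEventTable(res$events, out, seed = seed,
                        inputs = c(fasta, annotation))
    res
}

# ---- cohort summaries -----------------------------------------------------

#' Summarize an event table
#'
#' Cohort-level marginals recomputed from a confirmed-event table: event
#' count, fraction with a changed substitution, events changing all three
#' codon bases, and the germline genotype split (over germline variants, not
#' events).
#'
#' @param events event data.frame in the [writeEventTable()] schema.
#' @return list with `nEvents`, `fractionChanged`, `nThreeBase`,
#'   `genotypeCounts` (hom/het), `homFraction`, `changeBreakdown`.
#' @export
summarizeEventTable <- function(events) {
    genos <- unlist(strsplit(events$germline, ";", fixed = TRUE))
    nHom <- sum(grepl("(hom_alt)", genos, fixed = TRUE))
    nHet <- sum(grepl("(het)", genos, fixed = TRUE))
    list(nEvents = nrow(events),
         fractionChanged = if (nrow(events))
             mean(events$change_category != "no_change") else NA_real_,
         nThreeBase = sum(events$n_positions_changed == 3L),
         genotypeCounts = c(hom = nHom, het = nHet),
         homFraction = if (nHom + nHet > 0) nHom / (nHom + nHet)
                       else NA_real_,
         changeBreakdown = table(events$change_category))
}

#' Codon-position frequencies of germline variants
#'
#' Fraction of germline coding variants at each codon position, mapped
#' through the first transcript containing each variant.
#'
#' @param germline germline variant data.frame.
#' @param transcripts named list of [CodingTranscript].
#' @return length-3 frequency vector (sums to 1).
#' @export
germlineCodonPositionFreqs <- function(germline, transcripts) {
    counts <- c(0, 0, 0)
    for (i in seq_len(nrow(germline))) {
        for (tx in transcripts) {
            if (tx@chrom != germline$chrom[i]) next
            m <- mapGenomicToCodon(tx, germline$pos[i])
            if (!is.null(m)) {
                counts[m$codonPos] <- counts[m$codonPos] + 1
                break
            }
        }
    }
    if (sum(counts) == 0) stop("no coding germline variants")
    counts / sum(counts)
}

#' Ordered codon-position pair counts of candidate events
#'
#' For candidates composed of one germline and one somatic variant, counts
#' the ordered (germline position, somatic position) pairs in the order
#' `1>2, 1>3, 2>1, 2>3, 3>1, 3>2` (primary transcript frame).
#'
#' @param candidates list of `CandidateEvent`.
#' @param transcripts named list of [CodingTranscript].
#' @return named length-6 integer vector.
#' @export
candidateCodonPairCounts <- function(candidates, transcripts) {
    counts <- stats::setNames(rep(0L, 6L), codonPairLabels())
    for (cand in candidates) {
        if (nrow(cand$germline) != 1L || nrow(cand$somatic) != 1L) next
        tx <- transcripts[[cand$transcripts[1L]]]
        gp <- mapGenomicToCodon(tx, cand$germline$pos)$codonPos
        sp <- mapGenomicToCodon(tx, cand$somatic$pos)$codonPos
        if (gp == sp) next
        lab <- paste0(gp, ">", sp)
        counts[lab] <- counts[lab] + 1L
    }
    counts
}

#' Run the cohort statistics battery
#'
#' Runs every test the supplied inputs permit and records a reason for every
#' test skipped for lack of inputs or data. All stochastic components are
#' driven by `seed`.
#'
#' @param detect result of [detectEvents()]/[runDetect()], or a list with at
#'   least `events` and `perPatient`.
#' @param mafPool optional population MAF pool for the resampling null.
#' @param backgroundAaFreqs optional named background amino-acid frequencies.
#' @param cosmicGenes,universeGenes optional gene lists for enrichment.
#' @param vafOther optional VAFs of somatic variants *not* in events, for the
#'   VAF comparison.
#' @param transcripts transcripts (needed for codon-position expectations).
#' @param nDraws resampling draws for the MAF null.
#' @param seed RNG seed.
#' @return `list(results = named list of [NullModelResult], tables = named
#'   list of data.frames, skipped = named character vector of reasons)`.
#' @export
runStats <- function(detect, transcripts = NULL, mafPool = NULL,
                     backgroundAaFreqs = NULL, cosmicGenes = NULL,
                     universeGenes = NULL, vafOther = NULL, nDraws = 1000L,
                     seed = 1L) {
    events <- detect$events
    results <- list(); tables <- list(); skipped <- character()
    counts <- detect$counts

    # cis/trans selection vs genotype expectation
    germGenos <- unlist(strsplit(events$germline, ";", fixed = TRUE))
    nHom <- sum(grepl("(hom_alt)", germGenos, fixed = TRUE))
    nHet <- sum(grepl("(het)", germGenos, fixed = TRUE))
    nCis <- unname(counts["n_cis"]); nTrans <- unname(counts["n_trans"])
    if (!is.na(nCis) && nCis + nTrans > 0 && nHom + nHet > 0) {
        ef <- expectedCisFraction(nHom, nHet)
        results$cis_trans <- cisTransSelectionTest(nCis, nTrans, ef)
    } else {
        skipped["cis_trans"] <- "no phased candidates or no genotypes"
    }

    # codon-position pair expectation (conditioned + naive)
    if (!is.null(transcripts) && length(detect$candidates)) {
        freqs <- try(germlineCodonPositionFreqs(
            do.call(rbind, lapply(detect$candidates, `[[`, "germline")),
            transcripts), silent = TRUE)
        pairCounts <- candidateCodonPairCounts(detect$candidates, transcripts)
        if (!inherits(freqs, "try-error") && sum(pairCounts) > 0) {
            cpe <- codonPositionExpectation(freqs, pairCounts)
            results$codon_pair_conditioned <- cpe$conditioned
            results$codon_pair_naive <- cpe$naiveTest
        } else {
            skipped["codon_pair"] <- "no 1+1 candidate pairs"
        }
    } else {
        skipped["codon_pair"] <- "transcripts or candidates unavailable"
    }

    # MAF resampling null
    if (!is.null(mafPool) && !is.null(detect$confirmed) &&
        length(detect$confirmed)) {
        obsMafs <- unlist(lapply(detect$confirmed, function(ev)
            ev$germline$maf))
        obsMafs <- obsMafs[!is.na(obsMafs)]
        if (length(obsMafs) >= 2L && length(mafPool) > length(obsMafs)) {
            results$maf_null <- mafNullTest(obsMafs, mafPool, nDraws, seed)
        } else {
            skipped["maf_null"] <- "too few observed MAFs or pool too small"
        }
    } else {
        skipped["maf_null"] <- "no MAF pool supplied"
    }

    # amino-acid representation
    if (!is.null(backgroundAaFreqs) && nrow(events)) {
        aaCounts <- table(substr(events$reported_substitution, 1L, 1L))
        art <- aaRepresentationTest(
            stats::setNames(as.integer(aaCounts), names(aaCounts)),
            backgroundAaFreqs)
        results$aa_representation <- art$correlation
        tables$aa_proportions <- art$perAa
    } else {
        skipped["aa_representation"] <- "no background frequencies or no events"
    }

    # burden-event correlation
    pp <- detect$perPatient
    if (!is.null(pp) && nrow(pp) >= 3L && stats::sd(pp$burden) > 0 &&
        stats::sd(pp$n_events) > 0) {
        bec <- burdenEventCorrelation(pp$burden, pp$n_events)
        results$burden_event <- bec$overall
    } else {
        skipped["burden_event"] <- "fewer than 3 patients or constant counts"
    }

    # cancer-gene enrichment
    if (!is.null(cosmicGenes) && !is.null(universeGenes) && nrow(events)) {
        results$cosmic <- cosmicEnrichment(unique(events$gene), cosmicGenes,
                                           universeGenes)
    } else {
        skipped["cosmic"] <- "no gene lists or no events"
    }

    # paired impact shift
    if (nrow(events) >= 6L) {
        results$paired_impact <- pairedImpactTest(events$reported_score,
                                                  events$true_score)
    } else {
        skipped["paired_impact"] <- "fewer than 6 events"
    }

    # VAF comparison
    eventVafs <- suppressWarnings(as.numeric(unlist(
        strsplit(events$somatic_vaf, ";", fixed = TRUE))))
    eventVafs <- eventVafs[!is.na(eventVafs)]
    if (!is.null(vafOther) && length(eventVafs) >= 2L &&
        length(vafOther) >= 2L) {
        results$vaf_comparison <- vafComparison(eventVafs, vafOther)
    } else {
        skipped["vaf_comparison"] <- "need >= 2 VAFs in each group"
    }

    results <- results[!vapply(results, is.null, TRUE)]
    list(results = results, tables = tables, skipped = skipped)
}

#' Write the stats report
#'
#' One JSON and one TSV record per executed test (model inputs, statistic,
#' p-value, seed) plus the skip reasons.
#'
#' @param stats result of [runStats()].
#' @param jsonPath,tsvPath output paths (either may be `NULL`).
#' @return invisibly, the report as a data.frame.
#' @export
writeStatsReport <- function(stats, jsonPath = NULL, tsvPath = NULL) {
    rows <- lapply(stats$results, function(r)
        data.frame(model = r@modelName, method = r@method,
                   statistic = r@statistic, p_value = r@pValue, n = r@n,
                   seed = r@seed, stringsAsFactors = FALSE))
    report <- do.call(rbind, c(rows, list(data.frame(
        model = character(), method = character(), statistic = numeric(),
        p_value = numeric(), n = integer(), seed = integer()))))
    rownames(report) <- NULL
    if (!is.null(tsvPath))
        utils::write.table(report, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    if (!is.null(jsonPath)) {
        payload <- list(
            tests = lapply(stats$results, function(r) list(
                model = r@modelName, method = r@method,
                observed = as.list(r@observed), expected = as.list(r@expected),
                statistic = r@statistic, p_value = r@pValue, n = r@n,
                seed = if (is.na(r@seed)) NULL else r@seed,
                extra = r@extra[!vapply(r@extra, is.null, TRUE)])),
            skipped = as.list(stats$skipped))
        jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    }
    invisible(report)
}

#' Nonconservative-proportion table runner
#'
#' Delegates to [fig1bSummary()] and optionally writes the 61-row table with
#' a footer row of column averages.
#'
#' @param out optional TSV path.
#' @return as [fig1bSummary()].
#' @export
runFig1b <- function(out = NULL) {
    fb <- fig1bSummary()
    if (!is.null(out)) {
        con <- file(out, "w")
        on.exit(close(con))
        writeLines(paste(c("codon", "aa", "p1", "p2", "p3"),
                         collapse = "\t"), con)
        utils::write.table(fb$table, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        writeLines(sprintf("average\t-\t%.6f\t%.6f\t%.6f",
                           fb$averages["p1"], fb$averages["p2"],
                           fb$averages["p3"]), con)
    }
    fb
}
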