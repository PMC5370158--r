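# Per-patient variant IO: germline/somatic VCF readers (SNV-only,
# multi-allelic decomposition), event-table writer/reader, and the minimal
# VCF emitters used by the simulator.

eventTableColumns <- function() {
    c("patient", "cancer_type", "gene", "transcript", "codon_index",
      "n_positions_changed", "germline", "somatic_alleles", "somatic_vaf",
      "reported_substitution", "true_substitution", "change_category",
      "reported_score", "true_score", "delta_score", "phase_support_reads")
}

isSnv <- function(ref, alt) {
    nchar(ref) == 1L && nchar(alt) == 1L &&
        ref %in% c("A", "C", "G", "T") && alt %in% c("A", "C", "G", "T") &&
        ref != alt
}

# Split "0/1", "1|2", ... into integer allele indices; NA when missing.
gtAlleles <- function(gt) {
    if (is.na(gt) || gt %in% c(".", "./.", ".|."))
        return(NULL)
    a <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
    if (any(is.na(a))) NULL else a
}

#' Read a per-patient germline VCF
#'
#' Reads SNV germline calls with genotypes. Multi-allelic records are
#' decomposed into per-allele SNVs; a genotype carrying one copy of the
#' allele is `het`, two copies `hom_alt`, zero copies is dropped. Indels and
#' MNVs are skipped and counted. Population minor allele frequency is taken
#' from the `MAF` (else `AF`) INFO field when present.
#'
#' @param path VCF 4.x file.
#' @param patientId patient identifier attached to every variant (patient
#'   identity is supplied externally, file-per-patient).
#' @return data.frame with columns `patient_id, chrom, pos, ref, alt,
#'   genotype, maf`; attribute `"skipped"` counts skipped records by reason.
#' @export
readGermlineVcf <- function(path, patientId) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt))
        stop("germline VCF '", path, "' has no GT FORMAT field")
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(rr$REF)
    alts <- rr$ALT
    info <- VariantAnnotation::info(vcf)
    mafInfo <- if ("MAF" %in% names(info)) info$MAF
               else if ("AF" %in% names(info)) info$AF else NULL
    skipped <- c(indel = 0L, missing_gt = 0L, absent_allele = 0L)
    rows <- vector("list", length(rr))
    for (i in seq_along(rr)) {
        alleles <- gtAlleles(gt[i, 1L])
        altSeq <- as.character(alts[[i]])
        if (is.null(alleles)) {
            skipped["missing_gt"] <- skipped["missing_gt"] + 1L
            warning("record ", i, " in '", basename(path),
                    "': missing GT, skipped", call. = FALSE)
            next
        }
        recRows <- list()
        for (k in seq_along(altSeq)) {
            if (!isSnv(refs[i], altSeq[k])) {
                skipped["indel"] <- skipped["indel"] + 1L
                next
            }
            copies <- sum(alleles == k)
            if (copies == 0L) {
                skipped["absent_allele"] <- skipped["absent_allele"] + 1L
                next
            }
            maf <- NA_real_
            if (!is.null(mafInfo)) {
                m <- mafInfo[[i]]
                if (length(m) >= k && !is.na(m[k])) maf <- as.numeric(m[k])
            }
            recRows[[length(recRows) + 1L]] <- data.frame(
                patient_id = patientId,
                chrom = as.character(GenomicRanges::seqnames(rr))[i],
                pos = GenomicRanges::start(rr)[i],
                ref = refs[i], alt = altSeq[k],
                genotype = if (copies >= 2L) "hom_alt" else "het",
                maf = maf, stringsAsFactors = FALSE)
        }
        if (length(recRows))
            rows[[i]] <- do.call(rbind, recRows)
    }
    out <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                            list(emptyGermline(patientId))))
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

emptyGermline <- function(patientId) {
    data.frame(patient_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), genotype = character(),
               maf = numeric(), stringsAsFactors = FALSE)
}

emptySomatic <- function() {
    data.frame(patient_id = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), vaf = numeric(),
               filter = character(), stringsAsFactors = FALSE)
}

#' Read a per-patient somatic VCF
#'
#' Retains PASS SNVs only. Tumor variant allele fraction is taken, in fixed
#' precedence, from the tumor sample's `AF` FORMAT field when present, else
#' derived from `AD` as alt/(ref+alt), else left missing. The tumor sample
#' column is the one named `TUMOR` (case-insensitive) when present, else the
#' sole sample, else the first sample with a warning.
#'
#' @param path VCF 4.x file.
#' @param patientId patient identifier.
#' @return data.frame with columns `patient_id, chrom, pos, ref, alt, vaf,
#'   filter`; attributes `"skipped"` (counters) and `"vafSource"`.
#' @export
readSomaticVcf <- function(path, patientId) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    rr <- SummarizedExperiment::rowRanges(vcf)
    refs <- as.character(rr$REF)
    alts <- rr$ALT
    filt <- VariantAnnotation::fixed(vcf)$FILTER
    g <- VariantAnnotation::geno(vcf)
    samples <- colnames(vcf)
    sampleIdx <- NA_integer_
    if (length(samples)) {
        hit <- which(toupper(samples) == "TUMOR")
        sampleIdx <- if (length(hit)) hit[1L]
            else if (length(samples) == 1L) 1L
            else { warning("multiple samples in '", basename(path),
                           "', none named TUMOR; using first", call. = FALSE)
                   1L }
    }
    afMat <- if ("AF" %in% names(g)) g$AF else NULL
    adMat <- if ("AD" %in% names(g)) g$AD else NULL
    vafSource <- if (!is.null(afMat)) "AF"
                 else if (!is.null(adMat)) "AD" else "missing"
    skipped <- c(not_pass = 0L, indel = 0L)
    rows <- list()
    for (i in seq_along(rr)) {
        if (is.na(filt[i]) || filt[i] != "PASS") {
            skipped["not_pass"] <- skipped["not_pass"] + 1L
            next
        }
        altSeq <- as.character(alts[[i]])
        for (k in seq_along(altSeq)) {
            if (!isSnv(refs[i], altSeq[k])) {
                skipped["indel"] <- skipped["indel"] + 1L
                next
            }
            vaf <- NA_real_
            if (!is.na(sampleIdx)) {
                if (!is.null(afMat)) {
                    af <- afMat[i, sampleIdx][[1L]]
                    if (length(af) >= k && !is.na(af[k]))
                        vaf <- as.numeric(af[k])
                }
                if (is.na(vaf) && !is.null(adMat)) {
                    ad <- adMat[i, sampleIdx][[1L]]
                    if (length(ad) >= k + 1L && !anyNA(ad[c(1L, k + 1L)]) &&
                        sum(ad[c(1L, k + 1L)]) > 0)
                        vaf <- ad[k + 1L] / (ad[1L] + ad[k + 1L])
                }
            } else if (vafSource == "AD") {
                warning("no tumor sample column in '", basename(path),
                        "'; VAF set to missing", call. = FALSE)
            }
            rows[[length(rows) + 1L]] <- data.frame(
                patient_id = patientId,
                chrom = as.character(GenomicRanges::seqnames(rr))[i],
                pos = GenomicRanges::start(rr)[i],
                ref = refs[i], alt = altSeq[k], vaf = vaf,
                filter = filt[i], stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, c(rows, list(emptySomatic())))
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    attr(out, "vafSource") <- vafSource
    out
}

provenanceHeader <- function(seed = NA_integer_, inputs = character()) {
    c(sprintf("#tool=codoncooc"),
      sprintf("#version=%s",
              as.character(utils::packageVersion("codoncooc"))),
      sprintf("#inputs=%s",
              if (length(inputs)) paste(inputs, collapse = ",") else "."),
      sprintf("#seed=%s", if (is.na(seed)) "." else as.character(seed)))
}

#' Write the confirmed-event table
#'
#' Writes one row per confirmed, annotated co-occurrence event as TSV with a
#' provenance header (`#tool`, `#version`, `#inputs`, `#seed`) and a
#' `#`-prefixed column-header line. Column order is stable (16 columns).
#'
#' @param events annotated event data.frame (see [annotateEvents()]).
#' @param path output path.
#' @param seed,inputs recorded in the provenance header.
#' @return `path`, invisibly.
#' @seealso [readEventTable()]
#' @export
writeEventTable <- function(events, path, seed = NA_integer_,
                            inputs = character()) {
    cols <- eventTableColumns()
    if (nrow(events) && !all(cols %in% names(events)))
        stop("event table missing columns: ",
             paste(setdiff(cols, names(events)), collapse = ", "))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(provenanceHeader(seed, inputs), con)
    writeLines(paste0("#", paste(cols, collapse = "\t")), con)
    if (nrow(events)) {
        body <- events[, cols, drop = FALSE]
        utils::write.table(body, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE, na = "NA")
    }
    invisible(path)
}

#' Read an event table written by [writeEventTable()]
#'
#' @param path TSV path.
#' @return data.frame with the 16 event columns.
#' @export
readEventTable <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#[a-z_]+\t", lines, value = TRUE)
    if (!length(hdr))
        stop("'", path, "' has no event-table column header")
    cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1]]
    body <- lines[!startsWith(lines, "#")]
    if (!length(body)) {
        out <- as.data.frame(stats::setNames(
            replicate(length(cols), character(), simplify = FALSE), cols),
            stringsAsFactors = FALSE)
        return(coerceEventTypes(out))
    }
    out <- utils::read.table(text = body, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = "character")
    names(out) <- cols
    coerceEventTypes(out)
}

coerceEventTypes <- function(df) {
    for (col in c("codon_index", "n_positions_changed", "phase_support_reads"))
        if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
    for (col in c("reported_score", "true_score", "delta_score"))
        if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    df
}

# --- minimal VCF emitters (simulator output; consumed back via readVcf) ----

vcfHeaderLines <- function(formatIds, sample) {
    defs <- c(
        GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        AF = "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">")
    c("##fileformat=VCFv4.2",
      "##source=codoncooc-simulator",
      "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"Population minor allele frequency\">",
      unname(defs[formatIds]),
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", sample), collapse = "\t"))
}

writeGermlineVcf <- function(variants, path, sample = "NORMAL") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(vcfHeaderLines("GT", sample), con)
    if (nrow(variants)) {
        variants <- variants[order(variants$chrom, variants$pos), ,
                             drop = FALSE]
        gt <- ifelse(variants$genotype == "hom_alt", "1/1", "0/1")
        info <- ifelse(is.na(variants$maf), ".",
                       sprintf("MAF=%.4f", variants$maf))
        writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                         variants$alt, ".", "PASS", info, "GT", gt,
                         sep = "\t"), con)
    }
    invisible(path)
}

writeSomaticVcf <- function(variants, path, sample = "TUMOR", depth = 50L) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(vcfHeaderLines(c("GT", "AD", "AF"), sample), con)
    if (nrow(variants)) {
        variants <- variants[order(variants$chrom, variants$pos), ,
                             drop = FALSE]
        vaf <- ifelse(is.na(variants$vaf), 0.5, variants$vaf)
        altDp <- round(vaf * depth)
        fmt <- sprintf("0/1:%d,%d:%.4f", depth - altDp, altDp, vaf)
        writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                         variants$alt, ".", variants$filter, ".", "GT:AD:AF",
                         fmt, sep = "\t"), con)
    }
    invisible(path)
}
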