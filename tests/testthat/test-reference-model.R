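test_that("codon translation follows the standard genetic code", {
    expect_identical(translateCodon("ATG"), "M")
    expect_identical(translateCodon("TAA"), "*")
    expect_identical(translateCodon("GTA"), "V")
    expect_identical(translateCodon("atg"), "M")
    expect_error(translateCodon("ANG"), "invalid codon")
    expect_error(translateCodon("AT"), "3-letter")
})

test_that("genomic-to-codon mapping handles strand, frame and splicing", {
    txPlus <- makeTx(seqGenomic = "ATGGTTAAA", starts = 101L)
    m <- mapGenomicToCodon(txPlus, 101L)
    expect_identical(codonIndex(m$context), 1L)
    expect_identical(m$codonPos, 1L)
    m <- mapGenomicToCodon(txPlus, 106L)   # coding offset 6 -> codon 2, pos 3
    expect_identical(codonIndex(m$context), 2L)
    expect_identical(m$codonPos, 3L)
    expect_identical(refCodon(m$context), "GTT")
    expect_null(mapGenomicToCodon(txPlus, 100L))
    expect_null(mapGenomicToCodon(txPlus, 110L))

    # minus strand: coding direction runs high -> low
    txMinus <- makeTx(strand = "-", starts = 101L, seqGenomic = "ATGGTTAAA")
    m <- mapGenomicToCodon(txMinus, 109L)
    expect_identical(codonIndex(m$context), 1L)
    expect_identical(m$codonPos, 1L)
    expect_identical(genomicPositions(m$context), c(109L, 108L, 107L))

    # spliced CDS: two segments, codon spanning the junction
    txSpliced <- new("CodingTranscript", transcriptId = "sp", gene = "g",
        chrom = "chr1", strand = "+",
        cdsSegments = IRanges::IRanges(c(101L, 201L), c(104L, 205L)),
        cdsSequence = Biostrings::DNAString("ATGGTTAAA"))
    m <- mapGenomicToCodon(txSpliced, 201L)   # 5th coding base: codon 2 pos 2
    expect_identical(codonIndex(m$context), 2L)
    expect_identical(m$codonPos, 2L)
    expect_identical(genomicPositions(m$context), c(104L, 201L, 202L))
})

test_that("mapping every CDS position reconstructs the coding sequence", {
    set.seed(7)
    for (strand in c("+", "-")) {
        seqCoding <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                           collapse = "")
        genomic <- if (strand == "+") seqCoding else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(seqCoding)))
        tx <- makeTx(strand = strand, starts = 501L, seqGenomic = genomic)
        rebuilt <- character(30)
        for (pos in 501:530) {
            m <- mapGenomicToCodon(tx, pos)
            offset <- 3L * (codonIndex(m$context) - 1L) + m$codonPos
            rebuilt[offset] <- substr(refCodon(m$context), m$codonPos,
                                      m$codonPos)
        }
        expect_identical(paste(rebuilt, collapse = ""),
                         as.character(cdsSequence(tx)))
    }
})

test_that("nonconservative classification follows the polarity scheme", {
    expect_false(isNonconservative("L", "I"))    # both nonpolar
    expect_true(isNonconservative("W", "*"))     # nonsense
    expect_true(isNonconservative("S", "A"))     # polar -> nonpolar
    expect_error(isNonconservative("*", "A"), "sense amino acid")
    cl <- aminoAcidClasses()
    for (a in names(cl))
        expect_false(isNonconservative(a, a))
    # the missense verdict is symmetric
    set.seed(1)
    for (i in 1:50) {
        pair <- sample(names(cl), 2L)
        expect_identical(isNonconservative(pair[1], pair[2]),
                         isNonconservative(pair[2], pair[1]))
    }
})

test_that("transcript loading reads FASTA + BED/GFF and skips bad frames", {
    dir <- withr::local_tempdir()
    fasta <- file.path(dir, "ref.fa")
    writeLines(c(">chr1 test contig",
                 paste(rep("A", 100), collapse = ""),
                 ">chr2",
                 "ACGTACGTACGTACGTACGT"), fasta)
    # BED 4..13 (0-based half-open) = 1-based 5..13 = ACGTACGTA
    bed <- file.path(dir, "cds.bed")
    writeLines(c("chr2\t4\t13\ttxA|geneA\t0\t+",
                 "chr2\t4\t13\ttxB|geneB\t0\t-",
                 "chr2\t0\t10\ttxC|geneC\t0\t+"), bed)   # length 10: skipped
    expect_warning(txs <- loadTranscripts(fasta, bed), "txC")
    expect_named(txs, c("txA", "txB"))
    expect_identical(as.character(cdsSequence(txs$txA)), "ACGTACGTA")
    expect_identical(as.character(cdsSequence(txs$txB)),
                     as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString("ACGTACGTA"))))
    expect_identical(geneSymbol(txs$txB), "geneB")

    # GFF3 dialect
    gff <- file.path(dir, "cds.gff3")
    writeLines(c("##gff-version 3",
                 paste("chr2", "test", "CDS", "5", "13", ".", "+", "0",
                       "ID=cds1;transcript_id=txG;gene_name=geneG",
                       sep = "\t")), gff)
    txs <- loadTranscripts(fasta, gff)
    expect_named(txs, "txG")
    expect_identical(as.character(cdsSequence(txs$txG)), "ACGTACGTA")

    # missing contig is a hard error naming the contig
    bedBad <- file.path(dir, "bad.bed")
    writeLines("chrX\t0\t9\ttx|g\t0\t+", bedBad)
    expect_error(loadTranscripts(fasta, bedBad), "chrX")

    # empty annotation: warning + empty collection
    gffEmpty <- file.path(dir, "empty.gff3")
    writeLines("##gff-version 3", gffEmpty)
    expect_warning(txs <- loadTranscripts(fasta, gffEmpty), "no CDS")
    expect_length(txs, 0L)
})

test_that("transcript validity rejects malformed CDS models", {
    expect_error(new("CodingTranscript", transcriptId = "t", gene = "g",
                     chrom = "c", strand = "+",
                     cdsSegments = IRanges::IRanges(1L, 10L),
                     cdsSequence = Biostrings::DNAString("ACGTACGTAC")),
                 "divisible by 3")
    expect_error(new("CodingTranscript", transcriptId = "t", gene = "g",
                     chrom = "c", strand = "*",
                     cdsSegments = IRanges::IRanges(1L, 9L),
                     cdsSequence = Biostrings::DNAString("ACGTACGTA")),
                 "strand")
})
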