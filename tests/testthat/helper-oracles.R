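# Independent oracles and small fixture builders shared across tests.
# The oracle tables below are typed out by hand (not derived from package
# code or from Biostrings) so that they form an independent reference path.

geneticCodeOracle <- function() {
    c(TTT = "F", TTC = "F", TTA = "L", TTG = "L",
      CTT = "L", CTC = "L", CTA = "L", CTG = "L",
      ATT = "I", ATC = "I", ATA = "I", ATG = "M",
      GTT = "V", GTC = "V", GTA = "V", GTG = "V",
      TCT = "S", TCC = "S", TCA = "S", TCG = "S",
      CCT = "P", CCC = "P", CCA = "P", CCG = "P",
      ACT = "T", ACC = "T", ACA = "T", ACG = "T",
      GCT = "A", GCC = "A", GCA = "A", GCG = "A",
      TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
      CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
      AAT = "N", AAC = "N", AAA = "K", AAG = "K",
      GAT = "D", GAC = "D", GAA = "E", GAG = "E",
      TGT = "C", TGC = "C", TGA = "*", TGG = "W",
      CGT = "R", CGC = "R", CGA = "R", CGG = "R",
      AGT = "S", AGC = "S", AGA = "R", AGG = "R",
      GGT = "G", GGC = "G", GGA = "G", GGG = "G")
}

aaClassOracle <- function() {
    cl <- character()
    for (a in c("G", "S", "T", "C", "Y", "N", "Q")) cl[a] <- "polar"
    for (a in c("A", "V", "L", "I", "P", "F", "W", "M")) cl[a] <- "nonpolar"
    for (a in c("D", "E")) cl[a] <- "acidic"
    for (a in c("K", "R", "H")) cl[a] <- "basic"
    cl
}

# Independent nonconservative verdict from the oracle tables only.
oracleNonconservative <- function(aaFrom, aaTo) {
    if (aaTo == "*") return(TRUE)
    cl <- aaClassOracle()
    aaFrom != aaTo && cl[[aaFrom]] != cl[[aaTo]]
}

# Independent enumeration: walk ALL 64 codons and keep those differing from
# `codon` at exactly `n` positions (a different route than the package's
# position/alt-base construction).
oracleEnumerate <- function(codon, n) {
    code <- geneticCodeOracle()
    orig <- strsplit(codon, "")[[1]]
    aaFrom <- code[[codon]]
    hits <- 0L; total <- 0L
    for (other in names(code)) {
        diffs <- sum(strsplit(other, "")[[1]] != orig)
        if (diffs != n) next
        total <- total + 1L
        if (oracleNonconservative(aaFrom, code[[other]]))
            hits <- hits + 1L
    }
    list(proportion = hits / total, nNonconservative = hits,
         nOutcomes = total)
}

# ---- fixture builders -----------------------------------------------------

makeTx <- function(id = "tx1", gene = "g1", chrom = "chr1", strand = "+",
                   starts = 101L, ends = NULL, seqGenomic = NULL) {
    if (is.null(ends))
        ends <- starts + nchar(seqGenomic) - 1L
    seg <- IRanges::IRanges(starts, ends)
    cds <- if (strand == "+") seqGenomic else
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seqGenomic)))
    new("CodingTranscript", transcriptId = id, gene = gene, chrom = chrom,
        strand = strand, cdsSegments = seg,
        cdsSequence = Biostrings::DNAString(cds))
}

germRow <- function(patient = "p1", pos, ref, alt, genotype = "het",
                    maf = NA_real_, chrom = "chr1") {
    data.frame(patient_id = patient, chrom = chrom, pos = as.integer(pos),
               ref = ref, alt = alt, genotype = genotype, maf = maf,
               stringsAsFactors = FALSE)
}

somRow <- function(patient = "p1", pos, ref, alt, vaf = 0.3,
                   filter = "PASS", chrom = "chr1") {
    data.frame(patient_id = patient, chrom = chrom, pos = as.integer(pos),
               ref = ref, alt = alt, vaf = vaf, filter = filter,
               stringsAsFactors = FALSE)
}

# Evidence rows for one read: bases named by position.
readRows <- function(readId, bases, qual = 30) {
    data.frame(read_id = readId, pos = as.integer(names(bases)),
               base = unname(bases), qual = qual, stringsAsFactors = FALSE)
}

writeLinesTo <- function(lines, name) {
    path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                      name)
    writeLines(lines, path)
    path
}

germlineVcfLines <- function(records) {
    c("##fileformat=VCFv4.2",
      "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"MAF\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "NORMAL"), collapse = "\t"),
      records)
}

somaticVcfLines <- function(records) {
    c("##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
      "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Fraction\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "TUMOR"), collapse = "\t"),
      records)
}

# Convert simulator pileup rows (one patient) to a SAM file: one alignment
# per read over its contiguous covered span.
pileupToSam <- function(reads, path, chrom = "chrSim", contigLen = 100000L) {
    lines <- c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, contigLen))
    for (unit in split(reads, reads$read_id)) {
        unit <- unit[order(unit$pos), , drop = FALSE]
        stopifnot(all(diff(unit$pos) == 1L))
        seq <- paste(unit$base, collapse = "")
        qual <- paste(rep("I", nrow(unit)), collapse = "")  # Phred 40
        lines <- c(lines, paste(unit$read_id[1L], 0L, chrom, unit$pos[1L],
                                60L, paste0(nrow(unit), "M"), "*", 0L, 0L,
                                seq, qual, sep = "\t"))
    }
    writeLines(lines, path)
    path
}
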