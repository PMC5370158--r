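ctxOf <- function(tx, pos) mapGenomicToCodon(tx, pos)$context

cisCall <- new("PhaseCall", verdict = "cis", nReadsSpanning = 10L,
               nReadsCis = 8L, nReadsTrans = 0L)
transCall <- new("PhaseCall", verdict = "trans", nReadsSpanning = 10L,
                 nReadsCis = 0L, nReadsTrans = 8L)

test_that("reported and true substitutions follow the worked examples", {
    # ATA (I): somatic pos3 A>C alone is silent (ATC, I); with germline
    # pos1 A>G in cis the tumor codon is GTC (V) -- the I..I -> I..V pattern
    tx <- makeTx(seqGenomic = "ATGATAAAA", starts = 101L)
    ctx <- ctxOf(tx, 104L)
    som <- somRow(pos = 106, ref = "A", alt = "C")
    germ <- germRow(pos = 104, ref = "A", alt = "G")
    rep <- reportedSubstitution(ctx, som, tx)
    expect_identical(formatSubstitution(rep), "I2I")
    expect_identical(rep@category, "silent")
    tru <- trueSubstitution(ctx, germ, som, cisCall, tx)
    expect_identical(formatSubstitution(tru), "I2V")
    expect_identical(classifyChange(rep, tru), "silent_to_missense")

    # GTT (V): germline pos2 T>A + somatic pos3 T>C -> GAC (D), reported V..V
    tx <- makeTx(seqGenomic = "ATGGTTAAA", starts = 101L)
    ctx <- ctxOf(tx, 104L)
    som <- somRow(pos = 106, ref = "T", alt = "C")
    germ <- germRow(pos = 105, ref = "T", alt = "A")
    rep <- reportedSubstitution(ctx, som, tx)
    tru <- trueSubstitution(ctx, germ, som, cisCall, tx)
    expect_identical(formatSubstitution(rep), "V2V")
    expect_identical(formatSubstitution(tru), "V2D")
    expect_identical(classifyChange(rep, tru), "silent_to_missense")

    # ACA (T): germline pos1 A>T + somatic pos2 C>G -> TGA stop; reported
    # alone is AGA (R): a missense call hiding a stopgain
    tx <- makeTx(seqGenomic = "ATGACAAAA", starts = 101L)
    ctx <- ctxOf(tx, 104L)
    som <- somRow(pos = 105, ref = "C", alt = "G")
    germ <- germRow(pos = 104, ref = "A", alt = "T")
    rep <- reportedSubstitution(ctx, som, tx)
    tru <- trueSubstitution(ctx, germ, som, cisCall, tx)
    expect_identical(formatSubstitution(rep), "T2R")
    expect_identical(formatSubstitution(tru), "T2*")
    expect_identical(tru@category, "nonsense")
    expect_identical(classifyChange(rep, tru), "missense_to_nonsense")

    # in trans the alleles do not combine: true equals reported
    tru <- trueSubstitution(ctx, germ, som, transCall, tx)
    expect_identical(formatSubstitution(tru), formatSubstitution(rep))

    # germline and somatic at the same position is an invalid event
    expect_error(trueSubstitution(ctx, germRow(pos = 105, ref = "C",
                                               alt = "T"), som, cisCall, tx),
                 "same position")
})

test_that("alleles are complemented into coding orientation on minus strand", {
    # genomic TTTACCCAT on minus strand codes ATG GGT AAA; codon 2 occupies
    # genomic 106,105,104 in codon order, so genomic 106 is codon 2 pos 1
    tx <- makeTx(strand = "-", starts = 101L, seqGenomic = "TTTACCCAT")
    m <- mapGenomicToCodon(tx, 106L)
    expect_identical(refCodon(m$context), "GGT")
    expect_identical(m$codonPos, 1L)
    expect_identical(genomicPositions(m$context), c(106L, 105L, 104L))
    # genomic C>T at 106 is coding G>A: GGT -> AGT, G2S
    som <- somRow(pos = 106, ref = "C", alt = "T")
    rep <- reportedSubstitution(m$context, som, tx)
    expect_identical(formatSubstitution(rep), "G2S")
})

test_that("change classification covers the category cross", {
    mk <- function(s) parseSubstitution(s)
    expect_identical(classifyChange(mk("R119H"), mk("R119H")), "no_change")
    expect_identical(classifyChange(mk("T316T"), mk("T316S")),
                     "silent_to_missense")
    expect_identical(classifyChange(mk("C871Y"), mk("C871H")),
                     "missense_to_missense")
    expect_identical(classifyChange(mk("T316T"), mk("T316*")),
                     "silent_to_nonsense")
    expect_identical(classifyChange(mk("T316I"), mk("T316T")),
                     "missense_to_silent")
    expect_identical(classifyChange(mk("W10*"), mk("W10*")), "no_change")
    expect_identical(classifyChange(mk("W10*"), mk("W10C")), "other")
    expect_error(classifyChange(mk("R119H"), mk("R120H")),
                 "different residues")
    expect_identical(classifyChange(mk("V226V"), mk("V336D"),
                                    strict = FALSE), "silent_to_missense")
})

test_that("impact scoring anchors silent at 0, stopgain at 100", {
    silent <- parseSubstitution("T10T")
    stopgain <- parseSubstitution("W10*")
    missense <- parseSubstitution("L10I")
    sc <- impactScorer()
    expect_identical(scoreSubstitution(silent, sc), 0)
    expect_identical(scoreSubstitution(stopgain, sc), 100)
    s <- scoreSubstitution(missense, sc)
    expect_gt(s, 0); expect_lte(s, 100)
    # the mildest missense (L/I, smallest Grantham distance) scores lowest
    radical <- scoreSubstitution(parseSubstitution("C10W"), sc)
    expect_identical(radical, 100)
    expect_lt(s, radical)

    # isoform aggregation
    expect_identical(scoreSubstitution(missense, sc,
                                       isoformScores = c(40, 60)), 50)
    scMax <- impactScorer(isoformMode = "max")
    expect_identical(scoreSubstitution(missense, scMax,
                                       isoformScores = c(40, 60)), 60)
})

test_that("Grantham surrogate reproduces published landmark distances", {
    g <- granthamMatrix()
    expect_equal(g["L", "I"], 5, tolerance = 0.05)
    expect_equal(g["C", "W"], 215, tolerance = 0.01)
    expect_equal(g["R", "L"], 102, tolerance = 0.02)
    expect_equal(mean(g[upper.tri(g)]), 100, tolerance = 1e-9)
    expect_true(isSymmetric(g))
    expect_identical(unname(diag(g)), rep(0, 20))
})

test_that("external score tables are honored with explicit missing handling", {
    tab <- data.frame(gene = "TP53", substitution = "R119H", score = 72.5)
    sub <- parseSubstitution("R119H", gene = "TP53")
    ext <- impactScorer("external", table = tab)
    expect_identical(scoreSubstitution(sub, ext), 72.5)
    other <- parseSubstitution("R120K", gene = "TP53")
    expect_error(scoreSubstitution(other, ext), "no external score")
    extFb <- impactScorer("external", table = tab, fallback = TRUE)
    expect_gt(scoreSubstitution(other, extFb), 0)
    # silent/nonsense anchors hold in external mode too
    expect_identical(scoreSubstitution(parseSubstitution("T10T"), ext), 0)
    expect_identical(scoreSubstitution(parseSubstitution("W10*"), ext), 100)
})

test_that("substitution enumeration matches hand-derived cases", {
    e <- enumerateNonconservative("TGG", 1L)
    expect_equal(e$proportion, 8 / 9)
    e <- enumerateNonconservative("CTG", 1L)
    expect_equal(e$proportion, 2 / 9)
    e <- enumerateNonconservative("GCA", 0L)
    expect_identical(e$proportion, 0)
    expect_error(enumerateNonconservative("TAA", 1L), "stop codon")
})

test_that("true == reported whenever the codon has no germline variant", {
    set.seed(42)
    for (i in 1:25) {
        codon <- sample(senseCodons <- setdiff(names(geneticCodeOracle()),
                                               c("TAA", "TAG", "TGA")), 1L)
        tx <- makeTx(seqGenomic = paste0("ATG", codon, "AAA"), starts = 101L)
        ctx <- ctxOf(tx, 104L)
        p <- sample(104:106, 1L)
        refBase <- substr(codon, p - 103L, p - 103L)
        som <- somRow(pos = p, ref = refBase,
                      alt = sample(setdiff(c("A", "C", "G", "T"), refBase), 1))
        rep <- reportedSubstitution(ctx, som, tx)
        noGerm <- germRow(pos = 1, ref = "A", alt = "C")[0, , drop = FALSE]
        tru <- trueSubstitution(ctx, noGerm, som, cisCall, tx)
        expect_identical(formatSubstitution(tru), formatSubstitution(rep))
    }
})

test_that("variant application order at disjoint positions is immaterial", {
    tx <- makeTx(seqGenomic = "ATGGTTAAA", starts = 101L)
    ctx <- ctxOf(tx, 104L)
    g2 <- rbind(germRow(pos = 104, ref = "G", alt = "C"),
                germRow(pos = 105, ref = "T", alt = "A"))
    som <- somRow(pos = 106, ref = "T", alt = "G")
    a <- trueSubstitution(ctx, g2, som, cisCall, tx)
    b <- trueSubstitution(ctx, g2[2:1, ], som, cisCall, tx)
    expect_identical(formatSubstitution(a), formatSubstitution(b))
})

test_that("annotated events satisfy the delta-score invariants", {
    pl <- plantEvents(12L, c(no_change = 1, silent_to_missense = 1,
                             missense_to_missense = 1,
                             missense_to_nonsense = 1), seed = 8L)
    det <- detectEvents(pl@transcripts, pl@germline, pl@somatic, pl@reads)
    ev <- det$events
    expect_identical(nrow(ev), 12L)
    expect_true(all(ev$delta_score >= -100 & ev$delta_score <= 100))
    expect_true(all(ev$delta_score[ev$change_category == "no_change"] == 0))
    expect_equal(ev$delta_score, ev$true_score - ev$reported_score)
})

test_that("the 61-codon summary has the right shape and ordering property", {
    fb <- fig1bSummary()
    expect_identical(nrow(fb$table), 61L)
    expect_false(any(c("TAA", "TAG", "TGA") %in% fb$table$codon))
    expect_true(all(fb$table$p1 >= 0 & fb$table$p1 <= 1))
    expect_true(all(fb$table$p2 >= 0 & fb$table$p2 <= 1))
    expect_true(all(fb$table$p3 >= 0 & fb$table$p3 <= 1))
    expect_lte(fb$averages["p1"], fb$averages["p3"])
})
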