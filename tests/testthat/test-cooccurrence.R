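# Toy frame used throughout: ATG GTT AAA at chr1:101-109 (plus strand),
# codon 2 = GTT (V) at 104-106.
toyTx <- function() makeTx(seqGenomic = "ATGGTTAAA", starts = 101L)

test_that("candidate discovery respects the 2-nt window and codon frame", {
    txs <- list(tx1 = toyTx())
    # germline at codon pos 1, somatic at codon pos 3 of the same codon
    cands <- findCandidates(germRow(pos = 104, ref = "G", alt = "A"),
                            somRow(pos = 106, ref = "T", alt = "C"), txs)
    expect_length(cands, 1L)
    expect_true(cands[[1]]$same_codon)
    expect_identical(cands[[1]]$nt_distance, 2L)

    # codon boundary: distance 1 but different codons -> control, not candidate
    g <- germRow(pos = 107, ref = "A", alt = "G")
    s <- somRow(pos = 106, ref = "T", alt = "C")
    expect_length(findCandidates(g, s, txs), 0L)
    ctrl <- findAdjacentControls(g, s, txs)
    expect_length(ctrl, 1L)
    expect_false(ctrl[[1]]$same_codon)

    # distance 3 is outside the window everywhere
    g <- germRow(pos = 103, ref = "G", alt = "C")
    expect_length(findCandidates(g, s, txs), 0L)
    expect_length(findAdjacentControls(g, s, txs), 0L)

    # same genomic position is never an event pair
    g <- germRow(pos = 106, ref = "T", alt = "A")
    expect_length(findCandidates(g, s, txs), 0L)
})

test_that("pairs sharing a codon merge into one multi-variant candidate", {
    txs <- list(tx1 = toyTx())
    g <- rbind(germRow(pos = 104, ref = "G", alt = "A"),
               germRow(pos = 105, ref = "T", alt = "C"))
    s <- somRow(pos = 106, ref = "T", alt = "C")
    cands <- findCandidates(g, s, txs)
    expect_length(cands, 1L)
    expect_identical(nrow(cands[[1]]$germline), 2L)
    expect_identical(nrow(cands[[1]]$somatic), 1L)
    expect_identical(cands[[1]]$nt_distance, 1L)
})

test_that("a codon shared by transcripts yields one candidate, all recorded", {
    txs <- list(tx1 = toyTx(), tx2 = makeTx(id = "tx2", gene = "g2",
                                            seqGenomic = "ATGGTTAAA",
                                            starts = 101L))
    cands <- findCandidates(germRow(pos = 104, ref = "G", alt = "A"),
                            somRow(pos = 106, ref = "T", alt = "C"), txs)
    expect_length(cands, 1L)
    expect_setequal(cands[[1]]$transcripts, c("tx1", "tx2"))
})

test_that("candidate generation is symmetric in input row order", {
    txs <- list(tx1 = toyTx())
    g <- rbind(germRow(pos = 105, ref = "T", alt = "C"),
               germRow(pos = 104, ref = "G", alt = "A"),
               germRow(pos = 101, ref = "A", alt = "G"))
    s <- rbind(somRow(pos = 106, ref = "T", alt = "C"),
               somRow(pos = 102, ref = "T", alt = "G"))
    keyOf <- function(cands) sort(vapply(cands, function(cd)
        paste(sort(c(cd$germline$pos, cd$somatic$pos)), collapse = "-"), ""))
    a <- findCandidates(g, s, txs)
    b <- findCandidates(g[3:1, ], s[2:1, ], txs)
    expect_identical(keyOf(a), keyOf(b))
})

test_that("reference stop codons are never eventized", {
    txs <- list(tx1 = makeTx(seqGenomic = "ATGTAAAAA", starts = 101L))
    cands <- findCandidates(germRow(pos = 104, ref = "T", alt = "C"),
                            somRow(pos = 106, ref = "A", alt = "G"), txs)
    expect_length(cands, 0L)
})

test_that("phase classification counts cis/trans support per evidence unit", {
    txs <- list(tx1 = toyTx())
    cand <- findCandidates(germRow(pos = 104, ref = "G", alt = "A"),
                           somRow(pos = 106, ref = "T", alt = "C"), txs)[[1]]
    cisRead <- function(id) readRows(id, c("104" = "A", "106" = "C"))
    transRead <- function(id) readRows(id, c("104" = "G", "106" = "C"))
    ev <- do.call(rbind, lapply(sprintf("r%d", 1:5), cisRead))
    ph <- classifyPhase(cand, ev)
    expect_identical(verdict(ph), "cis")
    expect_identical(unname(phaseCounts(ph)), c(5L, 5L, 0L))

    ev <- do.call(rbind, lapply(sprintf("r%d", 1:5), transRead))
    expect_identical(verdict(classifyPhase(cand, ev)), "trans")

    # single cis read is below min_support
    expect_identical(verdict(classifyPhase(cand, cisRead("r1"))), "ambiguous")
    expect_identical(verdict(classifyPhase(cand, cisRead("r1"),
                                           minSupport = 1L)), "cis")

    # exact tie -> ambiguous
    ev <- rbind(cisRead("a"), cisRead("b"), transRead("c"), transRead("d"))
    expect_identical(verdict(classifyPhase(cand, ev)), "ambiguous")

    # no spanning reads
    ph <- classifyPhase(cand, readRows("r1", c("104" = "A")))
    expect_identical(verdict(ph), "ambiguous")
    expect_identical(unname(phaseCounts(ph)["spanning"]), 0L)
})

test_that("low-quality bases are excluded from phase evidence", {
    txs <- list(tx1 = toyTx())
    cand <- findCandidates(germRow(pos = 104, ref = "G", alt = "A"),
                           somRow(pos = 106, ref = "T", alt = "C"), txs)[[1]]
    lowQ <- rbind(readRows("r1", c("104" = "A"), qual = 30),
                  readRows("r1", c("106" = "C"), qual = 10))
    expect_identical(unname(phaseCounts(classifyPhase(cand, lowQ))["spanning"]),
                     0L)
    # two mates of one fragment form one evidence unit
    mates <- rbind(readRows("fr1", c("104" = "A")),
                   readRows("fr1", c("106" = "C")),
                   readRows("fr2", c("104" = "A")),
                   readRows("fr2", c("106" = "C")))
    ph <- classifyPhase(cand, mates)
    expect_identical(verdict(ph), "cis")
    expect_identical(unname(phaseCounts(ph)["cis"]), 2L)
})

test_that("confirmation keeps cis events and conserves counts", {
    txs <- list(tx1 = toyTx())
    mk <- function(p, gpos, spos) findCandidates(
        germRow(patient = p, pos = gpos, ref = "G", alt = "A"),
        somRow(patient = p, pos = spos, ref = "T", alt = "C"), txs)[[1]]
    cands <- list(mk("p1", 104, 106), mk("p2", 104, 106), mk("p3", 104, 106))
    ev <- rbind(
        cbind(readRows("c1", c("104" = "A", "106" = "C")), patient_id = "p1"),
        cbind(readRows("c2", c("104" = "A", "106" = "C")), patient_id = "p1"),
        cbind(readRows("t1", c("104" = "G", "106" = "C")), patient_id = "p2"),
        cbind(readRows("t2", c("104" = "G", "106" = "C")), patient_id = "p2"))
    res <- confirmEvents(cands, ev)
    expect_identical(unname(res$counts),
                     c(3L, 1L, 1L, 1L))
    expect_length(res$events, 1L)
    expect_identical(res$events[[1]]$patient_id, "p1")
    expect_identical(sum(res$counts[2:4]), unname(res$counts[1]))

    # empty candidate list
    res <- confirmEvents(list(), ev)
    expect_identical(unname(res$counts), c(0L, 0L, 0L, 0L))
})

test_that("homozygous germline context cannot produce trans support", {
    # hom germline: both haplotypes carry the germline alt, so a read with
    # the germline reference base cannot exist
    cfg <- simulationConfig(nPatients = 30L, cisProb = 0.5, depth = 30L,
                            errorRate = 0, seed = 314L)
    co <- simulateCohort(cfg)
    homOnly <- co@germline[co@germline$genotype == "hom_alt", , drop = FALSE]
    det <- detectEvents(co@transcripts, homOnly, co@somatic, co@reads)
    expect_identical(unname(det$counts["n_trans"]), 0)
    expect_gt(det$counts["n_candidates"], 0)
})

test_that("window and codon invariants hold on simulated confirmed events", {
    cfg <- simulationConfig(nPatients = 20L, seed = 99L, errorRate = 0)
    co <- simulateCohort(cfg)
    det <- detectEvents(co@transcripts, co@germline, co@somatic, co@reads)
    for (ev in det$confirmed) {
        d <- outer(ev$germline$pos, ev$somatic$pos,
                   function(a, b) abs(a - b))
        expect_lte(min(d), 2L)
        tx <- co@transcripts[[ev$transcripts[1]]]
        idx <- vapply(c(ev$germline$pos, ev$somatic$pos), function(p)
            codonIndex(mapGenomicToCodon(tx, p)$context), 0L)
        expect_identical(length(unique(idx)), 1L)
    }
})
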