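test_that("simulation config validates its stated world", {
    expect_error(simulationConfig(), "mandatory")
    expect_error(simulationConfig(cisProb = 1.2, seed = 1), "out of \\[0,1\\]")
    expect_error(simulationConfig(nTranscripts = 2L, cdsCodons = 10L,
                                  burdenMean = 1000, seed = 1),
                 "coding positions")
    cfg <- simulationConfig(cancerType = "SKCM", seed = 1)
    expect_equal(cfg@burdenMean, 100)
    expect_error(cancerTypePreset("LUAD"), "unknown")
})

test_that("cohort simulation is deterministic given the seed", {
    cfg <- simulationConfig(nPatients = 5L, seed = 123L)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(a@germline, b@germline)
    expect_identical(a@somatic, b@somatic)
    expect_identical(a@reads, b@reads)
    expect_identical(a@truth, b@truth)
    expect_identical(as.character(a@reference), as.character(b@reference))
    # byte-identical on disk
    d1 <- file.path(withr::local_tempdir(), "c1")
    d2 <- file.path(withr::local_tempdir(), "c2")
    writeCohort(a, d1); writeCohort(b, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("zero somatic burden yields zero candidates downstream", {
    cfg <- simulationConfig(nPatients = 5L, burdenMean = 0, seed = 3L)
    co <- simulateCohort(cfg)
    expect_identical(nrow(co@somatic), 0L)
    expect_identical(nrow(co@truth), 0L)
    det <- detectEvents(co@transcripts, co@germline, co@somatic, co@reads)
    expect_identical(unname(det$counts["n_candidates"]), 0)
})

test_that("emitted germline SNPs show the configured third-position bias", {
    cfg <- simulationConfig(nPatients = 40L, thirdPosWeight = 3,
                            burdenMean = 0, seed = 21L)
    co <- simulateCohort(cfg)
    # population sites are the independent draws (per-patient genotype rows
    # of one site are correlated), so measure the bias on unique sites
    sites <- co@germline[!duplicated(co@germline$pos), , drop = FALSE]
    freqs <- germlineCodonPositionFreqs(sites, co@transcripts)
    n <- nrow(sites)
    expect_gt(n, 80L)
    # configured third-position probability is 3/5
    expect_lt(abs(freqs[3] - 0.6), 1.96 * sqrt(0.6 * 0.4 / n) + 0.02)
    expect_gt(freqs[3], freqs[1])
})

test_that("somatic VAFs follow the configured Beta model", {
    cfg <- simulationConfig(nPatients = 40L, seed = 22L)
    co <- simulateCohort(cfg)
    v <- co@somatic$vaf
    expect_gt(length(v), 300)
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - 0.3), 3 * se + 0.005)
})

test_that("germline MAFs are common-SNP shaped", {
    cfg <- simulationConfig(nPatients = 10L, burdenMean = 0, seed = 23L)
    co <- simulateCohort(cfg)
    sitesMaf <- co@germline$maf[!duplicated(co@germline$pos)]
    expect_gt(length(sitesMaf), 50)
    expect_lt(abs(mean(sitesMaf) - 0.49), 0.06)
})

test_that("planted events close the loop through the pipeline", {
    mix <- c(silent_to_missense = 10, missense_to_nonsense = 5,
             no_change = 5)
    pl <- plantEvents(20L, mix, seed = 12L)
    det <- detectEvents(pl@transcripts, pl@germline, pl@somatic, pl@reads)
    expect_identical(nrow(det$events), 20L)
    expect_identical(sum(det$events$change_category == "silent_to_missense"),
                     10L)
    expect_identical(sum(det$events$change_category == "missense_to_nonsense"),
                     5L)
    expect_identical(sum(det$events$change_category == "no_change"), 5L)
    # engineered stopgain pattern is realized from the code table
    mn <- det$events[det$events$change_category == "missense_to_nonsense", ]
    expect_true(all(substr(mn$true_substitution,
                           nchar(mn$true_substitution),
                           nchar(mn$true_substitution)) == "*"))
})

test_that("planted trans events are rejected by confirmation", {
    pl <- plantEvents(6L, c(no_change = 1), phases = "trans", seed = 13L)
    expect_identical(unique(pl@truth$phase), "trans")
    det <- detectEvents(pl@transcripts, pl@germline, pl@somatic, pl@reads)
    expect_identical(nrow(det$events), 0L)
    expect_identical(unname(det$counts["n_trans"]), 6)
})

test_that("unrealizable change categories fail loudly", {
    expect_error(plantEvents(2L, c(bogus_category = 1), seed = 1L),
                 "bogus_category")
})

test_that("the synthetic supplement stand-in satisfies its construction", {
    s1 <- syntheticS1Table(seed = 42L)
    expect_identical(nrow(s1), 392L)
    expect_identical(ncol(s1), 16L)
    # substitution strings are consistent with their change category
    agree <- s1$reported_substitution == s1$true_substitution
    expect_identical(unname(agree), s1$change_category == "no_change")
    # scores are internally consistent
    expect_equal(s1$delta_score, s1$true_score - s1$reported_score)
    expect_true(all(s1$reported_score >= 0 & s1$reported_score <= 100))
    # different seeds shuffle incidentals but keep the marginals
    s2 <- syntheticS1Table(seed = 7L)
    expect_identical(summarizeEventTable(s1)$genotypeCounts,
                     summarizeEventTable(s2)$genotypeCounts)
})
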