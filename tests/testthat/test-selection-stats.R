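test_that("expected cis fraction follows the genotype model", {
    expect_identical(expectedCisFraction(10, 0), 1)
    expect_identical(expectedCisFraction(0, 10), 0.5)
    expect_equal(expectedCisFraction(53, 47), 0.765)
    expect_error(expectedCisFraction(0, 0), "> 0")
})

test_that("cis/trans Fisher test behaves at the boundaries", {
    # observed exactly at expectation: identical columns, p = 1
    r <- cisTransSelectionTest(765, 235, 0.765)
    expect_identical(pValue(r), 1)
    # strong depletion
    r <- cisTransSelectionTest(0, 100, 0.765)
    expect_lt(pValue(r), 1e-6)
    expect_lt(r@extra$oddsRatio, 1)
    expect_error(cisTransSelectionTest(5, 5, 0.4), "0.5")
    expect_error(cisTransSelectionTest(0, 0, 0.8), "no observed")
    # cohort-scale expected column approximates the exact binomial test
    r <- cisTransSelectionTest(350, 150, 0.765, expectedN = 50000)
    b <- stats::binom.test(350, 500, 0.765)
    expect_equal(pValue(r), b$p.value, tolerance = 0.05)
})

test_that("codon-position pair expectation renormalizes correctly", {
    cpe <- codonPositionExpectation(rep(1 / 3, 3))
    expect_equal(unname(cpe$expected), rep(1 / 6, 6))
    expect_equal(sum(cpe$expected), 1)
    cpe <- codonPositionExpectation(c(0, 0, 1))
    expect_equal(unname(cpe$expected[c("3>1", "3>2")]), c(0.5, 0.5))
    expect_equal(sum(cpe$expected[c("1>2", "1>3", "2>1", "2>3")]), 0)
    # third-position-biased germline: conditioned test accepts what the
    # naive uniform test rejects
    f <- c(0.15, 0.15, 0.7)
    obs <- round(1000 * c(f[1] / 2, f[1] / 2, f[2] / 2, f[2] / 2,
                          f[3] / 2, f[3] / 2))
    cpe <- codonPositionExpectation(f, obs)
    expect_gt(pValue(cpe$conditioned), 0.9)
    expect_lt(pValue(cpe$naiveTest), 1e-10)
    expect_error(codonPositionExpectation(f, obs[1:5]), "length 6")
    expect_error(codonPositionExpectation(c(0.5, 0.5), NULL), "length 3")
})

test_that("MAF resampling null is centred and detects a common-SNP excess", {
    set.seed(5)
    pool <- runif(4000, 0, 0.5)
    obs <- sample(pool, 100)
    r <- mafNullTest(obs, pool, nDraws = 500, seed = 11)
    expect_lt(abs(r@statistic), 3)
    expect_gt(pValue(r), 0.01)
    # observed spiked near 0.5 against a uniform pool: large positive z
    spike <- runif(100, 0.45, 0.5)
    r <- mafNullTest(spike, pool, nDraws = 500, seed = 11)
    expect_gt(r@statistic, 5)
    expect_lt(pValue(r), 0.01)
    expect_error(mafNullTest(pool, pool, nDraws = 500, seed = 1),
                 "degenerate|smaller")
    expect_error(mafNullTest(obs, pool, nDraws = 50, seed = 1), ">= 100")
    expect_error(mafNullTest(obs, pool, nDraws = 500), "mandatory")
    # same seed, same draw
    a <- mafNullTest(obs, pool, nDraws = 200, seed = 3)
    b <- mafNullTest(obs, pool, nDraws = 200, seed = 3)
    expect_identical(a@statistic, b@statistic)
})

test_that("amino-acid representation test recovers exact agreement", {
    aas <- sort(names(aminoAcidClasses()))
    # a non-uniform background matched exactly: r = 1, proportion tests flat
    bg2 <- stats::setNames((1:20) / sum(1:20), aas)
    counts2 <- stats::setNames(as.integer((1:20) * 10), aas)
    r2 <- aaRepresentationTest(counts2, bg2)
    expect_equal(r2$correlation@statistic, 1, tolerance = 1e-9)
    expect_true(all(r2$perAa$p > 0.99))
    # everything in one amino acid: that proportion test collapses
    one <- stats::setNames(c(400L, rep(0L, 19)), aas)
    r3 <- aaRepresentationTest(one, bg2)
    expect_lt(r3$perAa$p[r3$perAa$aa == aas[1]], 1e-10)
    expect_error(aaRepresentationTest(stats::setNames(integer(20), aas), bg2),
                 "zero total")
})

test_that("burden-event correlation handles ties, groups and degeneracy", {
    b <- c(10, 20, 30, 40, 50)
    r <- burdenEventCorrelation(b, b * 2)
    expect_equal(r$overall@statistic, 1)
    expect_error(burdenEventCorrelation(b, rep(3, 5)), "constant")
    set.seed(2)
    grp <- rep(c("A", "B"), length.out = 40)
    bb <- rpois(40, 30); ee <- rpois(40, 3)
    r <- burdenEventCorrelation(bb, ee, grp)
    expect_identical(nrow(r$byGroup), 2L)
    expect_true(all(r$byGroup$n == 20))
})

test_that("hypergeometric enrichment matches a brute-force tail sum", {
    u <- sprintf("g%03d", 1:100)
    r <- cosmicEnrichment(u[1:10], u[c(1, 20:28)], u)
    brute <- sum(vapply(1:10, function(k)
        choose(10, k) * choose(90, 10 - k) / choose(100, 10), 0))
    expect_equal(pValue(r), brute, tolerance = 1e-12)
    expect_equal(pValue(r), 0.6695, tolerance = 1e-3)
    # no census genes among affected, none in universe overlap: p = 1
    expect_identical(pValue(cosmicEnrichment(u[1:10], character(0), u)), 1)
    # randomized instances against the brute-force oracle
    set.seed(77)
    for (i in 1:20) {
        nU <- sample(30:200, 1)
        uni <- sprintf("u%04d", seq_len(nU))
        cosmic <- sample(uni, sample(5:15, 1))
        affected <- sample(uni, sample(5:20, 1))
        k <- length(intersect(affected, cosmic))
        m <- length(cosmic); n <- nU - m; d <- length(affected)
        brute <- sum(vapply(k:min(d, m), function(x)
            choose(m, x) * choose(n, d - x) / choose(nU, d), 0))
        expect_equal(pValue(cosmicEnrichment(affected, cosmic, uni)), brute,
                     tolerance = 1e-9)
    }
    expect_error(cosmicEnrichment(c(u[1], "zzz"), u[1:5], u), "zzz")
})

test_that("paired impact test detects shifts and reports relative increase", {
    r <- pairedImpactTest(c(10, 20), c(20, 25))
    expect_equal(r@extra$meanRelativeIncreasePct, 62.5)
    same <- rep(c(10, 30, 50), 4)
    expect_warning(r <- pairedImpactTest(same, same), "zero")
    expect_identical(pValue(r), 1)
    expect_equal(r@extra$meanRelativeIncreasePct, 0)
    set.seed(3)
    rep20 <- runif(20, 10, 80)
    r <- pairedImpactTest(rep20, rep20 + 10)
    expect_lt(pValue(r), 0.001)
    rPratt <- pairedImpactTest(rep20, rep20 + 10, zeroMethod = "pratt")
    expect_lt(pValue(rPratt), 0.001)
})

test_that("VAF comparison uses Welch and survives degenerate groups", {
    set.seed(4)
    a <- rnorm(100, 0.3, 0.1); b <- rnorm(100, 0.5, 0.1)
    r <- vafComparison(a, b)
    expect_lt(pValue(r), 1e-6)
    expect_equal(r@extra$meanA, mean(a))
    same <- rnorm(50, 0.3, 0.05)
    expect_gte(pValue(vafComparison(same, same)), 0.999)
    expect_identical(pValue(vafComparison(rep(0.3, 5), rep(0.3, 5))), 1)
    expect_identical(pValue(vafComparison(rep(0.3, 5), rep(0.4, 5))), 0)
    expect_error(vafComparison(0.3, c(0.1, 0.2)), "at least 2")
})
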