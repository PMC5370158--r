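# Expectation / null models and cohort-level hypothesis tests: genotype-
# composition cis:trans expectation, codon-position pair expectation, MAF
# resampling null, amino-acid representation, burden-event correlation,
# cancer-gene enrichment, paired impact shift and VAF comparisons.
# All p-values are reported raw (no multiple-testing correction), and every
# stochastic operation takes an explicit seed.

nullResult <- function(modelName, observed, expected, statistic, pValue,
                       method, n, seed = NA_integer_, extra = list()) {
    new("NullModelResult", modelName = modelName,
        observed = as.numeric(observed), expected = as.numeric(expected),
        statistic = as.numeric(statistic), pValue = as.numeric(pValue),
        method = method, n = as.integer(n), seed = as.integer(seed),
        extra = extra)
}

roundHalfUp <- function(x) floor(x + 0.5)

#' Expected cis fraction from genotype composition
#'
#' A homozygous germline variant sits on both alleles, so any somatic variant
#' in the codon co-occurs with it in cis; a heterozygous variant is in cis
#' only half the time. The expected cis fraction among candidate events is
#' therefore `(n_hom + 0.5 * n_het) / (n_hom + n_het)`.
#'
#' @param nHom,nHet homozygous / heterozygous germline variant counts.
#' @return fraction in \[0.5, 1\].
#' @examples
#' expectedCisFraction(53, 47)  # 0.765
#' @export
expectedCisFraction <- function(nHom, nHet) {
    if (nHom < 0 || nHet < 0 || nHom + nHet <= 0)
        stop("need non-negative counts with nHom + nHet > 0")
    (nHom + 0.5 * nHet) / (nHom + nHet)
}

#' Cis/trans selection test
#'
#' Two-sided Fisher's exact test of the observed cis/trans split of candidate
#' events against the split expected from cohort genotype composition
#' ([expectedCisFraction()]). The expected column uses half-up-rounded counts
#' at the observed total. Depletion of cis events (odds ratio < 1) is the
#' negative-selection signal.
#'
#' @param observedCis,observedTrans observed candidate counts.
#' @param expectedFraction expected cis fraction in \[0.5, 1\].
#' @param expectedN scale at which the expected column is materialized.
#'   Default is the observed total; passing the cohort-wide germline variant
#'   count (the population the expectation is actually derived from) makes
#'   the test approach a calibrated exact binomial test against
#'   `expectedFraction`.
#' @return a [NullModelResult] (odds ratio in `extra$oddsRatio`).
#' @export
cisTransSelectionTest <- function(observedCis, observedTrans,
                                  expectedFraction, expectedN = NULL) {
    n <- observedCis + observedTrans
    if (n <= 0)
        stop("no observed events")
    if (expectedFraction < 0.5 || expectedFraction > 1)
        stop("'expectedFraction' must lie in [0.5, 1] under the genotype model")
    if (is.null(expectedN)) expectedN <- n
    expCis <- roundHalfUp(expectedFraction * expectedN)
    m <- matrix(c(observedCis, observedTrans, expCis, expectedN - expCis),
                nrow = 2L)
    ft <- stats::fisher.test(m, alternative = "two.sided")
    nullResult("cis_trans_selection",
               observed = c(cis = observedCis, trans = observedTrans),
               expected = c(cis = expCis, trans = expectedN - expCis),
               statistic = unname(ft$estimate), pValue = ft$p.value,
               method = "two-sided Fisher's exact test, observed vs genotype-expected cis:trans",
               n = n, extra = list(oddsRatio = unname(ft$estimate),
                                   expectedFraction = expectedFraction))
}

codonPairLabels <- function() {
    c("1>2", "1>3", "2>1", "2>3", "3>1", "3>2")
}

#' Codon-position pair expectation and goodness-of-fit
#'
#' Expected distribution of ordered (germline position, somatic position)
#' pairs within a codon under the model that germline variants follow the
#' cohort's codon-position frequencies while somatic variants have no codon
#' preference: `P(g, s) = f_g * 1/2` over the two non-germline positions
#' (same-position events are excluded events, so the support is the six
#' ordered pairs with `g != s`). A naive expectation with uniform germline
#' frequencies (1/3 each) is exposed alongside, reproducing the two-stage
#' reading: apparent third-position bias under the naive model, none after
#' conditioning on the germline composition.
#'
#' @param germlinePosFreqs length-3 frequency vector of germline codon
#'   positions (sums to 1).
#' @param observedPairCounts optional length-6 count vector in the order
#'   `1>2, 1>3, 2>1, 2>3, 3>1, 3>2`; when given, chi-square goodness-of-fit
#'   tests are run against both expectations.
#' @return `list(expected, naive, conditioned = NullModelResult or NULL,
#'   naiveTest = NullModelResult or NULL)`.
#' @export
codonPositionExpectation <- function(germlinePosFreqs,
                                     observedPairCounts = NULL) {
    if (length(germlinePosFreqs) != 3L)
        stop("'germlinePosFreqs' must have length 3")
    if (abs(sum(germlinePosFreqs) - 1) > 1e-9)
        stop("'germlinePosFreqs' must sum to 1")
    pairMat <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L), c(2L, 3L),
                     c(3L, 1L), c(3L, 2L))
    expect <- function(f) {
        p <- f[pairMat[, 1L]] * 0.5
        p <- p / sum(p)          # renormalization is a no-op when sum(f)=1
        stats::setNames(p, codonPairLabels())
    }
    expected <- expect(germlinePosFreqs)
    naive <- expect(rep(1 / 3, 3L))
    conditioned <- naiveTest <- NULL
    if (!is.null(observedPairCounts)) {
        if (length(observedPairCounts) != 6L)
            stop("'observedPairCounts' must have length 6 (ordered pairs ",
                 paste(codonPairLabels(), collapse = ", "), ")")
        run <- function(p, name, label) {
            keep <- p > 0
            ct <- suppressWarnings(
                stats::chisq.test(observedPairCounts[keep], p = p[keep],
                                  rescale.p = TRUE))
            nullResult(name, observed = observedPairCounts, expected = p,
                       statistic = unname(ct$statistic),
                       pValue = ct$p.value,
                       method = paste("chi-square goodness-of-fit,", label),
                       n = sum(observedPairCounts))
        }
        conditioned <- run(expected, "codon_pair_conditioned",
                           "germline-composition expectation")
        naiveTest <- run(naive, "codon_pair_naive",
                         "uniform-germline expectation")
    }
    list(expected = expected, naive = naive, conditioned = conditioned,
         naiveTest = naiveTest)
}

#' MAF resampling null
#'
#' Compares the mean minor allele frequency of the germline variants involved
#' in co-occurrence events against a resampling null: `nDraws` sets of the
#' same size drawn without replacement from a pool of population MAFs, the
#' mean recorded for each draw. Reports the z-score of the observed mean
#' against the null distribution of means and an empirical two-sided p.
#'
#' @param observedMafs MAFs of the event-involved germline variants.
#' @param mafPool population MAF pool to resample from.
#' @param nDraws number of resampled sets (>= 100).
#' @param seed RNG seed (mandatory).
#' @return a [NullModelResult] (z-score in `statistic` and `extra$z`).
#' @export
mafNullTest <- function(observedMafs, mafPool, nDraws = 1000L, seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    k <- length(observedMafs)
    if (k < 1L) stop("no observed MAFs")
    if (nDraws < 100L) stop("'nDraws' must be >= 100")
    if (length(mafPool) < k)
        stop("pool smaller than the observed set")
    if (length(mafPool) == k || stats::var(mafPool) == 0)
        stop("degenerate pool: null distribution of means has zero spread")
    nullMeans <- withSeed(seed, vapply(seq_len(nDraws), function(i)
        mean(sample(mafPool, k, replace = FALSE)), 0))
    s <- stats::sd(nullMeans)
    if (s == 0)
        stop("degenerate pool: null distribution of means has zero spread")
    obs <- mean(observedMafs)
    z <- (obs - mean(nullMeans)) / s
    pEmp <- (1 + sum(abs(nullMeans - mean(nullMeans)) >=
                     abs(obs - mean(nullMeans)))) / (nDraws + 1)
    nullResult("maf_resampling_null", observed = obs,
               expected = mean(nullMeans), statistic = z, pValue = pEmp,
               method = sprintf(
                   "resampling null of mean MAF (%d draws of %d from pool of %d)",
                   nDraws, k, length(mafPool)),
               n = k, seed = seed,
               extra = list(z = z, nullSd = s, nDraws = nDraws))
}

#' Amino-acid representation test
#'
#' Correlates the amino acids underlying co-occurrence events with their
#' background representation in vertebrate proteins (Pearson), and tests each
#' amino acid's observed proportion against its background proportion with a
#' one-sample proportion z-test (no continuity correction).
#'
#' @param eventAaCounts named count vector over the 20 amino acids (missing
#'   letters count 0).
#' @param backgroundFreqs named background frequencies over the 20 amino
#'   acids (sums to 1).
#' @return `list(correlation = NullModelResult, perAa = data.frame(aa,
#'   observed, expected_prop, z, p))`.
#' @export
aaRepresentationTest <- function(eventAaCounts, backgroundFreqs) {
    aas <- sort(names(aminoAcidClasses()))
    if (!all(names(backgroundFreqs) %in% aas) ||
        abs(sum(backgroundFreqs) - 1) > 1e-6)
        stop("'backgroundFreqs' must be named by amino acid and sum to 1")
    counts <- stats::setNames(rep(0, length(aas)), aas)
    counts[names(eventAaCounts)] <- eventAaCounts
    n <- sum(counts)
    if (n == 0) stop("zero total events")
    bg <- stats::setNames(rep(0, length(aas)), aas)
    bg[names(backgroundFreqs)] <- backgroundFreqs
    props <- counts / n
    ct <- stats::cor.test(props, bg, method = "pearson")
    z <- (props - bg) / sqrt(bg * (1 - bg) / n)
    perAa <- data.frame(aa = aas, observed = unname(counts),
                        expected_prop = unname(bg), z = unname(z),
                        p = unname(2 * stats::pnorm(-abs(z))),
                        stringsAsFactors = FALSE)
    corRes <- nullResult("aa_representation", observed = props, expected = bg,
                         statistic = unname(ct$estimate), pValue = ct$p.value,
                         method = "Pearson correlation of observed vs background amino-acid proportions",
                         n = n, extra = list(r = unname(ct$estimate)))
    list(correlation = corRes, perAa = perAa)
}

#' Somatic burden vs co-occurrence correlation
#'
#' Spearman rank correlation (average ranks for ties) between each patient's
#' somatic burden and their number of affected codons, overall and per group
#' when labels are supplied. A proportional relationship is what a purely
#' mutational (selection-free) origin of co-occurrences predicts.
#'
#' @param burden per-patient somatic variant counts.
#' @param nEvents per-patient co-occurrence counts (affected codons).
#' @param groups optional per-patient labels (e.g. cancer type).
#' @return `list(overall = NullModelResult, byGroup = data.frame or NULL)`.
#' @export
burdenEventCorrelation <- function(burden, nEvents, groups = NULL) {
    if (length(burden) != length(nEvents))
        stop("'burden' and 'nEvents' must have equal length")
    if (length(burden) < 3L) stop("need at least 3 patients")
    runOne <- function(x, y) {
        if (stats::sd(x) == 0 || stats::sd(y) == 0)
            stop("undefined correlation: constant vector",
                 call. = FALSE)
        suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    }
    ct <- runOne(burden, nEvents)
    overall <- nullResult("burden_event_correlation",
                          observed = unname(ct$estimate), expected = 0,
                          statistic = unname(ct$estimate),
                          pValue = ct$p.value,
                          method = "Spearman rank correlation, somatic burden vs affected codons",
                          n = length(burden),
                          extra = list(r = unname(ct$estimate)))
    byGroup <- NULL
    if (!is.null(groups)) {
        byGroup <- do.call(rbind, lapply(sort(unique(groups)), function(gr) {
            idx <- groups == gr
            res <- try(runOne(burden[idx], nEvents[idx]), silent = TRUE)
            if (inherits(res, "try-error"))
                data.frame(group = gr, n = sum(idx), r = NA_real_,
                           p = NA_real_, stringsAsFactors = FALSE)
            else
                data.frame(group = gr, n = sum(idx),
                           r = unname(res$estimate), p = res$p.value,
                           stringsAsFactors = FALSE)
        }))
    }
    list(overall = overall, byGroup = byGroup)
}

#' Cancer-gene enrichment
#'
#' Upper-tail hypergeometric probability that at least the observed number of
#' affected genes are census cancer genes, with the gene universe as
#' population.
#'
#' @param affectedGenes genes hit by co-occurrence events (duplicates
#'   collapsed).
#' @param cosmicGenes census cancer gene list.
#' @param universeGenes gene universe.
#' @return a [NullModelResult].
#' @export
cosmicEnrichment <- function(affectedGenes, cosmicGenes, universeGenes) {
    affected <- unique(affectedGenes)
    cosmic <- unique(cosmicGenes)
    universe <- unique(universeGenes)
    bad <- setdiff(affected, universe)
    if (length(bad))
        stop("affected genes outside the universe: ",
             paste(bad, collapse = ", "))
    bad <- setdiff(cosmic, universe)
    if (length(bad))
        stop("census genes outside the universe: ",
             paste(bad, collapse = ", "))
    k <- length(intersect(affected, cosmic))
    p <- stats::phyper(k - 1L, length(cosmic),
                       length(universe) - length(cosmic),
                       length(affected), lower.tail = FALSE)
    nullResult("cosmic_enrichment",
               observed = k,
               expected = length(affected) * length(cosmic) / length(universe),
               statistic = k, pValue = p,
               method = "upper-tail hypergeometric test of census-gene overlap",
               n = length(affected),
               extra = list(nCosmic = length(cosmic),
                            nUniverse = length(universe)))
}

#' Paired impact-score test
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test of true (germline-aware)
#' against reported (somatic-only) impact scores, plus the mean relative
#' score increase over pairs with a positive reported score (as a
#' percentage). Zero differences are dropped by default; `zeroMethod =
#' "pratt"` ranks them before discarding their signs (normal approximation).
#'
#' @param reportedScores,trueScores equal-length paired score vectors.
#' @param zeroMethod `"wilcox"` (drop zeros) or `"pratt"`.
#' @return a [NullModelResult] (`extra$meanRelativeIncreasePct`).
#' @export
pairedImpactTest <- function(reportedScores, trueScores,
                             zeroMethod = c("wilcox", "pratt")) {
    zeroMethod <- match.arg(zeroMethod)
    if (length(reportedScores) != length(trueScores))
        stop("paired score vectors must have equal length")
    d <- trueScores - reportedScores
    pos <- reportedScores > 0
    relInc <- if (any(pos))
        100 * mean((trueScores[pos] - reportedScores[pos]) /
                   reportedScores[pos]) else NA_real_
    if (all(d == 0)) {
        warning("all paired differences are zero; p set to 1")
        return(nullResult("paired_impact", observed = mean(trueScores),
                          expected = mean(reportedScores), statistic = 0,
                          pValue = 1,
                          method = "Wilcoxon matched-pairs signed-rank test (degenerate)",
                          n = length(d),
                          extra = list(meanRelativeIncreasePct = relInc)))
    }
    if (zeroMethod == "wilcox") {
        wt <- suppressWarnings(
            stats::wilcox.test(trueScores, reportedScores, paired = TRUE,
                               alternative = "two.sided"))
        stat <- unname(wt$statistic); p <- wt$p.value
    } else {
        # Pratt: rank |d| including zeros, drop zero ranks, normal approx.
        r <- rank(abs(d))
        keep <- d != 0
        wPlus <- sum(r[keep][d[keep] > 0])
        wMinus <- sum(r[keep][d[keep] < 0])
        nAll <- length(d)
        n0 <- sum(!keep)
        mu <- (nAll * (nAll + 1) / 2 - n0 * (n0 + 1) / 2) / 2
        sigma2 <- nAll * (nAll + 1) * (2 * nAll + 1) / 24 -
                  n0 * (n0 + 1) * (2 * n0 + 1) / 24
        ties <- table(r[keep])
        sigma2 <- sigma2 - sum(ties^3 - ties) / 48
        z <- (wPlus - mu) / sqrt(sigma2)
        stat <- wPlus
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    nullResult("paired_impact", observed = mean(trueScores),
               expected = mean(reportedScores), statistic = stat, pValue = p,
               method = sprintf(
                   "two-sided Wilcoxon matched-pairs signed-rank test (%s zeros)",
                   zeroMethod),
               n = sum(d != 0),
               extra = list(meanRelativeIncreasePct = relInc,
                            nZeroDifferences = sum(d == 0)))
}

#' Variant-allele-fraction comparison
#'
#' Welch two-sided t-test between two VAF groups (e.g. somatic variants
#' involved in co-occurrence events vs all others). Two constant equal groups
#' return p = 1 by convention; constant groups with different means return
#' p = 0.
#'
#' @param vafsA,vafsB VAF vectors, each with at least 2 values.
#' @return a [NullModelResult] (group means in `extra`).
#' @export
vafComparison <- function(vafsA, vafsB) {
    if (length(vafsA) < 2L || length(vafsB) < 2L)
        stop("each group needs at least 2 values")
    if (stats::sd(vafsA) == 0 && stats::sd(vafsB) == 0) {
        p <- if (mean(vafsA) == mean(vafsB)) 1 else 0
        stat <- if (p == 1) 0 else Inf
    } else {
        tt <- stats::t.test(vafsA, vafsB, var.equal = FALSE,
                            alternative = "two.sided")
        p <- tt$p.value; stat <- unname(tt$statistic)
    }
    nullResult("vaf_comparison", observed = mean(vafsA),
               expected = mean(vafsB), statistic = stat, pValue = p,
               method = "Welch two-sided t-test of VAF distributions",
               n = length(vafsA) + length(vafsB),
               extra = list(meanA = mean(vafsA), meanB = mean(vafsB)))
}
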