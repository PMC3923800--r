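reg6 <- paste0("t", 1:6)

test_that("mixture classes label unordered type pairs lexicographically", {
    tab <- mixtureClassTable(reg6)
    expect_identical(tab$mclass, LETTERS[1:15])
    expect_identical(tab$typeA[1], "t1")
    expect_identical(tab$typeB[1], "t2")
    expect_identical(unname(mixtureClass("t1", "t2", reg6)), "A")
    expect_identical(unname(mixtureClass("t4", "t5", reg6)), "M")
    expect_identical(unname(mixtureClass("t5", "t6", reg6)), "O")
    expect_identical(mixtureClass("t6", "t5", reg6),
                     mixtureClass("t5", "t6", reg6))
    # every table row agrees with the direct mapping, both argument orders
    for (k in seq_len(nrow(tab))) {
        expect_identical(unname(mixtureClass(tab$typeA[k], tab$typeB[k], reg6)),
                         tab$mclass[k])
        expect_identical(unname(mixtureClass(tab$typeB[k], tab$typeA[k], reg6)),
                         tab$mclass[k])
    }
    expect_error(mixtureClass("t3", "t3", reg6), "distinct")
    expect_error(mixtureClass("t1", "zz", reg6), "registry")
    expect_identical(classTypes("A", reg6), c("t1", "t2"))
    expect_identical(classTypes("O", reg6), c("t5", "t6"))
})

test_that("mixture enumeration matches combinatorial counts", {
    counts <- c(2L, 3L, 2L, 4L, 1L, 2L)
    rs <- generateReactions(counts = counts, seed = 5)
    ms <- enumerateMixtures(rs)
    types <- reactionTypes(rs)
    expect_identical(length(ms), brutePairCount(types))
    # per-class counts are products of the type sizes
    tab <- table(factor(mixtureClasses(ms), levels = LETTERS[1:15]))
    expect_identical(unname(tab[["A"]]), counts[1] * counts[2])
    expect_identical(unname(tab[["O"]]), counts[5] * counts[6])
    expect_identical(sum(tab), length(ms))
    # every record's class matches its constituent types
    man <- manifest(ms)
    expect_identical(man$mclass,
                     unname(mixtureClass(man$typeA, man$typeB,
                                         typeLevels(ms))))
    # no same-type pairs, no duplicated unordered pairs
    expect_true(all(man$typeA != man$typeB))
    expect_false(anyDuplicated(paste(pmin(man$rxnA, man$rxnB),
                                     pmax(man$rxnA, man$rxnB))) > 0)
    # a single type yields no mixtures
    expect_identical(length(enumerateMixtures(rs[types == "CC.CO.2p2"])), 0L)
})

test_that("mixture descriptors implement NORM * (RATIO * A + B)", {
    mkUnit <- function(bin) {
        v <- numeric(120); v[bin] <- 1
        new("BinnedSpectrum", values = v, lo = 0, hi = 12, binWidth = 0.1)
    }
    a <- mkUnit(30); b <- mkUnit(55)
    out <- binValues(mixtureDescriptor(a, b, ratio = 2, norm = 0.5))
    expect_equal(out[30], 1.0)
    expect_equal(out[55], 0.5)
    expect_equal(sum(out != 0), 2)
    expect_equal(binValues(mixtureDescriptor(a, b)),
                 binValues(a) + binValues(b))
    # commutative at unit ratio
    expect_equal(binValues(mixtureDescriptor(a, b)),
                 binValues(mixtureDescriptor(b, a)))
    zero <- mkUnit(1); zero@values[1] <- 0
    expect_true(all(binValues(mixtureDescriptor(zero, zero, 5, 0.3)) == 0))
    # the enumerated descriptors equal the sum of the reaction descriptors
    rs <- tinyReactionSet()
    ms <- enumerateMixtures(rs)
    D <- descriptorMatrix(rs)
    man <- manifest(ms)
    expect_equal(descriptors(ms),
                 D[man$rxnA, , drop = FALSE] + D[man$rxnB, , drop = FALSE],
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mixture-level partition is disjoint, exhaustive and seeded", {
    ms <- enumerateMixtures(tinyReactionSet())
    p <- partitionMixtures(ms, trainSize = 40, seed = 21)
    expect_identical(length(p$train), 40L)
    expect_identical(length(p$test), length(ms) - 40L)
    expect_length(intersect(manifest(p$train)$id, manifest(p$test)$id), 0)
    expect_setequal(c(manifest(p$train)$id, manifest(p$test)$id),
                    manifest(ms)$id)
    p2 <- partitionMixtures(ms, trainSize = 40, seed = 21)
    expect_identical(manifest(p$train)$id, manifest(p2$train)$id)
    # singleton test set at the boundary
    p3 <- partitionMixtures(ms, trainSize = length(ms) - 1, seed = 1)
    expect_identical(length(p3$test), 1L)
    expect_error(partitionMixtures(ms, trainSize = length(ms)), "between")
    expect_error(partitionMixtures(ms, trainSize = 0), "between")
})

test_that("reaction-level partition never shares a reaction across sides", {
    counts <- c(3, 4, 3, 5, 2, 3)
    rs <- generateReactions(counts = counts, seed = 31)
    trainCounts <- c(2L, 3L, 2L, 4L, 1L, 2L)
    p <- partitionReactions(rs, trainCounts, seed = 8)
    expect_length(intersect(p$trainIds, p$testIds), 0)
    expect_setequal(c(p$trainIds, p$testIds), reactionIds(rs))
    # mixtures are enumerated within each side only
    trainRxns <- unique(c(manifest(p$train)$rxnA, manifest(p$train)$rxnB))
    testRxns <- unique(c(manifest(p$test)$rxnA, manifest(p$test)$rxnB))
    expect_true(all(trainRxns %in% p$trainIds))
    expect_true(all(testRxns %in% p$testIds))
    expect_identical(length(p$train),
                     brutePairCount(reactionTypes(rs)[match(p$trainIds,
                                                            reactionIds(rs))]))
    expect_identical(unname(table(factor(mixtureClasses(p$train),
                                         levels = LETTERS[1:15]))[["A"]]),
                     trainCounts[1] * trainCounts[2])
    # a type with zero test reactions is absent from all test mixtures
    pAll <- partitionReactions(rs, c(3, 3, 3, 5, 2, 3), seed = 9)
    testTypes <- unique(c(manifest(pAll$test)$typeA,
                          manifest(pAll$test)$typeB))
    expect_false(typeLevels(rs)[1] %in% testTypes)
    expect_error(partitionReactions(rs, c(4, 3, 2, 4, 1, 2), seed = 1),
                 "type sizes")
})

test_that("perturbation batteries expand and sample as specified", {
    ms <- enumerateMixtures(tinyReactionSet())
    n <- length(ms)
    # fixed RATIO values: one record per (mixture, ratio)
    pm <- perturbMixtures(ms, ratios = c(2, 5))
    expect_identical(length(pm), 2L * n)
    expect_setequal(unique(manifest(pm)$ratio), c(2, 5))
    # descriptors obey the mixture formula
    man <- manifest(pm)
    D <- ms@rxnDescriptors
    expect_equal(descriptors(pm),
                 man$norm * (man$ratio * man$yieldA * D[man$rxnA, ] +
                             man$yieldB * D[man$rxnB, ]),
                 ignore_attr = TRUE, tolerance = 1e-12)
    # degenerate ranges reproduce the input descriptors
    pd <- perturbMixtures(ms, yieldRange = c(1, 1), normRange = c(1, 1),
                          ratioRange = c(1, 1), replicates = 1, seed = 5)
    expect_equal(unname(descriptors(pd)), unname(descriptors(ms)),
                 tolerance = 1e-12)
    # sampled ranges stay inside their bounds and are reproducible
    ps <- perturbMixtures(ms, yieldRange = c(0.5, 1), normRange = c(0.2, 1),
                          ratioRange = c(1, 4), replicates = 2, seed = 6)
    expect_identical(length(ps), 2L * n)
    man <- manifest(ps)
    expect_true(all(man$yieldA >= 0.5 & man$yieldA <= 1))
    expect_true(all(man$yieldB >= 0.5 & man$yieldB <= 1))
    expect_true(all(man$norm >= 0.2 & man$norm <= 1))
    expect_true(all(man$ratio >= 1 & man$ratio <= 4))
    ps2 <- perturbMixtures(ms, yieldRange = c(0.5, 1), normRange = c(0.2, 1),
                           ratioRange = c(1, 4), replicates = 2, seed = 6)
    expect_identical(descriptors(ps), descriptors(ps2))
    expect_error(perturbMixtures(ms), "battery")
})
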