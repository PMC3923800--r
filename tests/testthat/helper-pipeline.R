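# Full synthetic benchmark pipeline at CI scale, computed once and cached
# for the acceptance tests.  Study conditions: the default generator
# (per-type counts 20/31/20/73/10/27, drift 0.15 ppm) at seed 42; an
# 8280/4141 mixture-level split; a 7578-style reaction-level split with
# per-type training counts 16/23/16/56/8/21; a 300-tree forest; a 25x25
# toroidal SOM ensemble of five trained on a 2000-mixture subsample
# (>= 2 objects per neuron) for 50 cycles.
.pipelineCache <- new.env(parent = emptyenv())

benchmarkPipeline <- function() {
    if (!is.null(.pipelineCache$res)) return(.pipelineCache$res)

    rs <- generateReactions(seed = 42)
    ms <- enumerateMixtures(rs)
    p1 <- partitionMixtures(ms, trainSize = 8280, seed = 101)
    rf <- trainRF(descriptors(p1$train), mixtureClasses(p1$train),
                  nTrees = 300, seed = 102)
    predP1 <- rfPredict(rf, descriptors(p1$test))
    accP1 <- mixtureAccuracy(predP1$predicted, mixtureClasses(p1$test))

    p2 <- partitionReactions(rs, c(16, 23, 16, 56, 8, 21), seed = 103)
    rf2 <- trainRF(descriptors(p2$train), mixtureClasses(p2$train),
                   nTrees = 300, seed = 104)
    predP2 <- rfPredict(rf2, descriptors(p2$test))
    accP2 <- mixtureAccuracy(predP2$predicted, mixtureClasses(p2$test))

    sub <- withr::with_seed(105, sample.int(length(p1$train), 2000))
    somX <- descriptors(p1$train)[sub, ]
    somCls <- mixtureClasses(p1$train)[sub]
    ens <- suppressWarnings(
        somEnsemble(somX, somCls, nModels = 5, rows = 25, cols = 25,
                    epochs = 50, seed = 106))
    somVotes <- ensembleClassify(ens, descriptors(p1$test))
    somAcc <- mixtureAccuracy(somVotes, mixtureClasses(p1$test))

    yrand <- yRandomize(descriptors(p1$train), mixtureClasses(p1$train),
                        descriptors(p1$test), mixtureClasses(p1$test),
                        nRepeats = 5, nTrees = 100, seed = 107)

    battery <- runBattery(rf, p1$test, yields = c(0.7, 0.8, 0.9, 1),
                          ratios = c(1, 2, 5), normRange = c(0.2, 1),
                          seed = 108)

    # probability stratification on the fully randomized battery (yields
    # 50-100%, NORM 0.2-1, RATIO 1-4, two replicates -> 8282 records),
    # where vote probabilities spread over the whole range
    pert <- perturbMixtures(p1$test, yieldRange = c(0.5, 1),
                            normRange = c(0.2, 1), ratioRange = c(1, 4),
                            replicates = 2, seed = 109)
    predPert <- rfPredict(rf, descriptors(pert))
    reliab <- reliabilityTable(predPert, mixtureClasses(pert),
                               thresholds = c(0, 0.5, 0.6, 0.8))

    .pipelineCache$res <- list(
        rs = rs, ms = ms, p1 = p1, p2 = p2, rf = rf, rf2 = rf2,
        predP1 = predP1, accP1 = accP1, predP2 = predP2, accP2 = accP2,
        somAcc = somAcc, yrand = yrand, battery = battery, reliab = reliab)
    .pipelineCache$res
}
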