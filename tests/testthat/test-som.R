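test_that("toroidal distance wraps around both axes", {
    expect_identical(toroidalDistance(c(1, 1), c(49, 49), 49, 49), 1L)
    expect_identical(toroidalDistance(c(1, 1), c(25, 25), 49, 49), 24L)
    expect_identical(toroidalDistance(c(7, 3), c(7, 3), 49, 49), 0L)
    expect_identical(toroidalDistance(c(1, 5), c(2, 5), 49, 49), 1L)
    expect_error(toroidalDistance(c(0, 1), c(1, 1), 49, 49), "grid")
    expect_error(toroidalDistance(c(1, 1), c(50, 1), 49, 49), "grid")
})

test_that("toroidal neighbourhoods contain (2d+1)^2 neurons regardless of centre", {
    grid <- as.matrix(expand.grid(row = 1:49, col = 1:49))
    for (centre in list(c(1, 1), c(25, 25), c(49, 3))) {
        for (d in c(1L, 5L, 24L)) {
            within <- sum(apply(grid, 1, function(q)
                toroidalDistance(centre, q, 49, 49)) <= d)
            expect_identical(within, as.integer((2L * d + 1L)^2))
        }
    }
})

test_that("findWinner agrees with a brute-force scan and breaks ties low", {
    set.seed(77)
    W <- matrix(rnorm(25 * 8), 25, 8)
    for (k in seq_len(200)) {
        x <- rnorm(8)
        expect_identical(findWinner(W, x), bruteWinner(W, x))
    }
    # a vector equal to one neuron's weights wins there
    expect_identical(findWinner(W, W[17, ]), 17L)
    # exact duplicate neurons: smallest row-major index wins
    W2 <- W; W2[20, ] <- W2[4, ]
    expect_identical(findWinner(W2, W2[20, ]), 4L)
    expect_error(findWinner(W, rnorm(5)), "dimension")
})

test_that("weights initialize from per-variable mean and sd", {
    set.seed(12)
    x <- cbind(rnorm(300, 5, 2), rnorm(300, -1, 0.5), rep(3.25, 300))
    # lr0 = 0 freezes training, exposing the initialization
    m <- trainSOM(x, rows = 10, cols = 10, epochs = 5, lr0 = 0, seed = 42)
    W <- m@weights
    # constant column stays constant at the column value
    expect_true(all(W[, 3] == 3.25))
    nn <- nrow(W)
    for (j in 1:2) {
        expect_lt(abs(mean(W[, j]) - mean(x[, j])),
                  3 * sd(x[, j]) / sqrt(nn))
    }
    # epochs do not affect the initialization when lr0 = 0
    m2 <- trainSOM(x, rows = 10, cols = 10, epochs = 50, lr0 = 0, seed = 42)
    expect_identical(m@weights, m2@weights)
})

test_that("training is bitwise deterministic under a fixed seed", {
    set.seed(1); x <- matrix(rnorm(60 * 6), 60, 6)
    a <- trainSOM(x, rows = 4, cols = 5, epochs = 12, seed = 7)
    b <- trainSOM(x, rows = 4, cols = 5, epochs = 12, seed = 7)
    expect_identical(a@weights, b@weights)
    c <- trainSOM(x, rows = 4, cols = 5, epochs = 12, seed = 8)
    expect_false(identical(a@weights, c@weights))
})

test_that("winners contract toward their training points", {
    # two well-separated points; initialization spreads weights over the
    # pooled mean/sd, so each point's winner must move strictly closer
    set.seed(3)
    x <- rbind(rnorm(6, -5, 0.1), rnorm(6, 5, 0.1))
    m <- suppressWarnings(
        trainSOM(x, rows = 3, cols = 3, epochs = 100, lr0 = 0.5, seed = 9))
    init <- suppressWarnings(
        trainSOM(x, rows = 3, cols = 3, epochs = 100, lr0 = 0, seed = 9))
    for (i in 1:2) {
        xi <- x[rep(i, 9), ]
        dTrained <- min(sqrt(rowSums((m@weights - xi)^2)))
        dInit <- min(sqrt(rowSums((init@weights - xi)^2)))
        expect_lt(dTrained, dInit)
        expect_lt(dTrained, 0.1)
    }
})

test_that("well-separated clusters map to disjoint neuron sets", {
    set.seed(5)
    x <- rbind(matrix(rnorm(80, 0, 0.3), 40, 2),
               matrix(rnorm(80, 8, 0.3), 40, 2))
    # fewer than two objects per neuron triggers the map-size advisory
    expect_warning(m <- trainSOM(x, rows = 7, cols = 7, epochs = 30,
                                 seed = 13),
                   "two objects per neuron")
    w <- findWinner(m@weights, x)
    expect_length(intersect(unique(w[1:40]), unique(w[41:80])), 0)
})

test_that("neuron labeling partitions the grid into empty/label/conflict", {
    set.seed(6)
    x <- matrix(rnorm(30 * 4), 30, 4)
    m <- trainSOM(x, rows = 3, cols = 3, epochs = 15, seed = 2)
    # all one class: every non-empty neuron gets it, no conflicts
    m1 <- labelNeurons(m, x, rep("G", 30))
    lm <- m1@labelMap
    expect_identical(nrow(lm), 9L)
    expect_false(any(lm$status == "conflict"))
    expect_true(all(lm$label[lm$status == "label"] == "G"))
    expect_identical(sum(lm$status == "empty") + sum(lm$status == "label") +
                     sum(lm$status == "conflict"), 9L)
    # duplicate vectors with different classes force a conflict; an exact
    # tie leaves the whole map without a defined label, which is flagged
    xd <- rbind(x[1, ], x[1, ])
    expect_warning(m2 <- labelNeurons(m, xd, c("G", "N")), "defined label")
    w <- findWinner(m2@weights, x[1, , drop = FALSE])
    expect_identical(m2@labelMap$status[w], "conflict")
    # exact two-way tie -> no defined label -> undecided classification
    expect_true(is.na(m2@labelMap$label[w]))
})

test_that("classification follows label, plurality and nearest-neighbour rules", {
    # hand-crafted 2 x 3 map with far-apart neurons
    W <- rbind(c(0, 0), c(10, 0), c(20, 0),
               c(0, 10), c(10, 10), c(20, 10))
    m <- new("SOMModel", weights = W, rows = 2L, cols = 3L, config = list())
    # neuron 1: pure class A; neuron 2: conflict with plurality G (3 G, 1 N)
    xTrain <- rbind(c(0, 0),
                    c(10, 0), c(10, 0), c(10, 0), c(10, 0))
    m <- labelNeurons(m, xTrain, c("A", "G", "G", "G", "N"))
    expect_identical(m@labelMap$status[1:2], c("label", "conflict"))
    expect_identical(m@labelMap$label[2], "G")
    expect_identical(somClassify(m, c(0.1, 0)), "A")
    expect_identical(somClassify(m, c(10.1, 0)), "G")
    # empty winner falls back to the nearest defined neuron (torus metric):
    # neuron 3 is at distance 1 from both neurons 1 and 2 (cols wrap), so
    # the smaller row-major index (1 -> class A) wins the tie
    expect_identical(somClassify(m, c(20, 0)), "A")
    expect_error(somClassify(trainSOM(matrix(rnorm(20), 10, 2), rows = 2,
                                      cols = 2, epochs = 2, seed = 1),
                             c(0, 0)),
                 "label")
})

test_that("ensembles decide by plurality with undecided votes excluded", {
    expect_identical(majorityVote(c("A", "A", "B", NA, "A")), "A")
    expect_identical(majorityVote(c("A", "B")), NA_character_)
    expect_identical(majorityVote(c(NA_character_, NA_character_)),
                     NA_character_)
    votes <- rbind(c("A", "B"), c("A", "B"), c("C", "B"))
    expect_identical(majorityVote(votes), c("A", "B"))
    # an ensemble of identical models votes like any single member
    set.seed(8)
    x <- matrix(rnorm(40 * 3), 40, 3)
    cls <- rep(c("A", "B"), each = 20)
    m <- trainSOM(x, rows = 3, cols = 3, epochs = 10, seed = 4)
    m <- labelNeurons(m, x, cls)
    expect_identical(ensembleClassify(list(m, m, m), x), somClassify(m, x))
})

test_that("som ensembles train reproducibly from a master seed", {
    set.seed(10)
    x <- matrix(rnorm(50 * 4), 50, 4)
    cls <- rep(c("A", "B"), 25)
    e1 <- somEnsemble(x, cls, nModels = 3, rows = 3, cols = 3, epochs = 8,
                      seed = 99)
    e2 <- somEnsemble(x, cls, nModels = 3, rows = 3, cols = 3, epochs = 8,
                      seed = 99)
    expect_identical(lapply(e1, slot, "weights"), lapply(e2, slot, "weights"))
    # members differ from one another
    expect_false(identical(e1[[1]]@weights, e1[[2]]@weights))
})
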