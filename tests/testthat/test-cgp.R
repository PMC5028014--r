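# CGP genome: decode, protected evaluation, mutation, evolution, and the
# exported expression.

test_that("an output wired to an input has an empty active set", {
  g <- makeGenome(list(), output = 0)
  expect_length(activeNodes(g), 0)
  expect_equal(evaluateGenome(g, c(7.5, rep(0, 9))), 7.5)
})

test_that("a single add node is the whole active set", {
  g <- makeGenome(list(list("+", 0, 1)), output = 10)
  expect_equal(activeNodes(g), 0L)
  expect_equal(evaluateGenome(g, c(2, 3, rep(0, 8))), 5)
})

test_that("protected semantics: division by zero and logical coercion", {
  gdiv <- makeGenome(list(list("/", 0, 1)), output = 10)
  expect_equal(evaluateGenome(gdiv, c(5, 0, rep(0, 8))), 1)
  expect_equal(evaluateGenome(gdiv, c(6, 3, rep(0, 8))), 2)
  gnand <- makeGenome(list(list("NAND", 0, 1)), output = 10)
  expect_equal(evaluateGenome(gnand, c(2, -1, rep(0, 8))), 1)
  expect_equal(evaluateGenome(gnand, c(2, 1, rep(0, 8))), 0)
  gsqrt <- makeGenome(list(list("SQRT", 0, 0)), output = 10)
  expect_equal(evaluateGenome(gsqrt, c(-9, rep(0, 9))), 3)
})

test_that("decode matches brute-force reachability on random genomes", {
  set.seed(101)
  for (i in 1:50) {
    g <- randomGenome(10, 70)
    expect_identical(activeNodes(g), bruteActiveNodes(g))
  }
})

test_that("evaluate agrees with the full-graph interpreter", {
  set.seed(202)
  for (i in 1:40) {
    g <- randomGenome(10, 70)
    X <- matrix(runif(10 * 10, -5, 5), 10)
    got <- evaluateGenome(g, X)
    want <- apply(X, 1, function(x) bruteEvaluateCGP(g, x))
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("evaluation is total on adversarial magnitudes", {
  set.seed(303)
  for (i in 1:20) {
    g <- randomGenome(10, 70)
    x <- runif(10, -1e90, 1e90)
    expect_true(is.finite(evaluateGenome(g, x)))
  }
  expect_error(evaluateGenome(randomGenome(10, 70), c(Inf, rep(0, 9))),
               "finite")
})

test_that("mutation at rate 0 is the identity; at rate 1 stays valid", {
  set.seed(9)
  g <- randomGenome(10, 70)
  m0 <- mutateGenome(g, 0)
  expect_identical(m0@funcGene, g@funcGene)
  expect_identical(m0@connGene, g@connGene)
  expect_identical(m0@outputGene, g@outputGene)
  for (i in 1:10) expect_no_error(validObject(mutateGenome(g, 1)))
  # the input genome is never modified in place
  snapshot <- list(g@funcGene, g@connGene, g@outputGene)
  invisible(mutateGenome(g, 1))
  expect_identical(list(g@funcGene, g@connGene, g@outputGene), snapshot)
})

test_that("per-gene change rate matches the resampling-collision expectation", {
  set.seed(42)
  g <- randomGenome(10, 70)
  ni <- 10; nc <- 70
  ranges <- c(rbind(14,
                    vapply(0:(nc - 1), function(k) ni + min(k, nc), numeric(1)),
                    vapply(0:(nc - 1), function(k) ni + min(k, nc), numeric(1))),
              ni + nc)
  expected <- mean(0.01 * (1 - 1 / ranges))
  frac <- replicate(10000, {
    m <- mutateGenome(g, 0.01)
    (sum(m@funcGene != g@funcGene) + sum(m@connGene != g@connGene) +
        (m@outputGene != g@outputGene)) / 211
  })
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - expected), 3 * se)
})

test_that("fitness counts threshold agreements", {
  one <- makeGenome(list(list("CONST1", 0, 0)), output = 10)
  X <- matrix(runif(40), 4)
  expect_equal(cgpFitness(one, X, rep("pos", 4), "pos"), 1)
  expect_equal(cgpFitness(one, X, c("pos", "pos", "neg", "neg"), "pos"), 0.5)
  ident <- makeGenome(list(), output = 0)
  labs <- ifelse(X[, 1] > 0.5, "hi", "lo")
  expect_equal(cgpFitness(ident, X, labs, "hi", threshold = 0.5), 1)
})

test_that("evolution solves a separable table and its trace never decreases", {
  tab <- generateFeatureTable(trendTableConfig(sd = 0, nPerClass = 6,
                                               seed = 2))
  fit <- evolveClassifier(tab, evolutionParams(generations = 2000, seed = 3))
  expect_equal(fit$fitness, 1)
  expect_false(is.unsorted(fit$trace))
  expect_equal(classifierAccuracy(fit$classifier, tab), 1)
})

test_that("a one-class table is solved immediately", {
  tab <- generateFeatureTable(trendTableConfig(sd = 0.1, nPerClass = 6,
                                               seed = 4))
  tab <- tab[tab$label == "PPADS", ]
  fit <- evolveClassifier(tab, evolutionParams(generations = 100, seed = 1))
  expect_equal(fit$fitness, 1)
  expect_lte(fit$generations, 100)
})

test_that("evolution is reproducible for a fixed seed", {
  tab <- generateFeatureTable(trendTableConfig(sd = 0.3, nPerClass = 6,
                                               seed = 8))
  p <- evolutionParams(generations = 150, seed = 99)
  a <- evolveClassifier(tab, p); b <- evolveClassifier(tab, p)
  expect_identical(a$classifier@genome@funcGene, b$classifier@genome@funcGene)
  expect_identical(a$classifier@genome@connGene, b$classifier@genome@connGene)
  expect_identical(a$classifier@genome@outputGene,
                   b$classifier@genome@outputGene)
  expect_identical(a$trace, b$trace)
})

test_that("expression export: examples and used-input bookkeeping", {
  expect_equal(toExpression(makeGenome(list(), output = 0))$expression,
               "avg_migration_speed")
  expect_equal(toExpression(makeGenome(list(), output = 0))$used_inputs, 0L)
  g <- makeGenome(list(list("*", 1, 2), list("+", 0, 10)), output = 11)
  ex <- toExpression(g)
  expect_equal(ex$expression,
               "(avg_migration_speed + (post_contact_speed * in_contact_speed))")
  expect_equal(ex$used_inputs, 0:2)
})

test_that("exported expressions round-trip through evaluation", {
  set.seed(404)
  for (i in 1:30) {
    g <- randomGenome(10, 70)
    ex <- toExpression(g)
    X <- as.data.frame(matrix(runif(10 * 10, -3, 3), 10))
    names(X) <- featureNames()
    expect_lt(max(abs(evalExpression(ex$expression, X) -
                        evaluateGenome(g, X))), 1e-9)
  }
})

test_that("perturbing an unused input never changes the output", {
  set.seed(505)
  for (i in 1:20) {
    g <- randomGenome(10, 70)
    ex <- toExpression(g)
    unused <- setdiff(0:9, ex$used_inputs)
    if (!length(unused)) next
    x <- runif(10, -2, 2)
    y <- x
    y[unused + 1] <- runif(length(unused), -100, 100)
    expect_identical(evaluateGenome(g, x), evaluateGenome(g, y))
  }
})

test_that("classifier JSON serialization round-trips", {
  tab <- generateFeatureTable(trendTableConfig(sd = 0.2, nPerClass = 5,
                                               seed = 10))
  fit <- evolveClassifier(tab, evolutionParams(generations = 50, seed = 7))
  path <- tempfile(fileext = ".json")
  writeClassifier(fit$classifier, path)
  back <- readClassifier(path)
  expect_identical(back@genome@funcGene, fit$classifier@genome@funcGene)
  expect_identical(back@genome@connGene, fit$classifier@genome@connGene)
  expect_identical(back@genome@outputGene, fit$classifier@genome@outputGene)
  expect_equal(back@rangeMin, fit$classifier@rangeMin)
  expect_equal(predict(back, tab), predict(fit$classifier, tab))
})
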