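test_that("newick parsing checks structure and measures path lengths", {
  tree <- readNewickTree("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tree), 3)
  depths <- ape::node.depth.edgelength(tree)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- readNewickTree(f)
  expect_identical(ape::write.tree(back), ape::write.tree(tree))
  expect_error(readNewickTree("((A,B),C);"), "branch length")
  expect_warning(readNewickTree("((A:1,B:1.5):1,C:2);"), "ultrametric")
})

test_that("the BM covariance is the shared-path matrix", {
  tree <- readNewickTree("((A:1,B:1):1,C:2);")
  C <- bmCov(tree)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  star <- readNewickTree("(A:1,B:1,C:1,D:1);")
  expect_equal(unname(bmCov(star)), diag(4))
  ev <- eigen(bmCov(tree), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("the lambda transform rescales exactly the off-diagonal", {
  C <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(lambdaTransform(C, 1), C)
  expect_equal(lambdaTransform(C, 0), diag(diag(C)))
  half <- lambdaTransform(C, 0.5)
  expect_equal(half[1, 2], 0.5)
  expect_equal(diag(half), diag(C))
  expect_error(lambdaTransform(C, 1.2), "\\[0, 1\\]")
})

test_that("the continuous lambda fit maximizes over a dense grid", {
  set.seed(41)
  tree <- ape::rcoal(20)
  x <- simBM(tree, mean = 3)
  fit <- fitLambdaContinuous(tree, x)
  C <- bmCov(tree)
  X <- matrix(1, 20, 1)
  grid <- vapply(seq(0, 1, length.out = 1001), function(l)
    ctcount:::.profileLogLik(C, l, X, as.numeric(x[tree$tip.label]))$logL,
    numeric(1))
  expect_gte(fit$logL, max(grid) - 1e-6)
  expect_gte(fit$logL, max(fit$logL0, fit$logL1) - 1e-6)
  expect_error(fitLambdaContinuous(tree, setNames(rep(1, 20),
                                                  tree$tip.label)),
               "variance")
})

test_that("lambda and its likelihood agree with an independent package", {
  library(phytools)
  set.seed(43)
  tree <- ape::rcoal(30)
  x <- simBM(tree, mean = 5)
  fit <- fitLambdaContinuous(tree, x)
  ps <- phytools::phylosig(tree, x, method = "lambda")
  ## phytools allows lambda slightly above 1; compare at the shared bound
  expect_equal(fit$logL1, unname(ps$lik(1)), tolerance = 1e-6)
  expect_equal(fit$logL0, unname(ps$lik(0)), tolerance = 1e-6)
  expect_lt(abs(fit$lambda - min(ps$lambda, 1)), 0.02)
})

test_that("likelihoods are invariant to tip permutation", {
  set.seed(47)
  tree <- ape::rcoal(12)
  x <- simBM(tree)
  perm <- sample(names(x))
  expect_equal(fitLambdaContinuous(tree, x)$logL,
               fitLambdaContinuous(tree, x[perm])$logL)
})

test_that("the two-tip symmetric model matches its closed form", {
  tree <- readNewickTree("(A:1.5,B:1.5);")
  states <- c(A = 0, B = 1)
  for (q in c(0.05, 0.3, 1)) {
    ## switch probability along each branch, summed over the root state
    pSwitch <- (1 - exp(-2 * q * 1.5)) / 2
    pStay <- 1 - pSwitch
    manual <- log(0.5 * (pStay * pSwitch + pSwitch * pStay))
    expect_equal(ctcount:::.pruneLogLik(tree, states[tree$tip.label], q),
                 manual, tolerance = 1e-12)
  }
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(53)
  for (n in c(4, 5, 6)) {
    tree <- ape::rcoal(n)
    states <- sample(0:1, n, replace = TRUE)
    while (length(unique(states)) < 2) states <- sample(0:1, n, TRUE)
    names(states) <- tree$tip.label
    for (q in c(0.1, 0.7, 2)) {
      expect_equal(ctcount:::.pruneLogLik(tree, states[tree$tip.label], q),
                   refMkLogLik(tree, states[tree$tip.label], q),
                   tolerance = 1e-10)
    }
  }
})

test_that("the symmetric rate fit behaves at its limits", {
  set.seed(59)
  tree <- ape::rcoal(8)
  states <- setNames(c(rep(0, 4), rep(1, 4)), tree$tip.label)
  fit <- fitDiscreteSym(tree, states)
  expect_gt(fit$q, 0)
  ## fitted rate is the likelihood maximum on a log-spaced grid
  grid <- vapply(exp(seq(log(1e-4), log(50), length.out = 400)), function(q)
    ctcount:::.pruneLogLik(tree, states[tree$tip.label], q), numeric(1))
  expect_gte(fit$logL, max(grid) - 1e-4)
  expect_error(fitDiscreteSym(tree, setNames(rep(1, 8), tree$tip.label)),
               "single state")
  joint <- fitDiscreteSym(tree, states, lambda = TRUE)
  expect_true(joint$lambda >= 0 && joint$lambda <= 1)
  expect_gte(joint$logL, fit$logL - 1e-6)
})

test_that("PGLS with lambda 0 is ordinary least squares exactly", {
  set.seed(61)
  tree <- ape::rcoal(25)
  d <- data.frame(species = tree$tip.label,
                  y = as.numeric(simBM(tree)), z = rnorm(25))
  pgfit <- pgls(y ~ z, d, tree, lambda = 0)
  ols <- lm(y ~ z, d)
  expect_equal(pgfit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(pgfit$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(pgfit$coefficients$p,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-10)
})

test_that("PGLS matches gls with a fixed Pagel correlation", {
  library(nlme)
  set.seed(67)
  tree <- ape::rcoal(20)
  d <- data.frame(species = tree$tip.label,
                  y = as.numeric(simBM(tree)) + rnorm(20, 0, 0.3),
                  z = rnorm(20))
  for (lam in c(0.4, 1)) {
    mine <- pgls(y ~ z, d, tree, lambda = lam)
    ref <- nlme::gls(y ~ z, data = d,
                     correlation = ape::corPagel(lam, tree, fixed = TRUE,
                                                 form = ~ species))
    expect_equal(mine$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
  }
})

test_that("shifting the response moves only the PGLS intercept", {
  set.seed(71)
  tree <- ape::rcoal(15)
  d <- data.frame(species = tree$tip.label,
                  y = as.numeric(simBM(tree)), z = rnorm(15))
  f1 <- pgls(y ~ z, d, tree, lambda = 0.7)
  d$y <- d$y + 10
  f2 <- pgls(y ~ z, d, tree, lambda = 0.7)
  expect_equal(f2$coefficients$estimate[1],
               f1$coefficients$estimate[1] + 10, tolerance = 1e-8)
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2],
               tolerance = 1e-8)
})
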