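test_that("Euclidean distance matrices follow the definition", {
  d <- euclideanDM(c(0, 3, 4))
  expect_equal(unname(d), rbind(c(0, 3, 4), c(3, 0, 1), c(4, 1, 0)))
  expect_equal(unname(euclideanDM(c(2, 2, 2))), matrix(0, 3, 3))
  two <- euclideanDM(rbind(c(0, 0), c(3, 4)))
  expect_equal(two[1, 2], 5)              # sqrt(3^2 + 4^2)
  expect_error(euclideanDM(c(1, NA)), "finite")
})

test_that("univariate pseudo-F equals the classical ANOVA F", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(12:30, 1)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    while (nlevels(droplevels(g)) < 2) g <- factor(sample(letters[1:3], n, TRUE))
    y <- rnorm(n, as.integer(g))
    fit <- permanova(euclideanDM(y), ~ g, data.frame(g = g), permutations = 0)
    ref <- anova(lm(y ~ g))
    expect_equal(fit$table$pseudoF[1], ref$`F value`[1], tolerance = 1e-12)
    expect_equal(fit$table$df[1:2], ref$Df)
    expect_equal(sum(fit$table$R2[1:2]), 1)
  }
})

test_that("sequential two-factor partitioning matches vegan's adonis2", {
  library(vegan)
  set.seed(5)
  n <- 36
  df <- data.frame(g = factor(rep(letters[1:3], each = 12)),
                   p = factor(rep(c("b", "m", "t"), 12)))
  y <- rnorm(n) + as.integer(df$g) + 0.5 * as.integer(df$p)
  fit <- permanova(euclideanDM(y), ~ g * p, df, permutations = 99, seed = 1)
  ref <- adonis2(dist(y) ~ g * p, data = df, permutations = 99, by = "terms")
  expect_equal(fit$table$SS[1:4], ref$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(fit$table$pseudoF[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(fit$table$R2[1:4], ref$R2[1:4], tolerance = 1e-10)
})

test_that("permutation p-values are seeded, bounded and flag degeneracy", {
  set.seed(8)
  y <- rnorm(20); g <- factor(rep(1:2, each = 10))
  a <- permanova(euclideanDM(y), ~ g, data.frame(g = g),
                 permutations = 199, seed = 10)
  b <- permanova(euclideanDM(y), ~ g, data.frame(g = g),
                 permutations = 199, seed = 10)
  expect_identical(a$table$p, b$table$p)
  expect_gte(a$table$p[1], 1 / 200)
  const <- rep(3, 10)
  expect_warning(z <- permanova(euclideanDM(const), ~ g,
                                data.frame(g = factor(rep(1:2, 5))),
                                permutations = 9), "identical")
  expect_true(z$undefined)
})

test_that("post hoc pairs use Bonferroni arithmetic over all level pairs", {
  set.seed(13)
  g <- factor(rep(letters[1:3], each = 8))
  y <- rnorm(24) + c(0, 0, 3)[as.integer(g)]
  ph <- permanovaPosthoc(euclideanDM(y), g, permutations = 199, seed = 2)
  expect_equal(nrow(ph$table), 3)
  expect_equal(ph$table$pAdj, pmin(1, ph$table$p * 3))
  expect_setequal(names(ph$letters), letters[1:3])
  ## the separated level c carries its own letter
  expect_false(ph$letters["c"] %in% ph$letters[c("a", "b")])
})

test_that("exact MWW agrees with complete enumeration for small samples", {
  set.seed(17)
  for (n1 in 1:4) for (n2 in n1:(10 - n1)) {
    x <- sample(1:50, n1); y <- sample(51:100, n2) - sample(0:60, n2, TRUE)
    while (anyDuplicated(c(x, y))) y <- y + runif(n2)
    got <- mwwExact(x, y)
    ref <- refMWW(x, y)
    expect_equal(got$Uxy, ref$Uxy)
    expect_equal(got$p, ref$p, tolerance = 1e-12,
                 label = sprintf("p at n1=%d n2=%d", n1, n2))
    expect_true(got$exact)
    expect_gte(got$W, 0); expect_lte(got$W, n1 * n2)
  }
})

test_that("MWW handles identical samples and matches wilcox.test tails", {
  tied <- mwwExact(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$exact)
  expect_equal(tied$p, 1)
  set.seed(23)
  x <- rnorm(5); y <- rnorm(7) + 2
  got <- mwwExact(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(got$Uxy, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("the regression F test matches the textbook formula", {
  x <- c(1, 2, 3, 4); y <- c(2.1, 3.9, 6.2, 7.8)
  got <- olsF(x, y)
  ## hand computation: SS_reg / (SS_res / (n - 2))
  fit <- lm(y ~ x)
  ssres <- sum(resid(fit)^2)
  ssreg <- sum((fitted(fit) - mean(y))^2)
  expect_equal(got$F, ssreg / (ssres / 2), tolerance = 1e-12)
  expect_equal(got$df1, 1); expect_equal(got$df2, 2)
  expect_equal(got$r2, ssreg / (ssreg + ssres), tolerance = 1e-12)
  perfect <- suppressWarnings(olsF(1:5, 2 * (1:5) + 3))
  expect_equal(perfect$r2, 1)
  expect_lt(perfect$p, 1e-10)
  expect_error(olsF(rep(1, 5), rnorm(5)), "constant")
})

test_that("group summaries are row-order invariant with SE = sd/sqrt(N)", {
  tab <- generateFlowerTable(seed = 3)
  gs <- groupSummary(tab)
  expect_equal(nrow(gs), 8)
  one <- tab[tab$species == gs$species[1], ]
  expect_equal(gs$pollenMean[1], mean(one$pollen))
  expect_equal(gs$pollenSE[1], sd(one$pollen) / sqrt(nrow(one)))
  expect_equal(gs$poVar[1], var(one$po))
  shuffled <- groupSummary(tab[sample(nrow(tab)), ])
  expect_equal(shuffled, gs)
})

test_that("strategy summaries weight species means by sample size", {
  ## single-species strategy: weighted mean equals the species mean
  df <- data.frame(species = c("x", "y"), strategy = c("rewarding", "deceptive"),
                   N = c(4, 6), ovuleMean = c(1000, 2000),
                   ovuleSE = c(10, 20), poVar = c(100, 25))
  ss <- strategySummary(df, traits = "ovule")
  expect_equal(ss$byStrategy$rewarding$ovuleMean, 1000)
  expect_equal(ss$byStrategy$deceptive$ovuleMean, 2000)
  expect_equal(ss$poVarRatio, 4)
  ## two species of one strategy: hand-computed weights
  df2 <- data.frame(species = c("x", "y"), strategy = "deceptive",
                    N = c(4, 12), ovuleMean = c(1000, 2000),
                    ovuleSE = c(10, 20))
  ss2 <- strategySummary(df2, traits = "ovule")
  expect_equal(ss2$byStrategy$deceptive$ovuleMean,
               (4 * 1000 + 12 * 2000) / 16)
  expect_equal(ss2$byStrategy$deceptive$ovuleSE,
               sqrt((4 / 16)^2 * 100 + (12 / 16)^2 * 400))
})
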