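test_that("forward pass recovers a pure hinge signal exactly", {
  x <- seq(0, 1, length.out = 41)   # includes 0.5 as a data value
  X <- cbind(x = x)
  y <- 2 * pmax(0, x - 0.5)
  fw <- mars_forward(X, y, max_bases = 4)
  expect_identical(fw$terms[[2]]$knots, 0.5)
  expect_lt(tail(fw$rss_trace, 1), 1e-20)
})

test_that("constant response yields the intercept-only model", {
  X <- matrix(rnorm(60), 20, 3)
  fw <- mars_forward(X, rep(2.5, 20), max_bases = 6)
  expect_identical(length(fw$terms), 1L)
  m <- mars_backward(fw, X, rep(2.5, 20))
  expect_equal(unname(predict(m, X)), rep(2.5, 20))
})

test_that("only the informative variable is selected among distractors", {
  set.seed(51)
  X <- matrix(rnorm(100 * 10), 100, 10)
  y <- 3 * pmax(0, X[, 1] - 0.2)
  fw <- mars_forward(X, y, max_bases = 6)
  vars <- unique(unlist(lapply(fw$terms[-1], `[[`, "vars")))
  expect_identical(vars, 1L)
})

test_that("forward RSS decreases strictly at every accepted step", {
  set.seed(52)
  X <- matrix(rnorm(200), 50, 4)
  y <- pmax(0, X[, 2]) - 0.5 * pmax(0, -X[, 3]) + rnorm(50, sd = 0.1)
  fw <- mars_forward(X, y, max_bases = 10)
  expect_true(all(diff(fw$rss_trace) < 0))
})

test_that("backward pruning drops pure-noise bases and respects GCV", {
  set.seed(53)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- rnorm(50)
  fw <- mars_forward(X, y, max_bases = 10)
  m <- mars_backward(fw, X, y)
  full_gcv <- snoRoR:::.gcv_score(tail(fw$rss_trace, 1), 50,
                                  length(fw$terms),
                                  snoRoR:::.n_knots(fw$terms), 2)
  expect_lte(m$gcv, full_gcv)
  expect_lte(length(m$terms) - 1, 2)

  # noise-free hinge signal survives pruning
  xg <- seq(-1, 1, length.out = 41)   # grid contains the knot 0.1
  Xg <- cbind(xg)
  yg <- pmax(0, xg - 0.1)
  mg <- mars_fit(Xg, yg, max_bases = 8)
  expect_true(any(vapply(mg$terms, function(t) length(t$vars) > 0 &&
                           isTRUE(all.equal(t$knots, 0.1)), logical(1))))
  expect_lt(mg$rss, 1e-18)
})

test_that("additive models have additive predictions", {
  set.seed(54)
  X <- matrix(rnorm(200), 50, 4)
  y <- pmax(0, X[, 1]) + pmax(0, X[, 2] - 0.5) + rnorm(50, sd = 0.05)
  m <- mars_fit(X, y, max_bases = 8, max_interaction = 1)
  new1 <- X; new1[, 1] <- X[, 1] + 1
  delta <- predict(m, new1) - predict(m, X)
  # shifting x1 changes predictions by an amount independent of x2..x4
  X2 <- X; X2[, 2:4] <- X2[, 2:4] * 2 + 1
  new2 <- X2; new2[, 1] <- X2[, 1] + 1
  expect_equal(predict(m, new2) - predict(m, X2), delta, tolerance = 1e-10)
})

test_that("variable importance scales the top variable to 100", {
  x <- seq(0, 1, length.out = 30)
  X <- cbind(a = x, b = rev(x))
  y <- 4 * pmax(0, x - 0.4)
  m <- mars_fit(X, y, max_bases = 6)
  expect_equal(unname(m$importance["a"]), 100)
  expect_equal(unname(m$importance["b"]), 0)

  set.seed(55)
  Xn <- matrix(rnorm(40 * 3), 40, 3)
  mn <- mars_fit(Xn, rnorm(40), max_bases = 8)
  if (length(mn$terms) == 1) expect_true(all(mn$importance == 0))
})

test_that("equal independent effects receive symmetric importance on average", {
  set.seed(56)
  scores <- t(replicate(50, {
    X <- matrix(rnorm(240), 120, 2)
    y <- pmax(0, X[, 1]) + pmax(0, X[, 2]) + rnorm(120, sd = 0.1)
    mars_fit(X, y, max_bases = 8)$importance
  }))
  expect_lt(abs(mean(scores[, 1]) - mean(scores[, 2])), 20)
  expect_gt(min(colMeans(scores)), 50)
})

test_that("knot location is recovered under mild noise", {
  set.seed(57)
  err <- replicate(100, {
    x <- sort(runif(200))
    y <- pmax(0, x - 0.5) + rnorm(200, sd = 0.01)
    fw <- mars_forward(cbind(x), y, max_bases = 2)
    abs(fw$terms[[2]]$knots - 0.5)
  })
  # knot localized to within twice the noise SD in nearly all runs
  expect_gte(mean(err <= 0.02), 0.95)
  expect_lt(median(err), 0.01)
})

test_that("AUC equals the pairwise concordance oracle, with ties half-counted", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(1:10, rep(c(0, 1), each = 5))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)

  auc_oracle <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(58)
  for (n in c(5, 20, 73, 200)) {
    s <- round(rnorm(n), 1)          # coarse scores force ties
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
    expect_equal(roc_auc(s, l)$auc, auc_oracle(s, l))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(59)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  base <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, base)
  expect_equal(roc_auc(rank(s), l)$auc, base)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(60)
  s <- rnorm(80); l <- rbinom(80, 1, 0.5)
  if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, l)$auc,
               as.numeric(suppressMessages(pROC::auc(l, s))))
})

test_that("ROC polyline is monotone from (0,0) to (1,1)", {
  set.seed(61)
  r <- roc_auc(rnorm(40), rep(c(0, 1), 20))
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("validation schemes behave at the two extremes", {
  set.seed(62)
  X <- rbind(matrix(rnorm(100, 0), 20, 5), matrix(rnorm(100, 3), 20, 5))
  y <- rep(c(0, 1), each = 20)
  v <- mars_validate(X, y, "cv10", seed = 3, max_bases = 6)
  expect_equal(v$auc_train, 1.0)
  expect_gt(v$auc_test, 0.9)
  v80 <- mars_validate(X, y, "split80_20", seed = 3, max_bases = 6)
  expect_equal(v80$auc_train, 1.0)

  # permuted labels: test AUC hovers at chance
  yp <- sample(y)
  vp <- mars_validate(X, yp, "cv10", seed = 4, max_bases = 6)
  expect_lt(abs(vp$auc_test - 0.5), 0.2)

  # reproducibility from the seed
  v2 <- mars_validate(X, y, "cv10", seed = 3, max_bases = 6)
  expect_identical(v$test_scores, v2$test_scores)
  expect_error(mars_validate(X[1:6, ], y[c(1:3, 21:23)][1:6], "cv10"),
               ">= 5 samples")
})
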