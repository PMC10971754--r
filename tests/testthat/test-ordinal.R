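test_that("multicollinearity screen keeps the standard candidate order", {
  set.seed(1)
  n <- 50
  rec <- data.frame(total_nodes = rnorm(n), total_edges = rnorm(n),
                    pos_neg_ratio = rnorm(n),
                    average_path_length = rnorm(n), modularity = rnorm(n),
                    average_degree = rnorm(n), heterogeneity = rnorm(n),
                    clustering_coefficient = rnorm(n),
                    positive_edges = rnorm(n), negative_edges = rnorm(n))
  keep <- multicollinearity_screen(rec)
  # independent noise: all eight candidates retained, in the fixed order;
  # sign-specific edge counts excluded a priori
  expect_equal(as.character(keep),
               c("total_nodes", "total_edges", "pos_neg_ratio",
                 "average_path_length", "modularity", "average_degree",
                 "heterogeneity", "clustering_coefficient"))
  # duplicated column: the later one is dropped
  rec2 <- rec
  rec2$average_degree <- rec2$total_edges
  keep2 <- multicollinearity_screen(rec2)
  expect_false("average_degree" %in% keep2)
  expect_true("total_edges" %in% keep2)
  # constant features are dropped up front
  rec3 <- rec
  rec3$modularity <- 1
  expect_false("modularity" %in% multicollinearity_screen(rec3))
})

test_that("cutpoint-only fits equal the empirical cumulative logits", {
  y <- factor(rep(c("Q1", "Q2", "Q3", "Q4"), times = c(10, 20, 30, 40)),
              ordered = TRUE)
  fit <- polr_fit(data.frame(row.names = seq_along(y)), y)
  expect_equal(fit$theta, qlogis(c(0.1, 0.3, 0.6)), tolerance = 1e-5)
  expect_equal(length(fit$coefficients), 0)
  # AIC identity
  expect_equal(fit$AIC, 2 * 3 - 2 * fit$logLik)
})

test_that("two categories reduce to binary logistic regression", {
  set.seed(7)
  n <- 400
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  eta <- 0.8 * X[, 1] - 0.4 * X[, 2]
  y01 <- rbinom(n, 1, plogis(eta - 0.3))
  y <- factor(ifelse(y01 == 1, "hi", "lo"), levels = c("lo", "hi"),
              ordered = TRUE)
  fit <- polr_fit(X, y)
  glm_fit <- glm(y01 ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(glm_fit)[2:3]),
               tolerance = 1e-4)
  expect_equal(unname(fit$theta), unname(-coef(glm_fit)[1]),
               tolerance = 1e-4)
  expect_equal(unname(fit$se),
               unname(summary(glm_fit)$coefficients[2:3, 2]),
               tolerance = 1e-3)
})

test_that("fits agree with the reference implementation", {
  skip_if_not_installed("MASS")
  d <- generate_topology_table(500, beta = c(1, -0.5), theta = c(-1, 0, 1),
                               seed = 3)
  fit <- polr_fit(d$X, d$y)
  mf <- MASS::polr(d$y ~ d$X, Hess = TRUE)
  expect_equal(unname(fit$coefficients), unname(coef(mf)), tolerance = 1e-4)
  expect_equal(unname(fit$theta), unname(mf$zeta), tolerance = 1e-4)
  expect_equal(fit$AIC, AIC(mf), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(mf)))[1:2]), tolerance = 1e-3)
})

test_that("coefficients are recovered and probabilities coherent", {
  d <- generate_topology_table(4000, beta = c(1, -0.5),
                               theta = c(-1.5, 0, 1.5), seed = 9)
  fit <- polr_fit(d$X, d$y)
  expect_lt(max(abs(fit$coefficients - c(1, -0.5))), 0.15)
  # likelihood at the estimate beats the empirical-logit start
  start_ll <- -kelpnet:::polr_nll(c(0, 0, fit$theta * 0 +
                                      qlogis(cumsum(table(d$y))[1:3] / 4000)),
                                  scale(d$X), as.integer(d$y), 4)
  expect_gte(fit$logLik, start_ll)
  # cell probabilities sum to one and are non-negative at random x
  th <- fit$theta
  for (i in 1:5) {
    x <- rnorm(2)
    cum <- c(plogis(th - sum(x * fit$coefficients)), 1)
    cell <- diff(c(0, cum))
    expect_true(all(cell >= 0))
    expect_equal(sum(cell), 1)
  }
  # missing rows are dropped and counted
  Xna <- d$X; Xna[1:7, 1] <- NA
  fit2 <- polr_fit(Xna, d$y)
  expect_equal(fit2$n_dropped, 7)
})

test_that("subset selection finds the informative feature", {
  hits_best <- 0L; agree <- 0L; null_sizes <- integer(0)
  for (s in 1:20) {
    d <- generate_topology_table(400, beta = c(1.2, 0, 0),
                                 theta = c(-1, 0, 1), seed = 100 + s)
    bs <- best_subset(d$X, d$y)
    st <- stepwise_aic(d$X, d$y)
    if ("f1" %in% bs) hits_best <- hits_best + 1L
    if (setequal(bs, st)) agree <- agree + 1L
    # all-noise case
    d0 <- generate_topology_table(400, beta = c(0, 0, 0),
                                  theta = c(-1, 0, 1), seed = 200 + s)
    null_sizes <- c(null_sizes, length(best_subset(d0$X, d0$y)))
  }
  expect_gte(hits_best, 18L)         # scaled from >= 90/100 seeds
  expect_gte(agree, 11L)             # majority agreement with stepwise
  expect_lte(median(null_sizes), 2)  # null sets stay small

  # single feature kept iff it beats the intercept-only model
  d1 <- generate_topology_table(400, beta = 1.5, theta = c(-1, 0, 1),
                                seed = 5)
  expect_equal(as.character(best_subset(d1$X[, 1, drop = FALSE], d1$y)),
               "f1")
  d0 <- generate_topology_table(400, beta = 0, theta = c(-1, 0, 1),
                                seed = 6)
  expect_equal(length(best_subset(d0$X[, 1, drop = FALSE], d0$y)), 0)

  # stepwise is deterministic and empty X gives the empty set
  expect_identical(stepwise_aic(d1$X, d1$y), stepwise_aic(d1$X, d1$y))
  expect_equal(length(stepwise_aic(d1$X[, 0, drop = FALSE], d1$y)), 0)
})

test_that("reconciliation prefers equality, then simplicity, then AIC", {
  expect_equal(reconcile(c("a", "b"), c("b", "a")), c("a", "b"))
  expect_equal(reconcile(c("a", "b", "c"), "a"), "a")
  # size tie broken by AIC
  sa <- structure("a", AIC = 100)
  sb <- structure("b", AIC = 90)
  expect_equal(as.character(reconcile(sa, sb)), "b")
})

test_that("odds ratios convert to the published fold interpretations", {
  # reciprocal rule for values below one
  r <- interpret_odds_ratio(5.73e-1)
  expect_equal(r$direction, "less")
  expect_equal(r$fold, 1.75)
  r2 <- interpret_odds_ratio(2.46e-8)
  expect_equal(r2$direction, "less")
  expect_equal(r2$fold, 4.07e7)
  expect_equal(interpret_odds_ratio(1.0), list(direction = "more", fold = 1))
  expect_equal(interpret_odds_ratio(3.52e3)$fold, 3520)
  expect_error(interpret_odds_ratio(0))
  expect_error(interpret_odds_ratio(-2))
})
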