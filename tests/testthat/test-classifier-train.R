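test_that("the internal logistic solver agrees with stats::glm", {
  set.seed(401)
  for (i in 1:10) {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0)))
    fit <- scnpdx:::logit_fit(X, y)
    ref <- glm(y ~ X, family = binomial())
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
  }
})

test_that("prescreen recovers a planted node and reports provenance", {
  set.seed(402)
  hits <- replicate(20, {
    n <- 60
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("node", 1:6)
    y <- rbinom(n, 1, 0.5)
    X$node3 <- X$node3 + 1.6 * y          # strong planted signal
    pre <- prescreen_nodes(X, y, top_k = 3)
    "node3" %in% pre$candidates
  })
  expect_gte(mean(hits), 0.9)
  pre <- prescreen_nodes(data.frame(a = rnorm(40), b = rnorm(40)),
                         rep(0:1, 20), seed = 1)
  expect_true(all(c("univariate_p", "rf_rank", "provenance") %in%
                  names(pre$table)))
})

test_that("prescreen univariate false selections track the configured level", {
  set.seed(403)
  fp <- replicate(30, {
    X <- as.data.frame(matrix(rnorm(50 * 8), 50, 8))
    y <- rep(0:1, 25)
    sum(prescreen_nodes(X, y, alpha_level = 0.05, top_k = 2)$table$univariate_hit)
  })
  # 8 null nodes at level 0.05: expect ~0.4 hits per run
  expect_lt(mean(fp), 1.2)
})

test_that("prescreen drops all-missing nodes and is order invariant", {
  set.seed(404)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = NA_real_)
  y <- rep(0:1, 20)
  expect_message(pre <- prescreen_nodes(X, y, seed = 2), "all-missing")
  expect_false("c" %in% pre$table$feature)
  X2 <- data.frame(a = rnorm(60), b = rnorm(60), z = rnorm(60))
  y2 <- rbinom(60, 1, plogis(X2$a))
  s1 <- prescreen_nodes(X2, y2, seed = 7)$candidates
  s2 <- prescreen_nodes(X2[sample(60), ][order(1:60), ], y2, seed = 7)$candidates
  expect_setequal(s1, s2)
})

test_that("the penalized fit shrinks to zero under the null and recovers signal", {
  set.seed(405)
  null_sizes <- sapply(1:8, function(s) {
    X <- matrix(rnorm(80 * 5), 80, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- rbinom(80, 1, 0.5)
    length(fit_penalized_logistic(X, y, seed = s)$nonzero)
  })
  # outcome-independent features: the 1-SE penalty usually shrinks all to zero
  expect_gte(mean(null_sizes == 0), 0.5)
  expect_lt(mean(null_sizes), 1.5)
  set.seed(406)
  rec <- replicate(10, {
    X2 <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y2 <- rbinom(200, 1, plogis(2 * X2[, 2]))
    f <- fit_penalized_logistic(X2, y2)
    "v2" %in% f$nonzero && f$coefficients["v2"] > 0
  })
  expect_gte(mean(rec), 0.9)
  expect_error(fit_penalized_logistic(matrix(rnorm(40), 20), rep(1, 20)),
               "constant")
})

test_that("optimism adjustment is zero for a forced full-data bootstrap", {
  set.seed(406)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- rep(0:1, 30)
  r <- adjust_auroc_optimism(X, y, boot_indices = list(1:60))
  expect_equal(r$optimism, 0, tolerance = 1e-12)
  expect_equal(r$adjusted, r$apparent, tolerance = 1e-12)
})

test_that("optimism-adjusted AUROC is below apparent and near 0.5 on null data", {
  set.seed(407)
  res <- t(replicate(12, {
    X <- matrix(rnorm(80 * 3), 80, 3)
    y <- rep(0:1, 40)
    r <- adjust_auroc_optimism(X, y, B = 60)
    c(apparent = r$apparent, adjusted = r$adjusted)
  }))
  expect_gte(mean(res[, "adjusted"] <= res[, "apparent"]), 0.9)
  expect_lt(abs(mean(res[, "adjusted"]) - 0.5), 0.06)
})

test_that("OOB AUROC separates signal from null", {
  set.seed(408)
  n <- 100
  x <- c(rnorm(50, 2), rnorm(50))
  y <- rep(1:0, each = 50)
  r <- oob_auroc(matrix(x), y, B = 100)
  expect_gt(r$auroc, 0.85)
  r0 <- oob_auroc(matrix(rnorm(n)), sample(y), B = 100)
  expect_lt(abs(r0$auroc - 0.5), 0.15)
  expect_error(oob_auroc(matrix(x), y, B = 10), ">= 50")
})

test_that("combination enumeration covers all 2-to-4 subsets and ranks stably", {
  set.seed(409)
  X <- as.data.frame(matrix(rnorm(50 * 5), 50, 5))
  names(X) <- paste0("n", 1:5)
  y <- rbinom(50, 1, plogis(X$n1 - X$n2))
  r <- enumerate_combination_models(names(X), X, y, B = 10, seed = 5)
  expect_equal(nrow(r), choose(5, 2) + choose(5, 3) + choose(5, 4))
  r2 <- enumerate_combination_models(rev(names(X)), X, y, B = 10, seed = 5)
  expect_identical(r$model, r2$model)
  expect_true(all(diff(r$adjusted) <= 1e-12))
  expect_error(enumerate_combination_models("n1", X, y), "at least 2")
  expect_error(enumerate_combination_models(c("n1", "zz"), X, y), "unknown")
})

test_that("a planted two-node signal rises to the top of the ranking", {
  set.seed(410)
  top_hits <- replicate(10, {
    n <- 90
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- paste0("n", 1:6)
    y <- rbinom(n, 1, plogis(1.6 * X$n2 + 1.6 * X$n5))
    r <- enumerate_combination_models(names(X), X, y, B = 25)
    top <- strsplit(r$model[1], " + ", fixed = TRUE)[[1]]
    all(c("n2", "n5") %in% top)
  })
  expect_gte(mean(top_hits), 0.8)
})
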