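# Correlations, AUC, KM/log-rank, Cox, tertiles, contingency tests,
# Bonferroni.

test_that("Pearson helpers handle exact and degenerate cases", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearsonWithP(x, x)$rho, 1)
  expect_equal(pearsonWithP(x, -x)$rho, -1)
  expect_warning(r <- pearsonWithP(rep(1, 5), x), "zero variance")
  expect_true(is.na(r$rho))
  expect_error(pearsonWithP(1:2, 1:2), ">= 3")
  v1 <- make_fv(c(seg_001 = 1, seg_002 = 2, seg_003 = 3))
  v2 <- make_fv(c(seg_001 = 2, seg_002 = 4, seg_003 = 6))
  expect_equal(pairedProfileCorrelation(v1, v2)$rho, 1)
})

test_that("rank AUC matches its definition, symmetry and an external oracle", {
  expect_equal(rocAUC(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(rocAUC(-c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 0)
  # ties averaged: a constant score gives 0.5
  expect_equal(rocAUC(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(rocAUC(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(31)
  score <- rnorm(80)
  lab <- runif(80) < plogis(score)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(rocAUC(score, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                                direction = "<"))))
  }
  # Wilcoxon rank-sum normalization
  W <- wilcox.test(score[lab], score[!lab])$statistic
  expect_equal(rocAUC(score, lab), unname(W) / (sum(lab) * sum(!lab)))
})

test_that("labels independent of scores give AUC near one half", {
  set.seed(32)
  auc <- rocAUC(rnorm(2000), rep(c(TRUE, FALSE), 1000))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("KM estimator: no events, identical groups, no-censoring oracle", {
  km0 <- kmLogrank(times = c(1, 2, 3, 4), events = rep(0, 4),
                   groups = c("a", "a", "b", "b"))
  expect_true(all(km0$curves$surv == 1))
  expect_true(all(is.na(km0$median)))

  t2 <- rep(c(2, 4, 6, 8), 2)
  e2 <- rep(1, 8)
  g2 <- rep(c("a", "b"), each = 4)
  km2 <- kmLogrank(t2, e2, g2)
  expect_equal(km2$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(km2$logrank_p, 1, tolerance = 1e-10)

  # without censoring KM equals the empirical survival function
  set.seed(33)
  tt <- rexp(40)
  km <- kmLogrank(c(tt, tt + 10), rep(1, 80), rep(c("x", "y"), each = 40))
  cx <- km$curves[km$curves$group == "x", ]
  emp <- vapply(cx$time, function(u) mean(tt > u), numeric(1))
  expect_equal(cx$surv, emp)
})

test_that("log-rank p is invariant to group relabeling", {
  set.seed(34)
  tt <- rexp(60, rate = rep(c(0.5, 1, 2), each = 20))
  ev <- rbinom(60, 1, 0.8)
  g <- rep(c("a", "b", "c"), each = 20)
  p1 <- kmLogrank(tt, ev, g)$logrank_p
  relabel <- c(a = "z", b = "q", c = "m")
  p2 <- kmLogrank(tt, ev, relabel[g])$logrank_p
  expect_equal(p1, p2)
})

test_that("exponential groups with rate ratio 2 give a median ratio near 2", {
  set.seed(35)
  n <- 500
  tt <- c(rexp(n, 1), rexp(n, 0.5))
  km <- kmLogrank(tt, rep(1, 2 * n), rep(c("fast", "slow"), each = n))
  expect_equal(unname(km$median["slow"] / km$median["fast"]), 2,
               tolerance = 0.25)
  expect_lt(km$logrank_p, 1e-10)
})

test_that("Cox fits: null covariate, degenerate designs, CI bracketing", {
  set.seed(36)
  n <- 800
  x <- rnorm(n)
  tt <- rexp(n, 0.1)
  ev <- as.integer(tt < quantile(tt, 0.8))
  fit <- coxFit(tt, ev, data.frame(x = x))
  expect_equal(fit$status, "ok")
  hr <- fit$terms$hr[1]
  expect_lt(abs(log(hr)), 0.15)                     # HR near 1 under the null
  expect_true(fit$terms$ci_low[1] < hr && hr < fit$terms$ci_high[1])
  expect_gte(fit$n, fit$events)

  dup <- coxFit(tt, ev, data.frame(a = x, b = x))   # aliased covariate
  expect_equal(dup$status, "failed")
  const <- coxFit(tt, ev, data.frame(a = rep(1, n)))
  expect_equal(const$status, "failed")
  expect_error(coxFit(tt, rep(0, n), data.frame(x = x)), "at least one event")
})

test_that("tertiles: balanced split, frozen cutpoints, quantile recovery", {
  tg <- tertileGroups(1:9)
  expect_equal(as.vector(table(tg$labels)), c(3L, 3L, 3L))
  expect_equal(tg$cutpoints, unname(quantile(1:9, c(1, 2) / 3)))

  # frozen cutpoints applied to a new cohort keep their exact values
  new_scores <- c(-5, tg$cutpoints[1], 100)
  lab <- applyCutpoints(new_scores, tg$cutpoints)
  expect_equal(as.character(lab), c("low", "low", "high"))

  set.seed(37)
  tg2 <- tertileGroups(runif(3000))
  expect_equal(tg2$cutpoints, c(1 / 3, 2 / 3), tolerance = 0.03)
  expect_error(tertileGroups(rep(2, 10)), "distinct")
})

test_that("contingency tests follow the declared chi-square/Fisher rule", {
  r <- contingencyTest(matrix(c(10, 0, 0, 10), 2))
  expect_lt(r$p, 0.001)              # perfect association
  expect_equal(r$method, "chisq")    # expected cells exactly 5, not below
  r2 <- contingencyTest(matrix(c(50, 50, 50, 50), 2))
  expect_equal(r2$method, "chisq")
  expect_equal(r2$p, 1)
  # Fisher p equals exhaustive hypergeometric enumeration on a 2x2 table
  tab <- matrix(c(8, 1, 2, 9), 2)    # rows: groups, cols: outcome
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m1, k), m1, m2, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m1, m2, k) + 1e-12])
  r3 <- contingencyTest(tab)
  expect_equal(r3$method, "fisher")
  expect_equal(r3$p, p_oracle, tolerance = 1e-10)
  expect_error(contingencyTest(matrix(0, 2, 2)), "empty")
})

test_that("group rates and Bonferroni behave as printed", {
  gr <- groupRates(c("a", "a", "b", "b", "b"), c(1, 0, 1, 1, NA))
  expect_equal(gr$rate[gr$group == "a"], 0.5)
  expect_equal(gr$n[gr$group == "b"], 2L)
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni(1.5), "\\[0, 1\\]")
})
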