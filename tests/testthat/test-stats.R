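test_that("paired t matches the textbook formula and handles degeneracy", {
  expect_equal(paired_t(1:5, 1:5)$statistic, 0)
  expect_equal(paired_t(1:5, 1:5)$p, 1)
  expect_equal(paired_t(1:5, 1:5)$effect_sizes$cohens_d, 0)
  # zero mean difference with nonzero variance
  x <- c(1, 2, 3, 4); y <- c(0, 3, 2, 5)
  expect_equal(paired_t(x, y)$statistic, 0)
  # direct-formula oracle on a random fixture
  set.seed(15)
  a <- rnorm(15, 1, 2); b <- rnorm(15)
  res <- paired_t(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(15))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 14)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 14), tolerance = 1e-10)
  expect_equal(res$effect_sizes$cohens_d, mean(d) / sd(d), tolerance = 1e-10)
  # constant nonzero difference: degenerate flag, no exception
  deg <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.infinite(deg$statistic))
})

test_that("a two-level within factor reproduces F = t^2 exactly", {
  set.seed(20)
  for (i in 1:10) {
    Y <- cbind(rnorm(12, 1), rnorm(12))
    colnames(Y) <- c("a", "b")
    Fres <- rm_anova(Y)[[1]]
    tres <- paired_t(Y[, 1], Y[, 2])
    expect_equal(Fres$statistic, tres$statistic^2, tolerance = 1e-9)
    expect_equal(Fres$p, tres$p, tolerance = 1e-9)
  }
})

test_that("one-way RM-ANOVA equals a from-scratch sums-of-squares oracle", {
  # small fixture worked by explicit sums, not matrix shortcuts
  Y <- rbind(c(3, 5, 7), c(4, 4, 9), c(2, 6, 8))
  n <- 3; k <- 3
  g <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - g)^2)
  ss_subj <- k * sum((rowMeans(Y) - g)^2)
  ss_err <- sum((Y - outer(rowMeans(Y), rep(1, k)) -
                   outer(rep(1, n), colMeans(Y)) + g)^2)
  F_oracle <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  res <- rm_anova(Y, gg_rule = "never")[[1]]
  expect_equal(res$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(res$effect_sizes$eta_p2, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-12)
  expect_equal(res$effect_sizes$eta_g2,
               ss_cond / (ss_cond + ss_subj + ss_err), tolerance = 1e-12)
})

test_that("one-way RM-ANOVA agrees with the base aov error strata", {
  set.seed(30)
  n <- 10; k <- 4
  long <- expand.grid(subject = factor(1:n), condition = factor(1:k))
  long$value <- rnorm(n * k) + rep(rnorm(n), k) + rep(c(0, 0.4, 0.1, 0), each = n)
  fit <- summary(aov(value ~ condition + Error(subject / condition),
                     data = long))
  tab <- fit[["Error: subject:condition"]][[1]]
  res <- rm_anova(as.data.frame(long), dv = "value", subject = "subject",
                  within = "condition", gg_rule = "never")[[1]]
  expect_equal(res$statistic, tab[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p, tab[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("two-way RM-ANOVA agrees with aov on every stratum", {
  set.seed(41)
  n <- 8
  long <- expand.grid(subject = factor(1:n), A = factor(1:3), B = factor(1:2))
  long$value <- rnorm(nrow(long)) + rep(rnorm(n), 6) +
    as.numeric(long$A) * 0.3 + (long$A == 2 & long$B == 1) * 0.5
  fit <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = long))
  res <- rm_anova(as.data.frame(long), dv = "value", subject = "subject",
                  within = c("A", "B"), gg_rule = "never")
  expect_equal(res[[1]]$statistic,
               fit[["Error: subject:A"]][[1]][["F value"]][1],
               tolerance = 1e-9)
  expect_equal(res[[2]]$statistic,
               fit[["Error: subject:B"]][[1]][["F value"]][1],
               tolerance = 1e-9)
  expect_equal(res[[3]]$statistic,
               fit[["Error: subject:A:B"]][[1]][["F value"]][1],
               tolerance = 1e-9)
})

test_that("generalized eta squared never exceeds partial eta squared", {
  set.seed(52)
  for (i in 1:20) {
    Y <- matrix(rnorm(12 * 3), 12, 3) + rnorm(12)  # subject variance > 0
    res <- rm_anova(Y)[[1]]
    expect_lte(res$effect_sizes$eta_g2, res$effect_sizes$eta_p2)
  }
})

test_that("rm_anova rejects unbalanced designs", {
  long <- expand.grid(participant_id = 1:4, condition = c("a", "b", "c"))
  long$value <- rnorm(12)
  expect_error(rm_anova(long[-1, ], within = "condition"), "balanced")
})

test_that("Mauchly/GG match base R and the eigenvalue oracle", {
  # k = 2: a single contrast, sphericity trivially satisfied
  res2 <- mauchly_gg(cbind(rnorm(8), rnorm(8)))
  expect_equal(res2$W, 1)
  expect_equal(res2$epsilon, 1)
  # compound symmetry: W = 1, epsilon = 1
  set.seed(61)
  z <- rnorm(2000)
  Ycs <- sapply(1:4, function(j) z + rnorm(2000))
  mcs <- mauchly_gg(Ycs)
  expect_equal(mcs$W, 1, tolerance = 0.01)
  expect_equal(mcs$epsilon, 1, tolerance = 0.01)
  # strong AR(1) structure: epsilon < 1, matching a direct eigen oracle
  set.seed(62)
  n <- 20; k <- 4; rho <- 0.9
  Sigma <- rho^abs(outer(1:k, 1:k, "-"))
  L <- chol(Sigma)
  Y <- matrix(rnorm(n * k), n, k) %*% L
  res <- mauchly_gg(Y)
  expect_lt(res$epsilon, 1)
  C <- simbias:::orthonormal_contrasts(k)
  lam <- eigen(t(C) %*% cov(Y) %*% C, symmetric = TRUE)$values
  eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  expect_equal(res$epsilon, eps_oracle, tolerance = 1e-10)
  # base R cross-check of the W statistic and p value
  mt <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(res$W, unname(mt$statistic), tolerance = 1e-8)
  # base R's second-order Box term uses the raw dimension in one
  # coefficient where this implementation uses the contrast dimension
  # throughout; the p values agree to well under a percent
  expect_equal(res$p, mt$p.value, tolerance = 2e-3)
})

test_that("GG correction shrinks degrees of freedom when applied", {
  set.seed(63)
  n <- 14; k <- 4
  Sigma <- 0.95^abs(outer(1:k, 1:k, "-")) * c(1, 2, 4, 8)
  Y <- matrix(rnorm(n * k), n, k) %*% chol(Sigma)
  res <- rm_anova(Y, gg_rule = "always")[[1]]
  expect_true(res$corrected)
  eps <- res$sphericity$epsilon
  expect_true(eps > 1 / (k - 1) && eps < 1)
  expect_equal(res$df, c((k - 1) * eps, (n - 1) * (k - 1) * eps))
})

test_that("Bonferroni adjustment is capped, monotone, and complete", {
  set.seed(70)
  Y <- matrix(rnorm(10 * 4), 10, 4,
              dimnames = list(NULL, c("AO", "MI", "AO+MI", "IMIT")))
  pw <- bonferroni_pairwise(Y)
  expect_equal(nrow(pw), choose(4, 2))
  expect_equal(pw$p_adj, pmin(1, pw$p * 6))
  expect_true(all(pw$p_adj >= pw$p))
  # adjusted p is monotone in raw p (ties from the cap at 1 allowed)
  expect_true(all(diff(pw$p_adj[order(pw$p)]) >= -1e-15))
  # worked examples of the cap
  expect_equal(min(1, 0.01 * 3), 0.03)
  expect_equal(min(1, 0.5 * 3), 1.0)
  # agreement with p.adjust's bonferroni on the same raw p values
  expect_equal(pw$p_adj, unname(p.adjust(pw$p, "bonferroni")))
})

test_that("eta-squared/f conversions are exact and invertible", {
  expect_equal(eta_to_f(0.5), 1.0)
  expect_equal(eta_to_f(0), 0)
  expect_equal(eta_to_f(0.6), sqrt(0.6 / 0.4), tolerance = 1e-12)
  expect_equal(eta_to_f(0.6), 1.224745, tolerance = 1e-6)
  expect_equal(f_to_eta(1.0), 0.5)
  for (e in c(0.1, 0.3, 0.6, 0.9)) {
    expect_equal(f_to_eta(eta_to_f(e)), e, tolerance = 1e-12)
  }
  expect_error(eta_to_f(1), "\\[0, 1\\)")
})

test_that("noncentral-F power behaves like a power function", {
  # null effect: power equals alpha for any n
  for (n in c(3, 10, 50)) {
    expect_equal(rm_power(0, n), 0.05, tolerance = 1e-10)
  }
  # strictly increasing in n at fixed effect
  pw <- sapply(2:10, function(n) rm_power(1.2, n))
  expect_true(all(diff(pw) > 0))
  # required_n is minimal: power(n-1) < target <= power(n)
  for (f in c(0.5, 0.8, 1.2)) {
    n_req <- required_n(f, target_power = 0.8)
    expect_gte(rm_power(f, n_req), 0.8)
    if (n_req > 2) expect_lt(rm_power(f, n_req - 1), 0.8)
  }
  expect_error(required_n(1e-8, n_max = 100), "unreachable")
})

test_that("the one-way RM-ANOVA keeps its nominal size under the null", {
  # reduced-size calibration (the 10,000-replicate version is in the
  # acceptance suite): iid normal responses, 14 subjects x 4 conditions
  set.seed(80)
  rej <- mean(replicate(600, {
    rm_anova(matrix(rnorm(14 * 4), 14, 4))[[1]]$p < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.08)
})
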