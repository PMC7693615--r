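test_that("Greenhouse-Geisser epsilon: closed forms and oracle agreement", {
  # compound symmetry -> exactly 1
  S <- matrix(0.3, 4, 4)
  diag(S) <- 1
  expect_equal(gg_epsilon(S), 1)
  # k = 2: lower bound equals upper bound
  expect_equal(gg_epsilon(matrix(c(1, 0.1, 0.1, 2), 2)), 1)
  # random PSD matrices: double-centered formula agrees with the
  # orthonormal-contrast eigenvalue formula (independent derivation)
  set.seed(12)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A)
    C <- t(contr.helmert(k))
    C <- C / sqrt(rowSums(C^2))
    St <- C %*% S %*% t(C)
    ev <- eigen(St, symmetric = TRUE, only.values = TRUE)$values
    oracle <- max(1 / (k - 1), min(1, sum(ev)^2 / ((k - 1) * sum(ev^2))))
    expect_equal(gg_epsilon(S), oracle, tolerance = 1e-10)
  }
  expect_error(gg_epsilon(matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("toy mixed design reproduces the hand-computed partition", {
  # 2 groups x 2 subjects x 2 times; EG subjects (1,2), CG subjects (1,1)
  d <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("EG", "EG", "CG", "CG"), each = 2),
    time = rep(c("t1", "t2"), 4),
    y = c(1, 2, 1, 2, 1, 1, 1, 1)
  )
  res <- mixed_rm_anova(d, "y", "subject", "group", "time")
  ss <- setNames(res$SS, res$effect)
  # hand-computed sums of squares: grand mean 1.25, all effects 0.5
  expect_equal(unname(ss["group"]), 0.5)
  expect_equal(unname(ss["time"]), 0.5)
  expect_equal(unname(ss["group:time"]), 0.5)
  # both error strata are exactly zero -> degenerate flags
  expect_true(all(res$SS_err < 1e-12))
  expect_true(all(res$degenerate))
  # a 2-level within factor forces epsilon = 1
  expect_true(all(res$epsilon == 1))
})

test_that("mixed ANOVA agrees with an independent multivariate-route oracle", {
  set.seed(5)
  d <- simulate_rcs_cohort(seed = 5)
  res <- mixed_rm_anova(d, "rcs", "participant", "group", "time_point")
  wide <- reshape(d, idvar = c("participant", "group"),
                  timevar = "time_point", direction = "wide")
  Y <- as.matrix(wide[, paste0("rcs.", levels(d$time_point))])
  fit <- lm(Y ~ group, data = wide)
  idata <- data.frame(time = factor(levels(d$time_point),
                                    levels = levels(d$time_point)))
  s <- suppressWarnings(summary(car::Anova(fit, idata = idata,
                                           idesign = ~time, type = 2),
                                multivariate = FALSE))
  tab <- s$univariate.tests
  adj <- s$pval.adjustments
  for (pair in list(c("group", "group"), c("time_point", "time"),
                    c("group:time_point", "group:time"))) {
    i <- which(res$effect == pair[1])
    expect_equal(res$F[i], tab[pair[2], "F value"], tolerance = 1e-8)
    expect_equal(res$p[i], tab[pair[2], "Pr(>F)"], tolerance = 1e-8)
  }
  expect_equal(res$epsilon[res$effect == "time_point"],
               unname(adj["time", "GG eps"]), tolerance = 1e-10)
  expect_equal(res$p_gg[res$effect == "time_point"],
               unname(adj["time", "Pr(>F[GG])"]), tolerance = 1e-8)
  # SS decomposition is exhaustive on the balanced design
  total_ss <- sum((d$rcs - mean(d$rcs))^2)
  strata_ss <- sum(res$SS) + sum(unique(res$SS_err))
  expect_equal(strata_ss, total_ss, tolerance = 1e-8)
  # effect sizes and p-values stay in range
  expect_true(all(res$ges >= 0 & res$ges <= 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("three-within-factor ANOVA runs and keeps epsilon bounds", {
  set.seed(33)
  subj <- sprintf("P%02d", 1:12)
  d <- expand.grid(participant = subj, time = paste0("t", 1:4),
                   region = c("frontal", "parietal"),
                   hemisphere = c("left", "right"))
  d$group <- ifelse(d$participant %in% subj[1:6], "eg", "cg")
  d$y <- rnorm(nrow(d))
  res <- mixed_rm_anova(d, "y", "participant", "group",
                        c("time", "region", "hemisphere"))
  expect_equal(nrow(res), 15) # 2^4 factor crossings minus the intercept
  k4 <- res$effect %in% c("time", "group:time")
  expect_true(all(res$epsilon[k4] >= 1 / 3 & res$epsilon[k4] <= 1))
  expect_true(all(res$epsilon[res$effect %in%
                                c("region", "hemisphere",
                                  "group:region", "group:hemisphere")] == 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("planned contrasts detect shifts and handle degenerate inputs", {
  d0 <- data.frame(participant = rep(1:10, 2), group = "eg",
                   time = rep(c("pre", "post15"), each = 10),
                   y = rep(rnorm(10), 2))
  ct0 <- planned_contrasts(d0, "y", "participant", "group", "time")
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)
  # constant shift with zero variance of differences -> flagged degenerate
  d1 <- d0
  d1$y[d1$time == "post15"] <- d1$y[d1$time == "post15"] + 1
  ct1 <- planned_contrasts(d1, "y", "participant", "group", "time")
  expect_true(ct1$degenerate)
  # Bonferroni adjustment is monotone and capped
  set.seed(3)
  d2 <- simulate_rcs_cohort(seed = 3)
  ct2 <- planned_contrasts(d2, "rcs", "participant", "group", "time_point")
  expect_equal(nrow(ct2), 6)
  expect_true(all(ct2$p_adj >= ct2$p))
  expect_true(all(ct2$p_adj <= 1))
  expect_equal(ct2$p_adj, pmin(1, 3 * ct2$p))
})

test_that("a Table-2-sized shift is detected in most replicates", {
  # experimental-group pre -> post15 shift of +0.19 RCS at n = 19, with the
  # published spread: adjusted-alpha power should be at least 80%
  set.seed(55)
  hits <- vapply(1:120, function(i) {
    d <- simulate_rcs_cohort(seed = 9000 + i)
    ct <- planned_contrasts(d, "rcs", "participant", "group", "time_point")
    ct$p_adj[ct$group == "experimental" & ct$contrast == "pre vs post15"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Welch pairwise comparisons match the closed-form oracle", {
  set.seed(44)
  d <- data.frame(participant = sprintf("P%03d", 1:100),
                  cellf = rep(c("a", "b"), each = 50),
                  y = c(rnorm(50, 0), rnorm(50, 1)))
  res <- welch_pairwise(d, "y", "participant", "cellf")
  x <- d$y[d$cellf == "a"]
  y <- d$y[d$cellf == "b"]
  se2 <- var(x) / 50 + var(y) / 50
  t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 50)^2 / 49 + (var(y) / 50)^2 / 49)
  expect_equal(res$t, t_oracle, tolerance = 1e-8)
  expect_equal(res$df, df_oracle, tolerance = 1e-8)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), df_oracle), tolerance = 1e-8)
  # k cells emit k(k-1)/2 comparisons
  d2 <- data.frame(participant = rep(sprintf("P%02d", 1:10), 4),
                   g = rep(c("a", "b", "c", "d"), each = 10), y = rnorm(40))
  expect_equal(nrow(welch_pairwise(d2, "y", "participant", "g")), 6)
  # identical cells -> t = 0; zero-variance cells flagged
  d3 <- data.frame(participant = 1:20, g = rep(c("a", "b"), each = 10),
                   y = rep(1, 20))
  r3 <- welch_pairwise(d3, "y", "participant", "g")
  expect_equal(r3$t, 0)
  expect_true(r3$degenerate)
})

test_that("forced-entry regression reports B, beta, fit and guards rank", {
  # perfect 3-point fit
  d <- data.frame(y = c(0, 1, 2), x = c(0, 1, 2))
  r <- suppressWarnings(forced_entry_regression(d, "y", "x"))
  expect_equal(r$coefficients$B[r$coefficients$term == "x"], 1)
  expect_equal(r$coefficients$B[r$coefficients$term == "(Intercept)"], 0,
               tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # exact linear response in several predictors
  set.seed(2)
  d2 <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d2$y <- 2 * d2$x1 - d2$x2 + 3
  r2 <- suppressWarnings(forced_entry_regression(d2, "y", c("x1", "x2")))
  expect_equal(r2$adj_r_squared, 1, tolerance = 1e-10)
  # beta equals B rescaled by the SD ratio, and adj R2 <= R2
  d2$y <- d2$y + rnorm(30)
  r3 <- forced_entry_regression(d2, "y", c("x1", "x2"))
  b1 <- r3$coefficients[r3$coefficients$term == "x1", ]
  expect_equal(b1$beta, b1$B * sd(d2$x1) / sd(d2$y), tolerance = 1e-10)
  expect_lte(r3$adj_r_squared, r3$r_squared)
  # collinear predictors produce a named error
  d2$x3 <- d2$x1
  expect_error(forced_entry_regression(d2, "y", c("x1", "x2", "x3")), "x3")
  expect_error(forced_entry_regression(d2[1:3, ], "y", c("x1", "x2")),
               "complete cases")
})

test_that("null regressions stay null and coefficients recover the truth", {
  set.seed(66)
  null_ok <- vapply(1:60, function(i) {
    d <- data.frame(matrix(rnorm(300 * 4), 300, 4))
    d$y <- rnorm(300)
    r <- forced_entry_regression(d, "y", paste0("X", 1:4))
    betas <- r$coefficients$beta[-1]
    all(abs(betas) < 0.2)
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
  # generating coefficients recovered within 2 Monte-Carlo SEs at n = 200
  reps <- t(vapply(1:40, function(i) {
    x <- rnorm(200)
    y <- 0.5 * x + rnorm(200)
    r <- forced_entry_regression(data.frame(x = x, y = y), "y", "x")
    r$coefficients$B[r$coefficients$term == "x"]
  }, numeric(1)))
  expect_lt(abs(mean(reps) - 0.5), 2 * sd(reps) / sqrt(length(reps)))
})
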