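test_that("zscore standardizes, is idempotent, rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(40, 5, 3)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 10)), "constant")
  # missing values propagate without shifting the moments of the rest
  xm <- c(x, NA)
  expect_true(is.na(zscore(xm)[41]))
})

test_that("summary-statistic t-test agrees with t.test on raw samples", {
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(12 + i, mean = i, sd = 1 + i / 3)
    b <- rnorm(18, mean = 1, sd = 2)
    for (pooled in c(FALSE, TRUE)) {
      ref <- t.test(a, b, var.equal = pooled)
      got <- t_test_summary(mean(a), sd(a), length(a),
                            mean(b), sd(b), length(b), pooled = pooled)
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    }
  }
})

test_that("group comparisons map variable types to the right tests", {
  set.seed(7)
  df <- data.frame(
    status = rep(c("CADASIL", "control"), each = 20),
    age = rnorm(40, 52, 11),
    cdr = sample(c(0, 0.5, 1), 40, TRUE),
    sex = sample(c("F", "M"), 40, TRUE)
  )
  expect_equal(compare_groups(df, "age")$test, "t")
  expect_equal(compare_groups(df, "cdr")$test, "wilcoxon")
  expect_equal(compare_groups(df, "sex")$test, "chisq")
  # identical group compositions: chi-square p = 1
  df2 <- data.frame(status = rep(c("a", "b"), each = 24),
                    sex = rep(rep(c("F", "M"), c(16, 8)), 2))
  expect_equal(compare_groups(df2, "sex")$p.value, 1)
  # t mode matches stats::t.test on the same data
  ref <- t.test(age ~ status, data = df)
  expect_equal(compare_groups(df, "age")$p.value, ref$p.value)
})

test_that("fit_linear matches the closed-form simple-regression slope", {
  set.seed(12)
  for (i in 1:4) {
    n <- 20 + 5 * i
    df <- data.frame(x = rnorm(n), e = rnorm(n))
    df$y <- 1.5 + 0.5 * df$x + df$e
    r <- fit_linear(df, "y", "x")
    slope <- sum((df$x - mean(df$x)) * (df$y - mean(df$y))) /
      sum((df$x - mean(df$x))^2)
    expect_equal(r$beta, slope, tolerance = 1e-10)
    expect_true(r$ci_low <= r$beta && r$beta <= r$ci_high)
  }
  # outcome identical to predictor ("essentially perfect fit" warning is
  # the expected lm behaviour here)
  df <- data.frame(x = rnorm(30)); df$y <- df$x
  r <- suppressWarnings(fit_linear(df, "y", "x"))
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-12)
  # duplicated covariate is perfect collinearity
  df$x2 <- df$x
  expect_error(fit_linear(df, "y", "x", covariates = "x2"), "collinearity")
})

test_that("variance inflation factors match the dedicated implementation", {
  set.seed(4)
  n <- 60
  df <- data.frame(x = rnorm(n), a = rnorm(n), b = rnorm(n))
  df$c <- 0.8 * df$a + 0.6 * rnorm(n)  # moderately collinear
  df$y <- df$x + df$a - df$b + rnorm(n)
  r <- fit_linear(df, "y", "x", covariates = c("a", "b", "c"))
  ref <- car::vif(lm(y ~ x + a + b + c, data = df))
  expect_equal(unname(r$vif[names(ref)]), unname(ref), tolerance = 1e-8)
})

test_that("interaction beta equals the between-group slope difference", {
  set.seed(19)
  for (i in 1:4) {
    n <- 40
    df <- data.frame(status = rep(c("control", "CADASIL"), each = n / 2),
                     ePVS_z = rnorm(n))
    df$y <- 0.2 + 0.3 * (df$status == "CADASIL") + 0.1 * df$ePVS_z +
      0.6 * (df$status == "CADASIL") * df$ePVS_z + rnorm(n)
    r <- fit_interaction(df, "y")
    s_case <- coef(lm(y ~ ePVS_z, df[df$status == "CADASIL", ]))["ePVS_z"]
    s_ctrl <- coef(lm(y ~ ePVS_z, df[df$status == "control", ]))["ePVS_z"]
    expect_equal(r$beta, unname(s_case - s_ctrl), tolerance = 1e-10)
  }
  # plot data: one fitted line per group, partial residuals per subject
  df <- data.frame(status = rep(c("control", "CADASIL"), each = 20),
                   ePVS_z = rnorm(40))
  df$y <- rnorm(40)
  r <- fit_interaction(df, "y")
  expect_setequal(unique(r$plot_data$lines$group), c("control", "CADASIL"))
  expect_equal(nrow(r$plot_data$points), 40)
  expect_error(fit_interaction(df[df$status == "CADASIL", ], "y"), "both status")
})

test_that("BH adjustment matches hand computation and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.004), 0.004)
  expect_equal(bh_fdr(rep(0.02, 6)), rep(0.02, 6))
  set.seed(2)
  for (i in 1:5) {
    p <- runif(50)^(1 + i / 2)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone after sorting
    # order-preserving: hand step-up with cummin
    o <- order(p, decreasing = TRUE)
    hand <- pmin(1, cummin(p[o] * length(p) / rev(seq_along(p))))[order(o)]
    expect_equal(adj, hand, tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("table-one rows summarize groups and star significant contrasts", {
  ch <- generate_cohort(seed = 77)
  t1 <- build_table1(ch$subjects, c("age", "WMH_mm3", "BPF", "MMSE"))
  expect_equal(nrow(t1), 4)
  expect_equal(t1$star[t1$variable == "WMH_mm3"], "*")  # planted group gap
  # identical groups earn no stars
  half <- ch$subjects[ch$subjects$status == "CADASIL", ]
  dup <- rbind(half, transform(half, status = "control",
                               subject_id = paste0(half$subject_id, "b")))
  t2 <- build_table1(dup, c("age", "BPF"))
  expect_true(all(t2$star == ""))
})
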