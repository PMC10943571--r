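test_that("per-analyte screen finds planted associations and tracks direction", {
  ch <- generate_cohort(n_cases = 24, n_controls = 0, n_analytes = 80,
                        n_associated = 50, seed = 41)
  sc <- screen(ch$analytes, ch$subjects, "ePVS_z",
               analyte_info = ch$analyte_info)
  planted <- ch$analyte_info$probe_id[ch$analyte_info$associated]
  expect_gte(mean(planted %in% sc$significant), 0.8)
  expect_setequal(c(sc$positive, sc$negative), sc$significant)
  expect_length(intersect(sc$positive, sc$negative), 0)
  # analyte identical to the outcome: p ~ 0, positive direction
  an <- ch$analytes
  an[, 60] <- exp(ch$subjects$ePVS_z)
  sc2 <- screen(an, ch$subjects, "ePVS_z")
  row <- sc2$results[60, ]
  expect_lt(row$p, 1e-12)
  expect_equal(row$direction, "positive")
})

test_that("screen significance is monotone in alpha and honors exclusions", {
  ch <- generate_cohort(seed = 15, n_analytes = 60, n_associated = 8)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sizes <- vapply(alphas, function(a)
    length(screen(ch$analytes, ch$subjects, "ePVS_z", alpha = a)$significant),
    0L)
  expect_true(all(diff(sizes) >= 0))
  drop2 <- c("S003", "S040")
  sc <- screen(ch$analytes, ch$subjects, "ePVS_z", exclude_subjects = drop2)
  expect_equal(sc$n_used, nrow(ch$subjects) - 2)
  expect_length(intersect(sc$subjects_used, drop2), 0)
})

test_that("covariate-adjusted screen matches a per-analyte lm oracle", {
  ch <- generate_cohort(n_cases = 20, n_controls = 20, n_analytes = 12,
                        n_associated = 3, seed = 9)
  sc <- screen(ch$analytes, ch$subjects, "MMSE",
               covariates = c("age", "education"))
  X <- scale(log(ch$analytes))
  for (j in c(1, 5, 12)) {
    df <- data.frame(y = ch$subjects$MMSE, x = X[, j],
                     age = ch$subjects$age, edu = ch$subjects$education)
    ref <- summary(lm(y ~ x + age + edu, df))$coefficients["x", ]
    expect_equal(sc$results$beta[j], unname(ref["Estimate"]), tolerance = 1e-8)
    expect_equal(sc$results$p[j], unname(ref["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("PCA outlier detection flags constructed outliers only", {
  ch <- generate_cohort(seed = 3)
  an <- ch$analytes
  an["S010", ] <- an["S010", ] * exp(10 * 0.5)  # +10 SD on the log scale
  flagged <- pca_outliers(an)
  expect_true("S010" %in% flagged)
  # invariant to per-analyte multiplicative rescaling (affine on log scale)
  an2 <- sweep(an, 2, runif(ncol(an), 0.5, 2), `*`)
  expect_setequal(as.character(pca_outliers(an2)),
                  as.character(pca_outliers(an)))
  expect_error(pca_outliers(an[1:2, ]), "3 subjects")
  expect_error(pca_outliers(an[1:5, ], k_components = 5), "components")
  # re-screening after removal uses only the remaining subjects
  sc <- screen(ch$analytes, ch$subjects, "ePVS_z", exclude_subjects = flagged)
  expect_equal(sc$n_used, nrow(ch$analytes) - length(flagged))
})

test_that("edge lists normalize scores, drop self-loops, dedupe pairs", {
  el <- edge_list(c("A", "B", "C", "A", "A"),
                  c("B", "A", "C", "D", "D"),
                  c(900, 700, 950, 420, 380))
  expect_false(any(el$protein1 == el$protein2))  # self-loop gone
  expect_equal(nrow(el), 2)                      # A-B deduped, A-D kept once
  expect_equal(max(el$score), 0.9)               # 0-1000 normalized, max kept
  el2 <- edge_list(c("A", "B"), c("B", "C"), c(0.39, 0.41))
  expect_equal(nrow(el2), 1)                     # below-confidence edge gone
})

test_that("degrees count distinct neighbours and hubs are top-degree nodes", {
  leaves <- paste0("L", 1:5)
  star <- edge_list(rep("A", 5), leaves, 1)
  dh <- degree_and_hubs(star, top_n = 1)
  expect_equal(unname(dh$degree["A"]), 5)
  expect_equal(dh$hubs, "A")
  # sum of degrees = 2 x edge count
  set.seed(8)
  nodes <- paste0("P", 1:15)
  e <- edge_list(sample(nodes, 40, TRUE), sample(nodes, 40, TRUE), 1)
  dh2 <- degree_and_hubs(e)
  expect_equal(sum(dh2$degree), 2 * nrow(e))
  expect_length(degree_and_hubs(edge_list(character(0), character(0),
                                          numeric(0)))$hubs, 0)
  # a node wired to 24 distinct partners reports degree 24
  hub <- edge_list(rep("CCL2", 24), paste0("N", 1:24), 1)
  expect_equal(unname(degree_and_hubs(hub)$degree["CCL2"]), 24)
})

test_that("edge-count enrichment reports ratio and Poisson tail", {
  e <- enrichment_vs_expected(8, 4)
  expect_equal(e$ratio, 2)
  expect_equal(e$p, ppois(7, 4, lower.tail = FALSE))
  eq <- enrichment_vs_expected(6, 6)
  expect_equal(eq$ratio, 1)
  expect_gte(eq$p, 0.5)
  z <- enrichment_vs_expected(0, 0)
  expect_equal(z$ratio, 1)
  expect_false(is.null(z$note))
  expect_error(enrichment_vs_expected(3, -1), "negative")
  # an edge_list input counts its rows
  el <- edge_list(rep("A", 3), c("B", "C", "D"), 1)
  expect_equal(enrichment_vs_expected(el, 1)$observed, 3)
})

test_that("set overlaps count intersections and direction concordance", {
  o <- overlap_sets(c("a", "b"), c("c", "d"), c("e"))
  expect_true(all(c(o$ab, o$ac, o$bc, o$abc) == 0))
  s <- c("x", "y", "z")
  o2 <- overlap_sets(s, s, s)
  expect_equal(o2$abc, 3)
  dirs <- list(
    A = c(x = "positive", y = "positive"),
    B = c(x = "positive", y = "negative"),
    C = c(x = "positive")
  )
  o3 <- overlap_sets(c("x", "y"), c("x", "y"), "x", directions = dirs)
  expect_equal(o3$ab, 2)
  expect_true(o3$concordant$ab[["x"]])
  expect_false(o3$concordant$ab[["y"]])
})
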