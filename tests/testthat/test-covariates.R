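# Cross-cluster comparisons, taxonomy fractions, GC regression.

test_that("cluster comparisons flag a planted GC shift and pass nulls", {
  withr::with_seed(12, {
    gc <- c(rnorm(60, 0.62, 0.03), rnorm(60, 0.45, 0.03), rnorm(60, 0.45, 0.03))
  })
  labs <- rep(1:3, each = 60)
  cmp <- compareAcrossClusters(gc, labs, variable = "gc_content")
  d <- cmp@dunn
  expect_lt(max(d$p_bonferroni[d$group_a == "1" | d$group_b == "1"]), 0.001)
  expect_lt(cmp@p, 1e-10)

  withr::with_seed(13, nullv <- rnorm(90))
  cmpNull <- compareAcrossClusters(nullv, rep(1:3, each = 30))
  expect_gt(cmpNull@p, 0.01)

  # missing values are dropped and counted; an empty cluster is an error
  gc2 <- gc; gc2[1:3] <- NA
  cmp2 <- compareAcrossClusters(gc2, labs)
  expect_equal(unname(cmp2@nDropped["1"]), 3L)
  gc3 <- gc; gc3[labs == 2] <- NA
  expect_error(compareAcrossClusters(gc3, labs), "cluster '2'")
})

test_that("an archaea-enriched cluster is detected from taxonomy fractions", {
  sim <- simulateKOProfiles(smallScenario(seed = 3))
  prop <- taxonomyProportions(sim$taxonomy)
  cmp <- compareAcrossClusters(prop$archaea, sim$truth$clusters,
                               variable = "archaea")
  d <- cmp@dunn
  rich <- as.character(sim$truth$archaeaRichCluster)
  expect_lt(max(d$p_bonferroni[d$group_a == rich | d$group_b == rich]), 1e-6)
})

test_that("taxonomy proportions are exact fractions that sum to one", {
  tax <- data.frame(sample_id = c("S1", "S2"),
                    bacteria = c(990, 0), archaea = c(5, 0),
                    eukaryota = c(3, 0), viruses = c(2, 0),
                    unassigned = c(0, 0))
  expect_warning(prop <- taxonomyProportions(tax), "zero total")
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$bacteria, 0.99)
  expect_equal(rowSums(prop[, -1]), 1, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("GC regression matches lm/cor.test and handles degenerate KOs", {
  withr::with_seed(21, {
    gc <- runif(40, 0.3, 0.7)
    X <- cbind(exact = 2 * gc + 1,
               noisy = 1.5 * gc + rnorm(40, 0, 0.3),
               flat = rep(2, 40),
               indep = rnorm(40))
  })
  rownames(X) <- paste0("S", 1:40)
  res <- gcKORegression(X, gc)
  expect_equal(res$slope[1], 2, tolerance = 1e-10)
  expect_equal(res$pearson_r[1], 1, tolerance = 1e-10)
  expect_lt(res$wald_p[1], 1e-100)
  # noisy column against lm and cor.test
  fit <- lm(X[, "noisy"] ~ gc)
  expect_equal(res$slope[2], unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(res$intercept[2], unname(coef(fit)[1]), tolerance = 1e-10)
  ct <- cor.test(gc, X[, "noisy"])
  expect_equal(res$pearson_r[2], unname(ct$estimate), tolerance = 1e-10)
  expect_equal(res$wald_p[2], ct$p.value, tolerance = 1e-12)
  # r^2 equals the regression R^2
  expect_equal(res$pearson_r[2]^2, summary(fit)$r.squared, tolerance = 1e-10)
  # constant KO: slope 0, r 0, p 1
  expect_equal(res$slope[3], 0)
  expect_equal(res$wald_p[3], 1)
  expect_error(gcKORegression(X, rep(0.5, 40)), "constant")
})

test_that("a planted GC slope is recovered and tops the correlation ranking", {
  withr::with_seed(33, {
    gc <- runif(300, 0.35, 0.65)
    X <- cbind(planted_pos = 8 * gc + rnorm(300, 0, 0.5),
               planted_neg = -8 * gc + rnorm(300, 0, 0.5),
               matrix(rnorm(300 * 30), 300,
                      dimnames = list(NULL, sprintf("noise%02d", 1:30))))
  })
  rownames(X) <- paste0("S", 1:300)
  res <- gcKORegression(X, gc)
  se <- abs(res$slope[1] / res$t[1])
  expect_lt(abs(res$slope[1] - 8), 3 * se)
  ranked <- rankGCCorrelates(res, nTop = 3)
  expect_equal(ranked$positive$ko[1], "planted_pos")
  expect_equal(ranked$negative$ko[1], "planted_neg")
  # top-decile by |r|
  expect_lte(rank(-abs(res$pearson_r))[1], ceiling(0.1 * nrow(res)))

  full <- rankGCCorrelates(res, nTop = 1000)
  expect_equal(nrow(full$positive), nrow(res))
  # all-zero correlations rank deterministically by KO id
  resFlat <- gcKORegression(matrix(2, 10, 3,
                                   dimnames = list(paste0("S", 1:10),
                                                   c("b", "a", "c"))),
                            seq(0.3, 0.7, length.out = 10))
  expect_equal(rankGCCorrelates(resFlat, 3)$positive$ko, c("a", "b", "c"))
})

test_that("regression p-values are null-calibrated", {
  withr::with_seed(55, {
    fracs <- vapply(1:30, function(i) {
      gc <- runif(50, 0.3, 0.7)
      X <- matrix(rnorm(50 * 100), 50)
      rownames(X) <- paste0("S", 1:50)
      colnames(X) <- paste0("k", 1:100)
      mean(gcKORegression(X, gc)$wald_p < 0.05)
    }, numeric(1))
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.012)
})
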