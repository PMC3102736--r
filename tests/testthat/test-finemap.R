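# Small LD-structured cohort used across the stepwise tests.
finemap_fixture <- function(seed = 51, or = 1.5, n = 800) {
  set.seed(seed)
  sc <- scenario_ld_asymmetry_panels(n_background = 6)
  co <- scenario_finemap_cohort(sc, or = or, n_cases = n, n_controls = n)
  list(sc = sc, co = co)
}

test_that("a null region selects nothing at strict thresholds", {
  set.seed(52)
  mat <- sapply(1:8, function(j) rbinom(400, 2, 0.4)) * 1.0
  dm <- dm_from_matrix(mat)
  status <- rbinom(400, 1, 0.5)
  sw <- stepwise_select(dm, variant_ids(dm), status,
                        alpha_a = 1e-6, alpha_b = 1e-6)
  expect_length(sw$selected, 0)
  expect_null(sw$final_model)
})

test_that("stepwise recovers a strong planted signal and is deterministic", {
  fx <- finemap_fixture()
  cv <- data.frame(age = fx$co$samples$age)
  sw1 <- stepwise_select(fx$co$dosages, variant_ids(fx$co$dosages),
                         fx$co$samples$status, cv,
                         alpha_a = 0.004, alpha_b = 0.004)
  sw2 <- stepwise_select(fx$co$dosages, variant_ids(fx$co$dosages),
                         fx$co$samples$status, cv,
                         alpha_a = 0.004, alpha_b = 0.004)
  expect_gt(length(sw1$selected), 0)
  expect_identical(sw1$selected, sw2$selected)
  expect_identical(sw1$final_model, sw2$final_model)
  # every retained variant is below its threshold in the final model
  expect_true(all(sw1$final_model$p < sw1$alpha_used[sw1$selected]))
})

test_that("with equal thresholds the candidate partition is irrelevant", {
  fx <- finemap_fixture(seed = 53)
  ids <- variant_ids(fx$co$dosages)
  sw_a <- stepwise_select(fx$co$dosages, ids, fx$co$samples$status,
                          alpha_a = 0.001, alpha_b = 0.001,
                          correlated_ids = ids)
  sw_b <- stepwise_select(fx$co$dosages, ids, fx$co$samples$status,
                          alpha_a = 0.001, alpha_b = 0.001,
                          correlated_ids = ids[1:2])
  expect_identical(sw_a$selected, sw_b$selected)
})

test_that("perfectly collinear candidates are skipped with a reason", {
  set.seed(54)
  g <- rbinom(500, 2, 0.4)
  status <- rbinom(500, 1, plogis(-0.5 + 0.8 * g))
  mat <- cbind(v1 = g, v2 = g, v3 = rbinom(500, 2, 0.5)) * 1.0
  dm <- dm_from_matrix(mat)
  sw <- stepwise_select(dm, variant_ids(dm), status,
                        alpha_a = 0.01, alpha_b = 0.01)
  expect_true("collinear" %in% sw$skipped$reason)
  expect_length(intersect(sw$selected, c("v1", "v2")), 1)
})

test_that("mean-filled no-calls preserve the sample size in stepwise", {
  set.seed(55)
  g <- rbinom(600, 2, 0.4)
  status <- rbinom(600, 1, plogis(-0.5 + 0.7 * g))
  gm <- g * 1.0
  gm[sample(600, 60)] <- NA
  dm <- dm_from_matrix(cbind(v1 = gm))
  sw <- stepwise_select(dm, "v1", status, alpha_a = 0.01, alpha_b = 0.01)
  expect_equal(sw$selected, "v1")
  # the joint fit used all 600 samples: reproduce it by explicit mean fill
  filled <- gm
  filled[is.na(filled)] <- mean(gm, na.rm = TRUE)
  ref <- trend_test(filled, status)
  expect_equal(sw$final_model$beta, ref$beta, tolerance = 1e-9)
  expect_equal(ref$n, 600)
})

test_that("the dense-region scan restricts its pool to nominally associated variants", {
  set.seed(56)
  n <- 1500
  g1 <- rbinom(n, 2, 0.4)
  status <- rbinom(n, 1, plogis(-0.6 + 0.5 * g1))
  mat <- cbind(v1 = g1, v2 = rbinom(n, 2, 0.5), v3 = rbinom(n, 2, 0.3)) * 1.0
  dm <- dm_from_matrix(mat)
  scan <- assoc_scan(dm, status)
  res <- region_scan_multi(dm, status, entry_p = 0.05, retain_p = 0.001)
  outside <- scan$variant_id[!is.na(scan$p_trend) & scan$p_trend >= 0.05]
  expect_length(intersect(res$pool, outside), 0)
  expect_length(intersect(res$selected, outside), 0)
  expect_true("v1" %in% res$selected)
})

test_that("conditioning reduces to the plain trend test when the set is empty", {
  fx <- finemap_fixture(seed = 57, n = 400)
  dm <- fx$co$dosages
  status <- fx$co$samples$status
  a <- conditional_test(dm, fx$sc$causal_id, character(0), status)
  b <- trend_test(dm$dosages[, fx$sc$causal_id], status,
                  variant_id = fx$sc$causal_id)
  expect_equal(a$beta, b$beta)
  expect_equal(a$p_trend, b$p_trend)
})

test_that("conditioning on a perfect proxy removes the signal; on an independent variant it does not", {
  set.seed(58)
  n <- 2000
  g <- rbinom(n, 2, 0.4)
  status <- rbinom(n, 1, plogis(-0.5 + 0.5 * g))
  indep <- rbinom(n, 2, 0.5)
  mat <- cbind(v = g, proxy = g, other = indep) * 1.0
  dm <- dm_from_matrix(mat)
  cond <- conditional_test(dm, "v", "proxy", status)
  expect_equal(cond$flag, "collinear")
  expect_equal(cond$beta, 0)
  expect_equal(cond$p_trend, 1)
  # near-perfect proxy: tiny residual information, huge p
  mat2 <- mat
  flip <- sample(n, 20)
  mat2[flip, "proxy"] <- 2 - mat2[flip, "proxy"]
  dm2 <- dm_from_matrix(mat2)
  cond2 <- conditional_test(dm2, "v", "proxy", status)
  expect_gt(cond2$p_trend, 1e-4)
  plain <- trend_test(g, status)
  cond3 <- conditional_test(dm, "v", "other", status)
  expect_lt(abs(cond3$beta - plain$beta), plain$se)
})

test_that("dosage variance explained by other variants matches least squares", {
  set.seed(59)
  n <- 300
  x1 <- rbinom(n, 2, 0.5); x2 <- rbinom(n, 2, 0.3)
  y <- pmin(2, pmax(0, round((x1 + x2) / 2)))
  mat <- cbind(y = y, x1 = x1, x2 = x2) * 1.0
  dm <- dm_from_matrix(mat)
  r2 <- variance_explained_by_others(dm, "y", c("x1", "x2"))
  oracle <- summary(lm(y ~ x1 + x2))$r.squared
  expect_equal(r2, oracle, tolerance = 1e-9)
  # a perfect proxy among the others gives R2 = 1
  dm2 <- dm_from_matrix(cbind(y = y, proxy = y, x1 = x1) * 1.0)
  expect_equal(variance_explained_by_others(dm2, "y", c("proxy", "x1")), 1)
  # independent others explain ~ nothing
  dm3 <- dm_from_matrix(cbind(y = rbinom(n, 2, 0.5) * 1.0,
                              a = rbinom(n, 2, 0.5) * 1.0))
  expect_lt(variance_explained_by_others(dm3, "y", "a"), 0.05)
  expect_error(variance_explained_by_others(dm, "y", "y"), ">= 1")
})

test_that("stepwise prefers the causal variant over an ancestry-biased index marker", {
  # structural single-replicate version of the recovery experiment: index
  # correlated with the causal allele only in the minority ancestry
  fx <- finemap_fixture(seed = 60, or = 1.5, n = 1500)
  cv <- data.frame(age = fx$co$samples$age)
  sw <- stepwise_select(fx$co$dosages, variant_ids(fx$co$dosages),
                        fx$co$samples$status, cv,
                        alpha_a = 0.004, alpha_b = 0.004)
  d <- fx$co$dosages$dosages
  first <- sw$selected[1]
  r2_first <- pairwise_r2(d[, first], d[, fx$sc$causal_id])
  r2_index <- pairwise_r2(d[, fx$sc$index_id], d[, fx$sc$causal_id])
  expect_true(first == fx$sc$causal_id || r2_first > r2_index)
})
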