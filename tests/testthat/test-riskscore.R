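test_that("the allele count sums dosages with 2xRAF fill for missing calls", {
  mat <- rbind(c(2, 2, 2, 2),
               c(0, 1, NA, 2),
               c(1, NA, NA, 0),
               c(0, 0, 0, 0),
               c(2, 1, 1, NA)) * 1.0
  dm <- dm_from_matrix(mat)
  sv <- data.frame(variant_id = paste0("v", sprintf("%03d", 1:4)),
                   raf = c(0.5, 0.4, 0.4, 0.25))
  counts <- build_score(dm, sv)
  # hand-summed oracle, missing -> 2 * RAF
  expect_equal(unname(counts),
               c(8, 0 + 1 + 0.8 + 2, 1 + 0.8 + 0.8 + 0, 0, 2 + 1 + 1 + 0.5),
               tolerance = 1e-12)
  # homozygous risk everywhere gives the maximum 2m
  expect_equal(unname(counts[1]), 8)
  # a single missing call at RAF 0.4 contributes exactly 0.8
  expect_equal(unname(counts[3]) - (1 + 0.8 + 0),
               0.8, tolerance = 1e-12)
  expect_error(build_score(dm, data.frame(variant_id = "nope", raf = 0.5)),
               "nope")
})

test_that("the score is additive over disjoint variant subsets", {
  set.seed(61)
  mat <- sapply(1:6, function(j) rbinom(40, 2, 0.5)) * 1.0
  mat[sample(length(mat), 20)] <- NA
  dm <- dm_from_matrix(mat)
  sv <- data.frame(variant_id = variant_ids(dm), raf = runif(6, 0.2, 0.8))
  all6 <- build_score(dm, sv)
  first3 <- build_score(dm, sv[1:3, ])
  last3 <- build_score(dm, sv[4:6, ])
  expect_equal(all6, first3 + last3, tolerance = 1e-12)
})

test_that("the per-allele OR matches brute-force ML on a fixture", {
  set.seed(62)
  n <- 30
  counts <- rnorm(n, 30, 3)
  age <- rnorm(n, 60, 8)
  y <- rbinom(n, 1, plogis(-3 + 0.1 * counts))
  res <- per_allele_or(counts, y, data.frame(age = age))
  par <- optim_logistic(cbind(counts, age), y)
  expect_equal(res$beta, par[2], tolerance = 1e-6)
  expect_error(per_allele_or(rep(30, 10), rbinom(10, 1, 0.5)), "variance")
})

test_that("control quartiles split controls evenly and reproduce crude ORs", {
  set.seed(63)
  n <- 2000
  counts <- rnorm(n, 31, 3)
  status <- rbinom(n, 1, plogis(-0.8 + 0.15 * (counts - 31)))
  qa <- quartile_analysis(counts, status)
  ctrl_q <- table(cut(counts[status == 0],
                      c(-Inf, qa$cutpoints, Inf)))
  expect_true(max(ctrl_q) - min(ctrl_q) <= 1)
  expect_equal(length(qa$cutpoints), 3)
  # crude Q4-vs-Q1 OR equals the 2x2 closed form
  q <- cut(counts, c(-Inf, qa$cutpoints, Inf), labels = paste0("Q", 1:4))
  a <- sum(status == 1 & q == "Q4"); b <- sum(status == 0 & q == "Q4")
  c_ <- sum(status == 1 & q == "Q1"); d <- sum(status == 0 & q == "Q1")
  expect_equal(qa$overall$or[4], (a * d) / (b * c_), tolerance = 1e-6)
  # risk grows monotonically across quartiles under this model
  expect_true(all(diff(qa$overall$or) > 0))
})

test_that("family-history stratification uses FH-negative Q1 as the common reference", {
  set.seed(64)
  n <- 3000
  counts <- rnorm(n, 31, 3)
  status <- rbinom(n, 1, plogis(-0.8 + 0.15 * (counts - 31)))
  fh <- rbinom(n, 1, plogis(-2 + 0.4 * status))
  fh[sample(n, 200)] <- NA
  qa <- quartile_analysis(counts, status, family_history = fh)
  bf <- qa$by_family_history
  ref <- bf[bf$stratum == "FHneg" & bf$quartile == "Q1", ]
  expect_equal(ref$or, 1)
  expect_equal(nrow(bf), 8)
  expect_true(all(bf$or[bf$stratum == "FHpos"] > 0, na.rm = TRUE))
})

test_that("the case-only severity test recovers a planted effect and matches ML", {
  set.seed(65)
  n <- 1500
  counts <- rnorm(n, 31, 3)
  sev <- rbinom(n, 1, plogis(-0.5 + 0.05 * (counts - 31)))
  res <- severity_case_only_test(counts, sev)
  par <- optim_logistic(cbind(counts - 31), sev)
  # same fit up to the intercept reparameterization from centring
  expect_equal(res$beta, par[2], tolerance = 1e-5)
  expect_error(severity_case_only_test(counts, rep(1, n)), "classes")
})

test_that("the familial relative risk estimate equals the 2x2 closed form", {
  set.seed(66)
  n <- 4000
  fh <- rbinom(n, 1, 0.12)
  status <- rbinom(n, 1, plogis(-0.6 + log(1.55) * fh))
  res <- familial_rr_estimate(status, fh)
  a <- sum(status == 1 & fh == 1); b <- sum(status == 0 & fh == 1)
  c_ <- sum(status == 1 & fh == 0); d <- sum(status == 0 & fh == 0)
  expect_equal(res$or, (a * d) / (b * c_), tolerance = 1e-6)
  expect_error(familial_rr_estimate(status, rep(0, n)), "variation")
})

test_that("the familial-risk closed form reproduces its worked example digit for digit", {
  fr <- familial_risk_explained(m0 = 30.66, m1 = 32.13, lambda = 1.17,
                                rho_obs = 1.55, r = 0.5)
  expect_equal(fr$rounded$m_rel, 31.03)
  expect_equal(fr$rounded$delta, 0.37)
  expect_equal(fr$rounded$rho_score, 1.06)
  expect_equal(fr$rounded$fraction_pct, 11)
  # full-precision path stays close to the display path
  expect_equal(fr$m_rel, 30.66 * 0.75 + 32.13 * 0.25, tolerance = 1e-12)
  expect_lt(abs(fr$fraction_pct - 11), 1)
})

test_that("the familial-risk fraction behaves at its boundaries and is monotone", {
  # no case-control enrichment: nothing explained
  fr0 <- familial_risk_explained(30, 30, 1.2, 1.5)
  expect_equal(fr0$delta, 0)
  expect_equal(fr0$rho_score, 1)
  expect_equal(fr0$fraction, 0)
  # a null per-allele effect explains nothing regardless of enrichment
  fr1 <- familial_risk_explained(30, 33, 1.0, 1.5)
  expect_equal(fr1$rho_score, 1)
  expect_equal(fr1$fraction, 0)
  expect_error(familial_risk_explained(30, 32, 1.2, 1.0), "rho_obs")
  expect_error(familial_risk_explained(30, 32, 0, 1.5), "lambda")
  # monotone in the case mean and in the per-allele OR
  f_m1 <- vapply(seq(30.5, 33, by = 0.5), function(m1)
    familial_risk_explained(30, m1, 1.2, 1.5)$fraction, numeric(1))
  expect_true(all(diff(f_m1) > 0))
  f_lam <- vapply(seq(1.05, 1.4, by = 0.05), function(l)
    familial_risk_explained(30, 32, l, 1.5)$fraction, numeric(1))
  expect_true(all(diff(f_lam) > 0))
})

test_that("single-variant and joint-model betas agree for independent variants", {
  set.seed(67)
  n <- 3000
  g <- sapply(1:6, function(j) rbinom(n, 2, runif(1, 0.3, 0.7)))
  colnames(g) <- paste0("v", 1:6)
  eta <- g %*% rep(log(1.15), 6)
  status <- rbinom(n, 1, plogis(-1.5 + eta))
  dm <- dm_from_matrix(g * 1.0)
  chk <- independence_check(dm, colnames(g), status)
  expect_false(any(chk$table$collinear))
  diffs <- abs(chk$table$beta_joint - chk$table$beta_single) /
    chk$table$se_single
  expect_lt(median(diffs), 0.5)
  # a duplicated variant is flagged collinear
  dm2 <- dm_from_matrix(cbind(g, dup = g[, 1]) * 1.0)
  chk2 <- independence_check(dm2, c(colnames(g), "dup"), status)
  expect_true(chk2$table$collinear[chk2$table$variant_id == "dup"])
  expect_error(independence_check(dm, "v1", status), ">= 2")
})
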