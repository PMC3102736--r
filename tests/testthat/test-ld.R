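test_that("pairwise r-squared matches hand-computed Pearson values", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(pairwise_r2(a, a), 1.0)
  expect_equal(pairwise_r2(a, c(2, 2, 1, 1, 0, 0)), 1.0)
  b <- c(0, 1, 1, 2, 1, 2)
  expect_equal(pairwise_r2(a, b), cor(a, b)^2, tolerance = 1e-12)
  # hand arithmetic: cov = 0.4, var_a = 0.8
  expect_equal(pairwise_r2(a, b), 0.4^2 / (0.8 * var(b)), tolerance = 1e-12)
  expect_true(is.na(pairwise_r2(a, rep(1, 6))))
  expect_true(is.na(pairwise_r2(c(0, NA), c(1, 2))))
})

test_that("the LD matrix is symmetric with unit diagonal", {
  set.seed(41)
  mat <- sapply(1:6, function(j) rbinom(50, 2, 0.5)) * 1.0
  r <- ld_matrix(dm_from_matrix(mat))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
})

test_that("D-prime is 1 within a two-founder block", {
  set.seed(42)
  fo <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  pick <- sample(1:2, 400, replace = TRUE, prob = c(0.3, 0.7))
  haps <- fo[pick, ]
  g <- haps[1:200, ] + haps[201:400, ]
  expect_equal(dprime(g[, 1], g[, 2]), 1.0, tolerance = 1e-6)
  expect_equal(dprime(g[, 1], g[, 3]), 1.0, tolerance = 1e-6)
  expect_true(is.na(dprime(rep(0, 100), rbinom(100, 2, 0.5))))
})

test_that("EM haplotype frequencies match an exhaustive likelihood grid", {
  set.seed(43)
  # 20 unphased genotype pairs with moderate LD
  hA <- rbinom(80, 1, 0.4)
  hB <- ifelse(runif(80) < 0.7, hA, rbinom(80, 1, 0.5))
  ga <- hA[1:20] + hA[21:40]
  gb <- hB[1:20] + hB[21:40]
  em <- admixfine:::.em_haplotypes(ga, gb)
  # oracle: profile the likelihood over D on a fine grid
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  loglik <- function(D) {
    h <- c(pa * pb + D, pa * (1 - pb) - D, (1 - pa) * pb - D,
           (1 - pa) * (1 - pb) + D)
    if (any(h <= 0)) return(-Inf)
    ll <- 0
    for (i in 0:2) for (j in 0:2) {
      nij <- tab[i + 1, j + 1]
      if (nij == 0) next
      # genotype probability as a sum over compatible haplotype pairs
      pr <- 0
      for (x1 in 0:1) for (x2 in 0:1) for (y1 in 0:1) for (y2 in 0:1) {
        if (x1 + x2 == i && y1 + y2 == j) {
          idx1 <- 2 * (1 - x1) + (1 - y1) + 1
          idx2 <- 2 * (1 - x2) + (1 - y2) + 1
          hh <- c(h[1], h[2], h[3], h[4])
          hap_p <- function(x, y) h[c(4, 3, 2, 1)[2 * x + y + 1]]
          pr <- pr + hap_p(x1, y1) * hap_p(x2, y2)
        }
      }
      ll <- ll + nij * log(pr)
    }
    ll
  }
  grid <- seq(-min(pa * pb, (1 - pa) * (1 - pb)) + 1e-4,
              min(pa * (1 - pb), (1 - pa) * pb) - 1e-4, by = 1e-4)
  lls <- vapply(grid, loglik, numeric(1))
  D_star <- grid[which.max(lls)]
  D_em <- em["h11"] - (em["h11"] + em["h10"]) * (em["h11"] + em["h01"])
  expect_lt(abs(unname(D_em) - D_star), 1e-3)
})

test_that("D-prime is low under linkage equilibrium", {
  set.seed(44)
  dps <- replicate(40, {
    ga <- rbinom(1000, 2, 0.4)
    gb <- rbinom(1000, 2, 0.6)
    dprime(ga, gb)
  })
  expect_lt(median(dps), 0.3)
})

test_that("fine-mapping windows apply the flank and block-extension rules", {
  w <- build_window(1000000, flank = 250000)
  expect_equal(w$start, 750001)
  expect_equal(w$end, 1250000)
  # an index inside a 600 kb block: window covers the whole block
  blocks <- data.frame(start = 800000, end = 1400000)
  w2 <- build_window(1000000, flank = 250000, blocks = blocks)
  expect_equal(w2$start, 750001)
  expect_equal(w2$end, 1400000)
  # two indices 100 kb apart merge into one window
  w3 <- build_window(c(1000000, 1100000), flank = 250000)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$start, 750001)
  expect_equal(w3$end, 1350000)
  # far-apart indices stay separate
  w4 <- build_window(c(1e6, 5e6), flank = 250000)
  expect_equal(nrow(w4), 2)
})

test_that("adjacent-pair D-prime chaining recovers a planted block", {
  set.seed(45)
  fo <- rbind(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L))
  pick <- sample(1:2, 800, replace = TRUE)
  haps <- cbind(fo[pick, ], matrix(rbinom(800 * 2, 1, 0.5), 800))
  g <- haps[1:400, ] + haps[401:800, ]
  dm <- dm_from_matrix(g * 1.0, pos = c(1:6 * 1000))
  bl <- infer_ld_blocks(dm, threshold = 0.8)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 1000)
  expect_equal(bl$end, 4000)
})

test_that("correlated sets include exactly the variants in LD with an index", {
  set.seed(46)
  n <- 2000
  idx <- rbinom(n, 2, 0.5)
  mk_corr <- function(target_r2) {
    keep <- runif(n) < sqrt(target_r2)
    out <- ifelse(keep, idx, rbinom(n, 2, 0.5))
    # rescale empirically until close to target
    out
  }
  strong <- ifelse(runif(n) < 0.85, idx, rbinom(n, 2, 0.5))
  weak <- ifelse(runif(n) < 0.25, idx, rbinom(n, 2, 0.5))
  stopifnot(pairwise_r2(idx, strong) > 0.2, pairwise_r2(idx, weak) < 0.2)
  mat <- cbind(idx, strong, weak) * 1.0
  colnames(mat) <- c("vidx", "vstrong", "vweak")
  dm <- dm_from_matrix(mat, pos = c(1000, 2000, 3000))
  cs <- correlated_set(dm, "vidx", r2_index = 0.2)
  expect_setequal(cs, c("vidx", "vstrong"))
  # isolated index: only itself
  cs2 <- correlated_set(dm, "vweak", r2_index = 0.999)
  expect_identical(cs2, "vweak")
})

test_that("greedy tagging covers every member and matches graph extremes", {
  ids <- paste0("v", 1:5)
  full <- matrix(1, 5, 5, dimnames = list(ids, ids))
  expect_length(greedy_tags(ids, full, 0.8), 1)
  none <- diag(5); dimnames(none) <- list(ids, ids)
  expect_length(greedy_tags(ids, none, 0.8), 5)
})

test_that("greedy tag sets are valid covers, near brute-force optimal on small instances", {
  set.seed(47)
  for (rep in 1:8) {
    k <- sample(6:10, 1)
    ids <- paste0("v", seq_len(k))
    r2 <- matrix(runif(k * k), k, k, dimnames = list(ids, ids))
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    tags <- greedy_tags(ids, r2, r2_tag = 0.8,
                        pos = setNames(seq_len(k), ids))
    cov <- r2 >= 0.8; diag(cov) <- TRUE
    # every member covered by at least one tag
    expect_true(all(colSums(cov[tags, , drop = FALSE]) > 0))
    # greedy never beats the exhaustive optimum
    expect_gte(length(tags), brute_min_cover(cov)$size)
    # raising the coverage threshold never shrinks the tag set
    tags_strict <- greedy_tags(ids, r2, r2_tag = 0.95,
                               pos = setNames(seq_len(k), ids))
    expect_gte(length(tags_strict), length(tags))
  }
})

test_that("significance thresholds derive from tag counts by 0.05/n", {
  al <- derive_alphas(c(r1 = 12), total_tags = 12, mode = "per_region")
  expect_equal(unname(al$alpha_a["r1"]), 0.05 / 12)
  al2 <- derive_alphas(c(r1 = 10, r2 = 14), total_tags = 8929)
  # global-average mode: one shared alpha_a from the mean count
  expect_equal(unname(al2$alpha_a), rep(0.05 / 12, 2))
  expect_equal(al2$alpha_b, 0.05 / 8929)
  expect_lt(al2$alpha_b, 5.7e-6)
  expect_gt(al2$alpha_b, 5.5e-6)
  expect_equal(derive_alphas(c(r = 1), 1)$alpha_b, 0.05)
  expect_error(derive_alphas(c(r = 0), 5), "counts")
})
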