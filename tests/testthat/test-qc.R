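test_that("variant filters remove exactly the engineered failures", {
  qc <- filter_variants(toy_panel(), call_rate_min = 0.95, maf_min = 0.01)
  expect_setequal(qc$report$entity, c("v001", "v002", "v003"))
  expect_equal(ncol(qc$dosages$dosages), 7)
  expect_equal(qc$report$reason[qc$report$entity == "v001"], "call_rate")
  expect_equal(qc$report$reason[qc$report$entity == "v003"], "maf")
  # boundary: MAF exactly at the threshold is retained
  expect_true("v004" %in% variant_ids(qc$dosages))
  # each removal cites exactly one rule
  expect_equal(anyDuplicated(qc$report$entity), 0)
  expect_error(filter_variants(subset_dosage(toy_panel(),
                                             variants = integer(0))),
               "empty")
})

test_that("call-rate and MAF filters commute on typed data", {
  dm <- toy_panel()
  a <- filter_variants(filter_variants(dm, 0.95, 0)$dosages, 1e-9, 0.01)
  b <- filter_variants(filter_variants(dm, 1e-9, 0.01)$dosages, 0.95, 0)
  expect_setequal(variant_ids(a$dosages), variant_ids(b$dosages))
})

test_that("replicate QC mismatches beyond the tolerance remove a variant", {
  set.seed(8)
  mat <- sapply(1:5, function(j) rbinom(6, 2, 0.5)) * 1.0
  mat[2, ] <- mat[1, ]; mat[4, ] <- mat[3, ]
  mat[2, 5] <- (mat[1, 5] + 1) %% 3     # one mismatch at v005 (tolerated)
  mat[2, 4] <- (mat[1, 4] + 1) %% 3     # two mismatches at v004
  mat[4, 4] <- (mat[3, 4] + 1) %% 3
  dm <- dm_from_matrix(mat)
  pairs <- data.frame(id1 = c("S001", "S003"), id2 = c("S002", "S004"))
  qc <- filter_variants(dm, 0, 0, replicate_pairs = pairs,
                        max_qc_mismatch = 1)
  expect_equal(qc$report$entity, "v004")
  expect_equal(qc$report$reason, "qc_mismatch")
})

test_that("sample call-rate filter runs before variant filters", {
  set.seed(9)
  mat <- sapply(1:20, function(j) rbinom(10, 2, 0.4)) * 1.0
  mat[1, 1:3] <- NA            # sample call rate 0.85
  dm <- dm_from_matrix(mat)
  sq <- filter_samples(dm, 0.95)
  expect_equal(sq$report$entity, "S001")
  expect_equal(nrow(sq$dosages$dosages), 9)
})

test_that("replicate concordance equals the hand count", {
  mat <- rbind(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0), c(0, 2, 2, 1, 0),
               c(NA, 1, 2, NA, 0)) * 1.0
  dm <- dm_from_matrix(mat)
  pairs <- data.frame(id1 = c("S001", "S001", "S001"),
                      id2 = c("S002", "S003", "S004"))
  cc <- replicate_concordance(dm, pairs)
  expect_equal(cc$concordance, c(1.0, 4 / 5, 3 / 3))
  expect_equal(cc$n_compared, c(5L, 5L, 3L))
  # a 99/100 matching fixture
  m2 <- matrix(rep(1, 200), nrow = 2) * 1.0
  m2[2, 100] <- 2
  cc2 <- replicate_concordance(dm_from_matrix(m2),
                               data.frame(id1 = "S001", id2 = "S002"))
  expect_equal(cc2$concordance, 0.99)
  # no comparable calls -> NA
  m3 <- rbind(c(NA, 1), c(0, NA)) * 1.0
  cc3 <- replicate_concordance(dm_from_matrix(m3),
                               data.frame(id1 = "S001", id2 = "S002"))
  expect_true(is.na(cc3$concordance))
})

test_that("duplicate samples give Z2 near 1 and classify as MZ", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_variants = 2000,
                    fst = 0.1, block_len_mean = 1, miss_rate = 0,
                    imputed_frac = 0, prevalence = 0.3, seed = 3,
                    relatives = data.frame(relationship = "duplicate",
                                           count = 2L))
  co <- simulate_case_control(cfg)
  rel <- co$truth$relatives
  for (k in seq_len(nrow(rel))) {
    est <- estimate_ibd(co$dosages, c(rel$id1[k], rel$id2[k]))
    expect_gt(est$z[3], 0.95)
    expect_equal(classify_relationship(est), "MZ")
  }
})

test_that("parent-offspring pairs classify from their Z vector; unrelated pairs have high Z0", {
  cfg <- sim_config(n_cases = 40, n_controls = 40, n_variants = 3000,
                    fst = 0.15, block_len_mean = 1, miss_rate = 0,
                    imputed_frac = 0, prevalence = 0.3, seed = 5,
                    relatives = data.frame(relationship = "parent-offspring",
                                           count = 2L))
  co <- simulate_case_control(cfg)
  rel <- co$truth$relatives
  for (k in seq_len(nrow(rel))) {
    est <- estimate_ibd(co$dosages, c(rel$id1[k], rel$id2[k]))
    expect_lt(abs(est$z[2] - 1), 0.1)
    expect_equal(classify_relationship(est), "parent-offspring")
  }
  est_u <- estimate_ibd(co$dosages, c("S1", "S2"))
  expect_gt(est_u$z[1], 0.8)
  expect_equal(classify_relationship(est_u), "unrelated")
})

test_that("Z-vector classification follows the within-1-SD rule", {
  expect_equal(classify_relationship(c(0.26, 0.49, 0.25), sd = 0.05),
               "full-sibling")
  expect_equal(classify_relationship(c(1, 0, 0), sd = 0.1), "unrelated")
  # between full- and half-sibling, matching neither fully
  expect_equal(classify_relationship(c(0.37, 0.50, 0.13), sd = 0.05),
               "unrelated")
  # multiple matches resolved by Euclidean distance
  expect_equal(classify_relationship(c(0.37, 0.5, 0.13), sd = 0.2),
               "full-sibling")
})

test_that("IBD estimation errors without overlapping calls", {
  mat <- rbind(c(NA, NA, 1), c(0, 1, NA)) * 1.0
  dm <- dm_from_matrix(mat)
  expect_error(suppressWarnings(estimate_ibd(dm, c("S001", "S002"))),
               "overlapping")
})

test_that("degree-based pruning removes hubs first and empties the graph", {
  pairs <- data.frame(id1 = c("A", "A"), id2 = c("B", "C"))
  expect_identical(prune_related(pairs, seed = 1), "A")
  # isolated pair: seeded and reproducible
  single <- data.frame(id1 = "A", id2 = "B")
  expect_identical(prune_related(single, seed = 42),
                   prune_related(single, seed = 42))
  expect_true(prune_related(single, seed = 42) %in% c("A", "B"))
  # two disjoint triangles: removal count equals the brute-force minimum
  # vertex cover size for this fixture
  tri <- data.frame(id1 = c("A", "B", "C", "D", "E", "F"),
                    id2 = c("B", "C", "A", "E", "F", "D"))
  removed <- prune_related(tri, seed = 7)
  nodes <- sort(unique(c(tri$id1, tri$id2)))
  cov <- t(sapply(nodes, function(v) tri$id1 == v | tri$id2 == v))
  expect_equal(length(removed), brute_min_cover(cov)$size)
  # survivors have no remaining edges
  left <- tri[!(tri$id1 %in% removed) & !(tri$id2 %in% removed), ]
  expect_equal(nrow(left), 0)
})

test_that("pruning empties random relatedness graphs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    nodes <- LETTERS[1:n]
    all_pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(all_pairs)) < 0.4
    if (!any(sel)) next
    pairs <- data.frame(id1 = all_pairs[sel, 1], id2 = all_pairs[sel, 2])
    removed <- prune_related(pairs, seed = rep)
    left <- pairs[!(pairs$id1 %in% removed) & !(pairs$id2 %in% removed), ]
    expect_equal(nrow(left), 0)
  }
})
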