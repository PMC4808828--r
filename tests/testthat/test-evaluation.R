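# independent greedy matcher used as the oracle for candidate-truth matching:
# explicit loop over the globally sorted pair list
match_oracle <- function(cands, truth) {
  lab <- cands$.label
  pos <- which(lab == "nodule")
  pairs <- data.frame()
  for (ci in pos) {
    for (ti in seq_len(nrow(truth))) {
      d <- sqrt((cands$cx_mm[ci] - truth$cx_mm[ti])^2 +
                  (cands$cy_mm[ci] - truth$cy_mm[ti])^2 +
                  (cands$cz_mm[ci] - truth$cz_mm[ti])^2)
      if (d <= truth$radius_mm[ti]) pairs <- rbind(pairs, data.frame(ci, ti, d))
    }
  }
  used_c <- used_t <- integer(0)
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$d), ]
    for (k in seq_len(nrow(pairs))) {
      if (pairs$ci[k] %in% used_c || pairs$ti[k] %in% used_t) next
      used_c <- c(used_c, pairs$ci[k]); used_t <- c(used_t, pairs$ti[k])
    }
  }
  TP <- length(used_c)
  FP <- length(pos) - TP
  # non-nodule candidates overlapping a remaining (unmatched) truth are missed
  neg <- which(lab == "non-nodule")
  remaining <- setdiff(seq_len(nrow(truth)), used_t)
  miss <- 0L
  for (ti in remaining) {
    for (ci in neg) {
      d <- sqrt((cands$cx_mm[ci] - truth$cx_mm[ti])^2 +
                  (cands$cy_mm[ci] - truth$cy_mm[ti])^2 +
                  (cands$cz_mm[ci] - truth$cz_mm[ti])^2)
      if (d <= truth$radius_mm[ti]) {
        miss <- miss + 1L
        neg <- setdiff(neg, ci)
        break
      }
    }
  }
  TN <- length(which(lab == "non-nodule")) - miss
  confusion_counts(TP = TP, TN = TN, FP = FP, FN = nrow(truth) - TP)
}

random_scenario <- function(seed) {
  set.seed(seed)
  n_truth <- sample(0:4, 1)
  truth <- tibble::tibble(
    cx_mm = runif(n_truth, 0, 60), cy_mm = runif(n_truth, 0, 60),
    cz_mm = runif(n_truth, 0, 60), radius_mm = runif(n_truth, 3, 8)
  )
  n_cand <- sample(0:8, 1)
  near <- sample(c(TRUE, FALSE), n_cand, replace = TRUE)
  cands <- tibble::tibble(
    cx_mm = runif(n_cand, 0, 60), cy_mm = runif(n_cand, 0, 60),
    cz_mm = runif(n_cand, 0, 60),
    .label = sample(c("nodule", "non-nodule"), n_cand, replace = TRUE)
  )
  if (n_truth > 0 && n_cand > 0) {
    for (i in which(near)) {
      t <- sample(n_truth, 1)
      cands[i, c("cx_mm", "cy_mm", "cz_mm")] <-
        truth[t, c("cx_mm", "cy_mm", "cz_mm")] + runif(3, -3, 3)
    }
  }
  list(cands = cands, truth = truth)
}

test_that("candidate-truth matching handles the canonical cases", {
  truth <- tibble::tibble(cx_mm = 10, cy_mm = 10, cz_mm = 10, radius_mm = 4)
  hit <- tibble::tibble(cx_mm = 10, cy_mm = 10, cz_mm = 10, .label = "nodule")
  cc <- match_candidates_to_truth(hit, truth)
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(1L, 0L, 0L, 0L))

  cc2 <- match_candidates_to_truth(hit[0, ], truth)
  expect_equal(cc2$FN, 1L)
  expect_equal(cc2$TP + cc2$FP + cc2$TN, 0L)

  # each truth matched at most once: two candidates on one truth -> 1 TP 1 FP
  two <- tibble::tibble(cx_mm = c(10, 11), cy_mm = c(10, 10), cz_mm = c(10, 10),
                        .label = "nodule")
  cc3 <- match_candidates_to_truth(two, truth)
  expect_equal(c(cc3$TP, cc3$FP), c(1L, 1L))
})

test_that("matching agrees with the brute-force oracle and conserves counts", {
  for (seed in 1:25) {
    sc <- random_scenario(seed)
    cc <- match_candidates_to_truth(sc$cands, sc$truth)
    oc <- match_oracle(sc$cands, sc$truth)
    expect_identical(unclass(cc), unclass(oc), info = paste("seed", seed))
    # conservation: TP+FN = truths; TP+FP+TN+misclassified overlaps = candidates
    expect_equal(cc$TP + cc$FN, nrow(sc$truth))
    n_miss_overlap <- sum(sc$cands$.label == "non-nodule") - cc$TN
    expect_equal(cc$TP + cc$FP + cc$TN + n_miss_overlap, nrow(sc$cands))
    expect_gte(n_miss_overlap, 0L)
  }
})

test_that("metrics reproduce the printed formulas", {
  cc <- confusion_counts(TP = 49L, FN = 3L, TN = 50L, FP = 9L)
  m <- metrics(cc)
  expect_equal(m$percent[m$metric == "sensitivity"], 94.23)
  expect_equal(m$percent[m$metric == "specificity"], 84.75)
  expect_equal(m$percent[m$metric == "accuracy"], 89.19)
  expect_equal(m$value[m$metric == "accuracy"], 99 / 111)

  m2 <- metrics(confusion_counts(TP = 1L, FN = 1L))
  expect_equal(m2$percent[m2$metric == "sensitivity"], 50)

  # zero denominator -> undefined, not 0
  m3 <- metrics(confusion_counts(TP = 3L, FN = 1L))
  expect_true(is.na(m3$value[m3$metric == "specificity"]))
})

test_that("metric arithmetic agrees with direct computation on random counts", {
  set.seed(99)
  for (i in 1:30) {
    k <- as.integer(sample(0:500, 4, replace = TRUE) + 1L)
    cc <- confusion_counts(TP = k[1], TN = k[2], FP = k[3], FN = k[4])
    m <- metrics(cc)
    expect_equal(m$value[m$metric == "sensitivity"], k[1] / (k[1] + k[4]),
                 tolerance = 1e-12)
    expect_equal(m$value[m$metric == "specificity"], k[2] / (k[2] + k[3]),
                 tolerance = 1e-12)
    expect_equal(m$value[m$metric == "accuracy"], (k[1] + k[2]) / sum(k),
                 tolerance = 1e-12)
  }
})

test_that("false positives per scan is FP / n_scans", {
  expect_equal(fp_per_scan(confusion_counts(FP = 9L), 45), 0.2)
  expect_equal(fp_per_scan(confusion_counts(FP = 0L), 12), 0)
  expect_equal(fp_per_scan(confusion_counts(FP = 10L), 4), 2.5)
  expect_error(fp_per_scan(confusion_counts(FP = 1L), 0), "n_scans")
})

test_that("leave-two-out enumerates all pairs when feasible", {
  toy <- separable_toy_features(10, seed = 5)[c(1:3, 21:22), ]  # n = 5
  pairs <- nodulecad:::lto_pairs(5, max_folds = 500, seed = 1)
  expect_equal(nrow(pairs), 10L)
  expect_equal(as.integer(table(c(pairs))), rep(4L, 5))  # each row tested n-1 times
})

test_that("sampled pairs are distinct and cover every row", {
  pairs <- nodulecad:::lto_pairs(60, max_folds = 200, seed = 3)
  expect_equal(nrow(pairs), 200L)
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  expect_false(any(duplicated(key)))
  expect_setequal(unique(c(pairs)), 1:60)
})

test_that("leave-two-out CV is perfect on separable data", {
  toy <- separable_toy_features(12, seed = 6)
  cv <- leave_two_out_cv(toy, epsilon_p = 0.4, seed = 2, n_per_class = 8)
  m <- metrics(cv$counts)
  expect_equal(m$value[m$metric == "sensitivity"], 1)
  expect_equal(m$value[m$metric == "accuracy"], 1)
  expect_equal(glance(cv)$sensitivity, 1)
  expect_error(leave_two_out_cv(toy[1:3, ]), "at least 4")
})

test_that("the ROC sweep over epsilon yields operating points deterministically", {
  toy <- separable_toy_features(10, seed = 13)
  roc <- roc_over_epsilon(toy, epsilons = 0.4, seed = 3, max_folds = 40,
                          n_per_class = 8)
  op <- roc[roc$operating_point, ]
  expect_equal(nrow(op), 1L)
  expect_equal(op$epsilon, 0.4)

  roc2 <- roc_over_epsilon(toy, epsilons = c(0.2, 0.2), seed = 3, max_folds = 40,
                           n_per_class = 8)
  a <- roc2[roc2$epsilon == 0.2, ]
  half <- nrow(a) / 2
  expect_equal(a$sensitivity[1:half], a$sensitivity[half + 1:half])

  expect_error(roc_over_epsilon(toy, numeric(0)), "nonempty")
  expect_error(roc_over_epsilon(toy, c(0.4, 1.2)), "epsilon")
})
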