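test_that("roc_auc matches hand examples and the pair-counting oracle", {
  expect_equal(roc_auc(c(0, 1, 2, 3), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")

  for (s in 1:40) {
    dat <- tpas:::with_seed(s, {
      n <- sample(4:60, 1)
      scores <- round(runif(n), 2)      # induce ties
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      list(s = scores, l = labels)
    })
    expect_identical(roc_auc(dat$s, dat$l), bruteforce_auc(dat$s, dat$l))
  }
})

test_that("delong_test agrees with pROC and is degenerate-safe", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    dat <- tpas:::with_seed(s, {
      n <- 60
      l <- c(0, 1, rbinom(n - 2, 1, 0.5))
      base <- rnorm(n) + l
      list(l = l, a = base + rnorm(n, 0, 0.5), b = base + rnorm(n, 0, 0.8))
    })
    got <- delong_test(dat$a, dat$b, dat$l)
    ref <- pROC::roc.test(
      pROC::roc(dat$l, dat$a, quiet = TRUE, direction = "<"),
      pROC::roc(dat$l, dat$b, quiet = TRUE, direction = "<"),
      method = "delong")
    expect_equal(got$p, as.numeric(ref$p.value), tolerance = 1e-10)
    expect_equal(got$delta, as.numeric(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-12)
  }
  # identical scorers: delta 0, p 1
  sc <- c(0.2, 0.8, 0.4, 0.9)
  lb <- c(0, 1, 0, 1)
  got <- delong_test(sc, sc, lb)
  expect_equal(got$delta, 0)
  expect_equal(got$p, 1)
})

test_that("single-model DeLong variance matches the jackknife estimate", {
  for (s in 1:6) {
    dat <- tpas:::with_seed(s, {
      n <- 40
      l <- c(rep(0, 20), rep(1, 20))
      list(l = l, a = rnorm(n) + l)
    })
    got <- delong_test(dat$a, dat$a, dat$l)
    # leave-one-out jackknife variance of the AUC
    n <- length(dat$l)
    theta <- vapply(seq_len(n), function(i)
      roc_auc(dat$a[-i], dat$l[-i]), 0)
    vjack <- (n - 1) / n * sum((theta - mean(theta))^2)
    # DeLong and jackknife variance estimators agree to O(1/n); allow 10%
    expect_equal(got$varA, vjack, tolerance = 0.10)
  }
})

test_that("delong p agrees with a paired permutation oracle", {
  dat <- tpas:::with_seed(99, {
    n <- 40
    l <- c(rep(0, 20), rep(1, 20))
    base <- rnorm(n) + 0.8 * l
    list(l = l, a = base + rnorm(n, 0, 0.6), b = base + rnorm(n, 0, 0.6))
  })
  got <- delong_test(dat$a, dat$b, dat$l)
  # sign-flip permutation of the model assignment within patients
  obs <- abs(roc_auc(dat$a, dat$l) - roc_auc(dat$b, dat$l))
  perm <- tpas:::with_seed(7, vapply(seq_len(10000), function(i) {
    flip <- runif(length(dat$l)) < 0.5
    a2 <- ifelse(flip, dat$b, dat$a)
    b2 <- ifelse(flip, dat$a, dat$b)
    abs(roc_auc(a2, dat$l) - roc_auc(b2, dat$l))
  }, 0))
  p_perm <- mean(perm >= obs - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(got$p - p_perm), 4 * mc_se + 0.03)
})

test_that("average precision matches hand example and brute-force oracle", {
  # ranked TP, FP, TP with 2 ground-truth lesions -> (1 + 2/3)/2
  cand <- data.frame(case_id = "c1", cand_id = 1:3,
                     probability = c(0.9, 0.8, 0.7),
                     is_tp = c(TRUE, FALSE, TRUE))
  expect_equal(lesion_pr_auprc(list(candidates = cand, n_gt = 2L)),
               0.833333333333, tolerance = 1e-9)
  # all TP, all matched
  cand2 <- data.frame(case_id = "c1", cand_id = 1:2,
                      probability = c(0.9, 0.8), is_tp = TRUE)
  expect_equal(lesion_pr_auprc(list(candidates = cand2, n_gt = 2L)), 1)
  # no candidates
  expect_equal(lesion_pr_auprc(list(candidates = cand[0, ], n_gt = 2L)), 0)
  expect_error(lesion_pr_auprc(list(candidates = cand, n_gt = 0L)), "ground-truth")

  for (s in 1:40) {
    dat <- tpas:::with_seed(s, {
      n <- sample(1:25, 1)
      data.frame(case_id = sample(sprintf("c%02d", 1:5), n, replace = TRUE),
                 cand_id = seq_len(n),
                 probability = round(runif(n), 2),
                 is_tp = runif(n) < 0.4)
    })
    n_gt <- sum(dat$is_tp) + tpas:::with_seed(s + 1, sample(0:3, 1))
    if (n_gt == 0) next
    expect_equal(lesion_pr_auprc(list(candidates = dat, n_gt = n_gt)),
                 bruteforce_ap(dat$probability, dat$is_tp, dat$case_id,
                               dat$cand_id, n_gt))
  }
})

test_that("bootstrap AUPRC comparison is paired, seeded and null-safe", {
  mk_cohort <- function(flip = FALSE) {
    cand <- data.frame(
      case_id = rep(sprintf("c%02d", 1:10), each = 2),
      cand_id = rep(1:2, 10),
      probability = tpas:::with_seed(5, round(runif(20), 2)),
      is_tp = tpas:::with_seed(6, runif(20) < if (flip) 0.3 else 0.6))
    lc <- list(candidates = cand, n_gt = 15L)
    lc$gt_per_case <- setNames(rep(1.5, 10), sprintf("c%02d", 1:10))
    lc
  }
  a <- mk_cohort(); b <- mk_cohort(TRUE)
  r1 <- bootstrap_auprc_diff(a, b, B = 200, seed = 3)
  r2 <- bootstrap_auprc_diff(a, b, B = 200, seed = 3)
  expect_identical(r1$deltas, r2$deltas)
  expect_true(r1$ci[1] <= r1$ci[2])
  # identical cohorts: every resampled delta 0, p = 1
  r0 <- bootstrap_auprc_diff(a, a, B = 150, seed = 1)
  expect_true(all(r0$deltas == 0))
  expect_equal(r0$p, 1)
  expect_error(bootstrap_auprc_diff(a, b, B = 50, seed = 1), ">= 100")
  # CI endpoints monotone in coverage
  r90 <- bootstrap_auprc_diff(a, b, B = 200, seed = 3, conf = 0.90)
  expect_gte(r90$ci[1], r1$ci[1])
  expect_lte(r90$ci[2], r1$ci[2])
})

test_that("dice closed forms", {
  A <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(1, 2, 2))
  B <- array(c(FALSE, FALSE, TRUE, TRUE), dim = c(1, 2, 2))
  expect_equal(as.numeric(dice(A, A)), 1)
  expect_equal(as.numeric(dice(A, B)), 0)
  A4 <- array(FALSE, dim = c(1, 4, 2)); A4[1, 1:2, ] <- TRUE
  B4 <- array(FALSE, dim = c(1, 4, 2)); B4[1, 2:3, ] <- TRUE
  expect_equal(as.numeric(dice(A4, B4)), 0.5)   # |A|=|B|=4, |I|=2
  empty <- array(FALSE, dim = c(1, 2, 2))
  d0 <- dice(empty, empty)
  expect_equal(as.numeric(d0), 1)
  expect_true(attr(d0, "both_empty"))
  expect_error(dice(A, array(TRUE, dim = c(1, 3, 2))), "shape")
})

test_that("weighted kappa: identity, independence, and a hand-computed table", {
  r <- sample(1:4, 50, replace = TRUE)
  expect_equal(weighted_kappa(r, r), 1)

  # independent ratings at large n drift to 0
  dat <- tpas:::with_seed(2, list(a = sample(1:4, 2000, TRUE),
                                  b = sample(1:4, 2000, TRUE)))
  expect_lt(abs(weighted_kappa(dat$a, dat$b)), 0.05)

  # 2x2 hand computation: O = [[2,1],[1,2]]/6, linear weights on K=2
  r1 <- c(1, 1, 1, 2, 2, 2)
  r2 <- c(1, 1, 2, 1, 2, 2)
  # sum(wO) = 2/6; E marginals both (1/2,1/2): sum(wE) = 1/2; kappa = 1/3
  expect_equal(weighted_kappa(r1, r2, K = 2), 1 / 3)
  expect_error(weighted_kappa(c(0, 1), c(1, 1)), "outside")

  # quadratic weights differ when disagreements span > 1 grade
  q1 <- c(1, 4, 2, 3, 1, 4)
  q2 <- c(4, 1, 2, 3, 1, 4)
  expect_false(isTRUE(all.equal(weighted_kappa(q1, q2),
                                weighted_kappa(q1, q2, weights = "quadratic"))))
})

test_that("delong rejection rate under the null is calibrated", {
  # both scorers = same signal + independent noise; alpha = 0.05
  rejections <- tpas:::with_seed(1234, {
    vapply(seq_len(500), function(r) {
      n <- 100
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
      base <- rnorm(n) + l
      a <- base + rnorm(n, 0, 0.7)
      b <- base + rnorm(n, 0, 0.7)
      delong_test(a, b, l)$p < 0.05
    }, TRUE)
  })
  rate <- mean(rejections)
  expect_gte(rate, 0.028)
  expect_lte(rate, 0.078)
})
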