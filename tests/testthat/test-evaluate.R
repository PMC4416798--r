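# Kappa machinery, accuracy, all-or-nothing scoring, ROC/AUC and output
# time-courses.

test_that("class-wise accuracy normalises rows before averaging", {
  expect_equal(classwise_accuracy(matrix(c(18, 0, 0, 18), 2))$mean, 100)
  expect_equal(classwise_accuracy(matrix(c(18, 0, 0, 18), 2))$sd, 0)
  expect_equal(classwise_accuracy(matrix(c(9, 9, 9, 9), 2))$mean, 50)
  a <- classwise_accuracy(matrix(c(12, 3, 6, 15), 2))
  expect_equal(a$mean, 75)
  expect_equal(a$sd, 11.785, tolerance = 1e-3)
  expect_error(classwise_accuracy(matrix(c(0, 3, 0, 15), 2)), "trial")
})

test_that("kappa formulas match the hand-worked adjusted-Wald example", {
  expect_equal(kappa_score(matrix(c(10, 0, 0, 10), 2))$k, 1)
  k0 <- kappa_score(matrix(c(5, 5, 5, 5), 2))
  expect_equal(k0$k, 0)
  expect_false(k0$significant)
  # N = 16, C = 12, symmetric marginals (p0 = 0.5)
  km <- kappa_score(matrix(c(6, 2, 2, 6), 2))
  expect_equal(km$N, 16)
  expect_equal(km$C, 12)
  expect_equal(km$p0, 0.5)
  expect_equal(km$p_hat, 0.7)
  expect_equal(km$k_hat, 0.4)
  expect_lt(abs(km$k_l - (-0.00168)), 1e-4)
  expect_false(km$significant)
  expect_error(kappa_score(matrix(c(10, 0, 0, 0), 2)), "undefined")
})

test_that("balanced symmetric matrices satisfy k = 2 accuracy - 1", {
  set.seed(81)
  for (i in 1:25) {
    a <- sample(1:30, 1); b <- sample(1:30, 1)
    cm <- matrix(c(a, b, b, a), 2)
    k <- kappa_score(cm)$k
    acc <- classwise_accuracy(cm)$mean / 100
    expect_equal(k, 2 * acc - 1, tolerance = 1e-12)
    expect_lte(k, 1)
  }
})

test_that("condition splits pool correctly and degenerate t-tests give p = 1", {
  ft <- data.frame(subject = rep(1:3, each = 40),
                   condition = rep(rep(c("cued", "uncued"), each = 20), 3),
                   truth = rep(c("change", "constant"), 60),
                   pred = rep(c("change", "constant"), 60),
                   stringsAsFactors = FALSE)
  # make every subject imperfect in the same way
  ft$pred[ft$truth == "change" & seq_len(nrow(ft)) %% 10 == 1] <- "constant"
  res <- split_condition_kappa(ft)
  expect_equal(res$t_test, 1)
  # condition matrices sum to the overall matrix
  cm_all <- confusion_matrix(ft$truth, ft$pred)
  cm_sum <- confusion_matrix(ft$truth[ft$condition == "cued"],
                             ft$pred[ft$condition == "cued"]) +
    confusion_matrix(ft$truth[ft$condition == "uncued"],
                     ft$pred[ft$condition == "uncued"])
  expect_equal(as.numeric(cm_all), as.numeric(cm_sum))
})

test_that("cue-independent decoding rarely yields a condition difference", {
  set.seed(82)
  nonsig <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    ft <- NULL
    for (s in 1:8) {
      for (cond in c("cued", "uncued")) {
        n <- if (cond == "cued") 252 else 96
        truth <- rep(c("change", "constant"), n / 2)
        hit <- runif(n) < 0.75
        pred <- ifelse(hit, truth,
                       ifelse(truth == "change", "constant", "change"))
        ft <- rbind(ft, data.frame(subject = s, condition = cond,
                                   truth = truth, pred = pred,
                                   stringsAsFactors = FALSE))
      }
    }
    if (split_condition_kappa(ft)$t_test > 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig / n_rep, 0.9)
})

test_that("subclass kappas partition the change trials", {
  subcl <- rep(c("0->1", "1->2", "2->1", "1->0"), times = c(3, 6, 6, 3))
  ft <- data.frame(subject = 1,
                   condition = "cued",
                   truth = rep(c("change", "constant"), each = 18),
                   subclass = c(subcl, sub("->.*", "", subcl)),
                   pred = rep(c("change", "constant"), each = 18),
                   stringsAsFactors = FALSE)
  for (sc in c("0->1", "1->2", "2->1", "1->0")) {
    kr <- subclass_kappa(ft, sc)
    expect_equal(kr$k, 1)
  }
  # restricted totals: change trials partition (3, 6, 6, 3) and each
  # pairs with all constant trials at its preceding speed (3, 9, 6, 9)
  ns <- vapply(c("0->1", "1->2", "2->1", "1->0"),
               function(sc) subclass_kappa(ft, sc)$N, 0)
  expect_equal(unname(ns), c(3 + 3, 6 + 9, 6 + 6, 3 + 9))
  expect_warning(subclass_kappa(ft[ft$subclass == "9->9", ], "0->1"),
                 "no paired")
})

test_that("all-or-nothing scores are monotone in the averaging order", {
  expect_equal(allornothing_score(rep(0.2, 9), 1), 0.2)
  expect_equal(allornothing_score(rep(0.2, 9), 3), 0.2)
  expect_equal(allornothing_score(c(0.1, 0.9, 0.1, 0.1), 2), 0.5)
  expect_error(allornothing_score(c(0.1, 0.9), 3), "exceeds")
  # the unaveraged maximum dominates every averaged score (m2 and m3
  # are not mutually ordered: e.g. probabilities 1,0,1 give m3 > m2)
  set.seed(83)
  for (i in 1:200) {
    p <- runif(9)
    s <- vapply(1:3, function(m) allornothing_score(p, m), 0)
    expect_true(s[1] >= s[2] && s[1] >= s[3])
  }
  expect_gt(allornothing_score(c(1, 0, 1), 3),
            allornothing_score(c(1, 0, 1), 2))
})

test_that("trapezoid AUC equals the Mann-Whitney pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), c("constant", "constant",
                                             "constant", "change",
                                             "change"))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 8), rep(c("change", "constant"), 4))$auc,
               0.5)
  expect_error(roc_auc(1:4, rep("change", 4)), "both classes")
  set.seed(84)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- sample(c("change", "constant"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, mann_whitney_auc(scores, labels),
                 tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("output time-courses summarise per-bin quartiles", {
  tc <- output_timecourse(rep(0.3, 12), rep(c(-1, 0, 1), 4),
                          rep("change", 12))
  expect_equal(tc$median, rep(0.3, 3))
  expect_equal(tc$q75 - tc$q25, rep(0, 3))
  tc2 <- output_timecourse(c(0.1, 0.2, 0.9), rep(0, 3), rep("change", 3))
  expect_equal(tc2$median, 0.2)
})
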