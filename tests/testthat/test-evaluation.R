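test_that("ROC points match a brute-force threshold sweep", {
  # perfect separation: a threshold between the scores attains sens = spec = 1
  pts <- roc_points(c(0.9, 0.1), c(1, 0))
  at <- pts[pts$threshold == 0.1, ]
  expect_equal(at$sensitivity, 1)
  expect_equal(at$specificity, 1)

  # all scores tied: only the degenerate corners exist
  pts <- roc_points(rep(0.5, 6), c(1, 1, 0, 0, 1, 0))
  expect_setequal(paste(pts$sensitivity, pts$specificity),
                  c("1 0", "0 1"))

  # random set vs direct counting at every distinct score
  set.seed(10)
  scores <- round(runif(50), 2)
  labels <- rbinom(50, 1, 0.4)
  pts <- roc_points(scores, labels)
  for (t in sort(unique(scores))) {
    row <- pts[pts$threshold == t, ]
    expect_equal(row$sensitivity, mean(scores[labels == 1] > t))
    expect_equal(row$specificity, mean(scores[labels == 0] <= t))
  }
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
  expect_error(roc_points(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC equals the pairwise concordance statistic", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(11)
  for (rep in 1:5) {
    scores <- round(runif(40), 1)  # coarse grid forces ties
    labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC properties: complement symmetry and monotone invariance", {
  set.seed(12)
  scores <- runif(30)  # tie-free
  labels <- rbinom(30, 1, 0.5)
  expect_equal(auc_score(scores, labels) + auc_score(-scores, labels), 1,
               tolerance = 1e-12)
  expect_equal(auc_score(scores, labels),
               auc_score(qlogis(scores), labels), tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- round(runif(200), 2)
  labels <- rbinom(200, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("Youden cutoff maximizes J with the smallest-cutoff tie break", {
  cut <- youden_cutoff(c(0.1, 0.9), c(0, 1))
  expect_equal(as.numeric(cut), 0.1)
  expect_equal(attr(cut, "J"), 1)

  cut <- youden_cutoff(rep(0.5, 4), c(0, 1, 0, 1))
  expect_equal(attr(cut, "J"), 0)

  set.seed(14)
  for (rep in 1:5) {
    scores <- round(runif(50), 1)
    labels <- rbinom(50, 1, 0.5)
    if (length(unique(labels)) < 2) next
    cut <- youden_cutoff(scores, labels)
    oracle <- oracle_youden(scores, labels)
    expect_equal(as.numeric(cut), oracle$best)
    expect_equal(attr(cut, "J"), oracle$maxJ, tolerance = 1e-12)
  }
})

test_that("confusion metrics match direct tabulation and flag empty cells", {
  # TP=2, FN=0, TN=1, FP=1
  m <- confusion_metrics(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 50)
  expect_equal(m$ppv, 200 / 3, tolerance = 1e-12)
  expect_equal(m$npv, 100)
  expect_equal(m$accuracy, 75)

  # all predicted negative: PPV has an empty denominator and warns
  expect_warning(m <- confusion_metrics(c(0.1, 0.2), c(1, 0), 0.9), "PPV")
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 100)
  expect_true(is.nan(m$ppv))

  set.seed(15)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5)
  m <- confusion_metrics(scores, labels, 0.5)
  tp <- sum(scores > 0.5 & labels == 1); fp <- sum(scores > 0.5 & labels == 0)
  fn <- sum(scores <= 0.5 & labels == 1); tn <- sum(scores <= 0.5 & labels == 0)
  expect_equal(m$tp, tp); expect_equal(m$fp, fp)
  expect_equal(m$sensitivity, 100 * tp / (tp + fn))
  expect_equal(m$npv, 100 * tn / (tn + fn))
  expect_equal(m$accuracy, 100 * (tp + tn) / 30)
  expect_error(confusion_metrics(scores, labels, Inf), "finite")
})

test_that("evaluate_model pools boxes and produces a reproducible report", {
  ds <- generate_dataset(synth_config(6, image_size = 70, seed = 17))
  pp <- prep_dataset(ds, 20)

  # a constant-output model is degenerate: AUC 1/2 and a flagged cutoff
  net <- build_ann(ann_spec(20, 49, 1), seed = 1)
  const <- kmcloc:::net_set_params(net, rep(0, sum(count_parameters(net))))
  # the constant model warns twice: degenerate cutoff, then undefined PPV
  warns <- character()
  rep_const <- withCallingHandlers(
    evaluate_model(const, pp),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(warns, "degenerate", all = FALSE)
  expect_equal(rep_const$auc, 0.5)
  expect_true(attr(rep_const, "degenerate"))

  # an oracle model emitting the true targets (+- epsilon) is perfect
  set.seed(1)
  scores <- as.vector(pmin(pmax(pp$y + rnorm(length(pp$y), 0, 1e-3), 1e-6),
                           1 - 1e-6))
  expect_equal(auc_score(scores, as.vector(pp$y)), 1)
  m <- confusion_metrics(scores, as.vector(pp$y),
                         as.numeric(youden_cutoff(scores, as.vector(pp$y))))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)

  # bit-for-bit reproducible from the same network and data (the untrained
  # net may predict no positives at its cutoff, so PPV may warn)
  r1 <- suppressWarnings(evaluate_model(net, pp))
  r2 <- suppressWarnings(evaluate_model(net, pp))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 1)
  expect_named(as.data.frame(r1),
               c("model", "auc", "cutoff", "sensitivity", "specificity",
                 "ppv", "npv", "accuracy"))
})

test_that("report CSV uses the standard column heads", {
  ds <- generate_dataset(synth_config(4, image_size = 70, seed = 18))
  pp <- prep_dataset(ds, 20)
  r <- evaluate_model(build_ann(ann_spec(20, 49, 1), seed = 3), pp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(r, path)
  header <- readLines(path, n = 1)
  expect_equal(header,
    '"Model","AUC","Cut-off","Sensitivity%","Specificity%","PPV%","NPV%","Accuracy%"')
})

test_that("display rounding is half-up at one decimal", {
  expect_equal(kmcloc:::round_half_up(82.65, 1), 82.7)
  expect_equal(kmcloc:::round_half_up(82.64, 1), 82.6)
})
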