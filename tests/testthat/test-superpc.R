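test_that("train/test split is deterministic, disjoint and stratified", {
  o <- bin_outcome(c(rep(0, 6), rep(1, 4)))
  s1 <- split_train_test(o, "binary", train_prop = 0.7, seed = 2)
  s2 <- split_train_test(o, "binary", train_prop = 0.7, seed = 2)
  expect_identical(s1, s2)
  expect_equal(sum(s1$set == "train"), 7)
  expect_setequal(s1$set, c("train", "test"))

  strat <- split_train_test(o, "binary", train_prop = 0.5, seed = 3, stratify = TRUE)
  tr <- strat$sample_id[strat$set == "train"]
  expect_equal(sum(o$label[o$sample_id %in% tr] == 0), 3)
  expect_equal(sum(o$label[o$sample_id %in% tr] == 1), 2)

  expect_error(split_train_test(cont_outcome(rnorm(4)), "continuous",
                                train_prop = 0.95, seed = 1),
               "empty")
})

test_that("threshold grid follows the documented quantile convention", {
  sc <- tibble::tibble(feature_id = letters[1:4], score = c(-1, 2, -3, 4),
                       abs_score = c(1, 2, 3, 4))
  g <- make_threshold_grid(sc, 2)
  expect_equal(g, unname(quantile(c(1, 2, 3, 4), c(0, 0.95), type = 7)))
  expect_equal(g, c(1, 3.85))

  g2 <- make_threshold_grid(sc, 7)
  expect_true(!is.unsorted(g2, strictly = TRUE))
  expect_true(all(g2 >= 1 & g2 <= 4))

  expect_error(make_threshold_grid(sc, 1), "n_thresholds")
  expect_error(make_threshold_grid(dplyr::mutate(sc, score = 2), 3), "equal")
})

test_that("screening keeps exactly the strictly-above features, in order", {
  sc <- tibble::tibble(feature_id = c("a", "b", "c"), score = c(-3, 1, 2))
  expect_equal(screen_features(sc, 1.5), c("a", "c"))
  expect_equal(screen_features(sc, 0), c("a", "b", "c"))
  expect_error(screen_features(sc, 3), "removes all features")

  # monotonicity: larger thresholds select nested subsets
  sc2 <- tibble::tibble(feature_id = sprintf("f%d", 1:50),
                        score = withr::with_seed(8, rnorm(50)))
  prev <- screen_features(sc2, 0)
  for (th in quantile(abs(sc2$score), c(0.2, 0.5, 0.8))) {
    cur <- screen_features(sc2, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("fit_pc recovers rank-1 structure and matches a full SVD", {
  a <- c(3, -1, 2)
  b <- c(1, -1, 2, -2)  # centered
  e <- expr_tbl(outer(a, b))
  m <- fit_pc(e)
  expect_equal(sum(m$loadings^2), 1)
  expect_equal(abs(m$loadings), abs(a) / sqrt(sum(a^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  sc <- project(m, e)$pc_score
  expect_equal(abs(cor(sc, b)), 1, tolerance = 1e-12)

  # single feature collapses to the centered feature values
  e1 <- expr_tbl(matrix(c(5, 7, 9), nrow = 1))
  m1 <- fit_pc(e1)
  expect_equal(unname(m1$loadings), 1)
  expect_equal(project(m1, e1)$pc_score, c(-2, 0, 2))

  # independent full SVD oracle
  x <- withr::with_seed(13, matrix(rnorm(40), nrow = 5))
  m2 <- fit_pc(expr_tbl(x))
  xc <- x - rowMeans(x)
  v <- svd(xc)$u[, 1]
  if (sign(v[which.max(abs(v))]) < 0) v <- -v
  expect_equal(unname(m2$loadings), v, tolerance = 1e-8)
})

test_that("projection is centered, affine and errors on missing features", {
  x <- withr::with_seed(4, matrix(rnorm(24), nrow = 4))
  e <- expr_tbl(x)
  m <- fit_pc(e)
  # new samples sitting at the training means project to exactly 0
  at_mean <- expr_tbl(matrix(rep(rowMeans(x), 2), ncol = 2),
                      feature_ids = sprintf("g%d", 1:4))
  expect_equal(project(m, at_mean)$pc_score, c(0, 0))
  expect_error(project(m, e[-2, ]), "g2")
})

test_that("projected held-out scores track the generating latent factor", {
  # every gene loads on the factor, so the matrix is near rank-1
  sim <- simulate_dataset("continuous", n_samples = 100, n_genes = 300,
                          n_signal = 300, effect = 2, seed = 21)
  ids <- expression_samples(sim$expression)
  train <- ids[1:50]; test <- ids[51:100]
  m <- fit_pc(sim$expression[, c("feature_id", train)])
  sc <- project(m, sim$expression[, c("feature_id", test)])
  u <- sim$truth$latent$u[match(test, sim$truth$latent$sample_id)]
  expect_gte(abs(cor(sc$pc_score, u)), 0.99)
})

test_that("cross-validation is deterministic and honest by construction", {
  sim <- simulate_dataset("continuous", n_samples = 45, n_genes = 40,
                          n_signal = 8, effect = 1.5, seed = 31)
  sc <- score_features(sim$expression, sim$outcome, "continuous")
  grid <- make_threshold_grid(sc, 4)
  folds <- make_folds(sim$outcome, "continuous", k = 3, seed = 31)
  cv1 <- cross_validate_threshold(sim$expression, sim$outcome, "continuous", grid, folds)
  cv2 <- cross_validate_threshold(sim$expression, sim$outcome, "continuous", grid, folds)
  expect_identical(cv1$stats, cv2$stats)
  expect_identical(cv1$optimal_threshold, cv2$optimal_threshold)

  # every fold statistic is reproducible from out-of-fold data alone
  ids <- expression_samples(sim$expression)
  for (f in seq_len(cv1$K)) {
    held_in <- folds$sample_id[folds$fold == f]
    oof <- setdiff(ids, held_in)
    e_oof <- sim$expression[, c("feature_id", oof)]
    o_oof <- sim$outcome[match(oof, sim$outcome$sample_id), ]
    s_oof <- score_features(e_oof, o_oof, "continuous")
    for (th in grid) {
      sel <- s_oof$feature_id[s_oof$abs_score > th]
      expected <- if (length(sel) == 0) 0 else {
        mod <- fit_pc(e_oof[match(sel, e_oof$feature_id), ])
        pc <- project(mod, sim$expression[, c("feature_id", held_in)])
        lr_statistic(pc$pc_score,
                     sim$outcome[match(held_in, sim$outcome$sample_id), ],
                     "continuous")
      }
      got <- cv1$stats$statistic[cv1$stats$fold == f & cv1$stats$threshold == th]
      expect_identical(got, expected)
    }
  }

  # corrupting a held-in fold cannot change that fold's training-side
  # screening (its selected-feature counts)
  e_bad <- sim$expression
  f1 <- folds$sample_id[folds$fold == 1]
  for (s in f1) e_bad[[s]] <- rev(e_bad[[s]])
  cv_bad <- cross_validate_threshold(e_bad, sim$outcome, "continuous", grid, folds)
  expect_identical(cv_bad$stats$n_features[cv_bad$stats$fold == 1],
                   cv1$stats$n_features[cv1$stats$fold == 1])
})

test_that("CV selects a threshold whose screened set captures the signal", {
  sim <- simulate_dataset("survival", n_samples = 60, n_genes = 200,
                          n_signal = 15, effect = 2, censor_rate = 0.3, seed = 77)
  sc <- score_features(sim$expression, sim$outcome, "survival")
  grid <- make_threshold_grid(sc, 8)
  folds <- make_folds(sim$outcome, "survival", k = 5, seed = 77)
  cv <- cross_validate_threshold(sim$expression, sim$outcome, "survival", grid, folds)
  sel <- screen_features(sc, cv$optimal_threshold)
  expect_gte(mean(sim$truth$signal_feature_ids %in% sel), 0.8)
})

test_that("CV rejects degenerate fold layouts", {
  sim <- simulate_dataset("survival", n_samples = 12, n_genes = 10, n_signal = 2,
                          effect = 1, censor_rate = 0.2, seed = 9)
  sc <- score_features(sim$expression, sim$outcome, "survival")
  grid <- make_threshold_grid(sc, 3)
  folds <- make_folds(sim$outcome, "survival", k = 3, seed = 9)
  expect_error(make_folds(sim$outcome, "survival", k = 13, seed = 1), "exceeds")

  # a fold whose training portion has no events
  o2 <- sim$outcome
  f1 <- folds$sample_id[folds$fold == 1]
  o2$event <- ifelse(o2$sample_id %in% f1, o2$event, 0L)
  if (sum(o2$event) > 0) {
    expect_error(cross_validate_threshold(sim$expression, o2, "survival", grid, folds),
                 "no events|fewer folds")
  }
})

test_that("the full pipeline is reproducible from seed or emitted fold file", {
  sim <- simulate_dataset("continuous", n_samples = 50, n_genes = 60, n_signal = 10,
                          effect = 2, seed = 55)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_superpc(sim$expression, sim$outcome, "continuous", n_thresholds = 4,
                    n_folds = 3, seed = 55, out_dir = d1)
  r2 <- run_superpc(sim$expression, sim$outcome, "continuous", n_thresholds = 4,
                    n_folds = 3, seed = 55, out_dir = d2)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_identical(r1$cv$curve, r2$cv$curve)

  d3 <- withr::local_tempdir()
  r3 <- run_superpc(sim$expression, sim$outcome, "continuous", n_thresholds = 4,
                    folds = file.path(d1, "folds.tsv"), out_dir = d3)
  expect_identical(readLines(file.path(d1, "cv_curve.tsv")),
                   readLines(file.path(d3, "cv_curve.tsv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d3, "summary.json")))
  expect_equal(sort(c("scores.tsv", "cv_curve.tsv", "folds.tsv", "model.json",
                      "predictions.tsv", "summary.json", "run-manifest.json",
                      "scatter.png", "scatter.svg")),
               sort(list.files(d1)))
})

test_that("tidiers and plots expose the fitted objects", {
  sim <- simulate_dataset("binary", n_samples = 50, n_genes = 40, n_signal = 8,
                          effect = 2, seed = 66)
  run <- run_superpc(sim$expression, sim$outcome, "binary", n_thresholds = 4,
                     n_folds = 3, seed = 66)
  expect_s3_class(tidy(run$model), "tbl_df")
  expect_equal(nrow(tidy(run$model)), length(run$model$feature_ids))
  expect_equal(glance(run)$test, "chi_square")
  expect_equal(sum(tidy(run$model)$loading^2), 1, tolerance = 1e-12)
  expect_s3_class(autoplot(run$cv), "ggplot")
  expect_s3_class(autoplot(run), "ggplot")
  expect_output(print(run), "binary outcome")
})
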