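# compact synthetic classification tables (direct construction, no simulator)
toy_table <- function(n_subjects = 6, trials_per_class = 3, sd = 0.1,
                      seed = 1, feature_names_ = c("u", "v")) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 0, 3, 3, 0, 3, 3), 4, 2, byrow = TRUE)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (cl in 1:4) {
      for (tr in seq_len(trials_per_class)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%02d", s), trial = tr, channel = 1L,
          label = cl,
          u = centers[cl, 1] + rnorm(1, 0, sd),
          v = centers[cl, 2] + rnorm(1, 0, sd))
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[5:6] <- feature_names_
  out
}

test_that("subject-level splits are disjoint, exhaustive and seeded", {
  ids <- sprintf("S%02d", 1:18)
  sp <- make_split(ids, 13, 5, seed = 9)
  expect_length(sp$train, 13)
  expect_length(sp$val, 5)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_identical(make_split(ids, 13, 5, seed = 9), sp)
  expect_false(identical(make_split(ids, 13, 5, seed = 10)$train, sp$train))
  expect_error(make_split(ids, 10, 5, seed = 1), "18 subjects")
})

test_that("LOSO model selection uses one fold per training subject and
           finds separable data trivially separable", {
  tab <- toy_table(n_subjects = 5, sd = 0.05)
  sel <- losocv_select(tab, spec_svm_linear(), c("u", "v"))
  expect_equal(sel$n_folds, 5)
  # separable: every C achieves 100 % CV accuracy; tie -> smallest C
  expect_equal(sel$cv_accuracy, 100)
  expect_true(all(sel$grid_accuracy$cv_accuracy == 100))
  expect_equal(sel$hp$cost, 0.1)
  expect_error(losocv_select(tab[tab$subject == "S01", ], spec_svm_linear(),
                             c("u", "v")), ">= 2")
})

test_that("hyperparameter ties resolve to the simplest model", {
  tab <- toy_table(n_subjects = 4, sd = 0.05)
  sel_knn <- losocv_select(tab, spec_knn(), c("u", "v"))
  expect_equal(sel_knn$hp$k, 1)
  sel_rbf <- losocv_select(tab, spec_svm_rbf(cost = c(1, 10),
                                             gamma = c(0.01, 0.1)),
                           c("u", "v"))
  expect_equal(sel_rbf$cv_accuracy, 100)
  expect_equal(unlist(sel_rbf$hp), c(cost = 1, gamma = 0.01))
})

test_that("label permutation drives CV accuracy to chance level", {
  accs <- vapply(1:5, function(i) {
    tab <- toy_table(n_subjects = 6, sd = 0.05, seed = 100 + i)
    tab$label <- sample(tab$label)
    losocv_select(tab, spec_knn(k = 3), c("u", "v"))$cv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 15)
  expect_lt(mean(accs), 35)
})

test_that("validation scoring is per subject and memorization-consistent", {
  tab <- toy_table(n_subjects = 4, sd = 0.3)
  res <- fit_predict(tab, tab, spec_knn(), data.frame(k = 1), c("u", "v"))
  expect_equal(res$mean_accuracy, 100)  # 1-NN memorizes its training set
  expect_length(res$per_subject, 4)
  # row order invariance
  tab2 <- toy_table(n_subjects = 5, sd = 0.2, seed = 3)
  tr <- tab2[tab2$subject %in% sprintf("S%02d", 1:3), ]
  te <- tab2[tab2$subject %in% sprintf("S%02d", 4:5), ]
  r1 <- fit_predict(tr, te, spec_lda(), data.frame(dummy = 0), c("u", "v"))
  perm <- sample(nrow(te))
  r2 <- fit_predict(tr, te[perm, ], spec_lda(), data.frame(dummy = 0),
                    c("u", "v"))
  expect_equal(sort(r2$per_subject), sort(r1$per_subject))
})

test_that("fitted models never see validation labels", {
  tab2 <- toy_table(n_subjects = 5, sd = 0.2, seed = 4)
  tr <- tab2[tab2$subject %in% sprintf("S%02d", 1:3), ]
  te <- tab2[tab2$subject %in% sprintf("S%02d", 4:5), ]
  te_shuffled <- te
  te_shuffled$label <- sample(te_shuffled$label)
  for (spec in list(spec_lda(), spec_svm_rbf(cost = 1, gamma = 0.1))) {
    hp <- spec$grid[1, , drop = FALSE]
    p1 <- fit_predict(tr, te, spec, hp, c("u", "v"))$predictions
    p2 <- fit_predict(tr, te_shuffled, spec, hp, c("u", "v"))$predictions
    expect_identical(p1, p2)
  }
})

test_that("the accuracy curve hits 100 % at m = 1 for a planted label copy
           and equals the all-features baseline at full m", {
  tab <- toy_table(n_subjects = 6, sd = 0.05, seed = 7,
                   feature_names_ = c("copy", "noise"))
  tab$copy <- tab$label + 0.01 * rnorm(nrow(tab))
  tab$noise <- rnorm(nrow(tab))
  split <- make_split(unique(tab$subject), 4, 2, seed = 2)
  train <- tab[tab$subject %in% split$train, ]
  rk <- rank_ig(train)
  expect_identical(rk$feature[1], "copy")
  curve <- accuracy_curve(tab, split, rk, spec_knn(k = c(1, 3)), ms = 1:2)
  expect_equal(nrow(curve), 2)
  expect_gte(curve$val_accuracy[1], 99)
  # full-m point is definitionally the no-selection evaluation
  spec <- spec_knn(k = c(1, 3))
  sel <- losocv_select(train, spec, c("copy", "noise"))
  base <- fit_predict(train, tab[tab$subject %in% split$val, ], spec,
                      sel$hp, c("copy", "noise"))
  expect_equal(curve$val_accuracy[curve$m == 2], base$mean_accuracy)
})

test_that("domain baselines cover the four disjoint feature groups", {
  groups <- list(feature_names("time"), feature_names("frequency"),
                 feature_names("wavelet"))
  expect_equal(vapply(groups, length, integer(1)), c(9L, 23L, 37L))
  expect_length(unlist(groups), 69)
  expect_identical(sort(unlist(groups)), sort(feature_names()))
})

test_that("domain baselines evaluate LDA on real extracted features, even
           with degenerate columns", {
  tab <- small_feature_table()
  split <- make_split(unique(tab$subject), 4, 2, seed = 3)
  b <- suppressWarnings(domain_baselines(tab, split, list(spec_lda())))
  expect_equal(nrow(b), 4)
  expect_identical(b$n_features, c(9L, 23L, 37L, 69L))
  expect_true(all(b$val_accuracy >= 0 & b$val_accuracy <= 100))
})
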