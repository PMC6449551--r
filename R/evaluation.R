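#' Subject-level train/validation split
#'
#' Uniformly random disjoint split of subjects into a training and a
#' validation group; every epoch of a subject falls on one side only, so no
#' cross-channel or cross-trial correlation leaks across the split.
#'
#' @param subject_ids Character vector of all subject ids.
#' @param n_train,n_val Group sizes; must sum to the number of subjects
#'   (defaults 13 and 5).
#' @param seed Integer seed making the split deterministic.
#' @return A list with `train`, `val` (character vectors) and `seed`.
#' @export
make_split <- function(subject_ids, n_train = 13, n_val = 5, seed = 1) {
  subject_ids <- unique(as.character(subject_ids))
  if (n_train + n_val != length(subject_ids)) {
    stop(sprintf("n_train + n_val = %d but there are %d subjects",
                 n_train + n_val, length(subject_ids)), call. = FALSE)
  }
  set.seed(seed)
  train <- sort(sample(subject_ids, n_train))
  list(train = train, val = sort(setdiff(subject_ids, train)), seed = seed)
}

#' Classifier specifications
#'
#' Model grids for the evaluation protocol: LDA (no hyperparameters), K-NN
#' with Euclidean distance and K searched over 1..20, and one-vs-one SVMs
#' with cost grid {0.1, 1, 10, 100} — linear kernel, Gaussian (RBF) kernel
#' with gamma in {0.001, 0.01, 0.1, 1}, and polynomial kernel of degree 3.
#' Grids are ordered simplest-first so hyperparameter ties resolve to the
#' smallest K / C / gamma.
#'
#' @param k,cost,gamma,degree Grid values; defaults as above.
#' @return A `model_spec` (kind + hyperparameter grid data frame).
#' @name model_specs
NULL

new_model_spec <- function(kind, grid) {
  structure(list(kind = kind, grid = grid), class = "model_spec")
}

#' @rdname model_specs
#' @export
spec_lda <- function() new_model_spec("LDA", data.frame(dummy = 0))

#' @rdname model_specs
#' @export
spec_knn <- function(k = 1:20) new_model_spec("KNN", data.frame(k = k))

#' @rdname model_specs
#' @export
spec_svm_linear <- function(cost = c(0.1, 1, 10, 100)) {
  new_model_spec("SVM_LINEAR", data.frame(cost = cost))
}

#' @rdname model_specs
#' @export
spec_svm_rbf <- function(cost = c(0.1, 1, 10, 100),
                         gamma = c(0.001, 0.01, 0.1, 1)) {
  new_model_spec("SVM_RBF", expand.grid(gamma = gamma, cost = cost)[
    , c("cost", "gamma")])
}

#' @rdname model_specs
#' @export
spec_svm_poly <- function(cost = c(0.1, 1, 10, 100), degree = 3) {
  new_model_spec("SVM_POLY", expand.grid(degree = degree, cost = cost)[
    , c("cost", "degree")])
}

# order the grid simplest-first (small K, small C, small gamma)
grid_order <- function(spec) {
  g <- spec$grid
  do.call(order, unname(as.list(g[, rev(names(g)), drop = FALSE])))
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, z) {
  sweep(sweep(as.matrix(X), 2, z$mu), 2, z$sd, "/")
}

fit_predict_once <- function(kind, hp, Xtr, ytr, Xte, seed = 1) {
  ytr <- factor(ytr, levels = sort(unique(ytr)))
  pred <- switch(
    kind,
    LDA = {
      # lda() refuses variables with (near-)zero pooled within-group
      # variance; such columns carry no discriminant information, drop them
      ok <- vapply(seq_len(ncol(Xtr)), function(j) {
        wv <- tapply(Xtr[, j], ytr, stats::var)
        sqrt(mean(wv, na.rm = TRUE)) > 1e-7
      }, logical(1))
      if (!any(ok)) {
        rep(names(which.max(table(ytr))), nrow(Xte))
      } else {
        fit <- MASS::lda(Xtr[, ok, drop = FALSE], grouping = ytr)
        stats::predict(fit, Xte[, ok, drop = FALSE])$class
      }
    },
    KNN = {
      set.seed(seed)  # knn breaks vote ties at random
      class::knn(Xtr, Xte, cl = ytr, k = hp$k)
    },
    SVM_LINEAR = stats::predict(
      e1071::svm(Xtr, ytr, kernel = "linear", cost = hp$cost, scale = FALSE,
                 tolerance = 0.01, cachesize = 200), Xte),
    SVM_RBF = stats::predict(
      e1071::svm(Xtr, ytr, kernel = "radial", cost = hp$cost,
                 gamma = hp$gamma, scale = FALSE,
                 tolerance = 0.01, cachesize = 200), Xte),
    SVM_POLY = stats::predict(
      e1071::svm(Xtr, ytr, kernel = "polynomial", cost = hp$cost,
                 degree = hp$degree, coef0 = 1, scale = FALSE,
                 tolerance = 0.01, cachesize = 200), Xte),
    stop("unknown model kind: ", kind, call. = FALSE))
  as.integer(as.character(pred))
}

#' Leave-one-subject-out hyperparameter selection
#'
#' For every hyperparameter combination in the grid, each training subject
#' is in turn held out, the model is fitted on the remaining subjects
#' (features z-scored with fold-train statistics only) and evaluated on the
#' held-out subject; the combination maximizing the mean per-subject
#' accuracy wins, ties resolving to the simplest model (smallest K, C,
#' gamma). With 13 training subjects this gives exactly 13 folds.
#'
#' Folds whose training side lacks one of the classes are skipped with a
#' warning (possible in tiny synthetic configurations).
#'
#' @param train_table Feature table restricted to training subjects.
#' @param spec A model spec (see [spec_lda()] and friends).
#' @param features Character vector of feature columns to use.
#' @return List with `hp` (chosen row of the grid), `cv_accuracy` (percent),
#'   `n_folds`, and `grid_accuracy` (per-combination CV accuracy).
#' @export
losocv_select <- function(train_table, spec,
                          features = feature_names()) {
  subjects <- unique(train_table$subject)
  if (length(subjects) < 2) stop("need >= 2 training subjects", call. = FALSE)
  folds <- lapply(subjects, function(s) {
    tr <- train_table$subject != s
    if (length(unique(train_table$label[tr])) < 4) {
      warning(sprintf("fold %s skipped: training side lacks a class", s))
      return(NULL)
    }
    z <- standardizer(train_table[tr, features, drop = FALSE])
    list(Xtr = apply_standardizer(train_table[tr, features, drop = FALSE], z),
         ytr = train_table$label[tr],
         Xte = apply_standardizer(train_table[!tr, features, drop = FALSE], z),
         yte = train_table$label[!tr])
  })
  folds <- Filter(Negate(is.null), folds)
  ord <- grid_order(spec)
  acc <- vapply(ord, function(gi) {
    hp <- spec$grid[gi, , drop = FALSE]
    mean(vapply(folds, function(f) {
      pred <- fit_predict_once(spec$kind, hp, f$Xtr, f$ytr, f$Xte)
      100 * mean(pred == f$yte)
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)  # first max = simplest thanks to grid order
  list(hp = spec$grid[ord[best], , drop = FALSE],
       cv_accuracy = acc[best],
       n_folds = length(folds),
       grid_accuracy = data.frame(spec$grid[ord, , drop = FALSE],
                                  cv_accuracy = acc, row.names = NULL))
}

#' Fit on all training subjects and score validation subjects
#'
#' Refits the model (chosen hyperparameters) on every training row,
#' z-scoring with training statistics, then reports one accuracy per
#' validation subject — correct predictions over that subject's
#' (trial x channel) rows — and their mean, in percent.
#'
#' @param train_table,test_table Feature tables for the two sides.
#' @param spec Model spec.
#' @param hp A single-row data frame of hyperparameters.
#' @param features Feature columns to use.
#' @return List with `per_subject` (named accuracies, %), `mean_accuracy`,
#'   and the raw `predictions` (integer class codes, one per test row).
#' @export
fit_predict <- function(train_table, test_table, spec, hp,
                        features = feature_names()) {
  z <- standardizer(train_table[, features, drop = FALSE])
  Xtr <- apply_standardizer(train_table[, features, drop = FALSE], z)
  Xte <- apply_standardizer(test_table[, features, drop = FALSE], z)
  pred <- fit_predict_once(spec$kind, hp, Xtr, train_table$label, Xte)
  subj <- test_table$subject
  per_subject <- vapply(split(pred == test_table$label, subj),
                        function(ok) 100 * mean(ok), numeric(1))
  list(per_subject = per_subject, mean_accuracy = mean(per_subject),
       predictions = pred)
}

#' Accuracy as a function of the number of top-ranked features
#'
#' For each requested subset size m, takes the ranking's top-m feature
#' names, selects hyperparameters by leave-one-subject-out CV on the
#' training subjects, refits, and scores the validation subjects. With
#' m = 69 this equals the no-selection baseline for the same classifier and
#' split.
#'
#' @param table Full feature table.
#' @param split A [make_split()] plan.
#' @param ranking A `ranking_result` (fitted on training subjects to avoid
#'   leakage).
#' @param spec Model spec.
#' @param ms Subset sizes to evaluate (default 1..number of ranked
#'   features).
#' @return Data frame with one row per m: criterion, classifier, m,
#'   CV accuracy, validation accuracy, chosen hyperparameters (as text).
#' @export
accuracy_curve <- function(table, split, ranking, spec,
                           ms = seq_along(ranking$feature)) {
  train <- table[table$subject %in% split$train, , drop = FALSE]
  test <- table[table$subject %in% split$val, , drop = FALSE]
  rows <- lapply(ms, function(m) {
    feats <- ranking$feature[seq_len(m)]
    sel <- losocv_select(train, spec, feats)
    res <- fit_predict(train, test, spec, sel$hp, feats)
    data.frame(criterion = ranking$criterion, classifier = spec$kind,
               m = m, cv_accuracy = sel$cv_accuracy,
               val_accuracy = res$mean_accuracy,
               hp = paste(names(sel$hp), unlist(sel$hp), sep = "=",
                          collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' No-selection baselines per feature domain
#'
#' Evaluates each classifier on the four fixed column groups — time (9),
#' frequency (23), wavelet (37) and all (69) features — without any
#' ranking.
#'
#' @param table Full feature table.
#' @param split A [make_split()] plan.
#' @param specs List of model specs.
#' @return Data frame, one row per (classifier, domain group).
#' @export
domain_baselines <- function(table, split, specs) {
  groups <- list(time = feature_names("time"),
                 frequency = feature_names("frequency"),
                 wavelet = feature_names("wavelet"),
                 all = feature_names())
  train <- table[table$subject %in% split$train, , drop = FALSE]
  test <- table[table$subject %in% split$val, , drop = FALSE]
  rows <- list()
  for (spec in specs) {
    for (g in names(groups)) {
      sel <- losocv_select(train, spec, groups[[g]])
      res <- fit_predict(train, test, spec, sel$hp, groups[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = spec$kind, domain = g,
        n_features = length(groups[[g]]),
        cv_accuracy = sel$cv_accuracy, val_accuracy = res$mean_accuracy,
        hp = paste(names(sel$hp), unlist(sel$hp), sep = "=", collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
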