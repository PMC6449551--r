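#' Run the full synthetic pain-classification pipeline
#'
#' Simulate a multi-subject dataset, preprocess every recording, extract the
#' 69-feature table, split subjects 13/5 (or proportionally for other
#' subject counts), rank features on the training subjects only, and trace
#' accuracy over top-m feature subsets for the requested classifiers.
#' Every stochastic step is seeded from `seed`, so the returned report is a
#' pure function of its arguments.
#'
#' @param cfg A [sim_config()]; its own `seed` is overridden by `seed`.
#' @param seed Master seed for simulation, splitting and evaluation.
#' @param criteria Ranking criteria to run, subset of
#'   `c("JMI", "IG", "CHI2")`.
#' @param specs List of model specs (default: Gaussian-kernel SVM).
#' @param ms Top-m subset sizes for the accuracy curves.
#' @param preprocess A [preprocess_config()].
#' @param baselines If `TRUE`, also compute the no-selection per-domain
#'   baselines.
#' @return A list of class `eval_report`: `features` (the feature table),
#'   `split`, `rankings`, `curves` (one data frame), and optionally
#'   `baselines`.
#' @export
run_pipeline <- function(cfg = sim_config(), seed = cfg$seed,
                         criteria = "JMI",
                         specs = list(spec_svm_rbf()),
                         ms = c(1, 5, 13, 25, 69),
                         preprocess = preprocess_config(),
                         baselines = FALSE) {
  cfg$seed <- as.integer(seed)
  sims <- simulate_dataset(cfg)
  epochs <- unlist(lapply(sims, function(s) {
    rec <- preprocess_recording(s$recording, preprocess,
                                rest_len_s = cfg$rest_len_s)
    extract_epochs(rec, cfg$epoch_len_s)
  }), recursive = FALSE)
  grid_s <- spectral_grid(cfg$epoch_len_s)
  tab <- extract_all(epochs, spectral = grid_s)

  subjects <- unique(tab$subject)
  n_val <- max(1L, round(length(subjects) * 5 / 18))
  split <- make_split(subjects, length(subjects) - n_val, n_val,
                      seed = seed + 1L)
  train <- tab[tab$subject %in% split$train, , drop = FALSE]

  rankers <- list(JMI = rank_jmi, IG = rank_ig, CHI2 = rank_chi2)
  rankings <- lapply(rankers[criteria], function(f) f(train))
  ms <- ms[ms <= length(feature_names())]

  curves <- list()
  for (cr in criteria) {
    for (spec in specs) {
      curves[[length(curves) + 1L]] <-
        accuracy_curve(tab, split, rankings[[cr]], spec, ms = ms)
    }
  }
  report <- list(features = tab, split = split, rankings = rankings,
                 curves = do.call(rbind, curves))
  if (baselines) {
    report$baselines <- domain_baselines(tab, split, specs)
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d samples x %d features; train %d / val %d subjects\n",
              nrow(x$features), length(feature_names()),
              length(x$split$train), length(x$split$val)))
  print(x$curves, ...)
  invisible(x)
}
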