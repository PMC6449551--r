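#' Discretization configuration for filter criteria
#'
#' Continuous features are binned before any information-theoretic or
#' chi-squared scoring. Equal-frequency binning (edges at empirical
#' quantiles, duplicate edges merged) is the default, as it is robust to the
#' heavy-tailed spectral and wavelet-energy features.
#'
#' @param n_bins Number of bins (default 10, minimum 2).
#' @param strategy `"equal-frequency"` or `"equal-width"`.
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(n_bins = 10,
                                  strategy = c("equal-frequency",
                                               "equal-width")) {
  strategy <- match.arg(strategy)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  structure(list(n_bins = as.integer(n_bins), strategy = strategy),
            class = "discretization_config")
}

#' Discretize a continuous feature into bins
#'
#' Maps each value to an integer bin index in `[0, n_bins)`. The mapping is
#' monotone; a constant feature collapses to a single bin (index 0), which
#' correctly yields zero mutual information downstream.
#'
#' @param values Numeric vector.
#' @param cfg A [discretization_config()].
#' @param breaks Optional pre-computed interior cut points (from a training
#'   split), as returned in the `breaks` attribute; when supplied the data
#'   are mapped onto those cuts, which is how evaluation avoids leakage.
#' @return Integer vector of 0-based bin indices, with the interior cut
#'   points attached as attribute `breaks`.
#' @export
discretize <- function(values, cfg = discretization_config(), breaks = NULL) {
  if (is.null(breaks)) {
    ux <- sort(unique(values))
    breaks <- if (length(ux) <= cfg$n_bins) {
      # few distinct values: keep each in its own bin (cuts at midpoints)
      (ux[-1] + ux[-length(ux)]) / 2
    } else if (cfg$strategy == "equal-frequency") {
      edges <- unique(stats::quantile(
        values, probs = seq(0, 1, length.out = cfg$n_bins + 1),
        names = FALSE, type = 7))
      edges[-c(1, length(edges))]
    } else {
      edges <- seq(min(values), max(values), length.out = cfg$n_bins + 1)
      edges[-c(1, length(edges))]
    }
  }
  idx <- findInterval(values, breaks, left.open = TRUE)
  structure(as.integer(idx), breaks = breaks)
}

#' Plug-in mutual information between two discrete vectors
#'
#' `I(A;B) = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )` over the empirical
#' joint distribution, in bits; zero-count cells contribute zero.
#'
#' @param a,b Equal-length vectors of discrete symbols.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  ai <- as.integer(factor(a))
  bi <- as.integer(factor(b))
  mi_codes(ai, max(ai), bi, max(bi))
}

# plug-in MI (bits) for 1-based integer codes with known alphabet sizes
mi_codes <- function(ai, na, bi, nb) {
  n <- length(ai)
  joint <- tabulate((ai - 1L) * nb + bi, nbins = na * nb) / n
  pa <- tabulate(ai, nbins = na) / n
  pb <- tabulate(bi, nbins = nb) / n
  pp <- as.vector(outer(pb, pa))  # column-major: b fastest, matches joint
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pp[nz]))
}

new_ranking <- function(criterion, names_, scores, trace = NULL) {
  structure(list(criterion = criterion, feature = names_,
                 score = unname(scores), trace = trace),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s, %d features; top 5: %s\n", x$criterion,
              length(x$feature), paste(utils::head(x$feature, 5),
                                       collapse = ", ")))
  invisible(x)
}

rank_input <- function(features) {
  fn <- intersect(feature_names(), names(features))
  if (!length(fn)) fn <- setdiff(names(features), feature_meta_cols())
  list(X = features[, fn, drop = FALSE],
       y = features$label, names = fn)
}

# descending stable order: ties keep canonical (input) feature order
order_desc_stable <- function(scores) order(-scores, seq_along(scores))

#' Rank features by information gain
#'
#' Scores each feature by the mutual information (bits) between its
#' discretized values and the class label, sorted descending with ties
#' broken by canonical feature order.
#'
#' @param features Feature table (metadata + feature columns, including
#'   `label`).
#' @param cfg A [discretization_config()].
#' @return A `ranking_result` (ordered names + scores).
#' @export
rank_ig <- function(features, cfg = discretization_config()) {
  inp <- rank_input(features)
  scores <- vapply(inp$X, function(v)
    mutual_information(discretize(v, cfg), inp$y), numeric(1))
  o <- order_desc_stable(scores)
  new_ranking("IG", inp$names[o], scores[o])
}

#' Rank features by the chi-squared statistic
#'
#' Pearson chi-squared statistic (no continuity correction) of the
#' feature-bin x class contingency table, per feature; descending, stable
#' ties.
#'
#' @inheritParams rank_ig
#' @return A `ranking_result`.
#' @export
rank_chi2 <- function(features, cfg = discretization_config()) {
  inp <- rank_input(features)
  scores <- vapply(inp$X, function(v) {
    tab <- table(discretize(v, cfg), inp$y)
    chi2_stat(tab)
  }, numeric(1))
  o <- order_desc_stable(scores)
  new_ranking("CHI2", inp$names[o], scores[o])
}

chi2_stat <- function(tab) {
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  ok <- expected > 0
  sum((tab[ok] - expected[ok])^2 / expected[ok])
}

#' Rank features by joint mutual information (greedy forward selection)
#'
#' The first feature maximizes `I(f; Y)`. Each subsequent pick maximizes
#' `J(f) = sum over selected s of I((f, s); Y)`, where `(f, s)` is the joint
#' symbol of the two discretized features — so a candidate is rewarded for
#' carrying label information jointly with what is already selected, which
#' demotes redundant duplicates in favour of complementary features. Ties
#' fall back to canonical feature order. The full permutation is returned
#' together with the per-step objective values.
#'
#' @inheritParams rank_ig
#' @return A `ranking_result`; `$trace` holds the greedy per-step objective.
#' @export
rank_jmi <- function(features, cfg = discretization_config()) {
  inp <- rank_input(features)
  yi <- as.integer(factor(inp$y))
  ny <- max(yi)
  disc <- lapply(inp$X, function(v) as.integer(discretize(v, cfg)) + 1L)
  nbin <- vapply(disc, max, integer(1))
  p <- length(disc)
  mi1 <- vapply(seq_len(p), function(j)
    mi_codes(disc[[j]], nbin[j], yi, ny), numeric(1))
  # step 1: single mutual information; afterwards the greedy objective
  # J(f) = sum_s I((f,s); Y) grows by one term per step, so it is
  # accumulated incrementally
  first <- order_desc_stable(mi1)[1]
  selected <- first
  remaining <- setdiff(seq_len(p), first)
  scores <- numeric(p)
  scores[1] <- mi1[first]
  jsum <- numeric(p)  # running J for every feature vs current selected set
  step <- 1L
  while (length(remaining)) {
    s <- selected[step]
    for (f in remaining) {
      joint <- (disc[[f]] - 1L) * nbin[s] + disc[[s]]
      jsum[f] <- jsum[f] + mi_codes(joint, nbin[f] * nbin[s], yi, ny)
    }
    step <- step + 1L
    pick <- remaining[order(-jsum[remaining], remaining)[1]]
    scores[step] <- jsum[pick]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  new_ranking("JMI", inp$names[selected], scores,
              trace = data.frame(step = seq_len(p),
                                 feature = inp$names[selected],
                                 objective = scores))
}
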