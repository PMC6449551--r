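test_that("equal-frequency discretization bins and maps monotonically", {
  set.seed(10)
  v <- sample(seq_len(100))
  b <- discretize(v, discretization_config(10))
  expect_identical(as.vector(table(b)), rep(10L, 10))
  expect_identical(sort(unique(as.integer(b))), 0:9)
  # monotone: v1 <= v2 => bin(v1) <= bin(v2)
  o <- order(v)
  expect_true(all(diff(as.integer(b)[o]) >= 0))
  # constant feature collapses to one bin
  expect_identical(as.integer(discretize(rep(5, 30))), rep(0L, 30))
  # training-fitted edges can be re-applied to held-out data
  tr <- rnorm(200)
  btr <- discretize(tr)
  bte <- discretize(rnorm(50), breaks = attr(btr, "breaks"))
  expect_true(all(as.integer(bte) %in% 0:9))
})

test_that("mutual information matches hand-computed plug-in values", {
  a <- rep(1:4, each = 25)
  expect_equal(mutual_information(a, a), 2)  # I(X;X) = H(X) = 2 bits
  # independent by construction: all 16 combinations equally often
  g <- expand.grid(a = 1:4, b = 1:4)
  expect_equal(mutual_information(g$a, g$b), 0)
  # 2x2 table [[3,1],[1,3]], n = 8: frozen hand-computed plug-in sum
  a2 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  b2 <- c(0, 0, 0, 1, 0, 1, 1, 1)
  expect_equal(mutual_information(a2, b2),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-12)
  expect_equal(mutual_information(a2, b2), 0.188721875540867,
               tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5), "same length")
})

test_that("information gain ranks a label copy first with score H(Y)", {
  set.seed(20)
  n <- 200
  y <- rep(1:4, each = n / 4)
  tab <- data.frame(label = y,
                    noise1 = rnorm(n), copy = y + 0, noise2 = rnorm(n))
  rk <- rank_ig(tab)
  expect_identical(rk$feature[1], "copy")
  expect_equal(rk$score[1], 2)  # H(Y) for 4 balanced classes
  # permutation invariance over rows
  perm <- sample(n)
  rk2 <- rank_ig(tab[perm, ])
  expect_identical(rk2$feature, rk$feature)
  expect_equal(rk2$score, rk$score)
  expect_setequal(rk$feature, c("noise1", "copy", "noise2"))
})

test_that("chi-squared ranking matches the 2x2 closed form", {
  # perfect association, 10 per diagonal cell: chi2 = N (ad-bc)^2 / products
  tab <- table(rep(0:1, each = 10), rep(0:1, each = 10))
  expect_equal(painfnirs:::chi2_stat(tab), 20)
  # factorizing balanced table -> 0
  g <- expand.grid(a = 0:1, b = 0:1)
  expect_equal(painfnirs:::chi2_stat(table(g$a, g$b)), 0)
  set.seed(31)
  feats <- data.frame(label = rep(1:4, 30),
                      f1 = rnorm(120), f2 = rnorm(120), f3 = rnorm(120))
  rk <- rank_chi2(feats)
  expect_true(all(rk$score >= 0))
  expect_setequal(rk$feature, c("f1", "f2", "f3"))
})

test_that("JMI promotes complementary features over redundant duplicates", {
  # y has two independent bits; f1/f2 both carry the high bit, f3 the parity
  set.seed(40)
  y <- rep(1:4, each = 30)
  hi <- as.integer(y > 2)
  parity <- y %% 2
  tab <- data.frame(label = y, f1 = hi + 0, f2 = hi + 0, f3 = parity + 0)
  rk <- rank_jmi(tab)
  expect_identical(rk$feature[1], "f1")          # tie broken by order
  expect_identical(rk$feature[2], "f3")          # complement beats duplicate
  expect_identical(rk$feature[3], "f2")
  expect_equal(rk$score[2], 2)                   # (f3, f1) determine Y fully
  # step-1 score is the plain mutual information maximum
  expect_equal(rk$score[1], 1)
})

test_that("greedy JMI equals an independent entropy-based oracle", {
  set.seed(50)
  n <- 150
  y <- sample(1:4, n, replace = TRUE)
  X <- data.frame(a = y + rnorm(n, 0, 0.5), b = rnorm(n),
                  c = (y %% 2) + rnorm(n, 0, 0.3), d = rnorm(n),
                  e = y + rnorm(n, 0, 2), f = runif(n))
  tab <- cbind(data.frame(label = y), X)
  rk <- rank_jmi(tab)
  expect_identical(rk$feature, jmi_oracle(X, y))
  # with a single selected feature, step 2 reduces to I((f, s1); Y)
  disc <- lapply(X, function(v) as.integer(discretize(v)))
  s1 <- rk$feature[1]
  pairwise <- vapply(setdiff(names(X), s1), function(f)
    mutual_information(paste(disc[[f]], disc[[s1]]), y), numeric(1))
  expect_identical(rk$feature[2], names(which.max(pairwise)))
  expect_equal(rk$score[2], unname(max(pairwise)))
})

test_that("all three criteria return permutations and find planted signal", {
  set.seed(60)
  n <- 160
  y <- rep(1:4, n / 4)
  hits <- c(IG = 0, CHI2 = 0, JMI = 0)
  n_trials <- 25
  for (i in seq_len(n_trials)) {
    tab <- data.frame(label = y, n1 = rnorm(n), n2 = rnorm(n),
                      planted = y + 0, n3 = rnorm(n))
    for (rk in list(rank_ig(tab), rank_chi2(tab), rank_jmi(tab))) {
      expect_setequal(rk$feature, c("n1", "n2", "planted", "n3"))
      if (rk$feature[1] == "planted") {
        hits[rk$criterion] <- hits[rk$criterion] + 1
      }
    }
  }
  expect_identical(unname(hits), rep(n_trials, 3))
})
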