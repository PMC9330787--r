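test_that("AIRM distance matches eigenvalue closed forms", {
  expect_equal(airm_distance(diag(4), diag(4)), 0)
  expect_equal(airm_distance(diag(5), 4 * diag(5)), sqrt(5) * log(4))

  p <- make_spd_pair(6, 2, seed = 1)
  expect_equal(airm_distance(p$a, p$a), 0, tolerance = 1e-10)
  # congruence invariance
  withr::with_seed(2, w <- matrix(rnorm(36), 6))
  expect_equal(airm_distance(t(w) %*% p$a %*% w, t(w) %*% p$b %*% w),
               airm_distance(p$a, p$b), tolerance = 1e-8)
  # symmetry
  expect_equal(airm_distance(p$a, p$b), airm_distance(p$b, p$a),
               tolerance = 1e-10)
  expect_error(airm_distance(diag(3), diag(4)))
  expect_error(airm_distance(matrix(c(1, 2, 3, 4), 2), diag(2)))
})

test_that("Riemannian mean agrees with closed forms", {
  a <- make_spd_pair(5, 2, seed = 3)$a
  expect_equal(riemann_mean(list(a)), a)
  # two points: geodesic midpoint
  p <- make_spd_pair(5, 2, seed = 4)
  expect_equal(riemann_mean(list(p$a, p$b)), spd_geodesic(p$a, p$b, 0.5),
               tolerance = 1e-7)
  # commuting diagonal family: elementwise geometric mean
  d1 <- diag(c(1, 2, 3)); d2 <- diag(c(4, 5, 6)); d3 <- diag(c(7, 8, 9))
  gm <- diag((c(1, 2, 3) * c(4, 5, 6) * c(7, 8, 9))^(1 / 3))
  expect_equal(riemann_mean(list(d1, d2, d3)), gm, tolerance = 1e-7)
})

test_that("sample covariance matches hand-computed values and regularizes", {
  # two channels in perfect anti-phase, unit variance
  w <- cbind(c(1, -1, 1, -1), c(-1, 1, -1, 1))
  s <- scm(w)
  expect_true(attr(s, "regularized"))  # correlation -1 -> rank 1 -> ridge
  ridge <- s[1, 1] - 4 / 3             # hand-computed variance 4/3
  expect_gt(ridge, 0); expect_lt(ridge, 1e-6)
  expect_equal(s[1, 2], -4 / 3)
  expect_equal(s[2, 2] - ridge, 4 / 3)
  expect_gt(min(eigen(s, symmetric = TRUE)$values), 0)

  # large-n white noise: approximately the diagonal of channel variances
  withr::with_seed(5, big <- matrix(rnorm(20000 * 3), ncol = 3) %*%
                     diag(c(1, 2, 3)))
  sb <- scm(big)
  expect_equal(diag(sb), c(1, 4, 9), tolerance = 0.1)
  expect_lt(max(abs(sb[upper.tri(sb)])), 0.1)

  expect_warning(scm(matrix(1, 10, 2)), "Zero-variance")
  cs <- suppressWarnings(scm(matrix(1, 10, 2)))
  expect_equal(cs[1, 2], 0)
  expect_gt(cs[1, 1], 0)
})

test_that("all four classifiers separate well-separated classes", {
  ep <- two_class_epochs(dim = 8, separation = 4, n_per_class = 64, seed = 9)
  for (k in c("mdm", "mdm_filter", "ts_lda", "ts_svm")) {
    mod <- fit_riemann(ep, k)
    acc <- mean(predict(mod, ep$cov)$label == ep$label)
    expect_gt(acc, 0.95)
  }
  expect_error(fit_riemann(dplyr::filter(ep, label == "walk"), "mdm"))
})

test_that("MDM predictions use geodesic means with walk-favoring ties", {
  ep <- two_class_epochs(dim = 5, separation = 3, n_per_class = 2,
                         n_samp = 60, seed = 10)
  mod <- fit_riemann(ep, "mdm")
  # 2 epochs/class: class means are geodesic midpoints
  for (cls in c("walk", "intent")) {
    pair <- ep$cov[ep$label == cls]
    expect_equal(mod$class_means[[cls]],
                 spd_geodesic(pair[[1]], pair[[2]], 0.5), tolerance = 1e-6)
  }
  # an epoch equal to a class mean is assigned to it
  expect_equal(predict(mod, mod$class_means$intent)$label, "intent")
  expect_equal(predict(mod, mod$class_means$walk)$label, "walk")
  # the geodesic midpoint of the class means is equidistant: tie -> walk
  mid <- spd_geodesic(mod$class_means$walk, mod$class_means$intent, 0.5)
  expect_equal(predict(mod, mid)$label, "walk")

  # permutation invariance of training
  ep_shuf <- ep[c(3, 1, 4, 2), ]
  mod2 <- fit_riemann(ep_shuf, "mdm")
  expect_equal(mod$class_means$walk, mod2$class_means$walk,
               tolerance = 1e-8)
})

test_that("classifier accuracy grows with class separation", {
  seps <- c(0.02, 0.2, 2)
  mean_acc <- vapply(seps, function(s) {
    accs <- vapply(1:5, function(seed) {
      tr <- two_class_epochs(dim = 5, separation = s, n_per_class = 24,
                             n_samp = 40, seed = 40 + seed)
      te <- two_class_epochs(dim = 5, separation = s, n_per_class = 12,
                             n_samp = 40, seed = 140 + seed)
      mod <- fit_riemann(tr, "mdm")
      mean(predict(mod, te$cov)$label == te$label)
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(mean_acc) >= 0))
  expect_gt(mean_acc[3], mean_acc[1])
})

test_that("electrode ranking recovers planted channel differences", {
  withr::with_seed(11, {
    base <- make_spd_pair(10, 0.5, seed = 12)$a
    bumped <- base
    bumped[3, 3] <- bumped[3, 3] * 4
    bumped[7, 7] <- bumped[7, 7] * 4
    bumped[3, 7] <- bumped[7, 3] <- bumped[3, 7] + 2
    ep <- tibble::tibble(
      label = rep(c("walk", "intent"), each = 24),
      cov = c(sample_cov_epochs(base, 24, 200),
              sample_cov_epochs(bumped, 24, 200)))
    rk <- rank_electrodes(ep, sizes = c(6, 4, 2))
    expect_setequal(rk$subsets$top2, c(3, 7))
    expect_true(all(rk$subsets$top2 %in% rk$subsets$top4))
    expect_true(all(rk$subsets$top4 %in% rk$subsets$top6))
    expect_true(all(rk$v >= 0))
  })
  # identical classes: degenerate ranking flagged
  ident <- tibble::tibble(label = rep(c("walk", "intent"), each = 2),
                          cov = rep(list(diag(4)), 4))
  expect_warning(rk0 <- rank_electrodes(ident, sizes = c(2)), "degenerate")
  expect_true(rk0$degenerate)
})

test_that("electrode-subset models act on the principal submatrix", {
  ep <- two_class_epochs(dim = 8, separation = 4, n_per_class = 16,
                         seed = 13)
  sub <- c(1, 3, 5)
  mod <- fit_riemann(ep, "mdm", electrodes = sub)
  expect_equal(dim(mod$class_means$walk), c(3, 3))
  direct <- fit_riemann(
    dplyr::mutate(ep, cov = lapply(cov, function(c) c[sub, sub])), "mdm")
  expect_equal(mod$class_means$walk, direct$class_means$walk,
               tolerance = 1e-8)
  p <- predict(mod, ep$cov)
  expect_true(all(p$label %in% c("walk", "intent")))
})
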