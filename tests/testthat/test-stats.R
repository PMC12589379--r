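# group_stats: ANCOVA/Tukey/Cohen's d, ROC/DeLong, severity regression,
# permutation cluster test

test_that("ANCOVA coefficients match a normal-equations oracle", {
  set.seed(12)
  n <- 12
  g <- factor(rep(c("a", "b"), each = 6))
  age <- runif(n, 50, 85)
  sex <- sample(c("m", "f"), n, replace = TRUE)
  y <- rnorm(n) + 2 * (g == "b") + 0.05 * age
  fit <- ancova(y, g, age, sex)
  X <- model.matrix(~ g + age + factor(sex))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
})

test_that("ANCOVA exact null and hand-computable Cohen's d", {
  g <- factor(rep(c("a", "b"), each = 3))
  age <- rep(c(60, 75, 80), 2)          # not collinear with the response
  y <- rep(c(1, 2, 3), 2)                              # identical multisets
  fit <- ancova(y, g, age)
  expect_equal(fit$group_t, 0, tolerance = 1e-10)
  expect_equal(fit$cohens_d["a", "b"], 0, tolerance = 1e-12)
  # {1,2,3} vs {3,4,5}: means 2 vs 4, pooled SD 1 -> d = 2
  fit2 <- ancova(c(1, 2, 3, 3, 4, 5), g)
  expect_equal(fit2$cohens_d["b", "a"], 2, tolerance = 1e-12)
  expect_equal(fit2$cohens_d["a", "b"], -2, tolerance = 1e-12)
})

test_that("ANCOVA with constant covariates reduces to the covariate-free model", {
  set.seed(3)
  y <- rnorm(10)
  g <- factor(rep(c("a", "b"), 5))
  plain <- ancova(y, g)
  degen <- ancova(y, g, age = rep(65, 10), sex = rep("m", 10))
  expect_equal(degen$group_t, plain$group_t, tolerance = 1e-12)
  expect_equal(degen$adjusted_means, plain$adjusted_means, tolerance = 1e-12)
})

test_that("ANCOVA validates groups and rank", {
  y <- rnorm(9)
  expect_error(ancova(y, rep("a", 9)), class = "petref_validation_error")
  g <- factor(rep(c("a", "b", "c"), each = 3))
  expect_error(ancova(y, g, age = as.numeric(g == "b") * 2 + 1),
               "collinear")
  # three-group Tukey matrix is symmetric with p in [0, 1]
  set.seed(8)
  fit <- ancova(rnorm(15), factor(rep(c("a", "b", "c"), each = 5)))
  expect_equal(fit$tukey_p, t(fit$tukey_p))
  expect_true(all(fit$tukey_p[upper.tri(fit$tukey_p)] >= 0 &
                    fit$tukey_p[upper.tri(fit$tukey_p)] <= 1))
  expect_equal(fit$cohens_d, -t(fit$cohens_d))
})

test_that("ROC matches exhaustive pair counting and handles the printed example", {
  sc <- c(1, 2, 3); sp <- c(2.5, 3.5, 4)
  scores <- c(sc, sp); labels <- rep(c(FALSE, TRUE), each = 3)
  r <- roc(scores, labels)
  expect_equal(r$auc, 8 / 9)
  expect_equal(r$auc, auc_oracle(scores, labels))
  # random fixtures with ties against the oracle
  set.seed(14)
  for (i in 1:10) {
    s <- sample(round(rnorm(20), 1))                   # induces ties
    l <- rep(c(TRUE, FALSE), each = 10)
    expect_equal(roc(s, l)$auc, auc_oracle(s, l))
  }
  expect_error(roc(1:5, rep(TRUE, 5)), class = "petref_validation_error")
})

test_that("ROC symmetry, perfect separation, cutoff brute-force oracle", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c(FALSE, TRUE), each = 3)
  r <- roc(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(roc(scores, !labels)$auc, 0)            # label flip
  set.seed(15)
  s <- round(rnorm(24), 1); l <- rep(c(TRUE, FALSE), 12)
  r2 <- roc(s, l)
  # brute-force threshold scan
  thr <- sort(unique(s))
  J <- sapply(thr, function(t) mean(s[l] >= t) + mean(s[!l] < t) - 1)
  expect_equal(r2$cutoff, thr[which(J == max(J))[1]])
  expect_equal(r2$sensitivity + r2$specificity - 1, max(J))
})

test_that("ROC AUC equals the trapezoidal area under the empirical curve", {
  set.seed(16)
  for (i in 1:5) {
    s <- round(rnorm(30), 1); l <- rep(c(TRUE, FALSE), 15)
    r <- roc(s, l)
    thr <- c(-Inf, sort(unique(s)), Inf)
    sens <- sapply(thr, function(t) mean(s[l] >= t))
    fpr <- sapply(thr, function(t) mean(s[!l] >= t))
    area <- -sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
    expect_equal(r$auc, area, tolerance = 1e-12)
  }
})

test_that("DeLong self-comparison and rank invariance", {
  set.seed(17)
  s <- rnorm(20); l <- rep(c(TRUE, FALSE), 10)
  expect_error(delong_compare(s, s, l), class = "petref_validation_error")
  s2 <- s + rnorm(20, 0, 0.5)
  dl <- delong_compare(s, s2, l)
  dl_mono <- delong_compare(exp(s), s2, l)             # rank-preserving map
  expect_equal(dl_mono$auc_a, dl$auc_a)
  expect_equal(dl_mono$z, dl$z, tolerance = 1e-12)
})

test_that("DeLong variance agrees with a subject-level bootstrap", {
  set.seed(18)
  n <- 15
  base <- c(rnorm(n, 1.5, 0.6), rnorm(n, 0, 0.6))
  labels <- rep(c(TRUE, FALSE), each = n)
  sa <- base + rnorm(2 * n, 0, 0.3)
  sb <- 0.6 * base + rnorm(2 * n, 0, 0.5)
  dl <- delong_compare(sa, sb, labels)
  auc_fast <- function(s, l) {
    r <- rank(s)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  set.seed(19)
  boots <- replicate(10000, {
    ip <- sample(which(labels), n, replace = TRUE)
    ic <- sample(which(!labels), n, replace = TRUE)
    idx <- c(ip, ic); lb <- labels[idx]
    auc_fast(sa[idx], lb) - auc_fast(sb[idx], lb)
  })
  expect_lt(abs(var(boots) / dl$var_diff - 1), 0.15)
})

test_that("severity regression identities and guards", {
  set.seed(20)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30, 0, 0.8)
  fit <- severity_regression(y, x)
  expect_equal(fit$beta, cor(x, y), tolerance = 1e-10)
  expect_equal(severity_regression(rep(5, 10), rnorm(10))$beta, 0)
  expect_error(severity_regression(rnorm(10), rep(1, 10)),
               class = "petref_validation_error")
  sev <- c(NA, NA, rnorm(10))
  fit2 <- severity_regression(sev, rnorm(12))
  expect_equal(fit2$n_dropped, 2L)
  expect_equal(fit2$n, 10L)
})

test_that("severity regression recovers the planted standardized effect", {
  # generative model: severity = a + b * VT + noise, VT lognormal
  a <- 5; b <- 8; sd_noise <- 6
  draw <- function(n) {
    vt <- 3.6 * exp(rnorm(n, 0, 0.17))
    list(vt = vt, sev = a + b * vt + rnorm(n, 0, sd_noise))
  }
  set.seed(22)
  big <- draw(2e5)                                     # Monte-Carlo oracle
  beta_true <- cor(big$vt, big$sev)
  betas <- sapply(1:50, function(i) {
    d <- draw(40)
    severity_regression(d$sev, d$vt)$beta
  })
  mc_se <- sd(betas) / sqrt(50)
  expect_lt(abs(mean(betas) - beta_true), 3 * mc_se + 0.01)
})

test_that("cluster test: degenerate and planted cases", {
  set.seed(23)
  d <- c(12L, 12L, 8L)
  mask <- array(TRUE, d)
  n <- 12
  # identical images in both groups -> no suprathreshold voxels
  base <- array(rnorm(prod(d)), d)
  maps_same <- lapply(1:n, function(i) static_image(base, c(2, 2, 2), "SUVr"))
  g <- rep(c(TRUE, FALSE), each = 6)
  res0 <- voxelwise_cluster_test(maps_same, g, mask, n_perm = 100, seed = 1)
  expect_equal(nrow(res0$clusters), 0L)
  # planted blob in patients: largest surviving cluster overlaps it
  blob <- array(FALSE, d); blob[4:8, 4:8, 3:6] <- TRUE
  dice <- sapply(1:5, function(s) {
    set.seed(100 + s)
    maps <- lapply(1:n, function(i) {
      v <- array(rnorm(prod(d), 0, 1), d)
      if (i <= 6) v[blob] <- v[blob] + 2.5
      static_image(v, c(2, 2, 2), "SUVr")
    })
    res <- voxelwise_cluster_test(maps, g, mask, n_perm = 200, seed = s)
    surv <- res$clusters[res$clusters$surviving, ]
    if (!nrow(surv)) return(0)
    top <- surv$id[which.max(surv$extent)]
    got <- res$cluster_labels == top
    2 * sum(got & blob) / (sum(got) + sum(blob))
  })
  expect_gte(sum(dice > 0.5), 4)
})

test_that("cluster test is seed-deterministic and t-map order-invariant", {
  set.seed(25)
  d <- c(10L, 10L, 6L)
  mask <- array(TRUE, d)
  maps <- lapply(1:12, function(i)
    static_image(array(rnorm(prod(d)), d), c(2, 2, 2), "SUVr"))
  g <- rep(c(TRUE, FALSE), 6)
  age <- runif(12, 50, 80)
  r1 <- voxelwise_cluster_test(maps, g, mask, age = age, n_perm = 120,
                               seed = 9)
  r2 <- voxelwise_cluster_test(maps, g, mask, age = age, n_perm = 120,
                               seed = 9)
  expect_identical(r1$clusters, r2$clusters)
  expect_identical(r1$tmap$voxels, r2$tmap$voxels)
  perm <- sample(12)
  r3 <- voxelwise_cluster_test(maps[perm], g[perm], mask, age = age[perm],
                               n_perm = 120, seed = 9)
  expect_equal(r3$tmap$voxels, r1$tmap$voxels, tolerance = 1e-10)
})
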