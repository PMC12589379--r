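# Validation statistics: ANCOVA with Tukey pairwise comparisons and Cohen's
# d, ROC with optimal cut-offs and paired DeLong AUC comparison, severity
# regression, and permutation-based voxel-wise cluster inference.

.drop_constant <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(unique(x[!is.na(x)])) < 2L) NULL else x
}

#' ANCOVA with Tukey pairwise comparisons and Cohen's d
#'
#' Fits `value ~ group + age + sex` (covariates optional; zero-variance
#' covariates are dropped, reducing exactly to the covariate-free model),
#' reports the overall group F-test, covariate-adjusted group means at the
#' covariate means, pairwise Tukey-HSD-adjusted p-values based on the
#' model's residual variance, and Cohen's d per pair computed from the raw
#' group values with pooled SD (a residualized-d matrix is also returned).
#' For two groups the signed group t-statistic (second level minus first)
#' is reported.
#'
#' @param values Numeric response.
#' @param groups Factor (or coercible) of group labels, each n >= 3.
#' @param age,sex Optional covariates (`sex` as `"m"`/`"f"` or factor).
#' @return An object of class `ancova_result`.
#' @export
ancova <- function(values, groups, age = NULL, sex = NULL) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  if (k < 2L) .stop_validation("need >= 2 groups")
  if (any(table(groups) < 3L)) .stop_validation("each group needs n >= 3")
  if (stats::sd(values) == 0) {
    # exactly constant response (e.g. fully self-cancelling ratios): the
    # model is degenerate and 0/0 statistics would be garbage; the exact
    # answer is a null effect
    zero <- matrix(0, k, k, dimnames = list(levels(groups), levels(groups)))
    return(structure(list(group_F = 0, group_p_overall = 1,
                          group_t = if (k == 2L) 0 else NA_real_,
                          group_p = if (k == 2L) 1 else NA_real_,
                          adjusted_means = stats::setNames(
                            rep(values[1], k), levels(groups)),
                          tukey_p = zero + 1, pairwise_t = zero,
                          cohens_d = zero, cohens_d_residualized = zero,
                          coefficients = NULL, covariate_coefficients = NULL,
                          df_residual = length(values) - k,
                          n = length(values)),
                     class = "ancova_result"))
  }
  age <- .drop_constant(age)
  sex <- .drop_constant(if (is.null(sex)) NULL else as.factor(sex))
  df <- data.frame(value = values, group = groups)
  form <- value ~ group
  if (!is.null(age)) { df$age <- age; form <- stats::update(form, . ~ . + age) }
  if (!is.null(sex)) { df$sex <- sex; form <- stats::update(form, . ~ . + sex) }
  X <- stats::model.matrix(form, df)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    .stop_validation("rank-deficient ANCOVA design; collinear columns: ",
                     paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                           collapse = ", "))
  fit <- stats::lm(form, df)
  red <- stats::update(fit, . ~ . - group)
  an <- stats::anova(red, fit)
  group_F <- an$F[2]; group_p <- an$`Pr(>F)`[2]
  # adjusted means at covariate means
  nd <- data.frame(group = factor(levels(groups), levels = levels(groups)))
  if (!is.null(age)) nd$age <- mean(age)
  if (!is.null(sex)) {
    # balanced sex: average predictions over sex levels
    nd <- merge(nd, data.frame(sex = factor(levels(sex),
                                            levels = levels(sex))))
  }
  pr <- stats::predict(fit, nd)
  adj <- tapply(pr, nd$group, mean)[levels(groups)]
  # Tukey HSD on adjusted means using the model residual variance
  V <- stats::vcov(fit)
  cn <- colnames(V)
  dfres <- fit$df.residual
  tukey <- matrix(NA_real_, k, k, dimnames = list(levels(groups),
                                                  levels(groups)))
  tstat <- tukey
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    ci <- numeric(ncol(V)); names(ci) <- cn
    term_i <- paste0("group", levels(groups)[i])
    term_j <- paste0("group", levels(groups)[j])
    if (term_i %in% cn) ci[term_i] <- 1
    if (term_j %in% cn) ci[term_j] <- -1
    dmean <- adj[i] - adj[j]
    se <- sqrt(drop(t(ci) %*% V %*% ci))
    tt <- dmean / se
    tstat[i, j] <- tt
    tukey[i, j] <- stats::ptukey(sqrt(2) * abs(tt), k, dfres,
                                 lower.tail = FALSE)
  }
  # Cohen's d (raw pooled SD) and residualized variant
  d_of <- function(v) {
    m <- tapply(v, groups, mean); s <- tapply(v, groups, stats::var)
    n <- tapply(v, groups, length)
    out <- matrix(NA_real_, k, k, dimnames = dimnames(tukey))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) { out[i, j] <- 0; next }
      sp <- sqrt(((n[i] - 1) * s[i] + (n[j] - 1) * s[j]) / (n[i] + n[j] - 2))
      out[i, j] <- (m[i] - m[j]) / sp
    }
    out
  }
  resid_v <- values
  if (!is.null(age) || !is.null(sex)) {
    covf <- stats::update(form, . ~ . - group)
    resid_v <- stats::residuals(stats::lm(covf, df)) + mean(values)
  }
  covcoef <- stats::coef(fit)
  covcoef <- covcoef[setdiff(names(covcoef),
                             c("(Intercept)", paste0("group", levels(groups))))]
  two_t <- if (k == 2L) tstat[2, 1] else NA_real_
  two_p <- if (k == 2L) 2 * stats::pt(-abs(two_t), dfres) else NA_real_
  structure(list(group_F = group_F, group_p_overall = group_p,
                 group_t = two_t, group_p = two_p,
                 adjusted_means = adj, tukey_p = tukey,
                 pairwise_t = tstat,
                 cohens_d = d_of(values), cohens_d_residualized = d_of(resid_v),
                 coefficients = stats::coef(fit),
                 covariate_coefficients = covcoef,
                 df_residual = dfres, n = length(values)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ancova_result: F = %.3f, p = %.3g (df resid %d)\n",
              x$group_F, x$group_p_overall, x$df_residual))
  cat("adjusted means:\n"); print(round(x$adjusted_means, 4))
  invisible(x)
}

#' ROC analysis with Youden-optimal cut-off and DeLong variance
#'
#' AUC via the Mann-Whitney pair-counting estimator (ties count 1/2),
#' variance via DeLong placement values, and a cut-off maximizing Youden's
#' J = sensitivity + specificity - 1 over all observed thresholds (ties
#' resolved to the lower threshold), calling `score >= cutoff` a patient.
#'
#' @param scores Numeric scores (patient-high direction).
#' @param labels Logical (or 0/1): `TRUE` = patient.
#' @param criterion `"youden"` (default) or `"closest01"`
#'   (closest-to-(0,1) corner).
#' @return An object of class `roc_result`: `auc`, `var_delong`, `cutoff`,
#'   `sensitivity`, `specificity`, `n_patient`, `n_control`.
#' @export
roc <- function(scores, labels, criterion = c("youden", "closest01")) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    .stop_validation("both classes must be present")
  sp <- scores[labels]; sc <- scores[!labels]
  np <- length(sp); nc <- length(sc)
  v10 <- vapply(sp, function(s) (sum(s > sc) + 0.5 * sum(s == sc)) / nc,
                numeric(1))
  v01 <- vapply(sc, function(s) (sum(sp > s) + 0.5 * sum(sp == s)) / np,
                numeric(1))
  auc <- mean(v10)
  var_delong <- stats::var(v10) / np + stats::var(v01) / nc
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(sp >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(sc < t), numeric(1))
  score_thr <- switch(criterion,
                      youden = sens + spec - 1,
                      closest01 = -sqrt((1 - sens)^2 + (1 - spec)^2))
  best <- which(score_thr == max(score_thr))[1]          # lower threshold
  structure(list(auc = auc, var_delong = var_delong, cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 criterion = criterion, direction = "patient-high",
                 n_patient = np, n_control = nc,
                 placements = list(v10 = v10, v01 = v01)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (DeLong SE %.3f), cutoff %.4g, sens %.2f, spec %.2f\n",
              x$auc, sqrt(x$var_delong), x$cutoff, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two score sets over the same subjects using the
#' placement-value covariance:
#' `z = (AUC_A - AUC_B) / sqrt(var_A + var_B - 2 cov_AB)`.
#'
#' @param scores_a,scores_b Numeric scores for the same subjects.
#' @param labels Logical: `TRUE` = patient.
#' @return A list: `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    .stop_validation("scores_a, scores_b and labels must align")
  ra <- roc(scores_a, labels); rb <- roc(scores_b, labels)
  np <- ra$n_patient; nc <- ra$n_control
  s10 <- stats::cov(cbind(ra$placements$v10, rb$placements$v10))
  s01 <- stats::cov(cbind(ra$placements$v01, rb$placements$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / np +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nc
  if (var_diff <= 0)
    .stop_validation("degenerate DeLong comparison: zero variance of the AUC difference")
  z <- (ra$auc - rb$auc) / sqrt(var_diff)
  list(auc_a = ra$auc, auc_b = rb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Severity regression
#'
#' Fits `severity ~ readout + age + sex` after z-scoring severity and
#' readout, so the readout coefficient is a standardized beta. Rows with
#' missing severity are dropped (count reported).
#'
#' @param severity Clinical severity scores (`NA` allowed).
#' @param readout PET readout values.
#' @param age,sex Optional covariates.
#' @return A list: `beta` (standardized), `p`, `n`, `n_dropped`,
#'   `covariate_coefficients`.
#' @export
severity_regression <- function(severity, readout, age = NULL, sex = NULL) {
  keep <- !is.na(severity)
  n_dropped <- sum(!keep)
  severity <- severity[keep]; readout <- readout[keep]
  if (!is.null(age)) age <- age[keep]
  if (!is.null(sex)) sex <- sex[keep]
  if (length(severity) < 4L) .stop_validation("need >= 4 complete cases")
  if (stats::sd(readout) == 0) .stop_validation("constant readout")
  z <- function(v) if (stats::sd(v) == 0) v * 0 else
    (v - mean(v)) / stats::sd(v)
  df <- data.frame(sev = z(severity), read = z(readout))
  form <- sev ~ read
  age <- .drop_constant(age)
  sex <- .drop_constant(if (is.null(sex)) NULL else as.factor(sex))
  if (!is.null(age)) { df$age <- age; form <- stats::update(form, . ~ . + age) }
  if (!is.null(sex)) { df$sex <- sex; form <- stats::update(form, . ~ . + sex) }
  fit <- stats::summary.lm(stats::lm(form, df))
  co <- fit$coefficients
  list(beta = co["read", "Estimate"], p = co["read", "Pr(>|t|)"],
       n = length(severity), n_dropped = n_dropped,
       covariate_coefficients = co[setdiff(rownames(co),
                                           c("(Intercept)", "read")),
                                   "Estimate"])
}

# ---- voxel-wise permutation cluster test -----------------------------------

.neighbor_offsets26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

.connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- .neighbor_offsets26()
  idx <- which(mask)
  if (!length(idx)) return(list(labels = lab, sizes = integer(0)))
  coords <- arrayInd(idx, d)
  # voxel lookup: position in idx for each linear index
  comp <- 0L
  sizes <- integer(0)
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    comp <- comp + 1L
    queue <- matrix(coords[s, ], 1)
    lab[idx[s]] <- comp
    size <- 1L
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, cur, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- comp
        size <- size + length(new)
        queue <- rbind(queue, arrayInd(new, d))
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = lab, sizes = sizes)
}

.voxel_t <- function(E, gs, df) {
  # E: n x V residualized data, gs: residualized centered group regressor
  gg <- sum(gs^2)
  slope <- drop(crossprod(gs, E)) / gg
  rss <- colSums(E^2) - slope^2 * gg
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / gg)
  t <- slope / se
  t[!is.finite(t)] <- 0
  t
}

#' Voxel-wise two-group comparison with permutation cluster correction
#'
#' Computes a per-voxel ANCOVA group t-statistic (patient minus control,
#' adjusted for age and sex), forms clusters as 26-connected components of
#' voxels exceeding the two-sided cluster-forming threshold (positive and
#' negative excursions clustered separately), and assigns each cluster a
#' family-wise-error p-value from the permutation distribution of the
#' maximum cluster extent. Group labels are permuted on
#' covariate-residualized data (Freedman-Lane scheme); seed-controlled.
#'
#' @param maps Named list of [static_image()] maps (one per subject) or a
#'   4D array with subjects in the 4th dimension.
#' @param groups Logical or two-level factor; `TRUE` / second level =
#'   patient.
#' @param mask Logical 3D analysis mask.
#' @param age,sex Optional covariates.
#' @param p_form Voxel-level cluster-forming p (two-sided, default 0.001).
#' @param alpha_cluster Cluster-level FWE threshold (default 0.05).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return An object of class `cluster_result`: `tmap` ([static_image()]),
#'   `cluster_labels` (integer array of surviving clusters), `clusters`
#'   (data.frame: id, sign, extent, p_fwe, surviving), `t_threshold`, `df`,
#'   `n_perm`.
#' @export
voxelwise_cluster_test <- function(maps, groups, mask, age = NULL,
                                   sex = NULL, p_form = 0.001,
                                   alpha_cluster = 0.05, n_perm = 1000L,
                                   seed = 1L) {
  if (n_perm < 100L) .stop_validation("n_perm must be >= 100")
  if (is.array(maps) && length(dim(maps)) == 4L) {
    d <- dim(maps)[1:3]
    Y <- t(matrix(maps, prod(d), dim(maps)[4]))
  } else {
    d <- dim(maps[[1]]$voxels)
    Y <- t(vapply(maps, function(m) as.numeric(m$voxels), numeric(prod(d))))
  }
  vidx <- which(mask)
  Y <- Y[, vidx, drop = FALSE]
  n <- nrow(Y)
  g <- if (is.logical(groups)) groups else as.factor(groups) ==
    levels(as.factor(groups))[2]
  if (sum(g) < 3L || sum(!g) < 3L)
    .stop_validation("need >= 3 subjects per group")
  spacing <- if (is.array(maps)) c(1, 1, 1) else maps[[1]]$spacing_mm
  Z <- cbind(rep(1, n), .drop_constant(age),
             if (!is.null(.drop_constant(sex)))
               as.numeric(as.factor(sex)) - 1)
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Rz <- diag(n) - Hz
  E <- Rz %*% Y
  gs <- drop(Rz %*% as.numeric(g))
  dfres <- n - ncol(Z) - 1L
  t_obs <- .voxel_t(E, gs, dfres)
  t_thr <- stats::qt(1 - p_form / 2, dfres)

  cluster_extents <- function(tv) {
    vol_p <- array(FALSE, d); vol_n <- array(FALSE, d)
    vol_p[vidx] <- tv >= t_thr
    vol_n[vidx] <- tv <= -t_thr
    cp <- .connected_components(vol_p)
    cn <- .connected_components(vol_n)
    list(pos = cp, neg = cn,
         max_extent = max(0L, cp$sizes, cn$sizes))
  }
  obs <- cluster_extents(t_obs)
  set.seed(seed)
  perm_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    Ep <- Rz %*% E[sample.int(n), , drop = FALSE]
    perm_max[b] <- cluster_extents(.voxel_t(Ep, gs, dfres))$max_extent
  }
  fwe_p <- function(extent) (1 + sum(perm_max >= extent)) / (n_perm + 1)
  rows <- list()
  lab_out <- array(0L, d)
  next_id <- 0L
  for (sgn in c("pos", "neg")) {
    cc <- obs[[sgn]]
    for (ci in seq_along(cc$sizes)) {
      next_id <- next_id + 1L
      p <- fwe_p(cc$sizes[ci])
      surv <- p < alpha_cluster
      rows[[next_id]] <- data.frame(id = next_id, sign = sgn,
                                    extent = cc$sizes[ci], p_fwe = p,
                                    surviving = surv)
      if (surv) lab_out[cc$labels == ci] <- next_id
    }
  }
  tvol <- array(0, d); tvol[vidx] <- t_obs
  structure(list(tmap = static_image(tvol, spacing, "tstat"),
                 cluster_labels = lab_out,
                 clusters = if (length(rows)) do.call(rbind, rows)
                 else data.frame(id = integer(0), sign = character(0),
                                 extent = integer(0), p_fwe = numeric(0),
                                 surviving = logical(0)),
                 t_threshold = t_thr, df = dfres, n_perm = n_perm,
                 perm_max_extent = perm_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: forming |t| >= %.3f (df %d), %d cluster(s), %d surviving (n_perm %d)\n",
              x$t_threshold, x$df, nrow(x$clusters),
              sum(x$clusters$surviving), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE, digits = 4)
  invisible(x)
}
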