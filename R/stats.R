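# Condition-comparison statistics: cluster-based permutation tests on
# time-frequency maps and repeated-measures ANOVA with planned contrasts.

#' Cluster-based permutation test between paired time-frequency maps
#'
#' Point-wise paired t statistics between conditions a and b; clusters are
#' formed from suprathreshold points (two-sided t at `cluster_alpha`) under
#' 4-connectivity on the (stride-phase, frequency) grid, with signed cluster
#' mass (sum of t). The null distribution of the maximum absolute cluster
#' mass is built by random within-subject sign flips of the condition
#' difference (the exact paired exchangeability scheme for two conditions);
#' cluster p-values are `(1 + #(null >= observed)) / (n_perm + 1)`.
#' Non-significant map points are not excluded: every grid point enters.
#'
#' @param maps_a,maps_b lists (one per subject) of `tf_map`s or plain
#'   matrices on identical grids; pairing is by list position.
#' @param n_perm number of permutations.
#' @param cluster_alpha two-sided alpha for the cluster-forming t threshold.
#' @param seed optional integer seed (fixed seed gives identical results).
#' @return object of class `cluster_result`: data frame `clusters` (id,
#'   sign, mass, n_points, p), the observed `t_map`, `labels` matrix,
#'   `null_max_mass`, and the test parameters.
#' @export
cluster_permutation_test <- function(maps_a, maps_b, n_perm = 5000,
                                     cluster_alpha = 0.05, seed = NULL) {
  n <- length(maps_a)
  if (n != length(maps_b)) stop("paired designs need equal subject counts")
  if (n < 2) stop("need at least 2 subjects")
  as_mat <- function(m) if (inherits(m, "tf_map")) m$values else as.matrix(m)
  A <- lapply(maps_a, as_mat); B <- lapply(maps_b, as_mat)
  dims <- dim(A[[1]])
  for (m in c(A, B)) if (!identical(dim(m), dims)) stop("mismatched grids")
  p <- prod(dims)
  D <- t(vapply(seq_len(n), function(i) as.vector(A[[i]] - B[[i]]),
                numeric(p)))                      # subjects x points
  ss <- colSums(D^2)                              # invariant under sign flips
  t_of <- function(s) {
    mu <- as.vector(s %*% D) / n
    v <- (ss - n * mu^2) / (n - 1)
    mu / sqrt(pmax(v, .Machine$double.xmin) / n)
  }
  t_obs <- t_of(rep(1, n))
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- label_clusters_cpp(matrix(t_obs, dims[1], dims[2]), tcrit)
  null_max <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    vapply(seq_len(n_perm), function(k) {
      max_cluster_mass_cpp(matrix(t_of(S[k, ]), dims[1], dims[2]), tcrit)
    }, numeric(1))
  })
  mass <- obs$mass
  clusters <- data.frame(
    id = seq_along(mass),
    sign = ifelse(mass >= 0, 1L, -1L),
    mass = mass,
    n_points = as.vector(table(factor(obs$labels[obs$labels > 0],
                                      levels = seq_along(mass)))),
    p = vapply(mass, function(m)
      (1 + sum(null_max >= abs(m))) / (n_perm + 1), numeric(1))
  )
  structure(
    list(clusters = clusters[order(clusters$p), ],
         t_map = matrix(t_obs, dims[1], dims[2]),
         labels = obs$labels, null_max_mass = null_max,
         n_perm = n_perm, cluster_alpha = cluster_alpha,
         t_critical = tcrit, n_subjects = n, seed = seed),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> paired cluster-based permutation test\n")
  cat(sprintf("  %d subjects, %d permutations, cluster-forming |t| > %.3f\n",
              x$n_subjects, x$n_perm, x$t_critical))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(utils::head(x$clusters, 10), row.names = FALSE)
  }
  invisible(x)
}

#' One-way repeated-measures ANOVA with planned pairwise comparisons
#'
#' Fits the one-way within-subject ANOVA (`stats::aov` with an
#' `Error(subject)` stratum), reporting F with df `(k - 1, (k - 1)(n - 1))`,
#' classical eta squared (`SS_condition / SS_total`) and partial eta squared
#' (`SS_condition / (SS_condition + SS_error)`), plus uncorrected paired
#' t-tests for each planned contrast.
#'
#' @param values numeric matrix, subjects x conditions (complete; missing
#'   cells are an error, no imputation).
#' @param conditions condition names (defaults to column names).
#' @param planned list of length-2 character vectors naming condition pairs;
#'   default: first condition vs each other condition.
#' @return object of class `rm_anova`: `F`, `df`, `p`, `eta_squared`,
#'   `partial_eta_squared`, `ss` and a `pairwise` data frame.
#' @export
rm_anova_planned <- function(values, conditions = colnames(values),
                             planned = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2) stop("need at least 2 subjects")
  if (anyNA(values)) stop("missing cells are not allowed (no imputation)")
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(k))
  colnames(values) <- conditions
  long <- data.frame(
    subject = factor(rep(seq_len(n), k)),
    condition = factor(rep(conditions, each = n), levels = conditions),
    value = as.vector(values)
  )
  fit <- stats::aov(value ~ condition + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  between <- summary(fit)[["Error: subject"]][[1]]
  ss_cond <- within["condition", "Sum Sq"]
  ss_err <- within["Residuals", "Sum Sq"]
  ss_subj <- between["Residuals", "Sum Sq"]
  Fval <- within["condition", "F value"]
  pval <- within["condition", "Pr(>F)"]
  if (!is.finite(Fval) && isTRUE(all.equal(ss_cond, 0))) {
    Fval <- 0; pval <- 1          # zero effect with zero residual variance
  }
  df <- c(k - 1L, (k - 1L) * (n - 1L))
  if (is.null(planned)) {
    planned <- lapply(conditions[-1], function(cc) c(conditions[1], cc))
  }
  pw <- do.call(rbind, lapply(planned, function(pair) {
    a <- values[, pair[1]]; b <- values[, pair[2]]
    if (stats::sd(a - b) == 0) {
      data.frame(contrast = paste(pair, collapse = " vs "),
                 mean_diff = mean(a - b), t = NA_real_,
                 df = n - 1L, p = if (all(a == b)) 1 else NA_real_)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(contrast = paste(pair, collapse = " vs "),
                 mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  }))
  structure(
    list(F = unname(Fval), df = df, p = unname(pval),
         eta_squared = unname(ss_cond / (ss_cond + ss_subj + ss_err)),
         partial_eta_squared = unname(ss_cond / (ss_cond + ss_err)),
         ss = c(condition = ss_cond, subject = ss_subj, error = ss_err),
         pairwise = pw, conditions = conditions, n_subjects = n),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> one-way repeated-measures ANOVA\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f (partial %.3f)\n",
              x$df[1], x$df[2], x$F, x$p, x$eta_squared,
              x$partial_eta_squared))
  cat("  planned pairwise comparisons (uncorrected):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
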