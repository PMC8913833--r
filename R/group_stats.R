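#' A metric traced over the correlation-threshold sweep
#'
#' @param thresholds strictly increasing thresholds.
#' @param values metric value at each threshold (sigma, or one metabolite's
#'   local efficiency).
#' @param metric_name label, e.g. `"sigma"` or `"elocal_Cr"`.
#' @param provenance list describing where the curve came from
#'   (group, time point or `"backbone"`).
#' @return a `threshold_curve`.
#' @export
threshold_curve <- function(thresholds, values, metric_name = "sigma",
                            provenance = list()) {
  if (length(thresholds) != length(values)) {
    stop_invalid("thresholds and values must have equal length")
  }
  if (any(diff(thresholds) <= 0)) stop_invalid("thresholds must be strictly increasing")
  structure(list(thresholds = as.numeric(thresholds),
                 values = as.numeric(values),
                 metric_name = metric_name, provenance = provenance),
            class = "threshold_curve")
}

#' Area under a threshold curve
#'
#' Trapezoidal integral of the metric against the threshold axis — the
#' threshold-sweep summary on which group comparisons are made. Exact for the
#' piecewise-linear curves a 9-point sweep produces.
#'
#' @param curve a `threshold_curve` with at least 2 points.
#' @return the AUC (metric units times threshold width).
#' @export
auc_over_thresholds <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  n <- length(curve$thresholds)
  if (n < 2L) stop_invalid("AUC needs at least 2 thresholds")
  sum(diff(curve$thresholds) * (curve$values[-1L] + curve$values[-n]) / 2)
}

#' Small-worldness curve of one group at one time point
#'
#' Binarizes the group's correlation matrix over the threshold sweep and
#' evaluates sigma at each threshold.
#'
#' @param table a concentration table.
#' @param group group label.
#' @param time_point time-point index.
#' @param thresholds threshold sweep.
#' @param n_random,n_swap_per_edge ensemble parameters (see
#'   [small_worldness()]).
#' @param seed integer seed.
#' @return a `threshold_curve` of sigma.
#' @export
sw_curve <- function(table, group, time_point,
                     thresholds = default_thresholds(),
                     n_random = 100, n_swap_per_edge = 10, seed = 1L) {
  mat <- spearman_matrix(table, group, time_point)
  nets <- threshold_sweep(mat, thresholds)
  sig <- vapply(seq_along(nets), function(i) {
    small_worldness(nets[[i]], n_random, n_swap_per_edge,
                    seed = derive_seed(seed, paste0("sw/", i)),
                    degenerate = "limit")$sigma
  }, numeric(1))
  threshold_curve(thresholds, sig, "sigma",
                  list(group = group, time_point = time_point))
}

#' Local-efficiency curve of one metabolite at one time point
#'
#' @inheritParams sw_curve
#' @param metabolite metabolite whose nodal local efficiency is traced.
#' @return a `threshold_curve` of that node's local efficiency.
#' @export
elocal_curve <- function(table, group, time_point, metabolite,
                         thresholds = default_thresholds()) {
  mat <- spearman_matrix(table, group, time_point)
  if (!metabolite %in% mat$panel) stop_invalid("unknown metabolite: ", metabolite)
  nets <- threshold_sweep(mat, thresholds)
  vals <- vapply(nets, function(n) local_efficiency(n)[[metabolite]], numeric(1))
  threshold_curve(thresholds, vals, paste0("elocal_", metabolite),
                  list(group = group, time_point = time_point))
}

#' Metric factories for the permutation test
#'
#' Each factory returns a function `f(table, group, seed)` producing a scalar
#' threshold-AUC for that group, the shape [permutation_test()] consumes:
#' `metric_sw_auc` gives the sigma-AUC at one time point,
#' `metric_elocal_auc` one metabolite's local-efficiency AUC at one time
#' point, and the `backbone_*` variants the same summaries on the sign-test
#' backbone network.
#'
#' @param time_point time point evaluated (per-time-point variants).
#' @param metabolite metabolite traced (local-efficiency variants).
#' @param thresholds threshold sweep.
#' @param n_random,n_swap_per_edge random-ensemble parameters.
#' @param alpha,aggregate,strict_threshold backbone parameters (see
#'   [backbone()]).
#' @return a metric function `f(table, group, seed) -> numeric`.
#' @export
metric_sw_auc <- function(time_point, thresholds = default_thresholds(),
                          n_random = 100, n_swap_per_edge = 10) {
  function(table, group, seed) {
    auc_over_thresholds(sw_curve(table, group, time_point, thresholds,
                                 n_random, n_swap_per_edge, seed))
  }
}

#' @rdname metric_sw_auc
#' @export
metric_elocal_auc <- function(time_point, metabolite,
                              thresholds = default_thresholds()) {
  function(table, group, seed) {
    auc_over_thresholds(elocal_curve(table, group, time_point, metabolite,
                                     thresholds))
  }
}

backbone_matrix_for_group <- function(table, group, alpha, aggregate,
                                      strict_threshold) {
  tps <- sort(unique(table$time_point[table$group == group]))
  mats <- lapply(tps, function(t) spearman_matrix(table, group, t))
  backbone(mats, alpha = alpha, aggregate = aggregate,
           strict_threshold = strict_threshold)$matrix
}

#' @rdname metric_sw_auc
#' @export
metric_backbone_sw_auc <- function(thresholds = default_thresholds(),
                                   alpha = 0.025, aggregate = "min",
                                   strict_threshold = NULL,
                                   n_random = 100, n_swap_per_edge = 10) {
  function(table, group, seed) {
    mat <- backbone_matrix_for_group(table, group, alpha, aggregate,
                                     strict_threshold)
    nets <- threshold_sweep(mat, thresholds)
    sig <- vapply(seq_along(nets), function(i) {
      small_worldness(nets[[i]], n_random, n_swap_per_edge,
                      seed = derive_seed(seed, paste0("bbsw/", i)),
                      degenerate = "limit")$sigma
    }, numeric(1))
    auc_over_thresholds(threshold_curve(thresholds, sig, "sigma",
                                        list(group = group, time_point = "backbone")))
  }
}

#' @rdname metric_sw_auc
#' @export
metric_backbone_elocal_auc <- function(metabolite,
                                       thresholds = default_thresholds(),
                                       alpha = 0.025, aggregate = "min",
                                       strict_threshold = NULL) {
  function(table, group, seed) {
    mat <- backbone_matrix_for_group(table, group, alpha, aggregate,
                                     strict_threshold)
    nets <- threshold_sweep(mat, thresholds)
    vals <- vapply(nets, function(n) local_efficiency(n)[[metabolite]],
                   numeric(1))
    auc_over_thresholds(threshold_curve(thresholds, vals,
                                        paste0("elocal_", metabolite),
                                        list(group = group, time_point = "backbone")))
  }
}

#' Permutation test of a two-group difference in a threshold-AUC summary
#'
#' Computes the observed difference (first group minus second) in the metric
#' AUC, then builds a permutation null by randomly reallocating whole subjects
#' — a subject's complete longitudinal record moves together — to the two
#' groups, preserving the original group sizes, and recomputing both AUCs.
#' Two decisions are reported: the one-tailed percentile rule (observed
#' difference above the 95th percentile of the null, the printed type-I level
#' of 0.05) and a two-sided permutation p-value
#' `(1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' A permutation on which the metric fails (e.g. a degenerate random
#' ensemble on a near-empty permuted network) is redrawn and counted; more
#' than 10\% redraws aborts the test.
#'
#' @param table a concentration table with exactly two groups.
#' @param metric a function `f(table, group, seed) -> numeric` (see
#'   [metric_sw_auc()]).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param groups optional length-2 character vector fixing group order
#'   (difference = first minus second).
#' @return a `permutation_comparison`.
#' @export
permutation_test <- function(table, metric, n_perm = 1000, seed = 1L,
                             groups = NULL) {
  assert_concentration_table(table)
  groups <- groups %||% sort(unique(table$group))
  if (length(groups) != 2L || !all(groups %in% table$group)) {
    stop_invalid("exactly two groups are required")
  }
  auc1 <- metric(table, groups[1L], derive_seed(seed, "obs/1"))
  auc2 <- metric(table, groups[2L], derive_seed(seed, "obs/2"))
  observed <- auc1 - auc2

  subj <- unique(table[, c("group", "subject")])
  n1 <- sum(subj$group == groups[1L])
  key_all <- paste(table$group, table$subject)
  key_subj <- paste(subj$group, subj$subject)

  null_diffs <- numeric(n_perm)
  redraws <- 0L
  max_redraws <- ceiling(0.1 * n_perm)
  r <- 1L
  attempt <- 0L
  while (r <= n_perm) {
    attempt <- attempt + 1L
    set.seed(derive_seed(seed, paste0("perm/", r, "/", attempt)))
    pick <- sample(nrow(subj), n1)
    new_group <- rep(groups[2L], nrow(subj))
    new_group[pick] <- groups[1L]
    perm_table <- table
    perm_table$group <- new_group[match(key_all, key_subj)]
    d <- tryCatch({
      a1 <- metric(perm_table, groups[1L],
                   derive_seed(seed, paste0("perm/", r, "/", attempt, "/1")))
      a2 <- metric(perm_table, groups[2L],
                   derive_seed(seed, paste0("perm/", r, "/", attempt, "/2")))
      a1 - a2
    }, error = function(e) NA_real_)
    if (is.na(d)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop_invalid("more than 10% of permutations failed (", redraws,
                     " redraws); metric too unstable under permutation")
      }
      next
    }
    null_diffs[r] <- d
    r <- r + 1L
    attempt <- 0L
  }

  critical_value <- unname(quantile(null_diffs, 0.95))
  p_value <- (1 + sum(abs(null_diffs) >= abs(observed))) / (n_perm + 1)
  structure(
    list(groups = groups, auc = setNames(c(auc1, auc2), groups),
         observed_diff = observed, null_diffs = null_diffs,
         critical_value = critical_value,
         reject_critical = observed > critical_value,
         p_value = p_value, p_fdr = NA_real_,
         n_perm = as.integer(n_perm), redraws = redraws,
         seed = as.integer(seed)),
    class = "permutation_comparison"
  )
}

#' @export
print.permutation_comparison <- function(x, ...) {
  cat(sprintf("Permutation comparison (%s - %s), n_perm = %d\n",
              x$groups[1L], x$groups[2L], x$n_perm))
  cat(sprintf("  AUC: %s = %.4f, %s = %.4f; diff = %.4f\n",
              x$groups[1L], x$auc[1L], x$groups[2L], x$auc[2L],
              x$observed_diff))
  cat(sprintf("  95%% critical value = %.4f -> %s; two-sided p = %.4f",
              x$critical_value,
              if (x$reject_critical) "reject" else "retain", x$p_value))
  if (!is.na(x$p_fdr)) cat(sprintf(" (FDR %.4f)", x$p_fdr))
  cat("\n")
  if (x$redraws > 0) cat("  redrawn permutations: ", x$redraws, "\n", sep = "")
  invisible(x)
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Validated wrapper over the standard step-up procedure: adjusted values are
#' order-preserving, never below the raw p-values, and capped at 1.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return adjusted p-values of the same length.
#' @export
fdr_correct <- function(p_values) {
  if (!is.numeric(p_values) || !length(p_values) ||
      any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
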