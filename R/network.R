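#' Default correlation-threshold sweep
#'
#' The range 0.41–0.49 at a 0.01 interval: nine thresholds, spanning the band
#' in which reference control networks retain their small-world signature.
#'
#' @return numeric vector of 9 thresholds.
#' @export
default_thresholds <- function() seq(0.41, 0.49, by = 0.01)

new_correlation_matrix <- function(values, group, time_point, panel) {
  structure(list(values = values, group = group, time_point = time_point,
                 panel = panel),
            class = "correlation_matrix")
}

#' Absolute Spearman correlation matrix for one group and time point
#'
#' Correlates every pair of metabolites across subjects using Spearman's rank
#' correlation (average ranks for ties) and takes absolute values: a
#' metabolic connection is an association of concentration variation across
#' individuals, and only its presence — not its sign — defines an edge.
#' The diagonal is fixed at 0 so that self-pairs never contribute edges.
#'
#' @param table a concentration table.
#' @param group group label to subset.
#' @param time_point time-point index to subset.
#' @return a `correlation_matrix` object; `$values` is the symmetric M-by-M
#'   matrix of `|rho|` with zero diagonal.
#' @export
spearman_matrix <- function(table, group, time_point) {
  assert_concentration_table(table)
  sub <- table[table$group == group & table$time_point == time_point, ]
  if (!nrow(sub)) stop_invalid("no records for group '", group,
                               "' at time point ", time_point)
  panel <- unique(table$metabolite)
  subjects <- unique(sub$subject)
  if (length(subjects) < 3L) {
    stop_invalid("insufficient data: need >= 3 subjects, have ", length(subjects))
  }
  wide <- matrix(NA_real_, length(subjects), length(panel),
                 dimnames = list(subjects, panel))
  wide[cbind(match(sub$subject, subjects), match(sub$metabolite, panel))] <-
    sub$concentration
  if (anyNA(wide)) stop_invalid("incomplete records for group '", group,
                                "' at time point ", time_point)
  zero_var <- apply(wide, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(abs(cor(wide, method = "spearman")))
  if (any(zero_var)) {
    warning("zero-variance metabolite(s) ",
            paste(panel[zero_var], collapse = ", "),
            ": correlations set to 0", call. = FALSE)
    rho[zero_var, ] <- 0
    rho[, zero_var] <- 0
  }
  diag(rho) <- 0
  new_correlation_matrix(rho, group, time_point, panel)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Absolute Spearman correlation matrix (", x$group, ", time point ",
      as.character(x$time_point), "), ", length(x$panel), " metabolites\n",
      sep = "")
  invisible(x)
}

#' Binarize a correlation matrix at a threshold
#'
#' An edge is present where `|rho|` is strictly above the threshold; entries
#' at or under the threshold carry no edge.
#'
#' @param matrix a `correlation_matrix`.
#' @param threshold correlation cutoff in \[0, 1).
#' @return a `binary_network` (0/1 symmetric adjacency, zero diagonal).
#' @export
binarize <- function(matrix, threshold) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop_invalid("threshold must lie in [0, 1)")
  }
  adj <- (matrix$values > threshold) * 1L
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  structure(list(adjacency = adj, threshold = threshold,
                 group = matrix$group, time_point = matrix$time_point,
                 panel = matrix$panel),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat("Binary metabolic network (", x$group, ", time point ",
      as.character(x$time_point), ") at threshold ", x$threshold, ": ",
      sum(x$adjacency) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Binarize over an increasing threshold sweep
#'
#' @param matrix a `correlation_matrix`.
#' @param thresholds strictly increasing thresholds, each in \[0, 1).
#' @return list of `binary_network`s, one per threshold (edge sets nested:
#'   non-increasing with threshold).
#' @export
threshold_sweep <- function(matrix, thresholds = default_thresholds()) {
  if (!length(thresholds)) stop_invalid("threshold list must be non-empty")
  if (any(diff(thresholds) <= 0)) stop_invalid("thresholds must be strictly increasing")
  lapply(thresholds, function(t) binarize(matrix, t))
}

#' Sign-test backbone of connections persisting across time
#'
#' For each metabolite pair, tests the consistency of the connection over the
#' time series with a one-tailed sign test: under the null of no connection
#' (`|rho| = 0`), each time point is a fair coin, so the p-value for observing
#' the connection at k of T time points is the binomial tail P(X >= k),
#' X ~ Bin(T, 1/2). Pairs with p below `alpha` enter the backbone; their
#' backbone weight is the minimum (default) or median `|rho|` across time, so
#' the backbone can itself be thresholded and swept.
#'
#' In the default mode a time point counts as a positive sign whenever
#' `|rho| > 0`; the `strict_threshold` mode counts only time points where
#' `|rho|` exceeds the analysis threshold, a stricter notion of "connected at
#' that time point".
#'
#' @param matrices list of `correlation_matrix` objects over time (same group
#'   and panel).
#' @param alpha one-tailed significance level (default 0.025).
#' @param aggregate `"min"` (default) or `"median"` aggregation of `|rho|`
#'   across time for eligible pairs.
#' @param strict_threshold optional correlation threshold; when given, a time
#'   point counts as a positive sign only if `|rho|` exceeds it.
#' @return a `backbone_result`: `$matrix` (a `correlation_matrix` with
#'   time_point `"backbone"`), `$sign_test_p`, `$eligible`, `$alpha`.
#' @export
backbone <- function(matrices, alpha = 0.025, aggregate = c("min", "median"),
                     strict_threshold = NULL) {
  aggregate <- match.arg(aggregate)
  if (length(matrices) < 2L) stop_invalid("backbone needs >= 2 time points")
  panel <- matrices[[1L]]$panel
  group <- matrices[[1L]]$group
  for (m in matrices) {
    stopifnot(inherits(m, "correlation_matrix"))
    if (!identical(m$panel, panel) || !identical(m$group, group)) {
      stop_invalid("all matrices must share the same panel and group")
    }
  }
  cut <- strict_threshold %||% 0
  tt <- length(matrices)
  stack <- vapply(matrices, function(m) m$values, matrices[[1L]]$values)
  k <- apply(stack > cut, c(1L, 2L), sum)
  p <- pbinom(k - 1L, size = tt, prob = 0.5, lower.tail = FALSE)
  eligible <- p < alpha
  diag(eligible) <- FALSE
  agg <- apply(stack, c(1L, 2L), if (aggregate == "min") min else stats::median)
  values <- ifelse(eligible, agg, 0)
  diag(values) <- 0
  dimnames(values) <- dimnames(p) <- dimnames(eligible) <-
    list(panel, panel)
  structure(
    list(matrix = new_correlation_matrix(values, group, "backbone", panel),
         sign_test_p = p, eligible = eligible, alpha = alpha,
         aggregate = aggregate, strict_threshold = strict_threshold),
    class = "backbone_result"
  )
}

#' @export
print.backbone_result <- function(x, ...) {
  cat("Backbone metabolic network (", x$matrix$group, "): ",
      sum(x$eligible) / 2, " of ",
      choose(length(x$matrix$panel), 2), " pairs eligible at alpha ",
      x$alpha, "\n", sep = "")
  invisible(x)
}

#' Export a binary network as a TSV edge list
#'
#' One row per edge, `metabolite_a<TAB>metabolite_b<TAB>weight`; suitable as
#' connectogram input.
#'
#' @param net a `binary_network`.
#' @param path optional output path; when NULL the edge tibble is returned.
#' @export
as_edge_list <- function(net, path = NULL) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency != 0, arr.ind = TRUE)
  edges <- tibble::tibble(metabolite_a = net$panel[idx[, 1L]],
                          metabolite_b = net$panel[idx[, 2L]],
                          weight = 1)
  if (!is.null(path)) {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  edges
}

#' Write a correlation matrix as square CSV with metabolite names
#'
#' @param matrix a `correlation_matrix`.
#' @param path output path.
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  write.csv(matrix$values, path, quote = FALSE)
  invisible(path)
}
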