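#' Convert a Spearman correlation to the matching Gaussian-copula Pearson value
#'
#' For a bivariate Gaussian with linear correlation r, the population Spearman
#' correlation is (6/pi) * asin(r/2). This is the inverse map: given a target
#' Spearman rho_s, it returns r = 2 sin(pi * rho_s / 6), the latent linear
#' correlation that makes copula-sampled data hit the target rank correlation.
#'
#' @param rho_s Spearman correlation(s) in \[-1, 1\].
#' @return Pearson correlation(s) of the generating Gaussian.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (!is.numeric(rho_s) || any(is.na(rho_s)) || any(abs(rho_s) > 1)) {
    stop_invalid("rho_s must be numeric in [-1, 1]")
  }
  2 * sin(pi * rho_s / 6)
}

new_template <- function(panel) {
  m <- diag(length(panel))
  dimnames(m) <- list(panel, panel)
  m
}

set_edge <- function(m, a, b, value) {
  m[a, b] <- value
  m[b, a] <- value
  m
}

set_clique <- function(m, nodes, value) {
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i != j) m[nodes[i], nodes[j]] <- value
    }
  }
  m
}

check_template_nodes <- function(panel, needed) {
  missing <- setdiff(needed, panel)
  if (length(missing)) {
    stop_invalid("panel lacks metabolite(s) required by the template: ",
                 paste(missing, collapse = ", "))
  }
}

# Metabolites carrying designed structure. Ala and PCh deliberately carry no
# designed edges: their concentrations are low and noisy in hippocampal MRS
# and their connections are absent from the reference covariance pattern.
.template_core <- c("Cr", "PCr", "Gln", "Glu", "NAA", "Tau", "GABA", "GSH", "Ins")

#' Control-group correlation template
#'
#' Builds the per-time-point target Spearman correlation structure of an
#' unstressed cohort: three node-disjoint tight clusters — the energy-buffer
#' cluster Cr–PCr–Gln, a glutamatergic/osmolyte cluster Glu–NAA–Tau and a
#' GABA–GSH–Ins cluster — on an otherwise independent background, with no
#' Ala- or PCh-related structure. Disjoint equicorrelated cliques keep the
#' matrix positive definite at any clique strength below 1, and the triangles
#' give the thresholded network the high local clustering that drives its
#' small-world signature.
#'
#' @param panel metabolite panel (must contain the nine core metabolites).
#' @param strength target within-cluster Spearman correlation, in (0, 1).
#' @param n_time_points number of time points to replicate the template over.
#' @return named list (one symmetric matrix per time point, Spearman scale).
#' @export
control_template <- function(panel = default_panel(), strength = 0.9,
                             n_time_points = 8) {
  panel <- metabolite_panel(panel)
  if (!is.numeric(strength) || length(strength) != 1L ||
      strength <= 0 || strength >= 1) {
    stop_invalid("strength must lie strictly inside (0, 1)")
  }
  stopifnot(is_count(n_time_points))
  check_template_nodes(panel, .template_core)
  m <- new_template(panel)
  m <- set_clique(m, c("Cr", "PCr", "Gln"), strength)
  m <- set_clique(m, c("Glu", "NAA", "Tau"), strength)
  m <- set_clique(m, c("GABA", "GSH", "Ins"), strength)
  setNames(rep(list(m), n_time_points), as.character(seq_len(n_time_points)))
}

#' Stress-group correlation template
#'
#' Starts from the control structure but removes the Cr–PCr and Cr–Gln links
#' at every time point (the backbone Cr cluster can never form), and at the
#' designated disrupted time points dissolves the clustered structure
#' entirely: every designed correlation is dropped except a Glu-centred vee
#' (Glu–Gln elevated, Glu–NAA elevated with opposite sign, Gln–NAA zero), the
#' emergent unclustered Glu connectivity seen after acute stress. Full
#' independence is the maximally de-clustered background a rank-correlation
#' generator can produce: any residual clustering in the sampled networks is
#' pure finite-sample noise, which is exactly what degree-matched rewiring
#' reproduces, so the disrupted networks lose their small-world margin. The
#' vee strength is capped at 0.66 Spearman, near the largest value for which
#' a triangle-free (zero Gln–NAA) target remains positive definite; the sign
#' alternation is what makes the open wedge feasible, since two strong
#' same-sign correlations force their third side positive.
#'
#' @param panel metabolite panel (must contain the nine core metabolites).
#' @param strength within-cluster Spearman correlation for the retained
#'   control structure, in (0, 1).
#' @param disrupted_time_points time-point indices at which the de-clustered
#'   structure replaces the control structure.
#' @param n_time_points number of time points.
#' @return named list of per-time-point target matrices (Spearman scale).
#' @export
stress_template <- function(panel = default_panel(), strength = 0.9,
                            disrupted_time_points = c(2, 3, 5),
                            n_time_points = 8) {
  panel <- metabolite_panel(panel)
  check_template_nodes(panel, .template_core)
  stopifnot(is_count(n_time_points))
  if (length(disrupted_time_points) &&
      (!all(disrupted_time_points %in% seq_len(n_time_points)))) {
    stop_invalid("disrupted_time_points must lie in 1..n_time_points")
  }
  ctrl <- control_template(panel, strength, n_time_points)[[1L]]
  # Cr-related links broken at every time point
  intact <- ctrl
  intact <- set_edge(intact, "Cr", "PCr", 0)
  intact <- set_edge(intact, "Cr", "Gln", 0)

  vee_strength <- min(strength, 0.66)
  disrupted <- new_template(panel)
  disrupted <- set_edge(disrupted, "Glu", "Gln", vee_strength)
  disrupted <- set_edge(disrupted, "Glu", "NAA", -vee_strength)

  out <- vector("list", n_time_points)
  for (t in seq_len(n_time_points)) {
    out[[t]] <- if (t %in% disrupted_time_points) disrupted else intact
  }
  setNames(out, as.character(seq_len(n_time_points)))
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Clips eigenvalues at a small floor and renormalises to unit diagonal.
#' Errors if the repair moves any entry by more than `max_shift`, which would
#' mean the requested target structure is not realisable as a correlation
#' matrix.
#'
#' @param sigma symmetric matrix with unit diagonal.
#' @param max_shift largest tolerated entry change (default 0.05).
#' @param context label used in the error message.
#' @return a positive semi-definite correlation matrix.
#' @export
psd_repair <- function(sigma, max_shift = 0.05, context = "template") {
  eig <- eigen(sigma, symmetric = TRUE)
  if (min(eig$values) >= 1e-8) return(sigma)
  vals <- pmax(eig$values, 1e-8)
  rep_mat <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(rep_mat))
  rep_mat <- rep_mat / outer(d, d)
  shift <- max(abs(rep_mat - sigma))
  if (shift > max_shift) {
    stop_invalid("correlation target for ", context,
                 " is not realisable: PSD repair shifts entries by ",
                 signif(shift, 3))
  }
  dimnames(rep_mat) <- dimnames(sigma)
  rep_mat
}
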