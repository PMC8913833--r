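#' Typical hippocampal metabolite concentrations (institutional units)
#'
#' Order-of-magnitude means used as the default log-normal marginal scales of
#' the simulator; values approximate murine hippocampal concentrations in mM.
#'
#' @return named numeric vector over the default panel.
#' @export
default_concentration_scale <- function() {
  c(Ala = 0.9, Cr = 8.5, PCr = 3.4, GABA = 2.3, Glu = 11.2, Gln = 4.0,
    PCh = 0.6, GSH = 1.4, Ins = 6.1, NAA = 8.8, Tau = 11.5)
}

#' Configuration of a synthetic longitudinal MRS cohort
#'
#' Bundles everything [generate_cohort()] needs: group sizes, time points,
#' metabolite panel, per-(group, time point) target Spearman correlation
#' templates, log-normal marginal scales, multiplicative noise level, the CRLB
#' model, and the master seed.
#'
#' @param n_subjects_per_group subjects per group (default 11).
#' @param n_time_points number of time points (default 8).
#' @param panel metabolite panel.
#' @param templates named list: one entry per group, each a list of
#'   per-time-point target Spearman matrices (see [control_template()]).
#'   Defaults to a control and a stress group at strength 0.9.
#' @param concentration_scale named positive means per metabolite (a scalar is
#'   recycled across the panel).
#' @param noise_cv coefficient of variation of the log-normal marginals
#'   (default 0.15, the scale of across-animal biological variability).
#' @param crlb_baseline baseline CRLB percentage attached to every estimate
#'   (scalar or named per metabolite; default 5).
#' @param crlb_failures optional list of injected quantification failures;
#'   each element a list with `group`, `subject` (index), `metabolite`,
#'   optional `time_points` (default all) and `crlb` (default 40).
#' @param seed master integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 11,
                          n_time_points = 8,
                          panel = default_panel(),
                          templates = NULL,
                          concentration_scale = default_concentration_scale(),
                          noise_cv = 0.15,
                          crlb_baseline = 5,
                          crlb_failures = NULL,
                          seed = 1L) {
  panel <- metabolite_panel(panel)
  if (!is_count(n_subjects_per_group, min = 3L)) {
    stop_invalid("n_subjects_per_group must be an integer >= 3")
  }
  if (!is_count(n_time_points)) stop_invalid("n_time_points must be a positive integer")
  if (!is.numeric(noise_cv) || noise_cv <= 0) stop_invalid("noise_cv must be > 0")
  if (is.null(templates)) {
    templates <- list(
      control = control_template(panel, n_time_points = n_time_points),
      stress  = stress_template(
        panel,
        disrupted_time_points = intersect(c(2, 3, 5), seq_len(n_time_points)),
        n_time_points = n_time_points)
    )
  }
  if (is.null(names(templates)) || any(names(templates) == "")) {
    stop_invalid("templates must be a named list (one entry per group)")
  }
  for (g in names(templates)) {
    if (length(templates[[g]]) != n_time_points) {
      stop_invalid("group '", g, "' template must cover all ", n_time_points,
                   " time points")
    }
  }
  if (length(concentration_scale) == 1L && is.null(names(concentration_scale))) {
    concentration_scale <- setNames(rep(concentration_scale, length(panel)), panel)
  }
  scale <- concentration_scale[panel]
  if (any(is.na(scale)) || any(scale <= 0)) {
    stop_invalid("concentration_scale must give a positive mean for every panel metabolite")
  }
  if (length(crlb_baseline) == 1L && is.null(names(crlb_baseline))) {
    crlb_baseline <- setNames(rep(crlb_baseline, length(panel)), panel)
  }
  baseline <- crlb_baseline[panel]
  if (any(is.na(baseline)) || any(baseline < 0)) {
    stop_invalid("crlb_baseline must be >= 0 for every panel metabolite")
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_time_points = as.integer(n_time_points),
         panel = panel,
         templates = templates,
         concentration_scale = scale,
         noise_cv = noise_cv,
         crlb_baseline = baseline,
         crlb_failures = crlb_failures,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# sample n latent Gaussian vectors with the given correlation via an
# eigen square root (robust to the PSD-repair floor, unlike Cholesky)
sample_latent <- function(n, sigma) {
  eig <- eigen(sigma, symmetric = TRUE)
  a <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow(sigma))
  z <- matrix(rnorm(n * nrow(sigma)), n, nrow(sigma))
  z %*% t(a)
}

#' Generate a synthetic longitudinal concentration table
#'
#' For each (group, time point), draws subject vectors from a Gaussian copula
#' whose latent correlation is the target Spearman template mapped through
#' [spearman_to_pearson()] (and PSD-repaired if needed), then transforms each
#' metabolite's latent margin through a log-normal with the configured mean
#' and coefficient of variation. Rank correlations are invariant to that
#' monotone transform, so the sampled data reproduce the Spearman targets
#' asymptotically while concentrations stay strictly positive. CRLB values
#' are attached from the baseline model plus any injected failures.
#' Deterministic given the config seed: each (group, time point) block draws
#' from its own named substream.
#'
#' @param config a [cohort_config()].
#' @return a tibble with columns
#'   `group, subject, time_point, metabolite, concentration, crlb`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  panel <- config$panel
  m <- length(panel)
  n <- config$n_subjects_per_group
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  meanlog <- log(config$concentration_scale) - sdlog^2 / 2

  blocks <- list()
  for (g in names(config$templates)) {
    subjects <- sprintf("%s_%02d", g, seq_len(n))
    for (t in seq_len(config$n_time_points)) {
      target <- config$templates[[g]][[t]]
      if (!isTRUE(all.equal(unname(target), unname(t(target)))) ||
          any(abs(diag(target) - 1) > 1e-12)) {
        stop_invalid("template for group '", g, "', time point ", t,
                     " is not a unit-diagonal symmetric matrix")
      }
      sigma <- psd_repair(spearman_to_pearson(target),
                          context = paste0("group '", g, "', time point ", t))
      set.seed(derive_seed(config$seed, paste0("cohort/", g, "/", t)))
      z <- sample_latent(n, sigma)
      conc <- qlnorm(pnorm(z),
                     meanlog = rep(meanlog, each = n),
                     sdlog = sdlog)
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        group = g,
        subject = rep(subjects, times = m),
        time_point = t,
        metabolite = rep(panel, each = n),
        concentration = as.vector(conc),
        crlb = rep(unname(config$crlb_baseline), each = n)
      )
    }
  }
  table <- do.call(rbind, blocks)

  for (f in config$crlb_failures %||% list()) {
    tps <- f$time_points %||% seq_len(config$n_time_points)
    subj <- sprintf("%s_%02d", f$group, f$subject)
    hit <- table$group == f$group & table$subject == subj &
      table$metabolite == f$metabolite & table$time_point %in% tps
    if (!any(hit)) stop_invalid("crlb failure matches no record (group ",
                                f$group, ", subject ", f$subject, ")")
    table$crlb[hit] <- f$crlb %||% 40
  }
  table <- table[order(table$group, table$subject, table$time_point,
                       match(table$metabolite, panel)), ]
  assert_concentration_table(tibble::as_tibble(table))
}

#' Write / read a concentration table as tidy CSV
#'
#' @param table a concentration table.
#' @param path file path.
#' @return `read_cohort_csv` returns the table as a tibble.
#' @export
write_cohort_csv <- function(table, path) {
  assert_concentration_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  assert_concentration_table(tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE)))
}
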