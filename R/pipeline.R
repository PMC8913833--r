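#' Configuration of a full network analysis run
#'
#' @param input the cohort: a concentration table (data frame), a
#'   [cohort_config()] to simulate from, or a path to a tidy CSV.
#' @param thresholds correlation-threshold sweep (default 0.41–0.49 by 0.01).
#' @param crlb_threshold CRLB quality bound in percent (default 35).
#' @param sign_alpha one-tailed sign-test level for the backbone
#'   (default 0.025).
#' @param n_random random networks per small-worldness evaluation
#'   (default 1000).
#' @param n_perm permutations per group comparison (default 1000).
#' @param backbone_aggregate `"min"` or `"median"` backbone weight
#'   aggregation.
#' @param strict_backbone when TRUE, a time point counts toward backbone
#'   eligibility only if `|rho|` exceeds the lowest analysis threshold.
#' @param elocal_metabolites metabolites whose local-efficiency AUC is
#'   compared between groups (default `"Cr"`, the node of primary interest;
#'   each extra metabolite adds a full permutation test per time point).
#' @param seed master seed; every stage derives its own named stream.
#' @param output_dir optional directory for report and table exports.
#' @return an `analysis_config`.
#' @export
analysis_config <- function(input = NULL,
                            thresholds = default_thresholds(),
                            crlb_threshold = 35,
                            sign_alpha = 0.025,
                            n_random = 1000,
                            n_perm = 1000,
                            backbone_aggregate = c("min", "median"),
                            strict_backbone = FALSE,
                            elocal_metabolites = "Cr",
                            seed = 1L,
                            output_dir = NULL) {
  if (any(diff(thresholds) <= 0)) stop_invalid("thresholds must be strictly increasing")
  structure(
    list(input = input, thresholds = thresholds,
         crlb_threshold = crlb_threshold, sign_alpha = sign_alpha,
         n_random = as.integer(n_random), n_perm = as.integer(n_perm),
         backbone_aggregate = match.arg(backbone_aggregate),
         strict_backbone = isTRUE(strict_backbone),
         elocal_metabolites = elocal_metabolites,
         seed = as.integer(seed), output_dir = output_dir),
    class = "analysis_config"
  )
}

resolve_input <- function(config) {
  input <- config$input
  if (is.null(input)) stop_invalid("analysis_config has no input")
  if (inherits(input, "cohort_config")) return(generate_cohort(input))
  if (is.character(input)) return(read_cohort_csv(input))
  assert_concentration_table(input)
}

sigma_or_na <- function(net, n_random, seed) {
  tryCatch(small_worldness(net, n_random = n_random, seed = seed,
                           degenerate = "limit")$sigma,
           error = function(e) NA_real_)
}

#' Run the full metabolic-network analysis
#'
#' Executes the pipeline end to end: CRLB quality filtering, per-time-point
#' absolute Spearman networks over the threshold sweep, small-worldness and
#' per-metabolite local efficiency at every (group, time point, threshold),
#' sign-test backbone networks with their own sweeps, and permutation group
#' comparisons of the AUC summaries with FDR correction (small-worldness
#' comparisons form one FDR family across time points; local-efficiency
#' comparisons one family across metabolite-by-time-point; backbone
#' comparisons one family). A network whose random ensemble is degenerate
#' (e.g. an empty backbone at a high threshold) is recorded with `sigma = NA`
#' and `meets_criterion = FALSE` rather than aborting the run.
#'
#' Deterministic given the config seed; every stochastic stage draws from a
#' named substream, so two runs with identical config are identical.
#'
#' @param config an [analysis_config()].
#' @return an `analysis_report` list: `qc`, `sw` (tibble of sigma per group,
#'   time point and threshold), `elocal`, `backbone` (per-group results and
#'   sweeps), `comparisons` (summary tibble) and `comparison_objects`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  table <- resolve_input(config)
  qc <- filter_by_crlb(table, config$crlb_threshold)
  table <- qc$table
  groups <- sort(unique(table$group))
  tps <- sort(unique(table$time_point))
  th <- config$thresholds
  strict_cut <- if (config$strict_backbone) min(th) else NULL

  sw_rows <- list()
  el_rows <- list()
  mats <- list()
  for (g in groups) {
    mats[[g]] <- lapply(tps, function(t) spearman_matrix(table, g, t))
    for (ti in seq_along(tps)) {
      nets <- threshold_sweep(mats[[g]][[ti]], th)
      for (k in seq_along(nets)) {
        sig <- sigma_or_na(nets[[k]], config$n_random,
                           derive_seed(config$seed,
                                       paste0("sw/", g, "/", tps[ti], "/", k)))
        sw_rows[[length(sw_rows) + 1L]] <- tibble::tibble(
          group = g, time_point = tps[ti], threshold = th[k], sigma = sig,
          meets_criterion = !is.na(sig) && sig > 1)
        le <- local_efficiency(nets[[k]])
        el_rows[[length(el_rows) + 1L]] <- tibble::tibble(
          group = g, time_point = tps[ti], threshold = th[k],
          metabolite = names(le), e_local = unname(le))
      }
    }
  }
  sw_table <- do.call(rbind, sw_rows)
  elocal_table <- do.call(rbind, el_rows)

  backbone_results <- list()
  backbone_sw <- list()
  for (g in groups) {
    bb <- backbone(mats[[g]], alpha = config$sign_alpha,
                   aggregate = config$backbone_aggregate,
                   strict_threshold = strict_cut)
    nets <- threshold_sweep(bb$matrix, th)
    rows <- lapply(seq_along(nets), function(k) {
      sig <- sigma_or_na(nets[[k]], config$n_random,
                         derive_seed(config$seed, paste0("bbsw/", g, "/", k)))
      le <- local_efficiency(nets[[k]])
      tibble::tibble(group = g, threshold = th[k], sigma = sig,
                     meets_criterion = !is.na(sig) && sig > 1,
                     elocal = list(le))
    })
    backbone_results[[g]] <- bb
    backbone_sw[[g]] <- do.call(rbind, rows)
  }

  comp_objects <- list()
  comp_rows <- list()
  add_comparison <- function(label, scope, family, metric) {
    cmp <- permutation_test(table, metric, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, paste0("cmp/", label)),
                            groups = groups)
    comp_objects[[label]] <<- cmp
    comp_rows[[length(comp_rows) + 1L]] <<- tibble::tibble(
      metric = sub("/.*$", "", label), scope = scope, family = family,
      auc_1 = unname(cmp$auc[1L]), auc_2 = unname(cmp$auc[2L]),
      observed_diff = cmp$observed_diff, critical_value = cmp$critical_value,
      reject_critical = cmp$reject_critical, p_value = cmp$p_value,
      n_perm = cmp$n_perm, redraws = cmp$redraws)
  }

  if (length(groups) == 2L) {
    for (t in tps) {
      add_comparison(paste0("sw/", t), paste0("time_point=", t), "sw",
                     metric_sw_auc(t, th, n_random = config$n_random))
    }
    for (met in config$elocal_metabolites) {
      if (!met %in% qc$report$retained_metabolites) next
      for (t in tps) {
        add_comparison(paste0("elocal_", met, "/", t),
                       paste0("time_point=", t), "elocal",
                       metric_elocal_auc(t, met, th))
      }
    }
    add_comparison("backbone_sw", "backbone", "backbone",
                   metric_backbone_sw_auc(th, alpha = config$sign_alpha,
                                          aggregate = config$backbone_aggregate,
                                          strict_threshold = strict_cut,
                                          n_random = config$n_random))
    for (met in config$elocal_metabolites) {
      if (!met %in% qc$report$retained_metabolites) next
      add_comparison(paste0("backbone_elocal_", met), "backbone", "backbone",
                     metric_backbone_elocal_auc(met, th,
                                                alpha = config$sign_alpha,
                                                aggregate = config$backbone_aggregate,
                                                strict_threshold = strict_cut))
    }
  }

  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  if (!is.null(comparisons)) {
    comparisons$p_fdr <- NA_real_
    for (fam in unique(comparisons$family)) {
      idx <- comparisons$family == fam
      comparisons$p_fdr[idx] <- fdr_correct(comparisons$p_value[idx])
    }
    labels <- names(comp_objects)
    for (i in seq_along(labels)) {
      comp_objects[[labels[i]]]$p_fdr <- comparisons$p_fdr[i]
    }
  }

  report <- structure(
    list(qc = qc$report, sw = sw_table, elocal = elocal_table,
         backbone = backbone_results, backbone_sw = backbone_sw,
         comparisons = comparisons, comparison_objects = comp_objects,
         groups = groups,
         config = config[setdiff(names(config), "input")],
         version = as.character(utils::packageVersion("metabnet"))),
    class = "analysis_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$sw, file.path(dir, "smallworldness.csv"), row.names = FALSE)
  write.csv(report$elocal, file.path(dir, "local_efficiency.csv"),
            row.names = FALSE)
  if (!is.null(report$comparisons)) {
    write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  }
  for (g in names(report$backbone)) {
    bb <- report$backbone[[g]]
    write_matrix_csv(bb$matrix, file.path(dir, paste0("backbone_", g, ".csv")))
    net <- binarize(bb$matrix, report$config$thresholds[1L])
    as_edge_list(net, file.path(dir, paste0("backbone_", g, "_edges.tsv")))
  }
  jsonlite::write_json(
    list(qc = unclass(report$qc),
         config = report$config[c("thresholds", "crlb_threshold", "sign_alpha",
                                  "n_random", "n_perm", "backbone_aggregate",
                                  "strict_backbone", "seed")],
         version = report$version),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Metabolic network analysis report (metabnet ", x$version, ")\n", sep = "")
  cat("  groups: ", paste(x$groups, collapse = ", "), "\n", sep = "")
  for (g in x$groups) {
    met <- x$sw$meets_criterion[x$sw$group == g]
    cat(sprintf("  %s: small-world criterion met at %d of %d (time point, threshold) cells\n",
                g, sum(met), length(met)))
  }
  if (!is.null(x$comparisons)) {
    sig <- sum(x$comparisons$p_fdr < 0.05, na.rm = TRUE)
    cat("  group comparisons: ", nrow(x$comparisons), " (", sig,
        " with FDR p < 0.05)\n", sep = "")
  }
  invisible(x)
}
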