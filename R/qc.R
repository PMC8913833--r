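#' Filter a concentration table by CRLB quantification quality
#'
#' Applies the standard LCModel reliability screen: a metabolite estimate is
#' trusted only when its Cramér–Rao lower bound is strictly below the
#' threshold (default 35\%). Two filters are applied in order, mirroring the
#' usual workflow of first removing unusable animals and then fixing the
#' reportable panel:
#'
#' 1. *Subject exclusion*: a subject is dropped when any **core-panel**
#'    metabolite fails the bound at any time point in that subject's spectra.
#'    The core panel is the set of metabolites expected to be reliably
#'    quantifiable (by default the classic 11-metabolite hippocampal panel,
#'    intersected with the table's metabolites); a failure there indicates a
#'    bad fit or spectrum, not a hard-to-quantify metabolite.
#' 2. *Metabolite retention*: among the remaining subjects, a metabolite is
#'    retained only if every single estimate meets the bound at all time
#'    points. This is what trims an extended basis-set panel down to the
#'    reliably quantified metabolites.
#'
#' @param table a concentration table.
#' @param crlb_threshold CRLB percentage bound; estimates with
#'   `crlb >= crlb_threshold` fail (strict `<` to pass).
#' @param core_panel metabolites on which subjects are judged (see above);
#'   `NULL` disables subject exclusion, as does a core panel disjoint from
#'   the table.
#' @return a list with `table` (the filtered concentration table) and
#'   `report` (a `qc_report` listing exclusions).
#' @export
filter_by_crlb <- function(table, crlb_threshold = 35,
                           core_panel = default_panel()) {
  assert_concentration_table(table)
  if (!is.numeric(crlb_threshold) || crlb_threshold <= 0) {
    stop_invalid("crlb_threshold must be > 0")
  }
  panel <- unique(table$metabolite)
  core <- intersect(core_panel %||% character(), panel)

  excluded_subjects <- list()
  if (length(core)) {
    bad <- table[table$crlb >= crlb_threshold & table$metabolite %in% core, ]
    if (nrow(bad)) {
      key <- unique(bad[, c("group", "subject")])
      for (i in seq_len(nrow(key))) {
        hit <- bad[bad$group == key$group[i] & bad$subject == key$subject[i], ]
        worst <- which.max(hit$crlb)
        excluded_subjects[[length(excluded_subjects) + 1L]] <- list(
          group = key$group[i], subject = key$subject[i],
          reason = sprintf("CRLB %.3g%% for %s at time point %d",
                           hit$crlb[worst], hit$metabolite[worst],
                           hit$time_point[worst])
        )
      }
      drop <- paste(table$group, table$subject) %in% paste(key$group, key$subject)
      table <- table[!drop, ]
      if (!nrow(table)) stop_invalid("QC failure: all subjects excluded")
    }
  }

  worst <- tapply(table$crlb, table$metabolite, max)
  failed <- names(worst)[worst >= crlb_threshold]
  excluded_metabolites <- lapply(failed, function(met) {
    hit <- table[table$metabolite == met & table$crlb >= crlb_threshold, ]
    list(metabolite = met, max_crlb = max(hit$crlb),
         time_point = hit$time_point[which.max(hit$crlb)])
  })
  retained <- setdiff(panel, failed)
  if (!length(retained)) stop_invalid("QC failure: all metabolites excluded")
  table <- table[table$metabolite %in% retained, ]

  report <- structure(
    list(retained_metabolites = retained,
         excluded_metabolites = excluded_metabolites,
         excluded_subjects = excluded_subjects,
         crlb_threshold = crlb_threshold),
    class = "qc_report"
  )
  list(table = tibble::as_tibble(table), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("CRLB quality report (threshold ", x$crlb_threshold, "%)\n", sep = "")
  cat("  retained metabolites: ", paste(x$retained_metabolites, collapse = ", "), "\n")
  cat("  excluded metabolites: ", length(x$excluded_metabolites), "\n")
  cat("  excluded subjects:    ", length(x$excluded_subjects), "\n")
  invisible(x)
}
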