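#' Run the full cohort-level statistical analysis
#'
#' Orchestrates the study statistics over a long-format cohort table: percent
#' change from baseline per animal for every metric with baseline data,
#' one-way ANOVA with Bonferroni post hoc tests for every metric x
#' post-baseline day (on percent changes; on raw values for metrics acquired
#' at a single day, e.g. histology counts), Kaplan-Meier curves per group and
#' pairwise log-rank tests. Fully deterministic given its inputs. When
#' `out_dir` is given, writes `comparisons.csv`, `pairwise.csv`,
#' `survival.csv`, `km_curves.csv` and `percent_change.csv` (and a
#' `km_curves.svg` plot when `plot = TRUE`).
#'
#' @param cohort cohort table (data.frame) or path to its CSV.
#' @param baseline_day baseline day for percent change.
#' @param ref reference group for the pairwise comparisons (default
#'   "control" when present).
#' @param m Bonferroni multiplier policy: `NULL` = number of pairwise tests
#'   per metric x day, or a fixed global count.
#' @param out_dir optional output directory.
#' @param plot write an SVG of the Kaplan-Meier curves.
#' @return list with `percent_change`, `comparisons` (data.frame),
#'   `pairwise` (data.frame), `km` (per-group curves), `logrank` (data.frame),
#'   `survival_records`.
#' @export
run_study <- function(cohort, baseline_day = 0, ref = NULL, m = NULL,
                      out_dir = NULL, plot = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(all(c("animal_id", "group", "day", "metric", "value") %in% names(cohort)))
  if (is.null(ref) && "control" %in% cohort$group) ref <- "control"

  metrics <- unique(cohort$metric)
  has_baseline <- vapply(metrics, function(mt) {
    any(cohort$day == baseline_day & cohort$metric == mt)
  }, logical(1L))

  pc <- suppressWarnings(
    percent_change(cohort[cohort$metric %in% metrics[has_baseline], , drop = FALSE],
                   baseline_day))

  analyses <- rbind(
    if (nrow(pc)) cbind(pc[, c("group", "day", "metric", "value")], unit = "pct_change"),
    {
      raw <- cohort[cohort$metric %in% metrics[!has_baseline], , drop = FALSE]
      if (nrow(raw)) cbind(raw[, c("group", "day", "metric", "value")], unit = "raw")
    })

  comp_rows <- list(); pw_rows <- list()
  if (!is.null(analyses) && nrow(analyses)) {
    for (mt in unique(analyses$metric)) {
      for (d in sort(unique(analyses$day[analyses$metric == mt]))) {
        sel <- analyses$metric == mt & analyses$day == d
        vals <- analyses$value[sel]; grps <- analyses$group[sel]
        if (sum(is.finite(vals)) == 0L || length(unique(grps)) < 2L) {
          warning(sprintf("metric %s day %s skipped: insufficient data", mt, d),
                  call. = FALSE)
          next
        }
        res <- tryCatch(anova_bonferroni(vals, grps, m = m, ref = ref),
                        error = function(e) NULL)
        if (is.null(res)) {
          warning(sprintf("metric %s day %s skipped: %s", mt, d, "comparison failed"),
                  call. = FALSE)
          next
        }
        gs <- res$group_stats
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          metric = mt, day = d, unit = analyses$unit[sel][1L],
          F = res$F, p = res$p,
          group = gs$group, mean = gs$mean, sd = gs$sd, n = gs$n,
          stringsAsFactors = FALSE)
        pw_rows[[length(pw_rows) + 1L]] <- cbind(metric = mt, day = d, res$pairwise)
      }
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL
  pairwise <- if (length(pw_rows)) do.call(rbind, pw_rows) else NULL

  sr <- unique(cohort[, c("animal_id", "group", "survival_time", "event")])
  names(sr)[names(sr) == "survival_time"] <- "time"
  km <- km_estimate(sr, by_group = TRUE)
  groups <- unique(sr$group)
  lr <- do.call(rbind, lapply(utils::combn(groups, 2L, simplify = FALSE), function(p) {
    t <- logrank_test(sr, p[1L], p[2L])
    data.frame(group1 = p[1L], group2 = p[2L], chisq = t$chisq, p = t$p,
               stringsAsFactors = FALSE)
  }))

  bundle <- list(percent_change = pc, comparisons = comparisons,
                 pairwise = pairwise, km = km, logrank = lr,
                 survival_records = sr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) if (!is.null(x) && nrow(x)) {
      utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    }
    wr(pc, "percent_change.csv")
    wr(comparisons, "comparisons.csv")
    wr(pairwise, "pairwise.csv")
    wr(km$curve, "km_curves.csv")
    wr(lr, "logrank.csv")
    wr(sr, "survival.csv")
    if (plot) {
      grDevices::svg(file.path(out_dir, "km_curves.svg"), width = 6, height = 5)
      fit <- survival::survfit(survival::Surv(time, event) ~ group, data = sr)
      graphics::plot(fit, col = seq_along(groups), xlab = "day",
                     ylab = "survival probability", lwd = 2)
      graphics::legend("bottomleft", legend = sub("^group=", "", names(fit$strata)),
                       col = seq_along(groups), lwd = 2, bty = "n")
      grDevices::dev.off()
    }
  }
  bundle
}
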