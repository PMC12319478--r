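#' Percent change from baseline, per animal and metric
#'
#' `100 * (value_day - value_baseline) / value_baseline` for every
#' post-baseline day. Records whose baseline is missing or zero are dropped
#' with a warning.
#'
#' @param table long-format cohort table (columns `animal_id`, `group`, `day`,
#'   `metric`, `value`; extra columns are carried through).
#' @param baseline_day day used as baseline (default 0).
#' @return cohort table of percent changes (post-baseline days only).
#' @export
percent_change <- function(table, baseline_day = 0) {
  stopifnot(all(c("animal_id", "day", "metric", "value") %in% names(table)))
  key <- interaction(table$animal_id, table$metric, drop = TRUE)
  base_rows <- table$day == baseline_day
  base_map <- tapply(table$value[base_rows], droplevels(key[base_rows]), `[`, 1L)
  post <- table[table$day > baseline_day, , drop = FALSE]
  bvals <- base_map[as.character(interaction(post$animal_id, post$metric, drop = TRUE))]
  bad <- is.na(bvals) | bvals == 0
  if (any(bad)) {
    warning(sprintf("%d record(s) dropped: missing or zero baseline", sum(bad)),
            call. = FALSE)
    post <- post[!bad, , drop = FALSE]
    bvals <- bvals[!bad]
  }
  post$value <- 100 * (post$value - bvals) / bvals
  rownames(post) <- NULL
  post
}

#' One-way ANOVA with Bonferroni-adjusted pairwise post hoc tests
#'
#' Fixed-effects one-way ANOVA across groups, followed by pairwise two-sample
#' t tests (pooled variance by default, Welch by flag) whose p-values are
#' multiplied by `m` and capped at 1. `m` defaults to the number of pairwise
#' tests performed.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param m Bonferroni multiplier; default = number of pairwise comparisons.
#' @param ref optional reference group: pairwise tests are then restricted to
#'   comparisons against it.
#' @param welch use Welch (unpooled) pairwise t tests.
#' @return list of class `comparison_result`: `F`, `p`, `df`, `group_stats`
#'   (mean, sd, n per group), `pairwise` (data.frame with raw and adjusted p),
#'   `m`.
#' @export
anova_bonferroni <- function(values, groups, m = NULL, ref = NULL, welch = FALSE) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(groups) < 2L)) stop("need >= 2 values per group", call. = FALSE)

  gm <- tapply(values, groups, mean)
  n_i <- tabulate(groups)
  grand <- mean(values)
  ss_between <- sum(n_i * (gm - grand)^2)
  ss_within <- sum((values - gm[as.integer(groups)])^2)
  df1 <- length(lv) - 1L
  df2 <- length(values) - length(lv)
  if (ss_within == 0 && ss_between == 0) {
    Fstat <- 0; pval <- 1
  } else if (ss_within == 0) {
    Fstat <- Inf; pval <- 0
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
    pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  if (!is.null(ref)) {
    if (!ref %in% lv) stop("reference group not present", call. = FALSE)
    pairs <- Filter(function(p) ref %in% p, pairs)
    pairs <- lapply(pairs, function(p) c(ref, setdiff(p, ref)))
  }
  m_used <- m %||% length(pairs)
  pw <- lapply(pairs, function(p) {
    x <- values[groups == p[1L]]; y <- values[groups == p[2L]]
    raw <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = !welch)$p.value
    }
    data.frame(group1 = p[1L], group2 = p[2L], raw_p = raw,
               adj_p = min(1, raw * m_used), stringsAsFactors = FALSE)
  })
  structure(list(F = Fstat, p = pval, df = c(df1, df2),
                 group_stats = data.frame(group = lv, mean = as.vector(gm),
                                          sd = as.vector(tapply(values, groups, stats::sd)),
                                          n = n_i, stringsAsFactors = FALSE),
                 pairwise = do.call(rbind, pw), m = m_used),
            class = "comparison_result")
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring, via the survival package.
#'
#' @param records data.frame with columns `time` and `event` (1 = event,
#'   0 = censored); optionally `group` when `by_group = TRUE`.
#' @param by_group estimate one curve per group.
#' @return list with `curve` (data.frame: time, n_risk, n_event, surv, and
#'   group when grouped) and `surv_fn` (step-function evaluator S(t),
#'   ungrouped only).
#' @export
km_estimate <- function(records, by_group = FALSE) {
  stopifnot(all(c("time", "event") %in% names(records)), nrow(records) > 0)
  if (by_group) {
    stopifnot("group" %in% names(records))
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
    s <- summary(fit, censored = TRUE)
    curve <- data.frame(group = sub("^group=", "", as.character(s$strata)),
                        time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                        surv = s$surv, stringsAsFactors = FALSE)
    return(list(curve = curve, surv_fn = NULL))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, censored = TRUE)
  curve <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                      surv = s$surv)
  surv_fn <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  list(curve = curve, surv_fn = surv_fn)
}

#' Two-group log-rank test
#'
#' Standard log-rank test (hypergeometric variance at each event time, ties
#' pooled), via survival::survdiff.
#'
#' @param records data.frame with `time`, `event`, `group`.
#' @param group_a,group_b the two group labels to compare.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records, group_a, group_b) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  sub <- records[records$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% sub$group)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (all(sub$event == 0)) return(list(chisq = 0, df = 1L, p = 1))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
  list(chisq = unname(sd_$chisq), df = 1L,
       p = stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE))
}
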