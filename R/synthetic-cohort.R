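#' Default per-group, per-day population parameters of the synthetic cohort
#'
#' Group means and SDs for the four treatment arms (saline control, MN58b,
#' TMZ, MN58b+TMZ) at scan days 0, 3 and 6, matching the summary statistics of
#' the GL261 study the package emulates: tissue diffusion coefficient D
#' (mm^2/s), the metabolite ratios tCho/NAA, mI/tCr, Lip+Lac/tCr, tCho/tCr and
#' Glx/tCr, tumor volume (mm^3), the perfusion parameters f and D*, ADC, and
#' the day-6-only histology metrics (mitotic_index, pct_caspase3). Where the
#' study reports no value (tCho/tCr at days 0/3 and for the monotherapy arms;
#' Glx/tCr, f, D*, ADC trajectories; day-3 tumor volume) the entries are
#' package conventions documented in the methods vignette.
#'
#' @return data.frame with columns `metric`, `group`, `day`, `mean`, `sd`.
#' @export
default_cohort_params <- function() {
  g <- c("control", "MN58b", "TMZ", "MN58b+TMZ")
  tab <- function(metric, m, s, days = c(0, 3, 6)) {
    data.frame(metric = metric,
               group = rep(g, each = length(days)),
               day = rep(days, times = length(g)),
               mean = as.vector(t(m)), sd = as.vector(t(s)),
               stringsAsFactors = FALSE)
  }
  D <- tab("D",
           m = rbind(c(1.35, 1.26, 1.25), c(1.36, 1.35, 1.33),
                     c(1.52, 1.40, 1.51), c(1.41, 1.46, 1.68)) * 1e-3,
           s = rbind(c(0.44, 0.21, 0.27), c(0.41, 0.24, 0.23),
                     c(0.32, 0.27, 0.30), c(0.46, 0.28, 0.32)) * 1e-3)
  tchonaa <- tab("tCho/NAA",
                 m = rbind(c(1.35, 1.65, 1.92), c(1.18, 1.66, 1.72),
                           c(1.24, 1.26, 1.34), c(1.31, 1.29, 1.24)),
                 s = rbind(c(0.29, 0.58, 0.50), c(0.20, 0.41, 0.64),
                           c(0.19, 0.15, 0.19), c(0.49, 0.21, 0.21)))
  mitcr <- tab("mI/tCr",
               m = rbind(c(1.19, 1.50, 2.37), c(0.92, 1.45, 1.85),
                         c(0.73, 0.97, 1.08), c(0.60, 0.82, 0.90)),
               s = rbind(c(0.54, 0.64, 1.20), c(0.54, 0.85, 0.83),
                         c(0.24, 0.39, 0.22), c(0.16, 0.27, 0.20)))
  liplac <- tab("Lip+Lac/tCr",
                m = rbind(c(2.51, 3.71, 7.13), c(2.07, 3.75, 5.51),
                          c(1.94, 2.90, 3.58), c(1.72, 1.80, 1.82)),
                s = rbind(c(1.16, 1.91, 2.49), c(0.82, 2.01, 3.62),
                          c(1.27, 1.69, 3.33), c(1.12, 0.60, 0.52)))
  tchotcr <- tab("tCho/tCr",
                 m = rbind(c(1.70, 2.00, 2.28), c(1.70, 1.95, 2.10),
                           c(1.70, 1.85, 1.95), c(1.70, 1.75, 1.59)),
                 s = rbind(c(0.50, 0.60, 0.69), c(0.50, 0.55, 0.60),
                           c(0.50, 0.50, 0.55), c(0.50, 0.40, 0.26)))
  glx <- tab("Glx/tCr",
             m = matrix(2.0, 4, 3), s = matrix(0.6, 4, 3))
  vol0 <- c(2.9, 3.1, 2.4, 2.8); vol6 <- c(15.8, 15.2, 17.5, 7.6)
  sd0 <- c(3.5, 2.6, 2.3, 1.9); sd6 <- c(17.7, 13.2, 16.7, 5.5)
  vol3 <- sqrt(vol0 * vol6)
  cv3 <- (sd0 / vol0 + sd6 / vol6) / 2
  vol <- tab("tumor_volume",
             m = cbind(vol0, vol3, vol6), s = cbind(sd0, cv3 * vol3, sd6))
  fpar <- tab("f", m = matrix(0.10, 4, 3), s = matrix(0.04, 4, 3))
  dstar <- tab("Dstar", m = matrix(0.012, 4, 3), s = matrix(0.006, 4, 3))
  adc <- D; adc$metric <- "ADC"; adc$mean <- adc$mean * 1.1; adc$sd <- adc$sd * 1.1
  mit <- tab("mitotic_index", m = cbind(c(7.40, 3.90, 4.10, 1.26)),
             s = cbind(c(0.80, 0.65, 0.70, 1.50)), days = 6)
  casp <- tab("pct_caspase3", m = cbind(c(0.63, 0.30, 0.24, 0.21)),
              s = cbind(c(0.45, 0.14, 0.11, 0.13)), days = 6)
  rbind(D, tchonaa, mitcr, liplac, tchotcr, glx, vol, fpar, dstar, adc, mit, casp)
}

#' Specification of a synthetic longitudinal cohort
#'
#' @param params long-format data.frame of per-metric, per-group, per-day
#'   population means and SDs; see [default_cohort_params()].
#' @param n_per_group named integer vector of animals per group; defaults to
#'   the four-arm study design (16 / 14 / 11 / 11).
#' @param days scan days, sorted.
#' @param survival_day_end named numeric vector: probability of surviving to
#'   the study end, per group (converted internally to a constant per-day
#'   hazard over days 1..study end; censoring at the study end). Defaults:
#'   control 0.58, MN58b 0.64, TMZ 0.85, MN58b+TMZ 1.
#' @param rho within-animal correlation of the log-scale draws across days
#'   (shared animal-level random effect).
#' @param seed integer seed; mandatory.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(params = default_cohort_params(),
                        n_per_group = c(control = 16L, MN58b = 14L,
                                        TMZ = 11L, `MN58b+TMZ` = 11L),
                        days = c(0L, 3L, 6L),
                        survival_day_end = c(control = 0.58, MN58b = 0.64,
                                             TMZ = 0.85, `MN58b+TMZ` = 1.0),
                        rho = 0.7,
                        seed) {
  stopifnot(all(c("metric", "group", "day", "mean", "sd") %in% names(params)))
  if (any(params$sd < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (is.unsorted(days)) stop("days must be sorted", call. = FALSE)
  if (any(n_per_group < 2L)) stop("n per group must be >= 2", call. = FALSE)
  groups <- names(n_per_group)
  unknown <- setdiff(names(survival_day_end), groups)
  if (length(unknown)) {
    stop("unknown group name in survival model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(groups %in% names(survival_day_end))) {
    stop("survival model must cover every group", call. = FALSE)
  }
  structure(list(params = params, n_per_group = n_per_group, days = days,
                 survival_day_end = survival_day_end, rho = rho, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic longitudinal treatment cohort
#'
#' Per animal and day, each metric is drawn from a lognormal law
#' moment-matched to its group/day population mean and SD, with a shared
#' animal-level random effect (`rho` on the log scale) inducing longitudinal
#' correlation; an SD of 0 collapses the draw to the exact mean. Positive
#' metrics drawn this way can never hit zero, keeping per-animal percent
#' change well defined. Survival times follow a constant per-day Bernoulli
#' hazard per group calibrated to the requested study-end survival
#' probability, with censoring at the study end. Output is seed-deterministic.
#'
#' @param spec a [cohort_spec()].
#' @return long-format data.frame (`cohort_table`): columns `animal_id`,
#'   `group`, `day`, `metric`, `value`, `survival_time`, `event`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- spec$params
  day_end <- max(spec$days)
  local_seed(spec$seed, {
    out <- list()
    for (grp in names(spec$n_per_group)) {
      p_surv <- spec$survival_day_end[[grp]]
      hazard <- 1 - p_surv^(1 / day_end)
      for (i in seq_len(spec$n_per_group[[grp]])) {
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", grp), i)
        z_animal <- stats::rnorm(1L)
        # survival: first day (1..day_end) on which the hazard fires
        stime <- day_end; event <- 0L
        if (hazard > 0) {
          fired <- which(stats::runif(day_end) < hazard)
          if (length(fired)) { stime <- fired[1L]; event <- 1L }
        }
        rows_m <- params[params$group == grp, , drop = FALSE]
        for (metric in unique(rows_m$metric)) {
          rows <- rows_m[rows_m$metric == metric, , drop = FALSE]
          rows <- rows[order(rows$day), , drop = FALSE]
          for (k in seq_len(nrow(rows))) {
            mu <- rows$mean[k]; sdv <- rows$sd[k]
            if (sdv == 0 || mu == 0) {
              value <- mu
              stats::rnorm(1L)  # keep the draw count fixed across SD settings
            } else {
              s2 <- log(1 + (sdv / mu)^2)
              lmu <- log(mu) - s2 / 2
              z <- spec$rho * z_animal + sqrt(1 - spec$rho^2) * stats::rnorm(1L)
              value <- exp(lmu + sqrt(s2) * z)
            }
            out[[length(out) + 1L]] <- data.frame(
              animal_id = id, group = grp, day = rows$day[k], metric = metric,
              value = value, survival_time = stime, event = event,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    tbl <- do.call(rbind, out)
    rownames(tbl) <- NULL
    class(tbl) <- c("cohort_table", "data.frame")
    tbl
  })
}
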