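## Functional-assay quantification: comparative-Ct (2^-ddCt) qPCR fold
## changes, Renilla-normalized dual-luciferase ratios, standard-curve
## calcium calibration and two-group comparisons reported as mean +/- SEM.

#' Standard error of the mean
#' @param x numeric vector.
#' @return sd(x)/sqrt(n).
#' @export
sem <- function(x) sd(x) / sqrt(length(x))

#' Comparative-Ct (2^-ddCt) relative quantification
#'
#' Per group and target: dCt = mean Ct(target) - mean Ct(reference);
#' ddCt = dCt(group) - dCt(control group); fold change = 2^-ddCt. Per-group
#' mean aggregation (rather than per-replicate pairing) is used; replicate
#' pairing across wells is rarely recorded. The control group's fold change
#' is 1 by construction and ddCt is invariant to adding a constant to every
#' Ct value (plate shift).
#'
#' @param tab assay table (columns `group`, `replicate`, `target`, `value`
#'   with Ct values).
#' @param reference_target reference gene (e.g. beta-actin).
#' @param control_group baseline group for ddCt.
#' @return `data.table` with one row per (group, target != reference):
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `percent_change` and,
#'   for knockdowns (fold < 1), `percent_knockdown`.
#' @export
delta_delta_ct <- function(tab, reference_target, control_group) {
  tab <- as.data.table(tab)
  groups <- unique(tab$group)
  if (!control_group %in% groups) vk_stop("control group '%s' not in table", control_group)
  targets <- setdiff(unique(tab$target), reference_target)
  ref_mean <- sapply(groups, function(g) {
    v <- tab$value[tab$group == g & tab$target == reference_target]
    if (!length(v)) vk_stop("group '%s' has no Ct values for reference '%s'",
                            g, reference_target)
    mean(v)
  })
  res <- rbindlist(lapply(targets, function(tg) {
    dct <- sapply(groups, function(g) {
      v <- tab$value[tab$group == g & tab$target == tg]
      if (!length(v)) vk_stop("group '%s' has no Ct values for target '%s'", g, tg)
      mean(v) - ref_mean[[g]]
    })
    ddct <- dct - dct[[control_group]]
    data.table(group = groups, target = tg, delta_ct = as.numeric(dct),
               delta_delta_ct = as.numeric(ddct),
               fold_change = 2^(-as.numeric(ddct)))
  }))
  res[, percent_change := (fold_change - 1) * 100]
  res[, percent_knockdown := ifelse(fold_change < 1, -percent_change, NA_real_)]
  res[]
}

#' Renilla-normalized dual-luciferase quantification
#'
#' Computes the per-well firefly/Renilla ratio (wells paired by group and
#' replicate), per-group mean and SEM of the ratio, and fold activation
#' relative to the control (empty-vector) group.
#'
#' @param tab assay table with targets `firefly` and `renilla`.
#' @param control_group baseline group for fold activation.
#' @return list with `wells` (per-well ratios) and `groups` (per-group
#'   `mean_ratio`, `sem_ratio`, `n`, `fold_activation`).
#' @export
normalize_luciferase <- function(tab, control_group) {
  tab <- as.data.table(tab)
  ff <- tab[target == "firefly"]
  rn <- tab[target == "renilla"]
  wells <- merge(ff[, .(group, replicate, firefly = value)],
                 rn[, .(group, replicate, renilla = value)],
                 by = c("group", "replicate"))
  if (nrow(wells) < nrow(ff) || nrow(wells) < nrow(rn)) {
    vk_stop("unpaired firefly/renilla wells")
  }
  if (any(wells$renilla == 0)) {
    bad <- wells[renilla == 0][1L]
    vk_stop("Renilla signal is zero in group '%s' replicate %s",
            bad$group, bad$replicate)
  }
  wells[, ratio := firefly / renilla]
  groups <- wells[, .(mean_ratio = mean(ratio), sem_ratio = sem(ratio),
                      n = .N), by = group]
  if (!control_group %in% groups$group) {
    vk_stop("control group '%s' not in table", control_group)
  }
  base <- groups$mean_ratio[groups$group == control_group]
  groups[, fold_activation := mean_ratio / base]
  list(wells = wells[], groups = groups[])
}

#' Calibrate sample calcium content against a CaCl2 standard curve
#'
#' Fits an ordinary least-squares line reading ~ concentration to the
#' standards, inverts it to interpolate sample concentrations, and divides
#' pool totals by the number of embryos per pool. Sample readings outside
#' the standard range are extrapolated with a warning and flagged. An
#' optional pool-size series (number of embryos vs total calcium) is
#' checked for linearity and its R-squared reported.
#'
#' @param standards data.frame with `concentration` and `reading` (>= 3
#'   points).
#' @param samples data.frame with `label` and `reading`.
#' @param n_embryos_per_pool embryos pooled per sample (default 20).
#' @param pool_series optional data.frame with `n_embryos` and `total`.
#' @return list with `slope`, `intercept`, `r_squared`, `samples`
#'   (`concentration`, `per_embryo`, `extrapolated`) and
#'   `pool_linearity_r_squared` (`NA` when no series given).
#' @export
calcium_from_standard_curve <- function(standards, samples,
                                        n_embryos_per_pool = 20L,
                                        pool_series = NULL) {
  standards <- as.data.table(standards)
  if (nrow(standards) < 3L) vk_stop("need at least 3 standard points")
  fit <- lm(reading ~ concentration, data = standards)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (slope == 0) vk_stop("flat standard curve (slope 0)")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((standards$reading - mean(standards$reading))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  samples <- as.data.table(samples)
  rng <- range(standards$reading)
  samples[, extrapolated := reading < rng[1L] | reading > rng[2L]]
  if (any(samples$extrapolated)) {
    warning(sprintf("%d sample reading(s) outside standard range; extrapolating",
                    sum(samples$extrapolated)))
  }
  samples[, concentration := (reading - intercept) / slope]
  samples[, per_embryo := concentration / n_embryos_per_pool]
  pool_r2 <- NA_real_
  if (!is.null(pool_series)) {
    pool_series <- as.data.table(pool_series)
    pfit <- lm(total ~ n_embryos, data = pool_series)
    sst <- sum((pool_series$total - mean(pool_series$total))^2)
    pool_r2 <- if (sst == 0) 1 else 1 - sum(pfit$residuals^2) / sst
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       samples = samples[], pool_linearity_r_squared = pool_r2)
}

#' Two-group comparison with mean +/- SEM and significance stars
#'
#' Welch's two-sample two-sided t-test by default (small n, unequal
#' variances); a permutation test on the difference of means is available
#' as an alternative. Degenerate input where both groups are constant is
#' handled directly (p = 1 when equal, p = 0 when separated). Stars: `*`
#' p < 0.05, `**` p < 0.01.
#'
#' @param a,b numeric vectors of replicate measurements.
#' @param method `"welch"` (default) or `"permutation"`.
#' @param n_perm permutations for the permutation test.
#' @return list with `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `stars`.
#' @export
compare_groups <- function(a, b, method = c("welch", "permutation"),
                           n_perm = 10000L) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) vk_stop("each group needs >= 2 replicates")
  if (method == "welch") {
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      statistic <- if (p == 1) 0 else Inf
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      p <- tt$p.value
      statistic <- unname(tt$statistic)
    }
  } else {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1L) / (n_perm + 1L)
    statistic <- obs
  }
  list(mean_a = mean(a), mean_b = mean(b), sem_a = sem(a), sem_b = sem(b),
       n_a = length(a), n_b = length(b), statistic = statistic, p_value = p,
       stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}
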