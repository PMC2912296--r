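# Liquid-vs-elastic discrimination of compressed aggregates and cohort
# statistics.
#
# A viscoelastic-liquid aggregate has the same apparent surface tension at
# two successive compressions (sigma2/sigma1 ~ 1) even though the applied
# force increases; an elastic-solid aggregate obeys Hooke's law, so its
# apparent tension scales with the force (sigma2/sigma1 ~ F2/F1). The
# elasticity index E interpolates between the two ideals.

# round half away from zero at `digits` decimals (report-style rounding;
# base round() rounds half to even)
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Elasticity index of a twice-compressed aggregate
#'
#' `E = (sigma2/sigma1 - 1) / (F2/F1 - 1)`. An ideal liquid keeps its
#' surface tension across compressions (`E = 0`); an ideal Hookean solid's
#' apparent tension scales with the applied force (`E = 1`).
#'
#' @param sigma1,sigma2 Apparent surface tensions (dyn/cm) at the first and
#'   second compression; `sigma1 > 0`.
#' @param F1,F2 Equilibrium forces (dyn); requires `F2 > F1 > 0`.
#' @return Dimensionless elasticity index (vectorized).
#' @export
elasticity_index <- function(sigma1, sigma2, F1, F2) {
  if (any(F1 <= 0)) stop("invalid force: F1 must be > 0")
  if (any(F2 <= F1)) stop("second compression not greater: need F2 > F1")
  if (any(sigma1 <= 0)) stop("invalid sigma1: must be > 0")
  (sigma2 / sigma1 - 1) / (F2 / F1 - 1)
}

#' Classify an aggregate as viscoelastic liquid or elastic solid
#'
#' Thresholds the elasticity index at the midpoint between the ideal-liquid
#' (`E = 0`) and ideal-solid (`E = 1`) limits; ties go to `"elastic"`.
#'
#' @param E Elasticity index, see [elasticity_index()] (vectorized).
#' @param threshold Verdict boundary; `E < threshold` is liquid.
#' @return Character vector, `"liquid"` or `"elastic"`.
#' @export
classify_aggregate <- function(E, threshold = 0.5) {
  if (any(!is.finite(E))) stop("elasticity index not computable")
  ifelse(E < threshold, "liquid", "elastic")
}

#' Paired t-test of sigma1 vs sigma2
#'
#' Two-sided paired Student t-test of the apparent surface tensions at the
#' two compressions of each aggregate. For a liquid cohort the differences
#' are pure noise and the test does not reject.
#'
#' @param sigma1,sigma2 Paired surface tensions, length >= 2.
#' @return List with `statistic` (t) and `p.value`. If every difference is
#'   exactly zero, `statistic = 0` and `p.value = 1`; a constant nonzero
#'   difference has no defined t and is an error.
#' @export
paired_sigma_test <- function(sigma1, sigma2) {
  if (length(sigma1) != length(sigma2)) stop("insufficient pairs: unequal lengths")
  n <- length(sigma1)
  if (n < 2) stop("insufficient pairs: need n >= 2")
  d <- sigma2 - sigma1
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(statistic = 0, p.value = 1))
    stop("degenerate variance: constant nonzero difference")
  }
  tt <- stats::t.test(sigma2, sigma1, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Pooled two-proportion z statistic
#'
#' `z = (p1 - p2) / sqrt(pbar (1 - pbar) (1/n1 + 1/n2))` with
#' `pbar = (n1 p1 + n2 p2) / (n1 + n2)`. In the cohort liquidity table this
#' is applied to the inverted ratios `sigma1/sigma2` and `F1/F2` (both <= 1
#' for a liquid cohort), with `n1 = n2 =` the aggregate count.
#'
#' @param p1,p2 Proportions in `[0, 1]`.
#' @param n1,n2 Sample sizes, >= 1.
#' @return The z statistic (standard normal under the null `p1 = p2`).
#' @export
two_proportion_z <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) stop("not a proportion")
  if (any(c(n1, n2) < 1)) stop("invalid sample size")
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) stop("degenerate pooled proportion")
  (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
}

#' Pair compression records into per-aggregate analysis records
#'
#' Computes the apparent surface tension of every compression record via
#' [compute_surface_tension()], pairs the two steps of each aggregate, and
#' attaches the elasticity index and liquid/elastic verdict.
#'
#' @param compressions Data frame with columns `aggregate_id`, `step` (1 or
#'   2), `F_dyn`, `X_um`, `R2_um`, `H_um`, and optionally `V_um3`, `clone`,
#'   `sFn_ug_ml`, `label`.
#' @param threshold Classification threshold, see [classify_aggregate()].
#' @return Data frame with one row per aggregate: `aggregate_id`, optional
#'   `clone`, `sFn_ug_ml`, `label`, then `sigma1`, `sigma2`, `F1`, `F2`,
#'   `V_um3`, `E`, `verdict`.
#' @export
analyze_compressions <- function(compressions, threshold = 0.5) {
  req <- c("aggregate_id", "step", "F_dyn", "X_um", "R2_um", "H_um")
  miss <- setdiff(req, names(compressions))
  if (length(miss) > 0) {
    stop("schema error: missing column ", paste(miss, collapse = ", "))
  }
  ids <- unique(compressions$aggregate_id)
  rows <- lapply(ids, function(id) {
    sub <- compressions[compressions$aggregate_id == id, ]
    if (!setequal(sub$step, c(1, 2)) || nrow(sub) != 2) {
      stop("row-level error for aggregate ", id, ": need exactly steps 1 and 2")
    }
    sub <- sub[order(sub$step), ]
    prof <- lapply(seq_len(2), function(i) {
      tryCatch(
        aggregate_profile(X = sub$X_um[i], R2 = sub$R2_um[i], H = sub$H_um[i]),
        error = function(e) {
          stop("row-level error for aggregate ", id, ": ", conditionMessage(e))
        })
    })
    sig <- vapply(seq_len(2), function(i) {
      compute_surface_tension(sub$F_dyn[i], prof[[i]], step = i)$sigma
    }, numeric(1))
    V <- if ("V_um3" %in% names(sub)) sub$V_um3[1] else
      profile_volume(profile = prof[[1]])
    out <- data.frame(aggregate_id = id,
                      sigma1 = sig[1], sigma2 = sig[2],
                      F1 = sub$F_dyn[1], F2 = sub$F_dyn[2],
                      V_um3 = V, stringsAsFactors = FALSE)
    for (extra in c("clone", "sFn_ug_ml", "label")) {
      if (extra %in% names(sub)) out[[extra]] <- sub[[extra]][1]
    }
    out
  })
  rec <- do.call(rbind, rows)
  rec$E <- elasticity_index(rec$sigma1, rec$sigma2, rec$F1, rec$F2)
  rec$verdict <- classify_aggregate(rec$E, threshold = threshold)
  rec
}

#' Percentage of liquid and elastic aggregates in a cohort
#'
#' @param verdicts Character vector of `"liquid"` / `"elastic"` verdicts, or
#'   a data frame with a `verdict` column.
#' @return Named numeric vector `c(pct_liquid, pct_elastic)` summing to 100.
#' @export
fraction_liquid <- function(verdicts) {
  if (is.data.frame(verdicts)) verdicts <- verdicts$verdict
  n <- length(verdicts)
  if (n < 1) stop("no records")
  pct_liquid <- 100 * sum(verdicts == "liquid") / n
  c(pct_liquid = pct_liquid, pct_elastic = 100 - pct_liquid)
}

#' Cohort liquidity summary table
#'
#' Summarizes one cohort (one clone at one soluble-fibronectin condition):
#' means and standard errors of sigma1 and sigma2, the paired t-test, the
#' ratio of mean tensions and of mean forces (reported at two decimals,
#' rounded half up), the pooled two-proportion z statistic on the inverted
#' ratios, and the liquid/elastic percentages.
#'
#' @param records Per-aggregate records as from [analyze_compressions()]:
#'   columns `sigma1`, `sigma2`, `F1`, `F2`, and optionally `E`/`verdict`
#'   (recomputed if absent), `clone`, `sFn_ug_ml`.
#' @param threshold Classification threshold used if `verdict` is absent.
#' @return List of class `"cohort_stats"`.
#' @export
cohort_liquidity_table <- function(records, threshold = 0.5) {
  for (col in c("clone", "sFn_ug_ml")) {
    if (col %in% names(records) && length(unique(records[[col]])) > 1) {
      stop("heterogeneous cohort: mixed ", col)
    }
  }
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("insufficient records: need n >= 2")
  if (!"verdict" %in% names(records)) {
    records$E <- elasticity_index(records$sigma1, records$sigma2,
                                  records$F1, records$F2)
    records$verdict <- classify_aggregate(records$E, threshold = threshold)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  m1 <- mean(records$sigma1); m2 <- mean(records$sigma2)
  mF1 <- mean(records$F1);    mF2 <- mean(records$F2)
  pt <- tryCatch(paired_sigma_test(records$sigma1, records$sigma2),
                 error = function(e) list(statistic = NA_real_,
                                          p.value = NA_real_))
  u <- m1 / m2
  v <- mF1 / mF2
  # z on the inverted ratios, signed so that a liquid cohort (force ratio
  # above tension ratio) gives a negative z, the conventional direction
  z <- if (u <= 1 && v <= 1) {
    two_proportion_z(v, n, u, n)
  } else {
    warning("sigma or force ratio of means exceeds 1; z not defined")
    NA_real_
  }
  fr <- fraction_liquid(records$verdict)
  structure(list(
    clone = if ("clone" %in% names(records)) records$clone[1] else NA,
    sFn_ug_ml = if ("sFn_ug_ml" %in% names(records)) records$sFn_ug_ml[1] else NA,
    n = n,
    mean_sigma1 = m1, sem_sigma1 = sem(records$sigma1),
    mean_sigma2 = m2, sem_sigma2 = sem(records$sigma2),
    p_paired = pt$p.value,
    ratio_sigma = .round_half_up(m2 / m1, 2),
    ratio_F = .round_half_up(mF2 / mF1, 2),
    z = z,
    frac_liquid = unname(fr["pct_liquid"]),
    frac_elastic = unname(fr["pct_elastic"])
  ), class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("cohort (clone %s, sFn %s ug/ml), n = %d aggregates\n",
              as.character(x$clone), as.character(x$sFn_ug_ml), x$n))
  cat(sprintf("  sigma1 = %.2f +/- %.2f, sigma2 = %.2f +/- %.2f dyn/cm\n",
              x$mean_sigma1, x$sem_sigma1, x$mean_sigma2, x$sem_sigma2))
  cat(sprintf("  sigma2/sigma1 = %.2f, F2/F1 = %.2f, paired p = %.3g, z = %.3g\n",
              x$ratio_sigma, x$ratio_F, x$p_paired, x$z))
  cat(sprintf("  %.0f%% liquid / %.0f%% elastic\n",
              x$frac_liquid, x$frac_elastic))
  invisible(x)
}

#' Summarize several cohorts at once
#'
#' Applies [cohort_liquidity_table()] to every `clone` x `sFn_ug_ml` group
#' and binds the results into one data frame (one row per cohort).
#'
#' @inheritParams cohort_liquidity_table
#' @return Data frame with the `cohort_stats` fields as columns.
#' @export
summarize_cohorts <- function(records, threshold = 0.5) {
  clone <- if ("clone" %in% names(records)) records$clone else "all"
  cond <- if ("sFn_ug_ml" %in% names(records)) records$sFn_ug_ml else NA
  key <- interaction(clone, cond, drop = TRUE)
  rows <- lapply(split(records, key), function(sub) {
    as.data.frame(unclass(cohort_liquidity_table(sub, threshold = threshold)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of surface tension on aggregate volume
#'
#' Ordinary least squares of the per-aggregate surface tension (mean of
#' sigma1 and sigma2) on volume, restricted to liquid-verdict records when a
#' `verdict` column is present. For a liquid cohort the slope should be
#' indistinguishable from zero and r^2 small: surface tension of a liquid is
#' independent of drop size.
#'
#' @param records Data frame with `sigma1`, `sigma2` (or a single `sigma`),
#'   `V_um3`, and optionally `verdict`.
#' @return List of class `"regression_result"`: `slope`, `intercept`, `r2`.
#' @export
volume_independence <- function(records) {
  if ("verdict" %in% names(records)) {
    records <- records[records$verdict == "liquid", , drop = FALSE]
  }
  sigma <- if ("sigma" %in% names(records)) records$sigma else
    (records$sigma1 + records$sigma2) / 2
  V <- records$V_um3
  if (length(sigma) < 3) stop("insufficient data: need n >= 3")
  if (any(!is.finite(sigma)) || any(!is.finite(V)) || any(V <= 0)) {
    stop("invalid data: sigma and V must be finite, V > 0")
  }
  if (stats::var(V) == 0) stop("degenerate regressor: zero volume variance")
  if (stats::var(sigma) == 0) {
    # constant response: flat line fits perfectly, no variance explained
    return(structure(list(slope = 0, intercept = sigma[1], r2 = 0),
                     class = "regression_result"))
  }
  fit <- stats::lm(sigma ~ V)
  # r^2 computed directly (summary.lm warns on numerically perfect fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((sigma - mean(sigma))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = min(1, max(0, r2))),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, intercept = %.4g, r^2 = %.4g\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD across groups of surface tensions
#'
#' Compares mean surface tension between cohorts (e.g. the four receptor
#' expression clones) by one-way ANOVA followed by Tukey's honestly
#' significant difference test for all pairwise contrasts.
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   surface tensions; >= 2 groups, each with n >= 2.
#' @return List with `F` (ANOVA F statistic), `p` (ANOVA p-value), and
#'   `pairwise` (data frame of Tukey-adjusted pairwise comparisons:
#'   `contrast`, `diff`, `p_adj`).
#' @export
compare_groups_sigma <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("insufficient group size: each group needs n >= 2")
  }
  df <- data.frame(
    sigma = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(sigma ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(contrast = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL,
                         stringsAsFactors = FALSE)
  list(F = an["group", "F value"], p = an["group", "Pr(>F)"],
       pairwise = pairwise)
}
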