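#' Voxels inside a spherical ROI
#'
#' Enumerates voxel centres of `grid` whose Euclidean distance to the ROI
#' centre is at most the radius (voxel-centre membership, no
#' partial-volume weighting). Warns if the sphere contains no voxel
#' centre.
#'
#' @param roi a [roi_spec()].
#' @param grid a [grid_spec()].
#' @return tibble with voxel indices `i`, `j`, `k` (1-based), world
#'   coordinates `x`, `y`, `z` (mm) and the column-major `linear` index.
#' @export
sphere_voxels <- function(roi = roi_spec(), grid = grid_spec()) {
  stopifnot(inherits(roi, "roi_spec"), inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dim[a]) - 1) * grid$voxel_size[a])
  g <- expand.grid(i = seq_len(grid$dim[1]), j = seq_len(grid$dim[2]),
                   k = seq_len(grid$dim[3]))
  x <- ax[[1]][g$i]; y <- ax[[2]][g$j]; z <- ax[[3]][g$k]
  d2 <- (x - roi$center[1])^2 + (y - roi$center[2])^2 + (z - roi$center[3])^2
  inside <- d2 <= roi$radius^2 + 1e-9
  if (!any(inside))
    warning("sphere ROI contains no voxel centre", call. = FALSE)
  lin <- g$i + (g$j - 1) * grid$dim[1] + (g$k - 1) * grid$dim[1] * grid$dim[2]
  tibble::tibble(i = g$i[inside], j = g$j[inside], k = g$k[inside],
                 x = x[inside], y = y[inside], z = z[inside],
                 linear = lin[inside])
}

#' Average a voxel series over an ROI
#'
#' Unweighted mean across the ROI voxels at each time point.
#'
#' @param series either a 4-D array (x, y, z, time) or a volumes x voxels
#'   matrix whose columns are indexed by `voxels$linear`.
#' @param voxels a [sphere_voxels()] table.
#' @return numeric vector, one value per time point.
#' @export
roi_average <- function(series, voxels) {
  if (nrow(voxels) == 0)
    stop_rtbold("empty voxel set", class = "rtbold_roi_error")
  if (is.array(series) && length(dim(series)) == 4) {
    nt <- dim(series)[4]
    m <- matrix(series, ncol = nt)  # (x*y*z) x time
    colMeans(matrix(m[voxels$linear, , drop = FALSE], ncol = nt))
  } else {
    m <- as.matrix(series)
    rowMeans(m[, voxels$linear, drop = FALSE])
  }
}

group_result <- function(kind, statistic, df, p, estimate, units = "signal") {
  structure(list(kind = kind, statistic = statistic, df = df, p = p,
                 estimate = estimate, units = units),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  dfs <- paste(round(x$df, 1), collapse = ", ")
  cat(sprintf("%s: stat = %.4f, df = (%s), p = %.4g, estimate = %.4f %s\n",
              x$kind, x$statistic, dfs, x$p, x$estimate, x$units))
  invisible(x)
}

#' One-sample t-test on per-participant effects
#'
#' Two-tailed test of the mean against 0 with `n - 1` degrees of freedom —
#' the second level of the summary-statistics random-effects analysis.
#'
#' @param values per-participant effect estimates (length >= 2).
#' @param units units label for the estimate.
#' @return a `group_result`.
#' @export
one_sample_t <- function(values, units = "signal") {
  if (length(values) < 2)
    stop_rtbold("need at least two participants", class = "rtbold_stat_error")
  if (sd(values) == 0)
    stop_rtbold("zero variance across participants; t undefined",
                class = "rtbold_stat_error")
  tt <- t.test(values, mu = 0, alternative = "two.sided")
  group_result("one_sample_t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, mean(values), units)
}

#' Congruency x sampling-method within-participant ANOVA
#'
#' A 2 x 2 within-participant ANOVA with factors congruency (congruent,
#' incongruent) and sampling method (RT-matched, RT-subsampled), computed
#' from the per-participant congruency effects of the two methods. With a
#' single pairwise factor each, the interaction F(1, n-1) is exactly the
#' squared paired t on the difference scores (subsampled effect - matched
#' effect), and the congruency main effect is the squared one-sample t on
#' the mean of the two effects.
#'
#' @param matched_effects per-participant incongruent - congruent effects
#'   in the RT-matched model.
#' @param subsampled_effects same participants, RT-subsampled model.
#' @return list with `congruency` and `interaction` `group_result`s.
#' @export
congruency_by_sampling_anova <- function(matched_effects,
                                         subsampled_effects) {
  n <- length(matched_effects)
  if (length(subsampled_effects) != n)
    stop_rtbold("effect vectors must be paired per participant",
                class = "rtbold_stat_error")
  if (n < 2)
    stop_rtbold("need at least two participants", class = "rtbold_stat_error")
  f_from_t <- function(v, kind) {
    if (sd(v) == 0) {
      # degenerate: no between-participant variability in the contrast
      f <- if (mean(v) == 0) 0 else Inf
      return(group_result(kind, f, c(1, n - 1),
                          if (mean(v) == 0) 1 else 0, mean(v)))
    }
    tt <- t.test(v, mu = 0)
    group_result(kind, unname(tt$statistic)^2, c(1, n - 1), tt$p.value,
                 mean(v))
  }
  list(congruency = f_from_t((matched_effects + subsampled_effects) / 2,
                             "anova_F_congruency"),
       interaction = f_from_t(subsampled_effects - matched_effects,
                              "anova_F_interaction"))
}

#' Congruency effect with mean-centred age as covariate
#'
#' Linear model `effect ~ intercept + (age - mean(age))`; the intercept
#' test is the congruency effect at the mean age, the slope test is the
#' age modulation.
#'
#' @param effects per-participant congruency effects.
#' @param ages participant ages (not all equal).
#' @return list with `congruency_at_mean_age` and `age_slope`
#'   `group_result`s.
#' @export
ancova_age <- function(effects, ages) {
  if (length(effects) != length(ages))
    stop_rtbold("effects and ages must be the same length",
                class = "rtbold_stat_error")
  if (sd(ages) == 0)
    stop_rtbold("ages are constant; the age slope is undefined",
                class = "rtbold_stat_error")
  age_c <- ages - mean(ages)
  fit <- lm(effects ~ age_c)
  sm <- summary(fit)$coefficients
  if (summary(fit)$sigma < max(abs(effects), 1e-300) * 1e-10)
    warning("residual variance is zero; effects are exactly linear in age",
            call. = FALSE)
  df <- fit$df.residual
  list(congruency_at_mean_age =
         group_result("ancova", sm["(Intercept)", "t value"], df,
                      sm["(Intercept)", "Pr(>|t|)"],
                      sm["(Intercept)", "Estimate"]),
       age_slope =
         group_result("ancova", sm["age_c", "t value"], df,
                      sm["age_c", "Pr(>|t|)"], sm["age_c", "Estimate"],
                      units = "signal per year"))
}
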