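# Statistical battery and the blinded-sample identification procedure:
# mixed-design repeated-measures ANOVA, post hoc adjustments, diagnostic
# tests, threshold screening, and grouped-suspect similarity testing.

#' Mixed-design repeated-measures ANOVA
#'
#' Two-factor mixed decomposition with one between-subject factor (group)
#' and one within-subject factor (time); subjects are particles. Sums of
#' squares are obtained from the sequential decomposition
#' group -> subjects-within-groups -> time -> group:time of a single linear
#' model fit, and F ratios are formed against the mixed-model error strata:
#' the between-group effect against the subjects-within-groups mean square,
#' the time and interaction effects against the within-subject residual.
#'
#' Requires a balanced time grid (every subject measured at the identical
#' times) and complete cases; group sizes may differ.
#'
#' @param data Long-format data frame.
#' @param value,group,subject,time Column names.
#' @return Data frame of class `anova_table` with one row per effect
#'   (`group`, `subject_within_group`, `time`, `group:time`, `residual`) and
#'   columns `SS`, `df`, `MS`, `F`, `p`. A zero-variance error stratum
#'   yields `F = NA` with a `zero_variance` attribute naming the stratum.
#' @export
rm_anova_mixed <- function(data, value = "percent_remaining",
                           group = "material", subject = "particle_id",
                           time = "time_s") {
  d <- data.frame(y = data[[value]],
                  g = factor(data[[group]]),
                  s = factor(data[[subject]]),
                  t = factor(data[[time]]))
  if (anyNA(d)) stop("complete cases required")
  if (nlevels(d$g) < 2L) stop("need at least 2 groups")
  # each subject belongs to exactly one group
  gs <- unique(d[, c("g", "s")])
  if (anyDuplicated(gs$s)) stop("a subject appears in more than one group")
  if (any(table(gs$g) < 2L)) stop("need at least 2 subjects per group")
  # balanced time grid: every subject has the same set of times, once each
  tt <- table(d$s, d$t)
  if (any(tt != 1L))
    stop("unbalanced time grid: every subject needs every time exactly once")
  n_t <- nlevels(d$t)
  fit <- stats::lm(y ~ g + s + t + g:t, data = d)
  a <- suppressWarnings(stats::anova(fit))  # degenerate strata handled below
  ss <- a[["Sum Sq"]]; df <- a[["Df"]]
  rn <- rownames(a)
  pick <- function(nm) which(rn == nm)
  SS <- c(group = ss[pick("g")], subject = ss[pick("s")],
          time = ss[pick("t")], inter = ss[pick("g:t")],
          resid = ss[pick("Residuals")])
  DF <- c(group = df[pick("g")], subject = df[pick("s")],
          time = df[pick("t")], inter = df[pick("g:t")],
          resid = df[pick("Residuals")])
  MS <- SS / DF
  zero <- character(0)
  eps <- 1e-12 * max(1, sum(SS))
  f_group <- if (MS[["subject"]] > eps) MS[["group"]] / MS[["subject"]]
             else { zero <- c(zero, "subject_within_group"); NA_real_ }
  if (MS[["resid"]] > eps) {
    f_time <- MS[["time"]] / MS[["resid"]]
    f_int <- MS[["inter"]] / MS[["resid"]]
  } else {
    zero <- c(zero, "residual"); f_time <- f_int <- NA_real_
  }
  out <- data.frame(
    effect = c("group", "subject_within_group", "time", "group:time",
               "residual"),
    SS = unname(SS), df = unname(DF), MS = unname(MS),
    F = c(f_group, NA, f_time, f_int, NA),
    p = c(if (is.na(f_group)) NA_real_ else
            stats::pf(f_group, DF[["group"]], DF[["subject"]],
                      lower.tail = FALSE),
          NA,
          if (is.na(f_time)) NA_real_ else
            stats::pf(f_time, DF[["time"]], DF[["resid"]],
                      lower.tail = FALSE),
          if (is.na(f_int)) NA_real_ else
            stats::pf(f_int, DF[["inter"]], DF[["resid"]],
                      lower.tail = FALSE),
          NA),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  attr(out, "n_times") <- n_t
  if (length(zero)) attr(out, "zero_variance") <- zero
  out
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise, with an explicit family size.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param m Family size; must be at least the number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvalues)) stop("family size m smaller than comparisons")
  pmin(1, pvalues * m)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups[[1L]], groups[[2L]])
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("need at least 2 values per group")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA on scalar summaries
#'
#' Standard between/within decomposition via a linear-model fit. With zero
#' within-group variance the F statistic is infinite (p = 0) when group
#' means differ and undefined (`NA`) when they coincide.
#'
#' @param groups Named list of numeric vectors (each length >= 2), or a
#'   two-column data frame (value, group).
#' @return List with `F`, `p`, and the `table` of SS/df/MS.
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  a <- suppressWarnings(stats::anova(stats::lm(v ~ g)))
  ss_b <- a[["Sum Sq"]][1L]; ss_w <- a[["Sum Sq"]][2L]
  df_b <- a[["Df"]][1L]; df_w <- a[["Df"]][2L]
  eps <- 1e-12 * max(1, ss_b + ss_w)
  if (ss_w <= eps) {
    if (ss_b <= eps) { Fv <- NA_real_; p <- NA_real_ }
    else { Fv <- Inf; p <- 0 }
  } else {
    Fv <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(Fv, df_b, df_w, lower.tail = FALSE)
  }
  list(F = Fv, p = p,
       table = data.frame(effect = c("between", "within"),
                          SS = c(ss_b, ss_w), df = c(df_b, df_w),
                          MS = c(ss_b / df_b, ss_w / df_w)))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range comparisons of group means with the pooled within-group
#' mean square (via [stats::TukeyHSD()]).
#'
#' @inheritParams one_way_anova
#' @return Data frame `comparison`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- as_group_list(groups)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (stats::var(v - stats::ave(v, g)) == 0 &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1L)
    return(data.frame(
      comparison = apply(utils::combn(levels(g), 2L), 2L,
                         paste, collapse = "-"),
      diff = 0, p_adj = 1, stringsAsFactors = FALSE))
  tk <- stats::TukeyHSD(stats::aov(v ~ g))$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Normality diagnostic (Shapiro-Wilk)
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `statistic` (W) and `p`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Equal-variance diagnostic (Brown-Forsythe)
#'
#' Median-centred Levene test via `car::leveneTest(center = median)`.
#'
#' @inheritParams one_way_anova
#' @return List with `statistic` (F) and `p`.
#' @export
variance_check <- function(groups) {
  groups <- as_group_list(groups)
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  lt <- car::leveneTest(v, g, center = stats::median)
  list(statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"])
}

#' Ordinary least squares with R-squared
#'
#' @param x,y Numeric vectors, n >= 3; `x` must not be constant. A constant
#'   `y` returns slope 0 and, by convention, R-squared 0.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("x is constant")
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Screen suspect particles
#'
#' A particle is suspect for a reference material when its final deformation
#' strictly exceeds that material's least-deforming-particle threshold
#' (e.g. 8.1 percentage points for PET, 20.0 for PVC, at t = 39 s).
#'
#' @param summaries Data frame from [summarize_profiles()].
#' @param threshold Threshold in percentage points.
#' @return Character vector of suspect `particle_id`s.
#' @export
screen_suspects <- function(summaries, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  summaries$particle_id[summaries$final_deformation > threshold]
}

#' Similarity of grouped suspects to a reference material
#'
#' Runs the mixed-design repeated-measures ANOVA with group =
#' suspect-vs-reference and returns the between-group p-value. A large
#' p-value (no detectable group difference) is the similarity signal used
#' for a presence call; note that failure to reject is not a demonstration
#' of equivalence.
#'
#' @param suspects,reference Long-format profile data frames on one common
#'   time grid, each with at least 2 particles.
#' @return List with `p_value`, `n_suspect`, `n_reference`, `anova`.
#' @export
similarity_to_reference <- function(suspects, reference) {
  n_s <- length(unique(suspects$particle_id))
  n_r <- length(unique(reference$particle_id))
  if (n_s < 2L)
    stop("similarity not assessable: fewer than 2 suspect profiles")
  if (n_r < 2L) stop("need at least 2 reference profiles")
  if (!setequal(unique(suspects$time_s), unique(reference$time_s)))
    stop("suspect and reference profiles must share one time grid")
  d <- rbind(
    data.frame(particle_id = paste0("S_", suspects$particle_id),
               side = "suspect", time_s = suspects$time_s,
               percent_remaining = suspects$percent_remaining),
    data.frame(particle_id = paste0("R_", reference$particle_id),
               side = "reference", time_s = reference$time_s,
               percent_remaining = reference$percent_remaining))
  at <- rm_anova_mixed(d, group = "side")
  list(p_value = at$p[at$effect == "group"],
       n_suspect = n_s, n_reference = n_r, anova = at)
}

#' Build a reference library of known-material profiles
#'
#' Simulated stand-in for a measured reference library: `n_per_material`
#' profiles per material on the screening time grid, plus the screening
#' thresholds (least-deforming-particle final deformation of each screenable
#' plastic: PET 8.1, PVC 20.0 percentage points at t = 39 s) and the
#' acquisition metadata.
#'
#' @param materials Named list of [material_params()].
#' @param n_per_material Profiles per material (default 5).
#' @param times Common time grid in seconds.
#' @param seed Integer seed.
#' @param thresholds Named screening thresholds in percentage points.
#' @param alpha Significance level for downstream calls.
#' @param beam_current Acquisition beam current in nA (metadata).
#' @return Object of class `reference_library`.
#' @export
build_reference_library <- function(materials = material_presets(),
                                    n_per_material = 5L,
                                    times = c(0, 2, 4, 10, 20, 39),
                                    seed = 100L,
                                    thresholds = c(PET = 8.1, PVC = 20.0),
                                    alpha = 0.05, beam_current = 37.9) {
  stopifnot(n_per_material >= 2L, all(thresholds > 0),
            all(names(thresholds) %in% names(materials)))
  profiles <- generate_profile_table(materials, n_per_material, times, seed)
  structure(list(profiles = profiles, times = times,
                 thresholds = thresholds, alpha = alpha,
                 beam_current = beam_current,
                 n_per_material = as.integer(n_per_material), seed = seed),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf(
    "<reference_library> %d materials x %d profiles, %d timepoints; %s\n",
    length(unique(x$profiles$material)), x$n_per_material, length(x$times),
    paste(sprintf("%s > %.1f", names(x$thresholds), x$thresholds),
          collapse = ", ")))
  invisible(x)
}

#' Classify a blinded sample against a reference library
#'
#' The identification procedure: for each screenable reference material in
#' ascending threshold order, (1) screen the sample for suspect particles
#' whose final deformation exceeds that material's threshold, (2) group the
#' suspects and test their profiles for similarity to the material's
#' reference profiles with the mixed-design repeated-measures ANOVA, and
#' (3) call the material present when there are at least `min_group`
#' suspects and the between-group p-value exceeds `alpha` (no detectable
#' difference). Singleton suspect sets are reported but flagged as not
#' assessable.
#'
#' @param sample_profiles Long-format profiles of the blinded sample on the
#'   library's time grid.
#' @param library A [build_reference_library()] object.
#' @param alpha Significance level (default the library's, 0.05).
#' @param min_group Minimum suspects for a similarity test (default 2).
#' @param final_time,rate_window Passed to [summarize_profiles()].
#' @param sample_id Label for the report.
#' @return Object of class `classification_report`: `results` data frame
#'   (`material`, `threshold`, `n_suspect`, `p_value`, `present`, `flag`),
#'   `suspects` (list of id vectors), `summaries`, `alpha`, `min_group`.
#' @export
classify_sample <- function(sample_profiles, library,
                            alpha = library$alpha, min_group = 2L,
                            final_time = 39, rate_window = 4,
                            sample_id = "sample") {
  stopifnot(inherits(library, "reference_library"))
  if (nrow(sample_profiles) == 0L) stop("empty sample")
  if (!setequal(unique(sample_profiles$time_s), library$times))
    stop("sample profiles are not on the library's time grid")
  summaries <- summarize_profiles(sample_profiles, final_time, rate_window)
  th <- sort(library$thresholds)
  res <- list(); susp <- list()
  for (m in names(th)) {
    ids <- screen_suspects(summaries, th[[m]])
    susp[[m]] <- ids
    if (length(ids) >= min_group) {
      sim <- similarity_to_reference(
        sample_profiles[sample_profiles$particle_id %in% ids, ,
                        drop = FALSE],
        library$profiles[library$profiles$material == m, , drop = FALSE])
      res[[m]] <- data.frame(
        material = m, threshold = th[[m]], n_suspect = length(ids),
        p_value = sim$p_value, present = sim$p_value > alpha,
        flag = "", stringsAsFactors = FALSE)
    } else {
      res[[m]] <- data.frame(
        material = m, threshold = th[[m]], n_suspect = length(ids),
        p_value = NA_real_, present = FALSE,
        flag = "insufficient suspects for similarity test",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(sample_id = sample_id,
                 results = do.call(rbind, c(res,
                                            list(make.row.names = FALSE))),
                 suspects = susp, summaries = summaries,
                 alpha = alpha, min_group = as.integer(min_group)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Blinded-sample classification: %s (alpha = %.2f)\n",
              x$sample_id, x$alpha))
  r <- x$results
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      "  %-10s threshold > %4.1f pp: %2d suspect(s), p = %s -> %s%s\n",
      r$material[i], r$threshold[i], r$n_suspect[i],
      ifelse(is.na(r$p_value[i]), "NA", sprintf("%.3f", r$p_value[i])),
      ifelse(r$present[i], "present", "not called"),
      ifelse(nzchar(r$flag[i]), paste0(" [", r$flag[i], "]"), "")))
  }
  cat("  Note: a presence call rests on failure to reject similarity;\n",
      " absence of evidence for a difference is not equivalence.\n")
  invisible(x)
}
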