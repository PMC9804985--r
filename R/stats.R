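#' Log10-transform positive metric values
#'
#' The study workflow transforms per-animal read-outs to log10 before
#' testing. Non-positive values (an animal with no detected islets reads
#' 0) are a domain error by default, naming the offenders; supplying a
#' positive `offset` switches to `log10(x + offset)` instead.
#'
#' @param values numeric vector.
#' @param offset optional positive constant added before the transform.
#' @param labels optional names (animal ids) used in error messages.
#' @return transformed numeric vector.
#' @export
log10_transform <- function(values, offset = NULL, labels = NULL) {
  if (!is.null(offset)) {
    stopifnot(offset > 0)
    return(log10(values + offset))
  }
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    who <- if (!is.null(labels)) labels[bad] else paste0("element ", bad)
    stop("log10 transform undefined for non-positive value(s): ",
         paste(who, collapse = ", "),
         " (use an offset, or exclude these animals)")
  }
  log10(values)
}

#' Variance-homogeneity and normality gates
#'
#' Bartlett's test across groups and Shapiro-Wilk per group, on the
#' (transformed) per-animal values. `pass` is TRUE when every p-value
#' exceeds 0.05; a failed gate does not halt the analysis -- it is
#' reported alongside the test results.
#'
#' @param groups named list of numeric vectors, each of length >= 3.
#' @return list with `bartlett_p`, `shapiro_p` (named per group), `pass`.
#' @export
check_assumptions <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, integer(1))
  if (any(n < 3))
    stop("each group needs n >= 3 for the assumption checks (got: ",
         paste(n, collapse = ", "), ")")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups) %||% seq_along(groups), n))
  bart <- stats::bartlett.test(values, labels)
  shap <- vapply(groups, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)  # shapiro.test errors on ties
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  list(bartlett_p = unname(bart$p.value), shapiro_p = shap,
       pass = bart$p.value > 0.05 && all(is.na(shap) | shap > 0.05))
}

# P(max_j |T_j| <= q) for Dunnett's many-to-one statistics under the
# global null: T_j = (lambda_j Z0 + sqrt(1-lambda_j^2) Z_j) / S with
# Z ~ iid N(0,1), S = sqrt(chisq_df / df), lambda_j = sqrt(n_j/(n_j+n0)).
# Evaluated by adaptive quadrature over the (Z0, S) factor representation.
pdunnett_maxabs <- function(q, lambda, df) {
  if (q <= 0) return(0)
  gam <- sqrt(1 - lambda^2)
  inner <- function(s) {
    f <- function(z) {
      out <- stats::dnorm(z)
      for (j in seq_along(lambda)) {
        out <- out * (stats::pnorm((q * s - lambda[j] * z) / gam[j]) -
                      stats::pnorm((-q * s - lambda[j] * z) / gam[j]))
      }
      out
    }
    stats::integrate(f, -9, 9, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
  dens_s <- function(s) 2 * df * s * stats::dchisq(df * s^2, df)
  stats::integrate(function(s) vapply(s, inner, numeric(1)) * dens_s(s),
                   0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Monte-Carlo evaluation of the same tail probability (used for many
# comparisons, where the quadrature product becomes ill-conditioned)
pdunnett_maxabs_mc <- function(q, lambda, df, n_draws = 1e6, seed = 20260924) {
  withr::with_seed(seed, {
    z0 <- stats::rnorm(n_draws)
    s <- sqrt(stats::rchisq(n_draws, df) / df)
    below <- rep(TRUE, n_draws)
    gam <- sqrt(1 - lambda^2)
    for (j in seq_along(lambda)) {
      tj <- (lambda[j] * z0 + gam[j] * stats::rnorm(n_draws)) / s
      below <- below & abs(tj) <= q
    }
    mean(below)
  })
}

#' Dunnett's many-to-one comparison against a control group
#'
#' Classical pooled-variance Dunnett test: the within-group variance is
#' pooled across all groups (df = N - k), each treatment is compared with
#' the control via `t = (mean_t - mean_c) / SE`,
#' `SE = sqrt(s2 * (1/n_t + 1/n_c))`, and two-sided p-values are adjusted
#' over the equicorrelated multivariate-t reference distribution with
#' correlations `rho_ij = lambda_i lambda_j`,
#' `lambda_j = sqrt(n_j / (n_j + n_c))`, evaluated by adaptive quadrature
#' (Monte Carlo with a fixed internal seed beyond `mc_threshold`
#' comparisons). With a single treatment group this reduces exactly to the
#' classical pooled two-sample two-sided t-test.
#'
#' @param control numeric vector of control-group values (n >= 2).
#' @param treatments named list of numeric vectors (each n >= 2).
#' @param alpha significance level recorded in the result (default 0.05).
#' @param mc_threshold number of comparisons above which the Monte-Carlo
#'   evaluator replaces quadrature (default 8).
#' @return data.frame with one row per treatment: `comparison`, `diff`
#'   (treatment minus control), `se`, `t`, `df`, `p_unadjusted`,
#'   `p_adjusted`, `alpha`, `significant`.
#' @export
dunnett_test <- function(control, treatments, alpha = 0.05,
                         mc_threshold = 8L) {
  if (!is.list(treatments)) treatments <- list(treatment = treatments)
  if (length(treatments) < 1) stop("at least one treatment group required")
  groups <- c(list(control = control), treatments)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("every group needs n >= 2")
  k <- length(groups)
  N <- sum(n)
  df <- N - k
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df
  if (s2 <= 0) stop("pooled within-group variance is zero; ",
                    "t statistics are undefined")
  n0 <- n[1]
  nt <- n[-1]
  lambda <- sqrt(nt / (nt + n0))
  diffs <- vapply(treatments, mean, numeric(1)) - mean(control)
  se <- sqrt(s2 * (1 / nt + 1 / n0))
  tval <- diffs / se
  p_unadj <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  m <- length(treatments)
  p_adj <- vapply(seq_len(m), function(j) {
    q <- abs(tval[j])
    if (q == 0) return(1)
    cov_p <- if (m > mc_threshold) pdunnett_maxabs_mc(q, lambda, df)
             else pdunnett_maxabs(q, lambda, df)
    min(max(1 - cov_p, 0), 1)
  }, numeric(1))
  data.frame(
    comparison = paste0(names(treatments) %||%
                          paste0("treatment", seq_len(m)), " - control"),
    diff = unname(diffs), se = unname(se), t = unname(tval), df = df,
    p_unadjusted = unname(p_unadj), p_adjusted = unname(p_adj),
    alpha = alpha, significant = unname(p_adj < alpha),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Run the full group-comparison workflow on a cohort table
#'
#' For each metric: log10 transform (per the configured zero policy),
#' Bartlett / Shapiro-Wilk assumption gates, Dunnett's two-sided test of
#' every non-control group against the control, and raw-scale
#' mean +/- sd summaries per group. Animals with missing values for a
#' metric are dropped from that metric's comparison (with a warning if a
#' whole group vanishes, in which case the metric is skipped).
#'
#' @param cohort data.frame with `animal_id`, `group`, and metric columns
#'   (e.g. from [aggregate_per_animal()]).
#' @param metrics character vector of metric column names to compare.
#' @param control control group name.
#' @param alpha significance level (default 0.05).
#' @param transform `"log10"` (default) or `"none"`.
#' @param zero_policy for non-positive values under log10: `"error"`
#'   (default), `"exclude"` (drop those animals with a warning), or
#'   `"offset"` (add `offset` before transforming).
#' @param offset constant for `zero_policy = "offset"`.
#' @return object of class `group_comparison_list`: named list (one per
#'   metric) of `group_comparison` objects holding the group summaries,
#'   assumption p-values, and the Dunnett table.
#' @export
compare_cohort <- function(cohort, metrics, control, alpha = 0.05,
                           transform = c("log10", "none"),
                           zero_policy = c("error", "exclude", "offset"),
                           offset = NULL) {
  transform <- match.arg(transform)
  zero_policy <- match.arg(zero_policy)
  stopifnot(all(c("animal_id", "group") %in% names(cohort)),
            control %in% cohort$group)
  out <- list()
  for (metric in metrics) {
    if (!metric %in% names(cohort)) stop("no such metric column: ", metric)
    sub <- cohort[!is.na(cohort[[metric]]), c("animal_id", "group", metric)]
    lost <- setdiff(unique(cohort$group), unique(sub$group))
    if (length(lost)) {
      warning("metric '", metric, "' skipped: no values left for group(s) ",
              paste(lost, collapse = ", "))
      next
    }
    values <- sub[[metric]]
    if (transform == "log10") {
      if (zero_policy == "exclude" && any(values <= 0)) {
        drop <- values <= 0
        warning("metric '", metric, "': excluded non-positive value(s) of ",
                paste(sub$animal_id[drop], collapse = ", "))
        sub <- sub[!drop, ]
        values <- sub[[metric]]
        lost <- setdiff(unique(cohort$group), unique(sub$group))
        if (length(lost)) {
          warning("metric '", metric, "' skipped after exclusion: group(s) ",
                  paste(lost, collapse = ", "), " empty")
          next
        }
      }
      tvalues <- log10_transform(values,
                                 offset = if (zero_policy == "offset")
                                   offset %||% 1e-3 else NULL,
                                 labels = sub$animal_id)
    } else tvalues <- values

    grp <- split(tvalues, sub$group)
    raw <- split(values, sub$group)
    grp <- grp[c(control, setdiff(names(grp), control))]
    if (any(vapply(grp, length, integer(1)) < 2)) {
      warning("metric '", metric, "' skipped: fewer than 2 animals left in ",
              "some group")
      next
    }
    assumptions <- tryCatch(check_assumptions(grp),
                            error = function(e)
                              list(bartlett_p = NA_real_,
                                   shapiro_p = setNames(
                                     rep(NA_real_, length(grp)), names(grp)),
                                   pass = NA))
    test <- dunnett_test(grp[[control]], grp[setdiff(names(grp), control)],
                         alpha = alpha)
    summaries <- data.frame(
      group = names(grp),
      n = vapply(raw[names(grp)], length, integer(1)),
      raw_mean = vapply(raw[names(grp)], mean, numeric(1)),
      raw_sd = vapply(raw[names(grp)], stats::sd, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    out[[metric]] <- structure(list(
      metric = metric, transform = transform, control = control,
      group_summary = summaries,
      bartlett_p = assumptions$bartlett_p,
      shapiro_p = assumptions$shapiro_p,
      assumptions_pass = assumptions$pass,
      dunnett = test, alpha = alpha
    ), class = "group_comparison")
  }
  structure(out, class = "group_comparison_list")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s (%s scale, control = %s)\n",
              x$metric, x$transform, x$control))
  s <- x$group_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-14s n=%2d  mean %.4g +/- %.4g (raw scale)\n",
                s$group[i], s$n[i], s$raw_mean[i], s$raw_sd[i]))
  cat(sprintf("  Bartlett p = %.4f; Shapiro-Wilk p = %s; gates %s\n",
              x$bartlett_p,
              paste(sprintf("%s %.4f", names(x$shapiro_p), x$shapiro_p),
                    collapse = ", "),
              if (isTRUE(x$assumptions_pass)) "passed" else "flagged"))
  d <- x$dunnett
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: diff=%.4f SE=%.4f t=%.3f df=%d p=%.4f%s\n",
                d$comparison[i], d$diff[i], d$se[i], d$t[i], d$df[i],
                d$p_adjusted[i], if (d$significant[i]) " *" else ""))
  invisible(x)
}

#' Flatten a list of group comparisons to one results table
#'
#' @param comparisons a `group_comparison_list` from [compare_cohort()].
#' @return data.frame with one row per metric x comparison.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) {
    d <- x$dunnett
    ctrl <- x$group_summary[x$group_summary$group == x$control, ]
    other <- x$group_summary[x$group_summary$group != x$control, ]
    data.frame(metric = x$metric, comparison = d$comparison,
               control_n = ctrl$n, control_mean = ctrl$raw_mean,
               control_sd = ctrl$raw_sd,
               group_n = other$n, group_mean = other$raw_mean,
               group_sd = other$raw_sd,
               transform = x$transform,
               bartlett_p = x$bartlett_p,
               assumptions_pass = x$assumptions_pass,
               diff = d$diff, se = d$se, t = d$t, df = d$df,
               p_adjusted = d$p_adjusted, alpha = d$alpha,
               significant = d$significant,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
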