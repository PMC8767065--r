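# Distribution-gated group-comparison ladder and reporting-style summaries.
# Branch selection is a pure function of (design, normality outcomes):
#   independent 2 groups : normal -> Welch t; non-normal -> Mann-Whitney
#   independent k groups : normal -> 1-way ANOVA + Sidak pairwise
#                          non-normal -> Kruskal-Wallis + Dunn
#   repeated time x group: 2-way RM ANOVA + Dunnett vs control
# Groups with n below the normality-test minimum force the nonparametric
# branch; every decision is logged in the audit trail.

#' Compare groups with the distribution-gated test ladder
#'
#' Gates each group through the D'Agostino-Pearson normality test (alpha =
#' 0.05 per group; any failure routes to the nonparametric branch), then
#' applies the matching test. Groups smaller than `normality_min_n` cannot
#' be normality-tested and force the nonparametric branch.
#'
#' @param groups for the independent designs, a named list of numeric
#'   vectors; for `repeated_time_by_group`, a data.frame with columns
#'   `value`, `group`, `time`, `subject`.
#' @param design `"independent_2"`, `"independent_k"` or
#'   `"repeated_time_by_group"`; `"auto"` picks between the independent
#'   designs by group count.
#' @param alpha significance level (default 0.05).
#' @param control reference group for Dunnett comparisons (repeated design);
#'   defaults to the first group level.
#' @param normality_min_n smallest group size the normality gate accepts.
#' @return an object of class `group_comparison`: list with `design`,
#'   `test`, `statistic`, `p_value`, `significant`, `normality` (per-group
#'   tibble), `pairwise` (tibble or `NULL`), `alpha` and `audit` (character
#'   vector logging every branch decision).
#' @export
test_group_difference <- function(groups,
                                  design = c("auto", "independent_2",
                                             "independent_k",
                                             "repeated_time_by_group"),
                                  alpha = 0.05, control = NULL,
                                  normality_min_n = 8L) {
  design <- match.arg(design)
  if (design == "repeated_time_by_group")
    return(rm_anova_dunnett(groups, alpha = alpha, control = control))
  if (!is.list(groups) || is.data.frame(groups))
    stop("independent designs need a named list of numeric vectors",
         call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 3L))
    stop("every group needs n >= 3", call. = FALSE)
  if (design == "auto")
    design <- if (k == 2L) "independent_2" else "independent_k"
  if (design == "independent_2" && k != 2L)
    stop("independent_2 design requires exactly 2 groups", call. = FALSE)

  audit <- sprintf("design: %s with %d groups (n = %s)", design, k,
                   paste(lengths(groups), collapse = ", "))
  norm <- normality_gate(groups, alpha, normality_min_n)
  audit <- c(audit, norm$audit)
  parametric <- norm$all_normal

  if (design == "independent_2") {
    if (parametric) {
      ht <- stats::t.test(groups[[1]], groups[[2]])
      test <- "Welch t-test"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      test <- "Mann-Whitney"
    }
    audit <- c(audit, sprintf("branch: %s (p = %.4g)", test, ht$p.value))
    return(new_group_comparison(design, test, unname(ht$statistic),
                                ht$p.value, NULL, norm$table, alpha, audit))
  }

  if (parametric) {
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups), lengths(groups))))
    fit <- stats::aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    p <- an[["Pr(>F)"]][1]
    # pooled-variance pairwise t with Sidak correction
    pt <- stats::pairwise.t.test(df$value, df$group, p.adjust.method = "none")
    praw <- pt$p.value
    pairs <- which(!is.na(praw), arr.ind = TRUE)
    m <- nrow(pairs)
    pw <- tibble::tibble(
      contrast = paste(rownames(praw)[pairs[, 1]],
                       colnames(praw)[pairs[, 2]], sep = " - "),
      p_raw = praw[pairs],
      p_adj = 1 - (1 - praw[pairs])^m)
    test <- "one-way ANOVA + Sidak"
    audit <- c(audit,
               sprintf("branch: %s (F = %.4g, p = %.4g, %d contrasts)",
                       test, an[["F value"]][1], p, m))
    return(new_group_comparison(design, test, an[["F value"]][1], p, pw,
                                norm$table, alpha, audit))
  }

  kw <- stats::kruskal.test(groups)
  pw <- dunn_test(groups)
  test <- "Kruskal-Wallis + Dunn"
  audit <- c(audit, sprintf("branch: %s (H = %.4g, p = %.4g)", test,
                            unname(kw$statistic), kw$p.value))
  new_group_comparison(design, test, unname(kw$statistic), kw$p.value, pw,
                       norm$table, alpha, audit)
}

normality_gate <- function(groups, alpha, min_n) {
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (length(g) < min_n || stats::sd(g) == 0) {
      return(tibble::tibble(group = nm, n = length(g),
                            statistic = NA_real_, p = NA_real_,
                            tested = FALSE, normal = FALSE))
    }
    dp <- dagostino_pearson(g)
    tibble::tibble(group = nm, n = length(g), statistic = dp$statistic,
                   p = dp$p.value, tested = TRUE, normal = dp$p.value > alpha)
  })
  tab <- do.call(rbind, rows)
  audit <- vapply(seq_len(nrow(tab)), function(i) {
    if (!tab$tested[i])
      sprintf("normality[%s]: skipped (n = %d < %d) -> nonparametric branch forced",
              tab$group[i], tab$n[i], min_n)
    else
      sprintf("normality[%s]: K2 = %.3f, p = %.4g -> %s", tab$group[i],
              tab$statistic[i], tab$p[i],
              if (tab$normal[i]) "normal" else "non-normal")
  }, character(1))
  list(table = tab, all_normal = all(tab$normal), audit = audit)
}

# Two-way repeated-measures ANOVA (time within subject, group between),
# with Dunnett comparisons of each group against the control.
rm_anova_dunnett <- function(data, alpha = 0.05, control = NULL) {
  need <- c("value", "group", "time", "subject")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("repeated design needs a data.frame with value, group, time, subject",
         call. = FALSE)
  data$group <- factor(data$group)
  data$time <- factor(data$time)
  data$subject <- factor(data$subject)
  if (nlevels(data$group) < 2L) stop("need >= 2 groups", call. = FALSE)
  mixed <- any(tapply(data$group, data$subject,
                      function(g) length(unique(g))) > 1)
  if (mixed)
    stop("mixed designs (subjects in several groups) are not supported",
         call. = FALSE)
  if (!is.null(control)) data$group <- stats::relevel(data$group, control)
  audit <- sprintf(
    "design: repeated_time_by_group (%d groups x %d times, %d subjects)",
    nlevels(data$group), nlevels(data$time), nlevels(data$subject))
  fit <- stats::aov(value ~ group * time + Error(subject), data = data)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  f_group <- between[["F value"]][1]
  p_group <- between[["Pr(>F)"]][1]
  audit <- c(audit, sprintf("RM ANOVA group effect: F = %.4g, p = %.4g",
                            f_group, p_group))
  lmm <- lme4::lmer(value ~ group * time + (1 | subject), data = data)
  glht <- multcomp::glht(lmm, linfct = multcomp::mcp(group = "Dunnett",
                                                     interaction_average = TRUE))
  sm <- summary(glht)
  pw <- tibble::tibble(contrast = names(sm$test$coefficients),
                       estimate = unname(sm$test$coefficients),
                       z = unname(sm$test$tstat),
                       p_adj = unname(sm$test$pvalues))
  audit <- c(audit, sprintf("Dunnett vs %s: %s",
                            levels(data$group)[1],
                            paste(sprintf("%s p = %.4g", pw$contrast, pw$p_adj),
                                  collapse = "; ")))
  new_group_comparison("repeated_time_by_group",
                       "two-way RM ANOVA + Dunnett", f_group, p_group, pw,
                       NULL, alpha, audit)
}

new_group_comparison <- function(design, test, statistic, p_value, pairwise,
                                 normality, alpha, audit) {
  structure(list(design = design, test = test, statistic = statistic,
                 p_value = p_value, significant = isTRUE(p_value < alpha),
                 pairwise = pairwise, normality = normality, alpha = alpha,
                 audit = audit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n  %s: statistic = %.4g, p = %.4g%s\n",
              x$design, x$test, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (adjusted):\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %-24s p = %.4g\n", x$pairwise$contrast[i],
                  x$pairwise$p_adj[i]))
  }
  invisible(x)
}

#' Reporting-style summary of a sample
#'
#' Nonparametric: median and quartiles (linear-interpolation quantiles, the
#' Tukey box-plot convention). Parametric: mean, SD, SEM.
#'
#' @param values numeric vector, non-empty.
#' @param distribution `"nonparametric"` or `"parametric"`.
#' @return one-row tibble (`median`, `q1`, `q3`, `n` or `mean`, `sd`,
#'   `sem`, `n`).
#' @export
summarize_values <- function(values,
                             distribution = c("nonparametric", "parametric")) {
  distribution <- match.arg(distribution)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (distribution == "nonparametric") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    return(tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                          n = length(values)))
  }
  s <- stats::sd(values)
  tibble::tibble(mean = mean(values), sd = s,
                 sem = s / sqrt(length(values)), n = length(values))
}
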