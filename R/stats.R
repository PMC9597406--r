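#' Compare crouch and transition-incline conditions statistically
#'
#' Implements the condition-comparison decision tree used for matched cost
#' data across three walking conditions (typically crouch, pre-transition
#' incline, post-transition incline). Normality is screened per condition
#' with the Shapiro-Wilk test at the 0.05 level; when no condition rejects,
#' the parametric branch runs a one-way repeated-measures ANOVA with paired
#' t-test post hocs, otherwise the nonparametric branch runs a Friedman test
#' with Wilcoxon signed-rank post hocs (exact p-values at small samples, the
#' default in R below n = 50 without ties). Post hocs are run only when the
#' omnibus test is significant at `alpha`, and each pairwise contrast is
#' declared against the Bonferroni-adjusted `posthoc_alpha`.
#'
#' Degenerate inputs are handled deterministically: if every value is
#' identical the omnibus is reported non-significant (p = 1) and no post hocs
#' run; a constant non-zero paired difference is reported as p = 0.
#'
#' @param data Tibble with columns `participant_id`, `condition` and the
#'   value column; every participant must have exactly one value per
#'   condition.
#' @param value Name of the value column (unquoted or string).
#' @param alpha Omnibus significance level.
#' @param posthoc_alpha Bonferroni-adjusted pairwise level (0.05/3 rounded to
#'   0.017).
#' @return A `condition_comparison` object; see [tidy.condition_comparison()]
#'   and [glance.condition_comparison()].
#' @export
compare_conditions <- function(data, value, alpha = 0.05,
                               posthoc_alpha = 0.017) {
  value_col <- rlang::as_name(rlang::ensym(value))
  needed <- c("participant_id", "condition", value_col)
  if (!all(needed %in% names(data))) {
    abort_config(paste0(
      "`data` needs columns: ", paste(needed, collapse = ", ")
    ))
  }
  df <- tibble(
    participant_id = as.character(data$participant_id),
    condition = as.character(data$condition),
    value = as.numeric(data[[value_col]])
  )
  conds <- unique(df$condition)
  counts <- df |>
    group_by(.data$participant_id) |>
    summarise(
      complete = length(unique(.data$condition)) == length(conds) &&
        n() == length(conds),
      .groups = "drop"
    )
  if (any(!counts$complete)) {
    abort_data(paste0(
      "unmatched/missing condition values for: ",
      paste(counts$participant_id[!counts$complete], collapse = ", ")
    ))
  }
  if (nrow(counts) < 3) abort_data("fewer than 3 complete participant sets")

  wide <- df |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    arrange(.data$participant_id)

  normality <- purrr::map_dfr(conds, function(cc) {
    x <- wide[[cc]]
    res <- tryCatch(shapiro.test(x),
      error = function(e) list(statistic = NA_real_, p.value = NA_real_)
    )
    tibble(condition = cc,
           statistic = unname(res$statistic),
           p.value = unname(res$p.value))
  })
  # constant samples cannot reject normality; NA p-values count as passes
  normal <- all(is.na(normality$p.value) | normality$p.value > 0.05)
  branch <- if (normal) "parametric" else "nonparametric"

  dfl <- df
  dfl$condition <- factor(dfl$condition, levels = conds)
  dfl$participant_id <- factor(dfl$participant_id)

  if (sd(df$value) == 0) {
    omnibus <- list(method = "degenerate (constant values)",
                    statistic = NA_real_, df = NA_real_, p.value = 1)
  } else if (normal) {
    fit <- aov(value ~ participant_id + condition, data = dfl)
    tab <- summary(fit)[[1]]
    row <- which(trimws(rownames(tab)) == "condition")
    omnibus <- list(
      method = "one-way repeated-measures ANOVA",
      statistic = tab[row, "F value"],
      df = tab[row, "Df"],
      p.value = tab[row, "Pr(>F)"]
    )
  } else {
    ft <- friedman.test(value ~ condition | participant_id, data = dfl)
    omnibus <- list(
      method = "Friedman rank sum test",
      statistic = unname(ft$statistic),
      df = unname(ft$parameter),
      p.value = ft$p.value
    )
  }
  omnibus$significant <- is.finite(omnibus$p.value) && omnibus$p.value < alpha

  posthoc <- NULL
  if (omnibus$significant) {
    prs <- utils::combn(conds, 2, simplify = FALSE)
    posthoc <- purrr::map_dfr(prs, function(pr) {
      x <- wide[[pr[1]]]
      y <- wide[[pr[2]]]
      d <- x - y
      if (sd(d) == 0) {
        p <- if (all(d == 0)) 1 else 0
        res <- list(statistic = NA_real_, p.value = p,
                    method = "degenerate (constant differences)")
      } else if (normal) {
        tt <- t.test(x, y, paired = TRUE)
        res <- list(statistic = unname(tt$statistic), p.value = tt$p.value,
                    method = "paired t-test")
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
        res <- list(statistic = unname(wt$statistic), p.value = wt$p.value,
                    method = "Wilcoxon signed-rank test")
      }
      tibble(
        contrast = paste(pr[1], "vs", pr[2]),
        method = res$method,
        statistic = res$statistic,
        p.value = res$p.value,
        significant = res$p.value < posthoc_alpha
      )
    })
  }

  structure(
    list(
      branch = branch, normality = normality, omnibus = omnibus,
      posthoc = posthoc, alpha = alpha, posthoc_alpha = posthoc_alpha,
      n = nrow(wide), conditions = conds, value = value_col
    ),
    class = "condition_comparison"
  )
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> %s (n = %d), %s branch\n", x$value, x$n, x$branch
  ))
  cat(sprintf(
    "  omnibus: %s, statistic = %.3g, p = %.4g%s\n",
    x$omnibus$method, x$omnibus$statistic, x$omnibus$p.value,
    if (x$omnibus$significant) " *" else ""
  ))
  if (!is.null(x$posthoc)) {
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf(
        "  %s: p = %.4g%s\n", x$posthoc$contrast[i], x$posthoc$p.value[i],
        if (x$posthoc$significant[i]) " *" else ""
      ))
    }
  } else {
    cat("  post hocs not run (omnibus non-significant)\n")
  }
  invisible(x)
}

#' Tidy pairwise results of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise contrasts (empty when post hocs were not run).
#' @export
tidy.condition_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    return(tibble(
      contrast = character(0), method = character(0),
      statistic = numeric(0), p.value = numeric(0), significant = logical(0)
    ))
  }
  x$posthoc
}

#' One-row summary of a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return One-row tibble: branch, omnibus method/statistic/p, significance.
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble(
    value = x$value, n = x$n, branch = x$branch,
    method = x$omnibus$method,
    statistic = x$omnibus$statistic,
    p.value = x$omnibus$p.value,
    significant = x$omnibus$significant,
    alpha = x$alpha, posthoc_alpha = x$posthoc_alpha
  )
}
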