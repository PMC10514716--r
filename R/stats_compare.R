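#' Paired comparison with a normality gate
#'
#' Implements the paired branch of the statistical decision tree: a
#' Lilliefors (Kolmogorov-Smirnov) normality test on the paired differences
#' decides between the Student paired t test (normal) and the Wilcoxon
#' signed-rank test (non-normal).  The signed-rank test uses the exact null
#' distribution for n <= 25 and the normal approximation with continuity
#' correction above.
#'
#' @param x,y paired measurements (equal length >= 3).
#' @param alpha significance level for the headline decision.
#' @param normality_alpha level of the Lilliefors gate (default 0.05).
#' @return an object of class `comparison_result`: list with `test_name`
#'   ("paired t test", "Wilcoxon signed-rank test" or "degenerate"),
#'   `statistic`, `p_value`, `n`, `normality_p`, `reject`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05, normality_alpha = 0.05) {
  stop_if(length(x) != length(y), "x and y must be paired (equal length)")
  stop_if(length(x) < 3, "need at least 3 pairs")
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(test_name = "degenerate", statistic = 0,
                          p_value = 1, n = length(d),
                          normality_p = NA_real_, reject = FALSE,
                          degenerate = TRUE),
                     class = "comparison_result"))
  }
  # Lilliefors needs > 4 observations and non-constant data
  norm_p <- if (length(d) > 4 && stats::sd(d) > 0)
    suppressWarnings(nortest::lillie.test(d)$p.value) else NA_real_
  use_t <- is.na(norm_p) || norm_p >= normality_alpha
  if (use_t) {
    ht <- stats::t.test(x, y, paired = TRUE)
    res <- list(test_name = "paired t test",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    exact <- length(d) <= 25
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = exact, correct = TRUE))
    res <- list(test_name = "Wilcoxon signed-rank test",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  structure(c(res, list(n = length(d), normality_p = norm_p,
                        reject = res$p_value < alpha, degenerate = FALSE)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %d%s\n",
              x$test_name, x$statistic, x$p_value, x$n,
              if (isTRUE(x$reject)) " (*)" else ""))
  if (!is.null(x$normality_p) && !is.na(x$normality_p))
    cat(sprintf("  normality (Lilliefors) p = %.3g\n", x$normality_p))
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor design (e.g. treatment x pulse position
#' measured in every cell).  Fits `y ~ treatment * position +
#' Error(subject/(treatment * position))` via [stats::aov()] and reports the
#' treatment main effect as the headline value.
#'
#' @param values 3-D numeric array `subjects x treatments x positions`, or a
#'   long data.frame with columns `subject`, `treatment`, `position`, `value`.
#' @param alpha significance level.
#' @return a `comparison_result` whose `statistic` is the treatment F; the
#'   full per-effect table is attached as `$effects` (data.frame with
#'   `effect`, `F`, `p`).
#' @export
rm_anova_two_way <- function(values, alpha = 0.05) {
  if (is.array(values) && length(dim(values)) == 3) {
    d <- dim(values)
    stop_if(d[2] < 2, "need at least 2 treatment levels")
    stop_if(d[3] < 2, "need at least 2 position levels")
    long <- expand.grid(subject = seq_len(d[1]), treatment = seq_len(d[2]),
                        position = seq_len(d[3]))
    long$value <- as.vector(values)
  } else {
    long <- as.data.frame(values)
    stop_if(!all(c("subject", "treatment", "position", "value") %in% names(long)),
            "long data needs columns subject, treatment, position, value")
    stop_if(length(unique(long$treatment)) < 2, "need at least 2 treatment levels")
    stop_if(length(unique(long$position)) < 2, "need at least 2 position levels")
  }
  stop_if(anyNA(long$value), "missing cells are not supported")
  counts <- table(long$subject, long$treatment, long$position)
  stop_if(any(counts != 1), "design must be complete and balanced")
  long$subject <- factor(long$subject)
  long$treatment <- factor(long$treatment)
  long$position <- factor(long$position)
  fit <- stats::aov(value ~ treatment * position +
                      Error(subject / (treatment * position)), data = long)
  sm <- summary(fit)
  pick <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  tr <- pick("Error: subject:treatment", "treatment")
  po <- pick("Error: subject:position", "position")
  ix <- pick("Error: subject:treatment:position", "treatment:position")
  effects <- data.frame(effect = c("treatment", "position", "interaction"),
                        F = c(tr["F"], po["F"], ix["F"]),
                        p = c(tr["p"], po["p"], ix["p"]))
  structure(list(test_name = "2-way repeated-measures ANOVA",
                 statistic = unname(tr["F"]), p_value = unname(tr["p"]),
                 n = length(unique(long$subject)), normality_p = NA_real_,
                 reject = unname(tr["p"]) < alpha, degenerate = FALSE,
                 effects = effects),
            class = "comparison_result")
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p values ascending and rejects `p_(i)` while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure; decisions
#' are mapped back to the input order.  (Computed via
#' `p.adjust(method = "holm")`, which implements exactly this rule.)
#'
#' @param p_values p values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return list with `reject` (logical, input order), `adjusted_p` and
#'   `alpha`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stop_if(any(p_values < 0 | p_values > 1), "p values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "holm")
  list(reject = adj <= alpha, adjusted_p = adj, alpha = alpha)
}
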