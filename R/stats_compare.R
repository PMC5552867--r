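.group_summary <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v)
    data.frame(mean = mean(v), sem = .sem(v), n = length(v))))
}

#' Two-group t test with degenerate-case conventions
#'
#' Wraps [stats::t.test()] for the package's group comparisons: unpaired
#' (Welch by default, pooled-variance classic form via `var_equal = TRUE`)
#' or paired, one- or two-tailed. Zero-variance degenerate inputs, which
#' the underlying test rejects, get explicit conventions: equal constant
#' groups give t = 0, p = 1; a constant non-zero (paired) difference gives
#' p = 0; both are flagged.
#'
#' @param x,y Numeric vectors (the two groups; paired designs require equal
#'   length in pairing order).
#' @param paired Paired design? Default FALSE.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative for the first group relative to the second, as in
#'   `t.test`).
#' @param var_equal Pooled-variance (classical) unpaired t instead of the
#'   Welch default.
#' @return An object of class `test_result`: `statistic`, `df`, `p_value`,
#'   `tail`, `test`, `group_summaries` (mean, SEM, n per group), `flag`.
#' @export
t_test <- function(x, y, paired = FALSE,
                   alternative = c("two.sided", "less", "greater"),
                   var_equal = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  if (paired && length(x) != length(y))
    stop("paired design needs complete pairs", call. = FALSE)
  tail <- if (alternative == "two.sided") "two" else "one"
  name <- if (paired) "paired t-test"
  else if (var_equal) "pooled-variance t-test" else "Welch t-test"
  summ <- .group_summary(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
  degenerate <- if (paired) stats::var(x - y) == 0
  else stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    delta <- if (paired) mean(x - y) else mean(x) - mean(y)
    if (delta == 0) {
      res <- list(statistic = 0, df = NA_real_, p_value = 1)
      flag <- "degenerate_equal"
    } else {
      res <- list(statistic = sign(delta) * Inf, df = NA_real_, p_value = 0)
      flag <- "degenerate_constant_difference"
    }
    return(structure(c(res, list(tail = tail, test = name,
                                 group_summaries = summ, flag = flag)),
                     class = "test_result"))
  }
  ht <- stats::t.test(x, y, paired = paired, alternative = alternative,
                      var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 tail = tail, test = name, group_summaries = summ,
                 flag = ""),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t = %.4g, df = %.3g, %s-tailed p = %.4g%s\n",
              x$test, x$statistic, x$df, x$tail, x$p_value,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Two-way fixed-effects ANOVA
#'
#' Crossed two-factor ANOVA with interaction. Balanced designs use the
#' standard sequential decomposition (for which the sums of squares are
#' orthogonal and add to the total); unbalanced designs use Type-II sums of
#' squares via [car::Anova()], the standard choice when the interaction is
#' not of primary interest.
#'
#' @param data A `data.frame`.
#' @param response Name of the numeric response column.
#' @param factor_a,factor_b Names of the two factor columns (>= 2 levels
#'   each; every crossed cell must be non-empty).
#' @return A `data.frame` of class `anova_table`: `effect`, `ss`, `df`,
#'   `statistic` (F), `p_value`, plus attributes `balanced` and `ss_type`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  stopifnot(is.data.frame(data),
            all(c(response, factor_a, factor_b) %in% names(data)))
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  y <- data[[response]]
  stopifnot(is.numeric(y), nlevels(a) >= 2, nlevels(b) >= 2)
  cells <- table(a, b)
  if (any(cells == 0))
    stop("two_way_anova: empty cell(s): ",
         paste(apply(which(cells == 0, arr.ind = TRUE), 1, function(i)
           paste(levels(a)[i[1]], levels(b)[i[2]], sep = ":")),
           collapse = ", "), call. = FALSE)
  d <- data.frame(y = y, a = a, b = b)
  balanced <- length(unique(as.vector(cells))) == 1L
  fit <- stats::lm(y ~ a * b, data = d)
  if (balanced) {
    tab <- stats::anova(fit)
    ss_type <- "sequential"
  } else {
    tab <- car::Anova(fit, type = 2)
    ss_type <- "II"
  }
  rn <- rownames(tab)
  eff <- gsub("\\ba\\b", factor_a, gsub("\\bb\\b", factor_b, rn))
  out <- data.frame(effect = eff,
                    ss = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    statistic = tab[["F value"]],
                    p_value = tab[["Pr(>F)"]])
  attr(out, "balanced") <- balanced
  attr(out, "ss_type") <- ss_type
  class(out) <- c("anova_table", "data.frame")
  out
}
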