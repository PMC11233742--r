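#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from the t transform \code{t = r sqrt(n-2) / sqrt(1-r^2)}
#' with \code{n - 2} degrees of freedom, on pairwise-complete observations.
#'
#' @param x,y numeric vectors.
#' @param alpha significance level for the convenience flag.
#' @return list(statistic = r, p_value, n, significant).
#' @export
pearson_r_p <- function(x, y, alpha = 0.05) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       significant = ct$p.value < alpha)
}

#' One-way ANOVA
#'
#' F statistic and p-value for a difference in group means.
#'
#' @param values numeric response.
#' @param groups grouping vector (>= 2 groups with >= 2 members each).
#' @param alpha significance level for the flag.
#' @return list(statistic = F, p_value, n, significant).
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  ok <- complete.cases(values, groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two members")
  fit <- anova(lm(values ~ groups))
  list(statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
       n = length(values), significant = fit$`Pr(>F)`[1] < alpha)
}

#' Format a descriptive statistic for a cohort table
#'
#' Quantitative inputs pass through a Shapiro-Wilk normality gate at
#' \code{alpha = 0.05}: normal-looking data are reported as
#' \code{"mean (SD)"}, otherwise \code{"median [q1; q3]"} (type-7 quartiles).
#' Categorical counts are given as \code{"k (p\%)"} with one decimal,
#' \code{p = 100 k / n}.
#'
#' @param values numeric vector (quantitative mode), or NULL.
#' @param count,n category count and total (categorical mode).
#' @param digits decimals for the quantitative mode.
#' @param gate \code{"auto"} (Shapiro-Wilk decides), or force
#'   \code{"mean"} / \code{"median"} presentation.
#' @return a formatted string.
#' @export
describe <- function(values = NULL, count = NULL, n = NULL, digits = 1,
                     gate = c("auto", "mean", "median")) {
  gate <- match.arg(gate)
  if (!is.null(count)) {
    stopifnot(!is.null(n), n > 0)
    return(sprintf("%d (%.1f%%)", count, 100 * count / n))
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  normal <- switch(gate,
    mean = TRUE,
    median = FALSE,
    auto = length(values) >= 3 && length(unique(values)) > 1 &&
      shapiro.test(values)$p.value >= 0.05)
  if (normal)
    sprintf("%.*f (%.*f)", digits, mean(values), digits, sd(values))
  else {
    q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    sprintf("%.*f [%.*f; %.*f]", digits, q[2], digits, q[1], digits, q[3])
  }
}

#' Correlation/ANOVA report for a feature table
#'
#' One row per feature: Pearson r and p for quantitative features, ANOVA F
#' and p for categorical ones (factors or character columns), with a
#' Benjamini-Hochberg adjusted column added as supplementary output.
#'
#' @param table data.frame of features.
#' @param target numeric target.
#' @return data.frame(variable, type, statistic, p_value, p_adj_BH, significant).
#' @export
association_report <- function(table, target) {
  rows <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    res <- tryCatch({
      if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2)
        c(type = "pearson", unlist(pearson_r_p(x, target)[c("statistic",
                                                            "p_value")]))
      else
        c(type = "anova", unlist(anova_oneway(target, x)[c("statistic",
                                                           "p_value")]))
    }, error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variable = nm, type = res[["type"]],
               statistic = as.numeric(res[["statistic"]]),
               p_value = as.numeric(res[["p_value"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(data.frame())
  out$p_adj_BH <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < 0.05
  out
}

#' Cohort descriptives table
#'
#' Formats every column of a clinical table with \code{\link{describe}}:
#' logical/binary columns as counts with percentages, numeric columns through
#' the normality gate.
#'
#' @param table data.frame.
#' @return data.frame(variable, value).
#' @export
descriptives_table <- function(table) {
  rows <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    val <- if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1, NA))))
      describe(count = sum(x == 1, na.rm = TRUE), n = sum(!is.na(x)))
    else if (is.numeric(x)) describe(values = x)
    else describe(count = sum(!is.na(x)), n = length(x))
    data.frame(variable = nm, value = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
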