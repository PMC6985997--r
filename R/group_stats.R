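# Period-wise statistical comparison scheme: Shapiro-Wilk normality gate,
# one-way repeated-measures ANOVA (Greenhouse-Geisser corrected when epsilon
# is low) or Friedman test within animals, two-way ANOVA between groups, Sidak
# multiple-comparison adjustment, and paired/unpaired t-tests.

#' Sidak multiple-comparison adjustment
#'
#' \code{p_adj = 1 - (1 - p)^m} for m comparisons.
#'
#' @param p raw p values.
#' @param m number of comparisons (default \code{length(p)}).
#' @return adjusted p values (never below the raw ones).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

# Greenhouse-Geisser epsilon from the within-subject sample covariance matrix
.gg_epsilon <- function(mat) {
  k <- ncol(mat)
  S <- stats::cov(mat)
  mg <- mean(S)
  row_m <- rowMeans(S)
  num <- (k * (mean(diag(S)) - mg))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_m^2) + k^2 * mg^2)
  if (den <= 0) return(1)
  min(1, num / den)
}

#' Compare baseline / response / recovery within animals
#'
#' Shapiro-Wilk is run on each period's values; if every period passes at
#' \code{shapiro_alpha} a one-way repeated-measures ANOVA is used (with
#' Greenhouse-Geisser correction when the sphericity epsilon falls below
#' \code{gg_eps_threshold}), otherwise a Friedman test. A significant omnibus
#' (p < \code{alpha}) is followed by Sidak-adjusted pairwise comparisons
#' (paired t-tests on the parametric branch, Wilcoxon signed-rank otherwise).
#'
#' @param values data.frame or matrix with one row per animal and columns
#'   \code{baseline}, \code{response}, \code{recovery}; incomplete rows are
#'   dropped listwise with a warning.
#' @param alpha omnibus significance level.
#' @param shapiro_alpha normality-gate level.
#' @param gg_eps_threshold apply the Greenhouse-Geisser correction when
#'   epsilon < this value.
#' @return a \code{test_report}: list with \code{test}, \code{statistic},
#'   \code{p}, \code{normality} (per-period Shapiro p), \code{gate_parametric},
#'   \code{posthoc} (data.frame or NULL), and \code{n}.
#' @export
compare_periods <- function(values, alpha = 0.05, shapiro_alpha = 0.05,
                            gg_eps_threshold = 0.75) {
  mat <- as.matrix(as.data.frame(values)[, period_names])
  cc <- complete.cases(mat)
  if (any(!cc)) {
    warning(sum(!cc), " animal(s) with incomplete period triples excluded")
    mat <- mat[cc, , drop = FALSE]
  }
  n <- nrow(mat)
  if (n < 3L) stop("need at least 3 animals with complete triples")
  sw <- vapply(period_names, function(p) {
    x <- mat[, p]
    if (sd(x) == 0) 0 else shapiro.test(x)$p.value  # constant: clearly non-normal
  }, numeric(1))
  parametric <- all(sw > shapiro_alpha)
  if (parametric) {
    df <- data.frame(y = as.vector(mat),
                     period = factor(rep(period_names, each = n),
                                     levels = period_names),
                     animal = factor(rep(seq_len(n), times = 3)))
    fit <- aov(y ~ period + Error(animal/period), data = df)
    tab <- summary(fit)[["Error: animal:period"]][[1]]
    Fv <- tab["period", "F value"]
    df1 <- tab["period", "Df"]; df2 <- tab["Residuals", "Df"]
    eps <- .gg_epsilon(mat)
    corrected <- eps < gg_eps_threshold
    p <- if (corrected) pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
         else pf(Fv, df1, df2, lower.tail = FALSE)
    test <- if (corrected) "RM-ANOVA (Greenhouse-Geisser)" else "RM-ANOVA"
    stat <- Fv
  } else {
    fr <- friedman.test(mat)
    test <- "Friedman"; stat <- unname(fr$statistic); p <- fr$p.value
    if (is.nan(stat)) { stat <- 0; p <- 1 }   # all ranks tied
    eps <- NA_real_
  }
  posthoc <- NULL
  if (!is.na(p) && p < alpha) {
    prs <- utils::combn(period_names, 2, simplify = FALSE)
    raw <- vapply(prs, function(pp) {
      a <- mat[, pp[1]]; b <- mat[, pp[2]]
      tryCatch(
        if (parametric) t.test(a, b, paired = TRUE)$p.value
        else wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value,
        error = function(e) NA_real_)
    }, numeric(1))
    posthoc <- data.frame(
      comparison = vapply(prs, paste, "", collapse = " vs "),
      p_raw = raw, p_sidak = sidak_adjust(raw, length(raw)))
  }
  structure(list(test = test, statistic = stat, p = p,
                 normality = sw, gate_parametric = parametric,
                 gg_epsilon = if (parametric) eps else NA_real_,
                 posthoc = posthoc, n = n),
            class = "test_report")
}

#' Two-way ANOVA across groups and periods with Sidak post hoc
#'
#' Parametric two-way ANOVA with factors group, period, and their interaction;
#' per-cell Shapiro-Wilk p values are reported for inspection but do not
#' switch the test. Pairwise group comparisons within each period follow the
#' omnibus (unpaired t-tests), Sidak-adjusted over all comparisons performed.
#'
#' @param data data.frame with columns \code{value}, \code{group},
#'   \code{period}.
#' @param alpha significance level gating the post hoc battery.
#' @return a \code{test_report} with the three effect rows in
#'   \code{anova_table}, \code{posthoc}, and per-cell \code{normality}.
#' @export
compare_groups <- function(data, alpha = 0.05) {
  stopifnot(all(c("value", "group", "period") %in% names(data)))
  data$group <- factor(data$group)
  data$period <- factor(data$period,
                        levels = intersect(c(period_names,
                                             levels(factor(data$period))),
                                           unique(as.character(data$period))))
  if (nlevels(data$group) < 2L || nlevels(data$period) < 2L)
    stop("need >= 2 groups and >= 2 periods")
  cells <- table(data$group, data$period)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)
    stop("cell with < 2 values: group ", rownames(cells)[bad[1, 1]],
         ", period ", colnames(cells)[bad[1, 2]])
  }
  sw <- tapply(data$value, list(data$group, data$period), function(x)
    if (length(x) < 3L || sd(x) == 0) NA_real_ else shapiro.test(x)$p.value)
  fit <- aov(value ~ group * period, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  anova_table <- data.frame(effect = rn[rn != "Residuals"],
                            F = tab[rn != "Residuals", "F value"],
                            p = tab[rn != "Residuals", "Pr(>F)"])
  p_group <- anova_table$p[anova_table$effect == "group"]
  posthoc <- NULL
  if (any(anova_table$p < alpha)) {
    gl <- levels(data$group)
    prs <- utils::combn(gl, 2, simplify = FALSE)
    rows <- list()
    for (per in levels(data$period))
      for (pp in prs) {
        a <- data$value[data$group == pp[1] & data$period == per]
        b <- data$value[data$group == pp[2] & data$period == per]
        rows[[length(rows) + 1L]] <- data.frame(
          period = per, comparison = paste(pp, collapse = " vs "),
          p_raw = tryCatch(t.test(a, b)$p.value,
                           error = function(e) NA_real_))
      }
    posthoc <- do.call(rbind, rows)
    posthoc$p_sidak <- sidak_adjust(posthoc$p_raw, nrow(posthoc))
  }
  structure(list(test = "two-way ANOVA", anova_table = anova_table,
                 statistic = anova_table$F[anova_table$effect == "group"],
                 p = p_group, normality = sw, gate_parametric = TRUE,
                 posthoc = posthoc, n = nrow(data)),
            class = "test_report")
}

#' Two-group t-test
#'
#' Paired (within-animal) or unpaired (between-group) two-sided t-test.
#'
#' @param a,b numeric samples; equal length required when paired.
#' @param paired logical.
#' @return a \code{test_report} with \code{statistic} (t) and \code{p}.
#' @export
two_group <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired test requires equal lengths")
    if (sd(a - b) == 0) stop("zero variance of paired differences")
  } else if (sd(a) == 0 && sd(b) == 0) {
    if (a[1] == b[1]) stop("both samples constant and equal: t undefined")
  }
  tt <- t.test(a, b, paired = paired)
  structure(list(test = if (paired) "paired t" else "unpaired t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 normality = NULL, gate_parametric = TRUE, posthoc = NULL,
                 n = c(length(a), length(b))),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic = %s, p = %s\n", x$test,
              format(x$statistic, digits = 4), format(x$p, digits = 4)))
  if (!is.null(x$normality))
    cat("  normality gate (Shapiro-Wilk p):",
        paste(format(x$normality, digits = 3), collapse = ", "), "\n")
  if (!is.null(x$posthoc)) {
    cat("  Sidak post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
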