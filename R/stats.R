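#' Pearson correlation with two-sided p-value
#'
#' Sample correlation with the usual t-based two-sided p on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3, non-zero variance).
#' @return A list with \code{r}, \code{p}, \code{n}.
#' @export
pearsonTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Welch's two-sample t-test
#'
#' Two-sided independent t-test with unequal population variances and
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return A list with \code{t}, \code{df}, \code{p}, \code{nA}, \code{nB}.
#' @export
welchT <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       nA = length(a), nB = length(b))
}

#' One-way ANOVA
#'
#' Classic fixed-effects between/within decomposition (equal-variance F).
#'
#' @param values numeric response vector.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @return A list with \code{F}, \code{dfBetween}, \code{dfWithin}, \code{p}.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 observations")
  ot <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ot$statistic), dfBetween = unname(ot$parameter[1L]),
       dfWithin = unname(ot$parameter[2L]), p = ot$p.value)
}

#' Per-mode associations between shape scores and covariates
#'
#' For each requested mode: Pearson correlation and OLS regression of the
#' SD-unit scores against age, BMI and lung volume, for the whole cohort and
#' separately by sex, plus Welch's t-test of the scores between sexes.
#' Covariates use the conventional alpha = 0.05 per-test flag with no
#' multiple-testing correction; an optional Benjamini-Hochberg adjusted
#' p-value column can be added.
#'
#' @param scores N x L matrix of SD-unit mode scores with subject ids as row
#'   names.
#' @param covariates data.frame with columns \code{subject_id, age, sex, bmi}
#'   and \code{volume_L} (or \code{volume}); \code{sex} coded F/M.
#' @param modes mode indices to test (default all columns of \code{scores}).
#' @param adjust add a BH-adjusted p column (default \code{FALSE}).
#' @param alpha significance level for the \code{significant} flag.
#' @return A data.frame with one row per (mode, covariate, stratum):
#'   \code{mode, covariate, stratum, statistic, estimate, p, n, slope,
#'   intercept, significant}. For Pearson rows \code{estimate} is the signed
#'   r (matching the signed R of a simple OLS regression); for the sex rows it
#'   is Welch's t.
#' @export
associationTable <- function(scores, covariates, modes = NULL,
                             adjust = FALSE, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (anyDuplicated(covariates$subject_id))
    stop("duplicate subject ids in covariate table")
  if (anyDuplicated(rownames(scores)))
    stop("duplicate subject ids in score table")
  if (is.null(rownames(scores)))
    stop("scores must carry subject ids as row names")
  if (!"volume_L" %in% names(covariates) && "volume" %in% names(covariates))
    covariates$volume_L <- covariates$volume
  need <- c("subject_id", "age", "sex", "bmi", "volume_L")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  ids <- intersect(rownames(scores), covariates$subject_id)
  dropped <- setdiff(rownames(scores), ids)
  cov <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  complete <- stats::complete.cases(cov[, need])
  if (any(!complete) || length(dropped))
    message(sum(!complete) + length(dropped),
            " subject(s) dropped for missing covariates")
  cov <- cov[complete, , drop = FALSE]
  sc <- scores[match(cov$subject_id, rownames(scores)), , drop = FALSE]
  if (is.null(modes)) modes <- seq_len(ncol(sc))
  sex <- toupper(substr(as.character(cov$sex), 1L, 1L))
  rows <- list()
  addRow <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (m in modes) {
    y <- sc[, m]
    for (covName in c("age", "bmi", "volume_L")) {
      xAll <- cov[[covName]]
      for (stratum in c("all", "F", "M")) {
        keep <- if (stratum == "all") rep(TRUE, length(y)) else sex == stratum
        if (sum(keep) < 3L || stats::sd(xAll[keep]) == 0 ||
            stats::sd(y[keep]) == 0) next
        pt <- pearsonTest(xAll[keep], y[keep])
        fit <- stats::lm(y[keep] ~ xAll[keep])
        co <- stats::coef(fit)
        addRow(mode = m, covariate = covName, stratum = stratum,
               statistic = "pearson_r", estimate = pt$r, p = pt$p, n = pt$n,
               slope = unname(co[2L]), intercept = unname(co[1L]))
      }
    }
    if (sum(sex == "F") >= 2L && sum(sex == "M") >= 2L) {
      wt <- welchT(y[sex == "F"], y[sex == "M"])
      addRow(mode = m, covariate = "sex", stratum = "all",
             statistic = "welch_t", estimate = wt$t, p = wt$p,
             n = wt$nA + wt$nB, slope = NA_real_, intercept = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  if (adjust) out$pAdjustBH <- stats::p.adjust(out$p, method = "BH")
  out
}

#' One-way ANOVA of scores over a user-supplied grouping
#'
#' Convenience wrapper comparing mode-score means across the levels of a
#' grouping column of the covariate table (e.g. recruitment centre or age
#' band).
#'
#' @inheritParams associationTable
#' @param groupColumn name of the grouping column in \code{covariates}.
#' @return A data.frame with one row per mode: \code{mode, F, dfBetween,
#'   dfWithin, p}.
#' @export
groupAnova <- function(scores, covariates, groupColumn, modes = NULL) {
  scores <- as.matrix(scores)
  if (!groupColumn %in% names(covariates))
    stop("no such covariate column: ", groupColumn)
  cov <- covariates[match(rownames(scores), covariates$subject_id), ,
                    drop = FALSE]
  if (is.null(modes)) modes <- seq_len(ncol(scores))
  do.call(rbind, lapply(modes, function(m) {
    a <- anovaOneway(scores[, m], cov[[groupColumn]])
    data.frame(mode = m, F = a$F, dfBetween = a$dfBetween,
               dfWithin = a$dfWithin, p = a$p)
  }))
}
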