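#' Pearson correlation with t-based significance
#'
#' Product-moment correlation between two covariates, with the usual
#' two-sided p-value from t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list of class `correlation_result` with elements `r`, `p_value`,
#'   `n`.
#' @export
pearson_cor <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    .stop_field("x and y must be numeric with no missing values")
  }
  if (length(x) != length(y)) .stop_field("x and y differ in length")
  if (length(x) < 3) .stop_field("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) .stop_field("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, p = %.4g, n = %d\n", x$r, x$p_value, x$n))
  invisible(x)
}

# shared summary extractor: lm fit -> coefficient table + fit statistics
.lm_to_fit <- function(model) {
  # summary.lm warns on exact (zero-residual) fits; the coefficient table is
  # still what we want (se 0, p NaN), so keep that advisory quiet
  s <- withCallingHandlers(summary(model), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  ct <- coef(s)
  out <- list(
    coefficients = data.frame(
      term = rownames(ct),
      estimate = ct[, "Estimate"],
      se = ct[, "Std. Error"],
      t = ct[, "t value"],
      p_value = ct[, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    n = length(model$residuals),
    df_residual = model$df.residual,
    model = model
  )
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.4f (adj. %.4f)\n", x$n, x$r_squared, x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Ordinary least squares regression
#'
#' Least-squares fit of a response on one or more predictor columns with
#' classical (homoskedastic) standard errors and two-sided t p-values.
#'
#' @param y numeric response vector.
#' @param X predictor columns: numeric vector, matrix or data frame. Column
#'   names are used as coefficient names.
#' @param add_intercept include an intercept term (default `TRUE`).
#' @return object of class `regression_fit`: coefficient table (`term`,
#'   `estimate`, `se`, `t`, `p_value`), `r_squared`, `adj_r_squared`, `n`,
#'   `df_residual` and the underlying [stats::lm] fit in `model`.
#' @export
ols_fit <- function(y, X, add_intercept = TRUE) {
  if (!is.numeric(y) || anyNA(y)) .stop_field("y must be numeric with no missing values")
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) .stop_field("y and X differ in number of rows")
  if (is.null(names(X)) || any(names(X) == "")) names(X) <- sprintf("x%d", seq_along(X))
  p <- ncol(X) + as.integer(add_intercept)
  if (length(y) <= p) .stop_field("need more observations (%d) than coefficients (%d)", length(y), p)
  dat <- if (ncol(X) == 0) data.frame(.y = y) else cbind(.y = y, X)
  rhs <- c(if (!add_intercept) "0", names(X))
  if (length(rhs) == 0) rhs <- "1"
  fm <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  model <- lm(fm, data = dat)
  if (anyNA(coef(model))) {
    .stop_field("singular design: collinear column(s) %s",
                paste(names(coef(model))[is.na(coef(model))], collapse = ", "))
  }
  .lm_to_fit(model)
}

#' Quadratic regression with hump/U-shape detection
#'
#' Fits y = a + b x + c x^2 and labels the response surface `HUMP` when the
#' curvature is negative, significant at `alpha`, and the vertex -b/(2c)
#' lies inside the observed x range (the symmetric rule with positive
#' curvature gives `U`); anything else is `NONE`. Requiring significance
#' avoids labelling noise, and requiring an interior vertex avoids calling a
#' monotone segment of a parabola a hump. Curvature whose total contribution
#' over the observed x range is numerically negligible relative to the
#' spread of y is treated as zero (an exactly linear response fitted in
#' floating point yields c ~ 1e-16 with a meaningless t statistic).
#'
#' @param y,x numeric vectors, n >= 4, x non-constant.
#' @param alpha significance level for the curvature term (default 0.05).
#' @return list of class `quadratic_fit`: `fit` (a `regression_fit` of the
#'   full quadratic), `a`, `b`, `c`, `vertex_x`, `shape`.
#' @export
quadratic_fit <- function(y, x, alpha = 0.05) {
  if (length(x) != length(y)) .stop_field("x and y differ in length")
  if (length(x) < 4) .stop_field("need at least 4 observations for a quadratic fit")
  if (sd(x) == 0) .stop_field("x is constant")
  fit <- ols_fit(y, data.frame(x = x, x_sq = x^2))
  cf <- fit$coefficients
  a <- cf$estimate[cf$term == "(Intercept)"]
  b <- cf$estimate[cf$term == "x"]
  cc <- cf$estimate[cf$term == "x_sq"]
  p_c <- cf$p_value[cf$term == "x_sq"]
  curv_span <- abs(cc) * (max(x) - min(x))^2 / 4
  negligible <- curv_span <= 1e-8 * max(diff(range(y)), .Machine$double.eps)
  vertex <- if (negligible) NA_real_ else -b / (2 * cc)
  shape <- "NONE"
  if (!negligible && !is.na(p_c) && p_c < alpha &&
      vertex >= min(x) && vertex <= max(x)) {
    shape <- if (cc < 0) "HUMP" else "U"
  }
  structure(list(fit = fit, a = a, b = b, c = if (negligible) 0 else cc,
                 vertex_x = vertex, shape = shape),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Quadratic fit: y = %.4g + %.4g x + %.4g x^2; vertex at x = %.4g; shape %s\n",
              x$a, x$b, x$c, x$vertex_x, x$shape))
  invisible(x)
}

#' Stepwise predictor selection
#'
#' Bidirectional stepwise screening of candidate predictors starting from
#' the intercept-only model. The default criterion is AIC via
#' [stats::step()]: at each step the single addition or removal with the
#' largest AIC decrease is taken, and the search stops when no move
#' improves. Candidates are considered in alphabetical name order, which
#' makes tie-breaking deterministic. A classical p-value entry/removal mode
#' (`criterion = "p"`) is available: forward-add the most significant
#' candidate with p < `alpha_enter`, then backward-remove terms with
#' p > `alpha_remove`, until stable.
#'
#' @param y numeric response vector.
#' @param candidates data frame of named candidate predictor columns.
#' @param criterion `"AIC"` (default) or `"p"`.
#' @param alpha_enter,alpha_remove entry/removal thresholds for
#'   `criterion = "p"`.
#' @return list of class `stepwise_result`: `selected` (character vector of
#'   chosen predictor names), `fit` (`regression_fit` of the final model)
#'   and `trace` (data frame of steps with the criterion value).
#' @export
stepwise_select <- function(y, candidates, criterion = c("AIC", "p"),
                            alpha_enter = 0.05, alpha_remove = 0.10) {
  criterion <- match.arg(criterion)
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0) {
    fit <- ols_fit(y, data.frame(row.names = seq_along(y)), add_intercept = TRUE)
    return(structure(list(selected = character(0), fit = fit,
                          trace = data.frame(step = 0L, action = "<start>",
                                             criterion = NA_real_)),
                     class = "stepwise_result"))
  }
  if (anyNA(candidates)) .stop_field("candidate predictors contain missing values")
  if (any(vapply(candidates, sd, numeric(1)) == 0)) {
    .stop_field("constant candidate column(s): %s",
                paste(names(candidates)[vapply(candidates, sd, numeric(1)) == 0],
                      collapse = ", "))
  }
  candidates <- candidates[, order(names(candidates)), drop = FALSE]
  dat <- cbind(.y = y, candidates)

  if (criterion == "AIC") {
    null_model <- lm(.y ~ 1, data = dat)
    upper <- as.formula(paste("~", paste(names(candidates), collapse = " + ")))
    final <- withCallingHandlers(
      step(null_model, scope = list(lower = ~1, upper = upper),
           direction = "both", trace = 0),
      # advisory from step() when a candidate fits (nearly) perfectly; the
      # search itself remains well-defined and deterministic
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    an <- final$anova
    trace <- data.frame(step = seq_len(nrow(an)) - 1L,
                        action = trimws(as.character(an$Step)),
                        criterion = an$AIC, stringsAsFactors = FALSE)
    trace$action[trace$action == ""] <- "<start>"
    selected <- attr(terms(final), "term.labels")
  } else {
    in_model <- character(0)
    trace <- data.frame(step = 0L, action = "<start>", criterion = NA_real_,
                        stringsAsFactors = FALSE)
    repeat {
      moved <- FALSE
      out_model <- setdiff(names(candidates), in_model)
      if (length(out_model) > 0) {
        pvals <- vapply(out_model, function(v) {
          f <- ols_fit(y, candidates[, c(in_model, v), drop = FALSE])
          f$coefficients$p_value[f$coefficients$term == v]
        }, numeric(1))
        best <- names(pvals)[order(pvals, names(pvals))][1]
        if (pvals[best] < alpha_enter) {
          in_model <- c(in_model, best)
          trace <- rbind(trace, data.frame(step = nrow(trace), action = paste("+", best),
                                           criterion = pvals[best]))
          moved <- TRUE
        }
      }
      if (length(in_model) > 0) {
        f <- ols_fit(y, candidates[, in_model, drop = FALSE])
        ps <- f$coefficients[f$coefficients$term != "(Intercept)", ]
        worst <- ps[order(-ps$p_value, ps$term), ][1, ]
        if (worst$p_value > alpha_remove) {
          in_model <- setdiff(in_model, worst$term)
          trace <- rbind(trace, data.frame(step = nrow(trace),
                                           action = paste("-", worst$term),
                                           criterion = worst$p_value))
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    selected <- in_model
    final <- if (length(in_model) > 0) {
      ols_fit(y, candidates[, sort(in_model), drop = FALSE])$model
    } else lm(.y ~ 1, data = dat)
  }
  structure(list(selected = selected, fit = .lm_to_fit(final), trace = trace),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("Stepwise selection: %s\n",
              if (length(x$selected) == 0) "(intercept only)" else paste(x$selected, collapse = ", ")))
  print(x$fit)
  invisible(x)
}
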