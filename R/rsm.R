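# Box-Behnken design construction, coded-unit quadratic fitting, ANOVA with
# lack-of-fit partitioning, and multi-response desirability optimization.

#' Factor specification for a three-factor Box-Behnken design
#'
#' Each factor is described by its name and its low / center / high actual
#' levels; coded units map low, center, high to -1, 0, +1. The center is
#' expected to be the midpoint of low and high (a warning is issued
#' otherwise, since the linear coding then distorts the star structure).
#'
#' @param name Character vector of 3 factor names.
#' @param low,high Numeric vectors of 3 actual low/high levels.
#' @param center Numeric vector of 3 actual center levels; defaults to the
#'   midpoints.
#' @return A data.frame of class `bbd_factors` with columns
#'   `name, low, center, high`.
#' @examples
#' bbd_factors(c("enzyme_dosage", "time", "solid_liquid_ratio"),
#'             low = c(1, 1.5, 20), high = c(1.5, 3, 35))
#' @export
bbd_factors <- function(name, low, high, center = (low + high) / 2) {
  if (length(name) != 3 || length(low) != 3 || length(high) != 3 ||
      length(center) != 3) {
    stop("exactly 3 factors are supported", call. = FALSE)
  }
  if (any(!(low < center & center < high))) {
    stop("each factor needs low < center < high", call. = FALSE)
  }
  mid <- (low + high) / 2
  if (any(abs(center - mid) > 1e-8 * pmax(abs(high - low), 1))) {
    warning("factor center is not the midpoint of low and high; ",
            "coded units will be asymmetric")
  }
  structure(data.frame(name = as.character(name), low = low,
                       center = center, high = high,
                       stringsAsFactors = FALSE),
            class = c("bbd_factors", "data.frame"))
}

#' Convert between actual and coded factor levels
#'
#' Standard linear coding \eqn{x = (actual - center) / ((high - low)/2)}:
#' the center maps to (0, 0, 0) and low/high to -1/+1. `uncode_point()`
#' inverts the transform exactly.
#'
#' @param factors A [bbd_factors()] specification.
#' @param actual,coded Numeric vector of length 3, or a matrix / data.frame
#'   with 3 columns (one row per point).
#' @return Numeric vector or matrix of the transformed point(s).
#' @export
code_point <- function(factors, actual) {
  stopifnot(inherits(factors, "bbd_factors"))
  half <- (factors$high - factors$low) / 2
  if (is.null(dim(actual))) {
    (as.numeric(actual) - factors$center) / half
  } else {
    sweep(sweep(as.matrix(actual), 2, factors$center), 2, half, "/")
  }
}

#' @rdname code_point
#' @export
uncode_point <- function(factors, coded) {
  stopifnot(inherits(factors, "bbd_factors"))
  half <- (factors$high - factors$low) / 2
  if (is.null(dim(coded))) {
    factors$center + as.numeric(coded) * half
  } else {
    sweep(sweep(as.matrix(coded), 2, half, "*"), 2, factors$center, "+")
  }
}

# canonical coded rows of the 3-factor Box-Behnken design: 12 edge midpoints
# (one factor at 0, the other two at +/-1) followed by the center
bbd3_coded <- function(n_center) {
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
  edges <- rbind(cbind(pm[, 1], pm[, 2], 0),
                 cbind(pm[, 1], 0, pm[, 2]),
                 cbind(0, pm[, 1], pm[, 2]))
  rbind(edges, matrix(0, nrow = n_center, ncol = 3))
}

#' Generate a three-factor Box-Behnken design
#'
#' Builds the standard 3-factor Box-Behnken design: 12 edge-midpoint runs
#' (each with exactly one factor at its center and the other two at their
#' low/high levels) plus `n_center` replicated center runs.
#'
#' @param factors A [bbd_factors()] specification.
#' @param n_center Number of center replicates (>= 1); 5 by default, the
#'   usual choice that gives 17 runs and 4 pure-error degrees of freedom.
#' @return A data.frame of class `bbd_design` with one actual-unit column
#'   per factor; the factor specification is attached as attribute
#'   `"factors"`.
#' @export
bbd_design <- function(factors, n_center = 5) {
  stopifnot(inherits(factors, "bbd_factors"))
  if (n_center < 1) stop("'n_center' must be >= 1", call. = FALSE)
  coded <- bbd3_coded(n_center)
  actual <- uncode_point(factors, coded)
  colnames(actual) <- factors$name
  out <- as.data.frame(actual)
  attr(out, "factors") <- factors
  class(out) <- c("bbd_design", "data.frame")
  out
}

#' Check the Box-Behnken structure of a design table
#'
#' Verifies, as an unordered multiset, that the coded image of the design's
#' factor columns equals the canonical 12-edge + n-center 3-factor
#' Box-Behnken layout. Run order is irrelevant.
#'
#' @param data Data.frame holding the factor columns in actual units.
#' @param factors A [bbd_factors()] specification naming those columns.
#' @param tol Tolerance on coded levels.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_bbd <- function(data, factors, tol = 1e-6) {
  stopifnot(inherits(factors, "bbd_factors"))
  miss <- setdiff(factors$name, names(data))
  if (length(miss)) {
    stop("design table lacks factor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  coded <- code_point(factors, data[, factors$name])
  lev <- round(coded)
  if (any(abs(coded - lev) > tol) || any(abs(lev) > 1)) {
    stop("factor levels do not code to {-1, 0, +1}", call. = FALSE)
  }
  n_zero <- rowSums(lev == 0)
  n_center <- sum(n_zero == 3)
  if (n_center < 1 || sum(n_zero == 1) != 12 || nrow(lev) != 12 + n_center) {
    stop("design is not a 3-factor Box-Behnken layout ",
         "(12 edge runs with one factor at center, plus center replicates)",
         call. = FALSE)
  }
  canon <- bbd3_coded(n_center)
  key <- function(m) sort(apply(m, 1, paste, collapse = "/"))
  if (!identical(key(lev), key(canon))) {
    stop("coded runs do not match the canonical Box-Behnken multiset",
         call. = FALSE)
  }
  invisible(TRUE)
}

# 10-column second-order model matrix from a coded n x 3 matrix
quad_model_matrix <- function(coded, names3 = c("A", "B", "C")) {
  x <- as.matrix(coded)
  m <- cbind(1, x,
             x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
             x[, 1]^2, x[, 2]^2, x[, 3]^2)
  colnames(m) <- c("(Intercept)", names3,
                   paste(names3[c(1, 1, 2)], names3[c(2, 3, 3)], sep = ":"),
                   paste0(names3, "^2"))
  m
}

#' Fit the full second-order model in coded units
#'
#' Ordinary least squares of one response on the 10-term quadratic model
#' (intercept, 3 linear, 3 two-way interaction and 3 pure quadratic terms)
#' with factors in coded -1/0/+1 units. On a 3-factor Box-Behnken design
#' the linear columns are mutually orthogonal, so each linear coefficient
#' equals (sum of the response at +1 minus at -1) / 8.
#'
#' @param data Design table (e.g. from [bbd_design()] or
#'   [read_design_table()]) holding the factor columns in actual units plus
#'   the response column.
#' @param response Name of the response column.
#' @param factors A [bbd_factors()] specification; taken from the design's
#'   `"factors"` attribute when omitted.
#' @return An object of class `rsm_fit`: coefficients (coded units),
#'   fitted values, residual/total sums of squares, grand mean and
#'   bookkeeping needed by [anova.rsm_fit()] and [predict.rsm_fit()].
#' @export
fit_quadratic <- function(data, response, factors = attr(data, "factors")) {
  if (is.null(factors)) stop("'factors' must be supplied", call. = FALSE)
  stopifnot(inherits(factors, "bbd_factors"))
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop("response '", response, "' must be finite numeric", call. = FALSE)
  }
  if (nrow(data) < 10) stop("need at least 10 runs to fit 10 terms", call. = FALSE)
  coded <- code_point(factors, data[, factors$name])
  X <- quad_model_matrix(coded, factors$name)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix", call. = FALSE)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(response = response,
                 factors = factors,
                 coefficients = fit$coefficients,
                 fitted = fit$fitted.values,
                 residuals = fit$residuals,
                 y = y,
                 coded = coded,
                 residual_ss = rss,
                 total_ss = tss,
                 grand_mean = mean(y),
                 df_residual = nrow(X) - ncol(X),
                 n = nrow(X)),
            class = "rsm_fit")
}

#' @export
print.rsm_fit <- function(x, digits = 2, ...) {
  cf <- round(x$coefficients, digits)
  terms <- names(cf)[-1]
  eqn <- paste0(format(cf[1], nsmall = digits),
                paste0(ifelse(cf[-1] >= 0, " + ", " - "),
                       format(abs(cf[-1]), nsmall = digits), " ", terms,
                       collapse = ""))
  cat("Second-order model (coded units) for", x$response, "\n ", eqn, "\n")
  cat(sprintf("  R2 = %.4f on %d runs\n", 1 - x$residual_ss / x$total_ss, x$n))
  invisible(x)
}

#' Predict from a fitted second-order model
#'
#' Evaluates the fitted coded-unit polynomial. Points may be given in coded
#' units (`coded`) or actual units (`actual`, converted via the fit's factor
#' specification). At the coded origin the prediction equals the intercept.
#'
#' @param object An `rsm_fit`.
#' @param coded,actual A length-3 point or an n x 3 matrix/data.frame;
#'   supply exactly one of the two.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.rsm_fit <- function(object, coded = NULL, actual = NULL, ...) {
  if (is.null(coded) == is.null(actual)) {
    stop("supply exactly one of 'coded' or 'actual'", call. = FALSE)
  }
  if (is.null(coded)) coded <- code_point(object$factors, actual)
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = 3, byrow = FALSE)
  drop(quad_model_matrix(coded, object$factors$name) %*% object$coefficients)
}

#' ANOVA with lack-of-fit partitioning for a second-order fit
#'
#' Decomposes the corrected total sum of squares of an [fit_quadratic()]
#' model into model and residual parts, splits the residual into lack of
#' fit and pure error (from replicated center runs), and reports per-term
#' partial (drop-one-term, Type-III-like) sums of squares. For each term,
#' F = term MS / residual MS; lack-of-fit F = LOF MS / pure-error MS;
#' p-values from the F distribution. Fit statistics: R-squared, adjusted
#' R-squared and the coefficient of variation
#' CV% = 100 sqrt(residual MS) / grand mean.
#'
#' Partial SS of individual quadratic terms are not additive (the squared
#' columns are correlated on a Box-Behnken design), so per-term SS need not
#' sum to the model SS; the model row is computed as total minus residual.
#'
#' @param object An `rsm_fit`.
#' @param ... Unused.
#' @return An object of class `rsm_anova`: a data.frame with columns
#'   `source, ss, df, ms, f, p` and attributes `r2`, `r2_adj`, `cv_percent`.
#'   If the design has fewer than 2 center replicates the lack-of-fit split
#'   is omitted with a warning.
#' @export
anova.rsm_fit <- function(object, ...) {
  X <- quad_model_matrix(object$coded, object$factors$name)
  y <- object$y
  rss <- object$residual_ss
  tss <- object$total_ss
  mss <- tss - rss
  df_res <- object$df_residual
  ms_res <- rss / df_res

  term_names <- colnames(X)[-1]
  term_ss <- vapply(seq_along(term_names), function(i) {
    red <- stats::lm.fit(X[, -(i + 1), drop = FALSE], y)
    sum(red$residuals^2) - rss
  }, numeric(1))

  rows <- data.frame(source = c("Model", term_names, "Residual"),
                     ss = c(mss, term_ss, rss),
                     df = c(9, rep(1, 9), df_res),
                     stringsAsFactors = FALSE)

  is_center <- rowSums(object$coded == 0) == 3
  n_center <- sum(is_center)
  if (n_center >= 2) {
    yc <- y[is_center]
    pe_ss <- sum((yc - mean(yc))^2)
    pe_df <- n_center - 1
    lof_ss <- rss - pe_ss
    lof_df <- df_res - pe_df
    rows <- rbind(rows,
                  data.frame(source = c("Lack of fit", "Pure error"),
                             ss = c(lof_ss, pe_ss), df = c(lof_df, pe_df)))
  } else {
    warning("fewer than 2 replicated center runs: lack-of-fit split omitted")
  }
  rows <- rbind(rows, data.frame(source = "Cor total", ss = tss, df = object$n - 1))

  rows$ms <- rows$ss / rows$df
  rows$f <- NA_real_
  rows$p <- NA_real_
  idx <- rows$source %in% c("Model", term_names)
  rows$f[idx] <- rows$ms[idx] / ms_res
  rows$p[idx] <- stats::pf(rows$f[idx], rows$df[idx], df_res, lower.tail = FALSE)
  if (n_center >= 2 && pe_df > 0 && lof_df > 0) {
    i <- rows$source == "Lack of fit"
    rows$f[i] <- (lof_ss / lof_df) / (pe_ss / pe_df)
    rows$p[i] <- stats::pf(rows$f[i], lof_df, pe_df, lower.tail = FALSE)
  }
  rows$ms[rows$source == "Cor total"] <- NA_real_

  structure(rows,
            class = c("rsm_anova", "data.frame"),
            response = object$response,
            r2 = mss / tss,
            r2_adj = 1 - (rss / df_res) / (tss / (object$n - 1)),
            cv_percent = 100 * sqrt(ms_res) / object$grand_mean)
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("ANOVA for response", attr(x, "response"), "\n")
  fmt <- data.frame(Source = x$source,
                    `Sum of Squares` = sprintf("%.2f", x$ss),
                    Df = x$df,
                    `Mean Square` = ifelse(is.na(x$ms), "", sprintf("%.2f", x$ms)),
                    `F-value` = ifelse(is.na(x$f), "", sprintf("%.2f", x$f)),
                    `p-value` = ifelse(is.na(x$p), "",
                                       ifelse(x$p < 1e-4, "<0.0001",
                                              sprintf("%.4f", x$p))),
                    check.names = FALSE)
  print(fmt, row.names = FALSE)
  cat(sprintf("R2 = %.4f  R2adj = %.4f  C.V. = %.2f%%\n",
              attr(x, "r2"), attr(x, "r2_adj"), attr(x, "cv_percent")))
  invisible(x)
}

#' Multi-response desirability optimization
#'
#' Derringer--Suich optimization over the coded cube [-1, 1]^3. Each fitted
#' response is mapped to an individual desirability d in [0, 1] -- linear
#' between per-response anchors (by default the observed minimum and
#' maximum of that response in the design), rising for `"maximize"` goals
#' and falling for `"minimize"` -- and the overall desirability is the
#' weighted geometric mean \eqn{D = (\prod d_i^{w_i})^{1/\sum w_i}}.
#' D is invariant to a common rescaling of the weights.
#'
#' The search is deterministic: a bounded quasi-Newton (L-BFGS-B) local
#' optimization from each point of the fixed 3^3 grid of cube corners,
#' edge midpoints and center; the best local solution is returned.
#'
#' @param fits List of `rsm_fit` objects sharing one factor specification.
#' @param goals Character vector, one of `"maximize"`/`"minimize"` per fit
#'   (recycled).
#' @param weights Positive weights, one per fit (recycled).
#' @param anchors Optional list of `c(lo, hi)` anchor pairs per response;
#'   defaults to each response's observed range.
#' @return A list of class `desirability_opt`: `point_coded`,
#'   `point_actual`, `predicted` (named per response), `desirability`, and
#'   the per-response `d_individual`.
#' @export
optimize_desirability <- function(fits, goals = "maximize", weights = 1,
                                  anchors = NULL) {
  if (!length(fits)) stop("'fits' must be a non-empty list", call. = FALSE)
  if (inherits(fits, "rsm_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "rsm_fit")))
  k <- length(fits)
  goals <- rep_len(match.arg(goals, c("maximize", "minimize"), several.ok = TRUE), k)
  weights <- rep_len(weights, k)
  if (any(weights <= 0)) stop("'weights' must be positive", call. = FALSE)
  if (is.null(anchors)) anchors <- lapply(fits, function(f) range(f$y))
  stopifnot(length(anchors) == k)

  d_one <- function(yhat, i) {
    a <- anchors[[i]]
    d <- (yhat - a[1]) / (a[2] - a[1])
    if (goals[i] == "minimize") d <- 1 - d
    min(max(d, 0), 1)
  }
  overall <- function(p) {
    ds <- vapply(seq_len(k), function(i) {
      d_one(predict.rsm_fit(fits[[i]], coded = p), i)
    }, numeric(1))
    prod(pmax(ds, 1e-12)^weights)^(1 / sum(weights))
  }

  starts <- as.matrix(expand.grid(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1),
                                  x3 = c(-1, 0, 1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], function(p) -overall(p),
                      method = "L-BFGS-B", lower = -1, upper = 1,
                      control = list(factr = 1e2, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- unname(best$par)
  preds <- vapply(fits, predict.rsm_fit, numeric(1), coded = p)
  names(preds) <- vapply(fits, `[[`, character(1), "response")
  ds <- vapply(seq_len(k), function(i) d_one(preds[i], i), numeric(1))
  names(ds) <- names(preds)
  structure(list(point_coded = p,
                 point_actual = uncode_point(fits[[1]]$factors, p),
                 predicted = preds,
                 desirability = -best$value,
                 d_individual = ds),
            class = "desirability_opt")
}

#' @export
print.desirability_opt <- function(x, ...) {
  cat("Desirability optimum (D =", sprintf("%.4f", x$desirability), ")\n")
  cat("  coded: ", paste(sprintf("%.4f", x$point_coded), collapse = ", "), "\n")
  cat("  actual:", paste(sprintf("%.4g", x$point_actual), collapse = ", "), "\n")
  for (nm in names(x$predicted)) {
    cat(sprintf("  %s predicted %.2f (d = %.3f)\n",
                nm, x$predicted[nm], x$d_individual[nm]))
  }
  invisible(x)
}
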