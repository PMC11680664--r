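#' Coefficient of determination on the proportion scale
#'
#' `r^2 = 1 - SSE/SST` with the total sum of squares taken about the mean of
#' the observed proportions. All fits in this package are scored on the
#' untransformed proportion scale so that r-squared values are comparable
#' across families, whatever space a family was linearized in for its
#' starting values. Values can be negative when a fit does worse than the
#' observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @return Scalar r-squared (`<= 1`).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("`observed` and `predicted` must have equal length >= 3",
         call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("zero total variance: r-squared is undefined; route this data set ",
         "through net-change classification instead", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / sst
}

# Sum of squared residuals of a family at (a, b), guarded for the
# hyperbolic family's positivity constraint on the evaluation domain.
family_sse <- function(family, a, b, t, m) {
  if (family == "hyperbolic_power" && any(a + b * sqrt(t) <= 1e-12)) {
    return(Inf)
  }
  pred <- family_value(family, a, b, t)
  if (any(!is.finite(pred))) return(Inf)
  sum((m - pred)^2)
}

# Linearizing-transform starting values for the nonlinear families.
# Proportions are floored at 1e-6 for the transforms only.
linearized_start <- function(family, t, m) {
  mf <- pmax(m, 1e-6)
  switch(family,
    power = {
      co <- stats::coef(stats::lm(log(mf) ~ log(t)))
      c(a = exp(co[[1L]]), b = co[[2L]])
    },
    exponential_power = {
      co <- stats::coef(stats::lm(log(mf) ~ sqrt(t)))
      c(a = exp(co[[1L]]), b = -co[[2L]])
    },
    hyperbolic_power = {
      co <- stats::coef(stats::lm(I(1 / mf) ~ sqrt(t)))
      c(a = co[[1L]], b = co[[2L]])
    },
    stop("no linearized start for family ", family, call. = FALSE)
  )
}

# Multi-start grid: +/-50% perturbations of each parameter around the
# linearization-based start (3 x 3), cheap insurance against local minima
# on very short series. Zero start components get a small additive spread
# instead, since scaling zero goes nowhere.
start_grid <- function(start) {
  perturb <- function(x) if (x == 0) c(-0.01, 0, 0.01) else x * c(0.5, 1, 1.5)
  grid <- expand.grid(a = perturb(start[["a"]]), b = perturb(start[["b"]]))
  grid
}

# Additional data-scaled coarse candidates, so highly non-monotone series
# (where the linearizing transforms are uninformative) still reach the
# global least-squares basin. For power and exponential-power the model is
# linear in `a` at fixed `b`, so `b` is profiled over a grid with the
# optimal `a` in closed form; the hyperbolic family gets a small 2-D
# lattice. All candidates are polished by the optimizer afterwards.
coarse_candidates <- function(family, t, m, top = 3L) {
  if (family %in% c("power", "exponential_power")) {
    bs <- if (family == "power") {
      seq(-2.5, 1.5, length.out = 41)
    } else {
      # rate scaled so b * sqrt(t_max) spans strong-to-negligible decay
      c(seq(-3, 8, length.out = 41)) / sqrt(max(t))
    }
    cand <- vapply(bs, function(b) {
      basis <- if (family == "power") t^b else exp(-b * sqrt(t))
      denom <- sum(basis^2)
      if (!is.finite(denom) || denom <= 0) return(c(NA_real_, Inf))
      a <- sum(m * basis) / denom
      c(a, family_sse(family, a, b, t, m))
    }, numeric(2))
    ok <- is.finite(cand[2L, ])
    ord <- order(cand[2L, ok])[seq_len(min(top, sum(ok)))]
    data.frame(a = cand[1L, ok][ord], b = bs[ok][ord])
  } else {
    inv <- 1 / pmax(m, 1e-6)
    as <- seq(0.5 * min(inv), 2 * max(inv), length.out = 25)
    bmax <- 3 * (max(inv) - min(inv) + 1) / sqrt(max(t))
    bs <- seq(-bmax, bmax, length.out = 25)
    grid <- expand.grid(a = as, b = bs)
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      family_sse(family, grid$a[i], grid$b[i], t, m)
    }, numeric(1))
    ok <- is.finite(sse)
    ord <- order(sse[ok])[seq_len(min(top, sum(ok)))]
    grid[ok, , drop = FALSE][ord, , drop = FALSE]
  }
}

#' Fit one function family to a retention data set
#'
#' Logarithmic and linear curves are linear in their parameters and are
#' solved in closed form by ordinary least squares of `M` on `ln(t)` and on
#' `t`. The power, exponential-power, and hyperbolic-power families are
#' fitted by nonlinear least squares (Levenberg-Marquardt,
#' [minpack.lm::nls.lm()]) minimizing the sum of squared residuals in
#' proportion space, started from their linearizing transforms plus a small
#' 3 x 3 multi-start grid of +/-50% perturbations and a few data-scaled
#' coarse candidates (the rate profiled over a grid with the scale solved in
#' closed form where the model is linear in `a`; a small lattice for the
#' hyperbolic family). The fit quality is always
#' [r_squared()] on the untransformed proportion scale, against unclamped
#' predictions.
#'
#' @param ds A [retention_dataset()].
#' @param family One of [retention_families].
#' @return A `fit_result`: list with `family`, `a`, `b`, `r2`, `converged`.
#'   `converged = FALSE` means every optimizer start failed and the best
#'   candidate from the start grid is reported instead.
#' @export
fit_family <- function(ds, family) {
  stopifnot(inherits(ds, "retention_dataset"))
  family <- match.arg(family, retention_families)
  t <- ds$times
  m <- ds$proportions
  if (stats::var(m) == 0) {
    stop("zero observed variance in data set ", ds$dataset_id,
         ": fitting is undefined; classify by net change instead",
         call. = FALSE)
  }

  if (family %in% c("logarithmic", "linear")) {
    x <- if (family == "logarithmic") log(t) else t
    co <- stats::coef(stats::lm(m ~ x))
    a <- co[[1L]]
    b <- if (family == "logarithmic") -co[[2L]] else co[[2L]]
    pred <- family_value(family, a, b, t)
    return(new_fit_result(family, a, b, r_squared(m, pred), TRUE))
  }

  start <- linearized_start(family, t, m)
  grid <- rbind(start_grid(start), coarse_candidates(family, t, m))
  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(grid))) {
    par0 <- c(a = grid$a[i], b = grid$b[i])
    cand_sse <- family_sse(family, par0[["a"]], par0[["b"]], t, m)
    if (is.finite(cand_sse) && (is.null(best) || cand_sse < best$sse)) {
      best <- list(a = par0[["a"]], b = par0[["b"]], sse = cand_sse)
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = par0,
        fn = function(p) {
          if (family == "hyperbolic_power" &&
              any(p[["a"]] + p[["b"]] * sqrt(t) <= 1e-12)) {
            return(rep(1e6, length(t)))
          }
          m - family_value(family, p[["a"]], p[["b"]], t)
        },
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      sse <- family_sse(family, p[["a"]], p[["b"]], t, m)
      ok <- fit$info %in% 1:4
      any_converged <- any_converged || (ok && is.finite(sse))
      if (is.finite(sse) && (is.null(best) || sse < best$sse)) {
        best <- list(a = p[["a"]], b = p[["b"]], sse = sse)
      }
    }
  }
  if (is.null(best)) {
    # Even the raw starts violated the domain (hyperbolic on pathological
    # data); report the plain linearized start, unconverged.
    best <- list(a = start[["a"]], b = start[["b"]], sse = NA_real_)
    pred <- rep(mean(m), length(m))
    return(new_fit_result(family, best$a, best$b, r_squared(m, pred) - 1,
                          FALSE))
  }
  pred <- family_value(family, best$a, best$b, t)
  new_fit_result(family, best$a, best$b, r_squared(m, pred), any_converged)
}

new_fit_result <- function(family, a, b, r2, converged) {
  structure(
    list(family = family, a = unname(a), b = unname(b), r2 = unname(r2),
         converged = converged),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s  a = %.6g, b = %.6g, r2 = %.4f%s\n",
              x$family, x$a, x$b, x$r2,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fit all five families to a data set
#'
#' @param ds A [retention_dataset()].
#' @return A `fit_set`: list with `dataset_id` and `fits`, a named list of
#'   one [fit_family()] result per family.
#' @export
fit_all <- function(ds) {
  fits <- lapply(retention_families, function(f) fit_family(ds, f))
  names(fits) <- retention_families
  structure(list(dataset_id = ds$dataset_id, fits = fits),
            class = "fit_set")
}

#' Select the best-fitting family
#'
#' Returns the family with maximal r-squared. Ties within `1e-10` are broken
#' by the fixed reporting order logarithmic > power > exponential_power >
#' hyperbolic_power > linear, and the tie is flagged.
#'
#' @param fs A `fit_set` from [fit_all()].
#' @return List with `family`, `fit` (the winning `fit_result`) and `tie`.
#' @export
best_fit <- function(fs) {
  stopifnot(inherits(fs, "fit_set"))
  r2 <- vapply(fs$fits[retention_families], function(f) f$r2, numeric(1))
  top <- max(r2)
  tied <- which(r2 >= top - 1e-10)
  winner <- retention_families[tied[1L]]
  list(family = winner, fit = fs$fits[[winner]], tie = length(tied) > 1L)
}

#' Tidy table of fit results
#'
#' @param fitsets List of `fit_set` objects.
#' @return Data frame with columns `dataset_id`, `family`, `a`, `b`, `r2`,
#'   `converged` (five rows per data set).
#' @export
fitsets_table <- function(fitsets) {
  do.call(rbind, lapply(fitsets, function(fs) {
    do.call(rbind, lapply(fs$fits, function(f) {
      data.frame(dataset_id = fs$dataset_id, family = f$family, a = f$a,
                 b = f$b, r2 = f$r2, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
  })) -> out
  rownames(out) <- NULL
  out
}

#' Cross-family correlations of fit quality
#'
#' Pearson correlations between the per-family r-squared vectors across data
#' sets. Highly correlated entries identify families that are hard to tell
#' apart on typical retention series.
#'
#' @param fitsets List of `fit_set` objects (>= 3).
#' @return Symmetric 5 x 5 correlation matrix with unit diagonal; entries
#'   involving a constant r-squared vector are `NA` (with a message).
#' @export
fit_quality_correlations <- function(fitsets) {
  if (length(fitsets) < 3L) {
    stop("need at least 3 fit sets to correlate fit quality", call. = FALSE)
  }
  r2 <- vapply(fitsets, function(fs) {
    vapply(fs$fits[retention_families], function(f) f$r2, numeric(1))
  }, numeric(length(retention_families)))
  r2 <- t(r2)
  colnames(r2) <- retention_families
  constant <- apply(r2, 2L, function(x) stats::var(x) == 0)
  if (any(constant)) {
    message("constant r2 vector(s), correlations reported as NA: ",
            paste(retention_families[constant], collapse = ", "))
  }
  out <- suppressWarnings(stats::cor(r2))
  diag(out) <- 1
  out
}
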