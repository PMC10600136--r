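# Higher-order co-dependence analyses across adjacency matrices: pairwise
# correlations, transition-class trends, sign-reversal tables, t'-score
# contralateral normalization, flux-vector amplitudes, Lineweaver-Burk
# double-reciprocal regressions and group comparisons.

#' Pearson correlation between two coefficient vectors
#'
#' Computed over the transition types where both coefficients are
#' available; fewer than 3 joint observations is an error.
#'
#' @param coef_a,coef_b numeric 100-vectors.
#' @return Pearson correlation coefficient.
#' @export
adjacency_correlation <- function(coef_a, coef_b) {
  stopifnot(length(coef_a) == length(coef_b))
  ok <- is.finite(coef_a) & is.finite(coef_b)
  if (sum(ok) < 3L)
    stop("need at least 3 jointly available transition types", call. = FALSE)
  cor(coef_a[ok], coef_b[ok])
}

#' All pairwise correlations among a suite's coefficient classes
#'
#' The 18 coefficient classes admit `choose(18, 2) = 153` unique unordered
#' pairings.
#'
#' @param suite an [adjacency_suite()].
#' @return data.frame with columns `coef_a`, `coef_b`, `r`, `n`.
#' @export
correlation_table <- function(suite) {
  cn <- colnames(suite$coefficients)
  pairs <- utils::combn(cn, 2L)
  out <- data.frame(coef_a = pairs[1L, ], coef_b = pairs[2L, ],
                    r = NA_real_, n = NA_integer_)
  for (i in seq_len(ncol(pairs))) {
    a <- suite$coefficients[, pairs[1L, i]]
    b <- suite$coefficients[, pairs[2L, i]]
    ok <- is.finite(a) & is.finite(b)
    out$n[i] <- sum(ok)
    out$r[i] <- if (sum(ok) >= 3L) cor(a[ok], b[ok]) else NA_real_
  }
  out
}

#' Per-class extrema of two coefficients
#'
#' For each transition class 0-5 reports the maximum absolute value of each
#' coefficient over the member types, summarizing the reciprocal
#' class trends (mean-amplitude range shrinking while flux amplitude
#' saturates with class number).
#'
#' @param coef_x,coef_y numeric 100-vectors.
#' @return data.frame with columns `class_m`, `n_types`, `max_abs_x`,
#'   `max_abs_y`.
#' @export
class_extrema <- function(coef_x, coef_y) {
  stopifnot(length(coef_x) == 100L, length(coef_y) == 100L)
  cls <- decode_transition(1:100)$class_m
  mx <- function(v, m) {
    v <- abs(v[cls == m]); v <- v[is.finite(v)]
    if (length(v)) max(v) else NA_real_
  }
  data.frame(class_m = 0:5,
             n_types = as.integer(table(factor(cls, levels = 0:5))),
             max_abs_x = vapply(0:5, function(m) mx(coef_x, m), 0),
             max_abs_y = vapply(0:5, function(m) mx(coef_y, m), 0))
}

#' Sign-reversal category table with group tests
#'
#' Partitions the off-diagonal transition types by whether the chosen
#' component's algebraic sign reverses ('1') or not ('0'; the ten
#' self-transitions are excluded from category '0'), and compares
#' coefficient values between the two categories (Welch unequal-variance
#' t-test) within each breast group, and between the two groups within
#' each category (paired t-test across transition types).
#'
#' @param groups named list of two elements (e.g. `T` and `N`), each an
#'   [adjacency_suite()] or a list of suites (then averaged with
#'   [suite_group_mean()]).
#' @param component component whose sign reversal defines the categories.
#' @param coefficients named list mapping row labels to functions of a
#'   suite returning a 100-vector; the default reproduces the standard
#'   table rows: transition probability, pre-transition dwell time, and the
#'   absolute averaged pre/post mean value of the saturation and total
#'   components.
#' @param geometry a [state_geometry()].
#' @return list with `summary` (coefficient, group, mean0, mean1,
#'   p_category) and `between` (coefficient, category, p_paired).
#' @export
sign_reversal_table <- function(groups, component = "total",
                                coefficients = NULL,
                                geometry = state_geometry()) {
  if (length(groups) != 2L || is.null(names(groups)))
    stop("`groups` must be a named list of two suite sets", call. = FALSE)
  suites <- lapply(groups, function(g) {
    if (inherits(g, "adjacency_suite")) g else suite_group_mean(g)
  })
  if (is.null(coefficients)) {
    abs_mean <- function(cmp) function(s)
      abs((suite_coefficient(s, paste0("mu_pre_", cmp)) +
             suite_coefficient(s, paste0("mu_post_", cmp))) / 2)
    coefficients <- list(
      prob = function(s) suite_coefficient(s, "prob"),
      dwell_pre = function(s) suite_coefficient(s, "dwell_pre"),
      mean_abs_sat = abs_mean("sat"),
      mean_abs_total = abs_mean("total")
    )
  }
  cat_flag <- reversal_category(1:100, component, geometry)
  diag_k <- decode_transition(1:100)$s1 == decode_transition(1:100)$s2
  idx0 <- which(cat_flag == 0L & !diag_k)
  idx1 <- which(cat_flag == 1L)
  if (!length(idx0) || !length(idx1)) stop("empty reversal category", call. = FALSE)

  summary <- do.call(rbind, lapply(names(coefficients), function(nm) {
    do.call(rbind, lapply(names(suites), function(g) {
      v <- coefficients[[nm]](suites[[g]])
      v0 <- v[idx0]; v1 <- v[idx1]
      p <- if (sd(v0, na.rm = TRUE) == 0 && sd(v1, na.rm = TRUE) == 0) {
        if (isTRUE(all.equal(mean(v0, na.rm = TRUE), mean(v1, na.rm = TRUE)))) 1 else 0
      } else t.test(v0, v1, var.equal = FALSE)$p.value
      data.frame(coefficient = nm, group = g,
                 mean0 = mean(v0, na.rm = TRUE), mean1 = mean(v1, na.rm = TRUE),
                 p_category = p)
    }))
  }))
  between <- do.call(rbind, lapply(names(coefficients), function(nm) {
    va <- coefficients[[nm]](suites[[1L]])
    vb <- coefficients[[nm]](suites[[2L]])
    pp <- vapply(list(`0` = idx0, `1` = idx1), function(ii) {
      d <- va[ii] - vb[ii]
      if (sd(d, na.rm = TRUE) == 0) return(if (all(d == 0, na.rm = TRUE)) 1 else 0)
      t.test(va[ii], vb[ii], paired = TRUE)$p.value
    }, 0)
    data.frame(coefficient = nm, category = c("0", "1"), p_paired = pp)
  }))
  rownames(summary) <- rownames(between) <- NULL
  list(summary = summary, between = between)
}

#' Contralateral t'-scores
#'
#' Standardizes a breast's per-type coefficient values against the mean and
#' standard deviation of the contralateral (reference) breast across all
#' 100 transition types: `t'_k = (x_k - m_ref) / s_ref`.
#'
#' @param x numeric 100-vector for the breast of interest.
#' @param ref numeric 100-vector for the contralateral reference breast.
#' @return dimensionless numeric 100-vector.
#' @export
tprime_scores <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  m <- mean(ref, na.rm = TRUE)
  s <- sd(ref, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("reference standard deviation is zero", call. = FALSE)
  (x - m) / s
}

#' Flux-vector amplitude
#'
#' Euclidean norm of the three dimensionless t'-score components (total-Hb
#' flux, saturation flux and dwell-time flux, i.e. post- minus
#' pre-transition dwell time): `A_k = sqrt(t1^2 + t2^2 + t3^2)`.  A missing
#' component yields a missing amplitude.
#'
#' @param t_total,t_sat,t_dwell aligned numeric vectors of t'-scores.
#' @return numeric vector of amplitudes.
#' @export
vector_amplitude <- function(t_total, t_sat, t_dwell) {
  stopifnot(length(t_total) == length(t_sat), length(t_sat) == length(t_dwell))
  sqrt(t_total^2 + t_sat^2 + t_dwell^2)
}

#' Lineweaver-Burk double-reciprocal regression
#'
#' Ordinary least-squares fit of a transformed response against the
#' reciprocal transition probability `1/P`.  With `transform =
#' "reciprocal"` the response is `1/|y|` and, by the enzyme-kinetics
#' analogy (probability as substrate, |flux| as velocity), `Vmax =
#' 1/intercept` and `Km = slope/intercept`; with `"log10-reciprocal"` the
#' response is `log10(1/|y|)`.  Points with non-positive `P` or zero `y`
#' are dropped with a logged count, as are points inside the optional
#' exclusion rectangle.
#'
#' @param P numeric vector of transition probabilities (percent).
#' @param y numeric vector (e.g. flux or vector amplitude), aligned with `P`.
#' @param subset optional logical or integer index selecting transition
#'   types (e.g. classes 3-5) before transformation.
#' @param transform `"reciprocal"` or `"log10-reciprocal"`.
#' @param exclude optional `list(x_max =, y_min =)`: points with
#'   `1/P < x_max` and transformed response `> y_min` are excluded
#'   (a rectangular high-probability / high-reciprocal-flux region).
#' @return object of class `lb_fit`: list with `slope`, `intercept`, `r`,
#'   `p`, `se_slope`, `se_intercept`, `n`, `n_dropped`, `vmax`, `km`
#'   (`NA` unless `transform = "reciprocal"`), `transform`, `x`, `y`.
#' @export
lineweaver_burk <- function(P, y, subset = NULL,
                            transform = c("reciprocal", "log10-reciprocal"),
                            exclude = NULL) {
  transform <- match.arg(transform)
  stopifnot(length(P) == length(y))
  if (!is.null(subset)) { P <- P[subset]; y <- y[subset] }
  n0 <- length(P)
  ok <- is.finite(P) & P > 0 & is.finite(y) & y != 0
  xr <- 1 / P[ok]
  ty <- 1 / abs(y[ok])
  if (transform == "log10-reciprocal") ty <- log10(ty)
  if (!is.null(exclude)) {
    drop <- xr < exclude$x_max & ty > exclude$y_min
    xr <- xr[!drop]; ty <- ty[!drop]
  }
  n <- length(xr)
  if (n < 3L) stop("fewer than 3 usable points for the regression", call. = FALSE)
  fit <- lm(ty ~ xr)
  sm <- suppressWarnings(summary(fit))   # exact fits trigger a benign warning
  slope <- coef(fit)[[2L]]; intercept <- coef(fit)[[1L]]
  structure(list(
    slope = slope, intercept = intercept,
    se_slope = sm$coefficients[2L, 2L], se_intercept = sm$coefficients[1L, 2L],
    r = if (sd(ty) == 0) NA_real_ else cor(xr, ty),
    p = sm$coefficients[2L, 4L],
    n = n, n_dropped = n0 - n,
    vmax = if (transform == "reciprocal") 1 / intercept else NA_real_,
    km = if (transform == "reciprocal") slope / intercept else NA_real_,
    transform = transform, x = xr, y = ty
  ), class = "lb_fit")
}

#' @export
print.lb_fit <- function(x, ...) {
  cat(sprintf("<lb_fit> %s: slope = %.4g, intercept = %.4g, r = %.3f, p = %.3g, n = %d\n",
              x$transform, x$slope, x$intercept, x$r, x$p, x$n))
  if (is.finite(x$vmax))
    cat(sprintf("  Vmax = %.4g, Km = %.4g\n", x$vmax, x$km))
  invisible(x)
}

#' Compare two independent regressions
#'
#' Two-sample t-tests on the slope and on the intercept of two independent
#' [lineweaver_burk()] fits, using the coefficient standard errors with
#' pooled degrees of freedom `n1 + n2 - 4`.
#'
#' @param fit1,fit2 `lb_fit` objects.
#' @return list with `p_slope`, `p_intercept`, `t_slope`, `t_intercept`,
#'   `df`.
#' @export
compare_regressions <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "lb_fit"), inherits(fit2, "lb_fit"))
  df <- fit1$n + fit2$n - 4L
  if (df < 1L) stop("too few points to compare regressions", call. = FALSE)
  tt <- function(b1, b2, s1, s2) (b1 - b2) / sqrt(s1^2 + s2^2)
  ts <- tt(fit1$slope, fit2$slope, fit1$se_slope, fit2$se_slope)
  ti <- tt(fit1$intercept, fit2$intercept, fit1$se_intercept, fit2$se_intercept)
  list(p_slope = 2 * pt(-abs(ts), df), p_intercept = 2 * pt(-abs(ti), df),
       t_slope = ts, t_intercept = ti, df = df)
}

#' Rank-order category of a t'-score triple
#'
#' Classifies each transition type by the ordering of the absolute
#' t'-scores of the three vector components: category 1 =
#' |total| > |sat| > |dwell|; 2 = |total| > |dwell| > |sat|; 3 =
#' |sat| > |total| > |dwell|; 4 = |sat| > |dwell| > |total|; the two
#' orderings in which the dwell component is largest map to `"other"`.
#' Ties are broken by the fixed component precedence total > sat > dwell.
#'
#' @param t_total,t_sat,t_dwell aligned numeric vectors of t'-scores.
#' @return character vector with values `"1"`-`"4"` or `"other"`
#'   (`NA` where any component is missing).
#' @export
rank_order_category <- function(t_total, t_sat, t_dwell) {
  stopifnot(length(t_total) == length(t_sat), length(t_sat) == length(t_dwell))
  vapply(seq_along(t_total), function(i) {
    v <- abs(c(t_total[i], t_sat[i], t_dwell[i]))
    if (any(!is.finite(v))) return(NA_character_)
    ord <- order(-v, 1:3)          # precedence total > sat > dwell on ties
    key <- paste(ord, collapse = "")
    switch(key, "123" = "1", "132" = "2", "213" = "3", "231" = "4", "other")
  }, character(1L))
}

#' Marker-group tests on per-type vector amplitudes
#'
#' Averages amplitudes across subjects within each marker group (one net
#' value per transition type) and compares the marker-positive and
#' marker-negative per-type means with a Welch unequal-variance t-test,
#' over all class 3-5 types and within each rank-order category.
#'
#' @param amplitudes numeric matrix, subjects x 100 transition types.
#' @param marker logical (or two-level) vector of length `nrow(amplitudes)`
#'   giving each subject's marker status (`TRUE` = positive).
#' @param categories character 100-vector of rank-order categories (from
#'   [rank_order_category()]); only classes 3-5 types are used.
#' @return data.frame with one row per subset: `subset`, `n_types`,
#'   `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`, `p`, `p_bh`
#'   (Benjamini-Hochberg adjusted, reported for transparency only).
#' @export
marker_group_tests <- function(amplitudes, marker, categories = NULL) {
  if (!is.matrix(amplitudes) || ncol(amplitudes) != 100L)
    stop("`amplitudes` must be a subjects x 100 matrix", call. = FALSE)
  marker <- as.logical(marker)
  if (length(marker) != nrow(amplitudes) || any(is.na(marker)))
    stop("`marker` must be logical, one value per subject", call. = FALSE)
  cls <- decode_transition(1:100)$class_m
  in35 <- cls >= 3L
  m_pos <- colMeans(amplitudes[marker, , drop = FALSE], na.rm = TRUE)
  m_neg <- colMeans(amplitudes[!marker, , drop = FALSE], na.rm = TRUE)
  subsets <- list(`all_classes_3_5` = which(in35))
  if (!is.null(categories)) {
    stopifnot(length(categories) == 100L)
    for (cc in c("1", "2", "3", "4")) {
      subsets[[paste0("rank_order_", cc)]] <-
        which(in35 & !is.na(categories) & categories == cc)
    }
  }
  out <- do.call(rbind, lapply(names(subsets), function(nm) {
    ii <- subsets[[nm]]
    p <- if (length(ii) >= 3L)
      t.test(m_pos[ii], m_neg[ii], var.equal = FALSE)$p.value else NA_real_
    data.frame(subset = nm, n_types = length(ii),
               mean_pos = mean(m_pos[ii]), sd_pos = sd(m_pos[ii]),
               mean_neg = mean(m_neg[ii]), sd_neg = sd(m_neg[ii]), p = p)
  }))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
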