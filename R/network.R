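# Transition-network coefficients.
#
# With S the n_frames x n_voxels state matrix, the synchronous transition
# matrix is T = 10*(S[1:(Nt-1), ] - 1) + S[2:Nt, ]; self-transitions are
# counted, giving 100 transition types.  From T (and the component
# matrices) eighteen classes of adjacency coefficients are derived: the
# transition probability, pre- and post-transition dwell times, and, for
# each of the five Hb components, pre- and post-transition means and the
# flux (mean per-occurrence change).

check_state_matrix <- function(S) {
  if (is.data.frame(S)) S <- as.matrix(S)
  if (!is.matrix(S)) stop("`S` must be a matrix", call. = FALSE)
  if (nrow(S) < 2L) stop("need at least 2 time frames", call. = FALSE)
  if (any(is.na(S)) || any(S < 1L | S > 10L) || any(S != round(S)))
    stop("state values must be integers in 1..10", call. = FALSE)
  storage.mode(S) <- "integer"
  S
}

#' Synchronous transition-type matrix
#'
#' Compares the state of each voxel in every frame to the one immediately
#' following it: `T[i, j] = 10 * (S[i, j] - 1) + S[i + 1, j]`.  Equal
#' successive states count as (self-)transitions, so 100 types exist.
#'
#' @param S integer state matrix (`n_frames x n_voxels`, values 1-10).
#' @return integer matrix `(n_frames - 1) x n_voxels` of types 1-100.
#' @export
transition_index <- function(S) {
  S <- check_state_matrix(S)
  nt <- nrow(S)
  10L * (S[-nt, , drop = FALSE] - 1L) + S[-1L, , drop = FALSE]
}

#' Transition counts and probabilities
#'
#' `transition_counts` tallies occurrences of each of the 100 transition
#' types; `transition_probabilities` normalizes the counts to percent,
#' `P = 100 * c / sum(c)`.
#'
#' @param T integer transition matrix from [transition_index()].
#' @param counts a 100-vector of non-negative counts.
#' @return `transition_counts`: integer 100-vector; `transition_probabilities`:
#'   numeric 100-vector summing to 100.
#' @export
transition_counts <- function(T) {
  if (length(T) == 0L) stop("empty transition matrix", call. = FALSE)
  if (any(is.na(T)) || any(T < 1L | T > 100L))
    stop("transition types must lie in 1..100", call. = FALSE)
  tabulate(as.integer(T), nbins = 100L)
}

#' @rdname transition_counts
#' @export
transition_probabilities <- function(counts) {
  if (length(counts) != 100L || any(counts < 0))
    stop("`counts` must be a non-negative 100-vector", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("no transitions counted", call. = FALSE)
  100 * counts / tot
}

#' Mean pre- and post-transition dwell times
#'
#' For each occurrence of transition type `k = (s1 -> s2)` at time step `i`
#' (between frames `i` and `i + 1`), the pre-dwell is the number of
#' consecutive frames spent in `s1` up to and including frame `i`, and the
#' post-dwell the number of consecutive frames spent in `s2` from frame
#' `i + 1` on.  Pre-dwells of first-step occurrences and post-dwells of
#' last-step occurrences are undefined and excluded from the sums.  For the
#' ten self-transition types, a run of equal states yields consecutive
#' occurrences of the same type; only the largest pre- and post-dwell in
#' each such sequence enters the sums (no double counting).  Sums are
#' normalized by the full occurrence count `c_k` and converted to seconds.
#'
#' @param S integer state matrix.
#' @param frame_rate frames per second (default 1.8).
#' @return list with numeric 100-vectors `tau_pre`, `tau_post` (seconds;
#'   `NA` where the type never occurs) and integer `counts`.
#' @export
dwell_times <- function(S, frame_rate = 1.8) {
  S <- check_state_matrix(S)
  nt <- nrow(S); nts <- nt - 1L
  counts <- transition_counts(transition_index(S))
  pre_sum <- post_sum <- numeric(100L)
  for (j in seq_len(ncol(S))) {
    r <- rle(S[, j])
    L <- r$lengths; st <- r$values; R <- length(L)
    b <- cumsum(L)          # run end frames
    a <- b - L + 1L         # run start frames
    # inter-run (non-self) transitions at step i = b[r], r = 1..R-1
    if (R >= 2L) {
      for (r_ in seq_len(R - 1L)) {
        k <- 10L * (st[r_] - 1L) + st[r_ + 1L]
        if (b[r_] >= 2L) pre_sum[k] <- pre_sum[k] + L[r_]
        if (b[r_] <= nts - 1L) post_sum[k] <- post_sum[k] + L[r_ + 1L]
      }
    }
    # self transitions inside runs of length >= 2: one max-value
    # contribution per run, subject to the step-range limits
    for (r_ in which(L >= 2L)) {
      k <- 11L * st[r_] - 10L
      # pre-dwell at step i is i - a + 1, maximal at i = b - 1 (needs i >= 2)
      i_hi <- b[r_] - 1L
      if (i_hi >= 2L) pre_sum[k] <- pre_sum[k] + (i_hi - a[r_] + 1L)
      # post-dwell at step i is b - i, maximal at i = a (needs i <= nts - 1)
      i_lo <- a[r_]
      if (i_lo <= nts - 1L) post_sum[k] <- post_sum[k] + (b[r_] - i_lo)
    }
  }
  tau_pre <- ifelse(counts > 0L, pre_sum / counts / frame_rate, NA_real_)
  tau_post <- ifelse(counts > 0L, post_sum / counts / frame_rate, NA_real_)
  list(tau_pre = tau_pre, tau_post = tau_post, counts = counts)
}

#' Per-type component means and fluxes
#'
#' For a component matrix `X` aligned with the state matrix, computes for
#' every transition type the mean pre-transition value (of `X[i, j]` over
#' occurrences `T[i, j] = k`), the mean post-transition value
#' (of `X[i + 1, j]`), and the flux, the mean transition-associated change
#' `X[i + 1, j] - X[i, j]`.
#'
#' Averaging schemes: `"GA"` (grand average, default) sums over time and
#' voxels simultaneously and normalizes by the occurrence count; `"TMSM"`
#' takes the spatial mean within each time step (over voxels where the type
#' occurs) and then the temporal mean over steps with at least one
#' occurrence; `"SMTM"` takes the temporal mean within each voxel and then
#' the spatial mean over voxels where the type occurs.
#'
#' @param X numeric component matrix (`n_frames x n_voxels`).
#' @param T transition matrix from [transition_index()],
#'   `(n_frames - 1) x n_voxels`.
#' @param scheme one of `"GA"`, `"TMSM"`, `"SMTM"`.
#' @return list of numeric 100-vectors `mu_pre`, `mu_post`, `flux`
#'   (`NA` where the type never occurs).
#' @export
component_transition_stats <- function(X, T, scheme = c("GA", "TMSM", "SMTM")) {
  scheme <- match.arg(scheme)
  X <- as_hb_matrix(X, "X")
  nt <- nrow(X)
  if (!identical(dim(T), c(nt - 1L, ncol(X))))
    stop("`T` must be (n_frames - 1) x n_voxels, aligned with `X`", call. = FALSE)
  ks <- as.integer(T)
  pre <- as.vector(X[-nt, , drop = FALSE])
  post <- as.vector(X[-1L, , drop = FALSE])
  one_stat <- function(val) {
    if (scheme == "GA") {
      cnt <- tabulate(ks, 100L)
      s <- numeric(100L)
      agg <- rowsum(val, ks)
      s[as.integer(rownames(agg))] <- agg
      return(ifelse(cnt > 0L, s / cnt, NA_real_))
    }
    nts <- nt - 1L; nv <- ncol(X)
    grp <- if (scheme == "TMSM") rep(seq_len(nts), nv) else rep(seq_len(nv), each = nts)
    ng <- if (scheme == "TMSM") nts else nv
    sm <- Matrix::sparseMatrix(i = ks, j = grp, x = val, dims = c(100L, ng))
    cm <- Matrix::sparseMatrix(i = ks, j = grp, x = 1, dims = c(100L, ng))
    means <- as.matrix(sm) / as.matrix(cm)   # NaN where no occurrence
    out <- rowMeans(means, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  list(mu_pre = one_stat(pre), mu_post = one_stat(post),
       flux = one_stat(post - pre))
}

#' Full adjacency-coefficient suite
#'
#' Computes, from a state matrix and the five component matrices, all 18
#' adjacency coefficient classes: transition probability (percent), pre-
#' and post-transition dwell times (seconds), and per-component pre/post
#' means and fluxes (component units).  Coefficients of transition types
#' that never occur are `NA` (never zero), except the probability which is
#' genuinely zero.
#'
#' @param series an [hb_series()] (states are assigned via `geometry`), or
#'   an integer state matrix accompanied by `components`.
#' @param geometry a [state_geometry()]; ignored when `series` is already a
#'   state matrix.
#' @param scheme averaging scheme for component statistics, see
#'   [component_transition_stats()].
#' @param components optional named list of component matrices when
#'   `series` is a state matrix.
#' @param frame_rate frames per second; taken from the `hb_series` when
#'   available.
#' @return object of class `adjacency_suite`: list with `counts` (integer
#'   100-vector), `coefficients` (100 x 18 numeric matrix, columns `prob`,
#'   `dwell_pre`, `dwell_post`, and `mu_pre_*`, `mu_post_*`, `flux_*` for
#'   the five components), `scheme`, `frame_rate`, `n_frames`, `n_voxels`.
#' @export
adjacency_suite <- function(series, geometry = state_geometry(),
                            scheme = c("GA", "TMSM", "SMTM"),
                            components = NULL, frame_rate = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(series, "hb_series")) {
    S <- assign_states(series, geometry)
    components <- series$components
    frame_rate <- series$frame_rate
  } else {
    S <- check_state_matrix(series)
    if (is.null(frame_rate)) frame_rate <- 1.8
  }
  T <- transition_index(S)
  counts <- transition_counts(T)
  dw <- dwell_times(S, frame_rate)
  coefs <- matrix(NA_real_, 100L, 0L)
  coefs <- cbind(prob = transition_probabilities(counts),
                 dwell_pre = dw$tau_pre, dwell_post = dw$tau_post)
  if (!is.null(components)) {
    for (cmp in COMPONENTS) {
      if (is.null(components[[cmp]]))
        stop("missing component matrix: ", cmp, call. = FALSE)
      st <- component_transition_stats(components[[cmp]], T, scheme)
      block <- cbind(st$mu_pre, st$mu_post, st$flux)
      colnames(block) <- paste0(c("mu_pre_", "mu_post_", "flux_"), cmp)
      coefs <- cbind(coefs, block)
    }
  }
  structure(list(counts = counts, coefficients = coefs, scheme = scheme,
                 frame_rate = frame_rate, n_frames = nrow(S), n_voxels = ncol(S)),
            class = "adjacency_suite")
}

#' @export
print.adjacency_suite <- function(x, ...) {
  cat(sprintf(
    "<adjacency_suite> %d coefficient classes, %d/100 transition types observed (%s scheme)\n",
    ncol(x$coefficients), sum(x$counts > 0L), x$scheme))
  invisible(x)
}

#' Extract one coefficient class
#'
#' @param suite an [adjacency_suite()].
#' @param coefficient column name of `suite$coefficients`, or
#'   `"dwell_flux"` for the post-minus-pre dwell-time difference.
#' @return numeric 100-vector.
#' @export
suite_coefficient <- function(suite, coefficient) {
  if (identical(coefficient, "dwell_flux"))
    return(suite$coefficients[, "dwell_post"] - suite$coefficients[, "dwell_pre"])
  if (!coefficient %in% colnames(suite$coefficients))
    stop("unknown coefficient: ", coefficient, call. = FALSE)
  suite$coefficients[, coefficient]
}

#' View a coefficient as a 10 x 10 adjacency matrix
#'
#' Rows are pre-transition states, columns post-transition states.
#'
#' @inheritParams suite_coefficient
#' @return 10 x 10 numeric matrix.
#' @export
as_adjacency_matrix <- function(suite, coefficient = "prob") {
  matrix(suite_coefficient(suite, coefficient), nrow = 10L, byrow = TRUE,
         dimnames = list(pre = 1:10, post = 1:10))
}

#' Missing-aware mean of several adjacency suites
#'
#' Arithmetic mean per transition type and coefficient over a list of
#' suites (e.g. subjects of one group, or the left/right pair of one
#' subject), ignoring missing values; the counts are summed.
#'
#' @param suites non-empty list of [adjacency_suite()] objects with equal
#'   coefficient sets.
#' @return an `adjacency_suite` whose coefficients are the element-wise
#'   group means; `n_subjects` records the list length.
#' @export
suite_group_mean <- function(suites) {
  stopifnot(length(suites) >= 1L)
  cn <- colnames(suites[[1L]]$coefficients)
  for (s in suites)
    if (!identical(colnames(s$coefficients), cn))
      stop("suites have unequal coefficient sets", call. = FALSE)
  arr <- vapply(suites, function(s) s$coefficients,
                matrix(0, 100L, length(cn)))
  mean_mat <- apply(arr, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  colnames(mean_mat) <- cn
  out <- suites[[1L]]
  out$coefficients <- mean_mat
  out$counts <- Reduce(`+`, lapply(suites, `[[`, "counts"))
  out$n_subjects <- length(suites)
  out
}

#' Long-format table of an adjacency suite
#'
#' One row per transition type and coefficient class, with the decoded
#' pre/post states and transition class, suited for cross-subject joins.
#'
#' @param suite an [adjacency_suite()].
#' @param subject,breast optional label columns.
#' @return data.frame with columns `subject`, `breast`,
#'   `coefficient_class`, `k`, `s1`, `s2`, `class_m`, `value`, `count`.
#' @export
suite_long <- function(suite, subject = NA_character_, breast = NA_character_) {
  dec <- decode_transition(1:100)
  cn <- colnames(suite$coefficients)
  out <- do.call(rbind, lapply(cn, function(nm) {
    data.frame(subject = subject, breast = breast, coefficient_class = nm,
               dec, value = suite$coefficients[, nm], count = suite$counts)
  }))
  rownames(out) <- NULL
  out
}
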