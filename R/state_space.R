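# Ten-state fixed-reference ordinal partition of the (dTotal, dSat) plane.
#
# Because total = deoxy + oxy, exc = deoxy - oxy and, to first order about
# the baseline, oxy = s0*total + (total0/100)*sat, the signs of all five
# components are determined by the position of a point in the
# (dTotalHb, dHbO2Sat) plane.  The five null lines (one per component) pass
# through the origin and cut the plane into 10 sectors; only the 10 sign
# permutations realised by these sectors are physiologically allowed (out
# of 2^5 = 32).

#' Build the ten-state partition geometry
#'
#' Constructs the five component null lines in the (dTotalHb, dHbO2Sat)
#' plane and enumerates the ten sectors they delimit, together with the
#' sign vector (deoxy, exc, oxy, sat, total) of each sector.
#'
#' Null-line slopes (percent saturation per molar total Hb) follow from the
#' linearized dependencies about the baseline state
#' (`s0` = baseline saturation fraction, `total0` = baseline total Hb):
#' * saturation null: the horizontal axis;
#' * total null: the vertical axis;
#' * deoxy null: slope `100 * (1 - s0) / total0` (positive);
#' * oxy null: slope `-100 * s0 / total0`;
#' * exc null: slope `100 * (1 - 2 * s0) / (2 * total0)`.
#'
#' State numbering convention: State 1 is the sector swept first when
#' rotating counterclockwise from the positive dTotalHb axis; numbering
#' proceeds counterclockwise, so antipodal sectors differ by 5.  All
#' derived network quantities are invariant under cyclic relabelling; use
#' `relabel` to rotate labels if a different convention is wanted.
#'
#' @param s0 baseline saturation fraction, `0 < s0 < 1`; the canonical
#'   physiological regime is `0.5 < s0 < 1`, outside it a warning is given.
#' @param total0 baseline total hemoglobin concentration (molar), positive.
#' @param relabel integer 0-9, cyclic offset added to state labels.
#' @return an object of class `state_geometry`: list with `s0`, `total0`,
#'   `null_slopes` (named, percent/M; `Inf` for the total null),
#'   `null_angles` (radians mod pi, in scaled coordinates
#'   `u = 100 * total / total0`, `v = sat`), `boundaries` (10 sorted sector
#'   boundary angles in `[0, 2*pi)`), and `sector_table` (data.frame with
#'   columns `state`, `deoxy`, `exc`, `oxy`, `sat`, `total`, signs +-1).
#' @export
state_geometry <- function(s0 = 0.7, total0 = 1e-4, relabel = 0L) {
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 <= 0 || s0 >= 1)
    stop("`s0` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(total0) || length(total0) != 1L || !is.finite(total0) || total0 <= 0)
    stop("`total0` must be positive", call. = FALSE)
  if (s0 <= 0.5)
    warning("s0 <= 0.5 is outside the canonical physiological regime")
  relabel <- as.integer(relabel) %% 10L

  # slopes in raw (molar, percent) coordinates
  null_slopes <- c(
    deoxy = 100 * (1 - s0) / total0,
    exc   = 100 * (1 - 2 * s0) / (2 * total0),
    oxy   = -100 * s0 / total0,
    sat   = 0,
    total = Inf
  )
  # angles in the scaled plane u = 100 * total / total0, v = sat, where the
  # slopes become (1 - s0), (1 - 2 s0)/2, -s0, 0, Inf: well-spread angles.
  scaled_slope <- c(deoxy = 1 - s0, exc = (1 - 2 * s0) / 2, oxy = -s0,
                    sat = 0, total = Inf)
  null_angles <- ifelse(is.infinite(scaled_slope), pi / 2, atan(scaled_slope)) %% pi
  names(null_angles) <- names(scaled_slope)
  if (anyDuplicated(round(null_angles, 12)))
    stop("degenerate geometry: null lines are not distinct", call. = FALSE)

  boundaries <- sort(c(null_angles, null_angles + pi))
  mids <- (boundaries + c(boundaries[-1L], 2 * pi + boundaries[1L])) / 2

  signs <- vapply(mids, function(th) {
    component_signs_uv(cos(th), sin(th), s0)
  }, numeric(5))
  sector_table <- data.frame(state = 1L:10L, t(signs))
  names(sector_table) <- c("state", COMPONENTS)

  geom <- structure(list(
    s0 = s0, total0 = total0, relabel = relabel,
    null_slopes = null_slopes, null_angles = null_angles,
    boundaries = unname(boundaries), sector_table = sector_table
  ), class = "state_geometry")
  if (relabel > 0L) {
    geom$sector_table$state <- ((geom$sector_table$state - 1L + relabel) %% 10L) + 1L
    geom$sector_table <- geom$sector_table[order(geom$sector_table$state), ]
    rownames(geom$sector_table) <- NULL
  }
  geom
}

# signs of (deoxy, exc, oxy, sat, total) at a point of the scaled plane;
# exact zeros take the positive sign (documented tie-break)
component_signs_uv <- function(u, v, s0) {
  vals <- c(
    deoxy = (1 - s0) * u - v,
    exc   = (1 - 2 * s0) / 2 * u - v,
    oxy   = s0 * u + v,
    sat   = v,
    total = u
  )
  ifelse(vals >= 0, 1, -1)
}

#' @export
print.state_geometry <- function(x, ...) {
  cat(sprintf("<state_geometry> s0 = %.3f, total0 = %.3g M\n", x$s0, x$total0))
  cat("sector sign table (deoxy, exc, oxy, sat, total):\n")
  print(x$sector_table, row.names = FALSE)
  invisible(x)
}

#' Assign each sample to one of the ten Hb states
#'
#' The observed sign vector of the five components is matched against the
#' sector table.  Exact zeros count as positive.  Observations whose sign
#' vector is not among the ten allowed permutations (possible when the
#' nonlinearity of the saturation computation moves a point across a null
#' line) fall back to the nearest sector by angle in the
#' (dTotalHb, dHbO2Sat) plane; the fallback count is reported via
#' `attr(, "n_fallback")` and a fallback rate above 1% is an error.
#'
#' @param series an [hb_series()], or a named list of the five component
#'   matrices.
#' @param geometry a [state_geometry()].
#' @return integer matrix `n_frames x n_voxels` of state labels 1-10, with
#'   attribute `n_fallback`.
#' @export
assign_states <- function(series, geometry = state_geometry()) {
  comps <- if (inherits(series, "hb_series")) series$components else series
  if (!all(COMPONENTS %in% names(comps)))
    stop("series must contain components: ", paste(COMPONENTS, collapse = ", "),
         call. = FALSE)
  st <- geometry$sector_table
  # 5-bit key of the sign pattern -> state label
  key_of <- function(sd, se, so, ss, stt)
    1L + (sd > 0) + 2L * (se > 0) + 4L * (so > 0) + 8L * (ss > 0) + 16L * (stt > 0)
  lut <- rep(NA_integer_, 32L)
  lut[key_of(st$deoxy, st$exc, st$oxy, st$sat, st$total)] <- st$state

  sgn <- function(m) ifelse(m >= 0, 1, -1)
  keys <- key_of(sgn(comps$deoxy), sgn(comps$exc), sgn(comps$oxy),
                 sgn(comps$sat), sgn(comps$total))
  S <- matrix(lut[keys], nrow = nrow(comps$total), ncol = ncol(comps$total))

  bad <- is.na(S)
  if (any(bad)) {
    # samples with an exact zero in some component (boundary points, the
    # origin) are resolved by the angle rule; they are a documented
    # tie-break, not a dependency violation
    zeroish <- Reduce(`|`, lapply(comps[COMPONENTS], function(m) m == 0))
    fix0 <- bad & zeroish
    if (any(fix0))
      S[fix0] <- state_from_angle(comps$total[fix0], comps$sat[fix0], geometry)
    bad <- bad & !zeroish
  }
  n_fallback <- sum(bad)
  if (n_fallback > 0L) {
    if (n_fallback > 0.01 * length(S))
      stop(sprintf(
        "%d of %d samples (%.1f%%) have sign vectors outside the sector table; inputs violate the component dependencies",
        n_fallback, length(S), 100 * n_fallback / length(S)), call. = FALSE)
    S[bad] <- state_from_angle(comps$total[bad], comps$sat[bad], geometry)
  }
  attr(S, "n_fallback") <- n_fallback
  S
}

# nearest-sector lookup by angle in the scaled plane
state_from_angle <- function(total, sat, geometry) {
  u <- 100 * total / geometry$total0
  th <- atan2(sat, u) %% (2 * pi)
  idx <- findInterval(th, geometry$boundaries)
  idx[idx == 0L] <- 10L          # below the first boundary wraps to last sector
  ((idx - 1L + geometry$relabel) %% 10L) + 1L
}

#' Transition class (cyclic sector distance)
#'
#' The class of an ordered state pair is the cyclic distance between the
#' two sectors, `m = min(|s1 - s2|, 10 - |s1 - s2|)`, which equals the
#' number of components whose algebraic sign flips during the transition
#' (each sector boundary crossed flips exactly one sign).
#'
#' @param s1,s2 integer state labels in 1..10 (vectorized).
#' @return integer vector of classes in 0..5.
#' @export
transition_class <- function(s1, s2) {
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (any(is.na(s1) | is.na(s2) | s1 < 1L | s1 > 10L | s2 < 1L | s2 > 10L))
    stop("states must be integers in 1..10", call. = FALSE)
  d <- abs(s1 - s2)
  pmin(d, 10L - d)
}

#' Decode a transition-type index
#'
#' Types are numbered `k = 10 * (s1 - 1) + s2` for pre-state `s1` and
#' post-state `s2`, so `s1 = ceiling(k / 10)` and `s2 = k - 10 * (s1 - 1)`.
#'
#' @param k integer vector of transition-type indices in 1..100.
#' @return data.frame with columns `k`, `s1`, `s2`, `class_m`.
#' @export
decode_transition <- function(k = 1:100) {
  k <- as.integer(k)
  if (any(is.na(k) | k < 1L | k > 100L))
    stop("transition types must be integers in 1..100", call. = FALSE)
  s1 <- (k - 1L) %/% 10L + 1L
  s2 <- k - 10L * (s1 - 1L)
  data.frame(k = k, s1 = s1, s2 = s2, class_m = transition_class(s1, s2))
}

#' Sign-reversal indicator for a component over transition types
#'
#' For each transition type, 1 if the named component's algebraic sign
#' differs between the pre- and post-transition sectors, else 0.
#'
#' @param k integer vector of transition types (default all 100).
#' @param component one of `"deoxy"`, `"exc"`, `"oxy"`, `"sat"`, `"total"`.
#' @param geometry a [state_geometry()].
#' @return integer vector of 0/1 flags.
#' @export
reversal_category <- function(k = 1:100, component = "total",
                              geometry = state_geometry()) {
  component <- match.arg(component, COMPONENTS)
  d <- decode_transition(k)
  sv <- geometry$sector_table[[component]][order(geometry$sector_table$state)]
  as.integer(sv[d$s1] != sv[d$s2])
}

#' Write / read a partition geometry as plain text
#'
#' Serializes the geometry (parameters, null angles, sector sign table) to
#' a small JSON file for reproducibility, and reads it back.
#'
#' @param geometry a [state_geometry()].
#' @param path file path.
#' @return `read_geometry` returns a `state_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(list(
    s0 = geometry$s0, total0 = geometry$total0, relabel = geometry$relabel,
    sector_table = geometry$sector_table
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- state_geometry(obj$s0, obj$total0, obj$relabel)
  stored <- as.data.frame(obj$sector_table)
  if (!isTRUE(all.equal(as.matrix(stored[COMPONENTS]),
                        as.matrix(geom$sector_table[COMPONENTS]),
                        check.attributes = FALSE)))
    stop("stored sector table does not match rebuilt geometry", call. = FALSE)
  geom
}
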