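# Synthetic inputs emulating resting-state hemoglobin image time series:
# a shared slow vasomotor oscillation plus voxel-specific autocorrelated
# noise, expressed in the (dTotalHb, dHbO2Sat) plane and mapped back to
# oxy/deoxy inputs; Markov-chain parameter-recovery fixtures; a geometric
# null model; and surrogate series (time shuffling, phase randomization).

#' Simulation configuration
#'
#' Defaults emulate the acquisition regime of resting-state optical
#' mammography: 700 frames at 1.8 frames/s (duration range 400-1000),
#' total-Hb component amplitudes of order 1e-8 to 1e-7 M and saturation
#' amplitudes of order 1e-2 to 1e-1 percent, a slow shared oscillation in
#' the 0.08-0.12 Hz vasomotor band, and AR(1) voxel noise with a ~5 s
#' correlation time.  The `sat_inflation` factor multiplies the
#' saturation-axis spread of the "affected" member of the generated pair.
#'
#' @param n_frames,n_voxels series dimensions.
#' @param frame_rate frames per second.
#' @param seed RNG seed (R's default Mersenne-Twister via `set.seed`).
#' @param osc_band length-2 frequency band (Hz) of the shared oscillation.
#' @param n_osc number of superposed shared oscillators.
#' @param total_amp,sat_amp oscillation amplitudes along the total-Hb (M)
#'   and saturation (%) axes.
#' @param noise_tc AR(1) noise correlation time (seconds).
#' @param noise_sd_total,noise_sd_sat stationary noise SDs (M, %).
#' @param baseline absolute molar baselines `c(oxy0, deoxy0)`.
#' @param sat_inflation saturation-spread multiplier for the affected series.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 700L, n_voxels = 2000L, frame_rate = 1.8,
                       seed = 1L, osc_band = c(0.08, 0.12), n_osc = 3L,
                       total_amp = 4e-8, sat_amp = 0.04,
                       noise_tc = 5, noise_sd_total = 2.5e-8,
                       noise_sd_sat = 0.025,
                       baseline = c(oxy0 = 7e-5, deoxy0 = 3e-5),
                       sat_inflation = 2) {
  if (n_frames < 2L || n_frames > 1e5L)
    stop("`n_frames` must be in [2, 1e5]", call. = FALSE)
  stopifnot(n_voxels >= 1L, frame_rate > 0, total_amp >= 0, sat_amp >= 0,
            noise_sd_total >= 0, noise_sd_sat >= 0, sat_inflation > 0)
  structure(as.list(environment()), class = "sim_config")
}

ar1_noise <- function(n, nv, rho, sd_stat) {
  if (sd_stat == 0) return(matrix(0, n, nv))
  innov <- matrix(rnorm(n * nv, sd = sd_stat * sqrt(1 - rho^2)), n, nv)
  innov[1L, ] <- rnorm(nv, sd = sd_stat)
  out <- innov
  for (i in 2:n) out[i, ] <- rho * out[i - 1L, ] + innov[i, ]
  out
}

#' Generate a paired synthetic hemoglobin series
#'
#' Simulates latent total-Hb and saturation trajectories (shared
#' oscillation in quadrature, so the pair traces rotating loops through the
#' state plane, plus voxel-specific AR(1) noise), maps them to oxy/deoxy
#' input matrices through the linearized baseline dependencies, and builds
#' the two [hb_series()] of a subject: `affected` (saturation spread
#' multiplied by `sat_inflation`) and `unaffected`.
#'
#' @param config a [sim_config()].
#' @return list with elements `affected`, `unaffected` (both `hb_series`)
#'   and `config`.
#' @export
generate_hb_series <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_frames; nv <- config$n_voxels
  s0 <- config$baseline[["oxy0"]] / sum(config$baseline)
  total0 <- sum(config$baseline)
  tt <- seq_len(n) / config$frame_rate
  fr <- runif(config$n_osc, config$osc_band[1L], config$osc_band[2L])
  ph <- runif(config$n_osc, 0, 2 * pi)
  osc <- function(amp, shift) {
    amp * rowMeans(vapply(seq_len(config$n_osc),
                          function(m) sin(2 * pi * fr[m] * tt + ph[m] + shift),
                          numeric(n)))
  }
  u_osc <- osc(config$total_amp, 0)
  v_osc <- osc(config$sat_amp, pi / 2)      # quadrature: loops, not a line
  rho <- exp(-1 / (config$noise_tc * config$frame_rate))

  one_series <- function(inflate) {
    total <- u_osc + ar1_noise(n, nv, rho, config$noise_sd_total)
    sat <- inflate * (v_osc + ar1_noise(n, nv, rho, config$noise_sd_sat))
    oxy <- s0 * total + total0 * sat / 100
    hb_series(oxy, total - oxy, baseline = config$baseline,
              frame_rate = config$frame_rate, detrend = TRUE)
  }
  list(affected = one_series(config$sat_inflation),
       unaffected = one_series(1),
       config = config)
}

#' Michaelis-Menten flux model
#'
#' Returns the saturable flux-magnitude model
#' `|flux|(P) = vmax * P / (km + P)` used to inject a known
#' probability-flux coupling into [markov_amplitude_fixture()].
#'
#' @param vmax,km positive kinetic parameters (P in percent).
#' @return function of a probability vector.
#' @export
mm_flux_model <- function(vmax, km) {
  stopifnot(vmax > 0, km > 0)
  function(P) vmax * P / (km + P)
}

#' State representative points consistent with the sector geometry
#'
#' One (total, sat) point per state at the sector's angular midpoint, at
#' the given radius in the scaled plane.
#'
#' @param geometry a [state_geometry()].
#' @param radius radius in scaled-plane units.
#' @return 10 x 2 matrix (columns `total` in M, `sat` in %), row i = state i.
#' @export
state_representatives <- function(geometry = state_geometry(), radius = 1) {
  b <- geometry$boundaries
  mids <- (b + c(b[-1L], 2 * pi + b[1L])) / 2
  u <- radius * cos(mids); v <- radius * sin(mids)
  ord <- ((seq_along(mids) - 1L + geometry$relabel) %% 10L) + 1L
  out <- matrix(NA_real_, 10L, 2L, dimnames = list(NULL, c("total", "sat")))
  out[ord, ] <- cbind(u * geometry$total0 / 100, v)
  out
}

expand_components <- function(total, sat, geometry) {
  s0 <- geometry$s0; total0 <- geometry$total0
  oxy <- s0 * total + total0 * sat / 100
  deoxy <- total - oxy
  list(deoxy = deoxy, exc = deoxy - oxy, oxy = oxy, sat = sat, total = total)
}

#' Markov-chain parameter-recovery fixture
#'
#' Samples voxel state sequences from the Markov chain implied by a target
#' transition-probability vector, and builds component matrices in one of
#' two modes:
#' * `mode = "state"`: each component value is the state's representative
#'   amplitude (see [state_representatives()]) plus Gaussian noise; the
#'   representatives are validated against the sector sign table
#'   (a sign-inconsistent amplitude model is an error).
#' * `mode = "flux"`: total and saturation series are cumulative walks
#'   whose per-occurrence increment for transition type `k` has magnitude
#'   `flux_fun(P_target_k)` (plus noise), applied antisymmetrically
#'   (positive for `s1 < s2`, negative for `s1 > s2`, zero on the
#'   diagonal), injecting a known probability-flux coupling.
#'
#' @param P_target numeric 100-vector of target probabilities, summing to
#'   100; in `"flux"` mode it should be symmetric in (s1, s2) so that
#'   magnitudes are well defined.
#' @param n_steps number of time steps (frames minus one) per voxel.
#' @param n_voxels number of independent voxel chains.
#' @param mode `"flux"` or `"state"`.
#' @param flux_fun magnitude model for `"flux"` mode, e.g. [mm_flux_model()].
#' @param representatives optional 10 x 2 matrix for `"state"` mode.
#' @param noise_sd additive Gaussian noise SD (relative to the component
#'   scales used internally).
#' @param geometry a [state_geometry()].
#' @param frame_rate frames per second.
#' @param seed RNG seed.
#' @return list with `S` (state matrix), `components` (named list of five
#'   matrices), `P_target`, `flux_target` (signed 100-vector, `"flux"`
#'   mode), `frame_rate`, `geometry`.
#' @export
markov_amplitude_fixture <- function(P_target = rep(1, 100), n_steps = 5000L,
                                     n_voxels = 40L, mode = c("flux", "state"),
                                     flux_fun = mm_flux_model(2, 0.5),
                                     representatives = NULL, noise_sd = 0.05,
                                     geometry = state_geometry(),
                                     frame_rate = 1.8, seed = NULL) {
  mode <- match.arg(mode)
  if (length(P_target) != 100L || any(P_target < 0))
    stop("`P_target` must be a non-negative 100-vector", call. = FALSE)
  if (abs(sum(P_target) - 100) > 1e-8)
    stop("`P_target` must sum to 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(P_target, 10L, 10L, byrow = TRUE)    # rows = pre-state
  rs <- rowSums(W)
  if (any(rs == 0)) stop("every pre-state needs positive outgoing mass", call. = FALSE)
  Q <- W / rs
  # stationary distribution of the chain
  pi0 <- Re(eigen(t(Q))$vectors[, 1L]); pi0 <- pi0 / sum(pi0)
  n_frames <- n_steps + 1L
  S <- matrix(NA_integer_, n_frames, n_voxels)
  S[1L, ] <- sample.int(10L, n_voxels, replace = TRUE, prob = pmax(pi0, 0))
  cum <- t(apply(Q, 1L, cumsum))
  for (i in seq_len(n_steps)) {
    u <- runif(n_voxels)
    S[i + 1L, ] <- max.col(cum[S[i, ], , drop = FALSE] >= u, ties.method = "first")
  }
  T <- transition_index(S)

  if (mode == "state") {
    if (is.null(representatives))
      representatives <- state_representatives(geometry, radius = 1)
    stopifnot(is.matrix(representatives), nrow(representatives) == 10L)
    # sign-consistency of the amplitude model with the sector table
    st <- geometry$sector_table[order(geometry$sector_table$state), ]
    for (s in 1:10) {
      cmp <- expand_components(representatives[s, 1L], representatives[s, 2L],
                               geometry)
      sg <- ifelse(vapply(cmp[COMPONENTS], unname, 0) >= 0, 1, -1)
      if (any(sg != as.numeric(st[s, COMPONENTS])))
        stop(sprintf("amplitude model is sign-inconsistent for state %d", s),
             call. = FALSE)
    }
    scl <- apply(abs(representatives), 2L, max)
    total <- matrix(representatives[S, 1L], n_frames, n_voxels) +
      rnorm(n_frames * n_voxels, sd = noise_sd * scl[1L])
    sat <- matrix(representatives[S, 2L], n_frames, n_voxels) +
      rnorm(n_frames * n_voxels, sd = noise_sd * scl[2L])
    flux_target <- NULL
  } else {
    dec <- decode_transition(1:100)
    mag <- flux_fun(P_target)
    flux_target <- sign(dec$s2 - dec$s1) * mag
    inc <- matrix(flux_target[T], n_steps, n_voxels)
    scl <- max(abs(flux_target))
    walk <- function() {
      noise <- matrix(rnorm(n_steps * n_voxels, sd = noise_sd * scl),
                      n_steps, n_voxels)
      rbind(0, apply(inc + noise, 2L, cumsum))
    }
    total <- walk(); sat <- walk()
  }
  list(S = S, components = expand_components(total, sat, geometry),
       P_target = P_target, flux_target = flux_target,
       frame_rate = frame_rate, geometry = geometry)
}

#' Geometric null model of pre-transition mean coordinates
#'
#' Monte-Carlo expectation, under a uniform spatial distribution over a
#' rectangle of the (dTotalHb, dHbO2Sat) plane and a transition likelihood
#' that decreases monotonically with the distance between the two points,
#' of the pre-transition coordinates for each of the 100 transition types.
#' Emits per-pre-state "spoke" linearity diagnostics (share of variance of
#' the 10 same-pre-state mean points captured by their principal axis) and
#' the post-state ordering along each spoke.
#'
#' @param geometry a [state_geometry()].
#' @param kernel monotone non-increasing function of distance (distances
#'   are measured in the scaled plane `u = 100 * total / total0`,
#'   `v = sat`); the default `function(d) exp(-d)` decays on the scale of
#'   the sampling region.  A non-monotone kernel is an error.
#' @param n_samples number of candidate point pairs.
#' @param region `c(x_max, y_max)`: half-widths of the sampling rectangle
#'   in raw units (M, %).
#' @param seed RNG seed.
#' @return list with `pre_means` (data.frame `k`, `s1`, `s2`, `n`,
#'   `total`, `sat` in raw units), `spoke_linearity` (length-10),
#'   `post_order` (10 x 10 matrix: row s1 = post states ordered along the
#'   spoke), `acceptance_rate`.
#' @export
geometric_null_model <- function(geometry = state_geometry(),
                                 kernel = function(d) exp(-d),
                                 n_samples = 1e5, region = c(1e-7, 0.1),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u_max <- 100 * region[1L] / geometry$total0
  v_max <- region[2L]
  dmax <- 2 * sqrt(u_max^2 + v_max^2)
  grid <- seq(0, dmax, length.out = 256L)
  kv <- kernel(grid)
  if (any(!is.finite(kv)) || any(diff(kv) > 1e-12 * max(abs(kv))))
    stop("`kernel` must be finite and monotone non-increasing", call. = FALSE)
  k0 <- kernel(0)

  u1 <- runif(n_samples, -u_max, u_max); v1 <- runif(n_samples, -v_max, v_max)
  u2 <- runif(n_samples, -u_max, u_max); v2 <- runif(n_samples, -v_max, v_max)
  d <- sqrt((u1 - u2)^2 + (v1 - v2)^2)
  keep <- runif(n_samples) < kernel(d) / k0
  u1 <- u1[keep]; v1 <- v1[keep]; u2 <- u2[keep]; v2 <- v2[keep]
  t0 <- geometry$total0
  s1 <- state_from_angle(u1 * t0 / 100, v1, geometry)
  s2 <- state_from_angle(u2 * t0 / 100, v2, geometry)
  k <- 10L * (s1 - 1L) + s2
  agg <- function(v) {
    s <- numeric(100L); a <- rowsum(v, k)
    s[as.integer(rownames(a))] <- a
    s
  }
  nk <- tabulate(k, 100L)
  mu_u <- ifelse(nk > 0, agg(u1) / nk, NA_real_)
  mu_v <- ifelse(nk > 0, agg(v1) / nk, NA_real_)
  dec <- decode_transition(1:100)
  pre_means <- data.frame(dec[c("k", "s1", "s2")], n = nk,
                          total = mu_u * t0 / 100, sat = mu_v)

  spoke_linearity <- numeric(10L)
  post_order <- matrix(NA_integer_, 10L, 10L)
  for (s in 1:10) {
    ii <- which(dec$s1 == s & nk > 0)
    pts <- cbind(mu_u[ii], mu_v[ii])
    if (nrow(pts) >= 3L) {
      ev <- eigen(stats::cov(pts), symmetric = TRUE)
      spoke_linearity[s] <- 1 - ev$values[2L] / sum(ev$values)
      proj <- pts %*% ev$vectors[, 1L]
      post_order[s, seq_along(ii)] <- dec$s2[ii][order(proj)]
    }
  }
  list(pre_means = pre_means, spoke_linearity = spoke_linearity,
       post_order = post_order, acceptance_rate = mean(keep))
}

#' Surrogate series
#'
#' `"shuffle_time"` applies one random permutation of the time frames to
#' all five components jointly (destroying temporal dynamics while exactly
#' preserving each voxel's value multiset).  `"phase_randomize"` replaces
#' the oxy/deoxy series of each voxel by phase-randomized surrogates (the
#' same random phases for both channels of a voxel, preserving each
#' channel's periodogram exactly and the pair's cross-spectrum) and
#' recomputes the dependent components.
#'
#' @param series an [hb_series()].
#' @param kind surrogate type.
#' @param seed RNG seed.
#' @return an `hb_series`.
#' @export
surrogate_series <- function(series, kind = c("shuffle_time", "phase_randomize"),
                             seed = NULL) {
  stopifnot(inherits(series, "hb_series"))
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- series$n_frames
  if (kind == "shuffle_time") {
    perm <- sample.int(n)
    out <- series
    out$components <- lapply(series$components, function(m) m[perm, , drop = FALSE])
    return(out)
  }
  if (n < 3L) stop("phase randomization requires at least 3 frames", call. = FALSE)
  half <- (n - 1L) %/% 2L                       # conjugate-pair bins
  randomize <- function(x, theta) {
    X <- fft(x)
    rot <- rep(1 + 0i, n)
    idx <- seq_len(half) + 1L
    rot[idx] <- exp(1i * theta)
    rot[n + 2L - idx] <- Conj(rot[idx])         # Nyquist (even n) untouched
    Re(fft(X * rot, inverse = TRUE)) / n
  }
  oxy <- series$components$oxy
  deoxy <- series$components$deoxy
  for (j in seq_len(ncol(oxy))) {
    theta <- runif(half, 0, 2 * pi)
    oxy[, j] <- randomize(oxy[, j], theta)
    deoxy[, j] <- randomize(deoxy[, j], theta)
  }
  hb_series(oxy, deoxy, baseline = series$baseline,
            frame_rate = series$frame_rate, detrend = FALSE)
}
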