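# Independent brute-force oracles: plain nested loops over individual
# transition occurrences, written directly from the coefficient
# definitions, deliberately sharing no code with the package internals.

random_state_matrix <- function(seed, max_nt = 10L, max_nv = 10L) {
  set.seed(seed)
  nt <- sample(2:max_nt, 1L)
  nv <- sample(1:max_nv, 1L)
  matrix(sample.int(10L, nt * nv, replace = TRUE), nt, nv)
}

oracle_counts <- function(S) {
  out <- integer(100L)
  for (j in seq_len(ncol(S))) for (i in seq_len(nrow(S) - 1L)) {
    k <- 10L * (S[i, j] - 1L) + S[i + 1L, j]
    out[k] <- out[k] + 1L
  }
  out
}

# per-occurrence dwell times with the first/last-step exclusions and the
# max-per-consecutive-sequence rule for self-transition types
oracle_dwell <- function(S, frame_rate = 1.8) {
  nt <- nrow(S); nts <- nt - 1L
  counts <- oracle_counts(S)
  pre_sum <- post_sum <- numeric(100L)
  for (j in seq_len(ncol(S))) {
    s <- S[, j]
    occ <- data.frame(i = seq_len(nts))
    occ$k <- 10L * (s[occ$i] - 1L) + s[occ$i + 1L]
    occ$n1 <- vapply(occ$i, function(i) {
      n <- 0L; ii <- i
      while (ii >= 1L && s[ii] == s[i]) { n <- n + 1L; ii <- ii - 1L }
      n
    }, 0L)
    occ$n2 <- vapply(occ$i, function(i) {
      n <- 0L; ii <- i + 1L
      while (ii <= nt && s[ii] == s[i + 1L]) { n <- n + 1L; ii <- ii + 1L }
      n
    }, 0L)
    occ$self <- s[occ$i] == s[occ$i + 1L]
    # non-self occurrences contribute individually
    for (r in which(!occ$self)) {
      k <- occ$k[r]
      if (occ$i[r] >= 2L) pre_sum[k] <- pre_sum[k] + occ$n1[r]
      if (occ$i[r] <= nts - 1L) post_sum[k] <- post_sum[k] + occ$n2[r]
    }
    # self occurrences: one max value per block of consecutive occurrences
    selfocc <- occ[occ$self, , drop = FALSE]
    if (nrow(selfocc)) {
      blk <- cumsum(c(TRUE, diff(selfocc$i) != 1L |
                        diff(selfocc$k) != 0L))
      for (b in unique(blk)) {
        rows <- selfocc[blk == b, , drop = FALSE]
        k <- rows$k[1L]
        pre_ok <- rows$i >= 2L
        post_ok <- rows$i <= nts - 1L
        if (any(pre_ok)) pre_sum[k] <- pre_sum[k] + max(rows$n1[pre_ok])
        if (any(post_ok)) post_sum[k] <- post_sum[k] + max(rows$n2[post_ok])
      }
    }
  }
  list(tau_pre = ifelse(counts > 0L, pre_sum / counts / frame_rate, NA_real_),
       tau_post = ifelse(counts > 0L, post_sum / counts / frame_rate, NA_real_),
       counts = counts)
}

oracle_component_stats <- function(X, S, scheme = "GA") {
  nt <- nrow(S); nts <- nt - 1L; nv <- ncol(S)
  kmat <- matrix(0L, nts, nv)
  for (j in seq_len(nv)) for (i in seq_len(nts))
    kmat[i, j] <- 10L * (S[i, j] - 1L) + S[i + 1L, j]
  get_vals <- function(which) {
    lapply(1:100, function(k) {
      vals <- list()
      for (j in seq_len(nv)) for (i in seq_len(nts)) if (kmat[i, j] == k) {
        v <- switch(which, pre = X[i, j], post = X[i + 1L, j],
                    flux = X[i + 1L, j] - X[i, j])
        vals[[length(vals) + 1L]] <- c(v = v, i = i, j = j)
      }
      if (length(vals)) do.call(rbind, vals) else NULL
    })
  }
  summarize <- function(tab) {
    vapply(tab, function(m) {
      if (is.null(m)) return(NA_real_)
      if (scheme == "GA") return(mean(m[, "v"]))
      by <- if (scheme == "TMSM") m[, "i"] else m[, "j"]
      mean(tapply(m[, "v"], by, mean))
    }, 0)
  }
  list(mu_pre = summarize(get_vals("pre")),
       mu_post = summarize(get_vals("post")),
       flux = summarize(get_vals("flux")))
}
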