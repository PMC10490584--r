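# Independent brute-force oracles. Deliberately written as plain loops,
# straight from the definitions, sharing no code with the package.

# windowed mean by explicit looping
oracle_moving_mean <- function(v, frame) {
  n <- length(v)
  hl <- frame %/% 2
  hr <- (frame - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hl)
    hi <- min(n, i + hr)
    out[i] <- mean(v[lo:hi])
  }
  out
}

# exhaustive constrained-maxima search: enumerate strict local maxima, apply
# height/prominence thresholds, then repeatedly keep the tallest remaining
# candidate (ties: earliest) and discard everything nearer than min_distance
oracle_find_peaks <- function(v, min_distance, min_height = NULL,
                              min_prominence = NULL) {
  n <- length(v)
  cand <- c()
  for (i in seq_len(n)) {
    if (i > 1 && i < n && v[i] > v[i - 1] && v[i] > v[i + 1]) cand <- c(cand, i)
  }
  if (!is.null(min_height)) cand <- cand[v[cand] >= min_height]
  if (!is.null(min_prominence) && length(cand)) {
    prom <- sapply(cand, function(i) {
      left <- i; lmin <- v[i]
      while (left > 1 && v[left - 1] <= v[i]) {
        left <- left - 1
        lmin <- min(lmin, v[left])
      }
      right <- i; rmin <- v[i]
      while (right < n && v[right + 1] <= v[i]) {
        right <- right + 1
        rmin <- min(rmin, v[right])
      }
      v[i] - max(lmin, rmin)
    })
    cand <- cand[prom >= min_prominence]
  }
  kept <- c()
  while (length(cand)) {
    best <- cand[order(-v[cand], cand)][1]
    kept <- c(kept, best)
    cand <- cand[abs(cand - best) >= min_distance]
  }
  sort(kept)
}

# agreement metrics straight from the defining formulas
oracle_metrics <- function(r, c_) {
  n <- length(r)
  mae <- sum(abs(r - c_)) / n
  pe <- sum(abs(r - c_) / r) / n * 100
  nrmse <- sqrt(sum((r - c_)^2) / n) / (max(r) - min(r))
  mr <- sum(r) / n; mc <- sum(c_) / n
  rho_p <- sum((r - mr) * (c_ - mc)) /
    sqrt(sum((r - mr)^2) * sum((c_ - mc)^2))
  s_rc <- sum((r - mr) * (c_ - mc)) / n
  s_r2 <- sum((r - mr)^2) / n
  s_c2 <- sum((c_ - mc)^2) / n
  rho_c <- 2 * s_rc / (s_r2 + s_c2 + (mr - mc)^2)
  tstat <- rho_p * sqrt((n - 2) / (1 - rho_p^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(mae = mae, pe = pe, nrmse = nrmse, rho_p = rho_p, p_value = p,
       rho_c = rho_c)
}

# exhaustive beat matcher under the 140 ms / 320 ms window rules:
# repeatedly pair the globally closest (detected, reference) within 140 ms;
# leftover detections falling 140-320 ms after some reference are T waves;
# the rest are false positives; unpaired references are false negatives.
oracle_classify <- function(det, ref, tp_window = 0.140,
                            t_wave_window = 0.320) {
  used_d <- rep(FALSE, length(det))
  used_r <- rep(FALSE, length(ref))
  tp <- 0
  repeat {
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_along(det)) {
      if (used_d[i]) next
      for (j in seq_along(ref)) {
        if (used_r[j]) next
        d <- abs(det[i] - ref[j])
        if (d <= tp_window && d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    if (bi == 0) break
    used_d[bi] <- TRUE; used_r[bj] <- TRUE; tp <- tp + 1
  }
  tw <- 0; fp <- 0
  for (i in seq_along(det)) {
    if (used_d[i]) next
    is_tw <- FALSE
    for (j in seq_along(ref)) {
      lag <- det[i] - ref[j]
      if (lag > tp_window && lag <= t_wave_window) is_tw <- TRUE
    }
    if (is_tw) tw <- tw + 1 else fp <- fp + 1
  }
  list(tp = tp, fp = fp, t_wave = tw, fn = sum(!used_r))
}

# nearest-truth signed timing errors for a detected series
timing_errors <- function(detected, truth) {
  sapply(detected, function(d) {
    d - truth[which.min(abs(d - truth))]
  })
}
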