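# shared fixtures and independent oracles

# one trained smile model reused across tests (training is deterministic)
fixture_smile_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      train <- gen_smile_training_features(shift = 3, seed = 11)
      cache <<- train_smile_model(train[train$label == "happy", ],
                                  train[train$label == "neutral", ])
    }
    cache
  }
})

# build a full 66-point frame tibble from a coordinate matrix
frame_from_points <- function(pts, yaw = 0, pitch = 0, roll = 0) {
  out <- tibble::tibble(frame = 0L, t = 0)
  for (i in 0:65) out[[paste0("x", i)]] <- pts[i + 1, 1]
  for (i in 0:65) out[[paste0("y", i)]] <- pts[i + 1, 2]
  out$yaw <- yaw; out$pitch <- pitch; out$roll <- roll
  out
}

# oracle: decision function recomputed from first principles
oracle_decision <- function(model, features_row) {
  x <- as.numeric(features_row[names(model$weights)])
  z <- (x - model$feature_means) / model$feature_sds
  sum(z * model$weights) + model$bias
}

# oracle: per-frame F0 by direct (loop, lag-by-lag) autocorrelation peak picking
oracle_frame_f0 <- function(x, sr, frame_s = 0.04, hop_s = 0.01,
                            f0_min = 75, f0_max = 500) {
  frame_len <- round(frame_s * sr)
  hop <- round(hop_s * sr)
  starts <- seq(1, length(x) - frame_len + 1, by = hop)
  vapply(starts, function(s) {
    fr <- x[s:(s + frame_len - 1)]
    fr <- fr - mean(fr)
    if (sqrt(mean(fr^2)) < 1e-6) return(NA_real_)
    lags <- max(2, floor(sr / f0_max)):ceiling(sr / f0_min)
    ac <- vapply(lags, function(l) {
      sum(fr[1:(frame_len - l)] * fr[(l + 1):frame_len])
    }, numeric(1))
    best <- lags[which.max(ac)]
    sr / best
  }, numeric(1))
}

# oracle: OLS by explicit normal equations
oracle_ols <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(t(xm) %*% xm, t(xm) %*% y))
}

# oracle: comment selection by explicit sort
oracle_select <- function(z, canonical) {
  d <- abs(z)
  ord <- names(z)[order(d, match(names(z), canonical))]
  n <- length(z)
  list(positive = ord[1], improve = ord[max(2, floor((n + 1) / 2))])
}

# all permutations of 1..n as a matrix (n! rows)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

sine_clip <- function(freq = 220, duration = 1, sr = 16000, amp = 0.5) {
  audio_clip(amp * sin(2 * pi * freq * seq(0, duration, by = 1 / sr)[-1]), sr)
}
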