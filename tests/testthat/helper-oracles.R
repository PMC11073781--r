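# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals they check.

# SD-ROM reference: plain loop, explicit order() ranking, both thresholds
# checked one by one.
sdrom_reference <- function(x, t1, t2) {
  y <- x
  for (n in seq_along(x)) {
    if (n < 3 || n > length(x) - 2) next
    nb <- c(y[n - 2], y[n - 1], y[n + 1], y[n + 2])
    r <- nb[order(nb)]
    rom <- (r[2] + r[3]) / 2
    if (y[n] <= rom) {
      d1 <- r[1] - y[n]
      d2 <- r[2] - y[n]
    } else {
      d1 <- y[n] - r[4]
      d2 <- y[n] - r[3]
    }
    if (d1 > t1 || d2 > t2) y[n] <- rom
  }
  y
}

# Renewal-process peak counter: step through cumulative truncated-normal R-R
# sums one draw at a time, consuming the uniform stream sequentially.
renewal_count <- function(hr_mean, hr_sd, duration, fs) {
  rr_mean <- 60 / hr_mean
  rr_sd <- rr_mean * hr_sd / hr_mean
  p_lo <- pnorm(0.2, rr_mean, rr_sd)
  p_hi <- pnorm(2, rr_mean, rr_sd)
  t <- 0
  count <- 0L
  repeat {
    u <- runif(1)
    rr <- if (rr_sd == 0) rr_mean else qnorm(p_lo + u * (p_hi - p_lo), rr_mean, rr_sd)
    t <- t + rr
    if (t > duration - 1 / fs) break
    count <- count + 1L
  }
  count
}

# Build a labeled frame_set directly from an array, for detector tests.
make_frames <- function(x, labels, fs = 1000) {
  frame_len <- dim(x)[2]
  info <- tibble::tibble(
    frame = seq_len(dim(x)[1]),
    start = (seq_len(dim(x)[1]) - 1L) * frame_len + 1L,
    subject = "T01",
    label = as.integer(labels)
  )
  structure(list(x = x, info = info, fs = fs, frame_len = frame_len),
            class = "frame_set")
}

# Single-channel constant-spacing detection table for post-processing tests:
# frames of `frame_len` samples with given predictions/posteriors.
make_detections <- function(pred, p1, frame_len = 65L) {
  tibble::tibble(
    frame = seq_along(pred),
    start = (seq_along(pred) - 1L) * as.integer(frame_len) + 1L,
    subject = "T01",
    p1 = p1,
    pred = as.integer(pred)
  )
}
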