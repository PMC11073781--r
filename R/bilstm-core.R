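# Native bidirectional LSTM core. The input projection of every timestep is
# a single BLAS GEMM on the R side; the sequential recurrence (gates, cell
# state, and their adjoints) runs in the compiled kernels of
# src/lstm_kernels.cpp. Gate order within stacked weights is i, f, g, o
# (input, forget, cell candidate, output); one parameter block per direction.
#
# Layout: a [B, T, D] sequence batch is handled as its column-major flattening
# `matrix(X, B*T, D)`, whose row block ((t-1)*B + 1):(t*B) is timestep t.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# One LSTM direction's parameters: Wx (4H x D), Wh (4H x H), b (4H) with unit
# forget-gate bias.
init_lstm_dir <- function(input_dim, hidden) {
  b <- numeric(4 * hidden)
  b[hidden + seq_len(hidden)] <- 1
  list(
    Wx = glorot(4 * hidden, input_dim, input_dim, 4 * hidden),
    Wh = glorot(4 * hidden, hidden, hidden, 4 * hidden),
    b = b
  )
}

init_bilstm_params <- function(input_dim, hidden, n_classes = 2) {
  layers <- vector("list", length(hidden))
  d <- input_dim
  for (l in seq_along(hidden)) {
    layers[[l]] <- list(fwd = init_lstm_dir(d, hidden[l]),
                        bwd = init_lstm_dir(d, hidden[l]))
    d <- 2 * hidden[l]
  }
  fc_in <- 2 * hidden[length(hidden)]
  list(layers = layers,
       fc = list(W = glorot(n_classes, fc_in, fc_in, n_classes),
                 b = numeric(n_classes)))
}

# Full network forward over a [B, T, D] batch: stacked BiLSTM layers with
# inter-layer dropout, sequence-to-label head on the concatenated final
# states (forward direction at t = T, backward direction at t = 1), softmax.
bilstm_forward <- function(X3, params, dropout = numeric(0), training = FALSE,
                           keep_cache = TRUE) {
  n_layers <- length(params$layers)
  d <- dim(X3); B <- d[1]; T_ <- d[2]
  inflat <- matrix(X3, B * T_, d[3])
  acts <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    par <- params$layers[[l]]
    H <- length(par$fwd$b) / 4
    fw <- lstm_seq_forward(inflat %*% t(par$fwd$Wx), par$fwd$Wh, par$fwd$b,
                           B, T_, FALSE, keep_cache)
    bw <- lstm_seq_forward(inflat %*% t(par$bwd$Wx), par$bwd$Wh, par$bwd$b,
                           B, T_, TRUE, keep_cache)
    Y <- cbind(fw$H, bw$H)
    mask <- NULL
    if (training && l <= length(dropout) && dropout[l] > 0) {
      mask <- matrix((runif(length(Y)) >= dropout[l]) / (1 - dropout[l]),
                     nrow(Y), ncol(Y))
      Y <- Y * mask
    }
    acts[[l]] <- list(input = inflat, fwd = fw, bwd = bw, mask = mask, H = H)
    inflat <- Y
  }
  H_last <- acts[[n_layers]]$H
  rows_T <- (T_ - 1L) * B + seq_len(B)
  rows_1 <- seq_len(B)
  s <- cbind(inflat[rows_T, seq_len(H_last), drop = FALSE],
             inflat[rows_1, H_last + seq_len(H_last), drop = FALSE])
  logits <- s %*% t(params$fc$W) + rep(params$fc$b, each = B)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  list(p = p, logits = logits, s = s, acts = acts, B = B, T_ = T_)
}

# Weighted cross-entropy loss and its gradient on the logits:
# L = mean_i( w[y_i] * -log p[i, y_i] )
weighted_ce <- function(p, y, w) {
  B <- nrow(p)
  idx <- cbind(seq_len(B), y + 1L)
  wi <- w[y + 1L]
  nll <- -log(pmax(p[idx], 1e-12))
  loss <- mean(wi * nll)
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (wi / B)
  list(loss = loss, dlogits = dlogits)
}

bilstm_backward <- function(fwdpass, dlogits, params) {
  acts <- fwdpass$acts
  n_layers <- length(acts)
  B <- fwdpass$B; T_ <- fwdpass$T_
  g_fc <- list(W = crossprod(dlogits, fwdpass$s), b = colSums(dlogits))
  ds <- dlogits %*% params$fc$W
  H_last <- acts[[n_layers]]$H
  dY <- matrix(0, B * T_, 2 * H_last)
  rows_T <- (T_ - 1L) * B + seq_len(B)
  dY[rows_T, seq_len(H_last)] <- ds[, seq_len(H_last)]
  dY[seq_len(B), H_last + seq_len(H_last)] <- ds[, H_last + seq_len(H_last)]
  g_layers <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    a <- acts[[l]]
    if (!is.null(a$mask)) dY <- dY * a$mask
    H <- a$H
    par <- params$layers[[l]]
    bk_f <- lstm_seq_backward(dY[, seq_len(H), drop = FALSE], a$fwd$H,
                              a$fwd$G, a$fwd$c_prev, a$fwd$tc,
                              par$fwd$Wh, B, T_, FALSE)
    bk_b <- lstm_seq_backward(dY[, H + seq_len(H), drop = FALSE], a$bwd$H,
                              a$bwd$G, a$bwd$c_prev, a$bwd$tc,
                              par$bwd$Wh, B, T_, TRUE)
    g_layers[[l]] <- list(
      fwd = list(Wx = crossprod(bk_f$dM, a$input), Wh = bk_f$dWh,
                 b = as.numeric(bk_f$db)),
      bwd = list(Wx = crossprod(bk_b$dM, a$input), Wh = bk_b$dWh,
                 b = as.numeric(bk_b$db))
    )
    dY <- bk_f$dM %*% par$fwd$Wx + bk_b$dM %*% par$bwd$Wx
  }
  list(layers = g_layers, fc = g_fc)
}

# -- flat parameter plumbing for the optimizer -------------------------------

flatten_params <- function(params) {
  out <- list()
  for (l in seq_along(params$layers)) {
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Wx", "Wh", "b")) {
        out[[sprintf("l%d_%s_%s", l, dir, nm)]] <- params$layers[[l]][[dir]][[nm]]
      }
    }
  }
  out$fc_W <- params$fc$W
  out$fc_b <- params$fc$b
  out
}

unflatten_params <- function(flat, template) {
  for (l in seq_along(template$layers)) {
    for (dir in c("fwd", "bwd")) {
      for (nm in c("Wx", "Wh", "b")) {
        template$layers[[l]][[dir]][[nm]] <- flat[[sprintf("l%d_%s_%s", l, dir, nm)]]
      }
    }
  }
  template$fc$W <- flat$fc_W
  template$fc$b <- flat$fc_b
  template
}

# Global L2-norm gradient clipping.
clip_global_norm <- function(flat_grads, threshold) {
  total <- sqrt(sum(vapply(flat_grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > threshold) {
    flat_grads <- lapply(flat_grads, function(g) g * (threshold / total))
  }
  flat_grads
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = flat, state = state)
}
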