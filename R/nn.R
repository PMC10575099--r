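# Minimal neural-network primitives for the stress forecaster: 1-D
# convolution, LSTM, (bi)GRU, additive attention, dense layers, Adam.
# Sequences are lists of T matrices (batch x features).  All backward passes
# are analytic and verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

rowvec <- function(v, B) matrix(v, B, length(v), byrow = TRUE)

## ---- dense ----------------------------------------------------------------

dense_init <- function(fin, fout) list(W = glorot(fin, fout), b = numeric(fout))

dense_forward <- function(x, p, act = c("linear", "relu", "tanh")) {
  act <- match.arg(act)
  a <- x %*% p$W + rowvec(p$b, nrow(x))
  h <- switch(act, linear = a, relu = pmax(a, 0), tanh = tanh(a))
  list(out = h, cache = list(x = x, a = a, h = h, act = act, p = p))
}

dense_backward <- function(dout, cache) {
  da <- switch(cache$act,
               linear = dout,
               relu = dout * (cache$a > 0),
               tanh = dout * (1 - cache$h^2))
  list(dx = da %*% t(cache$p$W),
       dW = t(cache$x) %*% da,
       db = colSums(da))
}

## ---- 1-D convolution over time (valid padding, ReLU) ----------------------

conv1d_init <- function(fin, channels, kernel) {
  list(W = lapply(seq_len(kernel), function(j) glorot(fin, channels)),
       b = numeric(channels))
}

conv1d_forward <- function(seq, p) {
  Tn <- length(seq)
  k <- length(p$W)
  stopifnot(Tn >= k)
  B <- nrow(seq[[1]])
  out <- vector("list", Tn - k + 1)
  pre <- vector("list", Tn - k + 1)
  for (t in seq_along(out)) {
    a <- rowvec(p$b, B)
    for (j in seq_len(k)) a <- a + seq[[t + j - 1]] %*% p$W[[j]]
    pre[[t]] <- a
    out[[t]] <- pmax(a, 0)
  }
  list(out = out, cache = list(seq = seq, pre = pre, p = p))
}

conv1d_backward <- function(dout, cache) {
  p <- cache$p
  k <- length(p$W)
  Tn <- length(cache$seq)
  dW <- lapply(p$W, function(w) w * 0)
  db <- numeric(length(p$b))
  dseq <- lapply(cache$seq, function(m) m * 0)
  for (t in seq_along(dout)) {
    da <- dout[[t]] * (cache$pre[[t]] > 0)
    db <- db + colSums(da)
    for (j in seq_len(k)) {
      dW[[j]] <- dW[[j]] + t(cache$seq[[t + j - 1]]) %*% da
      dseq[[t + j - 1]] <- dseq[[t + j - 1]] + da %*% t(p$W[[j]])
    }
  }
  list(dseq = dseq, dW = dW, db = db)
}

## ---- LSTM ------------------------------------------------------------------

lstm_init <- function(fin, hidden) {
  p <- list(Wx = glorot(fin, 4 * hidden), Wh = glorot(hidden, 4 * hidden),
            b = numeric(4 * hidden))
  p$b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias
  p
}

lstm_forward <- function(seq, p) {
  H <- nrow(p$Wh)
  B <- nrow(seq[[1]])
  h <- matrix(0, B, H); c0 <- matrix(0, B, H)
  Tn <- length(seq)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- seq[[t]] %*% p$Wx + h %*% p$Wh + rowvec(p$b, B)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(a[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c1 <- f * c0 + i * g
    tc <- tanh(c1)
    h1 <- o * tc
    cache[[t]] <- list(x = seq[[t]], h_prev = h, c_prev = c0,
                       i = i, f = f, o = o, g = g, c = c1, tc = tc)
    h <- h1; c0 <- c1
    hs[[t]] <- h
  }
  list(out = hs, cache = list(steps = cache, p = p))
}

lstm_backward <- function(dhs, cache) {
  p <- cache$p
  H <- nrow(p$Wh)
  steps <- cache$steps
  Tn <- length(steps)
  B <- nrow(dhs[[Tn]])
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- numeric(4 * H)
  dseq <- vector("list", Tn)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    dh <- dhs[[t]] + dh_next
    do <- dh * s$tc
    dc <- dh * s$o * (1 - s$tc^2) + dc_next
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dc_next <- dc * s$f
    da <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    dWx <- dWx + t(s$x) %*% da
    dWh <- dWh + t(s$h_prev) %*% da
    db <- db + colSums(da)
    dseq[[t]] <- da %*% t(p$Wx)
    dh_next <- da %*% t(p$Wh)
  }
  list(dseq = dseq, dWx = dWx, dWh = dWh, db = db)
}

## ---- GRU -------------------------------------------------------------------

gru_init <- function(fin, hidden) {
  list(Wxz = glorot(fin, hidden), Wxr = glorot(fin, hidden),
       Wxh = glorot(fin, hidden),
       Whz = glorot(hidden, hidden), Whr = glorot(hidden, hidden),
       U = glorot(hidden, hidden),
       bz = numeric(hidden), br = numeric(hidden), bh = numeric(hidden))
}

#' Single GRU cell step
#'
#' Gated recurrent update: update gate \eqn{z_t} and reset gate \eqn{r_t}
#' are sigmoid-gated affine maps of the input and previous state; the
#' candidate \eqn{\tilde h_t = \tanh(W_{xh} x + U (r_t \odot h_{t-1}) + b_h)};
#' the new state is the convex combination
#' \eqn{h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t}.
#'
#' @param x_t Input vector (or 1-row matrix) of length `fin`.
#' @param h_prev Previous hidden state of length `hidden`.
#' @param params List with matrices `Wxz`, `Wxr`, `Wxh` (fin x hidden),
#'   `Whz`, `Whr`, `U` (hidden x hidden) and biases `bz`, `br`, `bh`.
#' @return Hidden-state vector `h_t` of length `hidden`.
#' @export
gru_step <- function(x_t, h_prev, params) {
  x <- matrix(as.numeric(x_t), nrow = 1)
  h <- matrix(as.numeric(h_prev), nrow = 1)
  if (ncol(x) != nrow(params$Wxz) || ncol(h) != nrow(params$Whz)) {
    stop("gru_step: dimension mismatch between inputs and parameters", call. = FALSE)
  }
  z <- sigmoid(x %*% params$Wxz + h %*% params$Whz + rowvec(params$bz, 1))
  r <- sigmoid(x %*% params$Wxr + h %*% params$Whr + rowvec(params$br, 1))
  hc <- tanh(x %*% params$Wxh + (r * h) %*% params$U + rowvec(params$bh, 1))
  as.numeric((1 - z) * h + z * hc)
}

gru_forward <- function(seq, p) {
  H <- nrow(p$Whz)
  B <- nrow(seq[[1]])
  h <- matrix(0, B, H)
  Tn <- length(seq)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- seq[[t]]
    z <- sigmoid(x %*% p$Wxz + h %*% p$Whz + rowvec(p$bz, B))
    r <- sigmoid(x %*% p$Wxr + h %*% p$Whr + rowvec(p$br, B))
    hc <- tanh(x %*% p$Wxh + (r * h) %*% p$U + rowvec(p$bh, B))
    h1 <- (1 - z) * h + z * hc
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, hc = hc)
    h <- h1
    hs[[t]] <- h
  }
  list(out = hs, cache = list(steps = cache, p = p))
}

gru_backward <- function(dhs, cache) {
  p <- cache$p
  H <- nrow(p$Whz)
  steps <- cache$steps
  Tn <- length(steps)
  B <- nrow(dhs[[Tn]])
  g <- list(dWxz = p$Wxz * 0, dWxr = p$Wxr * 0, dWxh = p$Wxh * 0,
            dWhz = p$Whz * 0, dWhr = p$Whr * 0, dU = p$U * 0,
            dbz = numeric(H), dbr = numeric(H), dbh = numeric(H))
  dseq <- vector("list", Tn)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    s <- steps[[t]]
    dh <- dhs[[t]] + dh_next
    dz <- dh * (s$hc - s$h_prev)
    dhc <- dh * s$z
    dh_prev <- dh * (1 - s$z)
    dah <- dhc * (1 - s$hc^2)
    drh <- dah %*% t(p$U)
    dr <- drh * s$h_prev
    dh_prev <- dh_prev + drh * s$r
    daz <- dz * s$z * (1 - s$z)
    dar <- dr * s$r * (1 - s$r)
    dx <- dah %*% t(p$Wxh) + daz %*% t(p$Wxz) + dar %*% t(p$Wxr)
    dh_prev <- dh_prev + daz %*% t(p$Whz) + dar %*% t(p$Whr)
    g$dWxz <- g$dWxz + t(s$x) %*% daz
    g$dWxr <- g$dWxr + t(s$x) %*% dar
    g$dWxh <- g$dWxh + t(s$x) %*% dah
    g$dWhz <- g$dWhz + t(s$h_prev) %*% daz
    g$dWhr <- g$dWhr + t(s$h_prev) %*% dar
    g$dU <- g$dU + t(s$r * s$h_prev) %*% dah
    g$dbz <- g$dbz + colSums(daz)
    g$dbr <- g$dbr + colSums(dar)
    g$dbh <- g$dbh + colSums(dah)
    dseq[[t]] <- dx
    dh_next <- dh_prev
  }
  c(list(dseq = dseq), g)
}

## ---- BiGRU -----------------------------------------------------------------

bigru_init <- function(fin, hidden) {
  list(fwd = gru_init(fin, hidden), bwd = gru_init(fin, hidden))
}

bigru_forward <- function(seq, p) {
  f <- gru_forward(seq, p$fwd)
  b <- gru_forward(rev(seq), p$bwd)
  Tn <- length(seq)
  hs <- lapply(seq_len(Tn), function(t) cbind(f$out[[t]], b$out[[Tn - t + 1]]))
  list(out = hs, cache = list(f = f$cache, b = b$cache,
                              hidden = nrow(p$fwd$Whz)))
}

bigru_backward <- function(dhs, cache) {
  H <- cache$hidden
  Tn <- length(dhs)
  dfwd <- lapply(dhs, function(m) m[, 1:H, drop = FALSE])
  dbwd <- rev(lapply(dhs, function(m) m[, (H + 1):(2 * H), drop = FALSE]))
  gf <- gru_backward(dfwd, cache$f)
  gb <- gru_backward(dbwd, cache$b)
  dseq <- lapply(seq_len(Tn), function(t) gf$dseq[[t]] + gb$dseq[[Tn - t + 1]])
  list(dseq = dseq, fwd = gf[-1], bwd = gb[-1])
}

#' Bidirectional GRU encoding of a sequence
#'
#' Runs a forward GRU over t = 1..T and a backward GRU over t = T..1 and
#' concatenates the two hidden states at each position.
#'
#' @param sequence A numeric matrix (T x features) or list of row vectors.
#' @param params List with elements `fwd` and `bwd`, each a GRU parameter
#'   set as in [gru_step()], sharing the same hidden size.
#' @return A T x (2 * hidden) matrix of concatenated hidden states.
#' @export
bigru_encode <- function(sequence, params) {
  if (is.matrix(sequence)) {
    sequence <- lapply(seq_len(nrow(sequence)),
                       function(t) sequence[t, , drop = FALSE])
  }
  if (length(sequence) == 0) stop("bigru_encode: empty sequence", call. = FALSE)
  out <- bigru_forward(sequence, params)$out
  do.call(rbind, out)
}

## ---- attention -------------------------------------------------------------

#' Normalized attention weights from alignment scores
#'
#' Softmax of a score vector: strictly positive weights summing to 1,
#' invariant to adding a constant to all scores.
#'
#' @param scores Nonempty numeric vector of alignment scores.
#' @return Numeric vector of weights summing to 1.
#' @export
attention_weights <- function(scores) {
  if (length(scores) == 0) stop("attention_weights: empty scores", call. = FALSE)
  e <- exp(scores - max(scores))
  e / sum(e)
}

attention_init <- function(hidden, att_dim) {
  list(Wa = glorot(hidden, att_dim), Ua = glorot(hidden, att_dim),
       ba = numeric(att_dim), v = glorot(att_dim, 1))
}

# Additive attention over encoder states hs (list of B x H), query = hs[[T]].
# e_t = v' tanh(W h_t + U h_T + b); context = sum_t softmax(e)_t h_t.
attention_forward <- function(hs, p) {
  Tn <- length(hs)
  B <- nrow(hs[[1]])
  q <- hs[[Tn]]
  qU <- q %*% p$Ua
  tanhv <- vector("list", Tn)
  E <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    tv <- tanh(hs[[t]] %*% p$Wa + qU + rowvec(p$ba, B))
    tanhv[[t]] <- tv
    E[, t] <- tv %*% p$v
  }
  Em <- E - apply(E, 1, max)
  A <- exp(Em)
  A <- A / rowSums(A)
  ctx <- matrix(0, B, ncol(hs[[1]]))
  for (t in seq_len(Tn)) ctx <- ctx + A[, t] * hs[[t]]
  list(out = ctx, cache = list(hs = hs, tanhv = tanhv, A = A, p = p))
}

attention_backward <- function(dctx, cache) {
  p <- cache$p
  hs <- cache$hs
  A <- cache$A
  Tn <- length(hs)
  B <- nrow(dctx)
  dhs <- lapply(hs, function(m) m * 0)
  dA <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    dA[, t] <- rowSums(dctx * hs[[t]])
    dhs[[t]] <- dhs[[t]] + A[, t] * dctx
  }
  dE <- A * (dA - rowSums(dA * A))
  dWa <- p$Wa * 0; dUa <- p$Ua * 0; dba <- numeric(length(p$ba)); dv <- p$v * 0
  dq <- matrix(0, B, nrow(p$Ua))
  for (t in seq_len(Tn)) {
    tv <- cache$tanhv[[t]]
    dtv <- (dE[, t] %*% t(p$v)) * (1 - tv^2)    # B x A
    dv <- dv + t(tv) %*% dE[, t, drop = FALSE]
    dWa <- dWa + t(hs[[t]]) %*% dtv
    dUa <- dUa + t(hs[[Tn]]) %*% dtv
    dba <- dba + colSums(dtv)
    dhs[[t]] <- dhs[[t]] + dtv %*% t(p$Wa)
    dq <- dq + dtv %*% t(p$Ua)
  }
  dhs[[Tn]] <- dhs[[Tn]] + dq
  list(dhs = dhs, dWa = dWa, dUa = dUa, dba = dba, dv = dv)
}

## ---- parameter flattening + Adam -------------------------------------------

# Walk a nested list of numeric arrays, applying f(leaf_a, leaf_b) pairwise.
map_leaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.numeric(a[[nm]]) && length(a[[nm]]) && !is.list(a[[nm]])) {
        out[[nm]] <- f(a[[nm]], b[[nm]])
      } else if (is.list(a[[nm]])) {
        out[[nm]] <- map_leaves(a[[nm]], b[[nm]], f)
      }
    }
    out
  } else f(a, b)
}

leaf_apply <- function(a, f) map_leaves(a, a, function(x, y) f(x))

sum_leaves <- function(a, f) {
  tot <- 0
  walk <- function(x) {
    for (el in x) {
      if (is.list(el)) walk(el)
      else if (is.numeric(el) && length(el)) tot <<- tot + f(el)
    }
  }
  walk(a)
  tot
}

adam_state <- function(params) {
  list(m = leaf_apply(params, function(x) x * 0),
       v = leaf_apply(params, function(x) x * 0),
       t = 0)
}

adam_update <- function(params, grads, state, lr = 1e-2,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- map_leaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_leaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- map_leaves(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map_leaves(params, step, function(p, s) p - s)
  list(params = params, state = state)
}

clip_grads <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum_leaves(grads, function(x) sum(x^2)))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- leaf_apply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}
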