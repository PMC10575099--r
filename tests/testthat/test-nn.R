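ns <- asNamespace("aquavital")

test_that("attention weights are a proper softmax", {
  expect_equal(attention_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(attention_weights(c(0, log(2))), c(1 / 3, 2 / 3))
  # shift invariance and permutation equivariance
  s <- c(0.3, -1.2, 2.0, 0.7)
  expect_equal(attention_weights(s), attention_weights(s + 10))
  perm <- c(3, 1, 4, 2)
  expect_equal(attention_weights(s)[perm], attention_weights(s[perm]))
  expect_equal(sum(attention_weights(rnorm(9))), 1)
  expect_error(attention_weights(numeric(0)), "empty")
})

test_that("the GRU step is a convex gated update with exact closed forms", {
  H <- 3; Fin <- 2
  zero <- list(Wxz = matrix(0, Fin, H), Wxr = matrix(0, Fin, H),
               Wxh = matrix(0, Fin, H), Whz = matrix(0, H, H),
               Whr = matrix(0, H, H), U = matrix(0, H, H),
               bz = numeric(H), br = numeric(H), bh = numeric(H))
  h_prev <- c(0.4, -0.6, 1.0)
  # zero weights and biases: z = r = 1/2, candidate 0, h -> h_prev / 2
  expect_equal(gru_step(c(1, 2), h_prev, zero), h_prev / 2)

  # saturated update gate closed (z ~ 0): state unchanged
  p <- zero; p$bz <- rep(-50, H)
  expect_equal(gru_step(c(1, 2), h_prev, p), h_prev, tolerance = 1e-12)
  # saturated open (z ~ 1): state jumps to the candidate (here 0)
  p$bz <- rep(50, H)
  expect_equal(gru_step(c(1, 2), h_prev, p), rep(0, H), tolerance = 1e-12)

  # convexity: h_t lies componentwise between h_prev and the tanh-bounded
  # candidate for random parameters
  set.seed(7)
  p <- ns$gru_init(Fin, H)
  h1 <- gru_step(rnorm(Fin), h_prev, p)
  expect_true(all(h1 >= pmin(h_prev, -1) - 1e-12 &
                    h1 <= pmax(h_prev, 1) + 1e-12))
  expect_error(gru_step(c(1, 2, 3), h_prev, p), "dimension mismatch")
})

test_that("bigru_encode matches a hand-rolled two-pass evaluation", {
  set.seed(11)
  Fin <- 2; H <- 3; Tn <- 3
  p <- ns$bigru_init(Fin, H)
  xs <- matrix(rnorm(Tn * Fin), Tn, Fin)
  enc <- bigru_encode(xs, p)
  expect_equal(dim(enc), c(Tn, 2 * H))

  # oracle: independent step-by-step forward and backward passes
  hf <- numeric(H); fw <- matrix(0, Tn, H)
  for (t in 1:Tn) { hf <- gru_step(xs[t, ], hf, p$fwd); fw[t, ] <- hf }
  hb <- numeric(H); bw <- matrix(0, Tn, H)
  for (t in Tn:1) { hb <- gru_step(xs[t, ], hb, p$bwd); bw[t, ] <- hb }
  expect_equal(enc, cbind(fw, bw), tolerance = 1e-12)

  # T = 1: both directions see the single input
  one <- bigru_encode(xs[1, , drop = FALSE], p)
  expect_equal(one[1, 1:H], gru_step(xs[1, ], numeric(H), p$fwd))
  expect_equal(one[1, (H + 1):(2 * H)], gru_step(xs[1, ], numeric(H), p$bwd))

  # palindromic input with shared parameters: forward == reversed backward
  p2 <- p; p2$bwd <- p2$fwd
  pal <- rbind(xs[1, ], xs[2, ], xs[1, ])
  enc2 <- bigru_encode(pal, p2)
  expect_equal(enc2[, 1:H], enc2[rev(seq_len(3)), (H + 1):(2 * H)],
               tolerance = 1e-12)

  expect_error(bigru_encode(list(), p), "empty")
})

test_that("analytic gradients match finite differences in every architecture", {
  set.seed(42)
  archs <- list(
    hybrid_stage1 = ns$make_arch(cnn = list(channels = 4, kernel = 3),
                                 rnn = "lstm", layers = 2, hidden = 5,
                                 attention = TRUE, dense = 4),
    hybrid_stage2 = ns$make_arch(cnn = NULL, rnn = "bigru", layers = 2,
                                 hidden = 4, attention = TRUE, dense = c(5, 3)),
    lstm_baseline = ns$make_arch(cnn = NULL, rnn = "lstm", layers = 1,
                                 hidden = 4, attention = FALSE, dense = 3),
    gru_baseline = ns$make_arch(cnn = NULL, rnn = "gru", layers = 2,
                                hidden = 4, attention = FALSE, dense = 3))
  for (nm in names(archs)) {
    arch <- archs[[nm]]
    B <- 3; Tn <- 7; Fn <- 3
    x <- array(rnorm(B * Tn * Fn), c(B, Tn, Fn))
    y <- rnorm(B)
    params <- ns$init_net(arch, Fn)
    seqb <- ns$seq_from_array(x, 1:B)
    fw <- ns$net_forward(params, arch, seqb)
    grads <- ns$net_backward(params, arch, fw$caches, 2 * (fw$yhat - y) / B)

    sk <- utils::as.relistable(params)
    v0 <- unlist(sk)
    gv <- unlist(grads)
    expect_length(gv, length(v0))
    loss <- function(vec) {
      f <- ns$net_forward(utils::relist(vec, sk), arch, seqb)
      mean((f$yhat - y)^2)
    }
    eps <- 1e-5
    idxs <- sample(length(v0), 20)
    num <- vapply(idxs, function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (loss(vp) - loss(vm)) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - gv[idxs]) / pmax(1e-6, abs(num) + abs(gv[idxs]))
    expect_lt(max(rel), 1e-4)
  }
})
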