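# shared fixtures, memoized so expensive objects build once per run
.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

tiny_inventory <- function() memo("tiny_inv", build_inventory(seed = 3))

tiny_lexicon <- function() {
  memo("tiny_lex",
       generate_lexicon(tiny_inventory(), seed = 3, n_hf = 15, n_lf = 15,
                        n_nonwords = 8))
}

toy_state <- function(n_left = 3, n_right = 3, n_io = 4, seed = 7, ...) {
  init_network(network_config(n_left = n_left, n_right = n_right,
                              n_io = n_io, seed = seed, ...))
}

# a small trained model on the tiny lexicon, shared across tests
tiny_trained <- function() {
  memo("tiny_trained", {
    st <- init_network(network_config(n_left = 12, n_right = 6, seed = 2,
                                      learning_rate = 0.02))
    set.seed(2)
    train(st, tiny_lexicon(), tiny_inventory(), n_presentations = 20000,
          eval_every = 20000)
  })
}

weight_fields <- function(state) {
  state[grep("^(W_|b_)", names(state), value = TRUE)]
}

logistic <- function(x) 1 / (1 + exp(-x))

# Plain-R reference forward pass, written independently of the C++ core:
# the dual-route check for activations and the basis of the FD oracles.
ref_forward <- function(state, feats, silence = "none") {
  nL <- state$config$n_left; nR <- state$config$n_right
  nio <- state$config$n_io
  g <- state$gain
  p_l1 <- rep(0, nL); p_r1 <- rep(0, nR)
  p_l2 <- rep(0, nL); p_r2 <- rep(0, nR)
  out <- list(l1 = NULL, r1 = NULL, l2 = NULL, r2 = NULL, out = NULL)
  for (t in 1:6) {
    x <- if (t <= 3) feats[t, ] else rep(0, nio)
    net_l1 <- state$b_l1 + drop(p_l1 %*% state$W_ctx_l) +
      drop(p_r1 %*% state$W_x1_rl)
    if (silence != "left") net_l1 <- net_l1 + drop(x %*% state$W_in_l)
    net_r1 <- state$b_r1 + drop(p_r1 %*% state$W_ctx_r) +
      drop(p_l1 %*% state$W_x1_lr)
    if (silence != "right") net_r1 <- net_r1 + drop(x %*% state$W_in_r)
    a_l1 <- logistic(g["LH1"] * net_l1) * state$alive_l1
    a_r1 <- logistic(g["RH1"] * net_r1) * state$alive_r1
    a_l2 <- logistic(g["LH2"] * (state$b_l2 + drop(a_l1 %*% state$W_12_l) +
                                   drop(p_r2 %*% state$W_x2_rl))) * state$alive_l2
    a_r2 <- logistic(g["RH2"] * (state$b_r2 + drop(a_r1 %*% state$W_12_r) +
                                   drop(p_l2 %*% state$W_x2_lr))) * state$alive_r2
    a_out <- logistic(state$b_out + drop(a_l2 %*% state$W_out_l) +
                        drop(a_r2 %*% state$W_out_r))
    out$l1 <- rbind(out$l1, a_l1); out$r1 <- rbind(out$r1, a_r1)
    out$l2 <- rbind(out$l2, a_l2); out$r2 <- rbind(out$r2, a_r2)
    out$out <- rbind(out$out, a_out)
    p_l1 <- a_l1; p_r1 <- a_r1; p_l2 <- a_l2; p_r2 <- a_r2
  }
  out
}

ref_loss <- function(state, feats) {
  out <- ref_forward(state, feats)$out
  o <- pmin(pmax(out[4:6, , drop = FALSE], 1e-12), 1 - 1e-12)
  -sum(feats * log(o) + (1 - feats) * log(1 - o))
}

# Loss with the context / delayed-cross inputs frozen at the activations of
# the unperturbed run `A`; the truncated gradient is this function's exact
# gradient.
frozen_loss <- function(state, feats, A) {
  nio <- state$config$n_io
  g <- state$gain
  loss <- 0
  for (t in 1:6) {
    x <- if (t <= 3) feats[t, ] else rep(0, nio)
    p_l1 <- if (t > 1) A$l1[t - 1, ] else rep(0, ncol(A$l1))
    p_r1 <- if (t > 1) A$r1[t - 1, ] else rep(0, ncol(A$r1))
    p_l2 <- if (t > 1) A$l2[t - 1, ] else rep(0, ncol(A$l2))
    p_r2 <- if (t > 1) A$r2[t - 1, ] else rep(0, ncol(A$r2))
    a_l1 <- logistic(g["LH1"] * (state$b_l1 + drop(x %*% state$W_in_l) +
                                   drop(p_l1 %*% state$W_ctx_l) +
                                   drop(p_r1 %*% state$W_x1_rl))) * state$alive_l1
    a_r1 <- logistic(g["RH1"] * (state$b_r1 + drop(x %*% state$W_in_r) +
                                   drop(p_r1 %*% state$W_ctx_r) +
                                   drop(p_l1 %*% state$W_x1_lr))) * state$alive_r1
    a_l2 <- logistic(g["LH2"] * (state$b_l2 + drop(a_l1 %*% state$W_12_l) +
                                   drop(p_r2 %*% state$W_x2_rl))) * state$alive_l2
    a_r2 <- logistic(g["RH2"] * (state$b_r2 + drop(a_r1 %*% state$W_12_r) +
                                   drop(p_l2 %*% state$W_x2_lr))) * state$alive_r2
    a_out <- logistic(state$b_out + drop(a_l2 %*% state$W_out_l) +
                        drop(a_r2 %*% state$W_out_r))
    if (t > 3) {
      o <- pmin(pmax(a_out, 1e-12), 1 - 1e-12)
      tau <- feats[t - 3, ]
      loss <- loss - sum(tau * log(o) + (1 - tau) * log(1 - o))
    }
  }
  loss
}

# central finite differences of a scalar loss over every entry of the named
# weight blocks; returns per-block max of |num - ana| scaled by the block's
# gradient norm
gradcheck <- function(state, feats, truncated = FALSE, h = 1e-5) {
  g <- bisrn:::.srn_grads_cpp(state, feats, truncated)
  A <- if (truncated) ref_forward(state, feats) else NULL
  loss_fn <- if (truncated) {
    function(s) frozen_loss(s, feats, A)
  } else {
    function(s) ref_loss(s, feats)
  }
  blocks <- setdiff(names(g), "loss")
  vapply(blocks, function(b) {
    w <- state[[b]]
    num <- vapply(seq_along(w), function(i) {
      sp <- state; sp[[b]][i] <- w[i] + h
      sm <- state; sm[[b]][i] <- w[i] - h
      (loss_fn(sp) - loss_fn(sm)) / (2 * h)
    }, numeric(1))
    ana <- as.numeric(g[[b]])
    denom <- sqrt(sum(num^2)) + sqrt(sum(ana^2))
    if (denom < 1e-10) return(max(abs(num - ana)))
    sqrt(sum((num - ana)^2)) / denom
  }, numeric(1))
}

random_feats <- function(inventory, seed = 1) {
  with_seed_local(seed, {
    cons <- inventory$symbols[inventory$klass == "consonant"]
    vows <- inventory$symbols[inventory$klass == "vowel"]
    encode(c(sample(cons, 1), sample(vows, 1), sample(cons, 1)), inventory)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
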