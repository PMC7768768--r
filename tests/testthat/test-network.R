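test_that("initialization obeys the config and is deterministic", {
  cfg <- network_config(n_left = 60, n_right = 30, seed = 4)
  st <- init_network(cfg)
  expect_equal(dim(st$W_in_l), c(25, 60))
  expect_equal(dim(st$W_in_r), c(25, 30))
  expect_equal(dim(st$W_ctx_l), c(60, 60))
  expect_equal(dim(st$W_12_r), c(30, 30))
  expect_equal(dim(st$W_out_l), c(60, 25))
  expect_true(all(abs(st$W_in_l) <= cfg$init_range))
  # zero density: no cross connections at all
  expect_true(all(st$M_x1_lr == 0) && all(st$W_x1_lr == 0))
  expect_identical(init_network(cfg), st)
  expect_equal(unname(st$gain), rep(1, 4))
  expect_true(all(st$alive_l1 == 1))
  # uniform init: mean |w| approaches init_range / 2
  expect_equal(mean(abs(st$W_ctx_l)), cfg$init_range / 2,
               tolerance = 0.05)
})

test_that("cross-connection masks follow the requested density and constraint", {
  st <- toy_state(n_left = 40, n_right = 40, cross_density = 0.3, seed = 11)
  dens <- mean(c(st$M_x1_lr, st$M_x1_rl, st$M_x2_lr, st$M_x2_rl))
  expect_equal(dens, 0.3, tolerance = 0.05)
  expect_true(all(st$W_x1_lr[st$M_x1_lr == 0] == 0))
  stn <- toy_state(n_left = 10, n_right = 10, cross_density = 0.5,
                   cross_constraint = "negative_only", seed = 11)
  expect_true(all(stn$W_x1_lr <= 0) && all(stn$W_x2_rl <= 0))
})

test_that("forward trial matches an independent R implementation", {
  for (dens in c(0, 0.5)) {
    st <- toy_state(n_left = 5, n_right = 4, n_io = 6, seed = 13,
                    cross_density = dens)
    st$gain <- c(LH1 = 0.8, RH1 = 1, LH2 = 1, RH2 = 0.6)
    st$alive_r1[2] <- 0
    feats <- with_seed_local(1, matrix(rbinom(18, 1, 0.5), 3, 6))
    for (sil in c("none", "left", "right")) {
      tr <- forward_trial(st, feats, silence = sil)
      ref <- ref_forward(st, feats, silence = sil)
      for (lay in c("l1", "r1", "l2", "r2", "out"))
        expect_equal(unname(tr[[lay]]), unname(ref[[lay]]), tolerance = 1e-12)
    }
  }
})

test_that("trials span six ticks with activations in (0,1) for live units", {
  st <- toy_state()
  feats <- random_feats(tiny_inventory())[, 1:4]
  tr <- forward_trial(st, feats)
  expect_equal(nrow(tr$out), 6)
  expect_true(all(tr$out > 0 & tr$out < 1))
  expect_true(all(tr$l1 > 0 & tr$l1 < 1))
  expect_error(forward_trial(st, feats[1:2, ]), "3 x 4")
})

test_that("gain scales the logistic as specified", {
  st <- toy_state(seed = 21)
  feats <- with_seed_local(2, matrix(rbinom(12, 1, 0.5), 3, 4))
  base <- forward_trial(st, feats)
  # g = 1 is the identity case
  expect_identical(forward_trial(set_layer_gain(st, "LH1", 1), feats), base)
  # g = 0 pins live units at 0.5 on every tick
  g0 <- forward_trial(set_layer_gain(st, "LH1", 0), feats)
  expect_true(all(g0$l1 == 0.5))
  # g = 0.5 compresses activations strictly toward 0.5
  g5 <- forward_trial(set_layer_gain(st, "LH1", 0.5), feats)
  expect_true(all(abs(g5$l1 - 0.5) < abs(base$l1 - 0.5) + 1e-12))
  expect_error(set_layer_gain(st, "LH1", 1.5), "\\[0, 1\\]")
  expect_error(set_layer_gain(st, "XX", 1))
})

test_that("silencing one side changes the output relative to the full run", {
  st <- tiny_trained()$state
  feats <- random_feats(tiny_inventory(), seed = 5)
  full <- forward_trial(st, feats)$out
  expect_false(isTRUE(all.equal(forward_trial(st, feats, "left")$out, full)))
  expect_false(isTRUE(all.equal(forward_trial(st, feats, "right")$out, full)))
})

test_that("analytic gradients match finite differences on toy networks", {
  # plain, gained, lesioned, and cross-connected variants, both backprop modes
  variants <- list(
    function() toy_state(seed = 31),
    function() {
      st <- toy_state(seed = 32, cross_density = 0.6)
      st$gain <- c(LH1 = 0.4, RH1 = 1, LH2 = 0.9, RH2 = 0.7)
      st
    },
    function() {
      st <- toy_state(seed = 33, cross_density = 0.5,
                      cross_constraint = "negative_only")
      st$alive_l1[1] <- 0
      st$alive_r2[3] <- 0
      st
    })
  feats <- with_seed_local(3, matrix(rbinom(12, 1, 0.5), 3, 4))
  for (make in variants) {
    for (trunc in c(FALSE, TRUE)) {
      errs <- gradcheck(make(), feats, truncated = trunc)
      expect_lt(max(errs), 1e-5)
    }
  }
})

test_that("training steps descend the loss on a single pattern", {
  st <- toy_state(n_left = 6, n_right = 3, n_io = 5, seed = 41,
                  learning_rate = 0.02)
  feats <- with_seed_local(4, matrix(rbinom(15, 1, 0.5), 3, 5))
  losses <- numeric(50)
  for (i in 1:50) {
    res <- train_step(st, feats)
    st <- res$state
    losses[i] <- res$loss
  }
  expect_true(all(is.finite(losses)) && losses[1] > 0)
  expect_true(all(diff(losses) < 0))
})

test_that("dead units receive no updates and stay silent", {
  st <- toy_state(seed = 51, cross_density = 0.5)
  st$alive_l1[2] <- 0
  before <- st
  feats <- with_seed_local(5, matrix(rbinom(12, 1, 0.5), 3, 4))
  for (i in 1:5) st <- train_step(st, feats)$state
  # weights into and out of the dead unit are frozen
  expect_equal(st$W_in_l[, 2], before$W_in_l[, 2])
  expect_equal(st$W_ctx_l[, 2], before$W_ctx_l[, 2])
  expect_equal(st$W_ctx_l[2, ], before$W_ctx_l[2, ])
  expect_equal(st$W_12_l[2, ], before$W_12_l[2, ])
  expect_equal(st$W_x1_lr[2, ], before$W_x1_lr[2, ])
  expect_equal(st$b_l1[2], before$b_l1[2])
  # but live weights did move
  expect_false(isTRUE(all.equal(st$W_in_l[, 1], before$W_in_l[, 1])))
  expect_true(all(forward_trial(st, feats)$l1[, 2] == 0))
})

test_that("negative-only cross weights never become positive under training", {
  st <- toy_state(seed = 61, cross_density = 0.7,
                  cross_constraint = "negative_only", learning_rate = 0.1)
  for (i in 1:30) {
    feats <- matrix(rbinom(12, 1, 0.5), 3, 4)
    st <- train_step(st, feats)$state
    expect_true(max(st$W_x1_lr, st$W_x1_rl, st$W_x2_lr, st$W_x2_rl) <= 0)
  }
})

test_that("with no cross-connections the pathways are independent upstream of output", {
  st <- toy_state(n_left = 5, n_right = 5, seed = 71, cross_density = 0)
  feats <- with_seed_local(7, matrix(rbinom(12, 1, 0.5), 3, 4))
  base <- forward_trial(st, feats)
  st2 <- st
  st2$W_in_r <- st2$W_in_r + 0.5
  st2$W_ctx_r <- st2$W_ctx_r - 0.3
  st2$W_12_r <- st2$W_12_r + 1
  pert <- forward_trial(st2, feats)
  expect_identical(pert$l1, base$l1)
  expect_identical(pert$l2, base$l2)
  expect_false(isTRUE(all.equal(pert$out, base$out)))
  # and cross weights stay exactly zero through training
  stt <- st
  for (i in 1:10) stt <- train_step(stt, feats)$state
  expect_true(all(stt$W_x1_lr == 0) && all(stt$W_x2_rl == 0))
})

test_that("identical seeds and presentation sequences give bit-identical weights", {
  lex <- tiny_lexicon(); inv <- tiny_inventory()
  run <- function() {
    st <- init_network(network_config(n_left = 8, n_right = 4, seed = 9))
    set.seed(123)
    train(st, lex, inv, n_presentations = 500, eval_every = 500)
  }
  a <- run(); b <- run()
  expect_identical(weight_fields(a$state), weight_fields(b$state))
  expect_identical(a$log, b$log)
})

test_that("network checkpoints round-trip bit-exactly", {
  st <- tiny_trained()$state
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(st, f)
  expect_identical(load_network(f), st)
})
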