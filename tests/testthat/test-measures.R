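test_that("laterality index follows (L - R) / (L + R) and stays in [-1, 1]", {
  expect_equal(laterality_index(60, 30), 1 / 3)
  expect_equal(laterality_index(45, 45), 0)
  expect_equal(laterality_index(15, 75), -2 / 3)
  expect_error(laterality_index(0, 0), "undefined")
  for (i in 1:50) {
    lr <- with_seed_local(i, runif(2, 0, 10))
    if (sum(lr) == 0) next
    expect_true(abs(laterality_index(lr[1], lr[2])) <= 1)
  }
})

test_that("RDM entries equal hand-computed correlation distances", {
  # small matrix, oracle computed from the covariance formula directly
  p <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,
                4, 3, 2, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  rdm <- compute_rdm(p)
  pearson <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  expect_equal(rdm["a", "b"], 1 - pearson(p[1, ], p[2, ]))  # 0: collinear
  expect_equal(rdm["a", "b"], 0)
  expect_equal(rdm["a", "c"], 1 - pearson(p[1, ], p[3, ]))  # 2: reversed
  expect_equal(rdm["a", "c"], 2)
  expect_equal(diag(rdm), c(a = 0, b = 0, c = 0))
  expect_equal(rdm, t(rdm))
})

test_that("RDMs are symmetric, zero-diagonal, and bounded on random patterns", {
  p <- with_seed_local(6, matrix(runif(20 * 7), 20, 7))
  rdm <- compute_rdm(p)
  expect_equal(rdm, t(rdm))
  expect_true(all(diag(rdm) == 0))
  expect_true(all(rdm >= 0 & rdm <= 2))
})

test_that("zero-variance rows are rejected by name", {
  p <- matrix(runif(12), 3, 4, dimnames = list(c("w1", "w2", "w3"), NULL))
  p[2, ] <- 0.7
  expect_error(compute_rdm(p), "w2")
})

test_that("RSA score is the lower-triangle correlation of RDMs", {
  p <- with_seed_local(8, matrix(runif(10 * 6), 10, 6))
  rdm <- compute_rdm(p)
  expect_equal(rsa_score(rdm, rdm), 1)
  expect_error(rsa_score(rdm, rdm[1:5, 1:5]), "dimensions differ")
})

test_that("random patterns carry no representational signal (permutation baseline)", {
  inv <- memo("acc_inv_small", build_inventory(seed = 42))
  lex <- memo("rsa_lex", generate_lexicon(inv, seed = 42))
  tgt <- target_rdm(lex, inv)
  rand <- with_seed_local(9, matrix(runif(200 * 20), 200, 20))
  expect_lt(abs(rsa_score(compute_rdm(rand), tgt)), 0.1)
})

test_that("target RDM reflects shared phonemes", {
  inv <- tiny_inventory()
  lex <- tiny_lexicon()
  tgt <- target_rdm(lex, inv)
  expect_equal(dim(tgt), c(30, 30))
  w <- as.matrix(lex$words[, c("p1", "p2", "p3")])
  shared <- outer(seq_len(30), seq_len(30),
                  Vectorize(function(i, j) sum(w[i, ] == w[j, ])))
  lt <- lower.tri(tgt)
  m2 <- mean(tgt[lt][shared[lt] == 2])
  m0 <- mean(tgt[lt][shared[lt] == 0])
  expect_lt(m2, m0)
})

test_that("hidden patterns concatenate live units over the production ticks", {
  st <- tiny_trained()$state
  inv <- tiny_inventory(); lex <- tiny_lexicon()
  feats <- bisrn:::encode_items(lex$words, inv)
  pat <- hidden_patterns_for_rsa(st, feats, "LH1")
  expect_equal(dim(pat), c(30, 3 * sum(st$alive_l1 == 1)))
  # lesioned units drop out of the pattern
  les <- apply_lesion(st, lesion_spec("LH1", proportion = 0.5, seed = 1))
  expect_equal(ncol(hidden_patterns_for_rsa(les, feats, "LH1")),
               3 * sum(les$alive_l1 == 1))
  # a fully dead layer yields all-zero rows that compute_rdm rejects
  gone <- apply_lesion(st, lesion_spec("RH1", proportion = 1, seed = 1))
  pr <- hidden_patterns_for_rsa(gone, feats, "RH1")
  expect_equal(ncol(pr), 0)
})

test_that("pathway measures are pure and respect pathway independence", {
  st <- tiny_trained()$state
  inv <- tiny_inventory(); lex <- tiny_lexicon()
  feats <- bisrn:::encode_items(lex$words, inv)
  before <- weight_fields(st)
  fc_l <- functional_contribution(st, feats, "left")
  fc_r <- functional_contribution(st, feats, "right")
  act_l <- mean_output_activation(st, feats, "left")
  hid <- mean_hidden_activation(st, feats, "LH1")
  pat <- pathway_output_patterns(st, feats, "left")
  expect_identical(weight_fields(st), before)
  expect_true(fc_l >= -1 && fc_l <= 1 && fc_r >= -1 && fc_r <= 1)
  expect_true(act_l > 0 && act_l < 1)
  expect_true(hid > 0 && hid < 1)
  expect_equal(dim(pat), c(30, 75))
  # with zero cross-density, left-side measures ignore right-pathway weights
  st2 <- st
  st2$W_in_r <- st2$W_in_r * 0.1
  expect_equal(pathway_output_patterns(st2, feats, "left"), pat)
})

test_that("a pathway identical to the full model has contribution 1", {
  st <- toy_state(n_left = 6, n_right = 3, n_io = 25, seed = 19)
  st$W_in_r[] <- 0  # right input silent by construction
  feats <- bisrn:::encode_items(tiny_lexicon()$words, tiny_inventory())
  expect_equal(functional_contribution(st, feats, "left"), 1)
})

test_that("mean hidden activation subsets require and respect lesions", {
  st <- tiny_trained()$state
  feats <- bisrn:::encode_items(tiny_lexicon()$words, tiny_inventory())
  expect_error(mean_hidden_activation(st, feats, "LH1", "perilesional"),
               "requires a lesion")
  les <- apply_lesion(st, lesion_spec("LH1", proportion = 0.5, seed = 6))
  expect_equal(mean_hidden_activation(les, feats, "LH1", "lesioned"), 0)
  peri <- mean_hidden_activation(les, feats, "LH1", "perilesional")
  expect_true(peri > 0 && peri < 1)
  full <- apply_lesion(st, lesion_spec("LH1", proportion = 1, seed = 6))
  expect_error(mean_hidden_activation(full, feats, "LH1", "perilesional"),
               "empty")
})

test_that("weight statistics cover live entries and track changes", {
  st <- tiny_trained()$state
  ws <- weight_statistics(st, st)
  expect_equal(ws$mean_abs_dw, 0)
  expect_gt(ws$mean_abs_w, 0)
  stepd <- train_step(st, random_feats(tiny_inventory(), 3))$state
  expect_gt(weight_statistics(stepd, st)$mean_abs_dw, 0)
  other <- toy_state()
  expect_error(weight_statistics(st, other), "architectures differ")
})

test_that("RDMs export as square CSV with word ids", {
  lex <- tiny_lexicon()
  tgt <- target_rdm(lex, tiny_inventory())
  f <- withr::local_tempfile(fileext = ".csv")
  write_rdm(tgt, f)
  back <- as.matrix(read.csv(f, row.names = 1))
  expect_equal(unname(back), unname(tgt), tolerance = 1e-12)
  expect_equal(rownames(back), lex$words$word_id)
})
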