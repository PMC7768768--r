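test_that("statistical helpers match their standard definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(bonferroni(rep(0.01, 4)), rep(0.04, 4))
  tt <- paired_t(x, x + c(1, 2, 1, 2, 1))
  expect_equal(tt$t, t.test(x, x + c(1, 2, 1, 2, 1), paired = TRUE)$statistic,
               ignore_attr = TRUE)
})

test_that("phase bins must be contiguous and ordered", {
  b <- phase_bins()
  expect_equal(b$acute, c(0, 1000))
  expect_equal(b$chronic[2], 40000)
  expect_error(phase_bins(acute = c(0, 500), subacute = c(1000, 5000)),
               "contiguous")
})

test_that("phase means average checkpoints within each window", {
  tr <- data.frame(presentations = c(0, 500, 1000, 3000, 5000, 20000, 40000),
                   out_act_left = c(1, 2, 3, 4, 5, 6, 7))
  pm <- bisrn:::phase_means(tr, "out_act_left")
  expect_equal(unname(pm["acute"]), mean(c(1, 2)))
  expect_equal(unname(pm["subacute"]), mean(c(3, 4)))
  expect_equal(unname(pm["chronic"]), mean(c(5, 6, 7)))
})

test_that("correlate_measures validates input and flags degenerate series", {
  short <- data.frame(presentations = 1:5)
  expect_error(correlate_measures(short), "at least 10")
  n <- 12
  acc <- seq(0, 100, length.out = n)
  tr <- data.frame(presentations = seq_len(n) * 1000,
                   accuracy_words = acc,
                   out_act_left = acc / 200 + 0.1,
                   out_act_right = 0.5 - acc / 300,
                   rsa_l1 = acc / 100, rsa_r1 = rep(0.2, n),
                   rsa_l2 = acc / 120, rsa_r2 = 0.3 - acc / 500)
  expect_warning(res <- correlate_measures(tr), "constant")
  expect_equal(res$r[res$measure == "rsa_l1"], 1)
  expect_equal(res$r[res$measure == "out_act_right"], -1)
  expect_true(is.na(res$r[res$measure == "rsa_r1"]))
})

test_that("the capacity sweep runner produces per-model rows and pooled correlations", {
  lex <- tiny_lexicon(); inv <- tiny_inventory()
  res <- run_capacity_sweep(lex, inv, pairs = list(c(12, 6), c(6, 12)),
                            seeds = 1, n_presentations = 2000,
                            learning_rate = 0.02)
  expect_equal(nrow(res$table), 2)
  expect_equal(res$table$asymmetry, c(1 / 3, -1 / 3))
  expect_true(all(is.finite(c(res$r_functional, res$r_activation))))
  expect_true(all(abs(res$table$li_functional) <= 1))
})

test_that("the lesion sweep returns recovered accuracies per side, level and seed", {
  lex <- tiny_lexicon(); inv <- tiny_inventory()
  intact <- list(`1` = tiny_trained()$state)
  res <- run_lesion_sweep(lex, inv, levels = c(0.2, 0.8), sides = "LH1",
                          seeds = 1, n_rec = 1000, intact_states = intact)
  expect_equal(nrow(res), 2)
  expect_equal(as.character(res$group), c("mild", "severe"))
  expect_true(all(res$accuracy_words >= 0 & res$accuracy_words <= 100))
})

test_that("the recovery time-course runner yields trajectories and phase contrasts", {
  lex <- tiny_lexicon(); inv <- tiny_inventory()
  intact <- list(`1` = tiny_trained()$state, `2` = tiny_trained()$state)
  conds <- data.frame(name = "left_moderate", layer = "LH1",
                      proportion = 0.5, noise = 0.5)
  res <- run_recovery_timecourse(
    lex, inv, conditions = conds, seeds = 1:2, n_rec = 6000,
    eval_every = 500, bins = phase_bins(chronic = c(5000, 6000)),
    intact_states = intact)
  expect_setequal(unique(res$trajectories$seed), 1:2)
  expect_true(all(c("out_act_left", "out_act_right", "rsa_l1", "hid_peri")
                  %in% names(res$trajectories)))
  expect_equal(nrow(res$contrasts), 4)  # 2 sides x 2 transitions
  expect_true(all(res$contrasts$p_adj >= res$contrasts$p - 1e-12))
  # first checkpoint of each trajectory is immediately post-lesion
  expect_true(all(tapply(res$trajectories$presentations,
                         res$trajectories$seed, min) == 0))
})

test_that("the interconnectivity runner sweeps densities and collects cross weights", {
  lex <- tiny_lexicon(); inv <- tiny_inventory()
  conds <- data.frame(name = "left_moderate", layer = "LH1",
                      proportion = 0.5, noise = 0.5)
  res <- run_interconnectivity(
    lex, inv, densities = c(0, 0.5), conditions = conds, seeds = 1,
    n_dev = 2000, n_rec = 1500, eval_every = 500,
    bins = phase_bins(subacute = c(1000, 1200), chronic = c(1200, 1500)),
    n_left = 12, n_right = 6)
  expect_named(res, c("density_0", "density_0.5"))
  # no interconnections: no learned cross weights at all
  expect_length(res$density_0$cross_weights, 0)
  expect_gt(length(res$`density_0.5`$cross_weights), 0)
  # under the negative-only constraint every learned cross weight is <= 0
  resn <- run_interconnectivity(
    lex, inv, densities = 0.5, cross_constraint = "negative_only",
    conditions = conds, seeds = 1, n_dev = 1000, n_rec = 500,
    eval_every = 500,
    bins = phase_bins(subacute = c(1000, 1200), chronic = c(1200, 1500)),
    n_left = 12, n_right = 6)
  expect_lte(max(resn$`density_0.5`$cross_weights), 0)
})
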