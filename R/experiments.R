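#' The five capacity configurations
#'
#' Left/right hidden-layer sizes spanning strongly right-provisioned to
#' strongly left-provisioned bilateral networks with a fixed total of 90
#' units per layer pair.
#' @export
capacity_pairs <- function() {
  list(c(15, 75), c(30, 60), c(45, 45), c(60, 30), c(75, 15))
}

# develop one intact model: init + frequency-weighted training
develop_model <- function(n_left, n_right, seed, lexicon, inventory,
                          n_presentations, eval_every = 10000,
                          measures = FALSE, ...) {
  cfg <- network_config(n_left = n_left, n_right = n_right, seed = seed, ...)
  st <- init_network(cfg)
  set.seed(seed)
  train(st, lexicon, inventory, n_presentations, eval_every = eval_every,
        measures = measures)
}

#' Capacity sweep: structural asymmetry vs functional lateralization
#'
#' Trains a model for every (capacity pair, seed) combination, measures
#' both laterality indices (functional contribution and output-unit
#' activation) on the trained states, and correlates each against the
#' capacity asymmetry index `(nL - nR) / (nL + nR)` pooled over all models.
#'
#' @param lexicon,inventory Training environment.
#' @param pairs List of `c(n_left, n_right)` pairs (default
#'   [capacity_pairs()]).
#' @param seeds Integer vector of model seeds (the full protocol uses 20).
#' @param n_presentations Developmental presentations per model.
#' @param ... Further arguments to [network_config()].
#' @return A list: `table` (one row per model with capacities, asymmetry
#'   index, both laterality indices and accuracies), `r_functional` and
#'   `r_activation` (pooled Pearson correlations).
#' @export
run_capacity_sweep <- function(lexicon, inventory, pairs = capacity_pairs(),
                               seeds = 1:2, n_presentations = 150000, ...) {
  feats <- encode_items(lexicon$words, inventory)
  rows <- list()
  for (pair in pairs) for (seed in seeds) {
    fit <- develop_model(pair[1], pair[2], seed, lexicon, inventory,
                         n_presentations, ...)
    st <- fit$state
    fc_l <- functional_contribution(st, feats, "left")
    fc_r <- functional_contribution(st, feats, "right")
    act_l <- mean_output_activation(st, feats, "left")
    act_r <- mean_output_activation(st, feats, "right")
    ev <- utils::tail(fit$log, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      n_left = pair[1], n_right = pair[2], seed = seed,
      asymmetry = laterality_index(pair[1], pair[2]),
      li_functional = laterality_index(fc_l, fc_r),
      li_activation = laterality_index(act_l, act_r),
      fc_left = fc_l, fc_right = fc_r,
      act_left = act_l, act_right = act_r,
      accuracy_hf = ev$accuracy_hf, accuracy_lf = ev$accuracy_lf,
      accuracy_nw = ev$accuracy_nw)
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       r_functional = stats::cor(tab$asymmetry, tab$li_functional),
       r_activation = stats::cor(tab$asymmetry, tab$li_activation))
}

#' Lesion severity sweep
#'
#' For each seed, trains an intact model (or reuses supplied ones), then
#' applies every (side, level) lesion and retrains with the gain ramp,
#' recording the final recovered accuracies. Levels pair the damage
#' proportion with an equal noise level, the graded severity scheme; left
#' levels group into mild (0.1-0.3), moderate (0.4-0.6) and severe
#' (0.7-1.0).
#'
#' @param lexicon,inventory Training environment.
#' @param levels Numeric vector of paired proportion/noise levels.
#' @param sides Lesioned layers (default both `"LH1"` and `"RH1"`).
#' @param seeds Model seeds.
#' @param n_dev,n_rec Developmental and recovery presentations.
#' @param intact_states Optional named list (by seed) of pre-trained intact
#'   states to reuse.
#' @param ... Further arguments to [network_config()].
#' @return Data frame: side, level, group, seed, recovered accuracies per
#'   item type plus `accuracy_all`, the overall recovered accuracy over
#'   words and nonwords pooled.
#' @export
run_lesion_sweep <- function(lexicon, inventory, levels = seq(0.1, 1, 0.1),
                             sides = c("LH1", "RH1"), seeds = 1:2,
                             n_dev = 300000, n_rec = 100000,
                             intact_states = NULL, ...) {
  rows <- list()
  for (seed in seeds) {
    intact <- intact_states[[as.character(seed)]] %||%
      develop_model(60, 30, seed, lexicon, inventory, n_dev, ...)$state
    for (side in sides) for (lev in levels) {
      spec <- lesion_spec(side, proportion = lev, noise = lev,
                          seed = seed * 1000L + round(100 * lev))
      st <- apply_lesion(intact, spec)
      set.seed(seed * 7 + round(100 * lev) + (side == "RH1") * 13)
      rec <- retrain(st, lexicon, inventory, n_presentations = n_rec,
                     eval_every = max(1000, n_rec %/% 10))
      fin <- utils::tail(rec$trajectory, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, level = lev,
        group = cut(lev, c(0, 0.35, 0.65, 1),
                    labels = c("mild", "moderate", "severe")),
        seed = seed, accuracy_hf = fin$accuracy_hf,
        accuracy_lf = fin$accuracy_lf, accuracy_nw = fin$accuracy_nw,
        accuracy_words = fin$accuracy_words, accuracy_all = fin$accuracy_all)
    }
  }
  do.call(rbind, rows)
}

#' Recovery phase bins
#'
#' Half-open presentation windows into the retraining period approximating
#' the acute, subacute and chronic stages of patient recovery.
#'
#' @param acute,subacute,chronic Two-element `c(from, to)` windows; they
#'   must be contiguous and ordered.
#' @return A named list of windows.
#' @export
phase_bins <- function(acute = c(0, 1000), subacute = c(1000, 5000),
                       chronic = c(5000, 40000)) {
  bins <- list(acute = acute, subacute = subacute, chronic = chronic)
  edges <- unlist(bins)
  if (any(diff(edges) < 0) || acute[2] != subacute[1] ||
      subacute[2] != chronic[1])
    stopf("phase bins must be contiguous, non-overlapping and ordered")
  bins
}

# mean of a trajectory column within each phase window (checkpoints fall
# in a bin by their presentation count; the right edge is exclusive except
# for the final chronic edge)
phase_means <- function(trajectory, column, bins = phase_bins()) {
  vapply(names(bins), function(ph) {
    w <- bins[[ph]]
    inb <- trajectory$presentations >= w[1] &
      (trajectory$presentations < w[2] |
         (ph == "chronic" & trajectory$presentations <= w[2]))
    mean(trajectory[[column]][inb])
  }, numeric(1))
}

#' Recovery time-course experiment
#'
#' Runs development, lesion and retraining for a set of lesion conditions
#' across seeds, recording full recovery trajectories, and contrasts the
#' left/right pathway output activations between recovery phases
#' (subacute - acute, chronic - subacute) with paired t-tests across seeds,
#' Bonferroni-corrected.
#'
#' @param lexicon,inventory Training environment.
#' @param conditions Data frame with columns `name`, `layer`, `proportion`,
#'   `noise` (default: the left mild/moderate/severe and right severe
#'   conditions).
#' @param seeds Model seeds.
#' @param n_dev,n_rec Developmental and recovery presentations.
#' @param eval_every Trajectory checkpoint cadence.
#' @param bins Phase windows from [phase_bins()].
#' @param intact_states Optional named list (by seed) of pre-trained intact
#'   states.
#' @param ... Further arguments to [network_config()].
#' @return A list: `trajectories` (tidy data frame keyed by condition,
#'   seed, checkpoint), `phase_activations` (per condition x seed x phase),
#'   and `contrasts` (per condition x side x phase transition, with t, p
#'   and Bonferroni-adjusted p).
#' @export
run_recovery_timecourse <- function(lexicon, inventory,
                                    conditions = default_conditions(),
                                    seeds = 1:5, n_dev = 300000,
                                    n_rec = 40000, eval_every = 1000,
                                    bins = phase_bins(),
                                    intact_states = NULL, ...) {
  traj_rows <- list(); phase_rows <- list()
  for (seed in seeds) {
    intact <- intact_states[[as.character(seed)]] %||%
      develop_model(60, 30, seed, lexicon, inventory, n_dev, ...)$state
    for (i in seq_len(nrow(conditions))) {
      cond <- conditions[i, ]
      spec <- lesion_spec(cond$layer, proportion = cond$proportion,
                          noise = cond$noise, seed = seed * 1000L + i)
      st <- apply_lesion(intact, spec)
      set.seed(seed * 31 + i)
      rec <- retrain(st, lexicon, inventory, n_presentations = n_rec,
                     eval_every = eval_every, reference_state = intact)
      tr <- rec$trajectory
      tr$condition <- cond$name; tr$seed <- seed
      traj_rows[[length(traj_rows) + 1L]] <- tr
      for (side in c("left", "right")) {
        pm <- phase_means(tr, paste0("out_act_", side), bins)
        phase_rows[[length(phase_rows) + 1L]] <- data.frame(
          condition = cond$name, seed = seed, side = side,
          acute = pm[["acute"]], subacute = pm[["subacute"]],
          chronic = pm[["chronic"]])
      }
    }
  }
  phases <- do.call(rbind, phase_rows)
  contrasts <- list()
  for (cond in unique(phases$condition)) for (side in c("left", "right")) {
    d <- phases[phases$condition == cond & phases$side == side, ]
    for (tr in c("subacute_minus_acute", "chronic_minus_subacute")) {
      ab <- strsplit(tr, "_minus_")[[1]]
      tt <- paired_t(d[[ab[1]]], d[[ab[2]]])
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        condition = cond, side = side, transition = tr,
        delta = mean(d[[ab[1]]] - d[[ab[2]]]), t = tt$t, p = tt$p)
    }
  }
  contrasts <- do.call(rbind, contrasts)
  contrasts$p_adj <- stats::ave(contrasts$p, contrasts$condition,
                                FUN = bonferroni)
  list(trajectories = do.call(rbind, traj_rows),
       phase_activations = phases, contrasts = contrasts)
}

#' @rdname run_recovery_timecourse
#' @export
default_conditions <- function() {
  data.frame(name = c("left_mild", "left_moderate", "left_severe",
                      "right_severe"),
             layer = c("LH1", "LH1", "LH1", "RH1"),
             proportion = c(0.2, 0.5, 0.8, 0.8),
             noise = c(0.2, 0.5, 0.8, 0.8))
}

#' Interhemispheric connectivity experiment
#'
#' Repeats development and the standard lesion conditions at several
#' homotopic cross-connection densities, optionally under the
#' negative-only constraint, and summarizes the learned cross weights.
#'
#' @param lexicon,inventory Training environment.
#' @param densities Cross-connection densities to compare.
#' @param cross_constraint `"free"` or `"negative_only"`.
#' @param conditions,seeds,n_dev,n_rec,eval_every,bins As in
#'   [run_recovery_timecourse()].
#' @param n_left,n_right Hidden-layer capacities (default the standard
#'   60/30 model).
#' @param ... Further arguments to [network_config()].
#' @return A list per density: the recovery time-course results plus
#'   `cross_weights`, the pooled learned cross-connection weights (masked
#'   entries only) of the trained intact models.
#' @export
run_interconnectivity <- function(lexicon, inventory,
                                  densities = c(0, 0.3, 0.7),
                                  cross_constraint = "free",
                                  conditions = default_conditions(),
                                  seeds = 1:2, n_dev = 300000, n_rec = 40000,
                                  eval_every = 1000, bins = phase_bins(),
                                  n_left = 60, n_right = 30, ...) {
  out <- list()
  for (dens in densities) {
    intact <- list()
    cw <- numeric(0)
    for (seed in seeds) {
      fit <- develop_model(n_left, n_right, seed, lexicon, inventory, n_dev,
                           cross_density = dens,
                           cross_constraint = cross_constraint, ...)
      intact[[as.character(seed)]] <- fit$state
      st <- fit$state
      cw <- c(cw, st$W_x1_lr[st$M_x1_lr == 1], st$W_x1_rl[st$M_x1_rl == 1],
              st$W_x2_lr[st$M_x2_lr == 1], st$W_x2_rl[st$M_x2_rl == 1])
    }
    res <- run_recovery_timecourse(lexicon, inventory, conditions, seeds,
                                   n_dev, n_rec, eval_every, bins = bins,
                                   intact_states = intact,
                                   cross_density = dens,
                                   cross_constraint = cross_constraint, ...)
    res$cross_weights <- cw
    out[[sprintf("density_%g", dens)]] <- res
  }
  out
}

#' Correlate model performance with activation and RSA measures
#'
#' Across the checkpoints of a developmental training log or recovery
#' trajectory (pooled across seeds if a `seed` column is present), Pearson
#' correlations of overall accuracy with left/right pathway output
#' activation and with the RSA scores of the four hidden layers.
#'
#' @param trajectory A checkpoint data frame carrying measure columns
#'   (`measures = TRUE` in [train()], or any [retrain()] trajectory).
#' @return Data frame with columns `measure`, `r`, `p`, `n`; constant
#'   series yield `NA` with a warning rather than a silent zero.
#' @export
correlate_measures <- function(trajectory) {
  if (nrow(trajectory) < 10L)
    stopf("need at least 10 checkpoints, got %d", nrow(trajectory))
  need <- c("out_act_left", "out_act_right", "rsa_l1", "rsa_r1",
            "rsa_l2", "rsa_r2")
  missing_cols <- setdiff(need, names(trajectory))
  if (length(missing_cols) > 0)
    stopf("trajectory lacks measure columns: %s",
          paste(missing_cols, collapse = ", "))
  acc <- trajectory$accuracy_words
  rows <- lapply(need, function(m) {
    x <- trajectory[[m]]
    ok <- stats::complete.cases(acc, x)
    if (sum(ok) < 3L || stats::sd(acc[ok]) == 0 || stats::sd(x[ok]) == 0) {
      warning(sprintf("constant or insufficient series for %s; r undefined", m))
      return(data.frame(measure = m, r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    ct <- pearson_r(acc[ok], x[ok])
    data.frame(measure = m, r = ct$r, p = ct$p, n = sum(ok))
  })
  do.call(rbind, rows)
}

#' Basic statistical helpers
#'
#' Two-sided Pearson correlation test, paired t-test, and Bonferroni
#' adjustment, as thin wrappers over the base-R tests.
#'
#' @param x,y Numeric vectors.
#' @param p Numeric vector of p-values.
#' @return `pearson_r`: list with `r` and `p`. `paired_t`: list with `t`
#'   and `p`. `bonferroni`: adjusted p-values.
#' @export
pearson_r <- function(x, y) {
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @rdname pearson_r
#' @export
paired_t <- function(x, y) {
  d <- (x - y)[is.finite(x - y)]
  if (length(d) < 2) return(list(t = NA_real_, p = NA_real_))
  if (stats::sd(d) == 0) return(list(t = 0, p = 1))
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' @rdname pearson_r
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
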