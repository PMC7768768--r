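#' Decode an output pattern to phonemes and score a word
#'
#' Each production tick's 25-unit output vector is decoded to the nearest
#' inventory phoneme by Euclidean distance over the features (ties broken
#' by inventory order); the item is correct only when all three decoded
#' phonemes match the target triple.
#'
#' @param outputs A 3 x n_features matrix: the output activations of ticks
#'   4-6.
#' @param target Character vector of three phoneme symbols.
#' @param inventory An `srn_inventory`.
#' @return `score_word`: a single logical. `decode_phonemes`: character
#'   vector of the three decoded symbols.
#' @export
score_word <- function(outputs, target, inventory) {
  all(decode_phonemes(outputs, inventory) == as.character(target))
}

#' @rdname score_word
#' @export
decode_phonemes <- function(outputs, inventory) {
  stopifnot(inherits(inventory, "srn_inventory"))
  outputs <- as.matrix(outputs)
  feats <- inventory$features
  apply(outputs, 1L, function(o) {
    d2 <- rowSums(sweep(feats, 2L, o)^2)
    inventory$symbols[which.min(d2)]
  })
}

# Decode a batch: out_mat is items x (6 * n_io) tick-concatenated output
# activations; uses the production ticks (4-6). Returns items x 3 symbols.
decode_batch <- function(out_mat, inventory) {
  nio <- ncol(inventory$features)
  prod_cols <- 3L * nio + seq_len(3L * nio)
  t(apply(out_mat[, prod_cols, drop = FALSE], 1L, function(row) {
    decode_phonemes(matrix(row, nrow = 3L, byrow = TRUE), inventory)
  }))
}

#' Evaluate repetition accuracy
#'
#' Pure measurement: forward-runs every word and nonword, decodes the
#' produced phonemes, and reports whole-item accuracy (all three phonemes
#' correct) per item type. Never changes any weight.
#'
#' @param state An `srn_state`.
#' @param lexicon An `srn_lexicon`.
#' @param inventory The matching `srn_inventory`.
#' @return A list with `accuracy_hf`, `accuracy_lf`, `accuracy_nw`,
#'   `accuracy_words` (whole-word accuracy over the 200 words) and
#'   `accuracy_all` (overall accuracy over words and nonwords pooled), all
#'   in percent, plus the per-item logical vectors `word_correct`,
#'   `nonword_correct`.
#' @export
evaluate <- function(state, lexicon, inventory) {
  stopifnot(inherits(state, "srn_state"), inherits(lexicon, "srn_lexicon"))
  words <- lexicon$words
  items <- rbind(words[, c("p1", "p2", "p3")],
                 lexicon$nonwords[, c("p1", "p2", "p3")])
  feats <- encode_items(items, inventory)
  out <- run_items(state, feats)$out
  decoded <- decode_batch(out, inventory)
  correct <- rowSums(decoded == as.matrix(items)) == 3L
  n_words <- nrow(words)
  wc <- correct[seq_len(n_words)]
  nc <- correct[-seq_len(n_words)]
  hf <- words$freq_class == "HF"
  list(accuracy_hf = 100 * mean(wc[hf]),
       accuracy_lf = 100 * mean(wc[!hf]),
       accuracy_nw = 100 * mean(nc),
       accuracy_words = 100 * mean(wc),
       accuracy_all = 100 * mean(correct),
       word_correct = stats::setNames(wc, words$word_id),
       nonword_correct = nc)
}

# One checkpoint row; optionally with the activation/RSA measures used by
# the recovery analyses (computed from a single batched forward pass per
# silencing condition).
checkpoint_row <- function(state, lexicon, inventory, presentations,
                           mean_loss = NA_real_, measures = FALSE,
                           tgt_rdm = NULL, reference_state = NULL) {
  ev <- evaluate(state, lexicon, inventory)
  row <- data.frame(presentations = presentations,
                    accuracy_hf = ev$accuracy_hf,
                    accuracy_lf = ev$accuracy_lf,
                    accuracy_nw = ev$accuracy_nw,
                    accuracy_words = ev$accuracy_words,
                    accuracy_all = ev$accuracy_all,
                    mean_loss = mean_loss)
  if (!measures) return(row)
  words <- lexicon$words
  feats <- encode_items(words, inventory)
  row$out_act_left <- mean_output_activation(state, feats, "left")
  row$out_act_right <- mean_output_activation(state, feats, "right")
  full <- run_items(state, feats)
  for (layer in .layer_names) {
    key <- tolower(sub("H", "", layer))  # l1, r1, l2, r2
    acts <- full[[key]]
    alive <- state[[paste0("alive_", key)]]
    row[[paste0("hid_", key)]] <- if (any(alive == 1))
      mean(acts[, rep(alive == 1, 6), drop = FALSE]) else 0
    row[[paste0("rsa_", key)]] <- if (!is.null(tgt_rdm) && any(alive == 1)) {
      pat <- pattern_from_acts(acts, alive, ticks = 4:6)
      if (any(apply(pat, 1L, stats::sd) == 0)) NA_real_ else {
        # a degenerate (constant-dissimilarity) RDM carries no signal
        r <- suppressWarnings(rsa_score(compute_rdm(pat), tgt_rdm))
        if (is.nan(r)) NA_real_ else r
      }
    } else NA_real_
    if (!is.null(state$lesion) && state$lesion$layer == layer) {
      live_cols <- rep(alive == 1, 6)
      dead_cols <- rep(alive == 0, 6)
      row$hid_peri <- if (any(live_cols)) mean(acts[, live_cols]) else NA_real_
      row$hid_lesioned <- if (any(dead_cols)) mean(acts[, dead_cols]) else NA_real_
    }
  }
  if (!is.null(reference_state)) {
    ws <- weight_statistics(state, reference_state)
    row$mean_abs_w <- ws$mean_abs_w
    row$mean_abs_dw <- ws$mean_abs_dw
  }
  row
}

# columns of the tick-concatenated activation matrix belonging to `ticks`
tick_block <- function(acts, ticks) {
  n <- ncol(acts) / 6L
  cols <- as.vector(vapply(ticks, function(t) (t - 1L) * n + seq_len(n),
                           numeric(n)))
  acts[, cols, drop = FALSE]
}

#' Train the network on the lexicon
#'
#' Online frequency-weighted training: each presentation samples one word
#' i.i.d. from the lexicon's log-frequency presentation probabilities and
#' applies one gradient-descent step. The presentation sequence is drawn
#' from R's global RNG, so `set.seed()` before calling makes a run exactly
#' reproducible. Accuracy over all words and nonwords is evaluated every
#' `eval_every` presentations and at the end.
#'
#' @param state An `srn_state`.
#' @param lexicon,inventory Training environment.
#' @param n_presentations Total word presentations (the full developmental
#'   protocol uses 300,000).
#' @param eval_every Checkpoint cadence in presentations (default 5000).
#' @param measures If `TRUE`, each checkpoint also records pathway output
#'   activations, mean hidden activations and per-layer RSA scores.
#' @param gain_schedule Optional function `f(presentations_done)` returning
#'   a named gain assignment (see [retrain()]); used internally for the
#'   recovery gain ramp.
#' @param reference_state Optional snapshot for weight-change statistics at
#'   checkpoints.
#' @return A list with the trained `state` and `log`, a data frame of
#'   checkpoints (class `srn_training_log`).
#' @export
train <- function(state, lexicon, inventory, n_presentations,
                  eval_every = 5000, measures = FALSE,
                  gain_schedule = NULL, reference_state = NULL) {
  stopifnot(inherits(state, "srn_state"), n_presentations >= 0)
  feats_all <- encode_items(lexicon$words, inventory)
  cumprobs <- cumsum(lexicon$probs)
  truncated <- state$config$backprop == "truncated"
  lr <- state$config$learning_rate
  tgt <- if (measures) target_rdm(lexicon, inventory) else NULL
  if (!is.null(gain_schedule)) {
    g0 <- gain_schedule(0L)
    for (layer in names(g0)) state <- set_layer_gain(state, layer, g0[[layer]])
  }
  log_rows <- list(checkpoint_row(state, lexicon, inventory, 0L,
                                  measures = measures, tgt_rdm = tgt,
                                  reference_state = reference_state))
  done <- 0L
  while (done < n_presentations) {
    # honour gain-schedule boundaries within a chunk
    chunk <- min(eval_every, n_presentations - done)
    if (!is.null(gain_schedule)) {
      g <- gain_schedule(done)
      for (layer in names(g)) state <- set_layer_gain(state, layer, g[[layer]])
      nxt <- attr(g, "next_change")
      if (!is.null(nxt) && is.finite(nxt)) chunk <- min(chunk, nxt - done)
    }
    res <- .srn_train_chunk_cpp(state, feats_all, cumprobs, as.integer(chunk),
                                lr, truncated)
    state[names(res$weights)] <- res$weights
    done <- done + chunk
    if (done %% eval_every == 0 || done == n_presentations) {
      log_rows[[length(log_rows) + 1L]] <-
        checkpoint_row(state, lexicon, inventory, done, res$mean_loss,
                       measures = measures, tgt_rdm = tgt,
                       reference_state = reference_state)
    }
  }
  if (!is.null(gain_schedule)) {
    g <- gain_schedule(done)
    for (layer in names(g)) state <- set_layer_gain(state, layer, g[[layer]])
  }
  log <- do.call(rbind, log_rows)
  class(log) <- c("srn_training_log", class(log))
  list(state = state, log = log)
}

#' Write a training log as tidy CSV
#'
#' One row per checkpoint x item type (`HF`, `LF`, `NW`), plus any measure
#' columns carried by the log.
#'
#' @param log An `srn_training_log` (from [train()] or [retrain()]).
#' @param file File path.
#' @export
write_training_log <- function(log, file) {
  acc <- data.frame(
    presentations = rep(log$presentations, 3L),
    word_type = rep(c("HF", "LF", "NW"), each = nrow(log)),
    accuracy = c(log$accuracy_hf, log$accuracy_lf, log$accuracy_nw))
  extra <- setdiff(names(log), c("accuracy_hf", "accuracy_lf", "accuracy_nw",
                                 "accuracy_words", "accuracy_all",
                                 "presentations"))
  tidy <- cbind(acc, log[rep(seq_len(nrow(log)), 3L), extra, drop = FALSE])
  utils::write.csv(tidy, file, row.names = FALSE)
  invisible(tidy)
}
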