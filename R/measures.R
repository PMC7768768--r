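#' Pathway-silenced output patterns
#'
#' Runs every word with the opposite pathway's input links silenced (the
#' non-destructive probe behind the functional-contribution and
#' output-activation laterality measures) and returns the output
#' activations of the three production ticks.
#'
#' @param state An `srn_state`.
#' @param feats_all Encoded words, items x (3 * n_io) (see internal layout
#'   of [encode()]); build with `bisrn:::encode_items(lexicon$words, inv)`.
#' @param side `"left"` or `"right"`: the pathway whose unique contribution
#'   is measured (the other side's input is silenced).
#' @return A words x (3 * n_io) matrix of production-tick output
#'   activations.
#' @export
pathway_output_patterns <- function(state, feats_all, side = c("left", "right")) {
  side <- match.arg(side)
  silence <- if (side == "left") "right" else "left"
  out <- run_items(state, feats_all, silence = silence)$out
  tick_block(out, 4:6)
}

#' Functional contribution of one pathway
#'
#' Pearson correlation between the output patterns produced with only one
#' pathway receiving input and the full model's output patterns, over all
#' words, production ticks and output units. Each output unit x tick
#' column is centered across words first, so the correlation reflects the
#' word-discriminating (stimulus-driven) structure a pathway transmits
#' rather than shared baseline activation: a pathway that carries no
#' stimulus information contributes nothing even though its silenced run
#' still shows bias- and context-driven activity. A proxy for effective
#' connectivity.
#'
#' @inheritParams pathway_output_patterns
#' @return A single correlation. If either centered pattern has zero
#'   variance (e.g. the pathway is fully lesioned), the function returns 0
#'   with a warning.
#' @export
functional_contribution <- function(state, feats_all, side = c("left", "right")) {
  side <- match.arg(side)
  center <- function(m) sweep(m, 2L, colMeans(m))
  solo <- as.vector(center(pathway_output_patterns(state, feats_all, side)))
  full <- as.vector(center(tick_block(run_items(state, feats_all)$out, 4:6)))
  if (stats::sd(solo) == 0 || stats::sd(full) == 0) {
    warning("degenerate (zero-variance) output pattern; returning 0")
    return(0)
  }
  stats::cor(solo, full)
}

#' Mean pathway output activation
#'
#' Mean output-layer activation over all words and production ticks when
#' only one pathway receives input; a proxy for the fMRI activation
#' attributable to that pathway.
#'
#' @inheritParams pathway_output_patterns
#' @return A scalar in (0, 1).
#' @export
mean_output_activation <- function(state, feats_all, side = c("left", "right")) {
  mean(pathway_output_patterns(state, feats_all, side))
}

#' Laterality index
#'
#' `(L - R) / (L + R)` over any paired left/right signal; positive values
#' indicate left dominance. With nonnegative inputs the index lies in
#' `[-1, 1]`.
#'
#' @param L,R Nonnegative left and right signals with `L + R > 0`.
#' @return A scalar.
#' @export
#' @examples
#' laterality_index(60, 30)  # the 60/30 capacity asymmetry index, 1/3
laterality_index <- function(L, R) {
  if (L + R == 0) stopf("laterality index undefined for L + R = 0")
  (L - R) / (L + R)
}

#' Mean hidden-layer activation
#'
#' Mean activation of a chosen unit population over all words and all six
#' ticks. `"perilesional"` selects the surviving units of a lesioned layer,
#' `"lesioned"` the dead units (whose activation is clamped to 0).
#'
#' @inheritParams pathway_output_patterns
#' @param layer One of `"LH1"`, `"RH1"`, `"LH2"`, `"RH2"`.
#' @param subset `"all_live"`, `"perilesional"` or `"lesioned"`.
#' @return A scalar.
#' @export
mean_hidden_activation <- function(state, feats_all, layer,
                                   subset = c("all_live", "perilesional",
                                              "lesioned")) {
  layer <- match.arg(layer, .layer_names)
  subset <- match.arg(subset)
  key <- tolower(sub("H", "", layer))
  alive <- state[[paste0("alive_", key)]]
  if (subset != "all_live" &&
      (is.null(state$lesion) || state$lesion$layer != layer))
    stopf("subset '%s' requires a lesion in layer %s", subset, layer)
  keep <- switch(subset,
                 all_live = alive == 1,
                 perilesional = alive == 1,
                 lesioned = alive == 0)
  if (!any(keep)) stopf("empty unit subset '%s' in layer %s", subset, layer)
  acts <- run_items(state, feats_all)[[key]]
  mean(acts[, rep(keep, 6L), drop = FALSE])
}

#' Representational dissimilarity matrix
#'
#' Entry (i, j) is `1 - Pearson(r_i, r_j)` between the pattern vectors of
#' words i and j: symmetric, zero diagonal, entries in `[0, 2]`.
#'
#' @param patterns A words x features numeric matrix; rownames (if any) are
#'   carried over. Every row must have nonzero variance.
#' @return The square dissimilarity matrix.
#' @export
compute_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2L) stopf("need at least 2 words for an RDM")
  sds <- apply(patterns, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(patterns)[sds == 0] %||% which(sds == 0)
    stopf("zero-variance pattern row(s): %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  rdm <- 1 - stats::cor(t(patterns))
  diag(rdm) <- 0
  rdm
}

#' RSA score: second-order correlation of two RDMs
#'
#' Pearson correlation between the lower triangles (diagonal excluded) of a
#' model RDM and a target RDM over the same words in the same order.
#'
#' @param model_rdm,target_rdm Square dissimilarity matrices of equal size.
#' @return A single correlation.
#' @export
rsa_score <- function(model_rdm, target_rdm) {
  if (!all(dim(model_rdm) == dim(target_rdm)))
    stopf("RDM dimensions differ: %dx%d vs %dx%d",
          nrow(model_rdm), ncol(model_rdm),
          nrow(target_rdm), ncol(target_rdm))
  lt <- lower.tri(model_rdm)
  stats::cor(model_rdm[lt], target_rdm[lt])
}

#' Hidden-unit patterns for RSA
#'
#' Per word, the concatenated live-unit activations of one hidden layer
#' over the three production ticks (the constituent phonemes).
#'
#' @inheritParams mean_hidden_activation
#' @param ticks Which ticks constitute the pattern (default the production
#'   ticks 4-6; the input ticks 1-3 are available for sensitivity checks).
#' @return A words x (live units * length(ticks)) matrix.
#' @export
hidden_patterns_for_rsa <- function(state, feats_all, layer, ticks = 4:6) {
  layer <- match.arg(layer, .layer_names)
  key <- tolower(sub("H", "", layer))
  acts <- run_items(state, feats_all)[[key]]
  pattern_from_acts(acts, state[[paste0("alive_", key)]], ticks)
}

pattern_from_acts <- function(acts, alive, ticks) {
  tick_block(acts, ticks)[, rep(alive == 1, length(ticks)), drop = FALSE]
}

#' Target phonological RDM
#'
#' The reference dissimilarity structure: the RDM over the words'
#' ground-truth phonological codes (the three 25-feature target vectors
#' concatenated to one 75-vector per word). A produced-output variant is
#' available for sensitivity analyses via `patterns`.
#'
#' @param lexicon An `srn_lexicon`.
#' @param inventory The matching `srn_inventory`.
#' @param patterns `"target"` (default, ground-truth feature vectors) or a
#'   trained `srn_state`, in which case the model's produced output
#'   patterns are used instead.
#' @return An RDM over the lexicon's words.
#' @export
target_rdm <- function(lexicon, inventory, patterns = "target") {
  feats <- encode_items(lexicon$words, inventory)
  rownames(feats) <- lexicon$words$word_id
  if (inherits(patterns, "srn_state")) {
    produced <- tick_block(run_items(patterns, feats)$out, 4:6)
    rownames(produced) <- lexicon$words$word_id
    return(compute_rdm(produced))
  }
  compute_rdm(feats)
}

#' Weight strength and weight change
#'
#' Mean absolute weight and mean absolute change versus a reference
#' snapshot, over live weight entries only: weights touching dead units and
#' cross-connection entries outside the sparsity mask are excluded.
#'
#' @param state An `srn_state`.
#' @param reference_state A state with the same architecture (e.g. the
#'   pre-lesion snapshot).
#' @return A list with `mean_abs_w` and `mean_abs_dw`.
#' @export
weight_statistics <- function(state, reference_state) {
  blocks <- weight_block_masks(state)
  ref_blocks <- weight_block_masks(reference_state)
  if (!identical(lapply(blocks, function(b) dim(b$w)),
                 lapply(ref_blocks, function(b) dim(b$w))))
    stopf("architectures differ between state and reference_state")
  # the current state's live mask selects the same entries in both states,
  # so a lesioned model is compared with its own pre-lesion weights
  w <- unlist(lapply(blocks, function(b) b$w[b$mask]))
  w_ref <- unlist(mapply(function(b, rb) rb$w[b$mask], blocks, ref_blocks,
                         SIMPLIFY = FALSE))
  list(mean_abs_w = mean(abs(w)), mean_abs_dw = mean(abs(w - w_ref)))
}

# every weight block with a logical mask of its live entries
weight_block_masks <- function(state) {
  a <- function(key) state[[paste0("alive_", key)]] == 1
  l1 <- a("l1"); r1 <- a("r1"); l2 <- a("l2"); r2 <- a("r2")
  m <- function(w, rows, cols) list(w = w, mask = outer(rows, cols, "&"))
  nio <- rep(TRUE, state$config$n_io)
  list(
    m(state$W_in_l, nio, l1), m(state$W_in_r, nio, r1),
    m(state$W_ctx_l, l1, l1), m(state$W_ctx_r, r1, r1),
    m(state$W_12_l, l1, l2), m(state$W_12_r, r1, r2),
    m(state$W_out_l, l2, nio), m(state$W_out_r, r2, nio),
    list(w = state$W_x1_lr, mask = outer(l1, r1, "&") & state$M_x1_lr == 1),
    list(w = state$W_x1_rl, mask = outer(r1, l1, "&") & state$M_x1_rl == 1),
    list(w = state$W_x2_lr, mask = outer(l2, r2, "&") & state$M_x2_lr == 1),
    list(w = state$W_x2_rl, mask = outer(r2, l2, "&") & state$M_x2_rl == 1),
    list(w = as.matrix(state$b_l1), mask = as.matrix(l1)),
    list(w = as.matrix(state$b_r1), mask = as.matrix(r1)),
    list(w = as.matrix(state$b_l2), mask = as.matrix(l2)),
    list(w = as.matrix(state$b_r2), mask = as.matrix(r2)),
    list(w = as.matrix(state$b_out), mask = as.matrix(nio)))
}

#' Write an RDM as square CSV
#'
#' @param rdm A square dissimilarity matrix with word ids as dimnames.
#' @param file File path.
#' @export
write_rdm <- function(rdm, file) {
  utils::write.csv(as.data.frame(rdm), file, row.names = TRUE)
  invisible(rdm)
}
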