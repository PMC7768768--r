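#' Configuration for the bilateral simple recurrent network
#'
#' The network has two parallel pathways from a shared phonological input
#' layer to a shared phonological output layer: input -> LH1 -> LH2 -> output
#' on the left and input -> RH1 -> RH2 -> output on the right. Each first
#' hidden layer carries an Elman context (a copy of its own previous-tick
#' activation fed back as extra input). Optional sparse "homotopic"
#' cross-connections link LH1 with RH1 and LH2 with RH2 in both directions,
#' with a one-tick transmission delay.
#'
#' @param n_left,n_right Units per hidden layer on each side (LH1 and LH2
#'   both have `n_left` units; RH1 and RH2 both have `n_right`). The
#'   standard asymmetric model is 60/30.
#' @param n_io Width of the input and output phonological layers
#'   (default 25, one unit per phonetic feature).
#' @param cross_density Fraction of homotopic cross-connections present, in
#'   `[0, 1]`; 0 (default) means fully independent pathways.
#' @param cross_constraint `"free"` (cross weights develop freely) or
#'   `"negative_only"` (cross weights are clipped at 0 from above after
#'   every update, modelling purely inhibitory transcallosal links).
#' @param learning_rate Gradient-descent step per word presentation.
#' @param init_range Weights initialize i.i.d. uniform in
#'   `[-init_range, init_range]`.
#' @param backprop `"bptt"` (default): exact backpropagation through the six
#'   ticks of a trial, including the context copy; `"truncated"`: the Elman
#'   context (and delayed cross input) is treated as constant input at each
#'   tick, so no error crosses tick boundaries.
#' @param seed Integer seed controlling the initial weights and the
#'   cross-connection sparsity mask.
#' @return An object of class `srn_config`.
#' @export
network_config <- function(n_left = 60, n_right = 30, n_io = 25,
                           cross_density = 0,
                           cross_constraint = c("free", "negative_only"),
                           learning_rate = 0.02, init_range = 0.5,
                           backprop = c("bptt", "truncated"), seed = 1L) {
  cross_constraint <- match.arg(cross_constraint)
  backprop <- match.arg(backprop)
  if (n_left < 0 || n_right < 0 || n_left + n_right == 0)
    stopf("need a nonnegative number of units and at least one hidden unit")
  if (cross_density < 0 || cross_density > 1)
    stopf("cross_density must be in [0, 1]")
  if (learning_rate <= 0 || init_range <= 0)
    stopf("learning_rate and init_range must be positive")
  structure(list(n_left = as.integer(n_left), n_right = as.integer(n_right),
                 n_io = as.integer(n_io), cross_density = cross_density,
                 cross_constraint = cross_constraint,
                 learning_rate = learning_rate, init_range = init_range,
                 backprop = backprop, seed = as.integer(seed)),
            class = "srn_config")
}

#' Initialize a network state
#'
#' Draws all weights i.i.d. uniform in `[-init_range, init_range]`, draws
#' the cross-connection sparsity masks once (each direction independently,
#' entrywise with probability `cross_density`), zeroes the Elman contexts,
#' sets all layer gains to 1, and marks every unit alive. Under the
#' `negative_only` constraint the initial cross weights take the negative of
#' their absolute value, so the constraint holds from the start.
#'
#' @param config An `srn_config`.
#' @return An object of class `srn_state`: a list of weight matrices, bias
#'   vectors, sparsity masks, lesion (alive) masks, per-layer gains and the
#'   config. Weight matrices map row-activations to column-activations,
#'   e.g. `W_in_l` is `n_io x n_left`.
#' @export
#' @examples
#' st <- init_network(network_config(n_left = 8, n_right = 4, seed = 1))
#' dim(st$W_in_l)
init_network <- function(config) {
  stopifnot(inherits(config, "srn_config"))
  nL <- config$n_left; nR <- config$n_right; nio <- config$n_io
  r <- config$init_range
  with_seed(config$seed, {
    rmat <- function(a, b) matrix(stats::runif(a * b, -r, r), a, b)
    mmat <- function(a, b) matrix(stats::rbinom(a * b, 1, config$cross_density), a, b)
    masks <- list(M_x1_lr = mmat(nL, nR), M_x1_rl = mmat(nR, nL),
                  M_x2_lr = mmat(nL, nR), M_x2_rl = mmat(nR, nL))
    cross <- list(W_x1_lr = rmat(nL, nR) * masks$M_x1_lr,
                  W_x1_rl = rmat(nR, nL) * masks$M_x1_rl,
                  W_x2_lr = rmat(nL, nR) * masks$M_x2_lr,
                  W_x2_rl = rmat(nR, nL) * masks$M_x2_rl)
    if (config$cross_constraint == "negative_only")
      cross <- lapply(cross, function(w) -abs(w))
    st <- c(list(W_in_l = rmat(nio, nL), W_in_r = rmat(nio, nR),
                 W_ctx_l = rmat(nL, nL), W_ctx_r = rmat(nR, nR),
                 W_12_l = rmat(nL, nL), W_12_r = rmat(nR, nR),
                 W_out_l = rmat(nL, nio), W_out_r = rmat(nR, nio)),
            cross, masks,
            list(b_l1 = stats::runif(nL, -r, r), b_r1 = stats::runif(nR, -r, r),
                 b_l2 = stats::runif(nL, -r, r), b_r2 = stats::runif(nR, -r, r),
                 b_out = stats::runif(nio, -r, r),
                 alive_l1 = rep(1, nL), alive_r1 = rep(1, nR),
                 alive_l2 = rep(1, nL), alive_r2 = rep(1, nR),
                 gain = c(LH1 = 1, RH1 = 1, LH2 = 1, RH2 = 1),
                 neg_only = as.integer(config$cross_constraint == "negative_only"),
                 lesion = NULL, config = config))
    structure(st, class = "srn_state")
  })
}

#' @export
print.srn_state <- function(x, ...) {
  cfg <- x$config
  dead <- vapply(x[c("alive_l1", "alive_r1", "alive_l2", "alive_r2")],
                 function(a) sum(a == 0), numeric(1))
  cat(sprintf("<srn_state> %d/%d hidden units per layer, cross density %.2f (%s)\n",
              cfg$n_left, cfg$n_right, cfg$cross_density, cfg$cross_constraint))
  if (any(dead > 0))
    cat(sprintf("  lesioned: %s dead units in %s\n",
                paste(dead[dead > 0], collapse = "/"),
                paste(c("LH1", "RH1", "LH2", "RH2")[dead > 0], collapse = "/")))
  invisible(x)
}

.layer_names <- c("LH1", "RH1", "LH2", "RH2")
.silence_code <- function(silence) {
  match(match.arg(silence, c("none", "left", "right")),
        c("none", "left", "right")) - 1L
}

#' Run one six-tick trial
#'
#' Ticks 1-3 present the word's three phoneme feature vectors at the input
#' layer; ticks 4-6 present a zero input while the network must produce the
#' three phonemes at the output layer, driven by its Elman context. Hidden
#' activation is `logistic(gain * net)`, clamped to 0 for lesioned (dead)
#' units; contexts reset to zero at trial start.
#'
#' @param state An `srn_state`.
#' @param features A 3 x n_io feature matrix (see [encode()]).
#' @param silence `"none"`, `"left"` or `"right"`: zero the input-to-H1
#'   contribution of one side for this trial only (non-destructively), the
#'   pathway-silencing probe used by the laterality measures.
#' @return An object of class `srn_trial`: a list of 6 x n activation
#'   matrices `l1`, `r1`, `l2`, `r2`, `out` (one row per tick).
#' @export
forward_trial <- function(state, features, silence = "none") {
  stopifnot(inherits(state, "srn_state"))
  features <- as.matrix(features)
  if (nrow(features) != 3L || ncol(features) != state$config$n_io)
    stopf("features must be a 3 x %d matrix", state$config$n_io)
  acts <- .srn_forward_cpp(state, features, .silence_code(silence))
  structure(acts, class = "srn_trial")
}

#' One online training step
#'
#' Runs a forward trial on a word, computes the cross-entropy error of the
#' three production ticks against the word's feature rows, backpropagates,
#' and applies a plain gradient-descent update (step = `learning_rate`).
#' Dead units receive no updates; cross weights are re-projected onto their
#' sparsity mask and, under `negative_only`, clipped at 0 from above.
#'
#' @param state An `srn_state`.
#' @param features A 3 x n_io feature matrix (input and target).
#' @param learning_rate Optional override of the configured rate.
#' @return A list with the updated `state` and the pre-update `loss`.
#' @export
train_step <- function(state, features, learning_rate = NULL) {
  stopifnot(inherits(state, "srn_state"))
  features <- as.matrix(features)
  lr <- learning_rate %||% state$config$learning_rate
  res <- .srn_train_step_cpp(state, features, lr,
                             state$config$backprop == "truncated")
  state[names(res$weights)] <- res$weights
  list(state = state, loss = res$loss)
}

#' Set the gain of one hidden layer
#'
#' Gain multiplies the net input inside the logistic: activation =
#' `logistic(g * net)`. At `g = 0` a layer's live units are pinned at 0.5
#' and contribute no gradient (the derivative term `g * a * (1 - a)`
#' vanishes), which is how inefficient early relearning is modelled.
#'
#' @param state An `srn_state`.
#' @param layer One of `"LH1"`, `"RH1"`, `"LH2"`, `"RH2"`.
#' @param g Gain in `[0, 1]`.
#' @return The modified state.
#' @export
set_layer_gain <- function(state, layer, g) {
  stopifnot(inherits(state, "srn_state"))
  layer <- match.arg(layer, .layer_names)
  if (!is.finite(g) || g < 0 || g > 1) stopf("gain must be in [0, 1]")
  state$gain[layer] <- g
  state
}

#' Save / load a network checkpoint
#'
#' Checkpoints are single-file serialized images of the full state (all
#' weight blocks, masks, gains, lesion record and config); the round trip
#' is bit-exact.
#'
#' @param state An `srn_state`.
#' @param file File path.
#' @export
save_network <- function(state, file) {
  stopifnot(inherits(state, "srn_state"))
  saveRDS(state, file)
  invisible(state)
}

#' @rdname save_network
#' @export
load_network <- function(file) {
  state <- readRDS(file)
  stopifnot(inherits(state, "srn_state"))
  state
}

# Forward-run a batch of encoded items (items x 3*n_io) without learning.
# Returns per-layer matrices whose rows concatenate the six ticks.
run_items <- function(state, feats_all, silence = "none") {
  .srn_run_items_cpp(state, feats_all, .silence_code(silence))
}
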