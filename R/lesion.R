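#' Specify a lesion
#'
#' A lesion damages one first hidden layer: a random subset of its units
#' dies permanently, and one-time additive Gaussian noise perturbs every
#' weight into and out of the layer (surviving units' weights included).
#' The graded severity scheme pairs damage proportions 0.1-1.0 with noise
#' levels 0.1-1.0.
#'
#' @param layer `"LH1"` or `"RH1"`.
#' @param proportion Fraction of the layer's units to kill, in `[0, 1]`.
#' @param noise Noise level v >= 0 for the weight perturbation.
#' @param seed Integer seed for the lesion draw, independent of the
#'   training RNG.
#' @param noise_as `"variance"` (default): v is the Gaussian variance
#'   (sd = sqrt(v)); `"sd"`: v is the standard deviation. Graded noise
#'   levels of this kind are reported sometimes as a variance and sometimes
#'   as a range; the variance reading is the default and the switch makes
#'   the alternative testable (the qualitative behaviour should not depend
#'   on it).
#' @return An object of class `srn_lesion_spec`.
#' @export
lesion_spec <- function(layer = c("LH1", "RH1"), proportion, noise = 0,
                        seed = 1L, noise_as = c("variance", "sd")) {
  layer <- match.arg(layer)
  noise_as <- match.arg(noise_as)
  if (proportion < 0 || proportion > 1) stopf("proportion must be in [0, 1]")
  if (noise < 0) stopf("noise must be nonnegative")
  structure(list(layer = layer, proportion = proportion, noise = noise,
                 seed = as.integer(seed), noise_as = noise_as),
            class = "srn_lesion_spec")
}

#' Apply a lesion to a network
#'
#' Marks `floor(proportion * n_layer)` uniformly chosen live units of the
#' target layer dead (activation clamped to 0, no further weight updates)
#' and adds one draw of Gaussian noise to all weights into and out of the
#' layer: input, context, inter-layer and cross blocks. Cross-connection
#' noise respects the sparsity mask, and under the `negative_only`
#' constraint cross weights are re-clipped after the perturbation. Dead
#' units are masked rather than removed, so lesioned and perilesional
#' populations stay addressable for measurement.
#'
#' @param state An `srn_state`.
#' @param spec An `srn_lesion_spec`.
#' @return The lesioned state; `state$lesion` records the spec and the
#'   dead-unit indices.
#' @export
apply_lesion <- function(state, spec) {
  stopifnot(inherits(state, "srn_state"), inherits(spec, "srn_lesion_spec"))
  key <- if (spec$layer == "LH1") "l1" else "r1"
  alive <- state[[paste0("alive_", key)]]
  if (!any(alive == 1)) stopf("layer %s is already fully dead", spec$layer)
  n_layer <- length(alive)
  n_kill <- floor(spec$proportion * n_layer)
  live_idx <- which(alive == 1)
  if (n_kill > length(live_idx))
    stopf("requested %d dead units but only %d are alive", n_kill,
          length(live_idx))
  sd <- if (spec$noise_as == "sd") spec$noise else sqrt(spec$noise)
  state <- with_seed(spec$seed, {
    kill <- if (n_kill > 0) sample(live_idx, n_kill) else integer(0)
    alive[kill] <- 0
    state[[paste0("alive_", key)]] <- alive
    perturb <- function(w) w + stats::rnorm(length(w), 0, sd)
    if (spec$layer == "LH1") {
      state$W_in_l <- perturb(state$W_in_l)
      state$W_ctx_l <- perturb(state$W_ctx_l)
      state$W_12_l <- perturb(state$W_12_l)
      state$W_x1_lr <- perturb(state$W_x1_lr) * state$M_x1_lr
      state$W_x1_rl <- perturb(state$W_x1_rl) * state$M_x1_rl
    } else {
      state$W_in_r <- perturb(state$W_in_r)
      state$W_ctx_r <- perturb(state$W_ctx_r)
      state$W_12_r <- perturb(state$W_12_r)
      state$W_x1_rl <- perturb(state$W_x1_rl) * state$M_x1_rl
      state$W_x1_lr <- perturb(state$W_x1_lr) * state$M_x1_lr
    }
    if (state$neg_only == 1L) {
      state$W_x1_lr <- pmin(state$W_x1_lr, 0)
      state$W_x1_rl <- pmin(state$W_x1_rl, 0)
    }
    state$lesion <- list(layer = spec$layer, dead = sort(which(alive == 0)),
                         spec = spec)
    state
  })
  state
}

#' Gain ramp of the inefficient-learning recovery schedule
#'
#' During the first 10,000 presentations of retraining, the lesioned
#' layer's gain steps from 0 to 1 in increments of 0.1: g = 0 for
#' presentations [0, 1000), 0.1 for [1000, 2000), ..., 1 from 10,000 on.
#'
#' @param presentations Presentations completed since recovery started.
#' @return The gain value in `[0, 1]`.
#' @export
#' @examples
#' recovery_gain(5500)  # 0.5
recovery_gain <- function(presentations) {
  pmin(1, floor(presentations / 1000) / 10)
}

#' Retrain a lesioned network (recovery phase)
#'
#' Re-exposes the damaged model to its learning environment under the same
#' frequency-weighted sampling and update regime as [train()]. With
#' `ramp = TRUE` the lesioned layer's surviving units start with gain 0 and
#' regain it in steps of 0.1 over the first 10,000 presentations
#' ([recovery_gain()]), modelling initially inefficient relearning; all
#' other layers keep gain 1. Checkpoints record accuracy by item type,
#' left/right pathway output activation, mean hidden activation split into
#' perilesional and lesioned populations, per-layer RSA scores, and weight
#' statistics versus the pre-lesion snapshot when one is supplied.
#'
#' @param state A lesioned `srn_state` (ramp requires `state$lesion`).
#' @param lexicon,inventory Training environment.
#' @param n_presentations Recovery length (the full protocol uses 100,000).
#' @param ramp Enable the gain ramp (disable to probe its role).
#' @param eval_every Checkpoint cadence (default 1000: fine resolution for
#'   the acute phase).
#' @param reference_state Optional pre-lesion snapshot for weight-change
#'   statistics.
#' @return A list with the retrained `state` and `trajectory`, a checkpoint
#'   data frame whose first row is at 0 presentations (immediately
#'   post-lesion).
#' @export
retrain <- function(state, lexicon, inventory, n_presentations = 100000,
                    ramp = TRUE, eval_every = 1000, reference_state = NULL) {
  stopifnot(inherits(state, "srn_state"))
  schedule <- NULL
  if (ramp) {
    if (is.null(state$lesion))
      stopf("the gain ramp requires a lesioned state")
    layer <- state$lesion$layer
    schedule <- function(p) {
      g <- stats::setNames(recovery_gain(p), layer)
      nxt <- if (p < 10000) (floor(p / 1000) + 1) * 1000 else Inf
      attr(g, "next_change") <- nxt
      g
    }
  }
  res <- train(state, lexicon, inventory, n_presentations,
               eval_every = eval_every, measures = TRUE,
               gain_schedule = schedule, reference_state = reference_state)
  names(res)[names(res) == "log"] <- "trajectory"
  res
}
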