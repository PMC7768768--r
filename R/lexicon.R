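#' Generate a synthetic phoneme inventory
#'
#' Builds the alphabet of the phonological code: a set of consonants and
#' vowels, each represented by a 25-dimensional binary phonetic feature
#' vector. Feature 1 is a reserved consonant/vowel indicator (0 for
#' consonants, 1 for vowels); the remaining features are drawn at random,
#' with resampling to keep all feature vectors pairwise distinct. The
#' feature code is synthetic: it preserves the dimensionality and the
#' within-class similarity structure the repetition model needs, not the
#' phonetics of any particular language.
#'
#' @param seed Integer seed; the inventory is a deterministic function of it.
#' @param n_consonants,n_vowels Number of consonants and vowels. The
#'   defaults (18 and 6) allow 18 x 6 x 18 = 1944 distinct CVC triples.
#' @param n_features Feature dimensionality per phoneme slot (default 25).
#' @param feature_p Probability that a random feature is active (default
#'   0.3: phonetic feature codes are sparse; each phoneme activates a
#'   minority of the features).
#' @return An object of class `srn_inventory`: a list with `symbols`,
#'   `klass` (`"consonant"`/`"vowel"`), and a `features` matrix (phonemes x
#'   features, rownames = symbols).
#' @export
#' @examples
#' inv <- build_inventory(seed = 1)
#' dim(inv$features)
build_inventory <- function(seed, n_consonants = 18, n_vowels = 6,
                            n_features = 25, feature_p = 0.3) {
  if (n_consonants < 2 || n_vowels < 1)
    stopf("need at least 2 consonants and 1 vowel")
  if (n_features < 2)
    stopf("n_features must be >= 2 (one slot is the class indicator)")
  cons_pool <- c("p", "b", "t", "d", "k", "g", "m", "n", "f", "v", "s", "z",
                 "l", "r", "w", "j", "h", "c", "q", "x", "th", "sh", "ch", "ng")
  vowel_pool <- c("a", "e", "i", "o", "u", "y", "ee", "oo", "ai", "ou")
  label <- function(pool, n, prefix) {
    if (n <= length(pool)) pool[seq_len(n)]
    else c(pool, sprintf("%s%02d", prefix, seq_len(n - length(pool))))
  }
  symbols <- c(label(cons_pool, n_consonants, "C"),
               label(vowel_pool, n_vowels, "V"))
  klass <- rep(c("consonant", "vowel"), c(n_consonants, n_vowels))
  n <- n_consonants + n_vowels
  feats <- with_seed(seed, {
    f <- matrix(stats::rbinom(n * (n_features - 1), 1, feature_p), nrow = n)
    # resample any duplicated random part until all rows are distinct;
    # the class indicator alone cannot separate within-class pairs
    repeat {
      dup <- duplicated(apply(f, 1, paste, collapse = ""))
      if (!any(dup)) break
      f[dup, ] <- stats::rbinom(sum(dup) * (n_features - 1), 1, feature_p)
    }
    f
  })
  features <- cbind(as.numeric(klass == "vowel"), feats)
  dimnames(features) <- list(symbols, NULL)
  structure(list(symbols = symbols, klass = klass, features = features),
            class = "srn_inventory")
}

#' @export
print.srn_inventory <- function(x, ...) {
  cat(sprintf("<srn_inventory> %d consonants + %d vowels, %d features\n",
              sum(x$klass == "consonant"), sum(x$klass == "vowel"),
              ncol(x$features)))
  invisible(x)
}

#' Generate the training lexicon
#'
#' Samples distinct consonant-vowel-consonant (CVC) words split into a
#' high-frequency (HF) and a low-frequency (LF) band, assigns token
#' frequencies from two disjoint uniform ranges, derives the log-compressed
#' presentation probabilities, and builds the nonword probe list by
#' single-phoneme substitution.
#'
#' @param inventory An `srn_inventory`.
#' @param seed Integer seed.
#' @param n_hf,n_lf Number of high-/low-frequency words (defaults 100 each).
#' @param n_nonwords Number of nonword probes (default 25).
#' @param hf_range,lf_range Inclusive integer token-frequency ranges for the
#'   two bands; they must be disjoint with the HF band above the LF band so
#'   that every HF word outnumbers every LF word.
#' @return An object of class `srn_lexicon`: a list with `words` (data frame
#'   `word_id`, `p1`, `p2`, `p3`, `freq_class`, `token_freq`), `nonwords`
#'   (data frame `p1`, `p2`, `p3`), and `probs` (presentation probabilities
#'   over the words, summing to 1).
#' @export
#' @examples
#' inv <- build_inventory(seed = 1)
#' lex <- generate_lexicon(inv, seed = 1)
#' table(lex$words$freq_class)
generate_lexicon <- function(inventory, seed, n_hf = 100, n_lf = 100,
                             n_nonwords = 25,
                             hf_range = c(200, 2000), lf_range = c(1, 20)) {
  stopifnot(inherits(inventory, "srn_inventory"))
  if (lf_range[1] < 1) stopf("token frequencies must be positive")
  if (hf_range[1] <= lf_range[2])
    stopf("HF and LF frequency ranges must be disjoint (HF above LF)")
  cons <- inventory$symbols[inventory$klass == "consonant"]
  vows <- inventory$symbols[inventory$klass == "vowel"]
  n_words <- n_hf + n_lf
  n_combos <- length(cons)^2 * length(vows)
  if (n_words > n_combos)
    stopf("inventory supports only %d distinct CVC triples; %d requested",
          n_combos, n_words)
  lex <- with_seed(seed, {
    combos <- expand.grid(p1 = cons, p2 = vows, p3 = cons,
                          stringsAsFactors = FALSE)
    pick <- sample.int(nrow(combos), n_words)
    words <- combos[pick, , drop = FALSE]
    rownames(words) <- NULL
    words$word_id <- sprintf("w%03d", seq_len(n_words))
    words$freq_class <- rep(c("HF", "LF"), c(n_hf, n_lf))
    words$token_freq <- c(
      sample(hf_range[1]:hf_range[2], n_hf, replace = TRUE),
      sample(lf_range[1]:lf_range[2], n_lf, replace = TRUE))
    words[, c("word_id", "p1", "p2", "p3", "freq_class", "token_freq")]
  })
  out <- structure(list(words = lex, nonwords = NULL, probs = NULL),
                   class = "srn_lexicon")
  out$probs <- presentation_probabilities(out)
  out$nonwords <- generate_nonwords(out, inventory, seed = seed + 1L,
                                    n = n_nonwords)
  out
}

#' @export
print.srn_lexicon <- function(x, ...) {
  cat(sprintf("<srn_lexicon> %d words (%d HF, %d LF), %d nonwords\n",
              nrow(x$words), sum(x$words$freq_class == "HF"),
              sum(x$words$freq_class == "LF"),
              if (is.null(x$nonwords)) 0L else nrow(x$nonwords)))
  invisible(x)
}

#' Generate nonword probes by single-phoneme substitution
#'
#' Each nonword is built from a randomly chosen word by replacing the first
#' consonant, the vowel, or the final consonant with another phoneme of the
#' same class, and is accepted only if the resulting triple is not itself a
#' word and has not already been generated.
#'
#' @param lexicon An `srn_lexicon` (its `words` table is used).
#' @param inventory The `srn_inventory` the lexicon was built from.
#' @param seed Integer seed.
#' @param n Number of nonwords (default 25).
#' @return Data frame with columns `p1`, `p2`, `p3`.
#' @export
generate_nonwords <- function(lexicon, inventory, seed, n = 25) {
  stopifnot(inherits(lexicon, "srn_lexicon"))
  words <- lexicon$words
  word_keys <- paste(words$p1, words$p2, words$p3, sep = ".")
  cons <- inventory$symbols[inventory$klass == "consonant"]
  vows <- inventory$symbols[inventory$klass == "vowel"]
  with_seed(seed, {
    found <- character(0)
    out <- vector("list", n)
    tries <- 0L
    while (length(found) < n) {
      tries <- tries + 1L
      if (tries > 10000L)
        stopf("could not assemble %d distinct nonwords", n)
      w <- words[sample.int(nrow(words), 1L), ]
      slot <- sample.int(3L, 1L)
      pool <- if (slot == 2L) vows else cons
      old <- w[[c("p1", "p2", "p3")[slot]]]
      repl <- sample(setdiff(pool, old), 1L)
      cand <- c(w$p1, w$p2, w$p3)
      cand[slot] <- repl
      key <- paste(cand, collapse = ".")
      if (key %in% word_keys || key %in% found) next
      found <- c(found, key)
      out[[length(found)]] <- cand
    }
    nw <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
    names(nw) <- c("p1", "p2", "p3")
    nw
  })
}

#' Encode a phoneme triple as a feature sequence
#'
#' @param triple Character vector of three phoneme symbols (C, V, C).
#' @param inventory An `srn_inventory`.
#' @return A 3 x n_features numeric matrix; row t is the feature vector of
#'   phoneme t.
#' @export
encode <- function(triple, inventory) {
  stopifnot(inherits(inventory, "srn_inventory"))
  triple <- as.character(triple)
  if (length(triple) != 3L) stopf("a word is a triple of phoneme symbols")
  unknown <- setdiff(triple, inventory$symbols)
  if (length(unknown) > 0)
    stopf("unknown phoneme symbol(s): %s", paste(unknown, collapse = ", "))
  inventory$features[triple, , drop = FALSE]
}

# Encode a set of items (data frame with p1..p3 or character matrix) into
# the item x (3 * n_features) layout the C++ core consumes.
encode_items <- function(items, inventory) {
  if (is.data.frame(items)) items <- as.matrix(items[, c("p1", "p2", "p3")])
  t(apply(items, 1L, function(tr) as.vector(t(encode(tr, inventory)))))
}

#' Log-compressed presentation probabilities
#'
#' The probability of presenting word w during training is proportional to
#' `log(1 + token_freq(w))`, compressing the heavy-tailed token-frequency
#' distribution the way word-frequency effects are usually modelled.
#'
#' @param x An `srn_lexicon`, or a numeric vector of positive token
#'   frequencies.
#' @return Numeric probability vector summing to 1.
#' @export
presentation_probabilities <- function(x) {
  f <- if (inherits(x, "srn_lexicon")) x$words$token_freq else x
  if (any(!is.finite(f)) || any(f <= 0))
    stopf("token frequencies must be positive")
  w <- log1p(f)
  w / sum(w)
}

#' Write / read a lexicon as tab-separated text
#'
#' Words and nonwords are stored as two TSV files; the presentation
#' probabilities are recomputed from the token frequencies on read, so the
#' round trip is lossless.
#'
#' @param lexicon An `srn_lexicon`.
#' @param words_file,nonwords_file File paths.
#' @return `write_lexicon` returns the lexicon invisibly; `read_lexicon`
#'   returns an `srn_lexicon`.
#' @export
write_lexicon <- function(lexicon, words_file, nonwords_file) {
  stopifnot(inherits(lexicon, "srn_lexicon"))
  utils::write.table(lexicon$words, words_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(lexicon$nonwords, nonwords_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(lexicon)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(words_file, nonwords_file) {
  words <- utils::read.table(words_file, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "character", "character",
                                            "character", "integer"))
  nonwords <- utils::read.table(nonwords_file, sep = "\t", header = TRUE,
                                colClasses = "character")
  out <- structure(list(words = words, nonwords = nonwords, probs = NULL),
                   class = "srn_lexicon")
  out$probs <- presentation_probabilities(out)
  out
}

#' Write / read a phoneme inventory as JSON
#'
#' @param inventory An `srn_inventory`.
#' @param file File path.
#' @export
write_inventory <- function(inventory, file) {
  stopifnot(inherits(inventory, "srn_inventory"))
  obj <- lapply(seq_along(inventory$symbols), function(i) {
    list(klass = inventory$klass[i],
         features = as.numeric(inventory$features[i, ]))
  })
  names(obj) <- inventory$symbols
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(inventory)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  symbols <- names(obj)
  klass <- vapply(obj, function(x) x$klass, character(1))
  features <- do.call(rbind, lapply(obj, function(x) as.numeric(x$features)))
  dimnames(features) <- list(symbols, NULL)
  structure(list(symbols = symbols, klass = unname(klass),
                 features = features),
            class = "srn_inventory")
}
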