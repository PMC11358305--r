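#' Stimulus identifiers used by both tasks
#'
#' Both tasks present pairs drawn from a set of five stimuli, each worth
#' 1--5 drops of juice under the reward pattern currently in force.
#'
#' @return Character vector `c("S1", ..., "S5")`.
#' @export
stimuli <- function() paste0("S", 1:5)

stim_index <- function(stim) {
  idx <- match(stim, stimuli())
  if (anyNA(idx)) {
    abort(paste0("unknown stimulus id: ", paste(unique(stim[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Stimulus-reward map for a pattern
#'
#' Pattern A assigns stimulus `Si` a reward of `i` drops; pattern B is the
#' pointwise reversal, `6 - i` drops. A reversal swaps the two patterns, so
#' a 1-drop stimulus becomes a 5-drop stimulus, a 2-drop stimulus becomes a
#' 4-drop stimulus, and the 3-drop stimulus keeps its value.
#'
#' @param pattern `"A"` or `"B"`.
#' @return Named integer vector mapping each stimulus id to drops of juice,
#'   with a `pattern` attribute.
#' @examples
#' reward_map("A")
#' reverse_map(reward_map("A"))
#' @export
reward_map <- function(pattern = c("A", "B")) {
  pattern <- match.arg(pattern)
  drops <- if (pattern == "A") 1:5 else 6L - 1:5
  structure(setNames(as.integer(drops), stimuli()), pattern = pattern)
}

#' Reverse a stimulus-reward map
#'
#' @param map A map from [reward_map()].
#' @return The reversed map: each stimulus worth `r` drops becomes worth
#'   `6 - r`, and the pattern label is flipped.
#' @export
reverse_map <- function(map) {
  stopifnot(is.integer(map), length(map) == 5L, setequal(map, 1:5))
  pattern <- attr(map, "pattern")
  structure(setNames(6L - map, names(map)),
            pattern = if (identical(pattern, "A")) "B" else "A")
}
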