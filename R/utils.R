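#' @keywords internal
"_PACKAGE"

# Actions are coded internally as integers 1 (L) and 2 (R); user-facing tables
# carry the literal characters "L"/"R".
.ACTIONS <- c("L", "R")

#' Logistic sigmoid
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, computed stably for large `|x|`.
#' @export
sigmoid <- function(x) {
  # plogis is the numerically safe logistic CDF
  stats::plogis(x)
}

#' Softmax policy over action logits
#'
#' Converts a vector of per-action logits into a probability vector. The
#' maximum logit is subtracted before exponentiation so that arbitrarily
#' large logits do not overflow; the result is invariant to adding any
#' constant to all logits.
#'
#' @param logits numeric vector of finite per-action logits.
#' @return numeric probability vector of the same length, summing to 1.
#' @examples
#' softmax_policy(c(0, 0))        # c(0.5, 0.5)
#' softmax_policy(c(1, 0))        # sigmoid(1) on the first action
#' @export
softmax_policy <- function(logits) {
  if (anyNA(logits) || any(!is.finite(logits))) {
    stop("softmax_policy: logits must be finite and non-NA")
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

# Map "L"/"R" (or already-integer 1/2) to integer codes, with validation.
action_to_int <- function(action) {
  if (is.numeric(action)) {
    a <- as.integer(action)
    if (any(!a %in% c(1L, 2L))) stop("actions must be 1 (L) or 2 (R)")
    return(a)
  }
  a <- match(as.character(action), .ACTIONS)
  if (anyNA(a)) stop("unknown action symbol; expected 'L' or 'R'")
  a
}

int_to_action <- function(a) .ACTIONS[a]

check_prob <- function(p, what = "probability") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("invalid %s: values must lie in [0, 1]", what))
  }
  invisible(p)
}

check_reward <- function(r) {
  if (any(!r %in% c(0, 1))) stop("rewards must be 0 or 1")
  invisible(r)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Used so schedule building, jitter, etc. are
# reproducible without trampling the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit signed-integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 9973) %% 2147483647)
}
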