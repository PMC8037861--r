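# Internal helpers shared across modules.

ATTENTION <- "ATTENTION"
INATTENTION <- "INATTENTION"

#' Attention-state factor levels
#'
#' The two operator states recognized throughout the package, in the order
#' used for factor levels and confusion-matrix layout (INATTENTION is the
#' positive class).
#'
#' @return Character vector `c("ATTENTION", "INATTENTION")`.
#' @export
attention_levels <- function() c(ATTENTION, INATTENTION)

# Coerce a label vector to the canonical factor.
as_state_factor <- function(x) {
  f <- factor(as.character(x), levels = attention_levels())
  if (anyNA(f)) stop("labels must be 'ATTENTION' or 'INATTENTION'")
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# A NULL seed draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
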