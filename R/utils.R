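`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG state
#'
#' Runs \code{code} after \code{set.seed(seed)} and restores the caller's
#' \code{.Random.seed} on exit, so seeded package functions do not disturb the
#' session RNG stream.
#'
#' @param seed integer seed, or \code{NULL} to leave the RNG alone.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Conventional module colour order: largest module is "turquoise", the third
# largest "brown", etc. Overflow falls back to numbered labels.
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
)

module_color_names <- function(k) {
  if (k <= length(.module_colors)) .module_colors[seq_len(k)]
  else c(.module_colors, sprintf("module%d", seq_len(k - length(.module_colors)) +
                                   length(.module_colors)))
}

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

.check_matrix <- function(x, what = "x") {
  if (inherits(x, "clr_table")) x <- unclass(x)
  .assert(is.matrix(x) && is.numeric(x), sprintf("'%s' must be a numeric matrix", what))
  .assert(!is.null(colnames(x)), sprintf("'%s' must have column (taxon) names", what))
  x
}
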