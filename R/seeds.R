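#' Derive a reproducible sub-seed from a master seed
#'
#' Folds a master seed together with an arbitrary sequence of integer or
#' character labels into a new seed, so that independent random draws
#' (wiring, heterogeneity, initial conditions, realizations, sweep cells)
#' each get their own stream.  Adding new labels never changes the seed
#' obtained for existing ones, which keeps previously computed sweep cells
#' stable when a grid is extended.
#'
#' @param master integer master seed.
#' @param ... integers or character strings naming the sub-stream
#'   (e.g. `"wiring"`, or `"cell", 75, 5, 3`).
#' @return an integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' derive_seed(1, "wiring")
#' derive_seed(1, "cell", 75, 5, 1)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(master) %% m)
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.numeric(lab)
    for (x in codes) {
      # multiplicative fold; all intermediates stay below 2^53 (exact doubles)
      h <- (h * 48271 + (abs(x) %% m) + 1) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}
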