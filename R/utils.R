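# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that pipelines are reproducible without clobbering the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# keeping the result within R's 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name), class = "metvolume_input_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name), class = "metvolume_input_error")
  }
  invisible(x)
}

#' Convert between cubic millimetres and cubic centimetres
#'
#' METV is reported in mm\eqn{^3} while functional tumor volume (FTV) is
#' conventionally reported in cm\eqn{^3}; these helpers convert between the two.
#'
#' @param x Numeric vector of volumes.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' mm3_to_cm3(114)    # 0.114
#' cm3_to_mm3(2.8)    # 2800
mm3_to_cm3 <- function(x) x / 1000

#' @rdname mm3_to_cm3
#' @export
cm3_to_mm3 <- function(x) x * 1000
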