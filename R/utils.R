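# Internal helpers: seed substreams, validation, RNG hygiene.

# Derive a child seed from a master seed and a named substream + index.
# Keeps results < 2^31 and decorrelates streams so that, e.g., adding fields
# to a well does not perturb the draws of earlier fields.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  val <- (as.double(seed) * 48271 + h * 30269 + as.double(index) * 69621) %% 2147483629
  as.integer(val) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)),
          class = "evtirf_config_error")
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name),
          class = "evtirf_config_error")
  }
  invisible(x)
}

config_error <- function(msg) abort(msg, class = "evtirf_config_error")
input_error  <- function(msg) abort(msg, class = "evtirf_input_error")
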