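# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a stream name,
# so each simulation stage draws from its own independent, named stream.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(as.integer(seed)) + h) %% 2147483647)
}

# Run `expr` under the RNG state implied by (seed, stream) without touching
# the caller's RNG.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(stream_seed(seed, stream), expr)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_base <- function(x) {
  unname(DNA_COMPLEMENT[x])
}

# Transition partner of each base; anything else is a transversion.
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(ref, alt) {
  TRANSITION_PARTNER[ref] == alt
}

assert_columns <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}
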