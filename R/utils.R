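# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label, kept within the
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

assert_binary_mask <- function(m, name = "mask") {
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1); found other values", name),
         call. = FALSE)
  invisible(TRUE)
}

clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)
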