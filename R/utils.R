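`%||%` <- function(a, b) if (is.null(a)) b else a

sg_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

sg_check <- function(cond, fmt, ...) if (!isTRUE(cond)) sg_stop(fmt, ...)

is_odd <- function(k) k %% 2 == 1

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
sg_with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Derive n child seeds (< 2^31) from a parent seed, reproducibly.
sg_child_seeds <- function(seed, n) {
  sg_with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Ensure a (H, W, C, N) batch array from (H, W, C) or (H, W, C, N) input.
as_batch <- function(x) {
  d <- dim(x)
  sg_check(!is.null(d) && length(d) %in% c(3L, 4L),
           "expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}
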