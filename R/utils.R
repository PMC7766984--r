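#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.  All images are base R numeric
# matrices (grayscale) or H x W x 3 arrays (colour) with intensities in [0,1].

stop_stage <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  cond <- structure(
    class = c("medfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), stage = stage)
  )
  stop(cond)
}

assert_gray <- function(x, stage = "input", min_dim = 2L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_stage(stage, "expected a numeric matrix (grayscale image)")
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop_stage(stage, "image must be at least ", min_dim, "x", min_dim)
  if (!all(is.finite(x)))
    stop_stage(stage, "image contains non-finite values")
  invisible(x)
}

assert_same_shape <- function(stage = "input", ...) {
  imgs <- list(...)
  d <- dim(imgs[[1L]])
  for (im in imgs[-1L]) {
    if (!identical(dim(im), d))
      stop_stage(stage, "images must share the same shape")
  }
  invisible(NULL)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Derive a distinct sub-stream seed (< 2^31) from a user seed and a salt.
mix_seed <- function(seed, salt = 0) {
  ((abs(seed) %% 1e6) * 2654435 + salt * 9973 + 13) %% 2147483647
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
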