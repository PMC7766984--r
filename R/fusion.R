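# Trace-based fusion strategy.
#
# Each source's feature stack is reduced to a scalar salience: the sum over
# maps of the absolute matrix trace (sum of main-diagonal entries; for a
# symmetric map this is the sum of its eigenvalues).  Normalised saliences
# become convex weights and the fused stack is the weighted sum of the
# source stacks, map by map.

#' Trace of a feature map
#'
#' Sum of main-diagonal entries `m[d, d]`; rectangular maps use the
#' diagonal of length `min(nrow, ncol)`.  For square symmetric maps this
#' equals the sum of eigenvalues.
#'
#' @param m numeric matrix.
#' @return Scalar trace.
#' @examples
#' map_trace(diag(3))
#' @export
map_trace <- function(m) {
  if (!is.matrix(m)) stop_stage("fusion", "map_trace() expects a matrix")
  d <- seq_len(min(dim(m)))
  sum(m[cbind(d, d)])
}

stack_salience <- function(stack, signed = FALSE) {
  d <- dim(stack)
  tr <- vapply(seq_len(d[3]), function(j) map_trace(stack[, , j]), numeric(1))
  if (signed) sum(tr) else sum(abs(tr))
}

#' Trace-derived fusion weights
#'
#' One scalar weight per source: the per-stack sum of absolute map traces,
#' normalised to sum to one.  SeLU features can carry negative traces, so
#' absolute values keep the weights well defined; `signed = TRUE` preserves
#' the literal signed sums instead.  If every salience is zero the weights
#' fall back to uniform `1/k`.
#'
#' @param stacks list of >= 2 `feature_stack`s with identical shapes.
#' @param signed aggregate signed traces instead of absolute values.
#' @return Numeric weight vector of class `fusion_weights`, summing to 1.
#' @export
fusion_weights <- function(stacks, signed = FALSE) {
  check_stacks(stacks)
  s <- vapply(stacks, stack_salience, numeric(1), signed = signed)
  tot <- sum(s)
  w <- if (tot == 0) rep(1 / length(s), length(s)) else s / tot
  structure(w, class = "fusion_weights")
}

#' Fuse feature stacks by convex combination
#'
#' `fused[, , j] = sum_i w[i] * stacks[[i]][, , j]` for every map index j.
#'
#' @inheritParams fusion_weights
#' @param w weights, one per stack (any numeric vector summing to 1, e.g.
#'   from [fusion_weights()]).
#' @return A `feature_stack` of the common shape.
#' @export
fuse_features <- function(stacks, w = fusion_weights(stacks)) {
  check_stacks(stacks)
  if (length(w) != length(stacks))
    stop_stage("fusion", "need one weight per stack")
  out <- array(0, dim(stacks[[1L]]))
  for (i in seq_along(stacks)) out <- out + w[i] * unclass(stacks[[i]])
  feature_stack(out, source = "fused")
}

#' Mean (addition-strategy) fusion baseline
#'
#' Plain average of the source stacks; the addition strategy used as a
#' baseline against trace weighting.
#'
#' @inheritParams fusion_weights
#' @return A `feature_stack`.
#' @export
fuse_features_mean <- function(stacks) {
  fuse_features(stacks, rep(1 / length(stacks), length(stacks)))
}

check_stacks <- function(stacks) {
  if (!is.list(stacks) || length(stacks) < 2L)
    stop_stage("fusion", "need a list of at least two feature stacks")
  d <- dim(stacks[[1L]])
  for (s in stacks) {
    if (length(dim(s)) != 3L || !identical(dim(s), d))
      stop_stage("fusion", "feature stacks must share shape and map count")
  }
  invisible(stacks)
}
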