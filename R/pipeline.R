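# End-to-end fusion pipeline.
#
# Colour path: the functional RGB image is decomposed into YIQ; its luma and
# the structural image are independently enhanced by IFP; both are encoded,
# the feature stacks are combined with trace weights, decoded to a fused
# luma, and the luma is reinserted next to the untouched chroma channels
# before the inverse colour conversion.  Chroma passes through exactly
# (before the final RGB gamut clamp) — the defining property of the design.

#' Pipeline configuration
#'
#' Collects the knobs of the fusion pipeline: IFP grid and on/off switch,
#' fusion strategy, colour-matrix variant and metric parameter overrides.
#'
#' @param ifp_enabled apply intuitionistic fuzzy preprocessing (default TRUE).
#' @param ifp_grid exponent grid for [select_lambda()].
#' @param strategy `"trace"` (default) or `"mean"` feature fusion.
#' @param signed_traces use literal signed trace sums in the weights.
#' @param matrix colour matrix variant, see [rgb_to_yiq()].
#' @param metric_params list passed to [evaluate_all()].
#' @return A `fusion_control` list.
#' @export
fusion_control <- function(ifp_enabled = TRUE, ifp_grid = ifp_default_grid(),
                           strategy = c("trace", "mean"),
                           signed_traces = FALSE,
                           matrix = c("standard", "paper-literal"),
                           metric_params = list()) {
  structure(list(
    ifp_enabled = isTRUE(ifp_enabled),
    ifp_grid = ifp_grid,
    strategy = match.arg(strategy),
    signed_traces = isTRUE(signed_traces),
    matrix = match.arg(matrix),
    metric_params = metric_params
  ), class = "fusion_control")
}

fuse_stacks <- function(stacks, ctrl) {
  if (ctrl$strategy == "mean") {
    fuse_features_mean(stacks)
  } else {
    fuse_features(stacks, fusion_weights(stacks, signed = ctrl$signed_traces))
  }
}

#' Fuse a structural image with a colour functional image
#'
#' Runs the full colour pipeline (YIQ decomposition, IFP, encoding, trace
#' fusion, decoding, luma replacement, inverse conversion).  Set
#' `return_space = "YIQ"` to obtain the pre-clamp YIQ result, whose chroma
#' channels equal the functional input's exactly.
#'
#' @param structural grayscale matrix in \[0,1\].
#' @param functional RGB [color_image()] of the same spatial shape.
#' @param params trained [net_params][init_net_params()] (weights of the
#'   encoder/decoder).
#' @param ctrl a [fusion_control()].
#' @param return_space `"RGB"` (clamped, default) or `"YIQ"` (pre-clamp).
#' @return A [color_image()] of the input shape.
#' @export
fuse_pair <- function(structural, functional, params,
                      ctrl = fusion_control(),
                      return_space = c("RGB", "YIQ")) {
  return_space <- match.arg(return_space)
  assert_gray(structural, "pipeline", min_dim = 8L)
  if (!inherits(functional, "color_image") || color_space(functional) != "RGB")
    stop_stage("pipeline", "functional input must be an RGB color_image")
  if (!identical(dim(structural), dim(functional)[1:2]))
    stop_stage("pipeline", "structural and functional shapes differ")
  yiq <- rgb_to_yiq(functional, ctrl$matrix)
  o <- fuse_luma(structural, get_luma(yiq), params, ctrl)
  out <- replace_luma(yiq, o)
  if (return_space == "YIQ") out else yiq_to_rgb(out, ctrl$matrix)
}

fuse_luma <- function(structural, y, params, ctrl) {
  y_e <- ifp_preprocess(y, ctrl$ifp_grid, ctrl$ifp_enabled)
  s_e <- ifp_preprocess(structural, ctrl$ifp_grid, ctrl$ifp_enabled)
  stacks <- list(encode(y_e, params, source = "functional"),
                 encode(s_e, params, source = "structural"))
  decode(fuse_stacks(stacks, ctrl), params)
}

#' Fuse two grayscale images
#'
#' Grayscale-only path (e.g. MRI-CT): IFP on both inputs, encode, trace
#' fusion, decode.  No colour steps.
#'
#' @param a,b grayscale matrices of a common shape.
#' @inheritParams fuse_pair
#' @return Fused grayscale matrix in (0,1).
#' @export
fuse_gray_pair <- function(a, b, params, ctrl = fusion_control()) {
  assert_gray(a, "pipeline", min_dim = 8L)
  assert_gray(b, "pipeline", min_dim = 8L)
  assert_same_shape("pipeline", a, b)
  a_e <- ifp_preprocess(a, ctrl$ifp_grid, ctrl$ifp_enabled)
  b_e <- ifp_preprocess(b, ctrl$ifp_grid, ctrl$ifp_enabled)
  stacks <- list(encode(a_e, params, source = "a"),
                 encode(b_e, params, source = "b"))
  decode(fuse_stacks(stacks, ctrl), params)
}

#' Fuse and evaluate a set of phantom pairs
#'
#' Fuses each pair and evaluates the ten-metric suite on the fused luma
#' against the structural image and the functional luma.  Deterministic
#' given weights and inputs.
#'
#' @param pairs list of [make_phantom_pair()] objects.
#' @inheritParams fuse_pair
#' @param out optional path: write the table as CSV (`.csv`) or JSON.
#' @return Data frame with one row per pair and the ten metric columns.
#' @export
run_evaluation <- function(pairs, params, ctrl = fusion_control(),
                           out = NULL) {
  if (!length(pairs)) stop_stage("pipeline", "no pairs to evaluate")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    fused <- fuse_pair(p$structural, p$functional, params, ctrl)
    f_luma <- get_luma(rgb_to_yiq(fused, ctrl$matrix))
    a <- unclass_attr(p$structural)
    b <- get_luma(rgb_to_yiq(p$functional, ctrl$matrix))
    rep <- evaluate_all(a, b, f_luma, ctrl$metric_params)
    cbind(data.frame(pair = i, seed = p$seed), as.data.frame(t(rep$values)))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out)) {
    if (grepl("\\.csv$", out)) utils::write.csv(tab, out, row.names = FALSE)
    else jsonlite::write_json(tab, out, dataframe = "rows", digits = NA)
  }
  tab
}
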