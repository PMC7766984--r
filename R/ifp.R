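# Intuitionistic fuzzy preprocessing (IFP).
#
# Each image is mapped to a non-membership image
#   nu(g) = (gmax - g) / (gmax - gmin)
# from its own observed extrema, raised to an exponent lambda, and the
# enhanced image is xi = 1 - nu^lambda.  lambda is chosen from a grid by
# maximising a fuzzy-set entropy: the per-pixel ratio 2*mu*xi/(mu^2 + xi^2)
# with mu(g) = [(g - gmin)/(gmax - gmin)]^lambda (the membership mirror of
# nu), averaged over pixels.  The ratio is 1 where membership and enhanced
# intensity agree and falls to 0 as they diverge, so the criterion prefers
# exponents that keep the enhanced image informative about the original.

#' Non-membership image of an intuitionistic fuzzy set
#'
#' Linear non-membership \eqn{\nu(g) = (g_{max}-g)/(g_{max}-g_{min})}
#' computed from the image's own extrema, so the darkest pixel has
#' non-membership 1 and the brightest 0.  A constant image is degenerate
#' (extrema coincide): a zero matrix with attribute `degenerate = TRUE` is
#' returned along with a warning.
#'
#' @param img numeric matrix with values in \[0,1\].
#' @return Matrix of non-membership degrees in \[0,1\].
#' @export
non_membership <- function(img) {
  assert_gray(img, "ifp")
  gmin <- min(img); gmax <- max(img)
  if (gmax <= gmin) {
    warning("constant image: non-membership undefined, returning zeros")
    return(structure(array(0, dim(img)), dim = dim(img), degenerate = TRUE))
  }
  (gmax - img) / (gmax - gmin)
}

#' Membership, non-membership and enhanced images for one exponent
#'
#' For exponent `lam`, returns `nu` = \eqn{\nu^\lambda}, the enhanced image
#' `xi` = \eqn{1 - \nu^\lambda}, and the membership image `mu` =
#' \eqn{[(g-g_{min})/(g_{max}-g_{min})]^\lambda}.
#'
#' @inheritParams non_membership
#' @param lam positive exponent.
#' @return List with matrices `nu`, `xi`, `mu`, all in \[0,1\].
#' @export
ifs_images <- function(img, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop_stage("ifp", "lambda must be a positive number")
  nu0 <- non_membership(img)
  if (isTRUE(attr(nu0, "degenerate")))
    stop_stage("ifp", "constant image: fuzzy images undefined")
  nu <- nu0^lam
  list(nu = nu, xi = 1 - nu, mu = (1 - nu0)^lam)
}

#' Fuzzy-set entropy of an image at a given exponent
#'
#' Mean over pixels of \eqn{2\mu\xi / (\mu^2 + \xi^2)}, a symmetry measure
#' between the membership image and the enhanced image; pixels where both
#' are zero contribute 0.  Always lies in \[0,1\].
#'
#' @inheritParams ifs_images
#' @return Scalar entropy in \[0,1\].
#' @export
ifs_entropy <- function(img, lam) {
  im <- ifs_images(img, lam)
  num <- 2 * im$mu * im$xi
  den <- im$mu^2 + im$xi^2
  term <- ifelse(den == 0, 0, num / den)
  mean(term)
}

#' Select the enhancement exponent by entropy maximisation
#'
#' Evaluates [ifs_entropy()] at every grid value and keeps the maximiser
#' (ties broken toward the smallest exponent, for determinism).  On a
#' degenerate constant image the input is passed through unchanged with a
#' warning and `degenerate = TRUE`.
#'
#' @inheritParams non_membership
#' @param grid numeric vector of candidate exponents; default
#'   `c(200, 300, 400, 500, 600, 700, 800)`.
#' @return An object of class `ifp_result`: list with `enhanced` (matrix),
#'   `lambda_star`, `entropy_by_lambda` (named numeric), `degenerate`.
#' @examples
#' img <- matrix(seq(0, 1, length.out = 64), 8, 8)
#' res <- select_lambda(img)
#' res$lambda_star
#' @export
select_lambda <- function(img, grid = ifp_default_grid()) {
  assert_gray(img, "ifp")
  if (length(grid) < 1L || any(!is.finite(grid)) || any(grid <= 0))
    stop_stage("ifp", "grid must be a non-empty vector of positive exponents")
  grid <- as.numeric(grid)
  if (min(img) >= max(img)) {
    warning("constant image: IFP is a no-op")
    ent <- stats::setNames(rep(NA_real_, length(grid)), format(grid))
    return(structure(
      list(enhanced = img, lambda_star = grid[1L],
           entropy_by_lambda = ent, degenerate = TRUE),
      class = "ifp_result"
    ))
  }
  ent <- vapply(grid, function(l) ifs_entropy(img, l), numeric(1))
  names(ent) <- format(grid)
  best <- which(ent == max(ent))[1L]  # smallest-lambda tie break (grid order)
  structure(
    list(enhanced = ifs_images(img, grid[best])$xi,
         lambda_star = grid[best],
         entropy_by_lambda = ent,
         degenerate = FALSE),
    class = "ifp_result"
  )
}

#' @export
print.ifp_result <- function(x, ...) {
  cat(sprintf("<ifp_result lambda*=%g%s>\n", x$lambda_star,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @rdname select_lambda
#' @export
ifp_default_grid <- function() c(200, 300, 400, 500, 600, 700, 800)

#' Enhance an image by intuitionistic fuzzy preprocessing
#'
#' Convenience wrapper: runs [select_lambda()] over the default grid and
#' returns the enhanced image.  Constant images pass through unchanged.
#'
#' @inheritParams non_membership
#' @param grid candidate exponents, see [select_lambda()].
#' @param enabled set `FALSE` to bypass enhancement (ablation runs).
#' @return Enhanced matrix in \[0,1\].
#' @export
ifp_preprocess <- function(img, grid = ifp_default_grid(), enabled = TRUE) {
  if (!enabled) return(assert_gray(img, "ifp"))
  select_lambda(img, grid)$enhanced
}
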