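#' Phylogenetic independent contrasts
#'
#' Standardized contrasts by the pruning recursion (differences at internal
#' nodes divided by the square root of the summed, adjusted branch lengths).
#' Polytomies are resolved arbitrarily with zero-length branches first and
#' the resolution is recorded.  Tips without a value are an error naming the
#' tips: removing them is the caller's decision, detecting them is this
#' function's job.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths
#' @param trait named numeric vector over the tip labels
#' @return numeric vector of n - 1 contrasts, with attribute
#'   \code{"resolved_polytomies"} (logical)
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L)
    stop("tips without trait values: ", paste(missing, collapse = ", "))
  resolved <- FALSE
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    resolved <- TRUE
  }
  out <- ape::pic(trait[tree$tip.label], tree)
  attr(out, "resolved_polytomies") <- resolved
  out
}

.lambda_vcv <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

.gls_fit <- function(X, y, V) {
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  resid <- y - X %*% beta
  rss <- drop(crossprod(resid, Vi %*% resid))
  list(beta = drop(beta), rss = rss, XtViX = XtViX, Vi = Vi)
}

.REML_FAIL <- -1e300

.reml_loglik <- function(lambda, V, X, y) {
  n <- length(y)
  p <- ncol(X)
  Vl <- .lambda_vcv(V, lambda)
  fit <- tryCatch(.gls_fit(X, y, Vl), error = function(e) NULL)
  if (is.null(fit) || fit$rss <= 0) return(.REML_FAIL)
  sigma2 <- fit$rss / (n - p)
  ld_V <- determinant(Vl, logarithm = TRUE)$modulus
  ld_X <- determinant(fit$XtViX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi * sigma2) + ld_V + ld_X + (n - p))
}

#' PGLS regression with maximum-likelihood Pagel's lambda
#'
#' Generalized least squares of y on x under the Brownian tree covariance
#' with internal (off-diagonal) covariances scaled by Pagel's lambda.
#' Lambda is chosen by maximizing the restricted likelihood over
#' \code{bounds} (default [1e-6, 1], tolerance 1e-6, bounded scalar
#' optimization); when the optimization fails or returns a non-finite
#' optimum, lambda is set to 1 - the most conservative choice, treating the
#' full Brownian covariance as real - and flagged.
#'
#' @param tree an \code{ape::phylo} tree with branch lengths
#' @param x,y named numeric vectors over the tip labels
#' @param bounds lambda search interval
#' @return object of class \code{pgls_fit}: list with \code{slope},
#'   \code{intercept}, \code{lambda}, \code{lambda_fallback_used},
#'   \code{slope_se}, \code{t_value}, \code{p_value}, \code{df},
#'   \code{n_tips}, \code{logLik}
#' @export
pgls_lambda <- function(tree, x, y, bounds = c(1e-6, 1)) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels")
  tips <- tree$tip.label
  if (!all(tips %in% names(x)) || !all(tips %in% names(y)))
    stop("x and y must cover all tip labels")
  n <- length(tips)
  if (n < 4L) stop("need at least 4 tips")
  V <- ape::vcv(tree)
  xv <- x[tips]; yv <- y[tips]
  X <- cbind(intercept = 1, slope = xv)
  fallback <- FALSE
  lambda <- tryCatch({
    opt <- stats::optimize(function(l) .reml_loglik(l, V, X, yv),
                           interval = bounds, maximum = TRUE, tol = 1e-6)
    if (!is.finite(opt$objective) || opt$objective <= .REML_FAIL / 2)
      stop("REML optimization failed")
    opt$maximum
  }, error = function(e) NA_real_)
  if (is.na(lambda) || lambda < bounds[1] || lambda > bounds[2]) {
    lambda <- 1
    fallback <- TRUE
  }
  Vl <- .lambda_vcv(V, lambda)
  fit <- .gls_fit(X, yv, Vl)
  df <- n - 2L
  sigma2 <- fit$rss / df
  covb <- sigma2 * solve(fit$XtViX)
  se <- sqrt(diag(covb))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  structure(list(
    slope = fit$beta[["slope"]], intercept = fit$beta[["intercept"]],
    lambda = lambda, lambda_fallback_used = fallback,
    slope_se = se[["slope"]], t_value = tval[["slope"]],
    p_value = pval[["slope"]], df = df, n_tips = n,
    logLik = .reml_loglik(lambda, V, X, yv)
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS: slope %.4f (se %.4f), intercept %.4f, lambda %.4f%s, p %.3g (n = %d)\n",
    x$slope, x$slope_se, x$intercept, x$lambda,
    if (x$lambda_fallback_used) " [fallback]" else "", x$p_value, x$n_tips))
  invisible(x)
}

#' Contrast regression of y on x
#'
#' Regression through the origin of the y contrasts on the x contrasts,
#' the standard way to relate two traits under Brownian motion.
#'
#' @param tree an \code{ape::phylo}
#' @param x,y named numeric vectors over the tips
#' @return list with \code{slope}, \code{slope_se}, \code{t_value},
#'   \code{p_value}, \code{df}, \code{n_contrasts}
#' @export
pic_regression <- function(tree, x, y) {
  cx <- pic_contrasts(tree, x)
  cy <- pic_contrasts(tree, y)
  fit <- stats::lm(cy ~ cx - 1)
  sm <- summary(fit)$coefficients
  list(slope = sm[1, 1], slope_se = sm[1, 2], t_value = sm[1, 3],
       p_value = sm[1, 4], df = fit$df.residual,
       n_contrasts = length(cx))
}

#' Pairwise trait screen with BH correction
#'
#' Runs \code{\link{pgls_lambda}} (or \code{\link{pic_regression}}) on every
#' unordered pair of trait columns and applies Benjamini-Hochberg correction
#' across the pairs.
#'
#' @param tree an \code{ape::phylo}
#' @param traits data.frame or matrix, rows named by tip label
#' @param method \code{"pgls"} or \code{"pic"}
#' @return data.frame with one row per pair: \code{x}, \code{y},
#'   \code{slope}, \code{lambda} (NA for PIC), \code{p_value}, \code{q_value}
#' @export
trait_pair_screen <- function(tree, traits, method = c("pgls", "pic")) {
  method <- match.arg(method)
  traits <- as.data.frame(traits)
  cols <- colnames(traits)
  pairs <- utils::combn(cols, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    xa <- stats::setNames(traits[[a]], rownames(traits))
    yb <- stats::setNames(traits[[b]], rownames(traits))
    if (method == "pgls") {
      f <- pgls_lambda(tree, xa, yb)
      data.frame(x = a, y = b, slope = f$slope, lambda = f$lambda,
                 p_value = f$p_value, stringsAsFactors = FALSE)
    } else {
      f <- pic_regression(tree, xa, yb)
      data.frame(x = a, y = b, slope = f$slope, lambda = NA_real_,
                 p_value = f$p_value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
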