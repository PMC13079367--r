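#' Phylogenetic independent contrasts (Felsenstein's pruning)
#'
#' Computes variance-standardized independent contrasts of a tip trait
#' under the Brownian-motion model, by the standard pruning recursion: at
#' each internal node of the (binary) tree the contrast is
#' (x_left - x_right) / sqrt(v_left + v_right), the ancestral value is the
#' branch-length-weighted average of the daughters, and the branch above
#' the node is lengthened by v_left * v_right / (v_left + v_right) to
#' carry the estimation variance upward.
#'
#' Polytomies are resolved arbitrarily to binary with zero-length internal
#' branches (\code{ape::multi2di}); the extra contrasts at zero-length
#' nodes are legitimate under the standard extension because the daughter
#' variances carried up from the tips keep the standardizing variance
#' positive. A contrast with zero total variance (two zero-length
#' terminal branches) is an error.
#'
#' @param tree an \code{ape::phylo} tree, rooted, with branch lengths.
#' @param trait named numeric vector of tip values; names must cover all
#'   tip labels.
#' @return Numeric vector of n_tips - 1 standardized contrasts, with the
#'   standardizing variances in attribute \code{"variance"}. Signs depend
#'   on child ordering and are immaterial for through-origin regression.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' pic_contrasts(tr, c(A = 0, B = 1, C = 4, D = 9))
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)  # deterministic resolution
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tips <- tree$tip.label
  if (is.null(names(trait)) || !all(tips %in% names(trait)))
    stop("trait must be named and cover every tip label", call. = FALSE)
  if (anyNA(trait[tips])) stop("missing tip trait value", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)

  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tips)
  nnode <- tree$Nnode
  x <- numeric(ntip + nnode)           # working trait values per node
  v <- numeric(ntip + nnode)           # extra variance accumulated per node
  x[seq_len(ntip)] <- as.numeric(trait[tips])

  edge <- tree$edge
  elen <- tree$edge.length
  contr <- numeric(nnode)
  cvar <- numeric(nnode)
  # postorder edges come in sibling pairs (binary tree)
  for (i in seq(1L, nrow(edge), by = 2L)) {
    anc <- edge[i, 1L]
    c1 <- edge[i, 2L]; c2 <- edge[i + 1L, 2L]
    stopifnot(edge[i + 1L, 1L] == anc)
    v1 <- elen[i] + v[c1]
    v2 <- elen[i + 1L] + v[c2]
    tot <- v1 + v2
    if (tot <= 0)
      stop("zero total branch length at a contrast", call. = FALSE)
    j <- anc - ntip
    contr[j] <- (x[c1] - x[c2]) / sqrt(tot)
    cvar[j] <- tot
    x[anc] <- (v2 * x[c1] + v1 * x[c2]) / tot
    v[anc] <- v1 * v2 / tot
  }
  structure(contr, variance = cvar,
            names = if (!is.null(tree$node.label)) tree$node.label
                    else as.character(ntip + seq_len(nnode)))
}

#' Log-log scaling regression on contrasts or raw values
#'
#' Fits the allometric scaling exponent b in pg proportional to N^b. For
#' independent contrasts (\code{method = "pic"}) the regression is through
#' the origin, as standard for contrasts: slope = sum(xy)/sum(x^2),
#' r^2 = 1 - SSR/sum(y^2) (no-intercept convention), and a two-sided t
#' test with n - 1 degrees of freedom. For raw log values
#' (\code{method = "ols"}) an ordinary intercept-and-slope regression is
#' used. The exponent is invariant to the log base as long as both
#' variables use the same base.
#'
#' @param x,y predictor and response values: standardized contrasts of
#'   log N and log pg (pic) or the log-transformed species values (ols).
#' @param method \code{"pic"} or \code{"ols"}.
#' @return Object of class \code{"scaling_fit"}: list with \code{slope},
#'   \code{intercept} (NA for pic), \code{se}, \code{r2}, \code{p_value},
#'   \code{n_points}, \code{df}, \code{method}, and the fitting data.
#' @examples
#' fit_scaling(1:5, -1.2 * (1:5), method = "pic")  # exact line, r2 = 1
#' @export
fit_scaling <- function(x, y, method = c("pic", "ols")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  n <- length(x)
  if (method == "pic") {
    sxx <- sum(x^2)
    if (sxx == 0) stop("degenerate predictor: all contrasts zero", call. = FALSE)
    slope <- sum(x * y) / sxx
    ssr <- sum((y - slope * x)^2)
    sst <- sum(y^2)
    df <- n - 1L
    se <- sqrt(ssr / df / sxx)
    tval <- if (se > 0) slope / se else Inf * sign(slope)
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    out <- list(slope = slope, intercept = NA_real_, se = se,
                r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
                p_value = p, n_points = n, df = df, method = "pic",
                x = x, y = y)
  } else {
    fit <- stats::lm(y ~ x)
    # summary.lm warns on exact fits; exact synthetic data are legitimate here
    sm <- suppressWarnings(summary(fit))
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                se = sm$coefficients[2, 2],
                r2 = sm$r.squared,
                p_value = sm$coefficients[2, 4],
                n_points = n, df = fit$df.residual, method = "ols",
                x = x, y = y)
  }
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Scaling fit (%s%s): slope b = %s, r2 = %s, p = %s, n = %d\n",
              toupper(x$method),
              if (x$method == "pic") ", through origin" else "",
              signif(x$slope, digits), signif(x$r2, digits),
              format(x$p_value, digits = 3), x$n_points))
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  ci <- confint.scaling_fit(object)
  cat(sprintf("Allometric scaling fit, method = %s\n", object$method))
  cat(sprintf("  exponent b : %.6g  (se %.3g, 95%% CI [%.4g, %.4g])\n",
              object$slope, object$se, ci[1], ci[2]))
  if (object$method == "ols")
    cat(sprintf("  intercept  : %.6g\n", object$intercept))
  cat(sprintf("  r2         : %.4g%s\n", object$r2,
              if (object$method == "pic") "  (no-intercept convention, SST = sum(y^2))" else ""))
  cat(sprintf("  p (two-sided t, %d df): %s\n", object$df,
              format(object$p_value, digits = 3)))
  cat(sprintf("  points     : %d\n", object$n_points))
  invisible(object)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  if (object$method == "pic") c(slope = object$slope)
  else c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.scaling_fit <- function(object, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df)
  c(object$slope - tq * object$se, object$slope + tq * object$se)
}

#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  b0 <- if (is.na(object$intercept)) 0 else object$intercept
  b0 + object$slope * x
}

#' @export
residuals.scaling_fit <- function(object, ...) {
  object$y - predict.scaling_fit(object)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  lab <- if (x$method == "pic")
    c("contrast of log10 N", "contrast of log10 pg")
  else c("log10 cell number N", "log10 germ fraction pg")
  graphics::plot(x$x, x$y, xlab = lab[1], ylab = lab[2], ...)
  graphics::abline(a = if (is.na(x$intercept)) 0 else x$intercept,
                   b = x$slope, lty = 2)
  invisible(x)
}
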