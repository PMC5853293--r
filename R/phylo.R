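## Phylogenetic signal and correlated evolution.  Pagel's lambda scales the
## off-diagonal entries of the Brownian-motion covariance among species:
## lambda = 0 means traits evolved independently of the phylogeny, lambda =
## 1 means pure Brownian motion.  The continuous-trait fit maximizes the
## multivariate-normal likelihood over lambda with the rate and root mean
## profiled out analytically; the discrete fit is a two-state symmetric
## Markov model evaluated by Felsenstein's pruning algorithm; PGLS estimates
## a regression whose residual covariance is the lambda-transformed BM
## matrix.

#' Read a phylogeny from newick text or file
#'
#' @param source newick string or path to a newick file.
#' @return an `ape` `phylo` object; branch lengths are required, and a
#'   warning is issued when the tree deviates from ultrametricity by more
#'   than 1e-6 relative.
#' @export
readNewickTree <- function(source) {
  tree <- if (file.exists(source)) ape::read.tree(source)
          else ape::read.tree(text = source)
  if (is.null(tree)) stop("malformed newick input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("tip labels are not unique")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (diff(range(depths)) > 1e-6 * max(depths))
    warning("tree is not ultrametric (relative deviation ",
            signif(diff(range(depths)) / max(depths), 3), ")")
  tree
}

#' Brownian-motion covariance of a phylogeny
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips `i` and `j`;
#' `C[i, i]` is the depth of tip `i`.
#'
#' @param tree a `phylo`.
#' @return the `n x n` covariance matrix with tip-label dimnames.
#' @export
bmCov <- function(tree) ape::vcv(tree)

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' unchanged.
#'
#' @param C covariance matrix.
#' @param lambda value in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambdaTransform <- function(C, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be in [0, 1]")
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

## profile log-likelihood of a lambda-transformed BM model: the root mean
## (or regression coefficients) and the rate sigma^2 are profiled
## analytically; returns logL plus the profiled estimates
.profileLogLik <- function(C, lambda, X, y) {
  V <- lambdaTransform(C, lambda)
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  logdet <- 2 * sum(log(diag(ch)))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  fit <- qr(Xi)
  beta <- qr.coef(fit, yi)
  res <- yi - Xi %*% beta
  s2 <- sum(res^2) / n               # ML, not REML
  logL <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(logL = logL, beta = beta, sigma2 = s2, chol = ch, Xw = Xi, qr = fit)
}

## maximize over lambda in [0,1]: coarse grid bracket + local optimize,
## endpoints always considered
.maxLambda <- function(C, X, y, gridN = 21L) {
  f <- function(l) .profileLogLik(C, l, X, y)$logL
  grid <- seq(0, 1, length.out = gridN)
  gv <- vapply(grid, f, numeric(1))
  k <- which.max(gv)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(gridN, k + 1L)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1, grid[k])
  cv <- vapply(cand, f, numeric(1))
  list(lambda = cand[which.max(cv)], logL = max(cv))
}

#' Maximum-likelihood Pagel's lambda for a continuous trait
#'
#' Maximizes the multivariate-normal log-likelihood over
#' `(lambda, sigma^2, root mean)` with `lambda` bounded to `[0, 1]`;
#' `sigma^2` and the mean have analytic maxima at each `lambda`, so the
#' search is one-dimensional.
#'
#' @param tree a `phylo`.
#' @param x named trait values, one per tip (names matched to tip labels;
#'   unnamed values are taken in tip order).
#' @return a `ctLambdaFit`: `lambda`, `logL`, `logL0`, `logL1` (at the
#'   endpoints), `sigma2`, `rootMean`.
#' @export
fitLambdaContinuous <- function(tree, x) {
  n <- ape::Ntip(tree)
  if (n < 3) stop("need at least 3 tips")
  x <- .alignTips(tree, x)
  if (var(x) == 0) stop("trait has zero variance; lambda is unidentifiable")
  C <- bmCov(tree)
  X <- matrix(1, n, 1)
  best <- .maxLambda(C, X, x)
  at <- function(l) .profileLogLik(C, l, X, x)
  fit <- at(best$lambda)
  structure(list(lambda = best$lambda, logL = best$logL,
                 logL0 = at(0)$logL, logL1 = at(1)$logL,
                 sigma2 = fit$sigma2, rootMean = drop(fit$beta), n = n),
            class = "ctLambdaFit")
}

#' @export
print.ctLambdaFit <- function(x, ...) {
  cat(sprintf(paste0("Pagel's lambda (ML): lambda=%.4g, logL=%.4f ",
                     "(logL(0)=%.4f, logL(1)=%.4f)\n",
                     "  sigma2=%.4g, root mean=%.4g, n=%d\n"),
              x$lambda, x$logL, x$logL0, x$logL1, x$sigma2, x$rootMean, x$n))
  invisible(x)
}

.alignTips <- function(tree, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(tree$tip.label, names(x))
    if (length(miss)) stop("missing trait values for tips: ",
                           paste(miss, collapse = ", "))
    x <- x[tree$tip.label]
  } else if (length(x) != ape::Ntip(tree)) {
    stop("trait length does not match number of tips")
  }
  as.numeric(x)
}

#' Pagel's lambda branch-length transform of a tree
#'
#' Internal branches are multiplied by `lambda` and each terminal branch is
#' stretched so every tip keeps its original depth; equivalent to
#' [lambdaTransform()] on the BM covariance for ultrametric trees.
#'
#' @param tree a `phylo`.
#' @param lambda value in `[0, 1]`.
#' @return the transformed `phylo`.
#' @export
lambdaTree <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  el <- tree$edge.length * lambda
  tipEdge <- tree$edge[, 2] <= n
  parentDepth <- depth[tree$edge[tipEdge, 1]]
  el[tipEdge] <- depth[tree$edge[tipEdge, 2]] - lambda * parentDepth
  tree$edge.length <- el
  tree
}

## 2-state symmetric transition probability: stay = (1 + exp(-2qt))/2
.symP <- function(q, t) {
  same <- (1 + exp(-2 * q * t)) / 2
  matrix(c(same, 1 - same, 1 - same, same), 2, 2)
}

## Felsenstein pruning log-likelihood of a binary trait under the symmetric
## 2-state model, flat root prior
.pruneLogLik <- function(tree, states, q) {
  n <- ape::Ntip(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(0, n + tree$Nnode, 2)
  L[cbind(seq_len(n), states + 1L)] <- 1
  logScale <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    parent <- tree$edge[k, 1]
    P <- .symP(q, tree$edge.length[k])
    msg <- P %*% L[child, ]
    if (all(L[parent, ] == 0)) L[parent, ] <- msg
    else L[parent, ] <- L[parent, ] * msg
    m <- max(L[parent, ])
    if (m > 0 && m < 1e-100) { L[parent, ] <- L[parent, ] / m; logScale <- logScale + log(m) }
  }
  root <- n + 1L
  log(sum(0.5 * L[root, ])) + logScale
}

#' Symmetric two-state Markov fit for a binary trait
#'
#' Maximum-likelihood rate of the symmetric model (equal forward and
#' backward rates, flat root prior) evaluated by Felsenstein's pruning
#' algorithm; optionally a Pagel's lambda branch-scale transform is fitted
#' jointly with the rate.
#'
#' @param tree a `phylo`.
#' @param x binary trait (0/1, logical, or 2-level factor), named by tip or
#'   in tip order.
#' @param lambda `FALSE` (default) to fit the rate alone, `TRUE` to fit
#'   `(q, lambda)` jointly.
#' @return a `ctDiscreteFit`: `q`, `logL`, and `lambda` (`NA` unless fitted),
#'   with `model` labelling which variant was run.
#' @export
fitDiscreteSym <- function(tree, x, lambda = FALSE) {
  states <- .alignTips(tree, .asBinary(x))
  if (length(unique(states)) < 2)
    stop("trait has a single state; the rate is unidentifiable")
  depth <- max(ape::node.depth.edgelength(tree))
  f <- function(lq, tr) .pruneLogLik(tr, states, exp(lq))
  if (!lambda) {
    opt <- optimize(function(lq) f(lq, tree),
                    c(log(1e-8 / depth), log(1e3 / depth)), maximum = TRUE,
                    tol = 1e-10)
    structure(list(q = exp(opt$maximum), logL = opt$objective, lambda = NA,
                   model = "SYM"), class = "ctDiscreteFit")
  } else {
    obj <- function(par) -f(par[1], lambdaTree(tree, par[2]))
    opt <- optim(c(log(1 / depth), 0.5), obj, method = "L-BFGS-B",
                 lower = c(log(1e-8 / depth), 0),
                 upper = c(log(1e3 / depth), 1))
    structure(list(q = exp(opt$par[1]), logL = -opt$value,
                   lambda = opt$par[2], model = "SYM+lambda"),
              class = "ctDiscreteFit")
  }
}

.asBinary <- function(x) {
  v <- x
  if (is.factor(v) || is.character(v)) {
    lev <- sort(unique(as.character(v)))
    if (length(lev) > 2) stop("trait must be binary")
    out <- as.integer(factor(as.character(v), levels = lev)) - 1L
    names(out) <- names(x)
    return(out)
  }
  if (is.logical(v)) v <- as.integer(v)
  if (!all(v %in% c(0, 1))) stop("trait must be binary (0/1)")
  out <- as.integer(v)
  names(out) <- names(x)
  out
}

#' @export
print.ctDiscreteFit <- function(x, ...) {
  cat(sprintf("%s model: q=%.4g, logL=%.4f%s\n", x$model, x$q, x$logL,
              if (!is.na(x$lambda)) sprintf(", lambda=%.4g", x$lambda) else ""))
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with residual covariance `V = lambdaTransform(bmCov(tree),
#' lambda)`: `beta = (X' V^-1 X)^-1 X' V^-1 y`, coefficient covariance
#' `sigma2 * (X' V^-1 X)^-1` with the ML variance estimate.  `lambda` is by
#' default maximized on the residual likelihood; at `lambda = 0` the fit
#' equals ordinary least squares exactly.
#'
#' @param formula model formula over columns of `data`.
#' @param data `data.frame` with row names (or a `species` column) matching
#'   tip labels.
#' @param tree a `phylo`.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return a `ctPGLS`: coefficient table (`estimate`, `se`, `t`, `p` on
#'   `n - p` df), `lambda`, `logL`, `sigma2`, `n`.
#' @export
pgls <- function(formula, data, tree, lambda = "ML") {
  if (!is.null(data$species)) rownames(data) <- data$species
  miss <- setdiff(tree$tip.label, rownames(data))
  if (length(miss)) stop("no data for tips: ", paste(miss, collapse = ", "))
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  C <- bmCov(tree)
  n <- length(y)
  if (identical(lambda, "ML")) {
    best <- .maxLambda(C, X, y)
    lam <- best$lambda
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lam <- lambda
  }
  fit <- .profileLogLik(C, lam, X, y)
  p <- ncol(X)
  XtX <- crossprod(fit$Xw)
  covBeta <- solve(XtX) * fit$sigma2 * n / (n - p)   # unbiased residual var
  se <- sqrt(diag(covBeta))
  tval <- drop(fit$beta) / se
  ptab <- data.frame(estimate = drop(fit$beta), se = se, t = tval,
                     p = 2 * pt(-abs(tval), n - p),
                     row.names = colnames(X))
  structure(list(coefficients = ptab, lambda = lam, logL = fit$logL,
                 sigma2 = fit$sigma2, n = n, df = n - p),
            class = "ctPGLS")
}

#' @export
print.ctPGLS <- function(x, ...) {
  cat(sprintf("PGLS (lambda=%.4g, ML logL=%.4f, n=%d)\n",
              x$lambda, x$logL, x$n))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}
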