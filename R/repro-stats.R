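## Permutation and summary statistics for the per-flower count tables:
## Euclidean-distance permutation ANOVA (npANOVA) with sequential sums of
## squares and an adonis-style pseudo-F, Bonferroni-corrected pairwise post
## hoc tests, the exact two-sample Mann-Whitney-Wilcoxon test, the simple
## regression F test, and species/strategy group summaries.

#' Euclidean distance matrix
#'
#' @param values numeric vector (one value per sample) or matrix (samples in
#'   rows).
#' @return a symmetric, zero-diagonal `n x n` matrix of Euclidean distances
#'   (`|x_i - x_j|` for scalars).
#' @examples
#' euclideanDM(c(0, 3, 4))
#' @export
euclideanDM <- function(values) {
  x <- as.matrix(values)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(!is.finite(x))) stop("values must be finite")
  as.matrix(dist(x, method = "euclidean"))
}

## Gower-centred inner-product matrix of squared distances:
## G = -(1/2) C A C with A = d^2 and C the centring matrix.
## tr(H G) gives the sum of squares explained by the projection H.
.gowerG <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1, rm), 2, rm) + gm
}

## hat matrix of a design matrix via QR
.hat <- function(X) {
  q <- qr.Q(qr(X))
  tcrossprod(q)
}

#' Permutation multivariate ANOVA on a distance matrix (npANOVA)
#'
#' Partitions the total sum of squares implied by a distance matrix over the
#' model terms with sequential (Type I) sums of squares, in the order given
#' by the right-hand-side formula, and tests each term's pseudo-F statistic
#' by free permutation of the raw observations.  On univariate data with
#' Euclidean distances the pseudo-F of a one-factor model equals the
#' classical one-way ANOVA F exactly.
#'
#' @param d distance matrix (`n x n`, as from [euclideanDM()]) or a `dist`.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ species * position` (sequential terms: species, position,
#'   species:position).
#' @param data `data.frame` holding the factors.
#' @param permutations number of permutations (the study default is 9999).
#' @param seed optional integer seed for the permutation stream.
#' @return a `ctPermanova` object: a per-term table with `df`, `SS`,
#'   `pseudoF`, `R2` and permutation `p`, plus residual and total rows.
#' @export
permanova <- function(d, formula, data, permutations = 9999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("d must be a symmetric zero-diagonal distance matrix")
  if (nrow(data) != n) stop("data rows must match the distance matrix")
  trm <- terms(formula)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop("formula has no terms")
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) stop("variable not in data: ", v)
    lv <- data[[v]]
    if ((is.character(lv) || is.factor(lv)) &&
        length(unique(lv)) < 2)
      stop("factor ", v, " has fewer than 2 levels present")
    if (is.character(lv) || is.factor(lv)) {
      cnt <- table(lv)
      if (any(cnt == 1))
        message("factor ", v, " has level(s) with a single observation: ",
                paste(names(cnt)[cnt == 1], collapse = ", "))
    }
  }
  G <- .gowerG(d)
  ssTotal <- sum(diag(G))
  if (ssTotal <= 0) {
    warning("all observations identical: total sum of squares is zero")
    return(structure(list(table = NULL, undefined = TRUE,
                          permutations = permutations, seed = seed),
                     class = "ctPermanova"))
  }
  ## cumulative hat matrices: intercept, then + each sequential term
  Hs <- vector("list", length(labels) + 1L)
  Hs[[1]] <- matrix(1 / n, n, n)
  dfs <- integer(length(labels))
  for (j in seq_along(labels)) {
    f <- stats::reformulate(labels[seq_len(j)])
    X <- model.matrix(f, data)
    Hs[[j + 1]] <- .hat(X)
    dfs[j] <- qr(X)$rank - (if (j == 1) 1L else qr(model.matrix(
      stats::reformulate(labels[seq_len(j - 1)]), data))$rank)
  }
  traces <- function(Gp) vapply(Hs, function(H) sum(H * Gp), numeric(1))
  tr <- traces(G)
  ssTerm <- diff(tr)
  ssRes <- ssTotal - (tr[length(tr)] - tr[1])
  dfRes <- n - 1L - sum(dfs)
  Fobs <- (ssTerm / dfs) / (ssRes / dfRes)
  exceed <- rep(0L, length(labels))
  if (permutations > 0) {
    runPerm <- function() {
      for (k in seq_len(permutations)) {
        p <- sample.int(n)
        trp <- traces(G[p, p])
        ssp <- diff(trp)
        rsp <- ssTotal - (trp[length(trp)] - trp[1])
        Fp <- (ssp / dfs) / (rsp / dfRes)
        exceed <<- exceed + (Fp >= Fobs - 1e-12)
      }
    }
    if (is.null(seed)) runPerm() else withSeed(seed, runPerm())
  }
  pval <- (exceed + 1) / (permutations + 1)
  tab <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(dfs, dfRes, n - 1L),
    SS = c(ssTerm, ssRes, ssTotal),
    pseudoF = c(Fobs, NA, NA),
    R2 = c(ssTerm, ssRes, ssTotal) / ssTotal,
    p = c(pval, NA, NA))
  structure(list(table = tab, undefined = FALSE, permutations = permutations,
                 seed = seed), class = "ctPermanova")
}

#' @export
print.ctPermanova <- function(x, ...) {
  if (x$undefined) {
    cat("npANOVA: undefined (zero total sum of squares)\n")
    return(invisible(x))
  }
  cat(sprintf("npANOVA (Euclidean pseudo-F, %d free permutations)\n",
              x$permutations))
  print(transform(x$table, SS = signif(SS, 6), pseudoF = signif(pseudoF, 4),
                  R2 = round(R2, 3)), row.names = FALSE)
  invisible(x)
}

#' Pairwise npANOVA post hoc tests with Bonferroni correction
#'
#' Tests every pair of factor levels by [permanova()] on the pair's subset
#' of the distance matrix; adjusted p-values are `min(1, p * n_pairs)`.
#' Also derives a compact-letter grouping: levels that are not significantly
#' different at `alpha` share a letter.
#'
#' @param d distance matrix.
#' @param f factor (or character) with at least 3 levels.
#' @param permutations,seed as in [permanova()].
#' @param alpha significance level for the letter grouping.
#' @return a `ctPosthoc` object with the pairwise table and group letters.
#' @export
permanovaPosthoc <- function(d, f, permutations = 9999, seed = NULL,
                             alpha = 0.05) {
  d <- as.matrix(d)
  f <- as.factor(f)
  lev <- levels(droplevels(f))
  if (length(lev) < 3)
    message("fewer than 3 levels: the plain test suffices")
  prs <- combn(lev, 2)
  nPairs <- ncol(prs)
  res <- lapply(seq_len(nPairs), function(k) {
    sel <- f %in% prs[, k]
    sub <- data.frame(g = droplevels(f[sel]))
    fit <- permanova(d[sel, sel], ~ g, sub, permutations = permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    p <- fit$table$p[1]
    data.frame(level1 = prs[1, k], level2 = prs[2, k],
               pseudoF = fit$table$pseudoF[1], p = p,
               pAdj = min(1, p * nPairs))
  })
  tab <- do.call(rbind, res)
  ## compact letters by greedy grouping over the adjusted matrix
  sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
  for (k in seq_len(nPairs))
    sig[prs[1, k], prs[2, k]] <- sig[prs[2, k], prs[1, k]] <-
      tab$pAdj[k] < alpha
  groups <- list()
  for (l in lev) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(sig[l, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], l); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- l
  }
  letters_ <- setNames(rep("", length(lev)), lev)
  for (g in seq_along(groups))
    for (l in groups[[g]])
      letters_[l] <- paste0(letters_[l], letters[g])
  structure(list(table = tab, letters = letters_, alpha = alpha,
                 nPairs = nPairs), class = "ctPosthoc")
}

#' @export
print.ctPosthoc <- function(x, ...) {
  cat(sprintf("Pairwise npANOVA, Bonferroni over %d pairs\n", x$nPairs))
  print(transform(x$table, pseudoF = signif(pseudoF, 4)), row.names = FALSE)
  cat("groups:", paste(names(x$letters), x$letters, sep = "=",
                       collapse = "  "), "\n")
  invisible(x)
}

#' Exact two-sample Mann-Whitney-Wilcoxon test
#'
#' Reports the U statistics of both samples and `W = min(U_xy, U_yx)`, the
#' smaller-is-extreme convention of classical tables, together with the
#' two-sided p-value `2 * min(P(U <= u), P(U >= u))` capped at 1.  The
#' p-value uses the exact null distribution of U when there are no ties and
#' `choose(n1 + n2, n1) <= 1e6`, and the normal approximation with tie
#' correction otherwise (flagged in the result).
#'
#' @param x,y numeric samples.
#' @return a `ctMWW` object: `W`, `Uxy`, `Uyx`, `p`, `n1`, `n2`, `exact`.
#' @examples
#' mwwExact(c(152, 147, 175), c(49, 22, 23, 46, 30))
#' @export
mwwExact <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  Uxy <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Uyx <- n1 * n2 - Uxy
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && choose(n1 + n2, n1) <= 1e6
  if (exact) {
    lower <- pwilcox(Uxy, n1, n2)
    upper <- 1 - pwilcox(Uxy - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tieTab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * (nt + 1 - sum(tieTab^3 - tieTab) / (nt * (nt - 1)))
    z <- (Uxy - mu - sign(Uxy - mu) * 0.5) / sqrt(sig2)
    if (Uxy == mu) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  structure(list(W = min(Uxy, Uyx), Uxy = Uxy, Uyx = Uyx, p = p,
                 n1 = n1, n2 = n2, exact = exact), class = "ctMWW")
}

#' @export
print.ctMWW <- function(x, ...) {
  cat(sprintf("MWW test: n1=%d, n2=%d, W=%g (U=%g/%g), %s two-sided p=%.4g\n",
              x$n1, x$n2, x$W, x$Uxy, x$Uyx,
              if (x$exact) "exact" else "approximate", x$p))
  invisible(x)
}

#' Simple-regression F test
#'
#' Ordinary least-squares regression of `y` on `x` with the overall F test
#' on `(1, n - 2)` degrees of freedom.
#'
#' @param x predictor; must vary.
#' @param y response.
#' @return a list: `F`, `df1`, `df2`, `p`, `r2`, `slope`, `intercept`, `n`.
#' @export
olsF <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (var(x) == 0) stop("predictor is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fst <- sm$fstatistic
  list(F = unname(fst[1]), df1 = unname(fst[2]), df2 = unname(fst[3]),
       p = unname(pf(fst[1], fst[2], fst[3], lower.tail = FALSE)),
       r2 = sm$r.squared, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = length(x))
}

#' Per-species summary of a flower-record table
#'
#' Means, standard errors (`sd / sqrt(N)`), variances and sample sizes of
#' pollen count, ovule count and per-flower P:O, by species.
#'
#' @param records a flower-record `data.frame` with columns `species`,
#'   `strategy`, `pollen`, `ovule` (and `po`; computed if absent).
#' @return a `data.frame`, one row per species, with the per-trait
#'   `*Mean`, `*SE`, `*Var` and `N` columns plus `strategy`.
#' @export
groupSummary <- function(records) {
  stopifnot(all(c("species", "strategy", "pollen", "ovule") %in%
                names(records)))
  if (is.null(records$po))
    records$po <- pollenOvuleRatio(records$pollen, records$ovule)
  one <- function(df) {
    s <- function(v) c(mean = mean(v), se = sd(v) / sqrt(length(v)),
                       var = var(v))
    p <- s(df$pollen); o <- s(df$ovule); r <- s(df$po)
    data.frame(species = df$species[1], strategy = df$strategy[1],
               N = nrow(df),
               pollenMean = p["mean"], pollenSE = p["se"], pollenVar = p["var"],
               ovuleMean = o["mean"], ovuleSE = o["se"], ovuleVar = o["var"],
               poMean = r["mean"], poSE = r["se"], poVar = r["var"],
               row.names = NULL)
  }
  out <- do.call(rbind, lapply(split(records, records$species), one))
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' Strategy-level summary from a per-species table
#'
#' N-weighted strategy means of a per-species summary (weights are the
#' per-species sample sizes; a trait-specific sample-size column such as
#' `ovuleN` is used when present, else the shared `N`), the standard error
#' of each weighted mean propagated from the per-species standard errors
#' (`sqrt(sum(w_i^2 SE_i^2))`, `w_i = N_i / sum(N)`), and the ratio of the
#' mean per-species P:O variances, rewarding over deceptive.
#'
#' @param speciesTable a `data.frame` with columns `species`, `strategy`,
#'   `N` (and/or per-trait `*N`), and per-trait `*Mean`/`*SE`/`*Var` columns
#'   as produced by [groupSummary()] (or assembled from published
#'   per-species values).
#' @param traits which traits to summarize (column prefixes).
#' @return a `ctStrategySummary` object: per-strategy weighted means and
#'   SEs per trait, and `poVarRatio`.
#' @export
strategySummary <- function(speciesTable,
                            traits = c("pollen", "ovule", "po")) {
  stopifnot("strategy" %in% names(speciesTable))
  bys <- split(speciesTable, speciesTable$strategy)
  wm <- lapply(bys, function(df) {
    out <- list(N = if ("N" %in% names(df)) sum(df$N) else NA_integer_)
    for (tr in traits) {
      mcol <- paste0(tr, "Mean"); scol <- paste0(tr, "SE")
      ncol_ <- if (paste0(tr, "N") %in% names(df)) paste0(tr, "N") else "N"
      if (mcol %in% names(df) && ncol_ %in% names(df)) {
        w <- df[[ncol_]] / sum(df[[ncol_]])
        out[[paste0(tr, "Mean")]] <- sum(w * df[[mcol]])
        out[[paste0(tr, "N")]] <- sum(df[[ncol_]])
        out[[paste0(tr, "SE")]] <- if (scol %in% names(df) &&
                                       !anyNA(df[[scol]]))
          sqrt(sum(w^2 * df[[scol]]^2)) else NA_real_
      }
    }
    out
  })
  ratio <- NA_real_
  if ("poVar" %in% names(speciesTable) &&
      all(c("rewarding", "deceptive") %in% names(bys)))
    ratio <- mean(bys$rewarding$poVar) / mean(bys$deceptive$poVar)
  structure(list(byStrategy = wm, poVarRatio = ratio), class = "ctStrategySummary")
}

#' @export
print.ctStrategySummary <- function(x, ...) {
  for (s in names(x$byStrategy)) {
    w <- x$byStrategy[[s]]
    cat(sprintf("%s (N=%s):", s, w$N))
    for (nm in setdiff(names(w), "N"))
      cat(sprintf(" %s=%.4g", nm, w[[nm]]))
    cat("\n")
  }
  if (!is.na(x$poVarRatio))
    cat(sprintf("P:O variance ratio (rewarding/deceptive): %.4g\n",
                x$poVarRatio))
  invisible(x)
}

#' Published per-species orchid summary table
#'
#' The species-level summary of the eight European orchid species (three
#' rewarding, five deceptive) that the package's statistics reproduce:
#' per-species mean, SE and N for pollen grain number and ovule number, and
#' mean, SE and variance of the per-flower pollen-to-ovule ratio, with the
#' pollination strategy of each species.
#'
#' @return a `data.frame` with one row per species.
#' @examples
#' tab <- orchidSummaryTable()
#' mwwExact(tab$poVar[tab$strategy == "rewarding"],
#'          tab$poVar[tab$strategy == "deceptive"])
#' @export
orchidSummaryTable <- function() {
  read.csv(system.file("extdata", "orchid_species_summary.csv",
                       package = "ctcount", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
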