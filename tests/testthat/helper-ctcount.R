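# Shared fixtures and independent oracles.  Oracles here are deliberately
# naive (breadth-first flood fill, dense convolution, complete enumeration)
# and never share code with the implementation they check.

volFromArray <- function(a, spacing = c(1, 1, 1)) {
  Volume3D(array(as.numeric(a), dim(a)), spacing = spacing)
}

maskFromArray <- function(a, spacing = c(1, 1, 1)) {
  new("BinaryMask", data = array(as.logical(a), dim(a)), spacing = spacing)
}

# reference connected-component labelling: queue-based flood fill over an
# explicit neighbour enumeration
refLabel3d <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || lab[z, y, x] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(z, y, x), 1)
    lab[z, y, x] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

# reference 3D convolution: direct triple loop with symmetric padding
refConv3d <- function(a, k1) {
  d <- dim(a)
  h <- (length(k1) - 1) / 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  k3 <- outer(outer(k1, k1), k1)  # separable kernel, dims (z, y, x)
  out <- array(0, d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    acc <- 0
    for (ix in -h:h) for (iy in -h:h) for (iz in -h:h)
      acc <- acc + k3[iz + h + 1, iy + h + 1, ix + h + 1] *
        a[refl(z + iz, d[1]), refl(y + iy, d[2]), refl(x + ix, d[3])]
    out[z, y, x] <- acc
  }
  out
}

# complete-enumeration two-sided Mann-Whitney p-value and U statistics
refMWW <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  Uxy <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  lower <- mean(us <= Uxy)
  upper <- mean(us >= Uxy)
  list(Uxy = Uxy, Uyx = n1 * n2 - Uxy, p = min(1, 2 * min(lower, upper)))
}

# exhaustive-summation likelihood of the 2-state symmetric model
refMkLogLik <- function(tree, states, q) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  P <- function(t) {
    s <- (1 + exp(-2 * q * t)) / 2
    matrix(c(s, 1 - s, 1 - s, s), 2, 2)
  }
  tot <- 0
  for (a in 0:(2^m - 1)) {
    ss <- c(states, as.integer(intToBits(a))[seq_len(m)])
    pr <- 0.5
    for (k in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      pr <- pr * P(tree$edge.length[k])[ss[pa] + 1, ss[ch] + 1]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Brownian-motion tip values on a tree (exact multivariate-normal draw)
simBM <- function(tree, sigma2 = 1, mean = 0) {
  C <- ape::vcv(tree)
  z <- rnorm(nrow(C))
  setNames(mean + drop(t(chol(sigma2 * C)) %*% z), rownames(C))
}
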