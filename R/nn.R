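# Internal dense-network machinery for the conditional encoder-generator.
#
# A network is a list(layers = <list>, slope = <numeric>). Each layer is a
# list(W, b[, gamma, beta], conditioned, act) where W is in x out, b length
# out, and gamma/beta are nTissues x out matrices implementing the per-tissue
# instance-level affine of a tissue-conditioning block. Activations are leaky
# ReLU ("lrelu") or identity ("linear"). All functions are pure; gradients are
# returned, never stored in the network.

nnLayer <- function(inDim, outDim, nTissues, conditioned, act, gammaInit,
                    gammaMean = 0) {
  l <- list(
    W = matrix(stats::rnorm(inDim * outDim, sd = 1 / sqrt(inDim)),
               inDim, outDim),
    b = numeric(outDim),
    conditioned = conditioned,
    act = act)
  if (conditioned) {
    # near-identity random scales by default: conditioning is active from the
    # start without disrupting shared-feature alignment across tissues
    l$gamma <- matrix(stats::rnorm(nTissues * outDim, mean = gammaMean,
                                   sd = gammaInit),
                      nTissues, outDim)
    l$beta <- matrix(0, nTissues, outDim)
  }
  l
}

# dims: vector of layer widths incl. input; conditioned/act: per layer
nnNetwork <- function(dims, nTissues, conditioned, act, slope = 0.2,
                      gammaInit = 0.2, gammaMean = 1) {
  nl <- length(dims) - 1L
  stopifnot(length(conditioned) == nl, length(act) == nl)
  layers <- vector("list", nl)
  for (i in seq_len(nl))
    layers[[i]] <- nnLayer(dims[i], dims[i + 1L], nTissues,
                           conditioned[i], act[i], gammaInit, gammaMean)
  list(layers = layers, slope = slope, nTissues = nTissues)
}

nnForward <- function(net, X, ti = NULL, keepCache = FALSE,
                      keepActivations = FALSE) {
  slope <- net$slope
  n <- nrow(X)
  caches <- if (keepCache) vector("list", length(net$layers))
  acts <- if (keepActivations) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    H <- X %*% l$W + matrix(l$b, n, length(l$b), byrow = TRUE)
    A <- if (l$conditioned)
      l$gamma[ti, , drop = FALSE] * H + l$beta[ti, , drop = FALSE]
    else H
    if (l$act == "lrelu") {
      neg <- A < 0
      Y <- A
      Y[neg] <- slope * A[neg]
    } else {
      neg <- NULL
      Y <- A
    }
    if (keepCache) caches[[i]] <- list(X = X, H = H, neg = neg)
    if (keepActivations) acts[[i]] <- Y
    X <- Y
  }
  list(out = X, caches = caches, activations = acts)
}

# dY: gradient of the loss w.r.t. the network output.
# Returns list(grads = per-layer list(W, b[, gamma, beta]), dX).
nnBackward <- function(net, caches, dY, ti = NULL) {
  slope <- net$slope
  nT <- net$nTissues
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- caches[[i]]
    dA <- dY
    if (l$act == "lrelu") dA[cc$neg] <- dA[cc$neg] * slope
    g <- list()
    if (l$conditioned) {
      g$gamma <- rowsumFull(dA * cc$H, ti, nT)
      g$beta <- rowsumFull(dA, ti, nT)
      dH <- dA * l$gamma[ti, , drop = FALSE]
    } else {
      dH <- dA
    }
    g$W <- crossprod(cc$X, dH)
    g$b <- colSums(dH)
    grads[[i]] <- g
    dY <- tcrossprod(dH, l$W)
  }
  list(grads = grads, dX = dY)
}

rowsumFull <- function(m, ti, nT) {
  out <- matrix(0, nT, ncol(m))
  rs <- rowsum(m, ti)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

nnZeroGrads <- function(net) {
  lapply(net$layers, function(l) {
    g <- list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
    if (l$conditioned) {
      g$gamma <- array(0, dim(l$gamma))
      g$beta <- array(0, dim(l$beta))
    }
    g
  })
}

nnAccGrads <- function(acc, g, scale = 1) {
  for (i in seq_along(acc)) {
    for (p in names(acc[[i]])) {
      if (!is.null(g[[i]][[p]]))
        acc[[i]][[p]] <- acc[[i]][[p]] + scale * g[[i]][[p]]
    }
  }
  acc
}

nnGradNorms <- function(grads) {
  vapply(grads, function(g)
    sqrt(sum(vapply(g, function(p) sum(p^2), numeric(1)))), numeric(1))
}

adamInit <- function(net) {
  list(t = 0L,
       m = nnZeroGrads(net),
       v = nnZeroGrads(net))
}

adamStep <- function(net, state, grads, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    for (p in intersect(names(grads[[i]]), c("W", "b", "gamma", "beta"))) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

# mean-absolute-error and its gradient w.r.t. the first argument
l1Mean <- function(a, b) mean(abs(a - b))
l1Grad <- function(a, b) sign(a - b) / length(a)
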