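## A small tabular generative adversarial network trained by the standard
## minimax scheme with binary cross-entropy. Both networks are two-hidden-
## layer leaky-ReLU perceptrons trained with Adam; feature vectors are
## standardized per coordinate before training and de-standardized on
## sampling. The implementation is deliberately self-contained (dense
## forward/backward passes in base R) since the feature spaces involved are
## low-dimensional.

LEAKY_SLOPE <- 0.2

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) ifelse(Z > 0, Z, LEAKY_SLOPE * Z) else Z
  }
  list(out = acts[[L + 1L]], acts = acts)
}

## dOut is the gradient w.r.t. the (linear) output; returns parameter
## gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A <- fw$acts[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      dA <- delta %*% t(net$W[[l]])
      H <- fw$acts[[l]]  # post-activation of layer l-1's output
      delta <- dA * ifelse(H > 0, 1, LEAKY_SLOPE)
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(gW = gW, gb = gb, dX = delta)
}

adam_init <- function(net) {
  z <- function(p) lapply(p, function(x) x * 0)
  list(mW = z(net$W), vW = z(net$W), mb = z(net$b), vb = z(net$b), t = 0L)
}

adam_step <- function(net, st, grads, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- b1 * st$mW[[l]] + (1 - b1) * grads$gW[[l]]
    st$vW[[l]] <- b2 * st$vW[[l]] + (1 - b2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- b1 * st$mb[[l]] + (1 - b1) * grads$gb[[l]]
    st$vb[[l]] <- b2 * st$vb[[l]] + (1 - b2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a tabular GAN on a reference cohort
#'
#' Standard minimax training with binary cross-entropy: per epoch one
#' discriminator update on a minibatch of real and generated vectors,
#' followed by one non-saturating generator update. Architecture: latent
#' dimension 16, generator and discriminator each with two hidden layers of
#' 32 leaky-ReLU units, Adam with learning rate 1e-3.
#'
#' @param reference matrix of reference feature vectors (rows), at least
#'   `batch` of them.
#' @param epochs training epochs (default 2000).
#' @param batch minibatch size (default 5).
#' @param seed integer seed; the same seed reproduces identical weights.
#' @param latent_dim,hidden network sizes.
#' @return A `gan_model`: generator/discriminator weights, standardization
#'   parameters, and a per-epoch training `log` (discriminator and generator
#'   loss, discriminator accuracy on the minibatch).
#' @export
gan_train <- function(reference, epochs = 2000L, batch = 5L, seed = NULL,
                      latent_dim = 16L, hidden = 32L) {
  X <- as.matrix(reference)
  if (nrow(X) < batch) stopf("reference smaller than batch size")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- ncol(Z)
  with_seed(seed, {
    G <- mlp_init(c(latent_dim, hidden, hidden, n))
    D <- mlp_init(c(n, hidden, hidden, 1L))
    stG <- adam_init(G); stD <- adam_init(D)
    log <- data.frame(epoch = seq_len(epochs), d_loss = NA_real_,
                      g_loss = NA_real_, d_accuracy = NA_real_)
    for (ep in seq_len(epochs)) {
      real <- Z[sample.int(nrow(Z), batch, replace = nrow(Z) < batch), , drop = FALSE]
      zl <- matrix(stats::rnorm(batch * latent_dim), batch)
      fwG <- mlp_forward(G, zl)
      fake <- fwG$out
      ## discriminator step
      Xd <- rbind(real, fake)
      y <- c(rep(1, batch), rep(0, batch))
      fwD <- mlp_forward(D, Xd)
      p <- sigmoid(fwD$out[, 1])
      d_loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
      if (!is.finite(d_loss))
        stopf("GAN training diverged at epoch %d (non-finite loss)", ep)
      dOut <- matrix((p - y) / length(y), ncol = 1)
      gD <- mlp_backward(D, fwD, dOut)
      up <- adam_step(D, stD, gD); D <- up$net; stD <- up$st
      ## generator step (non-saturating): push D(fake) toward 1
      zl2 <- matrix(stats::rnorm(batch * latent_dim), batch)
      fwG2 <- mlp_forward(G, zl2)
      fwD2 <- mlp_forward(D, fwG2$out)
      p2 <- sigmoid(fwD2$out[, 1])
      g_loss <- -mean(log(pmax(p2, 1e-12)))
      if (!is.finite(g_loss))
        stopf("GAN training diverged at epoch %d (non-finite loss)", ep)
      dOut2 <- matrix((p2 - 1) / length(p2), ncol = 1)
      gD2 <- mlp_backward(D, fwD2, dOut2)
      gG <- mlp_backward(G, fwG2, gD2$dX)
      up <- adam_step(G, stG, gG); G <- up$net; stG <- up$st
      log$d_loss[ep] <- d_loss
      log$g_loss[ep] <- g_loss
      log$d_accuracy[ep] <- mean((p > 0.5) == (y == 1))
    }
    structure(list(G = G, D = D, latent_dim = latent_dim, hidden = hidden,
                   center = ctr, scale = scl, n = n, epochs = epochs,
                   batch = batch, seed = seed, log = log),
              class = "gan_model")
  })
}

#' @export
print.gan_model <- function(x, ...) {
  last <- utils::tail(x$log, 10)
  cat(sprintf("gan_model: %d -> %d, %d epochs (batch %d), final D accuracy %.2f\n",
              x$latent_dim, x$n, x$epochs, x$batch, mean(last$d_accuracy)))
  invisible(x)
}

#' Sample feature vectors from a trained GAN
#'
#' @param model a `gan_model`.
#' @param K number of samples.
#' @param seed integer seed.
#' @return A `K x n` cohort matrix, provenance `"gan"`.
#' @export
gan_sample <- function(model, K, seed = NULL) {
  if (K <= 0) stopf("K must be positive")
  with_seed(seed, {
    zl <- matrix(stats::rnorm(K * model$latent_dim), K)
    Z <- mlp_forward(model$G, zl)$out
    X <- sweep(sweep(Z, 2, model$scale, "*"), 2, model$center, "+")
    as_cohort(X, "gan", seed)
  })
}

#' Score vectors with the GAN discriminator
#'
#' @param model a `gan_model`.
#' @param X matrix of feature vectors (rows).
#' @return Probabilities in `[0, 1]` that each vector is "real".
#' @export
gan_discriminate <- function(model, X) {
  Z <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
  sigmoid(mlp_forward(model$D, Z)$out[, 1])
}
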