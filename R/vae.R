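# Mixed-likelihood variational autoencoder for tabular clinical data.
#
# Encoder and decoder are small tanh multilayer perceptrons; the latent
# posterior is diagonal gaussian against a standard normal prior, and the
# decoder likelihood is gaussian (learned per-column variance) for continuous
# columns and bernoulli (logit) for binary columns.  Training maximises the
# evidence lower bound
#   ELBO = E_q[ sum_j log p(x_j | z) ] - KL( q(z|x) || N(0, I) )
# with the reparameterisation trick, Adam updates, and a linear KL warm-up
# over the first fraction of epochs to avoid posterior collapse.  Everything
# is plain R matrix code, deterministic for a fixed seed.

#' Configure a variational autoencoder
#'
#' @param latent_dim dimension `d` of the latent space (must be < number of
#'   features).
#' @param hidden integer vector of hidden-layer widths for both encoder and
#'   decoder (default two layers of 64).
#' @param epochs fixed training budget (no early stopping, for
#'   reproducibility).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param kl_warmup fraction of epochs over which the KL weight ramps
#'   linearly from 0 to 1.
#' @param sigma2_floor floor on the learned per-column gaussian variance.
#' @param seed integer seed controlling initialisation, shuffling and
#'   reparameterisation noise.
#' @return an object of class `vae_config`.
#' @export
vae_config <- function(latent_dim, hidden = c(64, 64), epochs = 80,
                       batch_size = 128, learning_rate = 1e-3,
                       kl_warmup = 0.2, sigma2_floor = 1e-4, seed = 1L) {
  stopifnot(latent_dim >= 1, all(hidden >= 1), epochs >= 1, batch_size >= 1,
            learning_rate > 0, kl_warmup >= 0, kl_warmup <= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, kl_warmup = kl_warmup,
                 sigma2_floor = sigma2_floor, seed = as.integer(seed)),
            class = "vae_config")
}

vae_init_params <- function(p, hidden, d, n_cont) {
  layer <- function(fan_in, fan_out) {
    list(W = matrix(rnorm(fan_in * fan_out, sd = 1 / sqrt(fan_in)),
                    fan_in, fan_out),
         b = rep(0, fan_out))
  }
  enc <- list(); last <- p
  for (h in hidden) { enc[[length(enc) + 1L]] <- layer(last, h); last <- h }
  dec <- list(); dlast <- d
  for (h in rev(hidden)) { dec[[length(dec) + 1L]] <- layer(dlast, h); dlast <- h }
  list(enc = enc,
       mu = layer(last, d), lv = layer(last, d),
       dec = dec,
       out = layer(dlast, p),
       log_s2 = rep(0, n_cont))
}

# forward pass; returns activations needed for backprop
vae_forward <- function(par, X, eps) {
  hs <- list(X); h <- X
  for (l in par$enc) { h <- tanh(h %*% l$W + rep(l$b, each = nrow(h))); hs[[length(hs) + 1L]] <- h }
  mu <- h %*% par$mu$W + rep(par$mu$b, each = nrow(h))
  lv <- h %*% par$lv$W + rep(par$lv$b, each = nrow(h))
  lv <- pmin(pmax(lv, -10), 10)
  z <- mu + exp(0.5 * lv) * eps
  gs <- list(z); g <- z
  for (l in par$dec) { g <- tanh(g %*% l$W + rep(l$b, each = nrow(g))); gs[[length(gs) + 1L]] <- g }
  out <- g %*% par$out$W + rep(par$out$b, each = nrow(g))
  list(hs = hs, mu = mu, lv = lv, z = z, gs = gs, out = out)
}

# per-sample-averaged loss terms; cont/bin are column index vectors
vae_loss_terms <- function(par, X, fw, cont, bin, floor) {
  m <- nrow(X)
  ls2 <- pmax(par$log_s2, log(floor))
  recon <- 0
  if (length(cont)) {
    r <- X[, cont, drop = FALSE] - fw$out[, cont, drop = FALSE]
    recon <- recon + sum(sweep(r^2, 2, 2 * exp(ls2), "/")) / m +
      0.5 * m * sum(ls2 + log(2 * pi)) / m
  }
  if (length(bin)) {
    o <- fw$out[, bin, drop = FALSE]
    xb <- X[, bin, drop = FALSE]
    recon <- recon + sum(pmax(o, 0) - o * xb + log1p(exp(-abs(o)))) / m
  }
  kl <- 0.5 * sum(exp(fw$lv) + fw$mu^2 - 1 - fw$lv) / m
  list(recon = recon, kl = kl)
}

vae_backward <- function(par, X, fw, cont, bin, beta, floor) {
  m <- nrow(X)
  g <- list()
  dout <- matrix(0, m, ncol(X))
  ls2 <- pmax(par$log_s2, log(floor))
  if (length(cont)) {
    r <- fw$out[, cont, drop = FALSE] - X[, cont, drop = FALSE]
    dout[, cont] <- sweep(r, 2, exp(ls2), "/") / m
    g$log_s2 <- 0.5 * colSums(1 - sweep(r^2, 2, exp(ls2), "/")) / m
  } else g$log_s2 <- numeric(0)
  if (length(bin)) {
    o <- fw$out[, bin, drop = FALSE]
    dout[, bin] <- (plogis(o) - X[, bin, drop = FALSE]) / m
  }
  # decoder output layer
  glast <- fw$gs[[length(fw$gs)]]
  g$out <- list(W = crossprod(glast, dout), b = colSums(dout))
  dg <- dout %*% t(par$out$W)
  # decoder hidden layers (reverse)
  g$dec <- vector("list", length(par$dec))
  for (li in rev(seq_along(par$dec))) {
    act <- fw$gs[[li + 1L]]
    dpre <- dg * (1 - act^2)
    g$dec[[li]] <- list(W = crossprod(fw$gs[[li]], dpre), b = colSums(dpre))
    dg <- dpre %*% t(par$dec[[li]]$W)
  }
  dz <- dg
  dmu <- dz + beta * fw$mu / m
  eps <- (fw$z - fw$mu) / exp(0.5 * fw$lv)
  dlv <- dz * eps * 0.5 * exp(0.5 * fw$lv) + beta * 0.5 * (exp(fw$lv) - 1) / m
  dlv[fw$lv <= -10 | fw$lv >= 10] <- 0
  henc <- fw$hs[[length(fw$hs)]]
  g$mu <- list(W = crossprod(henc, dmu), b = colSums(dmu))
  g$lv <- list(W = crossprod(henc, dlv), b = colSums(dlv))
  dh <- dmu %*% t(par$mu$W) + dlv %*% t(par$lv$W)
  g$enc <- vector("list", length(par$enc))
  for (li in rev(seq_along(par$enc))) {
    act <- fw$hs[[li + 1L]]
    dpre <- dh * (1 - act^2)
    g$enc[[li]] <- list(W = crossprod(fw$hs[[li]], dpre), b = colSums(dpre))
    dh <- dpre %*% t(par$enc[[li]]$W)
  }
  g
}

# flatten/unflatten parameter lists so Adam state is a single vector pair
vae_flatten <- function(par) {
  unlist(list(
    enc = lapply(par$enc, function(l) c(l$W, l$b)),
    mu = c(par$mu$W, par$mu$b), lv = c(par$lv$W, par$lv$b),
    dec = lapply(par$dec, function(l) c(l$W, l$b)),
    out = c(par$out$W, par$out$b), log_s2 = par$log_s2), use.names = FALSE)
}

vae_unflatten <- function(theta, skel) {
  pos <- 0L
  take <- function(nr, nc = NULL) {
    len <- if (is.null(nc)) nr else nr * nc
    v <- theta[(pos + 1L):(pos + len)]; pos <<- pos + len
    if (is.null(nc)) v else matrix(v, nr, nc)
  }
  out <- skel
  for (i in seq_along(skel$enc)) {
    out$enc[[i]]$W <- take(nrow(skel$enc[[i]]$W), ncol(skel$enc[[i]]$W))
    out$enc[[i]]$b <- take(length(skel$enc[[i]]$b))
  }
  out$mu$W <- take(nrow(skel$mu$W), ncol(skel$mu$W)); out$mu$b <- take(length(skel$mu$b))
  out$lv$W <- take(nrow(skel$lv$W), ncol(skel$lv$W)); out$lv$b <- take(length(skel$lv$b))
  for (i in seq_along(skel$dec)) {
    out$dec[[i]]$W <- take(nrow(skel$dec[[i]]$W), ncol(skel$dec[[i]]$W))
    out$dec[[i]]$b <- take(length(skel$dec[[i]]$b))
  }
  out$out$W <- take(nrow(skel$out$W), ncol(skel$out$W)); out$out$b <- take(length(skel$out$b))
  out$log_s2 <- take(length(skel$log_s2))
  out
}

#' Fit a variational autoencoder to a feature matrix
#'
#' @param X a `feature_matrix` from [encode_features()] (complete,
#'   standardised).
#' @param config a [vae_config()].
#' @return object of class `vae`: fitted parameters, the config, the training
#'   schema, and `training_log` (per-epoch objective = reconstruction + KL,
#'   evaluated on the full data at the posterior mean).
#' @export
fit_vae <- function(X, config) {
  stopifnot(inherits(X, "feature_matrix"), inherits(config, "vae_config"))
  vals <- X$values
  p <- ncol(vals); n <- nrow(vals)
  if (config$latent_dim >= p) {
    stop("latent_dim must be smaller than the number of features", call. = FALSE)
  }
  cont <- which(X$schema$type == "continuous")
  bin <- which(X$schema$type == "binary")
  d <- config$latent_dim
  with_seed(config$seed, {
    par <- vae_init_params(p, config$hidden, d, length(cont))
    theta <- vae_flatten(par)
    mstate <- numeric(length(theta)); vstate <- numeric(length(theta))
    lr <- config$learning_rate; b1 <- 0.9; b2 <- 0.999; epsadam <- 1e-8
    step <- 0L
    warm_epochs <- max(1, ceiling(config$kl_warmup * config$epochs))
    log_df <- data.frame(epoch = integer(0), objective = numeric(0),
                         recon = numeric(0), kl = numeric(0),
                         kl_weight = numeric(0))
    floor_ls2 <- log(config$sigma2_floor)
    for (ep in seq_len(config$epochs)) {
      beta <- if (config$kl_warmup > 0) min(1, ep / warm_epochs) else 1
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- vals[idx, , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * d), length(idx), d)
        fw <- vae_forward(par, xb, eps)
        gr <- vae_backward(par, xb, fw, cont, bin, beta, config$sigma2_floor)
        gvec <- vae_flatten(gr)
        step <- step + 1L
        mstate <- b1 * mstate + (1 - b1) * gvec
        vstate <- b2 * vstate + (1 - b2) * gvec^2
        mhat <- mstate / (1 - b1^step)
        vhat <- vstate / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + epsadam)
        par <- vae_unflatten(theta, par)
        par$log_s2 <- pmax(par$log_s2, floor_ls2)
        theta <- vae_flatten(par)
      }
      # epoch-end accounting on the full data at the posterior mean
      fw <- vae_forward(par, vals, matrix(0, n, d))
      lt <- vae_loss_terms(par, vals, fw, cont, bin, config$sigma2_floor)
      log_df <- rbind(log_df, data.frame(epoch = ep,
                                         objective = lt$recon + lt$kl,
                                         recon = lt$recon, kl = lt$kl,
                                         kl_weight = beta))
    }
    structure(list(params = par, config = config, schema = X$schema,
                   scaling = X$scaling, training_log = log_df),
              class = "vae")
  })
}

#' @export
print.vae <- function(x, ...) {
  cat(sprintf("vae: %d features -> %d latent dims; hidden [%s]; %d epochs, final objective %.4f\n",
              nrow(x$schema), x$config$latent_dim,
              paste(x$config$hidden, collapse = ", "),
              x$config$epochs, utils::tail(x$training_log$objective, 1)))
  invisible(x)
}

check_schema <- function(fit_schema, X) {
  if (!identical(fit_schema$name, X$schema$name) ||
      !identical(fit_schema$type, X$schema$type)) {
    stop("feature schema does not match the one used in training", call. = FALSE)
  }
}

#' Encode data to latent posterior means
#'
#' Deterministic: returns the posterior mean, not a draw, so downstream
#' clustering is reproducible.
#'
#' @param fit a fitted [fit_vae()] object.
#' @param X a `feature_matrix` with the training schema.
#' @return object of class `embedding` (n x d coordinates).
#' @export
encode_mean <- function(fit, X) {
  stopifnot(inherits(fit, "vae"), inherits(X, "feature_matrix"))
  check_schema(fit$schema, X)
  vals <- X$values
  h <- vals
  for (l in fit$params$enc) h <- tanh(h %*% l$W + rep(l$b, each = nrow(h)))
  mu <- h %*% fit$params$mu$W + rep(fit$params$mu$b, each = nrow(h))
  structure(list(coords = mu, source = "vae", d = ncol(mu),
                 patient_id = X$patient_id,
                 training_log = fit$training_log),
            class = "embedding")
}

#' Decode latent posterior means back to the feature scale
#'
#' @param fit fitted `vae`.
#' @param X feature matrix to reconstruct.
#' @return n x p matrix: means for continuous columns, probabilities for
#'   binary columns.
#' @export
reconstruct <- function(fit, X) {
  emb <- encode_mean(fit, X)
  g <- emb$coords
  for (l in fit$params$dec) g <- tanh(g %*% l$W + rep(l$b, each = nrow(g)))
  out <- g %*% fit$params$out$W + rep(fit$params$out$b, each = nrow(g))
  bin <- which(fit$schema$type == "binary")
  if (length(bin)) out[, bin] <- plogis(out[, bin])
  colnames(out) <- fit$schema$name
  out
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d patients x %d dims\n", x$source,
              nrow(x$coords), x$d))
  invisible(x)
}

#' Linear (principal component) baseline embedding
#'
#' First `d` principal-component scores of the feature matrix, with the sign
#' convention that each component's largest-magnitude loading is positive.
#'
#' @param X a `feature_matrix`.
#' @param d number of components.
#' @return an `embedding` with `source = "pca"`.
#' @export
fit_pca <- function(X, d) {
  stopifnot(inherits(X, "feature_matrix"))
  pc <- stats::prcomp(X$values, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-12)
  if (d > rank) stop(sprintf("d = %d exceeds the data rank %d", d, rank),
                     call. = FALSE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, "*")
  structure(list(coords = scores, source = "pca", d = d,
                 patient_id = X$patient_id,
                 rotation = sweep(rot, 2, flip, "*"),
                 center = pc$center,
                 training_log = NULL),
            class = "embedding")
}
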