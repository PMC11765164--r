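## Transformer-encoder + dynamic-residual disease classifier.
##
## The network consumes the beta values of the d selected CpG sites of one
## sample, passes them through L Transformer encoder layers, optionally
## through a sigmoid-gated dynamic residual layer
##   T = H W_fc + b_fc,  G = sigmoid(H W_gate + b_gate),
##   O = G * T + (1 - G) * H,
## and classifies with a 2-way softmax. Two token layouts are supported:
##   "channel"  - the literal layout: one token of width d (C' in R^{1 x d}).
##                Self-attention over a single position is identity mixing,
##                so the attention sublayer reduces to its value/output
##                projections; the query/key weights exist but receive no
##                gradient. The whole batch vectorises to n x d matrix ops.
##   "per_site" - d tokens of width 1, each linearly embedded to embed_dim
##                with a learned positional embedding; full multi-head
##                attention over the d positions; a per-token linear read-out
##                brings the encoding back to a length-d vector for the
##                residual layer.
## All forward/backward passes are hand-derived; tests check the analytic
## gradients against central finite differences.

LN_EPS <- 1e-5

## flatten / unflatten a nested list of numeric leaves in unlist() order.
## utils::relist is far too slow for per-minibatch use, so the optimiser
## works on one flat numeric vector and rebuilds the weight tree with this.
tree_relist <- function(theta, template) {
  pos <- 0L
  rebuild <- function(t) {
    if (is.list(t)) return(lapply(t, rebuild))
    n <- length(t)
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dim(v) <- dim(t)
    v
  }
  rebuild(template)
}

addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise the diagnosis model
#'
#' Deterministic given \code{seed}. The baseline variant
#' (\code{use_dynamic_residual = FALSE}) feeds the encoder output directly
#' to the classifier.
#'
#' @param d number of input CpG sites (model dimension in channel mode).
#' @param layers encoder layers (default 2).
#' @param heads attention heads (default 4); must divide the model width
#'   (\code{d} in channel mode, \code{embed_dim} in per-site mode).
#' @param use_dynamic_residual include the gated residual layer.
#' @param tokens \code{"channel"} (one token of width d; default) or
#'   \code{"per_site"} (d tokens embedded to \code{embed_dim}).
#' @param embed_dim token embedding width for per-site mode.
#' @param dropout dropout rate used during training.
#' @param seed integer seed.
#' @return object of class \code{diagnosis_model}.
#' @export
init_model <- function(d, layers = 2L, heads = 4L,
                       use_dynamic_residual = TRUE,
                       tokens = c("channel", "per_site"),
                       embed_dim = 16L, dropout = 0.1, seed = 1L) {
  tokens <- match.arg(tokens)
  dm <- if (tokens == "channel") as.integer(d) else as.integer(embed_dim)
  if (dm %% heads != 0)
    stop(sprintf("model width %d is not divisible by %d heads", dm, heads),
         call. = FALSE)
  set.seed(seed)
  ff <- 2L * dm
  w <- list()
  if (tokens == "per_site") {
    w$embed <- list(w = matrix(stats::rnorm(dm, sd = 0.5), 1, dm),
                    b = numeric(dm),
                    pos = matrix(stats::rnorm(d * dm, sd = 0.02), d, dm))
    w$readout <- list(w = matrix(stats::rnorm(dm, sd = 0.5), dm, 1),
                      b = 0)
  }
  w$enc <- lapply(seq_len(layers), function(l) list(
    Wq = glorot(dm, dm), bq = numeric(dm),
    Wk = glorot(dm, dm), bk = numeric(dm),
    Wv = glorot(dm, dm), bv = numeric(dm),
    Wo = glorot(dm, dm), bo = numeric(dm),
    g1 = rep(1, dm), n1 = numeric(dm),
    W1 = glorot(dm, ff), b1 = numeric(ff),
    W2 = glorot(ff, dm), b2 = numeric(dm),
    g2 = rep(1, dm), n2 = numeric(dm)))
  if (use_dynamic_residual)
    # gate bias starts at -1 so the layer opens from near-identity,
    # highway-network style; avoids an initially saturated mixture
    w$res <- list(W_fc = glorot(d, d), b_fc = numeric(d),
                  W_gate = glorot(d, d), b_gate = rep(-1, d))
  # zero-initialised head: training starts at the chance loss log(2)
  # instead of a saturated plateau the optimiser must first escape
  w$cls <- list(W = matrix(0, d, 2L), b = numeric(2L))
  structure(list(
    arch = list(d = as.integer(d), layers = as.integer(layers),
                heads = as.integer(heads), dmodel = dm, ff = ff,
                tokens = tokens,
                use_dynamic_residual = isTRUE(use_dynamic_residual),
                dropout = dropout),
    weights = w, site_ids = NULL), class = "diagnosis_model")
}

#' @export
print.diagnosis_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(
    "diagnosis_model: d=%d, %d encoder layer(s), %d head(s), %s tokens, %s\n",
    a$d, a$layers, a$heads, a$tokens,
    if (a$use_dynamic_residual) "dynamic residual" else "baseline (no residual)"))
  invisible(x)
}

## ---- layer primitives -----------------------------------------------------

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  sigma <- sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc / sigma
  list(out = addb(sweep(xhat, 2, g, "*"), b), xhat = xhat, sigma = sigma)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; sigma <- cache$sigma
  dxhat <- sweep(dY, 2, g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sigma
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

drop_mask <- function(dim1, dim2, rate, training) {
  if (!training || rate <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

apply_mask <- function(M, mask) if (is.null(mask)) M else M * mask

## attention sublayer, degenerate (single-position) variant: rows of M are
## independent length-dm tokens, softmax over one position is 1, so the
## context equals the value projection.
attn_deg_fwd <- function(M, lp, rate, training) {
  V <- addb(M %*% lp$Wv, lp$bv)
  A <- addb(V %*% lp$Wo, lp$bo)
  mask <- drop_mask(nrow(A), ncol(A), rate, training)
  list(out = apply_mask(A, mask), V = V, mask = mask)
}

attn_deg_bwd <- function(dA, M, lp, cache) {
  dA <- apply_mask(dA, cache$mask)
  g <- list(Wo = crossprod(cache$V, dA), bo = colSums(dA))
  dV <- dA %*% t(lp$Wo)
  g$Wv <- crossprod(M, dV); g$bv <- colSums(dV)
  g$Wq <- lp$Wq * 0; g$bq <- lp$bq * 0
  g$Wk <- lp$Wk * 0; g$bk <- lp$bk * 0
  list(dM = dV %*% t(lp$Wv), g = g)
}

## full multi-head attention over the rows of M (S x dm), one sample.
attn_full_fwd <- function(M, lp, heads, rate, training) {
  dm <- ncol(M); dh <- dm %/% heads
  Q <- addb(M %*% lp$Wq, lp$bq)
  K <- addb(M %*% lp$Wk, lp$bk)
  V <- addb(M %*% lp$Wv, lp$bv)
  Ctx <- matrix(0, nrow(M), dm)
  P <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)
    E <- exp(S)
    P[[h]] <- E / rowSums(E)
    Ctx[, idx] <- P[[h]] %*% V[, idx, drop = FALSE]
  }
  A <- addb(Ctx %*% lp$Wo, lp$bo)
  mask <- drop_mask(nrow(A), ncol(A), rate, training)
  list(out = apply_mask(A, mask), Q = Q, K = K, V = V, P = P, Ctx = Ctx,
       mask = mask)
}

attn_full_bwd <- function(dA, M, lp, heads, cache) {
  dm <- ncol(M); dh <- dm %/% heads
  dA <- apply_mask(dA, cache$mask)
  g <- list(Wo = crossprod(cache$Ctx, dA), bo = colSums(dA))
  dCtx <- dA %*% t(lp$Wo)
  dQ <- matrix(0, nrow(M), dm); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    Ph <- cache$P[[h]]
    dCh <- dCtx[, idx, drop = FALSE]
    dP <- tcrossprod(dCh, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Ph, dCh)
    dS <- Ph * (dP - rowSums(dP * Ph))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  g$Wq <- crossprod(M, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(M, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(M, dV); g$bv <- colSums(dV)
  dM <- dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
  list(dM = dM, g = g)
}

enc_layer_fwd <- function(M, lp, heads, full_attn, rate, training) {
  at <- if (full_attn) attn_full_fwd(M, lp, heads, rate, training)
        else attn_deg_fwd(M, lp, rate, training)
  R1 <- M + at$out
  l1 <- ln_fwd(R1, lp$g1, lp$n1)
  Y1 <- l1$out
  pre <- addb(Y1 %*% lp$W1, lp$b1)
  Hf <- pmax(pre, 0)
  m2 <- drop_mask(nrow(Hf), ncol(Hf), rate, training)
  Hfd <- apply_mask(Hf, m2)
  Fo <- addb(Hfd %*% lp$W2, lp$b2)
  m3 <- drop_mask(nrow(Fo), ncol(Fo), rate, training)
  Fod <- apply_mask(Fo, m3)
  l2 <- ln_fwd(Y1 + Fod, lp$g2, lp$n2)
  list(out = l2$out,
       cache = list(M = M, at = at, l1 = l1, Y1 = Y1, pre = pre,
                    Hfd = Hfd, m2 = m2, m3 = m3, l2 = l2))
}

enc_layer_bwd <- function(dY2, lp, heads, full_attn, cache) {
  b2 <- ln_bwd(dY2, cache$l2, lp$g2)
  g <- list(g2 = b2$dg, n2 = b2$db)
  dR2 <- b2$dX
  dFo <- apply_mask(dR2, cache$m3)
  g$W2 <- crossprod(cache$Hfd, dFo); g$b2 <- colSums(dFo)
  dHfd <- dFo %*% t(lp$W2)
  dHf <- apply_mask(dHfd, cache$m2)
  dpre <- dHf * (cache$pre > 0)
  g$W1 <- crossprod(cache$Y1, dpre); g$b1 <- colSums(dpre)
  dY1 <- dR2 + dpre %*% t(lp$W1)
  b1 <- ln_bwd(dY1, cache$l1, lp$g1)
  g$g1 <- b1$dg; g$n1 <- b1$db
  dR1 <- b1$dX
  ab <- if (full_attn) attn_full_bwd(dR1, cache$M, lp, heads, cache$at)
        else attn_deg_bwd(dR1, cache$M, lp, cache$at)
  g[names(ab$g)] <- ab$g
  # flatten-order contract: gradients must mirror the weight-tree layout
  g <- g[c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "g1", "n1", "W1", "b1", "W2", "b2", "g2", "n2")]
  list(dM = dR1 + ab$dM, g = g)
}

## ---- dynamic residual -----------------------------------------------------

#' Dynamic gated-residual layer, forward pass
#'
#' Computes \eqn{T = H W_{fc} + b_{fc}}, gate
#' \eqn{G = \sigma(H W_{gate} + b_{gate})} and output
#' \eqn{O = G \odot T + (1 - G) \odot H}. With the gate saturated closed
#' (large negative \code{b_gate}) the layer is the identity; saturated open
#' it is the plain affine transform.
#'
#' @param H numeric vector of length d (or n x d matrix of row vectors).
#' @param params list with \code{W_fc} (d x d), \code{b_fc} (d),
#'   \code{W_gate} (d x d), \code{b_gate} (d).
#' @return vector (or matrix) of the same shape as \code{H}.
#' @export
dynamic_residual_forward <- function(H, params) {
  vec <- is.null(dim(H))
  Hm <- if (vec) matrix(H, 1) else H
  d <- ncol(Hm)
  stopifnot(all(dim(params$W_fc) == c(d, d)),
            all(dim(params$W_gate) == c(d, d)),
            length(params$b_fc) == d, length(params$b_gate) == d)
  Tm <- addb(Hm %*% params$W_fc, params$b_fc)
  G <- stats::plogis(addb(Hm %*% params$W_gate, params$b_gate))
  O <- G * Tm + (1 - G) * Hm
  if (vec) drop(O) else O
}

res_fwd <- function(H, rp) {
  Tm <- addb(H %*% rp$W_fc, rp$b_fc)
  G <- stats::plogis(addb(H %*% rp$W_gate, rp$b_gate))
  list(out = G * Tm + (1 - G) * H, Tm = Tm, G = G)
}

res_bwd <- function(dO, H, rp, cache) {
  G <- cache$G; Tm <- cache$Tm
  dG <- dO * (Tm - H)
  dT <- dO * G
  dH <- dO * (1 - G)
  dZg <- dG * G * (1 - G)
  g <- list(W_fc = crossprod(H, dT), b_fc = colSums(dT),
            W_gate = crossprod(H, dZg), b_gate = colSums(dZg))
  dH <- dH + dT %*% t(rp$W_fc) + dZg %*% t(rp$W_gate)
  list(dH = dH, g = g)
}

## ---- full model -----------------------------------------------------------

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

# forward over a batch X (n x d); returns probabilities and caches.
net_fwd <- function(X, model, training = FALSE) {
  a <- model$arch; w <- model$weights
  rate <- if (training) a$dropout else 0
  caches <- list()
  if (a$tokens == "channel") {
    M <- X
    for (l in seq_len(a$layers)) {
      st <- enc_layer_fwd(M, w$enc[[l]], a$heads, FALSE, rate, training)
      caches[[l]] <- st$cache
      M <- st$out
    }
    H <- M
    tok <- NULL
  } else {
    # per-sample token processing
    n <- nrow(X)
    H <- matrix(0, n, a$d)
    tok <- vector("list", n)
    for (i in seq_len(n)) {
      Emb <- addb(X[i, ] %o% drop(w$embed$w) + w$embed$pos, w$embed$b)
      M <- Emb
      ci <- list(Emb = Emb, layers = vector("list", a$layers))
      for (l in seq_len(a$layers)) {
        st <- enc_layer_fwd(M, w$enc[[l]], a$heads, TRUE, rate, training)
        ci$layers[[l]] <- st$cache
        M <- st$out
      }
      ci$Enc <- M
      H[i, ] <- drop(M %*% w$readout$w) + w$readout$b
      tok[[i]] <- ci
    }
  }
  if (a$use_dynamic_residual) {
    rs <- res_fwd(H, w$res)
    O <- rs$out
  } else {
    rs <- NULL
    O <- H
  }
  Z <- addb(O %*% w$cls$W, w$cls$b)
  P <- softmax_rows(Z)
  list(P = P, H = H, O = O, rs = rs, enc_caches = caches, tok = tok)
}

# cross-entropy loss and full gradient tree for a labelled batch.
net_loss_grad <- function(X, y, model, training = FALSE) {
  a <- model$arch; w <- model$weights
  fw <- net_fwd(X, model, training)
  n <- nrow(X)
  idx <- cbind(seq_len(n), y + 1L)
  p <- pmax(fw$P[idx], 1e-12)
  loss <- -mean(log(p))
  Y <- matrix(0, n, 2); Y[idx] <- 1
  dZ <- (fw$P - Y) / n

  g <- list()
  g$cls <- list(W = crossprod(fw$O, dZ), b = colSums(dZ))
  dO <- dZ %*% t(w$cls$W)
  if (a$use_dynamic_residual) {
    rb <- res_bwd(dO, fw$H, w$res, fw$rs)
    g$res <- rb$g
    dH <- rb$dH
  } else dH <- dO

  if (a$tokens == "channel") {
    dM <- dH
    genc <- vector("list", a$layers)
    for (l in rev(seq_len(a$layers))) {
      bl <- enc_layer_bwd(dM, w$enc[[l]], a$heads, FALSE, fw$enc_caches[[l]])
      genc[[l]] <- bl$g
      dM <- bl$dM
    }
    g$enc <- genc
  } else {
    genc <- lapply(w$enc, function(lp) lapply(lp, function(p) p * 0))
    gemb <- lapply(w$embed, function(p) p * 0)
    gro <- list(w = w$readout$w * 0, b = 0)
    for (i in seq_len(n)) {
      ci <- fw$tok[[i]]
      dEnc <- dH[i, ] %o% drop(w$readout$w)
      gro$w <- gro$w + t(ci$Enc) %*% matrix(dH[i, ], ncol = 1)
      gro$b <- gro$b + sum(dH[i, ])
      dM <- dEnc
      for (l in rev(seq_len(a$layers))) {
        bl <- enc_layer_bwd(dM, w$enc[[l]], a$heads, TRUE, ci$layers[[l]])
        genc[[l]] <- Map(`+`, genc[[l]], bl$g)
        dM <- bl$dM
      }
      gemb$w <- gemb$w + matrix(colSums(X[i, ] * dM), 1)
      gemb$b <- gemb$b + colSums(dM)
      gemb$pos <- gemb$pos + dM
    }
    g$embed <- gemb; g$readout <- gro; g$enc <- genc
  }
  # order gradient tree exactly like the weight tree
  g <- g[names(w)]
  list(loss = loss, grads = g, P = fw$P)
}

#' Forward pass for a single sample
#'
#' @param C numeric vector of length d (beta values of the selected sites).
#' @param model a \code{diagnosis_model}.
#' @return length-2 probability vector (healthy, disease), summing to 1.
#' @export
model_forward <- function(C, model) {
  stopifnot(inherits(model, "diagnosis_model"))
  if (length(C) != model$arch$d)
    stop(sprintf("input length %d != model dimension %d",
                 length(C), model$arch$d), call. = FALSE)
  if (any(!is.na(C) & (C < 0 | C > 1)))
    stop("beta values must lie in [0,1]", call. = FALSE)
  p <- net_fwd(matrix(C, 1), model, training = FALSE)$P
  stats::setNames(drop(p), c("healthy", "disease"))
}

## ---- training -------------------------------------------------------------

#' Training configuration
#'
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size (default 3e-4; 1e-3 is noticeably
#'   less stable on wide panels, see the package vignette).
#' @param optimizer only \code{"adam"} is implemented.
#' @param weight_decay L2 penalty added to the gradients.
#' @param clip_norm global gradient-norm ceiling per minibatch (standard
#'   stabiliser for attention/LayerNorm stacks, whose loss otherwise spikes
#'   and collapses to a constant predictor); \code{Inf} disables.
#' @param dropout dropout rate during training (overrides the model's).
#' @param patience early-stopping patience in epochs (on validation loss
#'   when \code{val_fraction > 0}, else on training loss).
#' @param val_fraction fraction of samples held out (stratified) for
#'   early-stopping validation; 0 disables the split.
#' @param seed integer seed governing shuffling, dropout and the split.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L,
                         learning_rate = 3e-4, optimizer = "adam",
                         weight_decay = 0, dropout = 0.1, patience = 20L,
                         val_fraction = 0, clip_norm = 1.0, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            identical(optimizer, "adam"), weight_decay >= 0,
            dropout >= 0, dropout < 1, patience >= 1,
            val_fraction >= 0, val_fraction < 1, clip_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 weight_decay = weight_decay, dropout = dropout,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the diagnosis model
#'
#' Minimises cross-entropy with Adam. With identical data, configuration and
#' seed the final weights are identical across runs (single-threaded BLAS
#' assumed for bitwise identity).
#'
#' @param x a \code{\link{methyl_matrix}} restricted to the selected sites,
#'   or a plain numeric samples x sites matrix.
#' @param labels integer status vector (0 healthy / 1 disease), parallel to
#'   the rows of \code{x}.
#' @param config a \code{\link{train_config}}.
#' @param model optionally a pre-initialised \code{\link{init_model}};
#'   otherwise one is created from \code{...}.
#' @param ... arguments passed to \code{\link{init_model}} when \code{model}
#'   is NULL (e.g. \code{layers}, \code{heads},
#'   \code{use_dynamic_residual}).
#' @return list with \code{model} (trained, carrying the training site
#'   order) and \code{history} (data.frame epoch, train_loss, val_loss).
#' @export
train_model <- function(x, labels, config = train_config(), model = NULL,
                        ...) {
  X <- if (inherits(x, "methyl_matrix")) unclass(x) else as.matrix(x)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop("labels length != rows of x", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  if (min(table(y)) < 2)
    stop("need >= 2 samples per class", call. = FALSE)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  if (is.null(model)) model <- init_model(d = ncol(X), seed = config$seed, ...)
  stopifnot(inherits(model, "diagnosis_model"), model$arch$d == ncol(X))
  model$arch$dropout <- config$dropout
  model$site_ids <- colnames(X)

  set.seed(config$seed)
  n <- nrow(X)
  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    for (cl in unique(y)) {
      members <- which(y == cl)
      k <- max(1L, floor(length(members) * config$val_fraction))
      val_idx <- c(val_idx, sample(members, k))
    }
    val_idx <- sort(val_idx)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  skel <- model$weights
  theta <- unlist(skel, use.names = FALSE)
  mom <- numeric(length(theta)); vel <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  n_tr <- length(tr_idx)
  for (ep in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(n_tr)]
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      b <- ord[start:min(start + config$batch_size - 1L, n_tr)]
      lg <- net_loss_grad(X[b, , drop = FALSE], y[b], model, training = TRUE)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                     ep, start),
             "try a lower learning rate", call. = FALSE)
      gvec <- unlist(lg$grads, use.names = FALSE)
      if (config$weight_decay > 0) gvec <- gvec + config$weight_decay * theta
      if (is.finite(config$clip_norm)) {
        gn <- sqrt(sum(gvec^2))
        if (gn > config$clip_norm) gvec <- gvec * (config$clip_norm / gn)
      }
      step <- step + 1L
      mom <- b1 * mom + (1 - b1) * gvec
      vel <- b2 * vel + (1 - b2) * gvec^2
      mhat <- mom / (1 - b1^step)
      vhat <- vel / (1 - b2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
      model$weights <- tree_relist(theta, skel)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    tl <- ep_loss / nb
    vl <- if (length(val_idx) > 0) {
      fwv <- net_fwd(X[val_idx, , drop = FALSE], model, training = FALSE)
      pv <- pmax(fwv$P[cbind(seq_along(val_idx), y[val_idx] + 1L)], 1e-12)
      -mean(log(pv))
    } else NA_real_
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = tl, val_loss = vl))
    mon <- if (is.na(vl)) tl else vl
    if (mon < best$loss - 1e-6) {
      best <- list(loss = mon, theta = theta, epoch = ep)
    } else if (ep - best$epoch >= config$patience) break
  }
  model$weights <- tree_relist(best$theta, skel)
  list(model = model, history = history)
}

#' Predict disease probabilities for new samples
#'
#' @param object a trained \code{diagnosis_model}.
#' @param newdata a \code{\link{methyl_matrix}} (or numeric matrix) whose
#'   columns match the training site order.
#' @param ... ignored.
#' @return numeric matrix, one row per sample, columns
#'   \code{healthy}/\code{disease}, each row summing to 1.
#' @export
predict.diagnosis_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "methyl_matrix")) unclass(newdata)
       else as.matrix(newdata)
  if (!is.null(object$site_ids)) {
    if (ncol(X) != length(object$site_ids))
      stop(sprintf("expected %d sites, got %d",
                   length(object$site_ids), ncol(X)), call. = FALSE)
    if (!is.null(colnames(X))) {
      mism <- which(colnames(X) != object$site_ids)
      if (length(mism) > 0)
        stop(sprintf(
          "site order mismatch at column %d: expected '%s', got '%s'",
          mism[1L], object$site_ids[mism[1L]], colnames(X)[mism[1L]]),
          call. = FALSE)
    }
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0.5
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  P <- net_fwd(X, object, training = FALSE)$P
  dimnames(P) <- list(rownames(X), c("healthy", "disease"))
  P
}

## ---- serialization --------------------------------------------------------

#' Save / load a trained diagnosis model
#'
#' A model directory holds \code{config.json} (architecture + site order;
#' the site order is part of the prediction contract) and
#' \code{weights.tsv} (flattened parameter vector as plain text).
#'
#' @param model a \code{diagnosis_model}.
#' @param dir directory to create/use.
#' @return \code{dir} (save) or the restored model (load).
#' @export
save_diagnosis_model <- function(model, dir) {
  stopifnot(inherits(model, "diagnosis_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(arch = model$arch, site_ids = model$site_ids),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  theta <- unlist(model$weights, use.names = FALSE)
  utils::write.table(
    data.frame(value = format(theta, digits = 17, scientific = TRUE)),
    file.path(dir, "weights.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname save_diagnosis_model
#' @export
load_diagnosis_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  a <- cfg$arch
  model <- init_model(d = a$d, layers = a$layers, heads = a$heads,
                      use_dynamic_residual = a$use_dynamic_residual,
                      tokens = a$tokens,
                      embed_dim = if (a$tokens == "per_site") a$dmodel else 16L,
                      dropout = a$dropout, seed = 1L)
  theta <- as.numeric(utils::read.table(file.path(dir, "weights.tsv"),
                                        header = TRUE)$value)
  model$weights <- tree_relist(theta, model$weights)
  if (!is.null(cfg$site_ids) && length(cfg$site_ids) > 0)
    model$site_ids <- cfg$site_ids
  model
}
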