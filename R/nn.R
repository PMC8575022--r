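# Neural-network core: a 1D convolution -> max-pooling -> bidirectional
# LSTM -> 1D convolution -> flatten -> three dense layers, trained with
# Adam on binary cross-entropy. Written against base matrix ops (BLAS)
# so the package has no deep-learning framework dependency; gradients
# are exercised by numerical-check tests.

#' Model configuration for the per-read classifier
#'
#' Defaults are DanQ-scale values sized for desktop CPU training; all
#' are tunable. The input is an `L x 5` matrix per read (one-hot bases
#' plus methylation channel); the output is a single value in `[0, 1]`
#' (the d-score).
#'
#' @param L Input read length. Default 66.
#' @param conv1_filters,conv1_width First convolution: number of kernels
#'   and kernel width. Defaults 64 and 8.
#' @param pool_width Max-pooling width (= stride). Default 2.
#' @param lstm_units LSTM units per direction. Default 32.
#' @param conv2_filters,conv2_width Second convolution. Defaults 32, 4.
#' @param dense_units Widths of the first two dense layers (the third is
#'   the single sigmoid output). Default `c(64, 16)`.
#' @param dropout Dropout probability after pooling and after the LSTM.
#'   Default 0.2.
#' @param learning_rate Adam step size. Default 1e-3.
#' @param batch_size Minibatch size. Default 128.
#' @param epochs Maximum training epochs. Default 20.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement). Default 3.
#' @param validation_fraction Fraction of the training pool held out for
#'   early stopping. Default 0.1.
#' @param seed Seed for initialization and training shuffles.
#' @return A `dismir_model_config` list with derived shape fields
#'   `P1` (conv1 positions), `T` (pooled steps), `P2` (conv2 positions).
#' @export
dismir_model_config <- function(L = 66L, conv1_filters = 64L,
                                conv1_width = 8L, pool_width = 2L,
                                lstm_units = 32L, conv2_filters = 32L,
                                conv2_width = 4L, dense_units = c(64L, 16L),
                                dropout = 0.2, learning_rate = 1e-3,
                                batch_size = 128L, epochs = 20L,
                                patience = 3L, validation_fraction = 0.1,
                                seed = 1L) {
  cfg <- list(L = as.integer(L), conv1_filters = as.integer(conv1_filters),
              conv1_width = as.integer(conv1_width),
              pool_width = as.integer(pool_width),
              lstm_units = as.integer(lstm_units),
              conv2_filters = as.integer(conv2_filters),
              conv2_width = as.integer(conv2_width),
              dense_units = as.integer(dense_units),
              dropout = dropout, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = as.integer(patience),
              validation_fraction = validation_fraction,
              seed = as.integer(seed))
  stopifnot(all(unlist(cfg[c("L", "conv1_filters", "conv1_width",
                             "pool_width", "lstm_units", "conv2_filters",
                             "conv2_width")]) > 0),
            length(cfg$dense_units) == 2L, all(cfg$dense_units > 0),
            cfg$dropout >= 0, cfg$dropout < 1)
  if (cfg$conv1_width > cfg$L) {
    stop("conv1_width (", cfg$conv1_width, ") exceeds input length L (",
         cfg$L, ")")
  }
  cfg$P1 <- cfg$L - cfg$conv1_width + 1L
  cfg$T <- cfg$P1 %/% cfg$pool_width
  if (cfg$T < cfg$conv2_width) {
    stop("conv2_width (", cfg$conv2_width, ") exceeds pooled sequence ",
         "length (", cfg$T, ")")
  }
  cfg$P2 <- cfg$T - cfg$conv2_width + 1L
  structure(cfg, class = "dismir_model_config")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build an untrained per-read classifier
#'
#' Parameters are initialized reproducibly from `cfg$seed`.
#'
#' @param cfg A [dismir_model_config].
#' @return A `dismir_model` list (`params`, `cfg`, empty training log).
#' @export
build_dismir_model <- function(cfg = dismir_model_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  H <- cfg$lstm_units
  F1 <- cfg$conv1_filters; F2 <- cfg$conv2_filters
  w1 <- cfg$conv1_width; w2 <- cfg$conv2_width
  flat <- cfg$P2 * F2
  d <- cfg$dense_units
  lstm_dir <- function() list(
    Wx = glorot(F1, 4L * H), Wh = glorot(H, 4L * H),
    # forget-gate bias starts at 1 (standard LSTM practice)
    b = c(rep(0, H), rep(1, H), rep(0, 2L * H))
  )
  fw <- lstm_dir(); bw <- lstm_dir()
  params <- list(
    W1 = array(glorot(w1 * 5L, F1), c(w1, 5L, F1)), b1 = rep(0, F1),
    fWx = fw$Wx, fWh = fw$Wh, fb = fw$b,
    bWx = bw$Wx, bWh = bw$Wh, bb = bw$b,
    W2 = array(glorot(w2 * 2L * H, F2), c(w2, 2L * H, F2)), b2 = rep(0, F2),
    Wd1 = glorot(flat, d[1L]), bd1 = rep(0, d[1L]),
    Wd2 = glorot(d[1L], d[2L]), bd2 = rep(0, d[2L]),
    Wd3 = glorot(d[2L], 1L), bd3 = 0
  )
  structure(list(params = params, cfg = cfg, log = NULL),
            class = "dismir_model")
}

conv1d_fwd <- function(X, W, b) {
  dims <- dim(X); B <- dims[1L]; Lin <- dims[2L]; Cin <- dims[3L]
  w <- dim(W)[1L]; Cout <- dim(W)[3L]
  P <- Lin - w + 1L
  Z <- matrix(0, B * P, Cout)
  for (k in seq_len(w)) {
    Xk <- matrix(X[, k:(k + P - 1L), , drop = FALSE], B * P, Cin)
    Z <- Z + Xk %*% matrix(W[k, , ], Cin, Cout)
  }
  Z <- sweep(Z, 2L, b, "+")
  array(Z, c(B, P, Cout))
}

conv1d_bwd <- function(X, W, dZ) {
  dims <- dim(X); B <- dims[1L]; Cin <- dims[3L]
  w <- dim(W)[1L]; Cout <- dim(W)[3L]
  P <- dim(dZ)[2L]
  dZm <- matrix(dZ, B * P, Cout)
  dW <- array(0, dim(W)); dX <- array(0, dims)
  for (k in seq_len(w)) {
    Xk <- matrix(X[, k:(k + P - 1L), , drop = FALSE], B * P, Cin)
    dW[k, , ] <- crossprod(Xk, dZm)
    dXk <- array(tcrossprod(dZm, matrix(W[k, , ], Cin, Cout)), c(B, P, Cin))
    dX[, k:(k + P - 1L), ] <- dX[, k:(k + P - 1L), , drop = FALSE] + dXk
  }
  list(dX = dX, dW = dW, db = colSums(dZm))
}

lstm_fwd <- function(S, Wx, Wh, b, reverse = FALSE) {
  dims <- dim(S); B <- dims[1L]; Tn <- dims[2L]; Cin <- dims[3L]
  H <- ncol(Wh) %/% 4L  # Wh is H x 4H
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  Hseq <- array(0, c(B, Tn, H)); Cseq <- array(0, c(B, Tn, H))
  G <- array(0, c(B, Tn, 4L * H)); TanhC <- array(0, c(B, Tn, H))
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (t in steps) {
    xt <- matrix(S[, t, , drop = FALSE], B, Cin)
    A <- xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, "+")
    gi <- stats::plogis(A[, i1, drop = FALSE])
    gf <- stats::plogis(A[, i2, drop = FALSE])
    gg <- tanh(A[, i3, drop = FALSE])
    go <- stats::plogis(A[, i4, drop = FALSE])
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    G[, t, ] <- cbind(gi, gf, gg, go)
    Cseq[, t, ] <- cc; TanhC[, t, ] <- tc; Hseq[, t, ] <- h
  }
  list(Hseq = Hseq, cache = list(G = G, Cseq = Cseq, TanhC = TanhC,
                                 steps = steps, S = S))
}

lstm_bwd <- function(dH, fwd, Wx, Wh) {
  cache <- fwd$cache
  S <- cache$S; steps <- cache$steps
  dims <- dim(S); B <- dims[1L]; Cin <- dims[3L]
  H <- dim(fwd$Hseq)[3L]
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  dWx <- matrix(0, Cin, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- rep(0, 4L * H); dS <- array(0, dims)
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  npos <- length(steps)
  for (pos in rev(seq_len(npos))) {
    t <- steps[pos]
    gi <- matrix(cache$G[, t, i1], B, H); gf <- matrix(cache$G[, t, i2], B, H)
    gg <- matrix(cache$G[, t, i3], B, H); go <- matrix(cache$G[, t, i4], B, H)
    tc <- matrix(cache$TanhC[, t, ], B, H)
    c_prev <- if (pos > 1L) matrix(cache$Cseq[, steps[pos - 1L], ], B, H)
              else matrix(0, B, H)
    h_prev <- if (pos > 1L) matrix(fwd$Hseq[, steps[pos - 1L], ], B, H)
              else matrix(0, B, H)
    dh <- matrix(dH[, t, ], B, H) + dh_carry
    dgo <- dh * tc
    dct <- dh * go * (1 - tc^2) + dc_carry
    dgi <- dct * gg; dgg <- dct * gi; dgf <- dct * c_prev
    dc_carry <- dct * gf
    dA <- cbind(dgi * gi * (1 - gi), dgf * gf * (1 - gf),
                dgg * (1 - gg^2), dgo * go * (1 - go))
    xt <- matrix(S[, t, , drop = FALSE], B, Cin)
    dWx <- dWx + crossprod(xt, dA)
    dWh <- dWh + crossprod(h_prev, dA)
    db <- db + colSums(dA)
    dS[, t, ] <- tcrossprod(dA, Wx)
    dh_carry <- tcrossprod(dA, Wh)
  }
  list(dS = dS, dWx = dWx, dWh = dWh, db = db)
}

# Full forward pass. When train = TRUE, dropout masks are sampled from
# the current RNG stream and kept in the cache for the backward pass.
nn_forward <- function(params, cfg, X, train = FALSE) {
  B <- dim(X)[1L]
  pw <- cfg$pool_width; Tn <- cfg$T
  Z1 <- conv1d_fwd(X, params$W1, params$b1)
  A1 <- pmax(Z1, 0)
  # max-pool width pw, stride pw (trailing remainder dropped)
  pooled <- A1[, seq.int(1L, by = pw, length.out = Tn), , drop = FALSE]
  argj <- array(1L, dim(pooled))
  if (pw > 1L) for (j in 2:pw) {
    cand <- A1[, seq.int(j, by = pw, length.out = Tn), , drop = FALSE]
    upd <- cand > pooled
    pooled[upd] <- cand[upd]; argj[upd] <- j
  }
  drop1 <- NULL
  if (train && cfg$dropout > 0) {
    drop1 <- array(stats::rbinom(length(pooled), 1L, 1 - cfg$dropout) /
                     (1 - cfg$dropout), dim(pooled))
    pooled <- pooled * drop1
  }
  fw <- lstm_fwd(pooled, params$fWx, params$fWh, params$fb, reverse = FALSE)
  bw <- lstm_fwd(pooled, params$bWx, params$bWh, params$bb, reverse = TRUE)
  H <- cfg$lstm_units
  O <- array(0, c(B, Tn, 2L * H))
  O[, , seq_len(H)] <- fw$Hseq
  O[, , H + seq_len(H)] <- bw$Hseq
  drop2 <- NULL
  if (train && cfg$dropout > 0) {
    drop2 <- array(stats::rbinom(length(O), 1L, 1 - cfg$dropout) /
                     (1 - cfg$dropout), dim(O))
    O <- O * drop2
  }
  Z2 <- conv1d_fwd(O, params$W2, params$b2)
  A2 <- pmax(Z2, 0)
  Fl <- matrix(A2, B, cfg$P2 * cfg$conv2_filters)
  Zd1 <- sweep(Fl %*% params$Wd1, 2L, params$bd1, "+"); Ad1 <- pmax(Zd1, 0)
  Zd2 <- sweep(Ad1 %*% params$Wd2, 2L, params$bd2, "+"); Ad2 <- pmax(Zd2, 0)
  logit <- Ad2 %*% params$Wd3 + params$bd3
  p <- stats::plogis(as.vector(logit))
  list(p = p,
       cache = list(X = X, Z1 = Z1, argj = argj, pooled = pooled,
                    drop1 = drop1, fw = fw, bw = bw, O = O, drop2 = drop2,
                    Z2 = Z2, A2 = A2, Fl = Fl, Ad1 = Ad1, Zd1 = Zd1,
                    Ad2 = Ad2, Zd2 = Zd2))
}

# Backward pass for sigmoid output + binary cross-entropy (mean over the
# batch). Returns gradients named like the parameters.
nn_backward <- function(params, cfg, fwdres, y) {
  cache <- fwdres$cache
  B <- length(y)
  pw <- cfg$pool_width; Tn <- cfg$T; H <- cfg$lstm_units
  dlogit <- matrix((fwdres$p - y) / B, B, 1L)
  g <- list()
  g$Wd3 <- crossprod(cache$Ad2, dlogit); g$bd3 <- sum(dlogit)
  dAd2 <- tcrossprod(dlogit, params$Wd3) * (cache$Zd2 > 0)
  g$Wd2 <- crossprod(cache$Ad1, dAd2); g$bd2 <- colSums(dAd2)
  dAd1 <- tcrossprod(dAd2, params$Wd2) * (cache$Zd1 > 0)
  g$Wd1 <- crossprod(cache$Fl, dAd1); g$bd1 <- colSums(dAd1)
  dFl <- tcrossprod(dAd1, params$Wd1)
  dA2 <- array(dFl, c(B, cfg$P2, cfg$conv2_filters)) * (cache$Z2 > 0)
  cb2 <- conv1d_bwd(cache$O, params$W2, dA2)
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dO <- cb2$dX
  if (!is.null(cache$drop2)) dO <- dO * cache$drop2
  lf <- lstm_bwd(dO[, , seq_len(H), drop = FALSE], cache$fw,
                 params$fWx, params$fWh)
  lb <- lstm_bwd(dO[, , H + seq_len(H), drop = FALSE], cache$bw,
                 params$bWx, params$bWh)
  g$fWx <- lf$dWx; g$fWh <- lf$dWh; g$fb <- lf$db
  g$bWx <- lb$dWx; g$bWh <- lb$dWh; g$bb <- lb$db
  dpooled <- lf$dS + lb$dS
  if (!is.null(cache$drop1)) dpooled <- dpooled * cache$drop1
  dA1 <- array(0, dim(cache$Z1))
  for (j in seq_len(pw)) {
    sel <- array(0, dim(dpooled))
    m <- cache$argj == j
    sel[m] <- dpooled[m]
    idx <- seq.int(j, by = pw, length.out = Tn)
    dA1[, idx, ] <- dA1[, idx, , drop = FALSE] + sel
  }
  dZ1 <- dA1 * (cache$Z1 > 0)
  cb1 <- conv1d_bwd(cache$X, params$W1, dZ1)
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  g
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One loss + gradient evaluation (used by training and by the
# numerical gradient-check tests).
nn_loss_grad <- function(params, cfg, X, y, train = FALSE) {
  fwd <- nn_forward(params, cfg, X, train = train)
  list(loss = bce_loss(fwd$p, y), grads = nn_backward(params, cfg, fwd, y),
       p = fwd$p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the per-read classifier
#'
#' Minimizes binary cross-entropy with Adam on minibatches. A fraction
#' of the training pool is held out for early stopping. Reproducible
#' from `model$cfg$seed`.
#'
#' @param model A [build_dismir_model] result.
#' @param encoded An `encoded_reads` training set with 0/1 labels
#'   (see [balance_and_split]).
#' @return The model with trained parameters and a `log` data.frame of
#'   per-epoch training and validation loss.
#' @export
train_dismir <- function(model, encoded) {
  cfg <- model$cfg
  y <- encoded$info$label
  if (length(y) == 0L) stop("empty training set")
  if (anyNA(y)) stop("training reads must all be labeled 0/1")
  X <- encoded$x
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1000L)
  n <- length(y)
  n_val <- floor(cfg$validation_fraction * n)
  val_idx <- if (n_val >= 2L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- model$params
  state <- adam_init(params)
  best <- list(params = params, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    losses <- numeric(0)
    for (bstart in seq.int(1L, length(ord), by = cfg$batch_size)) {
      bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, length(ord))]
      lg <- nn_loss_grad(params, cfg, X[bidx, , , drop = FALSE], y[bidx],
                         train = TRUE)
      upd <- adam_step(params, lg$grads, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
      losses <- c(losses, lg$loss)
    }
    val_loss <- if (length(val_idx)) {
      bce_loss(nn_predict(params, cfg, X[val_idx, , , drop = FALSE]),
               y[val_idx])
    } else mean(losses)
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = val_loss))
    if (val_loss < best$val - 1e-5) {
      best <- list(params = params, val = val_loss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- if (length(val_idx)) best$params else params
  model$log <- log
  model
}

nn_predict <- function(params, cfg, X, batch = 1024L) {
  n <- dim(X)[1L]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (bstart in seq.int(1L, n, by = batch)) {
    idx <- bstart:min(bstart + batch - 1L, n)
    out[idx] <- nn_forward(params, cfg, X[idx, , , drop = FALSE])$p
  }
  out
}

#' Compute d-scores for encoded reads
#'
#' @param model A trained `dismir_model`.
#' @param encoded An `encoded_reads` object whose matrices match the
#'   model's input length.
#' @return Numeric vector of d-scores in `[0, 1]`, in read order.
#' @export
predict_dscore <- function(model, encoded) {
  if (dim(encoded$x)[2L] != model$cfg$L) {
    stop("encoded read length ", dim(encoded$x)[2L],
         " does not match model input length ", model$cfg$L)
  }
  nn_predict(model$params, model$cfg, encoded$x)
}

#' Train an ensemble of classifiers
#'
#' Trains `n_members` models on the same data with seeds
#' `cfg$seed + 0 .. n_members - 1`; the final d-score of a read is the
#' average over members, which removes the randomness of individual
#' trainings. The conventional ensemble size is 10.
#'
#' @param encoded Training `encoded_reads` with labels.
#' @param cfg A [dismir_model_config]; its seed anchors the member seeds.
#' @param n_members Ensemble size. Default 10.
#' @return A `dismir_ensemble` list of trained models.
#' @export
train_dismir_ensemble <- function(encoded, cfg = dismir_model_config(),
                                  n_members = 10L) {
  stopifnot(n_members >= 1L)
  members <- lapply(seq_len(n_members) - 1L, function(k) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k
    train_dismir(build_dismir_model(cfg_k), encoded)
  })
  structure(list(members = members, cfg = cfg), class = "dismir_ensemble")
}

#' Ensemble-averaged d-scores
#'
#' Arithmetic mean of the member d-scores per read.
#'
#' @param ensemble A `dismir_ensemble` (or a single `dismir_model`).
#' @param encoded An `encoded_reads` object.
#' @return Numeric vector of averaged d-scores.
#' @export
ensemble_dscore <- function(ensemble, encoded) {
  if (inherits(ensemble, "dismir_model")) {
    return(predict_dscore(ensemble, encoded))
  }
  stopifnot(inherits(ensemble, "dismir_ensemble"),
            length(ensemble$members) >= 1L)
  scores <- vapply(ensemble$members, predict_dscore,
                   numeric(dim(encoded$x)[1L]), encoded = encoded)
  if (is.null(dim(scores))) return(mean(scores))
  rowMeans(scores)
}

#' Save / load a trained ensemble
#'
#' One file per member plus a JSON manifest recording the member count,
#' configuration and seeds.
#'
#' @param ensemble A `dismir_ensemble`.
#' @param dir Output directory (created if absent).
#' @export
save_dismir_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[i]], file.path(dir, sprintf("member_%02d.rds", i)))
  }
  manifest <- list(n_members = length(ensemble$members),
                   seeds = vapply(ensemble$members,
                                  function(m) m$cfg$seed, integer(1)),
                   cfg = unclass(ensemble$cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_dismir_ensemble
#' @export
load_dismir_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- sprintf("member_%02d.rds", seq_len(manifest$n_members))
  members <- lapply(file.path(dir, files), readRDS)
  cfg <- members[[1L]]$cfg; cfg$seed <- manifest$cfg$seed
  structure(list(members = members, cfg = cfg), class = "dismir_ensemble")
}
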