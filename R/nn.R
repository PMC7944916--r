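# Minimal recurrent/dense neural engine (batch-vectorized, pure R).
#
# Implements exactly what the generator and QSAR modules need: stacked
# LSTM/GRU layers over token sequences (optionally through a learned
# embedding), a linear output head, inter-layer dropout, Adam with
# elementwise gradient clipping, and hand-derived backpropagation through
# time. Gradients are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

.mat_init <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

.addb <- function(z, b) z + matrix(b, nrow(z), ncol(z), byrow = TRUE)

# Create a recurrent network. input_dim is the vocabulary size; when
# embedding_dim is NULL tokens enter as one-hot vectors.
rnn_new <- function(input_dim, layers = 2L, units = 64L,
                    cell = c("lstm", "gru"), out_dim,
                    embedding_dim = NULL, dense_units = NULL, seed = 1L) {
  cell <- match.arg(cell)
  with_local_seed(seed, {
    p <- list()
    d <- if (!is.null(embedding_dim)) {
      p$E <- .mat_init(input_dim, embedding_dim)
      embedding_dim
    } else input_dim
    G <- if (cell == "lstm") 4L else 3L
    p$layers <- vector("list", layers)
    for (l in seq_len(layers)) {
      p$layers[[l]] <- list(Wx = .mat_init(d, G * units),
                            Wh = .mat_init(units, G * units),
                            b  = matrix(0, 1, G * units))
      if (cell == "lstm")  # forget-gate bias starts open
        p$layers[[l]]$b[1, (units + 1):(2 * units)] <- 1
      d <- units
    }
    head_in <- units
    if (!is.null(dense_units)) {
      p$Wd <- .mat_init(units, dense_units)
      p$bd <- matrix(0, 1, dense_units)
      head_in <- dense_units
    }
    p$Wy <- .mat_init(head_in, out_dim)
    p$by <- matrix(0, 1, out_dim)
    structure(list(params = p, cell = cell, n_layers = layers, units = units,
                   input_dim = input_dim, out_dim = out_dim,
                   dense = !is.null(dense_units),
                   embedding = !is.null(embedding_dim)),
              class = "dmg_rnn")
  })
}

.onehot_rows <- function(idx, dim) {
  m <- matrix(0, length(idx), dim)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# One cell step. Returns new h (and c for LSTM) plus the cache needed by the
# backward pass.
.cell_step <- function(cell, lp, x, h, c, units) {
  H <- units
  if (cell == "lstm") {
    z <- .addb(x %*% lp$Wx + h %*% lp$Wh, lp$b)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cn <- f * c + i * g
    tc <- tanh(cn)
    hn <- o * tc
    list(h = hn, c = cn,
         cache = list(x = x, hprev = h, cprev = c, i = i, f = f, o = o,
                      g = g, tc = tc))
  } else {
    zr <- .addb(x %*% lp$Wx[, 1:(2 * H), drop = FALSE] +
                h %*% lp$Wh[, 1:(2 * H), drop = FALSE],
                lp$b[, 1:(2 * H), drop = FALSE])
    zt <- sigmoid(zr[, 1:H, drop = FALSE])
    r  <- sigmoid(zr[, (H + 1):(2 * H), drop = FALSE])
    rh <- r * h
    nn <- tanh(.addb(x %*% lp$Wx[, (2 * H + 1):(3 * H), drop = FALSE] +
                     rh %*% lp$Wh[, (2 * H + 1):(3 * H), drop = FALSE],
                     lp$b[, (2 * H + 1):(3 * H), drop = FALSE]))
    hn <- (1 - zt) * nn + zt * h
    list(h = hn, c = c,
         cache = list(x = x, hprev = h, z = zt, r = r, n = nn, rh = rh))
  }
}

# Backward through one cell step. dh: gradient on h output; dc: on c output
# (LSTM). Returns gradients on parameters (to accumulate), on x, and on the
# previous h / c.
.cell_back <- function(cell, lp, cache, dh, dc, units) {
  H <- units
  if (cell == "lstm") {
    do_ <- dh * cache$tc
    dcn <- dc + dh * cache$o * (1 - cache$tc^2)
    di <- dcn * cache$g
    df <- dcn * cache$cprev
    dg <- dcn * cache$i
    dcprev <- dcn * cache$f
    dz <- cbind(di * cache$i * (1 - cache$i),
                df * cache$f * (1 - cache$f),
                do_ * cache$o * (1 - cache$o),
                dg * (1 - cache$g^2))
    list(dWx = crossprod(cache$x, dz), dWh = crossprod(cache$hprev, dz),
         db = colSums(dz), dx = dz %*% t(lp$Wx),
         dhprev = dz %*% t(lp$Wh), dcprev = dcprev)
  } else {
    dn <- dh * (1 - cache$z)
    dz <- dh * (cache$hprev - cache$n)
    dhprev <- dh * cache$z
    dan <- dn * (1 - cache$n^2)
    Whn <- lp$Wh[, (2 * H + 1):(3 * H), drop = FALSE]
    Wxn <- lp$Wx[, (2 * H + 1):(3 * H), drop = FALSE]
    drh <- dan %*% t(Whn)
    dr <- drh * cache$hprev
    dhprev <- dhprev + drh * cache$r
    daz <- dz * cache$z * (1 - cache$z)
    dar <- dr * cache$r * (1 - cache$r)
    dzr <- cbind(daz, dar)
    Wxzr <- lp$Wx[, 1:(2 * H), drop = FALSE]
    Whzr <- lp$Wh[, 1:(2 * H), drop = FALSE]
    dWx <- cbind(crossprod(cache$x, dzr), crossprod(cache$x, dan))
    dWh <- cbind(crossprod(cache$hprev, dzr), crossprod(cache$rh, dan))
    db <- c(colSums(dzr), colSums(dan))
    dx <- dzr %*% t(Wxzr) + dan %*% t(Wxn)
    dhprev <- dhprev + dzr %*% t(Whzr)
    list(dWx = dWx, dWh = dWh, db = db, dx = dx, dhprev = dhprev,
         dcprev = NULL)
  }
}

# Full teacher-forced forward pass over an integer token matrix X (batch x T).
# Returns per-step logits and, when train = TRUE, the caches for backward.
rnn_forward <- function(net, X, dropout = 0, train = FALSE) {
  p <- net$params
  B <- nrow(X); Tn <- ncol(X); H <- net$units; L <- net$n_layers
  h <- replicate(L, matrix(0, B, H), simplify = FALSE)
  c <- replicate(L, matrix(0, B, H), simplify = FALSE)
  logits <- vector("list", Tn)
  caches <- if (train) vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- if (net$embedding) p$E[X[, t], , drop = FALSE]
         else .onehot_rows(X[, t], net$input_dim)
    step_cache <- if (train) vector("list", L)
    for (l in seq_len(L)) {
      st <- .cell_step(net$cell, p$layers[[l]], x, h[[l]], c[[l]], H)
      h[[l]] <- st$h; c[[l]] <- st$c
      out <- st$h
      mask <- NULL
      if (train && dropout > 0 && l < L) {
        mask <- matrix(stats::rbinom(B * H, 1, 1 - dropout) / (1 - dropout), B, H)
        out <- out * mask
      }
      if (train) { st$cache$mask <- mask; step_cache[[l]] <- st$cache }
      x <- out
    }
    a <- x
    if (isTRUE(net$dense)) a <- pmax(.addb(x %*% p$Wd, p$bd), 0)
    logits[[t]] <- .addb(a %*% p$Wy, p$by)
    if (train) caches[[t]] <- list(layers = step_cache, h_top = x, a_dense = a)
  }
  list(logits = logits, caches = if (train) caches, h = h, c = c)
}

.zero_like_params <- function(p) {
  z <- list()
  if (!is.null(p$E)) z$E <- p$E * 0
  z$layers <- lapply(p$layers, function(lp)
    list(Wx = lp$Wx * 0, Wh = lp$Wh * 0, b = lp$b * 0))
  if (!is.null(p$Wd)) { z$Wd <- p$Wd * 0; z$bd <- p$bd * 0 }
  z$Wy <- p$Wy * 0; z$by <- p$by * 0
  z
}

# Backpropagation through time. dlogits: list (length T) of batch x out_dim
# gradients of the scalar loss with respect to each step's logits.
rnn_backward <- function(net, X, fwd, dlogits) {
  p <- net$params
  B <- nrow(X); Tn <- ncol(X); H <- net$units; L <- net$n_layers
  g <- .zero_like_params(p)
  dh_next <- replicate(L, matrix(0, B, H), simplify = FALSE)
  dc_next <- replicate(L, matrix(0, B, H), simplify = FALSE)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$caches[[t]]
    dl <- dlogits[[t]]
    dtop <- if (is.null(dl)) matrix(0, B, H) else if (isTRUE(net$dense)) {
      g$Wy <- g$Wy + crossprod(cc$a_dense, dl)
      g$by <- g$by + colSums(dl)
      da <- (dl %*% t(p$Wy)) * (cc$a_dense > 0)
      g$Wd <- g$Wd + crossprod(cc$h_top, da)
      g$bd <- g$bd + colSums(da)
      da %*% t(p$Wd)
    } else {
      g$Wy <- g$Wy + crossprod(cc$h_top, dl)
      g$by <- g$by + colSums(dl)
      dl %*% t(p$Wy)
    }
    for (l in rev(seq_len(L))) {
      lc <- cc$layers[[l]]
      up <- if (!is.null(lc$mask)) dtop * lc$mask else dtop
      dh <- dh_next[[l]] + up
      bk <- .cell_back(net$cell, p$layers[[l]], lc, dh, dc_next[[l]], H)
      g$layers[[l]]$Wx <- g$layers[[l]]$Wx + bk$dWx
      g$layers[[l]]$Wh <- g$layers[[l]]$Wh + bk$dWh
      g$layers[[l]]$b  <- g$layers[[l]]$b + bk$db
      dh_next[[l]] <- bk$dhprev
      if (net$cell == "lstm") dc_next[[l]] <- bk$dcprev
      dtop <- bk$dx
    }
    if (net$embedding) {
      agg <- rowsum(dtop, group = X[, t])
      rows <- as.integer(rownames(agg))
      g$E[rows, ] <- g$E[rows, , drop = FALSE] + agg
    }
  }
  g
}

# Incremental single-step API for autoregressive sampling (no caches).
rnn_state0 <- function(net, batch) {
  list(h = replicate(net$n_layers, matrix(0, batch, net$units), simplify = FALSE),
       c = replicate(net$n_layers, matrix(0, batch, net$units), simplify = FALSE))
}

rnn_step <- function(net, state, x_idx) {
  p <- net$params
  x <- if (net$embedding) p$E[x_idx, , drop = FALSE]
       else .onehot_rows(x_idx, net$input_dim)
  for (l in seq_len(net$n_layers)) {
    st <- .cell_step(net$cell, p$layers[[l]], x, state$h[[l]], state$c[[l]],
                     net$units)
    state$h[[l]] <- st$h; state$c[[l]] <- st$c
    x <- st$h
  }
  if (isTRUE(net$dense)) x <- pmax(.addb(x %*% p$Wd, p$bd), 0)
  list(logits = .addb(x %*% p$Wy, p$by), state = state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---------------------------------------------------------------------------
# Adam with elementwise gradient clipping, over arbitrarily nested parameter
# lists whose leaves are numeric matrices/vectors.

.walk2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- .walk2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

adam_new <- function(params) {
  zero <- function(p) if (is.list(p)) lapply(p, zero) else p * 0
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, clip = 3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  grads <- .walk2(grads, grads, function(g, .) pmin(pmax(g, -clip), clip))
  opt$m <- .walk2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- .walk2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  upd <- .walk2(opt$m, opt$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- .walk2(params, upd, function(p, u) p - u)
  list(params = params, opt = opt)
}

# ---------------------------------------------------------------------------
# Dense (fully connected) regression network for fingerprint inputs.

mlp_new <- function(input_dim, hidden, seed = 1L) {
  with_local_seed(seed, {
    dims <- c(input_dim, hidden, 1L)
    layers <- lapply(seq_len(length(dims) - 1L), function(k)
      list(W = .mat_init(dims[k], dims[k + 1]), b = matrix(0, 1, dims[k + 1])))
    structure(list(layers = layers, n_hidden = length(hidden)), class = "dmg_mlp")
  })
}

mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  acts <- list(X)
  masks <- vector("list", net$n_hidden)
  a <- X
  for (k in seq_along(net$layers)) {
    z <- .addb(a %*% net$layers[[k]]$W, net$layers[[k]]$b)
    if (k <= net$n_hidden) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        masks[[k]] <- matrix(stats::rbinom(length(a), 1, 1 - dropout) / (1 - dropout),
                             nrow(a), ncol(a))
        a <- a * masks[[k]]
      }
      acts[[k + 1]] <- a
    } else a <- z
  }
  list(pred = a, acts = acts, masks = masks)
}

mlp_backward <- function(net, fwd, dpred) {
  grads <- lapply(net$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  da <- dpred
  for (k in rev(seq_along(net$layers))) {
    a_in <- fwd$acts[[k]]
    grads[[k]]$W <- crossprod(a_in, da)
    grads[[k]]$b <- colSums(da)
    if (k > 1) {
      da <- da %*% t(net$layers[[k]]$W)
      if (!is.null(fwd$masks[[k - 1]])) da <- da * fwd$masks[[k - 1]]
      da <- da * (fwd$acts[[k]] > 0)   # relu mask of layer k-1 output
    }
  }
  grads
}
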