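# Minimal feed-forward engine: dense and 1-D convolution layers with manual
# backpropagation and Adam. Sized for the integration network (inputs of
# ~50 PCs, minibatches of tens of pairs), where plain matrix algebra is fast
# enough and keeps the computation fully deterministic and inspectable.
#
# A valid 1-D convolution over the PC axis is a linear map with tied
# weights; it is materialized as a structured (L*cin) x (P*cout) matrix
# rebuilt from the kernel each pass. Index layout is channel-major:
# input unit (channel ci, position pos) lives at column (ci-1)*L + pos.

act_fwd <- function(z, act) if (act == "relu") pmax(z, 0) else z

act_grad <- function(z, act) if (act == "relu") (z > 0) * 1 else 1

init_dense <- function(n_in, n_out, act) {
  sd <- sqrt((if (act == "relu") 2 else 1) / n_in)
  list(type = "dense", act = act,
       W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = numeric(n_out))
}

init_conv <- function(L, cin, cout, k, act) {
  if (L < k) stop("conv input length ", L, " shorter than kernel ", k)
  P <- L - k + 1L
  fan_in <- k * cin
  grid <- expand.grid(p = seq_len(P), j = seq_len(k),
                      ci = seq_len(cin), co = seq_len(cout))
  row <- (grid$ci - 1L) * L + grid$p + grid$j - 1L
  col <- (grid$co - 1L) * P + grid$p
  list(type = "conv", act = act, L = L, k = k, cin = cin, cout = cout, P = P,
       Wk = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                   fan_in, cout),
       b = numeric(cout),
       big_pos = row + (col - 1L) * (L * cin),
       w_idx = (grid$ci - 1L) * k + grid$j + (grid$co - 1L) * (k * cin))
}

conv_big <- function(ly) {
  Wbig <- matrix(0, ly$L * ly$cin, ly$P * ly$cout)
  Wbig[ly$big_pos] <- ly$Wk[ly$w_idx]
  Wbig
}

layer_forward <- function(ly, x) {
  if (ly$type == "dense") {
    z <- x %*% ly$W
    z <- sweep(z, 2, ly$b, `+`)
  } else {
    z <- x %*% conv_big(ly)
    z <- sweep(z, 2, rep(ly$b, each = ly$P), `+`)
  }
  list(out = act_fwd(z, ly$act), cache = list(x = x, z = z))
}

layer_backward <- function(ly, cache, dout) {
  dz <- dout * act_grad(cache$z, ly$act)
  if (ly$type == "dense") {
    list(dx = dz %*% t(ly$W),
         grad = list(W = crossprod(cache$x, dz), b = colSums(dz)))
  } else {
    Wbig <- conv_big(ly)
    dWbig <- crossprod(cache$x, dz)
    dWk <- matrix(rowsum(dWbig[ly$big_pos], ly$w_idx),
                  ly$k * ly$cin, ly$cout)
    db <- colSums(matrix(colSums(dz), ly$P, ly$cout))
    list(dx = dz %*% t(Wbig), grad = list(W = dWk, b = db))
  }
}

# spec: list of layer descriptors, each
#   list(type = "dense", n_out =, act =) or
#   list(type = "conv",  cout =, k =, act =)
# n_in: flat input width; conv layers interpret the running width as
# (length x channels) with channels tracked across consecutive convs.
init_layers <- function(spec, n_in) {
  layers <- vector("list", length(spec))
  width <- n_in
  cin <- 1L
  L <- n_in
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    if (s$type == "conv") {
      layers[[i]] <- init_conv(L, cin, s$cout, s$k, s$act)
      L <- layers[[i]]$P
      cin <- s$cout
      width <- L * cin
    } else {
      layers[[i]] <- init_dense(width, s$n_out, s$act)
      width <- s$n_out
      L <- width
      cin <- 1L
    }
  }
  attr(layers, "n_out") <- width
  layers
}

nn_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dout)
    grads[[i]] <- bw$grad
    dout <- bw$dx
  }
  list(dx = dout, grads = grads)
}

grads_add <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), g1, g2)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    W <- if (ly$type == "dense") ly$W else ly$Wk
    list(mW = W * 0, vW = W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    dW <- lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    db <- lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    if (layers[[i]]$type == "dense") layers[[i]]$W <- layers[[i]]$W - dW
    else layers[[i]]$Wk <- layers[[i]]$Wk - dW
    layers[[i]]$b <- layers[[i]]$b - db
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
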