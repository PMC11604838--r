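# Two-branch fully connected network: each branch maps the d-dimensional
# target vector through d/2, d/4, d/8 (leaky-ReLU after the first two
# layers) to a fixed 2560-wide output of which the first t samples form one
# RF channel (real or imaginary), in uT. Training is single-case (batch size
# one), so every weight gradient is the rank-one outer product of the layer's
# output adjoint and input; the AdamW update consumes that product directly
# in compiled code without materialising it.

MLP_OUT_MAX <- 2560L

kaiming_sd <- function(fan_in, slope) sqrt(2 / ((1 + slope^2) * fan_in))

#' Build the pulse-design MLP
#'
#' Layer widths follow the halving scheme `d -> d/2 -> d/4 -> d/8 -> 2560`
#' (integer division), with leaky-ReLU activations after the first two
#' layers; the output is truncated to the first `t` samples, so pulses up to
#' 2560 samples can be designed. Two independent branches produce the real
#' and imaginary RF channels. Weights are Kaiming-normal initialised,
#' deterministically per seed.
#'
#' @param d input dimension (the flattened target profile), `>= 8`.
#' @param t designed pulse length, `1 <= t <= 2560`.
#' @param seed RNG seed for the initialisation.
#' @param slope leaky-ReLU negative slope.
#' @return an object of class `mlp_designer`.
#' @export
build_mlp <- function(d, t, seed = 1L, slope = 0.01) {
  if (t > MLP_OUT_MAX)
    stop(sprintf("pulse length t = %d exceeds the network output cap of %d samples",
                 t, MLP_OUT_MAX))
  if (t < 1L) stop("t must be >= 1")
  if (d < 8L) stop("d must be >= 8")
  dims <- c(d, d %/% 2L, d %/% 4L, d %/% 8L, MLP_OUT_MAX)
  set.seed(seed)
  branch <- function() {
    lapply(seq_len(4L), function(l) {
      W <- matrix(rnorm(dims[l + 1] * dims[l], sd = kaiming_sd(dims[l], slope)),
                  nrow = dims[l + 1], ncol = dims[l])
      list(W = W, b = numeric(dims[l + 1]))
    })
  }
  structure(list(d = d, t = as.integer(t), slope = slope, dims = dims,
                 real = branch(), imag = branch(), seed = seed),
            class = "mlp_designer")
}

#' Total parameter count of one branch
#' @param net an `mlp_designer`.
#' @export
mlp_branch_params <- function(net) {
  sum(vapply(net$real, function(l) length(l$W) + length(l$b), numeric(1)))
}

lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lrelu_grad <- function(z, slope) ifelse(z > 0, 1, slope)

# Forward pass of one branch; LoRA side-products (scaling/rank in `lora`)
# are added per layer when present. Returns output (length t) and the cache
# needed for backprop.
branch_forward <- function(layers, x, t, slope, lora = NULL) {
  xs <- vector("list", 4L)   # inputs to each layer
  zs <- vector("list", 4L)   # pre-activations
  ax <- vector("list", 4L)   # LoRA inner products A x
  h <- x
  for (l in 1:4) {
    xs[[l]] <- h
    if (l < 4L) {
      z <- as.vector(layers[[l]]$W %*% h) + layers[[l]]$b
    } else {
      z <- as.vector(layers[[l]]$W[seq_len(t), , drop = FALSE] %*% h) +
        layers[[l]]$b[seq_len(t)]
    }
    if (!is.null(lora)) {
      ax[[l]] <- as.vector(lora$layers[[l]]$A %*% h)
      add <- lora$scaling * as.vector(lora$layers[[l]]$B %*% ax[[l]])
      z <- z + if (l < 4L) add else add[seq_len(t)]
    }
    zs[[l]] <- z
    h <- if (l <= 2L) lrelu(z, slope) else z
  }
  list(out = h, xs = xs, zs = zs, ax = ax)
}

# Backward pass of one branch: returns per-layer output adjoints gy (padded
# to the full layer height for layer 4) and, when LoRA is active, the
# adjoint reaching x through both the dense and the side path.
branch_backward <- function(layers, cache, g_out, t, slope, lora = NULL) {
  gys <- vector("list", 4L)
  gy <- g_out
  for (l in 4:1) {
    if (l == 4L) {
      gy_full <- numeric(MLP_OUT_MAX)
      gy_full[seq_len(t)] <- gy
      gys[[l]] <- gy_full
      gx <- as.vector(crossprod(layers[[l]]$W[seq_len(t), , drop = FALSE], gy))
      if (!is.null(lora))
        gx <- gx + lora$scaling *
          as.vector(crossprod(lora$layers[[l]]$A,
                              crossprod(lora$layers[[l]]$B[seq_len(t), , drop = FALSE], gy)))
    } else {
      gys[[l]] <- gy
      gx <- as.vector(crossprod(layers[[l]]$W, gy))
      if (!is.null(lora))
        gx <- gx + lora$scaling *
          as.vector(crossprod(lora$layers[[l]]$A,
                              crossprod(lora$layers[[l]]$B, gy)))
    }
    if (l > 1L) {
      # activations sit after layers 1 and 2 only
      gy <- if (l - 1L <= 2L) gx * lrelu_grad(cache$zs[[l - 1L]], slope) else gx
    }
  }
  gys
}

#' Network forward pass to a complex pulse
#'
#' @param net an `mlp_designer`.
#' @param x input vector of length `net$d`.
#' @param lora optional `lora_adapter`.
#' @return list with `re`, `im` (length `t`) and the branch caches.
#' @keywords internal
mlp_forward <- function(net, x, lora = NULL) {
  if (length(x) != net$d)
    stop(sprintf("input dimension %d does not match network d = %d",
                 length(x), net$d))
  fr <- branch_forward(net$real, x, net$t, net$slope,
                       if (is.null(lora)) NULL else lora$real)
  fi <- branch_forward(net$imag, x, net$t, net$slope,
                       if (is.null(lora)) NULL else lora$imag)
  list(re = fr$out, im = fi$out, cache_re = fr, cache_im = fi)
}

# ---- AdamW ---------------------------------------------------------------

adamw_state <- function(net) {
  zero_like <- function(layers) lapply(layers, function(l)
    list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b))))
  list(real = zero_like(net$real), imag = zero_like(net$imag), step = 0L)
}

# One AdamW step on both branches; `gys_*` are the per-layer output adjoints
# from branch_backward, `cache_*` the forward caches. Mutates the weight and
# moment matrices in place (compiled kernel); decoupled weight decay.
adamw_step_net <- function(net, opt, gys_re, cache_re, gys_im, cache_im, cfg) {
  opt$step <- opt$step + 1L
  upd <- function(layers, state, gys, cache) {
    for (l in 1:4) {
      .adamw_dense_cpp(layers[[l]]$W, state[[l]]$mW, state[[l]]$vW,
                       gys[[l]], cache$xs[[l]],
                       cfg$lr, cfg$beta1, cfg$beta2, cfg$eps,
                       cfg$weight_decay, opt$step)
      .adamw_vec_cpp(layers[[l]]$b, state[[l]]$mb, state[[l]]$vb, gys[[l]],
                     cfg$lr, cfg$beta1, cfg$beta2, cfg$eps,
                     cfg$weight_decay, opt$step)
    }
  }
  upd(net$real, opt$real, gys_re, cache_re)
  upd(net$imag, opt$imag, gys_im, cache_im)
  opt
}

# ---- LoRA ----------------------------------------------------------------

#' Attach a low-rank adaptation side network
#'
#' Adds rank-`rank` factor pairs `(A, B)` to every fully connected layer of
#' both branches: the effective weight becomes `W + (1/rank) * B %*% A`. `B`
#' is zero-initialised, so at attachment the adapted network is exactly the
#' base network; during online adaptation only the factors are trained and
#' the base stays frozen.
#'
#' @param net an `mlp_designer`.
#' @param rank adapter rank.
#' @param seed RNG seed for the `A` factors.
#' @return a `lora_adapter`.
#' @export
attach_lora <- function(net, rank = 4L, seed = 1L) {
  set.seed(seed)
  side <- function(layers) {
    list(layers = lapply(layers, function(l) {
      list(A = matrix(rnorm(rank * ncol(l$W), sd = 1 / sqrt(ncol(l$W))),
                      nrow = rank),
           B = matrix(0, nrow(l$W), rank))
    }), scaling = 1 / rank)
  }
  structure(list(rank = as.integer(rank),
                 real = side(net$real), imag = side(net$imag)),
            class = "lora_adapter")
}

lora_opt_state <- function(lora) {
  zero <- function(side) lapply(side$layers, function(l)
    list(mA = matrix(0, nrow(l$A), ncol(l$A)), vA = matrix(0, nrow(l$A), ncol(l$A)),
         mB = matrix(0, nrow(l$B), ncol(l$B)), vB = matrix(0, nrow(l$B), ncol(l$B))))
  list(real = zero(lora$real), imag = zero(lora$imag), step = 0L)
}

# AdamW step on the LoRA factors only (base network untouched).
adamw_step_lora <- function(lora, opt, gys_re, cache_re, gys_im, cache_im, cfg) {
  opt$step <- opt$step + 1L
  upd <- function(side, state, gys, cache) {
    for (l in 1:4) {
      gy <- gys[[l]]
      gyB <- side$scaling * as.vector(crossprod(side$layers[[l]]$B, gy))
      .adamw_dense_cpp(side$layers[[l]]$A, state[[l]]$mA, state[[l]]$vA,
                       gyB, cache$xs[[l]],
                       cfg$lr, cfg$beta1, cfg$beta2, cfg$eps,
                       cfg$weight_decay, opt$step)
      .adamw_dense_cpp(side$layers[[l]]$B, state[[l]]$mB, state[[l]]$vB,
                       side$scaling * gy, cache$ax[[l]],
                       cfg$lr, cfg$beta1, cfg$beta2, cfg$eps,
                       cfg$weight_decay, opt$step)
    }
  }
  upd(lora$real, opt$real, gys_re, cache_re)
  upd(lora$imag, opt$imag, gys_im, cache_im)
  opt
}
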