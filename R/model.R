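#' Model configuration
#'
#' Hyperparameters of the multiview denoising model.  `alpha` and `beta`
#' weight the spatial and morphology consistency losses in the objective
#' \deqn{L = \|X - D(Z)\|^2 + \alpha \|A - A_s\|^2 + \beta \|A - A_m\|^2;}
#' with no morphology view `beta` is 0 and the morphology term is omitted
#' entirely.  `sigma_std` is the standard deviation of the Gaussian
#' perturbation added to the second encoder branch during training
#' (default 1, i.e. standard-normal noise).
#'
#' @param latent_dim latent width d (default 64).
#' @param hidden_dims integer vector of encoder hidden widths (default 256);
#'   the decoder mirrors them.
#' @param alpha spatial consistency weight, >= 0 (default 1).
#' @param beta morphology consistency weight, >= 0 (default 1).
#' @param sigma_std perturbation scale, >= 0 (default 1).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs full-batch epochs, >= 1 (default 500).
#' @param seed RNG seed controlling init and perturbation draws (default 0).
#' @param filter_order graph filter order t used upstream (default 2).
#' @param k_spatial,k_morph KNN neighbor counts for the two affinity graphs
#'   (defaults 6 and 10).
#' @return A `model_config` list.
#' @export
model_config <- function(latent_dim = 64, hidden_dims = 256, alpha = 1,
                         beta = 1, sigma_std = 1, lr = 1e-3, epochs = 500,
                         seed = 0, filter_order = 2, k_spatial = 6,
                         k_morph = 10) {
  if (alpha < 0 || beta < 0 || sigma_std < 0)
    stop("alpha, beta and sigma_std must be >= 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dims = as.integer(hidden_dims),
                 alpha = alpha, beta = beta, sigma_std = sigma_std,
                 lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
                 filter_order = as.integer(filter_order),
                 k_spatial = as.integer(k_spatial),
                 k_morph = as.integer(k_morph)),
            class = "model_config")
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}
elu_grad <- function(x) {
  g <- x
  neg <- x < 0
  g[!neg] <- 1
  g[neg] <- exp(x[neg])
  g
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# parameter list for one MLP: dims = c(in, hidden..., out)
init_mlp <- function(dims) {
  L <- length(dims) - 1
  par <- vector("list", 2 * L)
  for (l in seq_len(L)) {
    par[[2 * l - 1]] <- glorot(dims[l], dims[l + 1])
    par[[2 * l]] <- rep(0, dims[l + 1])
  }
  names(par) <- as.vector(rbind(paste0("W", seq_len(L)), paste0("b", seq_len(L))))
  par
}

# forward through an MLP with ELU on all but the last (linear) layer;
# caches pre-activations and hidden activations for backprop
mlp_forward <- function(X, par) {
  L <- length(par) / 2
  pre <- vector("list", L)
  act <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    A <- H %*% par[[2 * l - 1]]
    A <- A + rep(par[[2 * l]], each = nrow(A))
    pre[[l]] <- A
    H <- if (l < L) elu(A) else A
    act[[l]] <- H
  }
  list(out = H, pre = pre, act = act)
}

# backprop: dOut is the gradient at the (linear) output; returns gradients
# for every parameter plus the gradient at the input
mlp_backward <- function(X, par, fw, dOut) {
  L <- length(par) / 2
  grads <- vector("list", 2 * L)
  names(grads) <- names(par)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    Hprev <- if (l == 1) X else fw$act[[l - 1]]
    grads[[2 * l - 1]] <- crossprod(Hprev, dA)
    grads[[2 * l]] <- colSums(dA)
    if (l > 1) dA <- tcrossprod(dA, par[[2 * l - 1]]) * elu_grad(fw$pre[[l - 1]])
  }
  list(grads = grads, dX = tcrossprod(dA, par[["W1"]]))
}

#' Squared-Frobenius reconstruction loss
#'
#' `sum((X - X_hat)^2)`: the summed squared entrywise difference between the
#' filtered expression and its reconstruction.
#'
#' @param X,X_hat equal-shaped matrices (a `filtered_expression` is accepted
#'   for `X`).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_hat) {
  X <- as_values(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat)))
    stop("shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(X_hat), collapse = "x"))
  sum((X - X_hat)^2)
}

row_l2_normalize <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  list(Zh = Z / safe, nrm = nrm, safe = safe)
}

#' Transcription affinity matrix
#'
#' Row-L2-normalizes the two latent branches and returns
#' `A = Zh1 %*% t(Zh2)`, the matrix of cosine similarities between branch-1
#' and branch-2 spot features; entries are bounded in `[-1, 1]` and all-zero
#' rows map to zero rows.  This is the learned spot-similarity matrix that
#' the consistency losses pull toward the binary spatial/morphology
#' affinities.
#'
#' @param Z1,Z2 spots x d latent matrices, or a `latent_features` object as
#'   first argument.
#' @return spots x spots numeric matrix.
#' @export
transcription_affinity <- function(Z1, Z2 = NULL) {
  if (is.list(Z1) && is.null(Z2)) { Z2 <- Z1$Z2; Z1 <- Z1$Z1 }
  Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
  if (!all(dim(Z1) == dim(Z2))) stop("Z1 and Z2 must have the same shape")
  tcrossprod(row_l2_normalize(Z1)$Zh, row_l2_normalize(Z2)$Zh)
}

#' Affinity-consistency loss
#'
#' `alpha * ||A - A_s||^2 + beta * ||A - A_m||^2` (squared Frobenius).  When
#' `beta = 0` the morphology term is omitted exactly, so a run without a
#' morphology view is identical to a run with `beta = 0`.
#'
#' @param A spots x spots transcription affinity.
#' @param As spatial `affinity_graph` (or binary matrix).
#' @param Am optional morphology `affinity_graph`; required when `beta > 0`.
#' @param alpha,beta non-negative weights.
#' @return Non-negative scalar.
#' @export
consistency_loss <- function(A, As, Am = NULL, alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (beta > 0 && is.null(Am))
    stop("beta > 0 requires a morphology affinity graph")
  A <- as.matrix(A)
  As <- adjacency_dense(As)
  if (!all(dim(A) == dim(As))) stop("A and As must both be n x n")
  loss <- alpha * sum((A - As)^2)
  if (beta > 0) {
    Am <- adjacency_dense(Am)
    if (!all(dim(A) == dim(Am))) stop("A and Am must both be n x n")
    loss <- loss + beta * sum((A - Am)^2)
  }
  loss
}

# consistency loss and its gradients with respect to the *unnormalized*
# latent branches Z1, Z2 (backprop through row normalization and the
# bilinear product).  Row-chunked so the dense n x n affinity never exceeds
# `chunk` rows at a time.
consistency_terms <- function(Z1, Z2, As, Am = NULL, alpha = 1, beta = 0,
                              chunk = 4096L) {
  n <- nrow(Z1)
  n1 <- row_l2_normalize(Z1); n2 <- row_l2_normalize(Z2)
  Zh1 <- n1$Zh; Zh2 <- n2$Zh
  Asp <- if (inherits(As, "affinity_graph")) As$adjacency else As
  Amp <- if (!is.null(Am)) {
    if (inherits(Am, "affinity_graph")) Am$adjacency else Am
  } else NULL
  if (n <= chunk) {                 # densify once; chunks then subset cheaply
    if (!is.matrix(Asp)) Asp <- as.matrix(Asp)
    if (!is.null(Amp) && !is.matrix(Amp)) Amp <- as.matrix(Amp)
  }
  loss <- 0
  dZh1 <- matrix(0, n, ncol(Z1))
  dZh2 <- matrix(0, n, ncol(Z2))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    Ac <- tcrossprod(Zh1[rows, , drop = FALSE], Zh2)
    Rs <- Ac - as.matrix(Asp[rows, , drop = FALSE])
    loss <- loss + alpha * sum(Rs^2)
    G <- (2 * alpha) * Rs
    if (beta > 0) {
      Rm <- Ac - as.matrix(Amp[rows, , drop = FALSE])
      loss <- loss + beta * sum(Rm^2)
      G <- G + (2 * beta) * Rm
    }
    dZh1[rows, ] <- G %*% Zh2
    dZh2 <- dZh2 + crossprod(G, Zh1[rows, , drop = FALSE])
  }
  # through row normalization: d z = (d zh - (zh . d zh) zh) / ||z||
  unnorm <- function(dZh, nz) {
    proj <- rowSums(nz$Zh * dZh)
    out <- (dZh - nz$Zh * proj) / nz$safe
    out[nz$nrm == 0, ] <- 0
    out
  }
  list(loss = loss, dZ1 = unnorm(dZh1, n1), dZ2 = unnorm(dZh2, n2))
}

#' Analytic gradient of the consistency loss
#'
#' Gradients of [consistency_loss()] (including the row-L2 normalization
#' inside [transcription_affinity()]) with respect to the raw latent
#' branches.  Exposed for gradient checking.
#'
#' @inheritParams consistency_loss
#' @param Z1,Z2 spots x d latent matrices.
#' @return List with `loss`, `dZ1`, `dZ2`.
#' @export
consistency_grad <- function(Z1, Z2, As, Am = NULL, alpha = 1, beta = 0) {
  if (beta > 0 && is.null(Am))
    stop("beta > 0 requires a morphology affinity graph")
  consistency_terms(as.matrix(Z1), as.matrix(Z2), As, Am, alpha, beta)
}

model_params_init <- function(p, hidden, d) {
  list(enc1 = init_mlp(c(p, hidden, d)),
       enc2 = init_mlp(c(p, hidden, d)),
       dec = init_mlp(c(d, rev(hidden), p)))
}

adam_init <- function(params) {
  zero <- function(x) { x[] <- 0; x }
  rapply(params, zero, how = "replace")
}

#' Train the multiview denoising model
#'
#' Full-batch Adam on the objective
#' `||X - D(Z)||^2 + alpha ||A - A_s||^2 + beta ||A - A_m||^2`, where
#' `Z = (Z1 + Z2) / 2`, `Z1/Z2` come from two independent MLP encoders,
#' the second branch receives a fresh Gaussian perturbation
#' (sd `sigma_std`) every epoch, and `A` is the row-normalized bilinear
#' affinity of the two branches.  Deterministic given `config$seed`.  When
#' `Am` is `NULL`, `beta` is forced to 0 (histology-free objective).
#'
#' @param X filtered expression (`filtered_expression` or spots x p matrix).
#' @param As spatial `affinity_graph`.
#' @param Am optional morphology `affinity_graph`.
#' @param config a [model_config()].
#' @return A `trained_model` with fields `params`, `config`, `loss_history`
#'   (data.frame epoch/recon/consistency/total) and `input_dim`.
#' @export
train_multiview <- function(X, As, Am = NULL, config = model_config()) {
  X <- as_values(X)
  n <- nrow(X); p <- ncol(X)
  Asp <- if (inherits(As, "affinity_graph")) As$adjacency else As
  if (nrow(Asp) != n) stop("spatial graph has ", nrow(Asp), " spots, X has ", n)
  beta <- config$beta
  if (is.null(Am)) beta <- 0
  if (!is.null(Am) && beta > 0) {
    Amp <- if (inherits(Am, "affinity_graph")) Am$adjacency else Am
    if (nrow(Amp) != n) stop("morphology graph has ", nrow(Amp), " spots, X has ", n)
  }
  alpha <- config$alpha
  hidden <- config$hidden_dims
  d <- config$latent_dim
  # densify affinity targets once when they fit comfortably in memory
  As_use <- if (n <= 4096) as.matrix(Asp) else Asp
  Am_use <- if (beta > 0) {
    Amp <- if (inherits(Am, "affinity_graph")) Am$adjacency else Am
    if (n <= 4096) as.matrix(Amp) else Amp
  } else NULL

  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  params <- model_params_init(p, hidden, d)
  m <- adam_init(params); v <- adam_init(params)
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  hist <- data.frame(epoch = seq_len(config$epochs), recon = NA_real_,
                     consistency = NA_real_, total = NA_real_)

  for (ep in seq_len(config$epochs)) {
    noise <- if (config$sigma_std > 0)
      matrix(stats::rnorm(n * d, sd = config$sigma_std), n, d) else NULL

    f1 <- mlp_forward(X, params$enc1)
    f2 <- mlp_forward(X, params$enc2)
    Z1 <- f1$out
    Z2 <- f2$out + if (is.null(noise)) 0 else noise
    Z <- (Z1 + Z2) / 2
    fd <- mlp_forward(Z, params$dec)
    Xhat <- fd$out

    recon <- sum((X - Xhat)^2)
    use_cons <- alpha > 0 || beta > 0
    ct <- if (use_cons)
      consistency_terms(Z1, Z2, As_use, Am_use, alpha, beta)
    else list(loss = 0, dZ1 = 0, dZ2 = 0)
    total <- recon + ct$loss
    if (!is.finite(recon))
      stop("non-finite reconstruction loss at epoch ", ep)
    if (!is.finite(ct$loss))
      stop("non-finite consistency loss at epoch ", ep)
    hist$recon[ep] <- recon
    hist$consistency[ep] <- ct$loss
    hist$total[ep] <- total

    # backward
    dXhat <- 2 * (Xhat - X)
    bd <- mlp_backward(Z, params$dec, fd, dXhat)
    dZ1 <- bd$dX / 2
    dZ2 <- bd$dX / 2
    if (use_cons) { dZ1 <- dZ1 + ct$dZ1; dZ2 <- dZ2 + ct$dZ2 }
    b1g <- mlp_backward(X, params$enc1, f1, dZ1)
    b2g <- mlp_backward(X, params$enc2, f2, dZ2)
    grads <- list(enc1 = b1g$grads, enc2 = b2g$grads, dec = bd$grads)

    # Adam update
    bc1 <- 1 - b1^ep; bc2 <- 1 - b2^ep
    for (blk in names(params)) {
      for (nm in names(params[[blk]])) {
        g <- grads[[blk]][[nm]]
        m[[blk]][[nm]] <- b1 * m[[blk]][[nm]] + (1 - b1) * g
        v[[blk]][[nm]] <- b2 * v[[blk]][[nm]] + (1 - b2) * g^2
        params[[blk]][[nm]] <- params[[blk]][[nm]] -
          config$lr * (m[[blk]][[nm]] / bc1) / (sqrt(v[[blk]][[nm]] / bc2) + eps_adam)
      }
    }
  }
  cfg <- config
  cfg$beta <- beta
  structure(list(params = params, config = cfg, loss_history = hist,
                 input_dim = p), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  h <- x$loss_history
  cat("trained_model: input dim", x$input_dim, ", latent", x$config$latent_dim,
      ",", nrow(h), "epochs\n")
  cat("  loss:", format(h$total[1], digits = 6), "->",
      format(h$total[nrow(h)], digits = 6), "\n")
  invisible(x)
}

#' Encode spots into latent features
#'
#' Runs both encoder branches on `X`.  With `perturb = TRUE` a fresh
#' Gaussian perturbation (sd `sigma_std` from the model config) seeded by
#' `seed` is added to the second branch; with `perturb = FALSE` (the
#' inference default) both branches are deterministic.  The fused feature is
#' `Z = (Z1 + Z2) / 2`.
#'
#' @param model a `trained_model` (or any list with compatible `params`).
#' @param X filtered expression matrix, columns matching the training width.
#' @param perturb add Gaussian noise to branch 2 (default `FALSE`).
#' @param seed seed for the perturbation draw (default 0).
#' @return A `latent_features` list with `Z1`, `Z2`, `Z`.
#' @export
encode_spots <- function(model, X, perturb = FALSE, seed = 0) {
  X <- as_values(X)
  if (!is.list(model$params)) stop("model is not trained")
  if (ncol(X) != model$input_dim)
    stop("X has ", ncol(X), " features; model expects ", model$input_dim)
  Z1 <- mlp_forward(X, model$params$enc1)$out
  Z2 <- mlp_forward(X, model$params$enc2)$out
  if (perturb && model$config$sigma_std > 0) {
    Z2 <- Z2 + with_seed(seed, matrix(
      stats::rnorm(length(Z2), sd = model$config$sigma_std),
      nrow(Z2), ncol(Z2)))
  }
  structure(list(Z1 = Z1, Z2 = Z2, Z = (Z1 + Z2) / 2),
            class = "latent_features")
}

#' Denoised expression
#'
#' Decodes the perturbation-free fused latent features: `X_hat = D(Z)`,
#' the model's estimate of the clean expression profile, same shape as `X`.
#'
#' @param model a `trained_model`.
#' @param X filtered expression matrix used for encoding.
#' @return spots x features denoised matrix.
#' @export
denoise_expression <- function(model, X) {
  if (!inherits(model, "trained_model")) stop("model is not a trained_model")
  Z <- encode_spots(model, X, perturb = FALSE)$Z
  mlp_forward(Z, model$params$dec)$out
}
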