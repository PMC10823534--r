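#' Training configuration for the sparse autoencoder
#'
#' The embedding network has three layers: an input layer with one node
#' per (cell-cycle) gene, a hidden layer of `hidden_dim` nodes (default
#' 10), and an output layer reconstructing the input. It is trained by
#' full-batch gradient descent on
#' \deqn{E = \frac{1}{N}\sum_i \|x_i - y_i\|^2 + \lambda\|W\|^2 + \beta
#'   \sum_j \mathrm{KL}(\rho \,\|\, \hat\rho_j)}
#' where \eqn{N} is the number of cells, \eqn{y_i} the reconstruction of
#' cell \eqn{i}, \eqn{\|W\|^2} the squared Frobenius norms of encoder and
#' decoder weight matrices (biases excluded), and \eqn{\hat\rho_j} the
#' mean hidden activation of unit \eqn{j} over all cells.
#'
#' @param hidden_dim hidden layer width (default 10).
#' @param lambda_weight weight-decay coefficient (default 0.001).
#' @param sparsity_target target mean activation \eqn{\rho} (default 0.05).
#' @param sparsity_weight sparsity coefficient \eqn{\beta} (default 0.2;
#'   strong sparsity pressure makes the sigmoid units switch-like and can
#'   fragment continuous within-cluster variation, such as library-depth
#'   gradients, into spurious density modes).
#' @param epochs number of full-batch gradient steps.
#' @param learning_rate step size (> 0).
#' @param momentum classical momentum coefficient in \[0, 1) for the
#'   full-batch updates (default 0 = plain gradient descent, whose
#'   monotone-descent behavior at small learning rates is auditable).
#' @param seed integer seed for the weight initialization.
#' @param activation "sigmoid" (default; sigmoid output layer) or "relu"
#'   (linear output layer).
#' @param scale_input_unit if TRUE (default) min-max scale each gene to
#'   \[0, 1\] before training, so a sigmoid output can reach the data.
#' @return list of class `csa_ae_config`.
#' @export
ae_config <- function(hidden_dim = 10L, lambda_weight = 0.001,
                      sparsity_target = 0.05, sparsity_weight = 0.2,
                      epochs = 800L, learning_rate = 1.0, momentum = 0,
                      seed = 1L, activation = c("sigmoid", "relu"),
                      scale_input_unit = TRUE) {
  activation <- match.arg(activation)
  stopifnot(hidden_dim >= 1, epochs >= 1, learning_rate > 0,
            momentum >= 0, momentum < 1,
            sparsity_target > 0, sparsity_target < 1, sparsity_weight >= 0,
            lambda_weight >= 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 lambda_weight = lambda_weight,
                 sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed),
                 activation = activation,
                 scale_input_unit = isTRUE(scale_input_unit)),
            class = "csa_ae_config")
}

#' Construct an autoencoder model from explicit weights
#'
#' @param W_enc G x H encoder weights; @param b_enc length-H encoder bias.
#' @param W_dec H x G decoder weights; @param b_dec length-G decoder bias.
#' @param activation "sigmoid" or "relu".
#' @param genes optional gene symbols (length G) for input checking.
#' @param scale optional list(min, range) per gene, applied to inputs.
#' @return list of class `csa_ae_model`.
#' @export
ae_model <- function(W_enc, b_enc, W_dec, b_dec,
                     activation = c("sigmoid", "relu"), genes = NULL,
                     scale = NULL) {
  activation <- match.arg(activation)
  W_enc <- as.matrix(W_enc); W_dec <- as.matrix(W_dec)
  stopifnot(ncol(W_enc) == length(b_enc), nrow(W_dec) == length(b_enc),
            ncol(W_dec) == length(b_dec), nrow(W_enc) == ncol(W_dec))
  if (!all(is.finite(W_enc)) || !all(is.finite(W_dec))) {
    stop("non-finite model weights")
  }
  structure(list(W_enc = W_enc, b_enc = as.numeric(b_enc), W_dec = W_dec,
                 b_dec = as.numeric(b_dec), hidden_dim = ncol(W_enc),
                 activation = activation, genes = genes, scale = scale),
            class = "csa_ae_model")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.ae_act <- function(z, activation) {
  if (activation == "sigmoid") .sigmoid(z) else pmax(z, 0)
}

# Apply the model's stored per-gene min-max scaling (identity if none).
.ae_scale_input <- function(model, X) {
  if (is.null(model$scale)) return(X)
  sweep(sweep(X, 2, model$scale$min, "-"), 2, model$scale$range, "/")
}

# Forward pass on an already-scaled matrix. Hidden uses the configured
# activation; the output layer is sigmoid for sigmoid nets and linear for
# relu nets (a relu output could not reconstruct arbitrary positives and
# a sigmoid output could not exceed 1).
.ae_forward <- function(model, X) {
  Z1 <- sweep(X %*% model$W_enc, 2, model$b_enc, "+")
  H <- .ae_act(Z1, model$activation)
  Z2 <- sweep(H %*% model$W_dec, 2, model$b_dec, "+")
  Y <- if (model$activation == "sigmoid") .sigmoid(Z2) else Z2
  list(H = H, Y = Y)
}

.kl_bern <- function(rho, rhohat) {
  rhohat <- pmin(pmax(rhohat, 1e-12), 1 - 1e-12)
  rho * log(rho / rhohat) + (1 - rho) * log((1 - rho) / (1 - rhohat))
}

# Loss terms on an already-scaled matrix.
.ae_terms <- function(model, X, cfg) {
  fw <- .ae_forward(model, X)
  if (!all(is.finite(fw$Y))) stop("non-finite autoencoder forward pass")
  n <- nrow(X)
  recon <- sum((X - fw$Y)^2) / n
  weight <- cfg$lambda_weight * (sum(model$W_enc^2) + sum(model$W_dec^2))
  rhohat <- colMeans(fw$H)
  sparsity <- cfg$sparsity_weight *
    sum(.kl_bern(cfg$sparsity_target, rhohat))
  list(total = recon + weight + sparsity, recon = recon, weight = weight,
       sparsity = sparsity, H = fw$H, Y = fw$Y, rhohat = rhohat)
}

#' Evaluate the autoencoder training loss and its three terms
#'
#' @param model a [ae_model()] (its stored input scaling, if any, is
#'   applied to the data first).
#' @param data a `csa_norm` object or plain cells x genes matrix.
#' @param cfg a [ae_config()] supplying the loss coefficients.
#' @return list(total, recon, weight, sparsity); `total` is always the
#'   exact sum of the other three.
#' @export
ae_loss <- function(model, data, cfg = ae_config()) {
  X <- if (inherits(data, "csa_norm")) data$values else as.matrix(data)
  if (ncol(X) != nrow(model$W_enc)) {
    stop(sprintf("data has %d genes but model expects %d", ncol(X),
                 nrow(model$W_enc)))
  }
  t <- .ae_terms(model, .ae_scale_input(model, X), cfg)
  t[c("total", "recon", "weight", "sparsity")]
}

# Analytic gradient of the loss on an already-scaled matrix.
.ae_grad <- function(model, X, cfg) {
  n <- nrow(X)
  Z1 <- sweep(X %*% model$W_enc, 2, model$b_enc, "+")
  H <- .ae_act(Z1, model$activation)
  Z2 <- sweep(H %*% model$W_dec, 2, model$b_dec, "+")
  if (model$activation == "sigmoid") {
    Y <- .sigmoid(Z2)
    dZ2 <- (2 / n) * (Y - X) * Y * (1 - Y)
  } else {
    Y <- Z2
    dZ2 <- (2 / n) * (Y - X)
  }
  gW_dec <- crossprod(H, dZ2) + 2 * cfg$lambda_weight * model$W_dec
  gb_dec <- colSums(dZ2)
  dH <- dZ2 %*% t(model$W_dec)
  rhohat <- pmin(pmax(colMeans(H), 1e-12), 1 - 1e-12)
  dKL <- cfg$sparsity_weight *
    (-cfg$sparsity_target / rhohat +
       (1 - cfg$sparsity_target) / (1 - rhohat)) / n
  dH <- sweep(dH, 2, dKL, "+")
  dZ1 <- if (model$activation == "sigmoid") dH * H * (1 - H)
         else dH * (Z1 > 0)
  gW_enc <- crossprod(X, dZ1) + 2 * cfg$lambda_weight * model$W_enc
  gb_enc <- colSums(dZ1)
  list(W_enc = gW_enc, b_enc = gb_enc, W_dec = gW_dec, b_dec = gb_dec)
}

.xavier_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Train the sparse autoencoder by full-batch gradient descent
#'
#' Deterministic given the config seed: weights start from a seeded
#' Xavier-uniform initialization and every step uses the full batch, so
#' identical (data, config) pairs yield bit-identical traces.
#'
#' @param data a `csa_norm` object or plain cells x genes matrix
#'   (at least 2 cells and 2 genes).
#' @param cfg a [ae_config()].
#' @return list(model, trace): the trained [ae_model()] and a data.frame
#'   with per-epoch columns epoch, total, recon, weight, sparsity.
#' @export
ae_train <- function(data, cfg = ae_config()) {
  X <- if (inherits(data, "csa_norm")) data$values else as.matrix(data)
  genes <- if (inherits(data, "csa_norm")) data$gene_symbols else colnames(X)
  cells <- if (inherits(data, "csa_norm")) data$cell_ids else rownames(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 cells and 2 genes")
  scale <- NULL
  if (cfg$scale_input_unit) {
    mn <- apply(X, 2, min)
    rg <- apply(X, 2, max) - mn
    rg[rg == 0] <- 1          # constant genes map to 0
    scale <- list(min = mn, range = rg)
    X <- sweep(sweep(X, 2, mn, "-"), 2, rg, "/")
  }
  G <- ncol(X); Hd <- cfg$hidden_dim
  set.seed(cfg$seed)
  model <- ae_model(.xavier_init(G, Hd), numeric(Hd),
                    .xavier_init(Hd, G), numeric(G),
                    activation = cfg$activation, genes = genes,
                    scale = scale)
  trace <- data.frame(epoch = seq_len(cfg$epochs), total = NA_real_,
                      recon = NA_real_, weight = NA_real_,
                      sparsity = NA_real_)
  lr <- cfg$learning_rate
  mom <- if (is.null(cfg$momentum)) 0 else cfg$momentum
  vel <- list(W_enc = 0, b_enc = 0, W_dec = 0, b_dec = 0)
  for (ep in seq_len(cfg$epochs)) {
    g <- .ae_grad(model, X, cfg)
    for (nm in names(vel)) vel[[nm]] <- mom * vel[[nm]] - lr * g[[nm]]
    model$W_enc <- model$W_enc + vel$W_enc
    model$b_enc <- model$b_enc + vel$b_enc
    model$W_dec <- model$W_dec + vel$W_dec
    model$b_dec <- model$b_dec + vel$b_dec
    t <- .ae_terms(model, X, cfg)
    trace$total[ep] <- t$total; trace$recon[ep] <- t$recon
    trace$weight[ep] <- t$weight; trace$sparsity[ep] <- t$sparsity
    if (!is.finite(t$total) || t$total > 1e12) {
      stop(sprintf(paste0("training diverged at epoch %d (loss %g); ",
                          "reduce learning_rate"), ep, t$total))
    }
  }
  list(model = model, trace = trace)
}

#' Embed cells with a trained autoencoder
#'
#' Applies the encoder half: `coords = activation(x W_enc + b_enc)`, one
#' row per cell, after the model's stored input scaling.
#'
#' @param model a trained [ae_model()].
#' @param data a `csa_norm` object or matrix with the same genes the
#'   model was trained on.
#' @return object of class `csa_embedding`: list(coords, cell_ids).
#' @export
ae_embed <- function(model, data) {
  X <- if (inherits(data, "csa_norm")) data$values else as.matrix(data)
  cells <- if (inherits(data, "csa_norm")) data$cell_ids else rownames(X)
  if (ncol(X) != nrow(model$W_enc)) {
    stop(sprintf("data has %d genes but model expects %d", ncol(X),
                 nrow(model$W_enc)))
  }
  if (!is.null(model$genes) && !is.null(colnames(X)) &&
      !identical(toupper(colnames(X)), toupper(model$genes))) {
    stop("gene set/order of data does not match the model")
  }
  Xs <- .ae_scale_input(model, X)
  H <- .ae_act(sweep(Xs %*% model$W_enc, 2, model$b_enc, "+"),
               model$activation)
  as_embedding(H, cells)
}

#' Wrap a coordinate matrix as an embedding
#' @param coords numeric matrix, one row per cell.
#' @param cell_ids optional cell identifiers (default: row numbers).
#' @return object of class `csa_embedding`.
#' @export
as_embedding <- function(coords, cell_ids = NULL) {
  coords <- as.matrix(coords)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(coords)
    if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(coords)))
  }
  stopifnot(length(cell_ids) == nrow(coords), all(is.finite(coords)))
  structure(list(coords = coords, cell_ids = as.character(cell_ids)),
            class = "csa_embedding")
}
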