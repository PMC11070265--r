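#' Hyperparameters of the joint species distribution model
#'
#' Penalties are elastic nets applied separately to the three parameter
#' blocks: environment (feature-network weights), spatial trend-surface
#' coefficients, and latent-factor loadings. `mix` is the L1 share (1 = pure
#' lasso, 0 = pure ridge). `hidden` gives the widths of the feature network's
#' hidden layers (tanh activation); `integer(0)` is a linear model. `M` is
#' the number of Monte Carlo draws of the latent factors used during
#' training.
#'
#' @param env_penalty,env_mix elastic net on feature-network weights.
#' @param trend_penalty,trend_mix elastic net on trend-surface coefficients.
#' @param loading_penalty,loading_mix elastic net on species loadings.
#' @param latent_rank number of latent factors (0 = independent probits).
#' @param hidden integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param epochs full-batch epochs (early stop on a training-loss plateau:
#'   no improvement beyond 1e-5 over 50 epochs).
#' @param M Monte Carlo draws during training (default 100).
#' @param trend_degree trend-surface polynomial degree (0 disables it).
#' @return object of class `jsdm_hyperparams`.
#' @export
jsdm_hyperparams <- function(env_penalty = 1e-3, env_mix = 0.5,
                             trend_penalty = 1e-3, trend_mix = 0.5,
                             loading_penalty = 1e-3, loading_mix = 0.5,
                             latent_rank = 2, hidden = integer(0),
                             lr = 0.05, epochs = 300, M = 100,
                             trend_degree = 2) {
  hp <- list(env_penalty = env_penalty, env_mix = env_mix,
             trend_penalty = trend_penalty, trend_mix = trend_mix,
             loading_penalty = loading_penalty, loading_mix = loading_mix,
             latent_rank = as.integer(latent_rank),
             hidden = as.integer(hidden), lr = lr,
             epochs = as.integer(epochs), M = as.integer(M),
             trend_degree = as.integer(trend_degree))
  with(hp, {
    stopifnot(env_penalty >= 0, trend_penalty >= 0, loading_penalty >= 0,
              env_mix >= 0, env_mix <= 1, trend_mix >= 0, trend_mix <= 1,
              loading_mix >= 0, loading_mix <= 1,
              latent_rank >= 0, M >= 1, lr > 0, epochs >= 1,
              trend_degree >= 0)
  })
  structure(hp, class = "jsdm_hyperparams")
}

total_penalty <- function(hp)
  hp$env_penalty + hp$trend_penalty + hp$loading_penalty

#' Polynomial trend-surface basis over site coordinates
#'
#' Monomials of the standardized coordinates up to total degree `degree`,
#' excluding the constant (the intercept lives in the feature network):
#' degree 2 gives `{x, y, x2, xy, y2}`. Standardization parameters are
#' computed from the supplied coordinates unless given (prediction reuses
#' the training ones), which makes the basis invariant to shifting all
#' coordinates by a constant.
#'
#' @param coords numeric matrix/data.frame with two columns (x, y), metres.
#' @param degree polynomial degree (>= 1).
#' @param center,scale optional standardization parameters (length 2 each).
#' @return list: `basis` (n x q matrix), `degree`, `center`, `scale`.
#' @export
build_trend_surface <- function(coords, degree = 2, center = NULL,
                                scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have two columns (x, y)")
  if (nrow(coords) < 1) stop("need at least one site")
  if (degree < 1) stop("degree must be >= 1")
  if (is.null(center)) center <- colMeans(coords)
  if (is.null(scale)) {
    scale <- apply(coords, 2, stats::sd)
    if (any(!is.finite(scale)) || any(scale == 0))
      stop("zero variance in coordinates (all sites at one location?)")
  }
  xs <- (coords[, 1] - center[1]) / scale[1]
  ys <- (coords[, 2] - center[2]) / scale[2]
  cols <- list(); nms <- character(0)
  for (k in seq_len(degree)) {
    for (a in k:0) {
      b <- k - a
      cols[[length(cols) + 1L]] <- xs^a * ys^b
      nms <- c(nms, paste0(if (a > 0) paste0("x", if (a > 1) a else "") else "",
                           if (b > 0) paste0("y", if (b > 1) b else "") else ""))
    }
  }
  basis <- do.call(cbind, cols)
  colnames(basis) <- nms
  list(basis = basis, degree = degree, center = center, scale = scale)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability a random presence scores above a random
#' absence, ties counting one half. Returns `NA` when the labels contain a
#' single class (a species can be absent from a test fold).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA_real_` for single-class labels.
#' @export
auc <- function(scores, labels) {
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- probit likelihood internals ------------------------------------------

PROB_EPS <- 1e-7

# fused clamped log Bernoulli probability and score d log P(y|z) / dz
# (stable inverse-Mills form); one pass of the normal-tail evaluations
# shared by loss and gradient
bern_both <- function(Z, Ypos, grad = TRUE) {
  lp1 <- stats::pnorm(Z, log.p = TRUE)
  lp0 <- stats::pnorm(Z, lower.tail = FALSE, log.p = TRUE)
  lB <- lp0
  lB[Ypos] <- lp1[Ypos]
  lB <- pmin(pmax(lB, log(PROB_EPS)), log1p(-PROB_EPS))
  if (!grad) return(list(logp = lB))
  ld <- stats::dnorm(Z, log = TRUE)
  g <- -exp(ld - lp0)
  g[Ypos] <- exp((ld - lp1)[Ypos])
  list(logp = lB, score = g)
}

# Monte Carlo negative log-likelihood of the multivariate probit and its
# gradients wrt eta (n x S) and Lambda (S x r). H: M x r latent draws
# (common random numbers). r = 0 gives the exact independent-probit NLL.
mc_probit_core <- function(eta, Lambda, Ypos, H, grad = FALSE) {
  n <- nrow(eta); S <- ncol(eta)
  r <- if (is.null(Lambda)) 0L else ncol(Lambda)
  if (r == 0L) {
    bb <- bern_both(eta, Ypos, grad = grad)
    value <- -sum(bb$logp)
    if (!grad) return(list(value = value))
    return(list(value = value, grad_eta = -bb$score, grad_Lambda = NULL))
  }
  M <- nrow(H)
  LH <- Lambda %*% t(H)                                   # S x M
  Z <- outer(eta, rep(1, M)) +
    aperm(array(LH, c(S, M, n)), c(3, 1, 2))              # n x S x M
  Ypos3 <- array(Ypos, c(n, S, M))
  bb <- bern_both(Z, Ypos3, grad = grad)
  ll <- colSums(aperm(bb$logp, c(2, 1, 3)))               # n x M
  a <- apply(ll, 1, max)
  wu <- exp(ll - a)
  srow <- rowSums(wu)
  value <- -sum(a + log(srow / M))
  if (!grad) return(list(value = value))
  w <- wu / srow                                          # n x M softmax
  gw <- bb$score * aperm(array(w, c(n, M, S)), c(1, 3, 2))
  grad_eta <- -rowSums(gw, dims = 2)                      # n x S
  A <- colSums(gw)                                        # S x M
  list(value = value, grad_eta = grad_eta, grad_Lambda = -(A %*% H))
}

#' Monte Carlo probit negative log-likelihood
#'
#' The negative log of the Monte Carlo estimate of
#' `prod_i E_{h ~ N(0, I_r)} prod_j Bernoulli(y_ij | pnorm(eta_ij +
#' Lambda_j . h))`, the likelihood of the low-rank multivariate probit
#' (implied species covariance `Lambda Lambda' + I`). With `Lambda = NULL`
#' (rank 0) the value is the exact independent-probit negative
#' log-likelihood, free of Monte Carlo error. Probabilities inside logs are
#' clamped to `[1e-7, 1 - 1e-7]`. Penalties are not included; they belong to
#' [fit_jsdm()].
#'
#' @param eta linear predictor matrix (samples x species).
#' @param Lambda species loading matrix (species x rank) or `NULL`.
#' @param Y binary incidence matrix, same shape as `eta`.
#' @param M number of Monte Carlo draws (ignored when rank is 0).
#' @param seed seed for the latent draws.
#' @return list: `value` (scalar loss), `grad_eta`, `grad_Lambda`.
#' @export
mc_probit_nll <- function(eta, Lambda = NULL, Y, M = 100, seed = 1) {
  eta <- as.matrix(eta); Y <- as.matrix(Y)
  stopifnot(identical(dim(eta), dim(Y)), M >= 1)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  if (any(!is.finite(eta))) stop("non-finite values in eta")
  r <- if (is.null(Lambda)) 0L else ncol(Lambda)
  H <- NULL
  if (r > 0) {
    set.seed(seed)
    H <- matrix(stats::rnorm(M * r), M, r)
  }
  out <- mc_probit_core(eta, Lambda, Y == 1, H, grad = TRUE)
  out[c("value", "grad_eta", "grad_Lambda")]
}

# ---- feature network -------------------------------------------------------

init_params <- function(d, S, q_trend, hp, prevalence) {
  hs <- hp$hidden
  W <- list(); b <- list()
  sizes <- c(d, hs)
  for (l in seq_along(hs)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * hs[l], sd = 1 / sqrt(sizes[l])),
                     sizes[l], hs[l])
    b[[l]] <- numeric(hs[l])
  }
  last <- if (length(hs)) hs[length(hs)] else d
  list(W = W, b = b,
       W_out = matrix(stats::rnorm(last * S, sd = 0.1 / sqrt(last)), last, S),
       b_out = stats::qnorm(pmin(pmax(prevalence, 0.02), 0.98)),
       Gamma = if (q_trend > 0) matrix(0, q_trend, S) else NULL,
       Lambda = if (hp$latent_rank > 0)
         matrix(stats::rnorm(S * hp$latent_rank, sd = 0.1), S, hp$latent_rank)
       else NULL)
}

net_forward <- function(params, X) {
  Hs <- vector("list", length(params$W))
  A <- X
  for (l in seq_along(params$W)) {
    A <- tanh(sweep(A %*% params$W[[l]], 2, params$b[[l]], "+"))
    Hs[[l]] <- A
  }
  list(eta_env = sweep(A %*% params$W_out, 2, params$b_out, "+"), Hs = Hs)
}

# backprop of dLoss/deta_env through the network; returns gradient list
net_backward <- function(params, X, Hs, G) {
  L <- length(params$W)
  A_last <- if (L) Hs[[L]] else X
  gr <- list(W = vector("list", L), b = vector("list", L),
             W_out = t(A_last) %*% G, b_out = colSums(G))
  Gh <- G %*% t(params$W_out)
  if (L) for (l in L:1) {
    Gz <- Gh * (1 - Hs[[l]]^2)
    inp <- if (l > 1) Hs[[l - 1]] else X
    gr$W[[l]] <- t(inp) %*% Gz
    gr$b[[l]] <- colSums(Gz)
    Gh <- Gz %*% t(params$W[[l]])
  }
  gr
}

enet_value <- function(W, lambda, mix)
  lambda * (mix * sum(abs(W)) + (1 - mix) * sum(W^2))

# smooth (ridge) part of the elastic-net gradient; the L1 part is handled
# by a proximal soft-threshold after each Adam step, so lasso penalties can
# drive weights to exact zero instead of oscillating at the step size
enet_grad_l2 <- function(W, lambda, mix)
  lambda * 2 * (1 - mix) * W

soft_threshold <- function(W, thr)
  sign(W) * pmax(abs(W) - thr, 0)

# deterministic matrix product built from rank-1 outer products: each
# element of A[,k] %o% B[k,] is a single float multiply, and accumulation
# order is fixed over k, so results are bit-identical for any row subset
# (BLAS dgemm rounding varies with matrix shape, breaking chunk invariance)
detmm <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (k in seq_len(ncol(A))) out <- out + outer(A[, k], B[k, ])
  out
}

# forward pass via detmm: bit-identical predictions for any row chunking
net_forward_det <- function(params, X) {
  A <- X
  for (l in seq_along(params$W))
    A <- tanh(sweep(detmm(A, params$W[[l]]), 2, params$b[[l]], "+"))
  sweep(detmm(A, params$W_out), 2, params$b_out, "+")
}

# ---- fitting ---------------------------------------------------------------

#' Fit the joint species distribution model
#'
#' Multivariate probit with a feature network for the environment, an
#' additive polynomial trend surface over site coordinates, and a low-rank
#' latent covariance, fitted by full-batch Adam on the penalized Monte Carlo
#' negative log-likelihood. Latent draws are fixed at the start (common
#' random numbers), so the fit is a pure function of the data, the
#' hyperparameters and the seed. Covariates are standardized internally on
#' the training rows; the parameters are stored and reapplied at prediction.
#'
#' @param Y binary incidence matrix (samples x species, >= 2 species) or an
#'   [incidence_matrix()].
#' @param X covariate matrix/data.frame aligned with the samples.
#' @param coords optional site coordinates (n x 2) for the trend surface;
#'   `NULL` (or `trend_degree = 0`) omits it.
#' @param hyper a [jsdm_hyperparams()].
#' @param seed integer seed (initialization and latent draws).
#' @param verbose print the loss every 50 epochs.
#' @return object of class `jsdm_model` with fitted parameters, training
#'   standardization, and the per-epoch loss trace.
#' @export
fit_jsdm <- function(Y, X, coords = NULL, hyper = jsdm_hyperparams(),
                     seed = 1, verbose = FALSE) {
  if (inherits(Y, "incidence_matrix")) {
    if (is.null(coords) && !is.null(Y$x)) coords <- cbind(Y$x, Y$y)
    Y <- Y$Y
  }
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  if (ncol(Y) < 2) stop("joint model needs >= 2 species")
  if (anyNA(X)) stop("missing covariate values")
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("sp%03d", seq_len(ncol(Y)))

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0 | !is.finite(x_scale)] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")

  trend <- NULL; B <- NULL; q <- 0L
  if (!is.null(coords) && hyper$trend_degree >= 1) {
    ts <- build_trend_surface(coords, hyper$trend_degree)
    B <- ts$basis; q <- ncol(B)
    trend <- ts[c("degree", "center", "scale")]
  }

  n <- nrow(Y); S <- ncol(Y); r <- hyper$latent_rank
  Ypos <- Y == 1
  set.seed(seed)
  params <- init_params(ncol(Xs), S, q, hyper, colMeans(Y))
  H <- if (r > 0) matrix(stats::rnorm(hyper$M * r), hyper$M, r) else NULL

  # Adam state mirrors the parameter tree
  m1 <- param_zeros(params)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; ad_eps <- 1e-8
  best <- Inf; stall <- 0L
  trace <- numeric(0)

  for (epoch in seq_len(hyper$epochs)) {
    fw <- net_forward(params, Xs)
    eta <- fw$eta_env
    if (q > 0) eta <- eta + B %*% params$Gamma
    core <- mc_probit_core(eta, params$Lambda, Ypos, H, grad = TRUE)
    pen <- sum(vapply(params$W, enet_value, numeric(1),
                      hyper$env_penalty, hyper$env_mix)) +
      enet_value(params$W_out, hyper$env_penalty, hyper$env_mix) +
      (if (q > 0) enet_value(params$Gamma, hyper$trend_penalty,
                             hyper$trend_mix) else 0) +
      (if (r > 0) enet_value(params$Lambda, hyper$loading_penalty,
                             hyper$loading_mix) else 0)
    loss <- core$value + pen
    if (!is.finite(loss))
      stop(sprintf(
        "divergence (non-finite loss) at epoch %d [lr=%g, env_penalty=%g, rank=%d]",
        epoch, hyper$lr, hyper$env_penalty, r))
    trace <- c(trace, loss)
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %4d  loss %.4f", epoch, loss))

    bp <- net_backward(params, Xs, fw$Hs, core$grad_eta)
    for (l in seq_along(bp$W))
      bp$W[[l]] <- bp$W[[l]] +
        enet_grad_l2(params$W[[l]], hyper$env_penalty, hyper$env_mix)
    gr <- list(
      W = bp$W, b = bp$b,
      W_out = bp$W_out +
        enet_grad_l2(params$W_out, hyper$env_penalty, hyper$env_mix),
      b_out = bp$b_out,
      Gamma = if (q > 0)
        t(B) %*% core$grad_eta +
          enet_grad_l2(params$Gamma, hyper$trend_penalty, hyper$trend_mix)
      else NULL,
      Lambda = if (r > 0)
        core$grad_Lambda +
          enet_grad_l2(params$Lambda, hyper$loading_penalty,
                       hyper$loading_mix)
      else NULL)

    upd <- adam_step(params, gr, m1, m2, hyper$lr, b1, b2, ad_eps, epoch)
    params <- upd$params; m1 <- upd$m1; m2 <- upd$m2
    # proximal step for the L1 penalty components
    thr_env <- hyper$lr * hyper$env_penalty * hyper$env_mix
    if (thr_env > 0) {
      for (l in seq_along(params$W))
        params$W[[l]] <- soft_threshold(params$W[[l]], thr_env)
      params$W_out <- soft_threshold(params$W_out, thr_env)
    }
    if (q > 0 && hyper$trend_mix > 0)
      params$Gamma <- soft_threshold(
        params$Gamma, hyper$lr * hyper$trend_penalty * hyper$trend_mix)
    if (r > 0 && hyper$loading_mix > 0)
      params$Lambda <- soft_threshold(
        params$Lambda, hyper$lr * hyper$loading_penalty * hyper$loading_mix)

    if (loss < best - 1e-5) { best <- loss; stall <- 0L }
    else { stall <- stall + 1L; if (stall >= 50L) break }
  }

  # canonical parameter arrays carry no dimnames (schema lives in
  # covariate_names/species_names); keeps serialization round-trips exact
  params <- param_strip(params)
  structure(list(params = params, hyper = hyper,
                 x_center = x_center, x_scale = x_scale,
                 covariate_names = colnames(X),
                 species_names = colnames(Y),
                 trend = trend, loss_trace = trace, seed = seed,
                 n_train = n),
            class = "jsdm_model")
}

# drop dimnames/names from every array in a parameter tree
param_strip <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) {
    out <- lapply(p, param_strip)
    names(out) <- names(p)
    return(out)
  }
  dimnames(p) <- NULL
  names(p) <- NULL
  p
}

# zero-filled clone of a parameter tree, preserving NULL leaves
param_zeros <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) {
    out <- lapply(p, param_zeros)
    names(out) <- names(p)
    return(out)
  }
  p * 0
}

# one Adam update over the whole parameter tree
adam_step <- function(params, gr, m1, m2, lr, b1, b2, eps, t) {
  walk <- function(p, g, a, b) {
    if (is.null(p)) return(list(p = NULL, a = NULL, b = NULL))
    if (is.list(p)) {
      out <- Map(walk, p, g, a, b)
      return(list(p = lapply(out, `[[`, "p"),
                  a = lapply(out, `[[`, "a"),
                  b = lapply(out, `[[`, "b")))
    }
    a <- b1 * a + (1 - b1) * g
    b <- b2 * b + (1 - b2) * g^2
    ah <- a / (1 - b1^t); bh <- b / (1 - b2^t)
    list(p = p - lr * ah / (sqrt(bh) + eps), a = a, b = b)
  }
  out <- Map(walk, params, gr, m1, m2)
  list(params = lapply(out, `[[`, "p"),
       m1 = lapply(out, `[[`, "a"),
       m2 = lapply(out, `[[`, "b"))
}

#' @export
print.jsdm_model <- function(x, ...) {
  cat(sprintf(
    "jsdm_model: %d species, %d covariates, rank %d, hidden [%s]\n",
    length(x$species_names), length(x$covariate_names),
    x$hyper$latent_rank, paste(x$hyper$hidden, collapse = ", ")))
  cat(sprintf("final training loss %.4f after %d epochs\n",
              utils::tail(x$loss_trace, 1), length(x$loss_trace)))
  invisible(x)
}

#' Marginal occurrence probabilities for new samples
#'
#' Applies the training standardization to the new covariates, runs the
#' feature network plus trend surface, and returns the marginal probit
#' probability `pnorm(eta / sqrt(1 + ||Lambda_j||^2))` per species.
#'
#' @param model a fitted [fit_jsdm()] model.
#' @param X_new covariate matrix with the training schema (column names are
#'   checked; missing/extra covariates raise an error naming them).
#' @param coords_new site coordinates, required when the model has a trend
#'   surface.
#' @return matrix of probabilities, samples x species.
#' @export
predict_prob <- function(model, X_new, coords_new = NULL) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    missing <- setdiff(model$covariate_names, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$covariate_names)
    if (length(missing) || length(extra))
      stop("covariate schema mismatch; missing: [",
           paste(missing, collapse = ", "), "] extra: [",
           paste(extra, collapse = ", "), "]")
    X_new <- X_new[, model$covariate_names, drop = FALSE]
  } else if (ncol(X_new) != length(model$covariate_names)) {
    stop("covariate count mismatch and no column names to match on")
  }
  Xs <- sweep(sweep(X_new, 2, model$x_center), 2, model$x_scale, "/")
  eta <- net_forward_det(model$params, Xs)
  if (!is.null(model$trend)) {
    if (is.null(coords_new))
      stop("model has a trend surface; coords_new is required")
    B <- build_trend_surface(coords_new, model$trend$degree,
                             model$trend$center, model$trend$scale)$basis
    eta <- eta + detmm(B, model$params$Gamma)
  }
  s <- if (is.null(model$params$Lambda)) rep(1, ncol(eta))
       else sqrt(1 + rowSums(model$params$Lambda^2))
  P <- stats::pnorm(sweep(eta, 2, s, "/"))
  colnames(P) <- model$species_names
  P
}

# ---- serialization ---------------------------------------------------------

encode_num <- function(x) {
  if (is.null(x)) return(NULL)
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       b64 = jsonlite::base64_enc(writeBin(as.vector(as.double(x)), raw())))
}

decode_num <- function(e) {
  if (is.null(e)) return(NULL)
  v <- readBin(jsonlite::base64_dec(e$b64), "double",
               n = prod(unlist(e$dim)))
  if (length(e$dim) == 2) matrix(v, e$dim[[1]], e$dim[[2]]) else v
}

#' Save / load a fitted model
#'
#' Single-file JSON archive: plain metadata plus base64-encoded IEEE-754
#' doubles for every parameter array, so a load followed by
#' [predict_prob()] is bit-identical to the original model.
#'
#' @param model a `jsdm_model`.
#' @param path file path (`.json`).
#' @return `path` invisibly; `load_jsdm` returns the model.
#' @export
save_jsdm <- function(model, path) {
  p <- model$params
  obj <- list(
    package = "sidewaysmap", format = 1L,
    hyper = unclass(model$hyper),
    covariate_names = model$covariate_names,
    species_names = model$species_names,
    seed = model$seed, n_train = model$n_train,
    x_center = encode_num(model$x_center),
    x_scale = encode_num(model$x_scale),
    trend = if (is.null(model$trend)) NULL else list(
      degree = model$trend$degree,
      center = encode_num(model$trend$center),
      scale = encode_num(model$trend$scale)),
    loss_trace = encode_num(model$loss_trace),
    params = list(
      W = lapply(p$W, encode_num), b = lapply(p$b, encode_num),
      W_out = encode_num(p$W_out), b_out = encode_num(p$b_out),
      Gamma = encode_num(p$Gamma), Lambda = encode_num(p$Lambda)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname save_jsdm
#' @export
load_jsdm <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                            simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  hp <- obj$hyper
  hyper <- jsdm_hyperparams(hp$env_penalty, hp$env_mix, hp$trend_penalty,
                            hp$trend_mix, hp$loading_penalty, hp$loading_mix,
                            hp$latent_rank, unlist(hp$hidden), hp$lr,
                            hp$epochs, hp$M, hp$trend_degree)
  params <- list(
    W = lapply(obj$params$W, decode_num),
    b = lapply(obj$params$b, decode_num),
    W_out = decode_num(obj$params$W_out),
    b_out = decode_num(obj$params$b_out),
    Gamma = decode_num(obj$params$Gamma),
    Lambda = decode_num(obj$params$Lambda))
  trend <- if (is.null(obj$trend)) NULL else list(
    degree = obj$trend$degree,
    center = decode_num(obj$trend$center),
    scale = decode_num(obj$trend$scale))
  structure(list(params = params, hyper = hyper,
                 x_center = stats::setNames(decode_num(obj$x_center),
                                            unlist(obj$covariate_names)),
                 x_scale = stats::setNames(decode_num(obj$x_scale),
                                           unlist(obj$covariate_names)),
                 covariate_names = unlist(obj$covariate_names),
                 species_names = unlist(obj$species_names),
                 trend = trend, loss_trace = decode_num(obj$loss_trace),
                 seed = obj$seed, n_train = obj$n_train),
            class = "jsdm_model")
}
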