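#' Cross-entropy training loss for one query
#'
#' The default form is binary cross-entropy averaged over the toolbox,
#' \deqn{L = -\frac{1}{u}\sum_{i=1}^{u} y_i \log\hat y_i +
#'   (1-y_i)\log(1-\hat y_i),}
#' with \code{y} the one-hot ground truth — the printed training objective
#' of this architecture, applied to the softmax outputs. Because this is an
#' unusual pairing, \code{loss = "categorical"} selects the standard
#' categorical cross-entropy \code{-log(yhat[target])} for comparison.
#' Probabilities are clamped to \code{[eps, 1 - eps]} inside the logs.
#'
#' @param y_hat probability vector over the toolbox.
#' @param target toolbox index of the ground-truth tool (1-based).
#' @param loss \code{"binary"} or \code{"categorical"}.
#' @param eps clamp width (default 1e-7).
#' @return scalar loss.
#' @export
compute_loss <- function(y_hat, target, loss = c("binary", "categorical"),
                         eps = 1e-7) {
  loss <- match.arg(loss)
  u <- length(y_hat)
  if (target < 1L || target > u) stop("target index out of toolbox range")
  yc <- pmin(pmax(y_hat, eps), 1 - eps)
  if (loss == "categorical") return(-log(yc[target]))
  y <- numeric(u); y[target] <- 1
  -mean(y * log(yc) + (1 - y) * log(1 - yc))
}

# dL/dyhat for both loss forms (clamped probabilities inside divisions)
loss_grad_yhat <- function(y_hat, target, loss, eps = 1e-7) {
  u <- length(y_hat)
  yc <- pmin(pmax(y_hat, eps), 1 - eps)
  if (loss == "categorical") {
    g <- numeric(u); g[target] <- -1 / yc[target]
    return(g)
  }
  y <- numeric(u); y[target] <- 1
  -(y / yc - (1 - y) / (1 - yc)) / u
}

zero_grads <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
}

add_grads <- function(acc, g, scale = 1) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + scale * g[[nm]]
  acc
}

#' Backpropagate through one query's forward pass
#'
#' Reverse-mode differentiation of the full pipeline (scoring, fusion,
#' aggregation, gated propagation, embedding lookup) with respect to every
#' learnable parameter. The description matrix is frozen: no gradient is
#' produced for it. The tool embedding table receives gradient both from
#' the scoring layer and from the embedding lookup (weight tying).
#'
#' @param fw output of \code{\link{forward_query}} with
#'   \code{keep_cache = TRUE}.
#' @param target ground-truth toolbox index.
#' @param params the \code{rec_params} used in the forward pass.
#' @return list with \code{loss} (scalar) and \code{grads} (list shaped
#'   like \code{params}).
#' @export
backward_query <- function(fw, target, params) {
  cache <- fw$cache
  if (is.null(cache)) stop("forward pass was run without keep_cache = TRUE")
  config <- cache$config
  d_t <- config$d_t; d_c <- config$d_c
  u <- nrow(params$Wtool) - 1L
  g <- zero_grads(params)

  loss <- compute_loss(fw$yhat, target, config$loss)
  gy <- loss_grad_yhat(fw$yhat, target, config$loss)
  # softmax jacobian
  dlogits <- fw$yhat * (gy - sum(gy * fw$yhat))

  w_s <- cache$fus$w_s; w_c <- cache$fus$w_c; cat_lg <- cache$fus$cat
  g$Wtool[seq_len(u), ] <- g$Wtool[seq_len(u), ] + outer(dlogits, w_s)
  dw_s <- drop(crossprod(params$Wtool[seq_len(u), , drop = FALSE], dlogits))

  g$W4 <- g$W4 + outer(dw_s, w_c)
  dw_c <- drop(crossprod(params$W4, dw_s))
  g$W3 <- g$W3 + outer(dw_c, cat_lg)
  dcat <- drop(crossprod(params$W3, dw_c))
  dw_l <- dcat[seq_len(d_c)]
  dw_g <- dcat[d_c + seq_len(d_c)]

  n <- cache$n
  dS_all <- matrix(0, n, d_c)
  ac <- cache$agg
  real <- ac$real
  S <- ac$S
  if (config$use_attention) {
    H <- ac$H
    alpha <- ac$alpha
    dalpha <- drop(S %*% dw_g)
    if (config$attention_softmax)
      dalpha <- alpha * (dalpha - sum(dalpha * alpha))
    dS <- outer(alpha, dw_g)
    g$q_vec <- g$q_vec + drop(crossprod(H, dalpha))
    dU <- outer(dalpha, params$q_vec) * H * (1 - H)
    g$W2 <- g$W2 + crossprod(dU, S)
    dS <- dS + dU %*% params$W2
    sum_dU <- colSums(dU)
    g$W1 <- g$W1 + outer(sum_dU, cache$w_l)
    g$b_att <- g$b_att + sum_dU
    dw_l <- dw_l + drop(crossprod(params$W1, sum_dU))
  } else {
    dS <- matrix(dw_g / length(real), length(real), d_c, byrow = TRUE)
  }
  dS_all[real, ] <- dS
  r <- cache$qg$r_nodes
  dS_all[r, ] <- dS_all[r, , drop = FALSE] +
    matrix(dw_l / length(r), length(r), d_c, byrow = TRUE)

  dV <- if (is.null(cache$mask_s)) dS_all else dS_all * cache$mask_s

  # propagation rounds, reversed
  a_out <- cache$conn$a_out
  for (t in rev(seq_along(cache$prop))) {
    pc <- cache$prop[[t]]
    dZ <- dV * (pc$Cand - pc$V)
    dCand <- dV * pc$Z
    dVprev <- dV * (1 - pc$Z)

    dPreH <- dCand * (1 - pc$Cand^2)
    g$Wh <- g$Wh + crossprod(dPreH, pc$Act)
    dAct <- dPreH %*% params$Wh
    dRV <- dPreH %*% params$Uh
    g$Uh <- g$Uh + crossprod(dPreH, pc$RV)
    dRt <- dRV * pc$V
    dVprev <- dVprev + dRV * pc$Rt

    dPreR <- dRt * pc$Rt * (1 - pc$Rt)
    g$Wr <- g$Wr + crossprod(dPreR, pc$Act)
    dAct <- dAct + dPreR %*% params$Wr
    dVprev <- dVprev + dPreR %*% params$Ur
    g$Ur <- g$Ur + crossprod(dPreR, pc$V)

    dPreZ <- dZ * pc$Z * (1 - pc$Z)
    g$Wz <- g$Wz + crossprod(dPreZ, pc$Act)
    dAct <- dAct + dPreZ %*% params$Wz
    dVprev <- dVprev + dPreZ %*% params$Uz
    g$Uz <- g$Uz + crossprod(dPreZ, pc$V)

    g$b <- g$b + colSums(dAct)
    dM_in <- dAct[, seq_len(d_c), drop = FALSE]
    dM_out <- dAct[, d_c + seq_len(d_c), drop = FALSE]
    dVprev <- dVprev + a_out %*% dM_in + crossprod(a_out, dM_out)

    dV <- dVprev
  }

  # embedding lookup: only the tool-ID block is learnable
  dXt <- dV[, seq_len(d_t), drop = FALSE]
  if (!is.null(cache$mask_e)) dXt <- dXt * cache$mask_e
  rows <- ifelse(cache$qg$node_tools == QUERY_TOOL, u + 1L,
                 cache$qg$node_tools)
  for (i in seq_len(n))
    g$Wtool[rows[i], ] <- g$Wtool[rows[i], ] + dXt[i, ]

  list(loss = loss, grads = g)
}

#' One Adam update step
#'
#' Standard Adam with optional L2 penalty added to the raw gradients.
#' @param params,grads parameter and gradient lists of identical shape.
#' @param state optimizer state (NULL on first call).
#' @param lr learning rate.
#' @param l2 L2 penalty coefficient.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @return list with updated \code{params} and \code{state}.
#' @export
adam_step <- function(params, grads, state = NULL, lr = 1e-3, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state))
    state <- list(m = zero_grads(params), v = zero_grads(params), t = 0L)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]] + l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
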