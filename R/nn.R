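# Forward/backward evaluation of a model graph and the Adam optimizer.
#
# Feature maps travel through the graph as numeric matrices with one row per
# channel and one column per voxel (n = (d*H + h)*W + w). Spatial dimensions
# (D, H, W) are tracked per node: pooling halves H and W, upsampling doubles
# them, depth D is never resampled.

node_param_names <- function(i) {
  c(w = paste0("n", i, ".w"), b = paste0("n", i, ".b"))
}

.op_codes <- c(input = 1L, conv = 2L, convT2 = 3L, relu = 4L, pool = 5L,
               up2 = 6L, concat = 7L, add = 8L)

# Encode the node list as the integer table the C++ executor consumes, with
# the parameter tensors laid out in node order.
encode_graph <- function(model) {
  nodes <- model$nodes
  n <- length(nodes)
  enc <- matrix(0L, n, 8)
  pnames <- character(0)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    enc[i, 1] <- .op_codes[[nd$op]]
    if (!is.null(nd$inputs)) {
      enc[i, 2] <- nd$inputs[1]
      if (length(nd$inputs) > 1) enc[i, 3] <- nd$inputs[2]
    }
    if (nd$op %in% c("conv", "convT2")) {
      pnames <- c(pnames, paste0("n", i, ".w"), paste0("n", i, ".b"))
      enc[i, 4] <- length(pnames) - 1L
      enc[i, 5] <- length(pnames)
      if (nd$op == "conv") enc[i, 6:8] <- nd$kdim
    }
  }
  list(nodes = enc, pnames = pnames)
}

# Batched forward(/backward) through the C++ executor. X and Y are lists of
# channel x voxel matrices sharing `dims`. Returns mean loss, averaged named
# gradients and (optionally) predictions.
exec_batch <- function(model, X, Y = NULL, dims, loss = NULL,
                       want_grads = FALSE, want_pred = FALSE, enc = NULL) {
  if (is.null(enc)) enc <- encode_graph(model)
  loss_code <- if (is.null(loss)) 0L else match(loss, c("l1", "l2"))
  r <- nn_exec_batch(enc$nodes, model$params[enc$pnames], X,
                     if (is.null(Y)) NULL else Y,
                     as.integer(dims), loss_code, want_grads, want_pred)
  out <- list(loss = r$loss / length(X), preds = r$preds)
  if (want_grads) {
    grads <- lapply(r$grads, `/`, length(X))
    names(grads) <- enc$pnames
    out$grads <- grads
  }
  out
}

# Evaluate the graph on one input map. When keep = TRUE all intermediate
# activations (and max-pool winner indices) are retained for backprop.
net_forward <- function(model, x, dims, keep = FALSE) {
  nodes <- model$nodes
  p <- model$params
  n <- length(nodes)
  vals <- vector("list", n)
  dimss <- vector("list", n)
  aux <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- nodes[[i]]
    if (nd$op == "input") {
      vals[[i]] <- x
      dimss[[i]] <- dims
      next
    }
    j <- nd$inputs[1]
    din <- dimss[[j]]
    out <- switch(nd$op,
      conv = {
        dimss[[i]] <- din
        nn_conv_fwd(vals[[j]], p[[paste0("n", i, ".w")]],
                    p[[paste0("n", i, ".b")]], din, nd$kdim)
      },
      convT2 = {
        dimss[[i]] <- c(din[1], 2L * din[2], 2L * din[3])
        nn_convT2_fwd(vals[[j]], p[[paste0("n", i, ".w")]],
                      p[[paste0("n", i, ".b")]], din)
      },
      relu = {
        dimss[[i]] <- din
        v <- vals[[j]]
        v[v < 0] <- 0
        v
      },
      pool = {
        dimss[[i]] <- c(din[1], din[2] %/% 2L, din[3] %/% 2L)
        r <- nn_maxpool2_fwd(vals[[j]], din)
        if (keep) aux[[i]] <- r$idx
        r$y
      },
      up2 = {
        dimss[[i]] <- c(din[1], 2L * din[2], 2L * din[3])
        nn_up2_fwd(vals[[j]], din)
      },
      concat = {
        dimss[[i]] <- din
        rbind(vals[[j]], vals[[nd$inputs[2]]])
      },
      add = {
        dimss[[i]] <- din
        vals[[j]] + vals[[nd$inputs[2]]]
      },
      stop("unknown op: ", nd$op))
    vals[[i]] <- out
    if (!keep) {
      # free activations no longer needed by any later node
      # (simple heuristic: inputs of linear chains); full tape kept otherwise
    }
  }
  list(vals = vals, dims = dimss, aux = aux, out = vals[[n]],
       out_dims = dimss[[n]])
}

# Backpropagate dout (gradient of the loss w.r.t. the head output) through a
# kept tape. Returns a named list of parameter gradients.
net_backward <- function(model, tape, dout) {
  nodes <- model$nodes
  p <- model$params
  n <- length(nodes)
  dvals <- vector("list", n)
  grads <- list()
  dvals[[n]] <- dout
  for (i in rev(seq_len(n))) {
    dy <- dvals[[i]]
    if (is.null(dy)) next
    nd <- nodes[[i]]
    if (nd$op == "input") next
    j <- nd$inputs[1]
    acc <- function(k, g) {
      dvals[[k]] <<- if (is.null(dvals[[k]])) g else dvals[[k]] + g
    }
    switch(nd$op,
      conv = {
        g <- nn_conv_bwd(tape$vals[[j]], p[[paste0("n", i, ".w")]], dy,
                         tape$dims[[j]], nd$kdim)
        grads[[paste0("n", i, ".w")]] <- g$dw
        grads[[paste0("n", i, ".b")]] <- g$db
        acc(j, g$dx)
      },
      convT2 = {
        g <- nn_convT2_bwd(tape$vals[[j]], p[[paste0("n", i, ".w")]], dy,
                           tape$dims[[j]])
        grads[[paste0("n", i, ".w")]] <- g$dw
        grads[[paste0("n", i, ".b")]] <- g$db
        acc(j, g$dx)
      },
      relu = {
        acc(j, dy * (tape$vals[[i]] > 0))
      },
      pool = {
        acc(j, nn_maxpool2_bwd(dy, tape$aux[[i]], tape$dims[[j]]))
      },
      up2 = {
        acc(j, nn_up2_bwd(dy, tape$dims[[j]]))
      },
      concat = {
        c1 <- nrow(tape$vals[[j]])
        acc(j, dy[seq_len(c1), , drop = FALSE])
        acc(nd$inputs[2], dy[-seq_len(c1), , drop = FALSE])
      },
      add = {
        acc(j, dy)
        acc(nd$inputs[2], dy)
      })
    dvals[[i]] <- NULL  # free
  }
  grads
}

#' Training losses
#'
#' Mean absolute difference (\code{loss_l1}) and mean squared difference
#' (\code{loss_l2}) between two equally shaped arrays.
#'
#' @param pred,target numeric arrays of identical shape.
#' @return a single non-negative number.
#' @export
loss_l1 <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("loss: shape mismatch", call. = FALSE)
  mean(abs(pred - target))
}

#' @rdname loss_l1
#' @export
loss_l2 <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("loss: shape mismatch", call. = FALSE)
  mean((pred - target)^2)
}

loss_grad <- function(loss, pred, target) {
  n <- length(pred)
  d <- pred - target
  if (loss == "l1") sign(d) / n else 2 * d / n
}

# One Adam step over all parameters; state holds first/second moments and the
# step counter. Conventional betas (0.9, 0.999), eps 1e-8.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
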