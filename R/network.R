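# Minimal executable network engine for model_graph objects.
#
# Activations are stored as (batch * height * width) x channels matrices,
# rows batch-major with column-major spatial order, so convolution and
# pooling reduce to one gather (im2col) plus a BLAS matrix product. With
# 1x1 spatial extent this layout degenerates to the plain (batch x
# features) matrix, so fully connected classifier graphs run through the
# same code path.

# --- gather (im2col) index construction -------------------------------

# Per-image patch index table: (Ho*Wo) x k^2, NA marks padding.
patch_table <- function(hi, wi, kernel, stride, padding) {
  if (padding == "same") {
    ho <- ceiling(hi / stride); wo <- ceiling(wi / stride)
    pad_h <- max((ho - 1L) * stride + kernel - hi, 0L) %/% 2L
    pad_w <- max((wo - 1L) * stride + kernel - wi, 0L) %/% 2L
  } else {
    ho <- floor((hi - kernel) / stride) + 1L
    wo <- floor((wi - kernel) / stride) + 1L
    pad_h <- pad_w <- 0L
    if (ho < 1 || wo < 1)
      stop_planefusion("valid-padding window larger than input", "graph_error")
  }
  oh <- rep(seq_len(ho), times = wo)
  ow <- rep(seq_len(wo), each = ho)
  G <- matrix(NA_integer_, ho * wo, kernel * kernel)
  t <- 0L
  for (kw in seq_len(kernel)) for (kh in seq_len(kernel)) {
    t <- t + 1L
    ih <- (oh - 1L) * stride + kh - pad_h
    iw <- (ow - 1L) * stride + kw - pad_w
    ok <- ih >= 1L & ih <= hi & iw >= 1L & iw <= wi
    G[ok, t] <- (iw[ok] - 1L) * hi + ih[ok]
  }
  attr(G, "out") <- c(ho, wo)
  G
}

# Batched gather matrix: (Ho*Wo*B) x k^2; padding -> the single extra row
# index B*hi*wi + 1.
batch_gather <- function(G1, hi, wi, batch) {
  n1 <- nrow(G1); k2 <- ncol(G1)
  pad_row <- batch * hi * wi + 1L
  G <- matrix(0L, n1 * batch, k2)
  for (b in seq_len(batch)) {
    Gb <- G1 + (b - 1L) * hi * wi
    Gb[is.na(Gb)] <- pad_row
    G[(b - 1L) * n1 + seq_len(n1), ] <- Gb
  }
  G
}

gather_for <- function(net, name, batch) {
  key <- sprintf("%s@%d", name, batch)
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  l <- net$graph$layers[[name]]
  s_in <- net$shapes[[in_edges(net$graph, name)[1]]]
  G1 <- patch_table(s_in[1], s_in[2], l$kernel, l$stride, l$padding)
  G <- batch_gather(G1, s_in[1], s_in[2], batch)
  net$cache[[key]] <- G
  G
}

# --- parameter initialization -----------------------------------------

#' Initialize network parameters
#'
#' He-normal initialization for conv and fc weights, zero biases, unit
#' batch-norm scale. Deterministic under `seed`.
#'
#' @param graph a [model_graph()].
#' @param seed integer seed.
#' @return an object of class `planefusion_network` holding the graph,
#'   inferred shapes and a parameter list.
#' @export
init_network <- function(graph, seed = 1L) {
  report <- infer_shapes(graph)
  params <- list()
  local_seed(seed, {
    for (n in names(graph$layers)) {
      l <- graph$layers[[n]]
      if (l$kind == "conv") {
        cin <- report$shapes[[in_edges(graph, n)[1]]][3]
        fan_in <- l$kernel^2 * cin
        params[[n]] <- list(
          W = matrix(stats::rnorm(fan_in * l$depth, sd = sqrt(2 / fan_in)),
                     fan_in, l$depth),
          b = numeric(l$depth))
      } else if (l$kind == "fc") {
        din <- prod(report$shapes[[in_edges(graph, n)[1]]])
        # the fc feeding softmax gets a small init so an untrained
        # classifier starts near the uniform-prediction cross-entropy;
        # hidden fc layers use He scaling like the convs
        consumers <- graph$edges[graph$edges[, 1] == n, 2]
        is_head <- any(vapply(graph$layers[consumers],
                              function(x) x$kind == "softmax", TRUE))
        sd0 <- if (is_head) 0.1 * sqrt(1 / din) else sqrt(2 / din)
        params[[n]] <- list(
          W = matrix(stats::rnorm(din * l$depth, sd = sd0), din, l$depth),
          b = numeric(l$depth))
      } else if (l$kind == "batchnorm") {
        ch <- report$shapes[[in_edges(graph, n)[1]]][3]
        params[[n]] <- list(gamma = rep(1, ch), beta = numeric(ch),
                            run_mean = numeric(ch), run_var = rep(1, ch))
      }
    }
  })
  structure(list(graph = graph, shapes = report$shapes,
                 order = topo_order(graph), params = params,
                 cache = new.env(parent = emptyenv())),
            class = "planefusion_network")
}

# --- forward / backward -----------------------------------------------

# A: input activation, (B*H*W) x C. Returns activations for every layer
# plus per-layer backward caches when train = TRUE.
network_forward <- function(net, A, batch, train = FALSE) {
  acts <- list(); caches <- list()
  g <- net$graph
  for (n in net$order) {
    l <- g$layers[[n]]
    ins <- in_edges(g, n)
    x <- if (length(ins)) acts[[ins[1]]]
    y <- switch(l$kind,
      input = A,
      conv = {
        G <- gather_for(net, n, batch)
        x_ext <- rbind(x, 0)
        M <- x_ext[as.vector(G), , drop = FALSE]
        PM <- matrix(array(M, c(nrow(G), ncol(G), ncol(x))), nrow(G))
        if (train) caches[[n]] <- list(PM = PM, G = G, n_in = nrow(x))
        sweep(PM %*% net$params[[n]]$W, 2, net$params[[n]]$b, "+")
      },
      maxpool = {
        G <- gather_for(net, n, batch)
        x_ext <- rbind(x, -Inf)
        k2 <- ncol(G)
        arr <- array(x_ext[as.vector(G), , drop = FALSE],
                     c(nrow(G), k2, ncol(x)))
        y <- arr[, 1, , drop = TRUE]
        if (is.null(dim(y))) y <- matrix(y, nrow(G))
        amax <- matrix(1L, nrow(G), ncol(x))
        if (k2 > 1) for (t in 2:k2) {
          cand <- arr[, t, ]
          if (is.null(dim(cand))) cand <- matrix(cand, nrow(G))
          better <- cand > y
          y[better] <- cand[better]
          amax[better] <- t
        }
        if (train) caches[[n]] <- list(G = G, amax = amax, n_in = nrow(x))
        y
      },
      relu = { if (train) caches[[n]] <- list(pos = x > 0); pmax(x, 0) },
      batchnorm = {
        p <- net$params[[n]]; eps <- 1e-5
        if (train) {
          mu <- colMeans(x)
          v <- colMeans(x^2) - mu^2
          invstd <- 1 / sqrt(v + eps)
          xhat <- sweep(sweep(x, 2, mu, "-"), 2, invstd, "*")
          # running stats handed back through the cache; the training
          # loop owns the network object and applies them
          caches[[n]] <- list(xhat = xhat, invstd = invstd,
                              run_mean = 0.9 * p$run_mean + 0.1 * mu,
                              run_var = 0.9 * p$run_var + 0.1 * v)
          sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
        } else {
          xhat <- sweep(sweep(x, 2, p$run_mean, "-"), 2,
                        1 / sqrt(p$run_var + eps), "*")
          sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
        }
      },
      add = acts[[ins[1]]] + acts[[ins[2]]],
      gap = {
        hw <- nrow(x) / batch
        if (train) caches[[n]] <- list(hw = hw)
        rowsum(x, rep(seq_len(batch), each = hw), reorder = FALSE) / hw
      },
      fc = {
        s_in <- net$shapes[[ins[1]]]
        hw <- s_in[1] * s_in[2]
        flat <- if (hw == 1L) x else
          matrix(aperm(array(x, c(hw, batch, ncol(x))), c(2, 1, 3)), batch)
        if (train) caches[[n]] <- list(flat = flat, hw = hw, cin = ncol(x))
        sweep(flat %*% net$params[[n]]$W, 2, net$params[[n]]$b, "+")
      },
      softmax = {
        z <- x - apply(x, 1, max)
        e <- exp(z)
        e / rowSums(e)
      })
    acts[[n]] <- y
  }
  list(acts = acts, caches = caches)
}

# Cross-entropy of softmax output rows against integer labels (1..k).
cross_entropy_loss <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p, 1e-12)))
}

# Backward pass; returns gradients for every parameterized layer.
# Softmax + cross-entropy is fused: d(logits) = (p - onehot)/B.
network_backward <- function(net, fwd, labels, batch) {
  g <- net$graph
  grads <- list()
  dacts <- list()
  for (n in rev(net$order)) {
    l <- g$layers[[n]]
    ins <- in_edges(g, n)
    if (l$kind == "softmax") {
      p <- fwd$acts[[n]]
      d <- p
      d[cbind(seq_along(labels), labels)] <-
        d[cbind(seq_along(labels), labels)] - 1
      dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + d / batch
      next
    }
    dy <- dacts[[n]]
    if (is.null(dy)) next  # layer not on a path to the loss
    switch(l$kind,
      input = NULL,
      conv = {
        cc <- fwd$caches[[n]]
        W <- net$params[[n]]$W
        grads[[n]] <- list(W = crossprod(cc$PM, dy), b = colSums(dy))
        dPM <- dy %*% t(W)
        k2 <- ncol(cc$G)
        cin <- nrow(W) / k2
        darr <- array(dPM, c(nrow(cc$G), k2, cin))
        dx <- matrix(0, cc$n_in, cin)
        for (t in seq_len(k2)) {
          rows <- cc$G[, t]
          ok <- rows <= cc$n_in
          dt <- darr[, t, , drop = TRUE]
          if (is.null(dim(dt))) dt <- matrix(dt, nrow(cc$G))
          dx[rows[ok], ] <- dx[rows[ok], ] + dt[ok, , drop = FALSE]
        }
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dx
      },
      maxpool = {
        cc <- fwd$caches[[n]]
        k2 <- ncol(cc$G)
        cin <- ncol(dy)
        dx <- matrix(0, cc$n_in, cin)
        for (t in seq_len(k2)) {
          sel <- cc$amax == t
          if (!any(sel)) next
          contrib <- dy * sel
          rows <- cc$G[, t]
          ok <- rows <= cc$n_in
          dx[rows[ok], ] <- dx[rows[ok], ] + contrib[ok, , drop = FALSE]
        }
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dx
      },
      relu = {
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dy * fwd$caches[[n]]$pos
      },
      batchnorm = {
        cc <- fwd$caches[[n]]
        p <- net$params[[n]]
        grads[[n]] <- list(gamma = colSums(dy * cc$xhat), beta = colSums(dy))
        m <- nrow(dy)
        dxhat <- sweep(dy, 2, p$gamma, "*")
        dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dy), byrow = TRUE) -
                      cc$xhat * matrix(colMeans(dxhat * cc$xhat), m, ncol(dy),
                                       byrow = TRUE),
                    2, cc$invstd, "*")
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dx
      },
      add = {
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dy
        dacts[[ins[2]]] <- (dacts[[ins[2]]] %||% 0) + dy
      },
      gap = {
        hw <- fwd$caches[[n]]$hw
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) +
          dy[rep(seq_len(nrow(dy)), each = hw), , drop = FALSE] / hw
      },
      fc = {
        cc <- fwd$caches[[n]]
        grads[[n]] <- list(W = crossprod(cc$flat, dy), b = colSums(dy))
        dflat <- dy %*% t(net$params[[n]]$W)
        dx <- if (cc$hw == 1L) dflat else
          matrix(aperm(array(dflat, c(batch, cc$hw, cc$cin)), c(2, 1, 3)),
                 cc$hw * batch)
        dacts[[ins[1]]] <- (dacts[[ins[1]]] %||% 0) + dx
      })
  }
  grads
}

# One SGDM update; velocity lives in `state` (an environment), the
# updated network is returned. L2 decay applies to weight matrices only
# (not biases or batch-norm affine terms).
sgdm_step <- function(net, grads, state, lr, momentum, l2) {
  for (n in names(grads)) {
    for (pn in names(grads[[n]])) {
      g <- grads[[n]][[pn]]
      if (pn == "W") g <- g + l2 * net$params[[n]][[pn]]
      key <- paste(n, pn)
      v <- state[[key]] %||% 0
      v <- momentum * v - lr * g
      state[[key]] <- v
      net$params[[n]][[pn]] <- net$params[[n]][[pn]] + v
    }
  }
  net
}

# Predict class probabilities for an input activation matrix.
network_predict <- function(net, A, batch) {
  fwd <- network_forward(net, A, batch, train = FALSE)
  fwd$acts[[net$order[length(net$order)]]]
}
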