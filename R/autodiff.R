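## Minimal reverse-mode automatic differentiation on a dynamically built tape.
## Values are plain numeric arrays; nodes are environments so gradients can be
## accumulated in place. Forward evaluation is eager: every ad_* op computes
## its value immediately, so the same network code serves both plain inference
## (read $value) and training (call ad_backward on a scalar loss).

node_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$requires <- length(parents) > 0L && any(vapply(parents, function(p) p$requires, logical(1)))
  e$grad <- NULL
  e$nid <- node_counter()
  class(e) <- "adnode"
  e
}

#' @keywords internal
ad_input <- function(x) {
  n <- ad_node(x)
  n$requires <- FALSE
  n
}

#' @keywords internal
ad_param <- function(x) {
  n <- ad_node(x)
  n$requires <- TRUE
  n
}

is_adnode <- function(x) inherits(x, "adnode")

## Accept plain arrays anywhere a node is expected (treated as constants).
as_adnode <- function(x) if (is_adnode(x)) x else ad_input(x)

ad_value <- function(x) if (is_adnode(x)) x$value else x

## Reverse pass from a scalar root. Topological order by iterative DFS.
ad_backward <- function(root, seed_grad = 1) {
  stopifnot(is_adnode(root))
  order <- list()
  state <- new.env(parent = emptyenv()) # nid -> 0 visiting / 1 done
  stack <- list(list(node = root, phase = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$nid)
    if (top$phase == 1L) {
      if (!is.null(state[[key]])) next
      state[[key]] <- 0L
      stack[[length(stack) + 1L]] <- list(node = nd, phase = 2L)
      for (p in nd$parents) {
        if (p$requires && is.null(state[[as.character(p$nid)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, phase = 1L)
        }
      }
    } else {
      state[[key]] <- 1L
      order[[length(order) + 1L]] <- nd
    }
  }
  for (nd in order) nd$grad <- NULL
  root$grad <- seed_grad
  for (k in rev(seq_along(order))) {
    nd <- order[[k]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    pg <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires || is.null(pg[[i]])) next
      if (is.null(p$grad)) p$grad <- pg[[i]] else p$grad <- p$grad + pg[[i]]
    }
  }
  invisible(root)
}

## ---- elementwise / scalar ops ----

ad_add <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  av <- a$value; bv <- b$value
  ad_node(av / bv, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_scale <- function(a, s) {
  a <- as_adnode(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_shift <- function(a, s) {
  a <- as_adnode(a)
  ad_node(a$value + s, list(a), function(g) list(g))
}

ad_log <- function(a) {
  a <- as_adnode(a)
  av <- a$value
  ad_node(log(av), list(a), function(g) list(g / av))
}

ad_exp <- function(a) {
  a <- as_adnode(a)
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_clamp <- function(a, lo, hi) {
  a <- as_adnode(a)
  av <- a$value
  pass <- (av >= lo) & (av <= hi)
  ad_node(pmin(pmax(av, lo), hi), list(a), function(g) list(g * pass))
}

ad_relu <- function(a) {
  a <- as_adnode(a)
  av <- a$value
  mask <- av > 0
  ad_node(av * mask, list(a), function(g) list(g * mask))
}

ad_leaky_relu <- function(a, alpha = 0.2) {
  a <- as_adnode(a)
  av <- a$value
  slope <- ifelse(av > 0, 1, alpha)
  ad_node(av * slope, list(a), function(g) list(g * slope))
}

ad_sigmoid <- function(a) {
  a <- as_adnode(a)
  v <- 1 / (1 + exp(-a$value))
  ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_gelu <- function(a) {
  a <- as_adnode(a)
  av <- a$value
  phi <- stats::pnorm(av)
  ad_node(av * phi, list(a), function(g) list(g * (phi + av * stats::dnorm(av))))
}

ad_sum_all <- function(a) {
  a <- as_adnode(a)
  d <- dim(a$value)
  n <- length(a$value)
  ad_node(sum(a$value), list(a), function(g) {
    out <- rep(g, n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

ad_mean_all <- function(a) {
  a <- as_adnode(a)
  ad_scale(ad_sum_all(a), 1 / length(a$value))
}

## ---- linear algebra / shape ops ----

ad_matmul <- function(a, b) {
  a <- as_adnode(a); b <- as_adnode(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_reshape <- function(a, dims) {
  a <- as_adnode(a)
  old <- dim(a$value)
  v <- a$value
  dim(v) <- dims
  ad_node(v, list(a), function(g) {
    dim(g) <- old
    list(g)
  })
}

## Bijective index rearrangement: y <- x[idx] with dim(y) = outdim.
ad_permute <- function(a, idx, outdim) {
  a <- as_adnode(a)
  old <- dim(a$value)
  v <- a$value[idx]
  dim(v) <- outdim
  ad_node(v, list(a), function(g) {
    gx <- numeric(length(idx))
    gx[idx] <- as.numeric(g)
    if (!is.null(old)) dim(gx) <- old
    list(gx)
  })
}

## Add a per-column bias vector to an [n, d] matrix (or per-channel to [h,w,c]).
ad_add_bias <- function(x, b) {
  x <- as_adnode(x); b <- as_adnode(b)
  xv <- x$value
  d <- dim(xv)
  nc <- length(b$value)
  m <- matrix(xv, ncol = nc)
  out <- m + rep(b$value, each = nrow(m))
  dim(out) <- d
  ad_node(out, list(x, b), function(g) {
    gm <- matrix(g, ncol = nc)
    list(array(g, dim = d), colSums(gm))
  })
}

ad_softmax_rows <- function(a) {
  a <- as_adnode(a)
  av <- a$value
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  p <- e / rowSums(e)
  ad_node(p, list(a), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

ad_l2norm_rows <- function(a, eps = 1e-12) {
  a <- as_adnode(a)
  av <- a$value
  nrm <- sqrt(rowSums(av * av)) + eps
  y <- av / nrm
  ad_node(y, list(a), function(g) {
    dot <- rowSums(g * y)
    list((g - y * dot) / nrm)
  })
}

## Layer normalisation over the rows of an [n, d] matrix.
ad_layernorm <- function(x, gamma = NULL, beta = NULL, eps = 1e-5) {
  x <- as_adnode(x)
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  if (is.null(gamma)) {
    ad_node(xhat, list(x), function(g) {
      gm <- rowMeans(g)
      gd <- rowMeans(g * xhat)
      list((g - gm - xhat * gd) * inv)
    })
  } else {
    gamma <- as_adnode(gamma); beta <- as_adnode(beta)
    gv <- gamma$value
    y <- sweep(xhat, 2L, gv, "*")
    y <- sweep(y, 2L, beta$value, "+")
    ad_node(y, list(x, gamma, beta), function(g) {
      ggam <- colSums(g * xhat)
      gbet <- colSums(g)
      gh <- sweep(g, 2L, gv, "*")
      gm <- rowMeans(gh)
      gd <- rowMeans(gh * xhat)
      list((gh - gm - xhat * gd) * inv, ggam, gbet)
    })
  }
}

## ---- spatial ops backed by the C++ kernels ----

ad_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_adnode(x); w <- as_adnode(w); b <- as_adnode(b)
  xv <- x$value; wv <- w$value
  dx <- dim(xv); dw <- dim(wv)
  need_gx <- x$requires
  yv <- cpp_conv2d_fwd(as.numeric(xv), dx[1], dx[2], dx[3],
                       as.numeric(wv), dw[1], dw[2], dw[4],
                       as.numeric(b$value), as.integer(stride), as.integer(pad))
  ho <- (dx[1] + 2 * pad - dw[1]) %/% stride + 1L
  wo <- (dx[2] + 2 * pad - dw[2]) %/% stride + 1L
  dim(yv) <- c(ho, wo, dw[4])
  ad_node(yv, list(x, w, b), function(g) {
    r <- cpp_conv2d_bwd(as.numeric(xv), dx[1], dx[2], dx[3],
                        as.numeric(wv), dw[1], dw[2], dw[4],
                        as.numeric(g), as.integer(stride), as.integer(pad), need_gx)
    gx <- if (need_gx) array(r$gx, dim = dx) else NULL
    list(gx, array(r$gw, dim = dw), r$gb)
  })
}

ad_maxpool2 <- function(x) {
  x <- as_adnode(x)
  d <- dim(x$value)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  r <- cpp_maxpool2_fwd(as.numeric(x$value), d[1], d[2], d[3])
  yv <- r$y
  dim(yv) <- c(d[1] %/% 2, d[2] %/% 2, d[3])
  arg <- r$argmax
  ad_node(yv, list(x), function(g) {
    gx <- numeric(prod(d))
    gx[arg] <- gx[arg] + as.numeric(g)
    dim(gx) <- d
    list(gx)
  })
}

ad_resize_bilinear <- function(x, ho, wo) {
  x <- as_adnode(x)
  d <- dim(x$value)
  yv <- cpp_resize_bilinear_fwd(as.numeric(x$value), d[1], d[2], d[3],
                                as.integer(ho), as.integer(wo))
  dim(yv) <- c(ho, wo, d[3])
  ad_node(yv, list(x), function(g) {
    gx <- cpp_resize_bilinear_bwd(as.numeric(g), d[1], d[2], d[3],
                                  as.integer(ho), as.integer(wo))
    dim(gx) <- d
    list(gx)
  })
}

ad_concat_c <- function(xs) {
  xs <- lapply(xs, as_adnode)
  dims <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  h <- dims[[1]][1]; w <- dims[[1]][2]
  vals <- lapply(xs, function(x) as.numeric(x$value))
  yv <- array(unlist(vals), dim = c(h, w, sum(cs)))
  ends <- cumsum(cs)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(yv, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      g[, , starts[i]:ends[i], drop = FALSE]
    })
  })
}

## Bilinear sampling of a [h, w, C] map at K continuous (row, col) positions
## (0-based, constant w.r.t. the graph). Returns [K, C].
ad_sample_bilinear <- function(x, coords) {
  x <- as_adnode(x)
  d <- dim(x$value)
  h <- d[1]; w <- d[2]; C <- d[3]
  K <- nrow(coords)
  r <- pmin(pmax(coords[, 1], 0), h - 1)
  cc <- pmin(pmax(coords[, 2], 0), w - 1)
  i0 <- pmin(floor(r), h - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(cc), w - 2); j0 <- pmax(j0, 0)
  fi <- r - i0; fj <- cc - j0
  xv <- x$value
  out <- matrix(0, K, C)
  wts <- matrix(0, K, 4)
  for (k in seq_len(K)) {
    w00 <- (1 - fi[k]) * (1 - fj[k]); w10 <- fi[k] * (1 - fj[k])
    w01 <- (1 - fi[k]) * fj[k]; w11 <- fi[k] * fj[k]
    wts[k, ] <- c(w00, w10, w01, w11)
    out[k, ] <- w00 * xv[i0[k] + 1, j0[k] + 1, ] + w10 * xv[i0[k] + 2, j0[k] + 1, ] +
      w01 * xv[i0[k] + 1, j0[k] + 2, ] + w11 * xv[i0[k] + 2, j0[k] + 2, ]
  }
  ad_node(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (k in seq_len(K)) {
      gx[i0[k] + 1, j0[k] + 1, ] <- gx[i0[k] + 1, j0[k] + 1, ] + wts[k, 1] * g[k, ]
      gx[i0[k] + 2, j0[k] + 1, ] <- gx[i0[k] + 2, j0[k] + 1, ] + wts[k, 2] * g[k, ]
      gx[i0[k] + 1, j0[k] + 2, ] <- gx[i0[k] + 1, j0[k] + 2, ] + wts[k, 3] * g[k, ]
      gx[i0[k] + 2, j0[k] + 2, ] <- gx[i0[k] + 2, j0[k] + 2, ] + wts[k, 4] * g[k, ]
    }
    list(gx)
  })
}

## ---- matrix slicing helpers used by multi-head attention ----

ad_transpose <- function(x) {
  x <- as_adnode(x)
  ad_node(t(x$value), list(x), function(g) list(t(g)))
}

ad_cols <- function(x, cols) {
  x <- as_adnode(x)
  xv <- x$value
  d <- dim(xv)
  ad_node(xv[, cols, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[, cols] <- g
    list(gx)
  })
}

ad_cbind <- function(xs) {
  xs <- lapply(xs, as_adnode)
  ncols <- vapply(xs, function(x) ncol(x$value), numeric(1))
  ends <- cumsum(ncols)
  starts <- c(1, utils::head(ends, -1) + 1)
  ad_node(do.call(cbind, lapply(xs, function(x) x$value)), xs, function(g) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_softplus <- function(a) {
  a <- as_adnode(a)
  av <- a$value
  v <- pmax(av, 0) + log1p(exp(-abs(av)))
  sig <- 1 / (1 + exp(-av))
  ad_node(v, list(a), function(g) list(g * sig))
}
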