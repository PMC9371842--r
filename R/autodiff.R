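# Reverse-mode automatic differentiation on a dynamic tape.
#
# Every training stage in this package (masked-autoencoder pretraining and
# detector training) differentiates its loss through this small engine. Nodes
# are environments holding a numeric value (scalar, vector or matrix), an
# accumulated gradient, their parent nodes, and a backward closure mapping the
# output gradient to parent gradients. Gradients ACCUMULATE across backward
# passes until ad_zero_grad() is called, which is how minibatches are summed.

.ad_tape <- new.env(parent = emptyenv())
.ad_tape$nodes <- vector("list", 4096L)
.ad_tape$n <- 0L

ad_node <- function(value, parents = list(), backfn = NULL, requires_grad = TRUE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires_grad <- requires_grad
  class(e) <- "ad"
  n <- .ad_tape$n + 1L
  if (n > length(.ad_tape$nodes)) {
    .ad_tape$nodes <- c(.ad_tape$nodes, vector("list", length(.ad_tape$nodes)))
  }
  .ad_tape$nodes[[n]] <- e
  .ad_tape$n <- n
  e
}

#' Create a constant (non-trainable) tape node
#' @param value Numeric scalar, vector or matrix.
#' @return An `ad` node with `requires_grad = FALSE`.
#' @export
ad_const <- function(value) ad_node(value, requires_grad = FALSE)

#' Create a trainable parameter node
#' @param value Initial numeric value (scalar, vector or matrix).
#' @return An `ad` node that receives gradients and is updated by [adam_step()].
#' @export
ad_param <- function(value) ad_node(value)

#' Value of a tape node (or pass-through for plain numerics)
#' @param x An `ad` node or numeric.
#' @return The numeric value.
#' @export
ad_value <- function(x) if (inherits(x, "ad")) x$value else x

as_ad <- function(x) if (inherits(x, "ad")) x else ad_const(x)

accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Runs reverse-mode accumulation through the recorded tape. Tape order is
#' creation order, and every node is created after its parents, so the reverse
#' sweep visits children before parents without an explicit topological sort.
#' Parameter gradients accumulate across calls (minibatch summation); call
#' [ad_zero_grad()] on the parameter list between optimizer steps. The tape is
#' cleared afterwards: each backward pass consumes the forward tape that built
#' its loss.
#'
#' @param root An `ad` node holding a scalar.
#' @export
ad_backward <- function(root) {
  root$grad <- 1
  n_tape <- .ad_tape$n
  nodes <- .ad_tape$nodes
  for (i in n_tape:1) {
    n <- nodes[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    parents <- n$parents
    for (j in seq_along(parents)) {
      p <- parents[[j]]
      if (!is.null(gs[[j]]) && p$requires_grad) {
        if (is.null(p$grad)) p$grad <- gs[[j]] else p$grad <- p$grad + gs[[j]]
      }
    }
  }
  .ad_tape$nodes[seq_len(n_tape)] <- list(NULL)
  .ad_tape$n <- 0L
  invisible(NULL)
}

#' Clear the recorded tape
#'
#' Discards all recorded forward nodes without backpropagating. Used by
#' inference-only code paths so forward passes do not retain memory; parameter
#' nodes and their accumulated gradients are unaffected.
#' @export
ad_tape_reset <- function() {
  .ad_tape$nodes[seq_len(.ad_tape$n)] <- list(NULL)
  .ad_tape$n <- 0L
  invisible(NULL)
}

# evaluate a node's value and drop the tape built to compute it
ad_run <- function(node) {
  v <- ad_value(node)
  ad_tape_reset()
  v
}

## ---- arithmetic ----

#' Matrix product of two tape nodes
#' @param a,b `ad` nodes or numerics (n x k and k x m).
#' @return An `ad` node holding `a %*% b`.
#' @export
ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

#' Elementwise / broadcast addition
#'
#' Adds two same-shape nodes, or broadcasts: a scalar over anything, or a
#' length-`ncol(a)` vector (bias) over the rows of a matrix.
#' @param a,b `ad` nodes or numerics.
#' @return An `ad` node.
#' @export
ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  if (is.matrix(av) && !is.matrix(bv) && length(bv) > 1) {
    # bias broadcast over rows
    stopifnot(length(bv) == ncol(av))
    val <- av + rep(bv, each = nrow(av))
    ad_node(val, list(a, b), function(g) list(g, colSums(g)))
  } else if (is.matrix(bv) && !is.matrix(av) && length(av) > 1) {
    ad_add(b, a)
  } else if (length(av) == 1 && length(bv) > 1) {
    ad_node(bv + as.numeric(av), list(a, b), function(g) list(sum(g), g))
  } else if (length(bv) == 1 && length(av) > 1) {
    ad_node(av + as.numeric(bv), list(a, b), function(g) list(g, sum(g)))
  } else {
    ad_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

#' Elementwise subtraction (same broadcasting as [ad_add()])
#' @param a,b `ad` nodes or numerics.
#' @return An `ad` node.
#' @export
ad_sub <- function(a, b) ad_add(a, ad_scale(as_ad(b), -1))

#' Multiply a node by a fixed scalar
#' @param a An `ad` node or numeric; `s` a plain scalar.
#' @param s Scalar multiplier (not differentiated).
#' @return An `ad` node.
#' @export
ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

#' Elementwise product of two same-shape nodes (or node x scalar node)
#' @param a,b `ad` nodes or numerics.
#' @return An `ad` node.
#' @export
ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  if (length(av) == 1 || length(bv) == 1) {
    ad_node(av * bv, list(a, b), function(g) {
      ga <- g * bv; gb <- g * av
      if (length(av) == 1) ga <- sum(ga)
      if (length(bv) == 1) gb <- sum(gb)
      list(ga, gb)
    })
  } else {
    stopifnot(identical(dim(av), dim(bv)) || length(av) == length(bv))
    ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  }
}

## ---- nonlinearities ----

#' GELU activation (tanh approximation)
#' @param a An `ad` node.
#' @return An `ad` node.
#' @export
ad_gelu <- function(a) {
  a <- as_ad(a)
  x <- a$value
  k <- sqrt(2 / pi)
  inner <- k * (x + 0.044715 * x^3)
  t <- tanh(inner)
  val <- 0.5 * x * (1 + t)
  ad_node(val, list(a), function(g) {
    dinner <- k * (1 + 3 * 0.044715 * x^2)
    dt <- (1 - t^2) * dinner
    list(g * (0.5 * (1 + t) + 0.5 * x * dt))
  })
}

#' ReLU activation
#' @param a An `ad` node.
#' @return An `ad` node.
#' @export
ad_relu <- function(a) {
  a <- as_ad(a)
  ad_node(pmax(a$value, 0), list(a), function(g) list(g * (a$value > 0)))
}

#' Logistic sigmoid
#' @param a An `ad` node.
#' @return An `ad` node.
#' @export
ad_sigmoid <- function(a) {
  a <- as_ad(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' Elementwise exponential
#' @param a An `ad` node.
#' @return An `ad` node.
#' @export
ad_exp <- function(a) {
  a <- as_ad(a)
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

#' Elementwise natural log
#' @param a An `ad` node.
#' @return An `ad` node.
#' @export
ad_log <- function(a) {
  a <- as_ad(a)
  ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

## ---- structural ops ----

#' Gather rows of a matrix node (with repetition allowed)
#' @param a An `ad` node holding a matrix.
#' @param idx 1-based row indices.
#' @return An `ad` node with `length(idx)` rows; the backward pass scatter-adds.
#' @export
ad_gather_rows <- function(a, idx) {
  a <- as_ad(a)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

#' Stack matrix nodes by rows
#' @param nodes List of `ad` nodes with equal column counts.
#' @return An `ad` node holding the row-concatenation.
#' @export
ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$value)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ad_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

#' Concatenate matrix nodes by columns
#' @param nodes List of `ad` nodes with equal row counts.
#' @return An `ad` node holding the column-concatenation.
#' @export
ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_ad)
  vals <- lapply(nodes, function(n) n$value)
  nc <- vapply(vals, ncol, integer(1))
  ends <- cumsum(nc)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ad_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

#' Select columns of a matrix node
#' @param a An `ad` node holding a matrix.
#' @param idx 1-based column indices.
#' @return An `ad` node.
#' @export
ad_cols <- function(a, idx) {
  a <- as_ad(a)
  ad_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- t(rowsum(t(g), group = idx))  # accumulates duplicated columns
    out[, as.integer(colnames(agg))] <- agg
    list(out)
  })
}

#' Transpose a matrix node
#' @param a An `ad` node holding a matrix.
#' @return An `ad` node holding `t(a)`.
#' @export
ad_transpose <- function(a) {
  a <- as_ad(a)
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

## ---- normalization / attention ----

#' Row-wise softmax, optionally with an additive mask
#'
#' @param a An `ad` node holding an n x m matrix of scores.
#' @param mask Optional plain n x m matrix added to the scores before the
#'   softmax (use large negative entries, e.g. -1e9, to forbid pairs).
#' @return An `ad` node whose rows sum to 1.
#' @export
ad_softmax_rows <- function(a, mask = NULL) {
  a <- as_ad(a)
  z <- a$value
  if (!is.null(mask)) z <- z + mask
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

#' Row-wise layer normalization with learnable gain and bias
#'
#' Each row is centred and scaled to unit variance (epsilon-stabilised), then
#' multiplied by `gamma` and shifted by `beta` per column.
#'
#' @param a An `ad` node holding an n x d matrix.
#' @param gamma,beta `ad` nodes holding length-d vectors.
#' @param eps Variance stabiliser.
#' @return An `ad` node, same shape as `a`.
#' @export
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ad(a); gamma <- as_ad(gamma); beta <- as_ad(beta)
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  nr <- nrow(x)
  val <- xhat * rep(as.numeric(gamma$value), each = nr) +
    rep(as.numeric(beta$value), each = nr)
  ad_node(val, list(a, gamma, beta), function(g) {
    gxhat <- g * rep(as.numeric(gamma$value), each = nr)
    # standard layernorm backward per row
    gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(gx, colSums(g * xhat), colSums(g))
  })
}

## ---- reductions / losses ----

#' Sum of all elements
#' @param a An `ad` node.
#' @return A scalar `ad` node.
#' @export
ad_sum <- function(a) {
  a <- as_ad(a)
  ad_node(sum(a$value), list(a), function(g) {
    list(array(g, dim = if (is.matrix(a$value)) dim(a$value) else length(a$value)))
  })
}

#' Mean of all elements
#' @param a An `ad` node.
#' @return A scalar `ad` node.
#' @export
ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(ad_value(a)))

#' Mean squared error against a fixed target
#'
#' `mean((a - target)^2)` over all elements, optionally restricted by a 0/1
#' `weight` mask (mean over the selected elements).
#'
#' @param a An `ad` node (predictions).
#' @param target Plain numeric array, same shape.
#' @param weight Optional 0/1 mask, same shape.
#' @return A scalar `ad` node.
#' @export
ad_mse <- function(a, target, weight = NULL) {
  a <- as_ad(a)
  d <- a$value - target
  if (is.null(weight)) {
    n <- length(d)
    ad_node(sum(d^2) / n, list(a), function(g) list(g * 2 * d / n))
  } else {
    n <- max(sum(weight), 1)
    ad_node(sum(weight * d^2) / n, list(a), function(g) list(g * 2 * weight * d / n))
  }
}

#' Binary cross-entropy on logits against fixed targets
#'
#' Numerically stable `mean(max(x,0) - x*t + log(1+exp(-|x|)))`, optionally
#' weighted per element (weighted mean with weight-sum normalisation).
#'
#' @param x An `ad` node of logits.
#' @param t Plain numeric targets in `[0,1]`, same shape.
#' @param weight Optional nonnegative weights, same shape.
#' @return A scalar `ad` node.
#' @export
ad_bce_logits <- function(x, t, weight = NULL) {
  x <- as_ad(x)
  xv <- x$value
  per <- pmax(xv, 0) - xv * t + log1p(exp(-abs(xv)))
  s <- 1 / (1 + exp(-xv))
  if (is.null(weight)) {
    n <- length(xv)
    ad_node(sum(per) / n, list(x), function(g) list(g * (s - t) / n))
  } else {
    n <- max(sum(weight), 1e-12)
    ad_node(sum(weight * per) / n, list(x), function(g) list(g * weight * (s - t) / n))
  }
}

## ---- parameters and optimizer ----

#' Flatten a nested parameter structure into a list of `ad` parameter nodes
#' @param params Arbitrarily nested list containing `ad` nodes.
#' @return Flat list of the `ad` nodes found.
#' @export
ad_param_list <- function(params) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ad")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(params)
  out
}

#' Zero the gradients of a parameter set
#' @param params Nested list of `ad` nodes (or flat list).
#' @export
ad_zero_grad <- function(params) {
  for (p in ad_param_list(params)) p$grad <- NULL
  invisible(NULL)
}

#' Initialise Adam optimizer state
#' @param params Nested list of `ad` parameter nodes.
#' @param lr Learning rate (default 1e-4, the pipeline's training default).
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @param weight_decay L2 penalty coefficient added to gradients (default
#'   5e-4, the pipeline's training default).
#' @return An optimizer state list for [adam_step()].
#' @export
adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 5e-4) {
  flat <- ad_param_list(params)
  list(params = flat, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, t = 0L,
       m = lapply(flat, function(p) ad_value(p) * 0),
       v = lapply(flat, function(p) ad_value(p) * 0))
}

#' One Adam update step (in place on the parameter nodes)
#' @param opt State from [adam_init()].
#' @return The updated state (pass it back in next step).
#' @export
adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * p$value
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# Gaussian init scaled like truncated-normal transformer init.
init_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

# Linear layer constructor + application on the tape.
linear_init <- function(d_in, d_out, sd = 0.02, zero = FALSE) {
  list(W = ad_param(if (zero) matrix(0, d_in, d_out) else init_mat(d_in, d_out, sd)),
       b = ad_param(rep(0, d_out)))
}

linear_apply <- function(layer, x) ad_add(ad_matmul(x, layer$W), layer$b)

layernorm_init <- function(d) list(gamma = ad_param(rep(1, d)), beta = ad_param(rep(0, d)))
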