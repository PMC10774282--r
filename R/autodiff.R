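# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value in a computation graph is an environment ("ad node") holding a
# numeric matrix, its parents, and a backward closure that pushes the node's
# gradient into its parents.  Graphs are built eagerly; ad_backward() runs a
# reverse topological sweep.  This is deliberately small: just the operations
# the subtype model needs, each with an analytic adjoint that is checked
# against finite differences in the test suite.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$id <- 0L

.ad_next_id <- function() {
  .ad_counter$id <- .ad_counter$id + 1L
  .ad_counter$id
}

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

#' Create a computation-graph node
#'
#' @param value numeric matrix held by the node.
#' @param parents list of parent nodes.
#' @param backward function(grad) returning a list of gradients, one per
#'   parent, each conforming to the parent's dimensions.
#' @return an `ad_node` environment.
#' @keywords internal
ad_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$grad <- NULL
  e$id <- .ad_next_id()
  class(e) <- "ad_node"
  e
}

#' @keywords internal
ad_const <- function(x) ad_node(.as_mat(x))

#' Leaf node holding trainable weights
#' @keywords internal
ad_param <- function(x) {
  n <- ad_node(.as_mat(x))
  n$is_param <- TRUE
  n
}

is_ad <- function(x) inherits(x, "ad_node")

.wrap <- function(x) if (is_ad(x)) x else ad_const(x)

#' Value of a node (plain matrix)
#' @keywords internal
ad_value <- function(x) x$value

# ---- arithmetic ------------------------------------------------------------

ad_add <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b)
  av <- a$value; bv <- b$value
  if (length(bv) == 1L) {
    return(ad_node(av + bv[1L], list(a, b), function(g)
      list(g, matrix(sum(g), 1L, 1L))))
  }
  if (length(av) == 1L) {
    return(ad_node(bv + av[1L], list(a, b), function(g)
      list(matrix(sum(g), 1L, 1L), g)))
  }
  if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, bv, "+")
  } else if (nrow(av) == 1L && nrow(bv) > 1L) {
    val <- sweep(bv, 2L, av, "+")
  } else {
    val <- av + bv
  }
  ad_node(val, list(a, b), function(g) {
    ga <- if (nrow(av) == 1L && nrow(.as_mat(g)) > 1L) matrix(colSums(g), 1L) else g
    gb <- if (nrow(bv) == 1L && nrow(.as_mat(g)) > 1L) matrix(colSums(g), 1L) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b)
  av <- a$value; bv <- b$value
  if (length(bv) == 1L && length(av) > 1L) {
    return(ad_node(av - bv[1L], list(a, b), function(g)
      list(g, matrix(-sum(g), 1L, 1L))))
  }
  if (length(av) == 1L && length(bv) > 1L) {
    return(ad_node(av[1L] - bv, list(a, b), function(g)
      list(matrix(sum(g), 1L, 1L), -g)))
  }
  ad_node(av - bv, list(a, b), function(g) {
    gb <- if (nrow(bv) == 1L && nrow(.as_mat(g)) > 1L) -matrix(colSums(g), 1L) else -g
    ga <- if (nrow(av) == 1L && nrow(.as_mat(g)) > 1L) matrix(colSums(g), 1L) else g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b)
  av <- a$value; bv <- b$value
  if (length(bv) == 1L) {
    ad_node(av * bv[1L], list(a, b), function(g)
      list(g * bv[1L], matrix(sum(g * av), 1L, 1L)))
  } else if (length(av) == 1L) {
    ad_node(bv * av[1L], list(a, b), function(g)
      list(matrix(sum(g * bv), 1L, 1L), g * av[1L]))
  } else if (ncol(bv) == 1L && ncol(av) > 1L) {
    # column-vector broadcast across columns of a (per-row weights)
    val <- av * as.vector(bv)
    ad_node(val, list(a, b), function(g)
      list(g * as.vector(bv), matrix(rowSums(g * av), ncol = 1L)))
  } else {
    ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
  }
}

ad_scale <- function(a, s) {
  a <- .wrap(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

ad_cbind <- function(...) {
  nodes <- lapply(list(...), .wrap)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  val <- do.call(cbind, lapply(nodes, ad_value))
  ad_node(val, nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[, (at + 1L):(at + widths[i]), drop = FALSE]
      at <- at + widths[i]
    }
    out
  })
}

ad_slice_cols <- function(a, idx) {
  a <- .wrap(a)
  av <- a$value
  ad_node(av[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, idx] <- ga[, idx] + g
    list(ga)
  })
}

# ---- nonlinearities --------------------------------------------------------

ad_leaky_relu <- function(a, slope = 0.2) {
  a <- .wrap(a)
  av <- a$value
  fac <- (av > 0) * (1 - slope) + slope
  ad_node(av * fac, list(a), function(g) list(g * fac))
}

ad_sigmoid <- function(a) {
  a <- .wrap(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_softplus <- function(a) {
  a <- .wrap(a)
  av <- a$value
  # numerically stable log(1 + exp(x))
  val <- pmax(av, 0) + log1p(exp(-abs(av)))
  sig <- 1 / (1 + exp(-av))
  ad_node(val, list(a), function(g) list(g * sig))
}

ad_exp <- function(a) {
  a <- .wrap(a)
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  a <- .wrap(a)
  av <- a$value
  ad_node(log(av), list(a), function(g) list(g / av))
}

ad_square <- function(a) {
  a <- .wrap(a)
  av <- a$value
  ad_node(av^2, list(a), function(g) list(2 * g * av))
}

ad_abs <- function(a) {
  a <- .wrap(a)
  av <- a$value
  ad_node(abs(av), list(a), function(g) list(g * sign(av)))
}

# Clamp with pass-blocked gradient outside the interval (standard subgradient).
ad_clamp <- function(a, lo, hi) {
  a <- .wrap(a)
  av <- a$value
  inside <- av >= lo & av <= hi
  ad_node(pmin(pmax(av, lo), hi), list(a), function(g)
    list(g * inside))
}

ad_softmax_rows <- function(a) {
  a <- .wrap(a)
  av <- a$value
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

# ---- reductions ------------------------------------------------------------

ad_sum <- function(a) {
  a <- .wrap(a)
  av <- a$value
  ad_node(matrix(sum(av), 1L, 1L), list(a), function(g)
    list(matrix(g[1L], nrow(av), ncol(av))))
}

ad_mean <- function(a) {
  a <- .wrap(a)
  av <- a$value
  n <- length(av)
  ad_node(matrix(mean(av), 1L, 1L), list(a), function(g)
    list(matrix(g[1L] / n, nrow(av), ncol(av))))
}

ad_rowsums <- function(a) {
  a <- .wrap(a)
  av <- a$value
  ad_node(matrix(rowSums(av), ncol = 1L), list(a), function(g)
    list(matrix(as.vector(g), nrow(av), ncol(av))))
}

# ---- backward sweep --------------------------------------------------------

#' Run reverse-mode differentiation from a scalar node
#'
#' Accumulates `$grad` on every node reachable from `loss`.
#' @param loss scalar `ad_node` (1 x 1 value).
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # iterative DFS topological order (avoid recursion limits)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  for (n in order) n$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# ---- Adam optimizer --------------------------------------------------------

#' Create Adam optimizer state for a list of parameter nodes
#' @keywords internal
adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = lapply(params, function(p) p$value * 0),
       v = lapply(params, function(p) p$value * 0),
       t = 0L)
}

#' Apply one Adam update from the gradients currently on the parameters
#' @keywords internal
adam_step <- function(opt, lr = NULL) {
  opt$t <- opt$t + 1L
  lr <- if (is.null(lr)) opt$lr else lr
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g^2
    p$value <- p$value - lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  opt
}

#' Clear gradients on a list of parameter nodes
#' @keywords internal
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
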