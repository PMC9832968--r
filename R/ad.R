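# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The networks in this package are small (tens of units, a few thousand
# weights), so a lightweight tape over vectorized base-R matrix operations is
# fast enough for full training runs while keeping every loss term exact and
# auditable. Nodes are recorded in creation order; backward() walks the tape
# in reverse, accumulating vector-Jacobian products. All values are numeric
# matrices (scalars are 1x1).

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

# internal: push a node, return its id
ad_push <- function(tape, value, parents = integer(0), backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, backward = backward)
  tape$n <- n
  n
}

ad_value <- function(tape, id) tape$nodes[[id]]$value

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# leaf holding data we do not differentiate through
ad_const <- function(tape, value) ad_push(tape, as_mat(value))

# leaf we want gradients for
ad_param <- function(tape, value) ad_push(tape, as_mat(value))

ad_matmul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$nodes[[a]]$value
  B <- tape$nodes[[b]]$value
  ad_push(tape, A %*% B, c(a, b), function(g) {
    list(g %*% t(B), crossprod(A, g))
  })
}

# elementwise binary ops; shapes must match, or one operand is 1x1 (broadcast)
ad_bcast <- function(G, target) {
  if (length(target) == 1L && length(G) > 1L) matrix(sum(G), 1L, 1L) else G
}

ad_add <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$nodes[[a]]$value
  B <- tape$nodes[[b]]$value
  V <- if (length(A) == 1L) A[1L] + B else if (length(B) == 1L) A + B[1L] else A + B
  ad_push(tape, as_mat(V), c(a, b), function(g) {
    list(ad_bcast(g, A), ad_bcast(g, B))
  })
}

ad_sub <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$nodes[[a]]$value
  B <- tape$nodes[[b]]$value
  V <- if (length(A) == 1L) A[1L] - B else if (length(B) == 1L) A - B[1L] else A - B
  ad_push(tape, as_mat(V), c(a, b), function(g) {
    list(ad_bcast(g, A), ad_bcast(-g, B))
  })
}

ad_mul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$nodes[[a]]$value
  B <- tape$nodes[[b]]$value
  V <- if (length(A) == 1L) A[1L] * B else if (length(B) == 1L) A * B[1L] else A * B
  ad_push(tape, as_mat(V), c(a, b), function(g) {
    gA <- if (length(B) == 1L) g * B[1L] else g * B
    gB <- if (length(A) == 1L) g * A[1L] else g * A
    list(ad_bcast(gA, A), ad_bcast(gB, B))
  })
}

# multiply by a constant (numeric, not a node)
ad_scale <- function(tape, a, k) {
  force(a)
  A <- tape$nodes[[a]]$value
  V <- if (length(k) == 1L) A * k else {
    stopifnot(length(k) == length(A) || is.matrix(k))
    A * k
  }
  ad_push(tape, as_mat(V), a, function(g) list(as_mat(g * k)))
}

# add a constant offset
ad_shift <- function(tape, a, k) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, as_mat(A + k), a, function(g) list(g))
}

# matrix (n x p) plus a bias row-vector node (1 x p or length-p)
ad_add_bias <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$nodes[[a]]$value
  bv <- as.numeric(tape$nodes[[b]]$value)
  stopifnot(ncol(A) == length(bv))
  ad_push(tape, sweep(A, 2L, bv, "+"), c(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_neg <- function(tape, a) ad_scale(tape, a, -1)

ad_exp <- function(tape, a) {
  force(a)
  V <- exp(tape$nodes[[a]]$value)
  ad_push(tape, V, a, function(g) list(g * V))
}

ad_log <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, log(A), a, function(g) list(g / A))
}

ad_sqrt <- function(tape, a) {
  force(a)
  V <- sqrt(tape$nodes[[a]]$value)
  ad_push(tape, V, a, function(g) list(g / (2 * V)))
}

ad_square <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, A * A, a, function(g) list(2 * g * A))
}

ad_tanh <- function(tape, a) {
  force(a)
  V <- tanh(tape$nodes[[a]]$value)
  ad_push(tape, V, a, function(g) list(g * (1 - V * V)))
}

ad_sigmoid <- function(tape, a) {
  force(a)
  V <- plogis(tape$nodes[[a]]$value)
  ad_push(tape, V, a, function(g) list(g * V * (1 - V)))
}

# numerically stable log(1 + exp(x)); gradient is sigmoid(x)
ad_softplus <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  V <- pmax(A, 0) + log1p(exp(-abs(A)))
  ad_push(tape, V, a, function(g) list(g * plogis(A)))
}

# clamp with zero gradient outside [lo, hi]
ad_clip <- function(tape, a, lo, hi) {
  force(a)
  A <- tape$nodes[[a]]$value
  V <- pmin(pmax(A, lo), hi)
  inside <- (A >= lo & A <= hi) * 1
  ad_push(tape, V, a, function(g) list(g * inside))
}

ad_abs <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, abs(A), a, function(g) list(g * sign(A)))
}

ad_sum <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, matrix(sum(A), 1L, 1L), a, function(g) {
    list(matrix(g[1L], nrow(A), ncol(A)))
  })
}

ad_mean <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, matrix(mean(A), 1L, 1L), a, function(g) {
    list(matrix(g[1L] / length(A), nrow(A), ncol(A)))
  })
}

# row sums of an n x p matrix -> n x 1
ad_rowsums <- function(tape, a) {
  force(a)
  A <- tape$nodes[[a]]$value
  ad_push(tape, matrix(rowSums(A), ncol = 1L), a, function(g) {
    list(matrix(g, nrow(A), ncol(A)))
  })
}

# run reverse-mode accumulation from scalar node `root`;
# returns list of gradients indexed by node id (only ids in `wanted` kept)
ad_backward <- function(tape, root, wanted) {
  grads <- vector("list", tape$n)
  rv <- tape$nodes[[root]]$value
  stopifnot(length(rv) == 1L)
  grads[[root]] <- matrix(1, 1L, 1L)
  for (i in seq.int(root, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    grads[[i]] <- NULL # free
  }
  out <- vector("list", length(wanted))
  names(out) <- names(wanted)
  for (k in seq_along(wanted)) {
    g <- grads[[wanted[[k]]]]
    v <- tape$nodes[[wanted[[k]]]]$value
    out[[k]] <- if (is.null(g)) matrix(0, nrow(v), ncol(v)) else g
  }
  out
}
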