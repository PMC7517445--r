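#' @useDynLib acaunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median
#' @importFrom utils write.csv modifyList
NULL

# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every tensor flowing through the network is a "node": an environment
# holding the forward value, references to its parent nodes, and a closure
# that maps the gradient at the node to gradients at each parent. The
# network forward pass builds the graph; backward_ag() traverses it once in
# reverse topological order. Trainable parameters live in persistent
# environments (see new_param) so optimiser state survives across graphs.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L
.ag$grad <- TRUE

grad_enabled <- function() isTRUE(.ag$grad)

# evaluate expr without caching backward buffers (inference mode)
with_no_grad <- function(expr) {
  old <- .ag$grad
  .ag$grad <- FALSE
  on.exit(.ag$grad <- old)
  expr
}

new_node <- function(value, parents = list(), backward = NULL, pref = NULL) {
  .ag$counter <- .ag$counter + 1L
  node <- new.env(parent = emptyenv())
  node$id <- .ag$counter
  node$value <- value
  # without gradients there is no backward traversal; dropping the links
  # lets intermediate activations be garbage-collected during inference
  if (!grad_enabled() && length(parents)) {
    parents <- list()
    backward <- NULL
  }
  node$parents <- parents
  node$backward <- backward
  node$pref <- pref
  node$grad <- NULL
  class(node) <- "ag_node"
  node
}

is_node <- function(x) inherits(x, "ag_node")

#' @noRd
ag_input <- function(value) new_node(value)

# p: parameter environment created by new_param()
ag_use_param <- function(p) new_node(p$value, pref = p)

#' Create a trainable parameter
#' @noRd
new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0      # same shape; vectors stay dimensionless
  class(p) <- "ag_param"
  p
}

zero_grads <- function(params) {
  for (p in params) p$grad[] <- 0
  invisible(params)
}

# reverse topological order by node id (ids increase along construction,
# and every parent is created before its child)
topo_sort <- function(root) {
  seen <- new.env(parent = emptyenv())
  nodes <- list()
  stack <- list(root)
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes[order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)]
}

add_grad <- function(node, g) {
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
}

#' Backpropagate from a scalar node
#'
#' Accumulates gradients into every reachable parameter environment.
#' @noRd
backward_ag <- function(root, seed = 1) {
  root$grad <- array(seed, dim = dim(root$value) %||% length(root$value))
  ordered <- topo_sort(root)
  for (nd in ordered) {
    if (is.null(nd$grad)) next       # not on a path to the root
    if (!is.null(nd$pref)) {
      g <- nd$grad
      if (is.null(dim(nd$pref$grad))) {
        nd$pref$grad <- nd$pref$grad + as.vector(g)
      } else {
        nd$pref$grad <- nd$pref$grad + array(g, dim = dim(nd$pref$grad))
      }
    }
    if (!is.null(nd$backward)) {
      gs <- nd$backward(nd$grad)
      for (i in seq_along(nd$parents)) {
        if (!is.null(gs[[i]])) add_grad(nd$parents[[i]], gs[[i]])
      }
    }
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# value extraction for public array-in/array-out wrappers
node_value <- function(x) if (is_node(x)) x$value else x
as_node <- function(x) if (is_node(x)) x else ag_input(x)
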