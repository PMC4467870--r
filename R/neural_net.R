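# Single-hidden-layer sigmoid multilayer perceptron, written from scratch:
# propagation S_i = sum_n w_ni x_n + b_i, activation y = 1/(1 + exp(-S)),
# error E = 1/2 sum (d - y)^2, trained by online backpropagation with
# momentum for a fixed number of cycles (overfitting is controlled by the
# cycle count, not by early stopping). The hidden and output layers use
# identical propagation/activation math.

#' Parse a topology string
#'
#' Topologies are written `input-intermediate-output`, e.g. `"10-18-1"` for
#' 10 input neurons, 18 intermediate neurons and 1 output neuron.
#'
#' @param text topology string.
#' @return A `topology` object (named integer list).
#' @export
#' @examples
#' parse_topology("25-41-3")
parse_topology <- function(text) {
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(parts) != 3 || !all(grepl("^[0-9]+$", parts)))
    stop("malformed topology: '", text, "' (expected 'a-b-c')")
  v <- as.integer(parts)
  if (any(v < 1)) stop("topology neurons must be positive: '", text, "'")
  structure(list(n_input = v[1], n_intermediate = v[2], n_output = v[3]),
            class = "topology")
}

#' @rdname parse_topology
#' @param topology a `topology` object.
#' @export
format_topology <- function(topology) {
  paste(topology$n_input, topology$n_intermediate, topology$n_output, sep = "-")
}

#' Initialize a network
#'
#' Weights and biases drawn independently from U[-0.5, 0.5] with the given
#' seed; identical (topology, seed) pairs give identical networks.
#'
#' @param topology a `topology` or topology string.
#' @param seed integer seed.
#' @return An `mlp_net`: list with `topology`, `W1` (input x hidden), `b1`,
#'   `W2` (hidden x output), `b2`, `seed`.
#' @export
init_network <- function(topology, seed = 1L) {
  if (is.character(topology)) topology <- parse_topology(topology)
  ni <- topology$n_input; nh <- topology$n_intermediate; no <- topology$n_output
  vals <- withr_seed(seed, stats::runif(ni * nh + nh + nh * no + no, -0.5, 0.5))
  k <- 0
  W1 <- matrix(vals[k + seq_len(ni * nh)], ni, nh); k <- k + ni * nh
  b1 <- vals[k + seq_len(nh)]; k <- k + nh
  W2 <- matrix(vals[k + seq_len(nh * no)], nh, no); k <- k + nh * no
  b2 <- vals[k + seq_len(no)]
  structure(list(topology = topology, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 seed = as.integer(seed)),
            class = "mlp_net")
}

#' @noRd
sigmoid <- function(s) 1 / (1 + exp(-s))

#' Forward propagation
#'
#' Applies the propagation and activation equations layer-wise: hidden
#' activations `sigmoid(x %*% W1 + b1)`, outputs
#' `sigmoid(hidden %*% W2 + b2)`. Outputs are strictly inside (0, 1) for
#' finite weights.
#'
#' @param net an `mlp_net`.
#' @param x numeric vector (one example) or matrix (rows = examples) with
#'   `n_input` columns.
#' @return List with `hidden` and `output` matrices (rows = examples).
#' @export
net_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$topology$n_input)
    stop("input length ", ncol(x), " does not match n_input ",
         net$topology$n_input)
  h <- sigmoid(sweep(x %*% net$W1, 2, net$b1, "+"))
  y <- sigmoid(sweep(h %*% net$W2, 2, net$b2, "+"))
  list(hidden = h, output = y)
}

#' Sum-of-squares network error
#'
#' `E = 1/2 * sum((desired - predicted)^2)`.
#'
#' @param desired,predicted numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' sse_error(c(1, 0), c(0.5, 0.5))  # 0.25
sse_error <- function(desired, predicted) {
  if (length(desired) != length(predicted)) stop("length mismatch")
  0.5 * sum((desired - predicted)^2)
}

#' Analytic gradient of the total error
#'
#' Gradient of `sum_examples E` with respect to all weights and biases at
#' fixed weights (no updates), used for gradient checking and as the
#' reference for the compiled online trainer's per-example step.
#'
#' @param net an `mlp_net`.
#' @param x input matrix (rows = examples).
#' @param d desired output matrix.
#' @return List with `W1`, `b1`, `W2`, `b2` gradients.
#' @export
net_gradient <- function(net, x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  fw <- net_forward(net, x)
  h <- fw$hidden; y <- fw$output
  delo <- (y - d) * y * (1 - y)
  delh <- (delo %*% t(net$W2)) * h * (1 - h)
  list(W1 = t(x) %*% delh, b1 = colSums(delh),
       W2 = t(h) %*% delo, b2 = colSums(delo))
}

#' Train a network by online backpropagation
#'
#' Per-example gradient descent on the sum-of-squares error with momentum.
#' One cycle is one pass over all training rows, reshuffled each cycle with
#' the training seed; exactly `cycles` cycles are run (no early stopping).
#' `cycles = 0` returns the network unchanged.
#'
#' @param net an `mlp_net`.
#' @param inputs numeric matrix (rows = examples), ideally scaled to [0, 1].
#' @param targets numeric matrix of desired outputs in [0, 1].
#' @param cycles number of training cycles.
#' @param learning_rate positive step size.
#' @param momentum momentum coefficient in [0, 1).
#' @param seed RNG seed for the per-cycle shuffles.
#' @param shuffle reshuffle example order each cycle.
#' @return The trained `mlp_net`, with the per-cycle error trace in
#'   attribute `"trace"`.
#' @export
train_network <- function(net, inputs, targets, cycles,
                          learning_rate = 0.6, momentum = 0.8,
                          seed = net$seed, shuffle = TRUE) {
  inputs <- as.matrix(inputs); targets <- as.matrix(targets)
  if (nrow(inputs) != nrow(targets)) stop("row counts of inputs and targets differ")
  if (ncol(inputs) != net$topology$n_input) stop("input width mismatch")
  if (ncol(targets) != net$topology$n_output) stop("target width mismatch")
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0, 1]")
  if (cycles == 0) {
    attr(net, "trace") <- numeric(0)
    return(net)
  }
  res <- withr_seed(seed, train_mlp_cpp(net$W1, net$b1, net$W2, net$b2,
                                        inputs, targets, as.integer(cycles),
                                        learning_rate, momentum, shuffle))
  if (res$bad_cycle > 0)
    stop("non-finite training error at cycle ", res$bad_cycle)
  net$W1 <- res$W1; net$b1 <- as.numeric(res$b1)
  net$W2 <- res$W2; net$b2 <- as.numeric(res$b2)
  attr(net, "trace") <- as.numeric(res$trace)
  net
}

#' Decode network outputs to class labels
#'
#' Each output neuron carries one categorical variable; its value is
#' decoded to the nearest equal-spaced code of that variable's codebook.
#'
#' @param net an `mlp_net`.
#' @param inputs input matrix.
#' @param codebooks named list, one ordered level vector per output neuron
#'   (in output-column order).
#' @return Data frame of predicted labels, one column per output variable.
#' @export
predict_classes <- function(net, inputs, codebooks) {
  if (length(codebooks) != net$topology$n_output)
    stop("need one codebook per output neuron")
  y <- net_forward(net, as.matrix(inputs))$output
  out <- as.data.frame(
    lapply(seq_along(codebooks), function(k) decode_target(y[, k], codebooks[[k]])),
    stringsAsFactors = FALSE, col.names = names(codebooks)
  )
  names(out) <- names(codebooks)
  out
}

#' Serialize / restore a network (JSON)
#'
#' Stores topology, weights, biases, seed and optional input scaling
#' statistics and codebooks, so a saved model evaluates identically after
#' reloading.
#'
#' @param net an `mlp_net`.
#' @param path file path.
#' @param scaling optional list with `min`/`max` named vectors.
#' @param codebooks optional named list of level vectors.
#' @export
write_network <- function(net, path, scaling = NULL, codebooks = NULL) {
  obj <- list(
    schema = "tomauth-mlp/1",
    topology = format_topology(net$topology),
    W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
    seed = net$seed,
    input_names = rownames(net$W1)
  )
  if (!is.null(scaling))
    obj$scaling <- list(min = as.list(scaling$min), max = as.list(scaling$max))
  if (!is.null(codebooks)) obj$codebooks <- codebooks
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(obj$schema, "tomauth-mlp/1")) stop("unrecognized model schema")
  topo <- parse_topology(obj$topology)
  net <- structure(
    list(topology = topo,
         W1 = matrix(obj$W1, topo$n_input, topo$n_intermediate),
         b1 = as.numeric(obj$b1),
         W2 = matrix(obj$W2, topo$n_intermediate, topo$n_output),
         b2 = as.numeric(obj$b2),
         seed = as.integer(obj$seed)),
    class = "mlp_net"
  )
  if (!is.null(obj$input_names) && length(obj$input_names))
    rownames(net$W1) <- obj$input_names
  if (!is.null(obj$scaling))
    attr(net, "scaling") <- list(min = unlist(obj$scaling$min),
                                 max = unlist(obj$scaling$max))
  if (!is.null(obj$codebooks))
    attr(net, "codebooks") <- lapply(obj$codebooks, as.character)
  net
}

#' @export
print.mlp_net <- function(x, ...) {
  cat("sigmoid MLP", format_topology(x$topology), "(seed", x$seed, ")\n")
  invisible(x)
}
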