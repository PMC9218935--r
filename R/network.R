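#' Create an empty network specification
#'
#' A `network_spec` is a framework-independent directed acyclic graph of layer
#' specifications. Nodes are appended in topological order (every node may only
#' reference previously added nodes), and exactly one node is designated the
#' network output. Shapes are stored as `c(channels, height, width)`.
#'
#' @param name identifier for the architecture.
#' @param input_shape integer vector `c(channels, height, width)` of the
#'   primary input. An input node named `"input"` is created automatically.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(name, input_shape) {
  stopifnot(length(input_shape) == 3, all(input_shape >= 1))
  net <- structure(
    list(name = name, input_shape = as.integer(input_shape),
         nodes = list(), output = NULL, last_fusion = NULL),
    class = "network_spec"
  )
  net_add(net, "input", "input", shape = as.integer(input_shape))
}

#' Append a node to a network specification
#'
#' @param net a `network_spec`.
#' @param id unique node identifier.
#' @param kind one of `"input"`, `"conv"`, `"ghost"`, `"deconv"`,
#'   `"maxpool"`, `"bilinear_up"`, `"add"`, `"concat"`.
#' @param inputs character vector of producer node ids (must already exist).
#' @param ... kind-specific fields: `kernel`, `out_channels`, `bias`,
#'   `batchnorm`, `activation`, `cheap_kernel`, `ratio`, `factor`, `shape`.
#' @return the updated `network_spec`.
#' @export
net_add <- function(net, id, kind, inputs = character(), ...) {
  stopifnot(inherits(net, "network_spec"))
  if (id %in% names(net$nodes)) stop("duplicate node id: ", id)
  missing_in <- setdiff(inputs, names(net$nodes))
  if (length(missing_in))
    stop("node '", id, "' references unknown inputs: ",
         paste(missing_in, collapse = ", "))
  node <- c(list(id = id, kind = kind, inputs = inputs), list(...))
  defaults <- switch(kind,
    conv    = list(kernel = 3L, bias = TRUE, batchnorm = TRUE, activation = "relu"),
    ghost   = list(kernel = 3L, cheap_kernel = 3L, ratio = 2L, bias = TRUE,
                   batchnorm = TRUE, activation = "relu"),
    deconv  = list(kernel = 2L, bias = TRUE, batchnorm = FALSE, activation = "none"),
    maxpool = list(factor = 2L),
    bilinear_up = list(factor = 2L),
    list()
  )
  for (f in names(defaults))
    if (is.null(node[[f]])) node[[f]] <- defaults[[f]]
  if (kind == "ghost") {
    if (node$ratio != 2L) stop("unsupported ghost ratio s = ", node$ratio,
                               " (only s = 2 is supported)")
    if (node$out_channels %% 2L != 0L)
      stop("ghost module out_channels must be even when s = 2")
  }
  if (kind %in% c("conv", "ghost") && node$kernel %% 2L != 1L)
    stop("stride-1 'same' convolutions require an odd kernel, got ", node$kernel)
  net$nodes[[id]] <- node
  net
}

net_set_output <- function(net, id) {
  stopifnot(id %in% names(net$nodes))
  net$output <- id
  net
}

#' Infer the output shape of every node
#'
#' Walks the graph in topological (insertion) order and derives each node's
#' `c(channels, height, width)` output shape, validating the shape contracts:
#' `add` requires identical shapes, pooling requires divisible spatial dims,
#' and `concat` sums channel counts.
#'
#' @param net a `network_spec`.
#' @return named list of integer shape vectors, one per node.
#' @export
network_shapes <- function(net) {
  shapes <- list()
  for (node in net$nodes) {
    ins <- lapply(node$inputs, function(i) shapes[[i]])
    shapes[[node$id]] <- node_out_shape(node, ins)
  }
  shapes
}

node_out_shape <- function(node, ins) {
  kind <- node$kind
  if (kind == "input") return(as.integer(node$shape))
  s <- ins[[1]]
  switch(kind,
    conv = c(as.integer(node$out_channels), s[2], s[3]),
    ghost = c(as.integer(node$out_channels), s[2], s[3]),
    deconv = {
      k <- as.integer(node$kernel)
      c(as.integer(node$out_channels), s[2] * k, s[3] * k)
    },
    maxpool = {
      f <- as.integer(node$factor)
      if (s[2] %% f != 0 || s[3] %% f != 0)
        stop("node '", node$id, "': spatial size ", s[2], "x", s[3],
             " not divisible by pooling factor ", f)
      c(s[1], s[2] %/% f, s[3] %/% f)
    },
    bilinear_up = {
      f <- as.integer(node$factor)
      c(s[1], s[2] * f, s[3] * f)
    },
    add = {
      for (o in ins[-1]) {
        if (!identical(o, s))
          stop("node '", node$id, "': additive fusion requires identical ",
               "shapes, got ", paste(s, collapse = "x"), " vs ",
               paste(o, collapse = "x"))
      }
      s
    },
    concat = {
      hw <- s[2:3]
      for (o in ins[-1]) {
        if (!identical(o[2:3], hw))
          stop("node '", node$id, "': concat requires matching spatial dims")
      }
      c(sum(vapply(ins, `[`, integer(1), 1L)), hw)
    },
    stop("unknown node kind: ", kind)
  )
}

#' Validate a network specification
#'
#' Checks that the graph is acyclic (guaranteed by construction order), that
#' every node's shape is derivable, and that the designated output exists.
#'
#' @param net a `network_spec`.
#' @return invisibly, the inferred shapes.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "network_spec"))
  if (is.null(net$output)) stop("network has no designated output")
  shapes <- network_shapes(net)
  invisible(shapes)
}

# ids of nodes the output depends on (side branches excluded from forward)
network_needed <- function(net, target = net$output) {
  needed <- character()
  stack <- target
  while (length(stack)) {
    id <- stack[[1]]; stack <- stack[-1]
    if (id %in% needed) next
    needed <- c(needed, id)
    stack <- c(stack, net$nodes[[id]]$inputs)
  }
  ids <- names(net$nodes)
  ids[ids %in% needed]
}

net_input_ids <- function(net) {
  ids <- names(net$nodes)
  ids[vapply(net$nodes, function(n) n$kind == "input", logical(1))]
}

#' @export
print.network_spec <- function(x, ...) {
  shapes <- tryCatch(network_shapes(x), error = function(e) NULL)
  cat("network_spec '", x$name, "': ", length(x$nodes), " nodes, input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  for (node in x$nodes) {
    sh <- if (!is.null(shapes)) paste(shapes[[node$id]], collapse = "x") else "?"
    extra <- switch(node$kind,
      conv = paste0("k", node$kernel, if (isTRUE(node$batchnorm)) "+bn",
                    if (node$activation != "none") paste0("+", node$activation)),
      ghost = paste0("k", node$kernel, "/d", node$cheap_kernel),
      deconv = paste0("k", node$kernel, " stride ", node$kernel),
      maxpool = paste0("/", node$factor),
      bilinear_up = paste0("x", node$factor),
      "")
    cat(sprintf("  %-24s %-12s %-10s <- %s\n", node$id, node$kind,
                sh, paste(node$inputs, collapse = ", ")))
  }
  cat("output:", x$output, "\n")
  invisible(x)
}

# Copy a set of nodes into a standalone sub-network. Edges crossing into the
# subgraph become fresh input nodes with the parent-inferred shapes.
subnetwork <- function(net, node_ids, name, output_id) {
  shapes <- network_shapes(net)
  sub <- structure(
    list(name = name, input_shape = NULL, nodes = list(),
         output = NULL, last_fusion = NULL),
    class = "network_spec"
  )
  made_inputs <- character()
  for (id in names(net$nodes)) {
    if (!(id %in% node_ids)) next
    node <- net$nodes[[id]]
    for (src in node$inputs) {
      if (!(src %in% node_ids) && !(src %in% made_inputs)) {
        iid <- paste0("in_", src)
        sub <- net_add(sub, iid, "input", shape = shapes[[src]])
        made_inputs <- c(made_inputs, src)
      }
    }
    node$inputs <- ifelse(node$inputs %in% node_ids, node$inputs,
                          paste0("in_", node$inputs))
    sub$nodes[[id]] <- node
  }
  first_in <- net_input_ids(sub)[1]
  sub$input_shape <- sub$nodes[[first_in]]$shape
  net_set_output(sub, output_id)
}
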