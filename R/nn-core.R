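#' @useDynLib axunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm
NULL

# ---- module framework -------------------------------------------------------
#
# A layer is an environment holding `params` (named list of numeric arrays),
# matching `grads`, optional `buffers` (non-trained state such as batch-norm
# running statistics), and closures `fw(x, training)` / `bw(dy)`. Composite
# blocks hold a named list `children` and their own fw/bw closures; parameters
# live only in leaves. The computation graph is the fixed U topology, so
# backpropagation is written out block by block rather than through a tape.

new_module <- function(class) {
  self <- new.env(parent = emptyenv())
  self$params <- list()
  self$grads <- list()
  self$buffers <- list()
  self$children <- list()
  class(self) <- c(class, "axu_module")
  self
}

#' @export
print.axu_module <- function(x, ...) {
  cat("<", class(x)[1], "> ", n_parameters(x), " trainable parameters\n", sep = "")
  invisible(x)
}

# Flat list of parameter slots: each entry list(env, name, path).
collect_parameters <- function(module, path = "") {
  out <- list()
  if (length(module$params)) {
    for (nm in names(module$params)) {
      out[[length(out) + 1L]] <- list(env = module, name = nm,
                                      path = paste0(path, nm))
    }
  }
  for (nm in names(module$children)) {
    out <- c(out, collect_parameters(module$children[[nm]],
                                     paste0(path, nm, ".")))
  }
  out
}

collect_buffers <- function(module, path = "") {
  out <- list()
  if (length(module$buffers)) {
    for (nm in names(module$buffers)) {
      out[[length(out) + 1L]] <- list(env = module, name = nm,
                                      path = paste0(path, nm))
    }
  }
  for (nm in names(module$children)) {
    out <- c(out, collect_buffers(module$children[[nm]], paste0(path, nm, ".")))
  }
  out
}

n_parameters <- function(module) {
  sum(vapply(collect_parameters(module),
             function(e) length(e$env$params[[e$name]]), numeric(1)))
}

zero_grads <- function(module) {
  for (e in collect_parameters(module)) {
    e$env$grads[[e$name]] <- array(0, dim_of(e$env$params[[e$name]]))
  }
  invisible(module)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Serializable weight state (params + buffers), keyed by dotted path.
state_dict <- function(module) {
  st <- list()
  for (e in collect_parameters(module)) st[[e$path]] <- e$env$params[[e$name]]
  for (e in collect_buffers(module)) st[[paste0("buffer:", e$path)]] <- e$env$buffers[[e$name]]
  st
}

load_state_dict <- function(module, state) {
  for (e in collect_parameters(module)) {
    v <- state[[e$path]]
    if (is.null(v)) stop("checkpoint is missing parameter '", e$path, "'")
    stopifnot(length(v) == length(e$env$params[[e$name]]))
    e$env$params[[e$name]] <- v
  }
  for (e in collect_buffers(module)) {
    v <- state[[paste0("buffer:", e$path)]]
    if (!is.null(v)) e$env$buffers[[e$name]] <- v
  }
  invisible(module)
}

# ---- shared helpers ---------------------------------------------------------

# Promote an (H,W,C) map to the internal (H,W,C,N) batch layout.
as_batch <- function(x) {
  if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
    attr(x, "squeeze") <- TRUE
  }
  if (length(dim(x)) != 4L) stop("feature maps must have dim (H, W, C) or (H, W, C, N)")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  x
}

check_same_shape <- function(...) {
  ds <- lapply(list(...), dim)
  if (!all(vapply(ds[-1], function(d) identical(d, ds[[1]]), logical(1))))
    stop("input feature maps must share the same shape")
  invisible(TRUE)
}

fan_in_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -b, b), dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Largest divisor of both channel counts not exceeding the requested group
# count; keeps the 32-group convolution well-defined for narrow models.
effective_groups <- function(requested, c_in, c_out) {
  g <- min(requested, c_in, c_out)
  while (g > 1L && (c_in %% g != 0L || c_out %% g != 0L)) g <- g - 1L
  as.integer(g)
}
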