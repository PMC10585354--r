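#' Expand a differentiation network into a stochastic quasi-reaction system
#'
#' Each flagged node contributes a duplication reaction `x_i -> 2 x_i`
#' (net effect +1 on `i`) and a death reaction `x_i -> 0` (net effect -1);
#' each edge `i -> j` contributes a differentiation reaction `x_i -> 2 x_j`
#' (net effect -1 on `i`, +2 on `j`). Reactions are ordered deterministically:
#' for each node in declaration order its duplication then its death reaction,
#' followed by the differentiation reactions in edge declaration order. The
#' rate vector `theta` keeps the conventional block layout
#' `(alpha_1..alpha_n, delta_1..delta_n, lambda_e1..lambda_eE)`; the
#' `rate_index` field maps each reaction to its `theta` coordinate.
#'
#' @param net a `diffnet`.
#' @return An object of class `reaction_system` with fields `nodes`, `kind`,
#'   `src`, `dst`, `V` (the n x K net-effect matrix), `theta_names`,
#'   `rate_index`, and per-block coordinate maps `alpha_idx`, `delta_idx`,
#'   `lambda_idx`.
#' @examples
#' net <- differentiation_network(c("A", "B"), rbind(c("A", "B")))
#' rs <- build_reaction_system(net)
#' rs$V
#' @export
build_reaction_system <- function(net) {
  stopifnot(inherits(net, "diffnet"))
  nodes <- net$nodes
  n <- length(nodes)
  dup_nodes <- nodes[net$dup]
  death_nodes <- nodes[net$death]
  edges <- net$edges

  theta_names <- c(
    if (length(dup_nodes)) paste0("alpha_", dup_nodes),
    if (length(death_nodes)) paste0("delta_", death_nodes),
    if (nrow(edges)) paste0("lambda_", edges[, "from"], "_", edges[, "to"])
  )
  alpha_idx <- setNames(match(paste0("alpha_", dup_nodes), theta_names), dup_nodes)
  delta_idx <- setNames(match(paste0("delta_", death_nodes), theta_names), death_nodes)
  lambda_idx <- if (nrow(edges)) {
    setNames(match(paste0("lambda_", edges[, "from"], "_", edges[, "to"]), theta_names),
             paste0(edges[, "from"], "->", edges[, "to"]))
  } else integer(0)

  kind <- character(0); src <- integer(0); dst <- integer(0); rate_index <- integer(0)
  for (i in seq_len(n)) {
    if (net$dup[i]) {
      kind <- c(kind, "duplication"); src <- c(src, i); dst <- c(dst, NA_integer_)
      rate_index <- c(rate_index, alpha_idx[[nodes[i]]])
    }
    if (net$death[i]) {
      kind <- c(kind, "death"); src <- c(src, i); dst <- c(dst, NA_integer_)
      rate_index <- c(rate_index, delta_idx[[nodes[i]]])
    }
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      kind <- c(kind, "differentiation")
      src <- c(src, match(edges[e, "from"], nodes))
      dst <- c(dst, match(edges[e, "to"], nodes))
      rate_index <- c(rate_index, lambda_idx[[e]])
    }
  }
  K <- length(kind)
  V <- matrix(0L, n, K, dimnames = list(nodes, NULL))
  for (k in seq_len(K)) {
    V[src[k], k] <- switch(kind[k], duplication = 1L, death = -1L,
                           differentiation = -1L)
    if (kind[k] == "differentiation") V[dst[k], k] <- 2L
  }
  structure(list(nodes = nodes, n = n, K = K, kind = kind, src = src,
                 dst = dst, V = V, theta_names = theta_names,
                 n_params = length(theta_names), rate_index = rate_index,
                 alpha_idx = alpha_idx, delta_idx = delta_idx,
                 lambda_idx = lambda_idx, edges = edges),
            class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat("Quasi-reaction system:", x$n, "lineages,", x$K, "reactions,",
      x$n_params, "rate parameters\n")
  lab <- ifelse(is.na(x$dst), x$nodes[x$src],
                paste0(x$nodes[x$src], "->", x$nodes[x$dst]))
  cat("  ", paste0(substr(x$kind, 1, 4), "(", lab, ")", collapse = " "), "\n")
  invisible(x)
}

#' Build a full rate-parameter vector
#'
#' Assembles the flattened rate vector `theta` in the system's canonical
#' block order (duplication rates `alpha`, death rates `delta`,
#' differentiation rates `lambda`, all in units 1/time). Scalars are
#' recycled; named vectors assign per node / per edge (edge names use
#' `"from->to"`).
#'
#' @param rs a `reaction_system`.
#' @param alpha,delta scalar or named vector of per-node rates.
#' @param lambda scalar or named vector of per-edge rates.
#' @return Named numeric vector of length `rs$n_params`.
#' @export
rate_parameters <- function(rs, alpha = 0, delta = 0, lambda = 0) {
  stopifnot(inherits(rs, "reaction_system"))
  theta <- setNames(numeric(rs$n_params), rs$theta_names)
  fill <- function(theta, idx, value) {
    if (!length(idx)) return(theta)
    if (is.null(names(value))) {
      theta[idx] <- rep_len(value, length(idx))
    } else {
      bad <- setdiff(names(value), names(idx))
      if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
      theta[idx[names(value)]] <- value
    }
    theta
  }
  theta <- fill(theta, rs$alpha_idx, alpha)
  theta <- fill(theta, rs$delta_idx, delta)
  theta <- fill(theta, rs$lambda_idx, lambda)
  if (any(theta < 0)) stop("rates must be nonnegative")
  theta
}

#' Differentiation transition probabilities
#'
#' The probability that lineage `i`'s next event is differentiation into `j`
#' rather than self-renewal or differentiation elsewhere:
#' `p_ij = lambda_ij / (alpha_i + sum_k lambda_ik)`, the multinomial weight
#' of edge `i -> j` among `i`'s competing duplication and differentiation
#' hazards. For each source the probabilities sum to at most 1, with equality
#' exactly when the source has no duplication (`alpha_i = 0`).
#'
#' @param net a `diffnet`.
#' @param theta full named rate vector (see [rate_parameters()]).
#' @return A data.frame with columns `from`, `to`, `lambda`, `probability`.
#' @examples
#' net <- differentiation_network(c("A", "B"), rbind(c("A", "B")))
#' rs <- build_reaction_system(net)
#' theta <- rate_parameters(rs, alpha = c(A = 0.2, B = 0), lambda = 0.3)
#' transition_probabilities(net, theta)  # p = 0.3 / (0.2 + 0.3) = 0.6
#' @export
transition_probabilities <- function(net, theta) {
  stopifnot(inherits(net, "diffnet"))
  rs <- build_reaction_system(net)
  if (is.null(names(theta))) names(theta) <- rs$theta_names
  if (any(theta < 0)) stop("rates must be nonnegative")
  edges <- net$edges
  if (!nrow(edges)) {
    return(data.frame(from = character(0), to = character(0),
                      lambda = numeric(0), probability = numeric(0)))
  }
  out <- data.frame(from = edges[, "from"], to = edges[, "to"],
                    lambda = NA_real_, probability = NA_real_,
                    stringsAsFactors = FALSE)
  for (srcnode in unique(edges[, "from"])) {
    rows <- which(out$from == srcnode)
    lam <- theta[rs$lambda_idx[paste0(srcnode, "->", out$to[rows])]]
    a <- if (srcnode %in% names(rs$alpha_idx)) theta[[rs$alpha_idx[[srcnode]]]] else 0
    denom <- a + sum(lam)
    if (denom <= 0) {
      stop("undefined transition probability: zero total hazard at source '",
           srcnode, "'")
    }
    out$lambda[rows] <- unname(lam)
    out$probability[rows] <- unname(lam) / denom
  }
  out
}
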