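#' Identifiability constraints for rates involving only unobserved lineages
#'
#' Rate parameters whose reactions involve only unobserved cell types cannot
#' be identified from the data alone. Two families of linear constraints
#' express them through identifiable rates:
#'
#' * **Flux conservation** (`use_conservation`): the differentiation rate
#'   into an unobserved compartment `b` that itself has outgoing edges equals
#'   the sum of `b`'s outgoing differentiation rates,
#'   `lambda_ab = sum_{c in O(b)} lambda_bc` — cells flowing into `b` are the
#'   cells that `b` later passes on.
#' * **Averaging** (`use_averaging`): an unobserved-to-unobserved
#'   differentiation rate equals the mean of the source's rates into its
#'   *observed* offspring; the duplication (death) rate of an unobserved node
#'   equals the mean duplication (death) rate of the observed nodes on the
#'   same branch that share its ancestor.
#'
#' When both rules could apply to the same coordinate, flux conservation
#' wins. Chained unobserved compartments (e.g. HSC -> MPP -> CMP all
#' unobserved) are resolved recursively towards observed rates. For the
#' averaging rule, a root node with branch `"none"` averages over both
#' branches, and when no observed node shares the unobserved node's declared
#' ancestor the set widens to observed branch-mates descending from that
#' ancestor (nearest-ancestor reading).
#'
#' The result is a nonnegative matrix `C` (`n_params` x `n_free`) such that
#' `theta_full = C %*% theta_free`; unconstrained coordinates map to
#' themselves.
#'
#' @param net a `diffnet`.
#' @param use_conservation apply the flux-conservation law (default `TRUE`).
#' @param use_averaging apply the averaging constraints (default `TRUE`).
#' @return An object of class `constraint_map` with fields `C`, `free_names`,
#'   `full_names`, `n_free`, and human-readable `descriptions`.
#' @export
build_constraint_map <- function(net, use_conservation = TRUE,
                                 use_averaging = TRUE) {
  stopifnot(inherits(net, "diffnet"))
  rs <- build_reaction_system(net)
  p <- rs$n_params
  nm <- rs$theta_names
  unobs <- !net$observed

  # Linear expression (in terms of other theta coordinates) for each
  # constrained coordinate; NULL marks a free coordinate.
  exprs <- vector("list", p)
  descriptions <- character(0)

  add_expr <- function(coord, idx, w, label) {
    exprs[[coord]] <<- list(idx = idx, w = w)
    descriptions <<- c(descriptions,
                       paste0(nm[coord], " = ",
                              paste(sprintf("%.4g*%s", w, nm[idx]), collapse = " + "),
                              "  [", label, "]"))
  }

  if (use_conservation || use_averaging) {
    # Differentiation rates between two unobserved lineages.
    for (key in names(rs$lambda_idx)) {
      coord <- rs$lambda_idx[[key]]
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      a <- ft[1]; b <- ft[2]
      if (!(unobs[[a]] && unobs[[b]])) next
      off_b <- offspring(net, b)
      if (use_conservation && length(off_b)) {
        idx <- rs$lambda_idx[paste0(b, "->", off_b)]
        add_expr(coord, unname(idx), rep(1, length(idx)), "flux conservation")
        next
      }
      if (use_averaging) {
        off_a_obs <- intersect(offspring(net, a), net$nodes[net$observed])
        if (!length(off_a_obs)) {
          stop("unidentifiable parameter '", nm[coord],
               "': source '", a, "' has no observed offspring to average over")
        }
        idx <- rs$lambda_idx[paste0(a, "->", off_a_obs)]
        add_expr(coord, unname(idx), rep(1 / length(idx), length(idx)),
                 "mean over observed offspring")
        next
      }
      stop("unidentifiable parameter '", nm[coord],
           "': target '", b, "' has no outgoing edges for flux conservation ",
           "and averaging is disabled")
    }
    # Duplication/death rates of unobserved lineages.
    if (use_averaging) {
      for (node in net$nodes[unobs]) {
        mates <- averaging_set(net, node)
        if (node %in% names(rs$alpha_idx)) {
          pool <- intersect(mates, names(rs$alpha_idx))
          if (!length(pool)) {
            stop("unidentifiable parameter '", nm[rs$alpha_idx[[node]]],
                 "': no observed branch-mates sharing an ancestor with '",
                 node, "'")
          }
          add_expr(rs$alpha_idx[[node]], unname(rs$alpha_idx[pool]),
                   rep(1 / length(pool), length(pool)),
                   "mean duplication rate of observed branch-mates")
        }
        if (node %in% names(rs$delta_idx)) {
          pool <- intersect(mates, names(rs$delta_idx))
          if (!length(pool)) {
            stop("unidentifiable parameter '", nm[rs$delta_idx[[node]]],
                 "': no observed branch-mates sharing an ancestor with '",
                 node, "'")
          }
          add_expr(rs$delta_idx[[node]], unname(rs$delta_idx[pool]),
                   rep(1 / length(pool), length(pool)),
                   "mean death rate of observed branch-mates")
        }
      }
    }
  }

  constrained <- !vapply(exprs, is.null, TRUE)
  free_names <- nm[!constrained]
  n_free <- length(free_names)
  free_pos <- setNames(seq_len(n_free), free_names)

  # Resolve each coordinate to a row over the free coordinates; chained
  # constraints are followed recursively (the dependency graph is acyclic on
  # tree-shaped networks, but cycles are detected defensively).
  rows <- vector("list", p)
  visiting <- logical(p)
  resolve <- function(coord) {
    if (!is.null(rows[[coord]])) return(rows[[coord]])
    if (visiting[coord]) {
      stop("cyclic constraint involving parameter '", nm[coord], "'")
    }
    visiting[coord] <<- TRUE
    row <- numeric(n_free)
    if (!constrained[coord]) {
      row[free_pos[[nm[coord]]]] <- 1
    } else {
      ex <- exprs[[coord]]
      for (i in seq_along(ex$idx)) {
        row <- row + ex$w[i] * resolve(ex$idx[i])
      }
    }
    visiting[coord] <<- FALSE
    rows[[coord]] <<- row
    row
  }
  C <- if (p == 0) matrix(numeric(0), 0, 0) else
    do.call(rbind, lapply(seq_len(p), resolve))
  dimnames(C) <- list(nm, free_names)

  structure(list(C = C, free_names = free_names, full_names = nm,
                 n_free = n_free, n_full = p, constrained = setNames(constrained, nm),
                 descriptions = descriptions),
            class = "constraint_map")
}

# Observed nodes eligible for the averaging rule for unobserved `node`:
# branch-compatible (a "none"-branch node averages over both branches) and
# sharing the node's declared ancestor; if that strict set is empty the set
# widens to observed branch-mates whose ancestor chain contains it.
averaging_set <- function(net, node) {
  obs_nodes <- setdiff(net$nodes[net$observed], node)
  br <- net$branch[[node]]
  if (br != "none") obs_nodes <- obs_nodes[net$branch[obs_nodes] == br]
  anc <- net$ancestor[[node]]
  if (is.na(anc)) return(obs_nodes)
  strict <- obs_nodes[!is.na(net$ancestor[obs_nodes]) &
                        net$ancestor[obs_nodes] == anc]
  if (length(strict)) return(strict)
  obs_nodes[vapply(obs_nodes, function(o) anc %in% ancestor_chain(net, o), TRUE)]
}

ancestor_chain <- function(net, node) {
  chain <- character(0)
  a <- net$ancestor[[node]]
  while (!is.na(a) && !(a %in% chain)) {
    chain <- c(chain, a)
    a <- net$ancestor[[a]]
  }
  chain
}

#' @export
print.constraint_map <- function(x, ...) {
  cat("Constraint map:", x$n_full, "rates ->", x$n_free, "free rates\n")
  if (length(x$descriptions)) cat(paste0("  ", x$descriptions, collapse = "\n"), "\n")
  invisible(x)
}

#' Expand free rates to the full rate vector
#'
#' @param cm a `constraint_map`.
#' @param theta_free numeric vector over `cm$free_names` (names optional;
#'   positional if unnamed).
#' @return Named full rate vector `C %*% theta_free`.
#' @export
expand_theta <- function(cm, theta_free) {
  stopifnot(inherits(cm, "constraint_map"))
  if (!is.null(names(theta_free))) theta_free <- theta_free[cm$free_names]
  if (length(theta_free) != cm$n_free) {
    stop("theta_free must have length ", cm$n_free)
  }
  setNames(as.vector(cm$C %*% theta_free), cm$full_names)
}

#' Restrict a full rate vector to its free coordinates
#'
#' @param cm a `constraint_map`.
#' @param theta full named rate vector.
#' @return Named vector over the free coordinates.
#' @export
restrict_theta <- function(cm, theta) {
  stopifnot(inherits(cm, "constraint_map"))
  theta[cm$free_names]
}
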