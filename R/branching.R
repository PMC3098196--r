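#' Offspring distribution of a two-child Galton-Watson branching process
#'
#' The universal metabolic network of the tree-structured toolbox model is a
#' rooted tree generated by a Galton-Watson process in which every node has
#' 0, 1 or 2 children at the next layer with probabilities `p0`, `p1`, `p2`.
#' The mean offspring number is \eqn{\Lambda = p_1 + 2 p_2}; the process is
#' critical when \eqn{\Lambda = 1}, i.e. when `p0 == p2`.
#'
#' @param p0,p1,p2 Probabilities of having 0, 1 or 2 children. Must be
#'   non-negative and sum to 1.
#' @return An object of class `branching_params` with fields `p0`, `p1`,
#'   `p2` and `lambda` (mean offspring number).
#' @examples
#' bp <- branching_params(0.25, 0.5, 0.25)
#' bp$lambda  # 1: critical
#' @export
branching_params <- function(p0, p1, p2) {
  p <- c(p0, p1, p2)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("offspring probabilities must be finite and non-negative")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("offspring probabilities must sum to 1 (got ", sum(p), ")")
  }
  structure(
    list(p0 = p0, p1 = p1, p2 = p2, lambda = p1 + 2 * p2),
    class = "branching_params"
  )
}

#' @export
print.branching_params <- function(x, ...) {
  cat(sprintf(
    "<branching_params> p0=%.4g p1=%.4g p2=%.4g  Lambda=%.4g (%s)\n",
    x$p0, x$p1, x$p2, x$lambda,
    if (abs(x$lambda - 1) < 1e-12) "critical"
    else if (x$lambda > 1) "supercritical" else "subcritical"
  ))
  invisible(x)
}

is_critical <- function(params) abs(params$lambda - 1) < 1e-12

new_layered_tree <- function(parent, depth, names = NULL, params = NULL,
                             seed = NULL, mode = NULL, excluded = character()) {
  structure(
    list(parent = as.integer(parent), depth = as.integer(depth),
         n = length(parent), names = names, params = params,
         seed = seed, mode = mode, excluded = excluded),
    class = "layered_tree"
  )
}

#' @export
print.layered_tree <- function(x, ...) {
  st <- layer_stats(x)
  cat(sprintf(
    "<layered_tree> %d nodes, %d leaves, depth %d%s\n",
    x$n, sum(st$L), max(x$depth),
    if (length(x$excluded)) sprintf(" (%d unreachable nodes excluded)",
                                    length(x$excluded)) else ""
  ))
  invisible(x)
}

# single unconditioned realization; NULL when the node cap is exceeded
gw_realization <- function(prob, max_depth = Inf, node_cap = Inf) {
  parent <- NA_integer_
  depth <- 0L
  n <- 1L
  cur <- 1L
  d <- 0L
  while (length(cur) > 0L && d < max_depth) {
    k <- sample.int(3L, length(cur), replace = TRUE, prob = prob) - 1L
    nk <- sum(k)
    if (nk == 0L) break
    ids <- n + seq_len(nk)
    parent[ids] <- rep(cur, k)
    depth[ids] <- d + 1L
    n <- n + nk
    if (n > node_cap) return(NULL)
    cur <- ids
    d <- d + 1L
  }
  list(parent = parent, depth = depth, n = n)
}

#' Sample a layered universal tree from a Galton-Watson process
#'
#' Generates a rooted tree layer by layer (root at depth 0, the "metabolic
#' core"); children of a depth-`d` node live at depth `d+1`. Two modes are
#' supported: `"fixed_depth"` truncates the process at a predefined layer
#' (required for supercritical processes, which never stop on their own),
#' and `"condition_on_size"` uses rejection sampling to return a tree whose
#' total node count lies within `tolerance` of `target_size`.
#'
#' @param params A [branching_params()] object.
#' @param mode `"fixed_depth"` or `"condition_on_size"`.
#' @param depth Maximal layer index for `"fixed_depth"` mode.
#' @param target_size Desired total number of nodes for
#'   `"condition_on_size"` mode.
#' @param tolerance Relative size tolerance for conditioning (default 10%).
#' @param min_size Minimal accepted node count in `"fixed_depth"` mode;
#'   trees that go extinct below this size are rejected and re-drawn
#'   (conditioning on survival). Default 1 (accept everything).
#' @param max_attempts Cap on rejection-sampling attempts.
#' @param node_budget Hard cap on nodes for fixed-depth generation of
#'   supercritical trees.
#' @param seed Optional integer seed.
#' @return A `layered_tree`: parent pointers (`NA` for the root), per-node
#'   depths, and the generation metadata.
#' @examples
#' tr <- sample_tree(branching_params(0.25, 0.5, 0.25),
#'                   mode = "condition_on_size", target_size = 200, seed = 1)
#' layer_stats(tr)
#' @export
sample_tree <- function(params,
                        mode = c("fixed_depth", "condition_on_size"),
                        depth = NULL, target_size = NULL, tolerance = 0.1,
                        min_size = 1L, max_attempts = 1e5,
                        node_budget = 1e6, seed = NULL) {
  stopifnot(inherits(params, "branching_params"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  prob <- c(params$p0, params$p1, params$p2)

  if (mode == "fixed_depth") {
    if (is.null(depth) || depth < 0) stop("fixed_depth mode needs depth >= 0")
    for (att in seq_len(max_attempts)) {
      r <- gw_realization(prob, max_depth = depth, node_cap = node_budget)
      if (is.null(r)) {
        stop("node budget (", node_budget, ") exceeded at depth cap ", depth,
             "; reduce depth or raise node_budget")
      }
      if (r$n >= min_size) {
        return(new_layered_tree(r$parent, r$depth, params = params,
                                seed = seed, mode = mode))
      }
    }
    stop("no tree of size >= ", min_size, " in ", max_attempts, " attempts")
  }

  if (is.null(target_size) || target_size < 1) {
    stop("condition_on_size mode needs target_size >= 1")
  }
  lo <- target_size * (1 - tolerance)
  hi <- target_size * (1 + tolerance)
  for (att in seq_len(max_attempts)) {
    r <- gw_realization(prob, node_cap = ceiling(hi))
    if (!is.null(r) && r$n >= lo && r$n <= hi) {
      return(new_layered_tree(r$parent, r$depth, params = params,
                              seed = seed, mode = mode))
    }
  }
  stop("failed to sample a tree of size ", target_size, " (+/-",
       100 * tolerance, "%) in ", max_attempts, " attempts")
}

n_children <- function(tree) {
  tabulate(tree$parent[!is.na(tree$parent)], nbins = tree$n)
}

#' Leaves of a layered tree
#'
#' Nodes without children; in the toolbox model each leaf is a nutrient and
#' the endpoint of one catabolic pathway.
#' @param tree A `layered_tree`.
#' @return Integer node indices.
#' @export
tree_leaves <- function(tree) which(n_children(tree) == 0L)

#' Per-layer node counts of a layered tree
#'
#' For every layer `d` (distance from the root) returns the total number of
#' nodes `M`, the number of leaves `L` (no children) and the number of
#' branch points `B` (exactly two children), together with `C`, the total
#' number of children emitted into layer `d+1`. For trees with at most two
#' children per node the edge-conservation identity
#' \eqn{M_{d+1} = M_d - L_d + B_d} holds exactly; for arbitrary branching
#' numbers (spanning trees of reaction graphs) the generalized identity is
#' \eqn{M_{d+1} = C_d}.
#'
#' @param tree A `layered_tree`.
#' @return A data frame with columns `d`, `M`, `L`, `B`, `C`.
#' @export
layer_stats <- function(tree) {
  stopifnot(inherits(tree, "layered_tree"))
  D <- max(tree$depth)
  kids <- n_children(tree)
  d_fac <- factor(tree$depth, levels = 0:D)
  M <- as.integer(table(d_fac))
  L <- as.integer(tapply(kids == 0L, d_fac, sum, default = 0L))
  B <- as.integer(tapply(kids == 2L, d_fac, sum, default = 0L))
  C <- as.integer(tapply(kids, d_fac, sum, default = 0L))
  data.frame(d = 0:D, M = M, L = L, B = B, C = C)
}

#' Layer-to-layer growth ratios of a tree or expansion profile
#'
#' Computes \eqn{\mu_d = M_{d+1} / M_d}, the ratio of node counts in two
#' consecutive layers. For a critical branching process conditioned on
#' survival this ratio approaches 1 algebraically; the reference curve
#' \eqn{1 + \theta/d} (default \eqn{\theta = 1}) is returned for
#' comparison. Supercritical trees instead plateau at \eqn{\Lambda > 1}.
#'
#' @param M Numeric vector of per-layer counts (`M[1]` is layer 0); must be
#'   positive and of length at least 2.
#' @param theta Coefficient of the `1 + theta/d` reference curve.
#' @return A data frame with columns `d` (layer index of the numerator's
#'   predecessor), `mu`, and `mu_ref`.
#' @export
criticality_profile <- function(M, theta = 1) {
  if (length(M) < 2) stop("need at least two layers to form ratios")
  if (any(M <= 0)) stop("layer counts must be positive")
  d <- seq_len(length(M) - 1) - 1L
  data.frame(d = d, mu = M[-1] / M[-length(M)],
             mu_ref = ifelse(d >= 1, 1 + theta / d, NA_real_))
}

#' Mean-field layer occupation of the toolbox model on a tree
#'
#' Iterates the layer-occupation recursion of the tree toolbox model. An
#' organism that has acquired a fraction `x` of all nutrients (leaves) holds
#' \eqn{\lambda_d = x \Lambda_d} leaves at layer `d` (nutrients are uniformly
#' distributed over layers). Each of its \eqn{m_{d+1}} metabolites at layer
#' `d+1` converts to a metabolite at layer `d`; pathways merge at branch
#' points, each of which is doubly occupied with probability
#' \eqn{p_{d+1}^2 = (m_{d+1}/M_{d+1})^2}, so
#' \deqn{m_d = x \Lambda_d + m_{d+1} - B_d (m_{d+1}/M_{d+1})^2.}
#' The recursion is run from the deepest layer (boundary
#' \eqn{m_D = x \Lambda_D}) towards the root. In the bulk of a critical
#' tree the occupation fraction approaches the fixed point
#' \eqn{p_\infty = \sqrt{x}}.
#'
#' @param stats Either a data frame with columns `M`, `L`, `B` (as returned
#'   by [layer_stats()]), a `layered_tree`, or a [branching_params()] object.
#'   When branching parameters are given, the expected flat profile
#'   (`M_d = 1`, `L_d = p0`, `B_d = p2`) is used, which requires `D`.
#' @param x Fraction of acquired leaves, in `[0, 1]`.
#' @param D Number of layers when `stats` is a `branching_params`.
#' @return An object of class `theory_profile`: a data frame with columns
#'   `d`, `M`, `L`, `B`, `m`, `lambda`, `b`, `p`, and attributes `x` and
#'   `p_bulk` (occupation fraction at the root-side end of the recursion,
#'   the converged bulk value for flat profiles).
#' @examples
#' pr <- mean_field_iterate(branching_params(0.25, 0.5, 0.25), x = 0.25, D = 300)
#' attr(pr, "p_bulk")  # ~ sqrt(0.25) = 0.5
#' @export
mean_field_iterate <- function(stats, x, D = NULL) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("x must be a single number in [0, 1]")
  }
  if (inherits(stats, "layered_tree")) stats <- layer_stats(stats)
  if (inherits(stats, "branching_params")) {
    if (is.null(D)) stop("D is required when iterating from branching_params")
    stats <- data.frame(d = 0:D, M = 1, L = stats$p0, B = stats$p2)
  }
  stopifnot(all(c("M", "L", "B") %in% names(stats)))
  M <- stats$M; L <- stats$L; B <- stats$B
  nd <- length(M)
  lambda <- x * L
  m <- numeric(nd)
  b <- numeric(nd)
  m[nd] <- lambda[nd]
  if (nd > 1) {
    for (i in (nd - 1):1) {
      p_next <- if (M[i + 1] > 0) m[i + 1] / M[i + 1] else 0
      b[i] <- B[i] * p_next^2
      m[i] <- lambda[i] + m[i + 1] - b[i]
    }
  }
  p <- ifelse(M > 0, m / M, 0)
  out <- data.frame(d = seq_len(nd) - 1L, M = M, L = L, B = B,
                    m = m, lambda = lambda, b = b, p = p)
  attr(out, "x") <- x
  attr(out, "p_bulk") <- p[1]
  class(out) <- c("theory_profile", "data.frame")
  out
}

#' Steady-state occupation fraction of the bulk layers
#'
#' Solves the bulk fixed point of the mean-field recursion,
#' \deqn{p_2 p^2 - (\Lambda - 1) p = x p_0,}
#' for the physical root \eqn{p \in [0, 1]}. In the critical case
#' (`p0 == p2`) this reduces to \eqn{p_\infty = \sqrt{x}}, which is the
#' origin of the quadratic scaling between the number of pathways and
#' network size. In the supercritical case the \eqn{x \to 0^+} limit is
#' \eqn{p_\infty = (\Lambda - 1)/p_2 = 1 - p_0/p_2}: an arbitrarily small
#' acquired fraction already occupies a finite fraction of the bulk, the
#' analogue of a first-order phase transition.
#'
#' @param params A [branching_params()] object.
#' @param x Fraction of acquired leaves in `[0, 1]` (vectorized).
#' @return Numeric vector of occupation fractions, same length as `x`.
#' @examples
#' steady_state_fraction(branching_params(0.25, 0.5, 0.25), 0.16)  # 0.4
#' @export
steady_state_fraction <- function(params, x) {
  stopifnot(inherits(params, "branching_params"))
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("x must lie in [0, 1]")
  p0 <- params$p0; p2 <- params$p2
  if (p2 == 0) {
    # linear branches only (or pure decay): occupation tracks x directly
    return(pmin(pmax(x, 0), 1))
  }
  disc <- (p2 - p0)^2 + 4 * p2 * p0 * x
  p <- ((p2 - p0) + sqrt(disc)) / (2 * p2)
  if (any(p < -1e-9 | p > 1 + 1e-9)) {
    stop("no physical root in [0, 1]; invalid branching parameters?")
  }
  pmin(pmax(p, 0), 1)
}

#' Write / read a layered tree as a TSV edge list
#'
#' The file holds `#`-prefixed header lines recording the offspring
#' probabilities and seed, followed by `child<TAB>parent` rows (the root is
#' omitted, it is the only node that never appears as a child). Node names
#' are written when present so metabolite-labelled spanning trees
#' round-trip exactly.
#'
#' @param tree A `layered_tree`.
#' @param path Output (input) file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns the
#'   reconstructed `layered_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "layered_tree"))
  hdr <- c(sprintf("# layered_tree n=%d", tree$n))
  if (!is.null(tree$params)) {
    hdr <- c(hdr, sprintf("# params p0=%.17g p1=%.17g p2=%.17g",
                          tree$params$p0, tree$params$p1, tree$params$p2))
  }
  if (!is.null(tree$seed)) hdr <- c(hdr, sprintf("# seed %d", tree$seed))
  id <- if (!is.null(tree$names)) tree$names else as.character(seq_len(tree$n))
  child <- which(!is.na(tree$parent))
  rows <- sprintf("%s\t%s", id[child], id[tree$parent[child]])
  writeLines(c(hdr, "child\tparent", rows), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  body <- body[-1]  # column header
  params <- NULL
  pm <- regmatches(hdr, regexec(
    "p0=([0-9.eE+-]+) p1=([0-9.eE+-]+) p2=([0-9.eE+-]+)", hdr))
  pm <- Filter(function(m) length(m) == 4, pm)
  if (length(pm)) {
    v <- as.numeric(pm[[1]][2:4])
    params <- branching_params(v[1], v[2], v[3])
  }
  sm <- regmatches(hdr, regexec("# seed (-?[0-9]+)", hdr))
  sm <- Filter(function(m) length(m) == 2, sm)
  seed <- if (length(sm)) as.integer(sm[[1]][2]) else NULL
  if (!length(body)) {
    return(new_layered_tree(NA_integer_, 0L, params = params, seed = seed))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  child <- vapply(parts, `[`, "", 1)
  par <- vapply(parts, `[`, "", 2)
  ids <- unique(c(setdiff(par, child), child))  # root(s) first
  n <- length(ids)
  parent <- rep(NA_integer_, n)
  parent[match(child, ids)] <- match(par, ids)
  depth <- rep(NA_integer_, n)
  depth[is.na(parent)] <- 0L
  todo <- which(!is.na(parent))
  while (length(todo)) {
    ready <- todo[!is.na(depth[parent[todo]])]
    if (!length(ready)) stop("malformed edge list: cycle or missing parent")
    depth[ready] <- depth[parent[ready]] + 1L
    todo <- setdiff(todo, ready)
  }
  named <- suppressWarnings(any(is.na(as.integer(ids)))) ||
    !identical(as.character(seq_len(n)), ids)
  new_layered_tree(parent, depth, names = if (named) ids else NULL,
                   params = params, seed = seed)
}

# internal sanity check used by tests
validate_layered_tree <- function(tree, max_children = 2L) {
  stopifnot(sum(is.na(tree$parent)) == 1, which(is.na(tree$parent)) == 1L)
  stopifnot(tree$depth[1] == 0L)
  nonroot <- which(!is.na(tree$parent))
  stopifnot(all(tree$depth[nonroot] == tree$depth[tree$parent[nonroot]] + 1L))
  if (is.finite(max_children)) stopifnot(all(n_children(tree) <= max_children))
  st <- layer_stats(tree)
  D <- nrow(st)
  if (D > 1) stopifnot(all(st$M[-1] == st$C[-D]))
  invisible(TRUE)
}
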