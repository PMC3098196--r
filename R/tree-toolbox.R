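#' Fresh organism state on a layered tree
#'
#' The organism starts empty; its network grows by pathway acquisition via
#' [add_random_pathway()]. `N_L` counts acquired leaves (pathways, hence
#' dedicated transcriptional regulators) and `N_M` counts acquired nodes
#' (metabolites; the number of enzymes/edges is `N_M - 1`).
#'
#' @param tree A `layered_tree`.
#' @return An `organism_tree_state`: logical acquisition mask plus counters.
#' @export
new_tree_state <- function(tree) {
  stopifnot(inherits(tree, "layered_tree"))
  structure(
    list(acquired = logical(tree$n), N_L = 0L, N_M = 0L),
    class = "organism_tree_state"
  )
}

#' Acquire one random nutrient pathway
#'
#' Picks an unacquired leaf uniformly at random and adds it together with
#' all its ancestors up to (and excluding) the first node already in the
#' organism's network; on the first acquisition the whole root path is
#' added, so the root (metabolic core) is present from then on. The
#' acquired set is therefore always a connected subtree containing the
#' root.
#'
#' @param tree A `layered_tree`.
#' @param state An `organism_tree_state`.
#' @param leaf Optional leaf index to acquire instead of a random one
#'   (used by enumeration oracles in tests).
#' @return The updated state.
#' @export
add_random_pathway <- function(tree, state, leaf = NULL) {
  stopifnot(inherits(state, "organism_tree_state"))
  if (is.null(leaf)) {
    pool <- setdiff(tree_leaves(tree), which(state$acquired))
    if (!length(pool)) stop("all leaves already acquired")
    leaf <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  v <- leaf
  added <- 0L
  while (!is.na(v) && !state$acquired[v]) {
    state$acquired[v] <- TRUE
    added <- added + 1L
    v <- tree$parent[v]
  }
  state$N_L <- state$N_L + 1L
  state$N_M <- state$N_M + added
  state
}

#' Full toolbox trajectory on a layered tree
#'
#' Acquires all leaves of the tree in uniform random order, recording
#' `(N_L, N_M)` after every pathway addition. The trajectory has one row
#' per leaf and always ends at the full tree, `(L_tot, M_tot)`.
#'
#' @param tree A `layered_tree`.
#' @param seed Optional integer seed.
#' @return A data frame of class `toolbox_trajectory` with columns `step`,
#'   `N_L`, `N_M`.
#' @examples
#' tr <- sample_tree(branching_params(0.25, 0.5, 0.25),
#'                   mode = "condition_on_size", target_size = 100, seed = 4)
#' tail(simulate_full_trajectory(tr, seed = 1), 1)  # (L_tot, M_tot)
#' @export
simulate_full_trajectory <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "layered_tree"))
  if (!is.null(seed)) set.seed(seed)
  leaves <- tree_leaves(tree)
  ord <- if (length(leaves) > 1L) sample(leaves) else leaves
  acquired <- logical(tree$n)
  N_M <- 0L
  out_NM <- integer(length(ord))
  parent <- tree$parent
  for (i in seq_along(ord)) {
    v <- ord[i]
    while (!is.na(v) && !acquired[v]) {
      acquired[v] <- TRUE
      N_M <- N_M + 1L
      v <- parent[v]
    }
    out_NM[i] <- N_M
  }
  out <- data.frame(step = seq_along(ord), N_L = seq_along(ord), N_M = out_NM)
  attr(out, "seed") <- seed
  class(out) <- c("toolbox_trajectory", "data.frame")
  out
}

#' Write / read a toolbox trajectory TSV
#'
#' Columns `step`, `N_L`, `N_M`; `#`-prefixed metadata header carries the
#' seed when one was recorded.
#'
#' @param trajectory A trajectory data frame.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  hdr <- character()
  if (!is.null(attr(trajectory, "seed"))) {
    hdr <- sprintf("# seed %d", attr(trajectory, "seed"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(trajectory, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  class(out) <- c("toolbox_trajectory", "data.frame")
  out
}

#' Convert a layered tree into a one-substrate/one-product reaction universe
#'
#' Orients every tree edge anabolically (parent makes child) and emits one
#' irreversible reaction per edge. With the root as the seed metabolite the
#' branched toolbox model on this universe degenerates to the tree toolbox
#' model: every multiplicity is (1, 1) and scope expansion is plain
#' reachability.
#'
#' @param tree A `layered_tree`.
#' @return A `metabolic_universe` whose metabolite ids are `M%05d` by node
#'   index, with attribute `seed_metabolites` set to the root.
#' @export
tree_to_universe <- function(tree) {
  stopifnot(inherits(tree, "layered_tree"))
  met <- sprintf("M%05d", seq_len(tree$n))
  child <- which(!is.na(tree$parent))
  uni <- metabolic_universe(
    id = sprintf("R%05d", seq_along(child)),
    substrates = as.list(met[tree$parent[child]]),
    products = as.list(met[child]),
    reversible = rep(FALSE, length(child))
  )
  attr(uni, "seed_metabolites") <- met[1]
  uni
}
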