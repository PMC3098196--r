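# Core engine shared by expand_scope() and the evolutionary simulation.
# `avail` marks producible metabolites, `rem` counts unsatisfied substrates
# per directed instance. Layer-synchronous saturation: a layer consists of
# all instances whose substrates are all available after the previous
# layer; their products become available at the next step.
expand_core <- function(cu, avail, rem, target = NULL, added = NULL) {
  if (is.null(added)) added <- logical(cu$n_inst)
  layers <- list()
  first_layer <- rep(NA_integer_, cu$n_met)
  first_layer[avail] <- 0L
  S <- sum(avail)
  frontier <- which(rem == 0L & !added)
  if (!is.null(target) && avail[target]) {
    return(list(layers = layers, first_layer = first_layer, avail = avail,
                rem = rem, added = added, S = S))
  }
  repeat {
    if (!length(frontier)) break
    layers[[length(layers) + 1L]] <- frontier
    added[frontier] <- TRUE
    pr <- unique(unlist(cu$inst_prod[frontier]))
    new_met <- pr[!avail[pr]]
    if (length(new_met)) {
      avail[new_met] <- TRUE
      first_layer[new_met] <- length(layers)
      touched <- unlist(cu$cons_by_met[new_met], use.names = FALSE)
      if (length(touched)) {
        rem <- rem - tabulate(touched, nbins = cu$n_inst)
        cand <- unique(touched)
        frontier <- cand[rem[cand] == 0L & !added[cand]]
      } else frontier <- integer()
    } else frontier <- integer()
    S <- c(S, sum(avail))
    if (!is.null(target) && avail[target]) break
  }
  list(layers = layers, first_layer = first_layer, avail = avail,
       rem = rem, added = added, S = S)
}

initial_rem <- function(cu, avail) {
  cu$sub_count - tabulate(cu$sub_inst[avail[cu$sub_flat]], nbins = cu$n_inst)
}

#' Scope expansion of a metabolite core
#'
#' Computes the scope of a core (seed) metabolite set under AND semantics:
#' a reaction can fire only once all of its substrates are producible.
#' Reactions are added layer by layer -- layer `n` holds every directed
#' reaction instance whose substrates all became available before step `n`
#' -- until no further reaction can be added, or (with `until = "target"`)
#' until the target metabolite is first produced. Reversible reactions
#' contribute both directed instances. The expansion is deterministic;
#' randomness enters only later, in [backtrack_pathway()].
#'
#' @param universe A `metabolic_universe`.
#' @param core Character vector of core metabolite ids.
#' @param until `"full"` or `"target"`.
#' @param target Target metabolite id (for `until = "target"`).
#' @return An object of class `scope_expansion`: list with `layers`
#'   (integer instance indices per expansion step), `instances` (data frame
#'   `rid`, `dir` describing each directed instance), `first_layer` (named
#'   integer; 0 for core metabolites, `NA` outside the scope), `S`
#'   (cumulative metabolite counts, `S[1]` is the core size), `reached`
#'   (metabolite ids in the scope), and `core`.
#' @examples
#' u <- parse_mapformula(c("R1: 00: A => B", "R2: 00: B => C"))
#' expand_scope(u, "A")$first_layer
#' @export
expand_scope <- function(universe, core, until = c("full", "target"),
                         target = NULL) {
  stopifnot(inherits(universe, "metabolic_universe"))
  until <- match.arg(until)
  if (!length(core)) stop("core must contain at least one metabolite")
  cu <- compile_universe(universe)
  core_i <- met_index(cu, core)
  tgt_i <- NULL
  if (until == "target") {
    if (is.null(target)) stop("until = 'target' requires a target id")
    tgt_i <- met_index(cu, target)
  }
  avail <- logical(cu$n_met)
  avail[core_i] <- TRUE
  res <- expand_core(cu, avail, initial_rem(cu, avail), target = tgt_i)
  if (until == "target" && !res$avail[tgt_i]) {
    stop("target '", target, "' is outside the scope of the core")
  }
  fl <- res$first_layer
  names(fl) <- cu$met
  structure(
    list(
      layers = res$layers,
      instances = data.frame(rid = universe$id[cu$inst_rxn],
                             dir = cu$inst_dir),
      first_layer = fl,
      S = res$S,
      reached = cu$met[res$avail],
      core = cu$met[core_i],
      cu = cu
    ),
    class = "scope_expansion"
  )
}

#' @export
print.scope_expansion <- function(x, ...) {
  cat(sprintf(
    "<scope_expansion> %d layers, %d reactions, %d/%d metabolites reached\n",
    length(x$layers), sum(lengths(x$layers)), length(x$reached),
    length(x$first_layer)
  ))
  invisible(x)
}

#' Layer-growth ratios of a scope expansion
#'
#' Returns \eqn{S_{n+1}/S_n}, where \eqn{S_n} is the cumulative number of
#' metabolites reached by expansion step `n` (step 0 = the core). A ratio
#' profile approaching 1, matched against the `1 + theta/n` reference
#' curve, is the criticality diagnostic for reaction universes.
#'
#' @param expansion A `scope_expansion` with at least two layers.
#' @param theta Coefficient of the reference curve.
#' @return Data frame with `step`, `S`, `ratio` (\eqn{S_{n}/S_{n-1}}), and
#'   `ref`.
#' @export
expansion_profile <- function(expansion, theta = 1) {
  stopifnot(inherits(expansion, "scope_expansion"))
  S <- expansion$S
  if (length(S) < 2) stop("degenerate expansion: fewer than two steps")
  n <- seq_len(length(S) - 1L)
  data.frame(step = n, S = S[-1], ratio = S[-1] / S[-length(S)],
             ref = 1 + theta / n)
}

# All instances in the metabolite's first layer that produce it.
producers_in_first_layer <- function(expansion, m_idx) {
  L <- expansion$first_layer[[m_idx]]
  if (is.na(L) || L == 0L) return(integer())
  layer <- expansion$layers[[L]]
  layer[vapply(expansion$cu$inst_prod[layer],
               function(p) m_idx %in% p, logical(1))]
}

# Closure replay restricted to a set of instances; TRUE if target becomes
# producible from the core using only those instances.
replay_feasible <- function(cu, inst, core_idx, target_idx) {
  avail <- logical(cu$n_met)
  avail[core_idx] <- TRUE
  pend <- inst
  repeat {
    ok <- pend[vapply(cu$inst_sub[pend],
                      function(s) all(avail[s]), logical(1))]
    if (!length(ok)) break
    avail[unlist(cu$inst_prod[ok])] <- TRUE
    pend <- setdiff(pend, ok)
    if (avail[target_idx]) return(TRUE)
  }
  avail[target_idx]
}

#' Backtrack a minimal pathway from a scope expansion
#'
#' Traces the expansion back from the target: pick (uniformly at random)
#' one of the reactions producing the target in its first expansion layer,
#' then recurse on every substrate of the chosen reaction that is neither
#' in the core nor already assigned a producer, always strictly descending
#' in layers. Each metabolite receives at most one producing reaction, and
#' a pathway never uses both directions of the same reversible reaction.
#' With `prune = TRUE` (default) redundant reactions are then removed until
#' the set is subset-minimal: feasibility is monotone in the reaction set,
#' so iterated single-reaction removal yields a pathway no proper subset of
#' which can synthesize the target.
#'
#' @param expansion A `scope_expansion`.
#' @param target Target metabolite id; must be in the scope and outside
#'   the core.
#' @param seed Optional integer seed for tie-breaking.
#' @param prune Remove redundant reactions after backtracking.
#' @return An object of class `pathway`: list with `instance` (indices into
#'   the expansion's directed instances), `rid`, `dir`, `layer` (expansion
#'   step of each reaction), `substrates`, `products` (lists of metabolite
#'   ids), `target`, and `length` (the target's first expansion layer).
#' @export
backtrack_pathway <- function(expansion, target, seed = NULL, prune = TRUE) {
  stopifnot(inherits(expansion, "scope_expansion"))
  if (!is.null(seed)) set.seed(seed)
  cu <- expansion$cu
  tgt <- met_index(cu, target)
  L_t <- expansion$first_layer[[tgt]]
  if (is.na(L_t)) stop("target '", target, "' is outside the scope")
  if (L_t == 0L) stop("target '", target, "' is already in the core")
  core_idx <- met_index(cu, expansion$core)

  chosen <- integer()
  chosen_key <- character()  # rid:dir of chosen instances
  producer_of <- rep(NA_integer_, cu$n_met)
  stack <- tgt
  while (length(stack)) {
    m <- stack[[1]]
    stack <- stack[-1]
    if (!is.na(producer_of[m]) || expansion$first_layer[[m]] == 0L) next
    cand <- producers_in_first_layer(expansion, m)
    reuse <- intersect(cand, chosen)
    if (length(reuse)) {
      pick <- reuse[1]
    } else {
      rid_c <- cu$inst_rxn[cand]
      dir_c <- cu$inst_dir[cand]
      opposite <- paste0(rid_c, ":", ifelse(dir_c == "f", "b", "f"))
      ok <- cand[!(opposite %in% chosen_key)]
      if (!length(ok)) {
        warning("all producers of '", cu$met[m],
                "' conflict with directions already in the pathway; ",
                "allowing a conflicting producer")
        ok <- cand
      }
      pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
      chosen <- c(chosen, pick)
      chosen_key <- c(chosen_key,
                      paste0(cu$inst_rxn[pick], ":", cu$inst_dir[pick]))
    }
    producer_of[m] <- pick
    need <- cu$inst_sub[[pick]]
    need <- need[expansion$first_layer[need] > 0L & is.na(producer_of[need])]
    stack <- c(stack, need)
  }

  if (prune && length(chosen) > 1L) {
    repeat {
      removed <- FALSE
      for (i in rev(seq_along(chosen))) {
        trial <- chosen[-i]
        if (replay_feasible(cu, trial, core_idx, tgt)) {
          chosen <- trial
          removed <- TRUE
          break
        }
      }
      if (!removed) break
    }
  }

  inst_layer <- rep(NA_integer_, length(chosen))
  for (j in seq_along(chosen)) {
    for (L in seq_along(expansion$layers)) {
      if (chosen[j] %in% expansion$layers[[L]]) { inst_layer[j] <- L; break }
    }
  }
  ord <- order(inst_layer)
  chosen <- chosen[ord]
  inst_layer <- inst_layer[ord]
  structure(
    list(
      instance = chosen,
      rid = expansion$instances$rid[chosen],
      dir = expansion$instances$dir[chosen],
      layer = inst_layer,
      substrates = lapply(cu$inst_sub[chosen], function(s) cu$met[s]),
      products = lapply(cu$inst_prod[chosen], function(p) cu$met[p]),
      target = cu$met[tgt],
      length = L_t
    ),
    class = "pathway"
  )
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("<pathway> target %s: %d reactions over %d layers\n",
              x$target, length(x$instance), x$length))
  invisible(x)
}

#' Check that a pathway can synthesize its target from a core
#'
#' Replays the pathway's reactions under AND semantics starting from the
#' core: a reaction fires once all of its substrates are available. Returns
#' `TRUE` when the target becomes producible using only the pathway's
#' reactions.
#'
#' @param pathway A `pathway`.
#' @param universe The `metabolic_universe` it came from.
#' @param core Character vector of core metabolite ids.
#' @param target Target id (defaults to the pathway's target).
#' @return Logical.
#' @export
pathway_is_feasible <- function(pathway, universe, core,
                                target = pathway$target) {
  cu <- compile_universe(universe)
  avail <- logical(cu$n_met)
  avail[met_index(cu, core)] <- TRUE
  tgt <- met_index(cu, target)
  key <- paste0(universe$id[cu$inst_rxn], ":", cu$inst_dir)
  inst <- match(paste0(pathway$rid, ":", pathway$dir), key)
  replay_feasible(cu, inst, which(avail), tgt)
}

#' Geometry statistics of an acquired pathway
#'
#' Quantifies a pathway's position relative to the core network it was
#' added to: `n_border_rxn` counts reactions touching the core as substrate
#' or product; `n_base` the core metabolites consumed by the pathway;
#' `n_feedback` the core metabolites produced by it; `n_byproduct` the
#' terminal products that are neither core nor target nor consumed within
#' the pathway (a metabolite that is both a core product and terminal is
#' counted as feedback, not byproduct); `length` the number of expansion
#' layers from core to target; `N_M_path` the non-core metabolites the
#' pathway creates (target, intermediates and byproducts); `N_R_path` its
#' reaction count.
#'
#' @param pathway A `pathway`.
#' @param core Character vector of core metabolite ids.
#' @param currency Currency metabolite ids excluded from byproduct counts
#'   (they are ubiquitously recycled); has no effect on metabolites already
#'   in `core`.
#' @param count_currency_byproducts Set `TRUE` to count currency byproducts
#'   after all.
#' @return A one-row data frame: `target`, `N_R_path`, `N_M_path`,
#'   `length`, `n_border_rxn`, `n_base`, `n_feedback`, `n_byproduct`.
#' @export
pathway_geometry <- function(pathway, core, currency = character(),
                             count_currency_byproducts = FALSE) {
  stopifnot(inherits(pathway, "pathway"))
  all_sub <- unique(unlist(pathway$substrates))
  all_prod <- unique(unlist(pathway$products))
  border <- mapply(function(s, p) any(c(s, p) %in% core),
                   pathway$substrates, pathway$products)
  byprod <- setdiff(all_prod, c(core, pathway$target, all_sub))
  if (!count_currency_byproducts) byprod <- setdiff(byprod, currency)
  data.frame(
    target = pathway$target,
    N_R_path = length(pathway$instance),
    N_M_path = length(setdiff(all_prod, core)),
    length = pathway$length,
    n_border_rxn = sum(border),
    n_base = length(intersect(core, all_sub)),
    n_feedback = length(intersect(core, all_prod)),
    n_byproduct = length(byprod),
    stringsAsFactors = FALSE
  )
}

#' Shortest simple-graph distance from a core to a target
#'
#' Hop count of the shortest directed path from any core metabolite to the
#' target on the simple-graph projection, i.e. ignoring the AND constraint
#' of multi-substrate reactions. Pathway lengths under AND semantics are
#' bounded below by this distance and on realistic universes exceed it
#' severalfold.
#'
#' @param universe A `metabolic_universe`.
#' @param core Character vector of core metabolite ids.
#' @param target Target metabolite id.
#' @param graph Optional precomputed [project_simple_graph()] result.
#' @return Integer hop count (0 when the target is in the core).
#' @export
shortest_distance_to_core <- function(universe, core, target, graph = NULL) {
  if (target %in% core) return(0L)
  if (is.null(graph)) graph <- project_simple_graph(universe)
  core <- intersect(core, igraph::V(graph)$name)
  if (!target %in% igraph::V(graph)$name || !length(core)) {
    stop("target '", target, "' unreachable from the core")
  }
  d <- suppressWarnings(
    igraph::distances(graph, v = core, to = target, mode = "out"))
  dmin <- min(d)
  if (!is.finite(dmin)) stop("target '", target, "' unreachable from the core")
  as.integer(dmin)
}
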