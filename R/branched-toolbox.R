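#' Initialize an organism on a reaction universe
#'
#' The organism starts with a seed core (by default the universe's
#' `seed_metabolites` attribute, i.e. central metabolism plus currency
#' co-factors) and no acquired reactions. The full scope of the seed set is
#' precomputed: it is the pool from which evolutionary targets are drawn.
#'
#' @param universe A `metabolic_universe`.
#' @param seed_metabolites Character vector of seed metabolite ids.
#' @param candidate_targets Optional character vector restricting the pool
#'   of evolutionary targets (default: every scope metabolite). Useful for
#'   targeting only terminal end-products, e.g. when comparing against the
#'   tree model whose targets are leaves.
#' @return An object of class `organism_state`.
#' @export
init_state <- function(universe,
                       seed_metabolites = attr(universe, "seed_metabolites"),
                       candidate_targets = NULL) {
  stopifnot(inherits(universe, "metabolic_universe"))
  if (is.null(seed_metabolites) || !length(seed_metabolites)) {
    stop("seed_metabolites must be a non-empty set of metabolite ids")
  }
  cu <- compile_universe(universe)
  core_i <- met_index(cu, seed_metabolites)
  avail <- logical(cu$n_met)
  avail[core_i] <- TRUE
  full <- expand_core(cu, avail, initial_rem(cu, avail))
  candidate <- full$avail
  if (!is.null(candidate_targets)) {
    cmask <- logical(cu$n_met)
    cmask[met_index(cu, candidate_targets)] <- TRUE
    candidate <- candidate & cmask
  }
  structure(
    list(
      cu = cu,
      seed = cu$met[core_i],
      core = avail,                        # current synthesizable set
      rem_core = initial_rem(cu, avail),   # unmet substrates wrt core
      scope = full$avail,                  # seed + everything reachable
      candidate = candidate,               # eligible targets within scope
      acquired_rxn = logical(n_reactions(universe)),
      N_L = 0L,
      trajectory = list(),
      pathways = list()
    ),
    class = "organism_state"
  )
}

#' @export
print.organism_state <- function(x, ...) {
  cat(sprintf(
    "<organism_state> N_L=%d, core %d/%d scope metabolites, %d reactions\n",
    x$N_L, sum(x$core), sum(x$scope), sum(x$acquired_rxn)
  ))
  invisible(x)
}

# Grow the core by `new_idx` and close it under the acquired reactions:
# owning an enzyme means both directions of its reaction can fire, so any
# owned instance whose substrates become available adds its products too.
grow_core <- function(state, new_idx) {
  cu <- state$cu
  queue <- new_idx[!state$core[new_idx]]
  while (length(queue)) {
    state$core[queue] <- TRUE
    touched <- unlist(cu$cons_by_met[queue], use.names = FALSE)
    if (length(touched)) {
      state$rem_core <- state$rem_core - tabulate(touched, nbins = cu$n_inst)
      ready <- unique(touched)
      ready <- ready[state$rem_core[ready] == 0L &
                       state$acquired_rxn[cu$inst_rxn[ready]]]
      prods <- unique(unlist(cu$inst_prod[ready]))
      queue <- prods[!state$core[prods]]
    } else queue <- integer()
  }
  state
}

#' Acquire a minimal pathway to one random target
#'
#' One evolutionary step of the branched toolbox model: a metabolite that
#' the organism cannot yet synthesize is drawn uniformly from the scope of
#' its seed set; scope expansion from the current core is run until the
#' target is reached; a minimal pathway is backtracked; its reactions are
#' horizontally transferred and the target plus every newly producible
#' metabolite joins the core. `N_L`, the number of pathways and hence of
#' dedicated transcriptional regulators, grows by one.
#'
#' @param state An `organism_state`.
#' @param target Optional target id (default: uniform random draw).
#' @return A list with the updated `state` and the acquired `pathway`.
#' @export
acquire_target <- function(state, target = NULL) {
  stopifnot(inherits(state, "organism_state"))
  cu <- state$cu
  pool <- which(state$candidate & !state$core)
  if (!length(pool)) stop("scope exhausted: evolution complete")
  tgt <- if (!is.null(target)) met_index(cu, target)
         else if (length(pool) == 1L) pool else sample(pool, 1L)

  ex <- expand_core(cu, state$core, state$rem_core, target = tgt)
  fl <- ex$first_layer
  names(fl) <- cu$met
  expansion <- structure(
    list(layers = ex$layers,
         instances = data.frame(rid = cu$universe$id[cu$inst_rxn],
                                dir = cu$inst_dir),
         first_layer = fl, S = ex$S, reached = cu$met[ex$avail],
         core = cu$met[state$core], cu = cu),
    class = "scope_expansion"
  )
  pw <- backtrack_pathway(expansion, cu$met[tgt])

  state$acquired_rxn[cu$inst_rxn[pw$instance]] <- TRUE
  new_mets <- unique(unlist(cu$inst_prod[pw$instance]))
  state <- grow_core(state, new_mets)
  state$N_L <- state$N_L + 1L
  list(state = state, pathway = pw)
}

#' Simulate the branched toolbox model to completion
#'
#' Repeats [acquire_target()] until the organism's network covers the
#' entire scope of its seed set, recording `(N_L, N_M)` after every
#' acquisition together with each pathway's geometry statistics.
#'
#' @param universe A `metabolic_universe`.
#' @param seed_metabolites Seed core ids (default: the universe's
#'   `seed_metabolites` attribute).
#' @param candidate_targets Optional restriction of the target pool; see
#'   [init_state()].
#' @param seed Optional integer seed.
#' @param max_pathways Stop after this many acquisitions (default: run to
#'   exhaustion).
#' @param include_seed_in_NM Count seed metabolites in `N_M` (default
#'   `TRUE`; the offset does not affect fitted exponents).
#' @param geometry Also record per-pathway geometry (small extra cost).
#' @return A list with `trajectory` (a `toolbox_trajectory` data frame),
#'   `pathways` (geometry rows, one per acquisition), and the final
#'   `state`.
#' @examples
#' u <- generate_synthetic_universe(120, 6, seed = 1, seed_size = 10)
#' res <- simulate_evolution(u, seed = 1)
#' tail(res$trajectory, 1)
#' @export
simulate_evolution <- function(universe,
                               seed_metabolites = attr(universe, "seed_metabolites"),
                               candidate_targets = NULL,
                               seed = NULL, max_pathways = Inf,
                               include_seed_in_NM = TRUE,
                               geometry = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(universe, seed_metabolites, candidate_targets)
  currency <- attr(universe, "currency")
  if (is.null(currency)) currency <- character()
  n_seed <- sum(state$core)
  NL <- integer(); NM <- integer()
  geom <- list()
  while (any(state$candidate & !state$core) && state$N_L < max_pathways) {
    core_before <- state$cu$met[state$core]
    res <- acquire_target(state)
    state <- res$state
    NL[state$N_L] <- state$N_L
    NM[state$N_L] <- sum(state$core) - if (include_seed_in_NM) 0L else n_seed
    if (geometry) {
      geom[[state$N_L]] <- pathway_geometry(res$pathway, core_before,
                                            currency = currency)
    }
  }
  traj <- data.frame(step = NL, N_L = NL, N_M = NM)
  attr(traj, "seed") <- seed
  class(traj) <- c("toolbox_trajectory", "data.frame")
  list(
    trajectory = traj,
    pathways = if (geometry && length(geom)) do.call(rbind, geom) else NULL,
    state = state
  )
}

#' Write a pathway-geometry table as TSV
#'
#' One row per acquired pathway with the columns produced by
#' [pathway_geometry()].
#'
#' @param pathways Data frame of geometry rows.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(pathways, path) {
  utils::write.table(pathways, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
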