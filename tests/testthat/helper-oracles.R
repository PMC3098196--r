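# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (full rescans, exhaustive enumeration) and share no
# code with the package internals they check.

# Directed instances of a universe as plain character-set records.
naive_instances <- function(universe) {
  inst <- list()
  for (i in seq_along(universe$id)) {
    inst[[length(inst) + 1]] <- list(
      key = paste0(universe$id[i], ":f"),
      sub = universe$substrates[[i]], prod = universe$products[[i]])
    if (universe$reversible[i]) {
      inst[[length(inst) + 1]] <- list(
        key = paste0(universe$id[i], ":b"),
        sub = universe$products[[i]], prod = universe$substrates[[i]])
    }
  }
  inst
}

# Fixed-point layering by repeated full rescans over all instances.
naive_scope <- function(universe, core) {
  inst <- naive_instances(universe)
  avail <- unique(core)
  used <- rep(FALSE, length(inst))
  layers <- list()
  first_layer <- stats::setNames(rep(0L, length(avail)), avail)
  repeat {
    ok <- which(!used & vapply(inst, function(r) all(r$sub %in% avail),
                               logical(1)))
    if (!length(ok)) break
    layers[[length(layers) + 1]] <- sort(vapply(inst[ok], `[[`, "", "key"))
    used[ok] <- TRUE
    new_met <- setdiff(unique(unlist(lapply(inst[ok], `[[`, "prod"))), avail)
    first_layer[new_met] <- length(layers)
    avail <- c(avail, new_met)
  }
  list(layers = layers, reached = sort(avail), first_layer = first_layer)
}

# AND-semantics feasibility of a set of instance keys, by brute replay.
naive_feasible <- function(universe, keys, core, target) {
  inst <- naive_instances(universe)
  inst <- inst[vapply(inst, `[[`, "", "key") %in% keys]
  avail <- unique(core)
  repeat {
    ok <- which(vapply(inst, function(r) all(r$sub %in% avail), logical(1)))
    if (!length(ok)) break
    avail <- union(avail, unlist(lapply(inst[ok], `[[`, "prod")))
    inst <- inst[-ok]
    if (target %in% avail) return(TRUE)
  }
  target %in% avail
}

# Exhaustive subset-minimality: no proper subset of `keys` is feasible.
naive_subset_minimal <- function(universe, keys, core, target) {
  n <- length(keys)
  if (n > 12) stop("exhaustive check limited to 12 reactions")
  if (n == 0) return(TRUE)
  for (mask in seq_len(2^n - 1) - 1) {  # all proper subsets incl. empty
    sel <- keys[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) == n) next
    if (naive_feasible(universe, sel, core, target)) return(FALSE)
  }
  TRUE
}

# Closure of a core under an owned subset of reactions (both directions of
# an owned reversible reaction may fire), by repeated full rescans.
naive_scope_closure <- function(universe, core, owned) {
  avail <- unique(core)
  inst <- naive_instances(universe)
  rids <- sub(":(f|b)$", "", vapply(inst, `[[`, "", "key"))
  inst <- inst[owned[match(rids, universe$id)]]
  repeat {
    ok <- which(vapply(inst, function(r) all(r$sub %in% avail), logical(1)))
    if (!length(ok)) break
    avail <- union(avail, unlist(lapply(inst[ok], `[[`, "prod")))
    inst <- inst[-ok]
  }
  sort(avail)
}

# Random small reaction universe for property tests. Uses the session RNG.
random_toy_universe <- function(n_rxn = 15, n_met = 12, p_rev = 0.3) {
  mets <- LETTERS[seq_len(n_met)]
  subs <- list(); prods <- list(); revs <- logical()
  for (i in seq_len(n_rxn)) {
    ns <- sample(1:2, 1)
    np <- sample(1:2, 1)
    s <- sample(mets, ns)
    p <- sample(setdiff(mets, s), np)
    subs[[i]] <- s; prods[[i]] <- p; revs[i] <- stats::runif(1) < p_rev
  }
  metabolic_universe(sprintf("T%03d", seq_len(n_rxn)), subs, prods, revs,
                     metabolites = mets)
}

# Expected N_M after acquiring k leaves, by exhaustive enumeration of
# ordered leaf tuples and direct union of root paths.
enumerate_expected_nm <- function(tree, k) {
  root_path <- function(v) {
    out <- integer()
    while (!is.na(v)) { out <- c(out, v); v <- tree$parent[v] }
    out
  }
  leaves <- tree_leaves(tree)
  tuples <- do.call(expand.grid, rep(list(leaves), k))
  tuples <- tuples[apply(tuples, 1, function(r) !anyDuplicated(r)), ,
                   drop = FALSE]
  mean(apply(tuples, 1, function(r) {
    length(unique(unlist(lapply(r, root_path))))
  }))
}

# The four-reaction AND-gate toy: F needs E, which needs both B and D.
and_gate_universe <- function(extra_shortcut = FALSE) {
  ids <- c("r1", "r2", "r3", "r4")
  subs <- list("A", "A", c("B", "D"), "E")
  prods <- list("B", "D", "E", "F")
  if (extra_shortcut) {
    ids <- c(ids, "r5")
    subs <- c(subs, list(c("X", "A")))  # X is never producible
    prods <- c(prods, list("E"))
  }
  metabolic_universe(ids, subs, prods, rep(FALSE, length(ids)))
}

# Small deterministic binary tree: root, 2 children, 4 grandchild leaves.
binary7_tree <- function() {
  toolboxevo:::new_layered_tree(
    parent = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
    depth = c(0L, 1L, 1L, 2L, 2L, 2L, 2L)
  )
}

pathway_keys <- function(pathway) paste0(pathway$rid, ":", pathway$dir)
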