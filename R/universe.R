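#' Construct a metabolic reaction universe
#'
#' A universe is a hypergraph of reactions over metabolite identifiers.
#' Each reaction has a non-empty substrate set and a non-empty product set;
#' a reversible reaction contributes two directed instances (forward and
#' backward) wherever directions matter. Metabolites appearing on both
#' sides of one reaction are vacuous under boolean (presence/absence)
#' semantics and are removed from the substrate side (both sides for
#' reversible reactions) during normalization; reactions emptied by
#' normalization are dropped and recorded in the `"dropped"` attribute.
#'
#' @param id Character vector of reaction ids (unique).
#' @param substrates,products Lists of character vectors of metabolite ids.
#' @param reversible Logical vector.
#' @param metabolites Optional character vector of additional metabolite
#'   ids to carry (e.g. seed metabolites no reaction touches); the ids
#'   appearing in reactions are always included.
#' @return An object of class `metabolic_universe` with fields
#'   `metabolites`, `id`, `substrates`, `products`, `reversible`.
#' @export
metabolic_universe <- function(id, substrates, products, reversible,
                               metabolites = character()) {
  stopifnot(length(id) == length(substrates),
            length(id) == length(products),
            length(id) == length(reversible))
  if (anyDuplicated(id)) stop("reaction ids must be unique")
  substrates <- lapply(substrates, function(s) unique(as.character(s)))
  products <- lapply(products, function(p) unique(as.character(p)))
  dropped <- character()
  for (i in seq_along(id)) {
    both <- intersect(substrates[[i]], products[[i]])
    if (length(both)) {
      substrates[[i]] <- setdiff(substrates[[i]], both)
      if (reversible[i]) products[[i]] <- setdiff(products[[i]], both)
    }
  }
  keep <- lengths(substrates) > 0 & lengths(products) > 0
  dropped <- id[!keep]
  uni <- structure(
    list(
      metabolites = sort(unique(c(as.character(metabolites),
                                  unlist(substrates[keep]),
                                  unlist(products[keep])))),
      id = id[keep],
      substrates = substrates[keep],
      products = products[keep],
      reversible = as.logical(reversible[keep])
    ),
    class = "metabolic_universe"
  )
  attr(uni, "dropped") <- dropped
  uni
}

#' @export
print.metabolic_universe <- function(x, ...) {
  cat(sprintf(
    "<metabolic_universe> %d metabolites, %d reactions (%d reversible)\n",
    length(x$metabolites), length(x$id), sum(x$reversible)
  ))
  invisible(x)
}

n_reactions <- function(universe) length(universe$id)

#' Parse the KEGG map-formula reaction dialect
#'
#' Reads lines of the form
#' `RID: MAPID: C00001 + C00002 => C00003 + C00004` with direction tokens
#' `=>`, `<=` or `<=>`. Lines with `<=` are normalized by swapping sides.
#' A reaction id observed with conflicting directions on different maps, or
#' with `<=>`, is marked reversible; repeated observations of one id are
#' merged (side-wise union in the normalized orientation). Stoichiometric
#' coefficients (leading integers such as `2 C00001`) are ignored: the
#' model is boolean.
#'
#' @param input A file path, a connection, or a character vector of lines.
#' @return A `metabolic_universe`.
#' @examples
#' parse_mapformula("R00001: 00010: C00001 + C00002 => C00003")
#' @export
parse_mapformula <- function(input) {
  ln <- if (is.character(input) && length(input) == 1 && file.exists(input)) {
    readLines(input)
  } else if (inherits(input, "connection")) {
    readLines(input)
  } else {
    as.character(input)
  }
  ln_raw <- ln
  ln <- trimws(ln)
  keep <- nzchar(ln) & !startsWith(ln, "#")
  idx <- which(keep)
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    m <- regexec("^([^:]+):\\s*([^:]+):\\s*(.*)$", ln[i])[[1]]
    if (m[1] == -1) stop("malformed map-formula line ", i, ": ", ln_raw[i])
    parts <- regmatches(ln[i], list(m))[[1]]
    rid <- trimws(parts[2])
    body <- parts[4]
    dir <- if (grepl("<=>", body, fixed = TRUE)) "<=>"
      else if (grepl("=>", body, fixed = TRUE)) "=>"
      else if (grepl("<=", body, fixed = TRUE)) "<="
      else stop("unknown direction token on line ", i, ": ", ln_raw[i])
    sides <- strsplit(body, dir, fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("malformed map-formula line ", i, ": ",
                                 ln_raw[i])
    split_side <- function(s) {
      toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      toks <- toks[nzchar(toks)]
      if (!length(toks)) stop("empty reaction side on line ", i, ": ",
                              ln_raw[i])
      # drop leading stoichiometric coefficients ("2 C00001", "2C00001")
      sub("^[0-9]+\\s*(?=[A-Za-z])", "", toks, perl = TRUE)
    }
    lhs <- split_side(sides[1])
    rhs <- split_side(sides[2])
    if (dir == "<=") { tmp <- lhs; lhs <- rhs; rhs <- tmp }
    recs[[k]] <- list(rid = rid, sub = lhs, prod = rhs, rev = dir == "<=>")
  }
  if (!length(recs)) {
    return(metabolic_universe(character(), list(), list(), logical()))
  }
  rid_all <- vapply(recs, `[[`, "", "rid")
  uids <- unique(rid_all)
  subs <- vector("list", length(uids))
  prods <- vector("list", length(uids))
  revs <- logical(length(uids))
  for (j in seq_along(uids)) {
    grp <- recs[rid_all == uids[j]]
    cs <- grp[[1]]$sub
    cp <- grp[[1]]$prod
    rv <- grp[[1]]$rev
    for (g in grp[-1]) {
      if (g$rev) rv <- TRUE
      if (setequal(g$sub, cp) && setequal(g$prod, cs)) {
        rv <- TRUE  # same reaction observed in the opposite direction
      } else {
        cs <- union(cs, g$sub)
        cp <- union(cp, g$prod)
      }
    }
    subs[[j]] <- cs; prods[[j]] <- cp; revs[j] <- rv
  }
  metabolic_universe(uids, subs, prods, revs)
}

#' Write / read a universe as TSV
#'
#' One row per reaction: `reaction_id`, `reversible` (0/1), comma-separated
#' `substrates` and `products`. Parsing a written file reproduces the
#' universe exactly (normalization is idempotent).
#'
#' @param universe A `metabolic_universe`.
#' @param path File path.
#' @return `write_universe` returns `path` invisibly; `read_universe` the
#'   universe.
#' @export
write_universe <- function(universe, path) {
  stopifnot(inherits(universe, "metabolic_universe"))
  rows <- sprintf(
    "%s\t%d\t%s\t%s", universe$id, as.integer(universe$reversible),
    vapply(universe$substrates, paste, "", collapse = ","),
    vapply(universe$products, paste, "", collapse = ",")
  )
  writeLines(c("reaction_id\treversible\tsubstrates\tproducts", rows), path)
  invisible(path)
}

#' @rdname write_universe
#' @export
read_universe <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  ln <- ln[-1]
  if (!length(ln)) {
    return(metabolic_universe(character(), list(), list(), logical()))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  metabolic_universe(
    id = vapply(parts, `[`, "", 1),
    reversible = vapply(parts, `[`, "", 2) == "1",
    substrates = lapply(parts, function(p) strsplit(p[3], ",")[[1]]),
    products = lapply(parts, function(p) strsplit(p[4], ",")[[1]])
  )
}

#' Remove currency metabolites from a universe
#'
#' Deletes the listed metabolite ids -- and, when `degree_threshold` is
#' given, any metabolite participating in more than that many reactions --
#' from every substrate and product set. Reactions left without substrates
#' or without products are dropped. Ubiquitous co-factors (water, ATP,
#' NAD, ...) create biochemically meaningless shortcuts in simple-graph
#' projections; removing them is a standard preprocessing step before
#' linearization.
#'
#' @param universe A `metabolic_universe`.
#' @param currency Character vector of metabolite ids (absent ids are
#'   ignored).
#' @param degree_threshold Optional integer; metabolites occurring in more
#'   than this many reactions are removed as well.
#' @return The reduced universe, with attribute `"removal_report"`: a list
#'   with `removed_metabolites` and `dropped_reactions`.
#' @export
remove_currency <- function(universe, currency = character(),
                            degree_threshold = NULL) {
  stopifnot(inherits(universe, "metabolic_universe"))
  remove <- intersect(currency, universe$metabolites)
  if (!is.null(degree_threshold)) {
    occ <- table(unlist(lapply(seq_along(universe$id), function(i) {
      unique(c(universe$substrates[[i]], universe$products[[i]]))
    })))
    remove <- union(remove, names(occ)[occ > degree_threshold])
  }
  subs <- lapply(universe$substrates, setdiff, y = remove)
  prods <- lapply(universe$products, setdiff, y = remove)
  keep <- lengths(subs) > 0 & lengths(prods) > 0
  out <- metabolic_universe(universe$id[keep], subs[keep], prods[keep],
                            universe$reversible[keep])
  attr(out, "removal_report") <- list(
    removed_metabolites = remove,
    dropped_reactions = universe$id[!keep]
  )
  out
}

#' Project a universe onto a simple directed metabolite graph
#'
#' Adds an edge substrate -> product for every (substrate, product) pair of
#' every directed reaction instance; reversible reactions contribute both
#' directions. Parallel edges are collapsed. This projection discards the
#' AND constraint of multi-substrate reactions and is used only for
#' linearization and shortest-distance baselines.
#'
#' @param universe A `metabolic_universe`.
#' @return An [igraph::graph] with metabolite ids as vertex names.
#' @export
project_simple_graph <- function(universe) {
  stopifnot(inherits(universe, "metabolic_universe"))
  ft <- vector("list", 2 * n_reactions(universe))
  k <- 0
  for (i in seq_along(universe$id)) {
    s <- universe$substrates[[i]]
    p <- universe$products[[i]]
    k <- k + 1
    ft[[k]] <- cbind(rep(s, each = length(p)), rep(p, times = length(s)))
    if (universe$reversible[i]) {
      k <- k + 1
      ft[[k]] <- cbind(rep(p, each = length(s)), rep(s, times = length(p)))
    }
  }
  ft <- do.call(rbind, ft[seq_len(k)])
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(universe$metabolites)
  if (!is.null(ft) && nrow(ft)) {
    g <- igraph::add_edges(g, t(ft))
    g <- igraph::simplify(g)
  }
  g
}

#' Linearize a reaction graph into a random spanning tree
#'
#' Reproduces the self-avoiding-random-walk linearization of a metabolic
#' network: repeatedly pick an uncovered metabolite (uniformly among those
#' that can reach the root) and walk along directed edges, avoiding
#' revisits, until the walk merges with the tree built so far or reaches
#' the root. A dead-ended walk is restarted from the same metabolite (up to
#' `max_restarts` times, then the shortest path is used for that metabolite
#' and the fallback is reported). Metabolites with no directed path to the
#' root are excluded and listed in the tree's `excluded` field.
#'
#' @param graph A directed [igraph::graph] with named vertices (e.g. from
#'   [project_simple_graph()]).
#' @param root Root metabolite id (e.g. pyruvate, KEGG `C00022`).
#' @param seed Optional integer seed.
#' @param max_restarts Restart cap per start metabolite.
#' @return A `layered_tree` with metabolite names; depths are tree
#'   distances to the root.
#' @export
random_spanning_tree <- function(graph, root, seed = NULL,
                                 max_restarts = 100) {
  vs <- igraph::V(graph)$name
  if (!root %in% vs) stop("root '", root, "' not present in graph")
  if (!is.null(seed)) set.seed(seed)
  reach <- igraph::subcomponent(graph, root, mode = "in")$name
  sub <- igraph::induced_subgraph(graph, reach)
  ids <- igraph::V(sub)$name
  n <- length(ids)
  adj <- igraph::adjacent_vertices(sub, igraph::V(sub), mode = "out")
  adj <- lapply(adj, as.integer)
  rooti <- match(root, ids)
  parent <- rep(NA_integer_, n)
  in_tree <- logical(n)
  in_tree[rooti] <- TRUE
  fallbacks <- character()
  repeat {
    pool <- which(!in_tree)
    if (!length(pool)) break
    start <- if (length(pool) == 1L) pool else sample(pool, 1L)
    walk <- NULL
    for (attempt in seq_len(max_restarts)) {
      w <- start
      cur <- start
      repeat {
        nb <- setdiff(adj[[cur]], w)
        if (!length(nb)) break  # dead end
        nxt <- if (length(nb) == 1L) nb else sample(nb, 1L)
        w <- c(w, nxt)
        if (in_tree[nxt]) { walk <- w; break }
        cur <- nxt
      }
      if (!is.null(walk)) break
    }
    if (is.null(walk)) {
      sp <- igraph::shortest_paths(sub, from = start, to = rooti,
                                   mode = "out")$vpath[[1]]
      sp <- as.integer(sp)
      hit <- which(in_tree[sp])[1]
      walk <- sp[seq_len(hit)]
      fallbacks <- c(fallbacks, ids[start])
    }
    for (j in seq_len(length(walk) - 1L)) {
      if (!in_tree[walk[j]]) {
        parent[walk[j]] <- walk[j + 1L]
        in_tree[walk[j]] <- TRUE
      }
    }
  }
  # depths follow parent chains to the root
  depth <- rep(NA_integer_, n)
  depth[rooti] <- 0L
  todo <- which(!is.na(parent))
  while (length(todo)) {
    ready <- todo[!is.na(depth[parent[todo]])]
    depth[ready] <- depth[parent[ready]] + 1L
    todo <- setdiff(todo, ready)
  }
  # reorder so the root is node 1 (layered_tree convention)
  ord <- order(depth, seq_len(n))
  rank <- match(seq_len(n), ord)
  tree <- new_layered_tree(
    parent = ifelse(is.na(parent[ord]), NA_integer_, rank[parent[ord]]),
    depth = depth[ord], names = ids[ord], seed = seed,
    mode = "random_walk", excluded = setdiff(vs, reach)
  )
  attr(tree, "fallbacks") <- fallbacks
  tree
}

#' Linearize a reaction graph into a shortest-path tree
#'
#' Breadth-first tree of shortest directed paths to the root: every
#' metabolite's depth equals its shortest directed distance to the root,
#' and its parent is drawn uniformly (seeded) among out-neighbors one step
#' closer. Metabolites that cannot reach the root are excluded and
#' reported. On dense reaction graphs this produces supercritical,
#' logarithmically shallow trees, in contrast to [random_spanning_tree()].
#'
#' @inheritParams random_spanning_tree
#' @return A `layered_tree` with metabolite names.
#' @export
shortest_path_tree <- function(graph, root, seed = NULL) {
  vs <- igraph::V(graph)$name
  if (!root %in% vs) stop("root '", root, "' not present in graph")
  if (!is.null(seed)) set.seed(seed)
  dist <- igraph::distances(graph, to = root, mode = "out")[, 1]
  reach <- names(dist)[is.finite(dist)]
  sub <- igraph::induced_subgraph(graph, reach)
  ids <- igraph::V(sub)$name
  d <- dist[ids]
  n <- length(ids)
  adj <- igraph::adjacent_vertices(sub, igraph::V(sub), mode = "out")
  adj <- lapply(adj, as.integer)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (d[i] == 0) next
    cand <- adj[[i]][d[adj[[i]]] == d[i] - 1]
    parent[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  ord <- order(d, seq_len(n))
  rank <- match(seq_len(n), ord)
  new_layered_tree(
    parent = ifelse(is.na(parent[ord]), NA_integer_, rank[parent[ord]]),
    depth = as.integer(d[ord]), names = ids[ord], seed = seed,
    mode = "shortest_path", excluded = setdiff(vs, reach)
  )
}

#' Substrate/product multiplicity counts of the KEGG reaction universe
#'
#' Empirical joint counts of (number of substrates, number of products) for
#' irreversible reactions and (sizes of the two ends) for reversible
#' reactions in the curated KEGG reaction set underlying the branched
#' toolbox model. Used as default sampling weights by
#' [generate_synthetic_universe()].
#'
#' @return A list with matrices `irreversible` (5x5, rows = substrates) and
#'   `reversible` (4x5, rows = one end).
#' @export
kegg_multiplicity_tables <- function() {
  irrev <- matrix(c(
    157, 141,   4,  0, 0,
     82, 491,  95,  7, 0,
      1, 123, 170, 31, 1,
      0,  10,  73, 15, 0,
      0,   0,   1,  0, 0
  ), nrow = 5, byrow = TRUE,
  dimnames = list(substrates = 1:5, products = 1:5))
  rev <- matrix(c(
    143, 231,   6,  0, 0,
      0, 553, 284, 15, 0,
      0,   0, 106, 69, 1,
      0,   0,   0,  6, 3
  ), nrow = 4, byrow = TRUE,
  dimnames = list(end1 = 1:4, end2 = 1:5))
  list(irreversible = irrev, reversible = rev)
}

sample_multiplicity <- function(weights, n) {
  idx <- sample.int(length(weights), n, replace = TRUE, prob = as.vector(weights))
  cbind(ns = as.integer((idx - 1) %% nrow(weights)) + 1L,
        np = as.integer((idx - 1) %/% nrow(weights)) + 1L)
}

#' Generate a layered synthetic reaction universe
#'
#' Emulates the structure of the curated metabolic universe used by the
#' branched toolbox model: metabolites are organized in layers 0..`n_layers`
#' (layer 0 is the seed set, whose first `currency_size` members play the
#' role of ubiquitous currency co-factors), and every reaction produces
#' metabolites of its own layer from substrates of strictly lower layers,
#' at least one of which sits in the immediately preceding layer. Reaction
#' multiplicities are drawn from empirical KEGG weights (see
#' [kegg_multiplicity_tables()]); additional substrates beyond the first
#' are currency metabolites with probability `currency_bias`, mirroring the
#' fact that most multi-substrate reactions pair one pathway intermediate
#' with a co-factor. Every non-seed metabolite is covered by at least one
#' producing reaction, so the scope of the seed set is the entire
#' metabolite set and scope expansion proceeds one layer per step
#' (critical-like algebraic growth). Beyond the covering reactions,
#' `extra_reaction_factor` times as many extra reactions are added with
#' uniformly chosen products, providing alternative producers and a
#' KEGG-like reaction/metabolite ratio.
#'
#' @param n_metabolites Total number of metabolites (including the seed).
#' @param n_layers Number of non-seed layers.
#' @param multiplicity_weights List with `irreversible` and `reversible`
#'   weight matrices; defaults to the KEGG counts.
#' @param reversibility_fraction Probability that a reaction is reversible.
#' @param seed Optional integer seed.
#' @param seed_size Number of seed (layer-0) metabolites.
#' @param currency_size Number of seed metabolites designated as currency.
#' @param currency_bias Probability that a secondary substrate is drawn
#'   from the currency set.
#' @param extra_reaction_factor Extra (non-covering) reactions per layer,
#'   as a multiple of the covering reactions.
#' @return A `metabolic_universe` with attributes `seed_metabolites`,
#'   `currency`, and `layer_of` (named integer vector).
#' @examples
#' u <- generate_synthetic_universe(120, 6, seed = 1, seed_size = 10)
#' length(expand_scope(u, attr(u, "seed_metabolites"))$reached)
#' @export
generate_synthetic_universe <- function(n_metabolites = 2000,
                                        n_layers = 40,
                                        multiplicity_weights = kegg_multiplicity_tables(),
                                        reversibility_fraction = 0.5,
                                        seed = NULL,
                                        seed_size = 40,
                                        currency_size = 10,
                                        currency_bias = 0.8,
                                        extra_reaction_factor = 2) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (seed_size < 1 || seed_size >= n_metabolites) {
    stop("seed_size must be in [1, n_metabolites)")
  }
  if (currency_size > seed_size) stop("currency_size cannot exceed seed_size")
  if (!is.null(seed)) set.seed(seed)

  n_rest <- n_metabolites - seed_size
  sizes <- rep(n_rest %/% n_layers, n_layers)
  extra <- n_rest %% n_layers
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (any(sizes < 1)) stop("layers too small: increase n_metabolites or reduce n_layers")
  layer_of <- c(rep(0L, seed_size), rep(seq_len(n_layers), sizes))
  met <- sprintf("M%05d", seq_len(n_metabolites))
  names(layer_of) <- met
  currency <- met[seq_len(currency_size)]
  mets_in <- split(met, layer_of)

  rid <- character()
  subs <- list()
  prods <- list()
  revs <- logical()
  k <- 0
  lower_noncur <- setdiff(mets_in[["0"]], currency)

  make_rxn <- function(layer, force_products = NULL) {
    rev <- stats::runif(1) < reversibility_fraction
    w <- if (rev) multiplicity_weights$reversible else multiplicity_weights$irreversible
    mult <- sample_multiplicity(w, 1)
    ns <- mult[1, "ns"]; np <- mult[1, "np"]
    here <- mets_in[[as.character(layer)]]
    np <- min(np, length(here))
    pr <- force_products
    if (length(pr) > np) pr <- pr[seq_len(np)]
    if (length(pr) < np) {
      pr <- c(pr, sample(setdiff(here, pr), np - length(pr)))
    }
    prev <- mets_in[[as.character(layer - 1)]]
    s1 <- if (length(prev) == 1L) prev else sample(prev, 1L)
    ss <- s1
    if (ns > 1) {
      for (j in seq_len(ns - 1)) {
        use_cur <- stats::runif(1) < currency_bias && length(setdiff(currency, ss))
        pool <- if (use_cur) setdiff(currency, ss) else setdiff(lower_noncur, ss)
        if (!length(pool)) pool <- setdiff(c(currency, lower_noncur), ss)
        if (!length(pool)) break
        ss <- c(ss, if (length(pool) == 1L) pool else sample(pool, 1L))
      }
    }
    list(sub = ss, prod = pr, rev = rev)
  }

  for (layer in seq_len(n_layers)) {
    here <- mets_in[[as.character(layer)]]
    uncovered <- here
    n_cover <- 0
    while (length(uncovered)) {
      r <- make_rxn(layer, force_products = uncovered)
      k <- k + 1; n_cover <- n_cover + 1
      rid[k] <- sprintf("R%05d", k)
      subs[[k]] <- r$sub; prods[[k]] <- r$prod; revs[k] <- r$rev
      uncovered <- setdiff(uncovered, r$prod)
    }
    n_extra <- round(extra_reaction_factor * n_cover)
    for (e in seq_len(n_extra)) {
      r <- make_rxn(layer)
      k <- k + 1
      rid[k] <- sprintf("R%05d", k)
      subs[[k]] <- r$sub; prods[[k]] <- r$prod; revs[k] <- r$rev
    }
    lower_noncur <- c(lower_noncur, here)
  }

  uni <- metabolic_universe(rid, subs, prods, revs, metabolites = met)
  attr(uni, "seed_metabolites") <- mets_in[["0"]]
  attr(uni, "currency") <- currency
  attr(uni, "layer_of") <- layer_of
  uni
}

# --- internal compiled form used by scope expansion and simulations ------

# Expands reversible reactions into directed instances and builds integer
# indexes: substrate membership (flat), consumer lists per metabolite, and
# per-instance substrate counts.
compile_universe <- function(universe) {
  met <- universe$metabolites
  n_met <- length(met)
  nr <- n_reactions(universe)
  rev <- universe$reversible
  n_inst <- nr + sum(rev)
  inst_rxn <- integer(n_inst)
  inst_dir <- character(n_inst)
  inst_sub <- vector("list", n_inst)
  inst_prod <- vector("list", n_inst)
  k <- 0
  for (i in seq_len(nr)) {
    s <- match(universe$substrates[[i]], met)
    p <- match(universe$products[[i]], met)
    k <- k + 1
    inst_rxn[k] <- i; inst_dir[k] <- "f"; inst_sub[[k]] <- s; inst_prod[[k]] <- p
    if (rev[i]) {
      k <- k + 1
      inst_rxn[k] <- i; inst_dir[k] <- "b"; inst_sub[[k]] <- p; inst_prod[[k]] <- s
    }
  }
  sub_count <- lengths(inst_sub)
  sub_flat <- unlist(inst_sub)
  sub_inst <- rep.int(seq_len(n_inst), sub_count)
  cons_by_met <- split(sub_inst, factor(sub_flat, levels = seq_len(n_met)))
  list(
    universe = universe, met = met, n_met = n_met, n_inst = n_inst,
    inst_rxn = inst_rxn, inst_dir = inst_dir,
    inst_sub = inst_sub, inst_prod = inst_prod,
    sub_count = sub_count, sub_flat = sub_flat, sub_inst = sub_inst,
    cons_by_met = cons_by_met
  )
}

met_index <- function(cu, ids) {
  i <- match(ids, cu$met)
  if (anyNA(i)) stop("unknown metabolite id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  i
}
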