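#' Edge-typed regular graphs
#'
#' An edge-typed regular graph on `N` nodes realises a [degree_profile()] at
#' every node: each node has exactly `g[i]` neighbours along type-`i` edges.
#' The graph is stored as two `N x k` matrices: `nbr` (neighbour ids, 1-based
#' internally) and `typ` (the edge type of each slot). Adjacency is symmetric
#' with matching types, with no self-loops and no parallel edges within or
#' across types.
#'
#' @name typed_graph
NULL

new_typed_graph <- function(N, profile, nbr, typ, weights = NULL) {
  structure(list(N = as.integer(N), profile = profile, nbr = nbr, typ = typ,
                 weights = weights),
            class = "typed_graph")
}

#' @export
print.typed_graph <- function(x, ...) {
  p <- x$profile
  cat("Edge-typed regular graph: N =", x$N, " k =", p$k, " g = (",
      paste(p$g, collapse = ", "), ")\n")
  if (!is.null(x$weights))
    cat("per-type weights zeta = (", paste(x$weights, collapse = ", "), ")\n")
  invisible(x)
}

#' Generate a random edge-typed regular graph
#'
#' Builds `n` independent random `g[i]`-regular simple graphs on the same
#' vertex set (one per edge type, via the configuration model with
#' simple-graph repair) and overlays them. If any pair of nodes ends up
#' connected in two layers the overlay is rejected and redrawn, up to
#' `max_tries` times. The result realises the profile exactly at every node.
#'
#' @param N Number of nodes, `N > k`.
#' @param profile A [degree_profile()].
#' @param seed Optional integer seed; generation is deterministic given the
#'   seed and restores the caller's RNG state.
#' @param weights Optional positive per-type edge weights `zeta`.
#' @param max_tries Retry budget for collision-free overlays (default 1000).
#' @return A `typed_graph` object.
#' @examples
#' g <- generate_typed_graph(50, degree_profile(4, c(3, 1)), seed = 1)
#' @export
generate_typed_graph <- function(N, profile, seed = NULL, weights = NULL,
                                 max_tries = 1000L) {
  profile <- as_profile(profile)
  N <- as.integer(N)
  if (N <= profile$k)
    stop("'N' must exceed the degree k", call. = FALSE)
  if (any((N * profile$g) %% 2L == 1L))
    stop("infeasible parity: N * g_i must be even for every type ",
         "(got N = ", N, ", g = ", paste(profile$g, collapse = ","), ")",
         call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != profile$n || any(weights <= 0))
      stop("'weights' must be one positive value per edge type",
           call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  for (try in seq_len(max_tries)) {
    layers <- lapply(profile$g, function(gi) {
      el <- igraph::as_edgelist(igraph::sample_k_regular(N, gi),
                                names = FALSE)
      storage.mode(el) <- "integer"
      el
    })
    layers <- repair_layer_collisions(layers, N)
    if (is.null(layers)) next
    nbr <- matrix(0L, N, profile$k)
    typ <- matrix(0L, N, profile$k)
    slot <- integer(N)
    for (j in seq_len(profile$n)) {
      el <- layers[[j]]
      for (e in seq_len(nrow(el))) {
        u <- el[e, 1L]; v <- el[e, 2L]
        slot[u] <- slot[u] + 1L; nbr[u, slot[u]] <- v; typ[u, slot[u]] <- j
        slot[v] <- slot[v] + 1L; nbr[v, slot[v]] <- u; typ[v, slot[v]] <- j
      }
    }
    return(new_typed_graph(N, profile, nbr, typ, weights))
  }
  stop("failed to find a collision-free edge-type overlay within ",
       max_tries, " tries; increase N or max_tries", call. = FALSE)
}

# The expected number of pairs connected in two layers is about
# g_i * g_j / 2 per layer pair, independent of N, so plain rejection of
# colliding overlays stalls for larger per-type degrees. Instead, colliding
# edges are removed by degree-preserving double-edge swaps inside their own
# layer, each swap vetted against self-loops, intra-layer duplicates and
# cross-layer collisions. Returns NULL if a collision resists repair (the
# caller then redraws all layers).
repair_layer_collisions <- function(layers, N, swap_tries = 200L) {
  ekey <- function(u, v) pmin(u, v) * (N + 1) + pmax(u, v)
  keys <- lapply(layers, function(el) ekey(el[, 1L], el[, 2L]))
  taken <- new.env(hash = TRUE, size = 4L * sum(lengths(keys)))
  for (j in seq_along(layers)) {
    el <- layers[[j]]
    for (e in seq_len(nrow(el))) {
      kk <- as.character(keys[[j]][e])
      if (is.null(taken[[kk]])) {
        taken[[kk]] <- TRUE
        next
      }
      # edge already present in an earlier layer: swap it away within layer j
      done <- FALSE
      for (t in seq_len(swap_tries)) {
        o <- sample.int(nrow(el), 1L)
        if (o == e) next
        u <- el[e, 1L]; v <- el[e, 2L]
        x <- el[o, 1L]; y <- el[o, 2L]
        if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
        if (u == x || u == y || v == x || v == y) next
        k1 <- ekey(u, x); k2 <- ekey(v, y)
        if (!is.null(taken[[as.character(k1)]]) ||
            !is.null(taken[[as.character(k2)]]) || k1 == k2) next
        ko <- as.character(keys[[j]][o])
        el[e, ] <- c(u, x); el[o, ] <- c(v, y)
        keys[[j]][e] <- k1; keys[[j]][o] <- k2
        taken[[as.character(k1)]] <- TRUE
        if (o < e) {
          # partner already claimed its old key: transfer the claim
          rm(list = ko, envir = taken)
          taken[[as.character(k2)]] <- TRUE
        }
        # o > e: the partner claims k2 (and resolves any residual clash)
        # when the sweep reaches it
        done <- TRUE
        break
      }
      if (!done) return(NULL)
    }
    layers[[j]] <- el
  }
  layers
}

#' Neighbourhood configuration of a node
#'
#' Counts, for each edge type, how many neighbours of `node` currently play
#' strategy A.
#'
#' @param graph A `typed_graph`.
#' @param node Node id (1-based).
#' @param strategies Logical or 0/1 vector of length `N`; `TRUE`/1 means the
#'   node plays A.
#' @return Integer vector `(s1, ..., sn)`.
#' @export
neighborhood_config <- function(graph, node, strategies) {
  if (node < 1L || node > graph$N)
    stop("unknown node id ", node, call. = FALSE)
  if (length(strategies) != graph$N)
    stop("'strategies' must cover all ", graph$N, " nodes", call. = FALSE)
  strategies <- as.logical(strategies)
  s <- integer(graph$profile$n)
  for (j in seq_len(graph$profile$k)) {
    if (strategies[graph$nbr[node, j]]) {
      t <- graph$typ[node, j]
      s[t] <- s[t] + 1L
    }
  }
  s
}

#' Write or read an edge-typed graph as a typed edge list
#'
#' Plain-text dialect: a header line
#' `#edgegames v1 N=<N> k=<k> g=<g1,...,gn>` followed by one undirected edge
#' per line, tab-separated `u<TAB>v<TAB>type[<TAB>weight]`, with 0-based node
#' ids and `u < v`; each undirected edge appears exactly once. The reader
#' rejects malformed lines (wrong column count, unknown type, `u >= v`,
#' duplicate edges) with the offending line number, and validates per-type
#' regularity against the header profile.
#'
#' @param graph A `typed_graph`.
#' @param path File path.
#' @return `read_typed_graph()` returns a `typed_graph`;
#'   `write_typed_graph()` returns `path` invisibly.
#' @export
write_typed_graph <- function(graph, path) {
  p <- graph$profile
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#edgegames v1 N=%d k=%d g=%s", graph$N, p$k,
                     paste(p$g, collapse = ",")), con)
  lines <- character(0)
  for (u in seq_len(graph$N)) {
    for (j in seq_len(p$k)) {
      v <- graph$nbr[u, j]
      if (u < v) {
        t <- graph$typ[u, j]
        ln <- sprintf("%d\t%d\t%d", u - 1L, v - 1L, t)
        if (!is.null(graph$weights))
          ln <- sprintf("%s\t%g", ln, graph$weights[t])
        lines <- c(lines, ln)
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_typed_graph
#' @export
read_typed_graph <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#edgegames"))
    stop("not a typed edge list (missing #edgegames header)", call. = FALSE)
  hdr <- parse_header_fields(lines[1L])
  profile <- degree_profile(hdr$k, hdr$g)
  N <- hdr$N
  if (is.null(N) || N <= profile$k)
    stop("header must declare N > k", call. = FALSE)
  nbr <- matrix(0L, N, profile$k)
  typ <- matrix(0L, N, profile$k)
  slot <- integer(N)
  seen <- new.env(hash = TRUE)
  weights <- rep(NA_real_, profile$n)
  has_weights <- FALSE
  for (i in seq_along(lines)[-1L]) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (!(length(fields) %in% c(3L, 4L)))
      stop("line ", i, ": expected 3 or 4 tab-separated columns",
           call. = FALSE)
    u <- suppressWarnings(as.integer(fields[1L])) + 1L
    v <- suppressWarnings(as.integer(fields[2L])) + 1L
    t <- suppressWarnings(as.integer(fields[3L]))
    if (anyNA(c(u, v, t)))
      stop("line ", i, ": non-integer node id or type", call. = FALSE)
    if (is.na(t) || t < 1L || t > profile$n)
      stop("line ", i, ": unknown type index ", fields[3L], call. = FALSE)
    if (u < 1L || v > N || u >= v)
      stop("line ", i, ": node ids must satisfy 0 <= u < v < N",
           call. = FALSE)
    key <- paste0(u, ":", v)
    if (!is.null(seen[[key]]))
      stop("line ", i, ": duplicate edge ", fields[1L], "-", fields[2L],
           call. = FALSE)
    seen[[key]] <- TRUE
    if (length(fields) == 4L) {
      has_weights <- TRUE
      w <- as.numeric(fields[4L])
      if (is.na(weights[t])) weights[t] <- w
      else if (weights[t] != w)
        stop("line ", i, ": inconsistent weight for type ", t, call. = FALSE)
    }
    if (slot[u] >= profile$k || slot[v] >= profile$k)
      stop("line ", i, ": node degree exceeds k", call. = FALSE)
    slot[u] <- slot[u] + 1L; nbr[u, slot[u]] <- v; typ[u, slot[u]] <- t
    slot[v] <- slot[v] + 1L; nbr[v, slot[v]] <- u; typ[v, slot[v]] <- t
  }
  if (any(slot != profile$k))
    stop("graph does not realise the declared profile: some node has ",
         "degree != k", call. = FALSE)
  g <- new_typed_graph(N, profile, nbr, typ,
                       if (has_weights) weights else NULL)
  validate_typed_graph(g)
  g
}

#' Validate the invariants of an edge-typed graph
#'
#' Checks symmetry with matching types, absence of self-loops and parallel
#' edges, and exact per-type regularity.
#'
#' @param graph A `typed_graph`.
#' @return `graph`, invisibly; errors otherwise.
#' @export
validate_typed_graph <- function(graph) {
  p <- graph$profile
  for (u in seq_len(graph$N)) {
    nb <- graph$nbr[u, ]
    if (any(nb == u)) stop("self-loop at node ", u, call. = FALSE)
    if (anyDuplicated(nb)) stop("parallel edges at node ", u, call. = FALSE)
    cnt <- tabulate(graph$typ[u, ], nbins = p$n)
    if (!identical(cnt, p$g))
      stop("node ", u, " does not realise the per-type degrees", call. = FALSE)
    for (j in seq_len(p$k)) {
      v <- nb[j]
      back <- which(graph$nbr[v, ] == u)
      if (length(back) != 1L || graph$typ[v, back] != graph$typ[u, j])
        stop("asymmetric adjacency between nodes ", u, " and ", v,
             call. = FALSE)
    }
  }
  invisible(graph)
}
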