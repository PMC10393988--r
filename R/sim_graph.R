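#' Admixture-graph specifications
#'
#' Defines the population-history truth used by the frequency simulator: a
#' rooted acyclic graph whose drift edges carry a Balding-Nichols drift amount
#' F >= 0 and whose admixture nodes mix two source populations with proportion
#' `alpha` (weight of `source_a`) before accumulating their own drift.
#'
#' @param edges data.frame with columns `parent`, `child`, `f` (drift, >= 0).
#' @param admixture optional data.frame with columns `source_a`, `source_b`,
#'   `child`, `alpha` (in `[0,1]`) and optionally `f` (post-admixture drift,
#'   default 0).
#' @param root_freq two-element numeric: bounds of the uniform spectrum for
#'   ancestral allele frequencies (default `c(0.05, 0.95)`).
#' @return An object of class `admixture_graph` with nodes in topological
#'   order.
#' @export
admixture_graph <- function(edges, admixture = NULL, root_freq = c(0.05, 0.95)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("parent", "child", "f") %in% names(edges)))
  if (any(edges$f < 0)) stop("admixture_graph: drift f must be >= 0")
  if (!is.null(admixture)) {
    admixture <- as.data.frame(admixture, stringsAsFactors = FALSE)
    stopifnot(all(c("source_a", "source_b", "child", "alpha") %in% names(admixture)))
    if (is.null(admixture$f)) admixture$f <- 0
    if (any(admixture$alpha < 0 | admixture$alpha > 1)) {
      stop("admixture_graph: alpha must lie in [0,1]")
    }
    if (any(admixture$f < 0)) stop("admixture_graph: post-admixture drift must be >= 0")
  }
  nodes <- unique(c(edges$parent, edges$child,
                    if (!is.null(admixture)) {
                      c(admixture$source_a, admixture$source_b, admixture$child)
                    }))
  children <- c(edges$child, if (!is.null(admixture)) admixture$child)
  if (anyDuplicated(children)) {
    stop("admixture_graph: node '", children[anyDuplicated(children)],
         "' has more than one parent specification")
  }
  roots <- setdiff(nodes, children)
  if (length(roots) != 1L) {
    stop("admixture_graph: expected exactly one root, found: ",
         paste(roots, collapse = ", "))
  }

  # Kahn topological sort; leftover nodes name a cycle.
  parents_of <- function(n) {
    p <- edges$parent[edges$child == n]
    if (!is.null(admixture)) {
      i <- which(admixture$child == n)
      if (length(i)) p <- c(admixture$source_a[i], admixture$source_b[i])
    }
    p
  }
  order <- character(0)
  placed <- roots
  pending <- setdiff(nodes, roots)
  repeat {
    ready <- pending[vapply(pending, function(n) all(parents_of(n) %in% placed), TRUE)]
    if (length(ready) == 0L) break
    order <- c(order, ready)
    placed <- c(placed, ready)
    pending <- setdiff(pending, ready)
  }
  if (length(pending) > 0L) {
    stop("admixture_graph: cycle involving nodes: ", paste(pending, collapse = ", "))
  }
  structure(list(nodes = c(roots, order), root = roots, edges = edges,
                 admixture = admixture, root_freq = root_freq),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$nodes), "nodes, root", x$root, "\n")
  invisible(x)
}

# Clamp frequencies away from fixation so likelihoods stay finite.
clamp_freq <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# One Balding-Nichols draw per element: mean p, variance f*p*(1-p).
bn_drift <- function(p, f) {
  if (f == 0) return(p)
  shape <- (1 - f) / f
  stats::rbeta(length(p), shape1 = p * shape, shape2 = (1 - p) * shape)
}

#' Simulate per-population allele frequencies on an admixture graph
#'
#' Draws ancestral frequencies from the root spectrum, then propagates them
#' down the graph: drift children are Balding-Nichols Beta draws around the
#' parent frequency with variance `f * p * (1 - p)`; admixed children are the
#' alpha-weighted mixture of their two sources, followed by their own drift.
#' All frequencies are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' Because the Balding-Nichols variance is exactly `f * p * (1-p)`, expected
#' f-statistics on the resulting frequencies follow path-overlap algebra and
#' can be computed exactly with [expected_f4()] and friends.
#'
#' @param graph an [admixture_graph()].
#' @param n_sites number of sites to simulate.
#' @param seed integer RNG seed.
#' @param panel optional `snp_panel` site map to attach frequencies to; when
#'   NULL a synthetic autosomal map is generated.
#' @return A `snp_panel` whose `freq` matrix has one column per graph node.
#' @export
simulate_graph_frequencies <- function(graph, n_sites, seed, panel = NULL) {
  stopifnot(inherits(graph, "admixture_graph"), n_sites >= 1)
  set.seed(seed)
  freq <- matrix(NA_real_, nrow = n_sites, ncol = length(graph$nodes),
                 dimnames = list(NULL, graph$nodes))
  freq[, graph$root] <- stats::runif(n_sites, graph$root_freq[1], graph$root_freq[2])
  for (node in setdiff(graph$nodes, graph$root)) {
    i <- which(graph$edges$child == node)
    if (length(i) == 1L) {
      p <- freq[, graph$edges$parent[i]]
      freq[, node] <- clamp_freq(bn_drift(p, graph$edges$f[i]))
    } else {
      j <- which(graph$admixture$child == node)
      a <- graph$admixture$alpha[j]
      p <- a * freq[, graph$admixture$source_a[j]] +
        (1 - a) * freq[, graph$admixture$source_b[j]]
      freq[, node] <- clamp_freq(bn_drift(p, graph$admixture$f[j]))
    }
  }
  if (is.null(panel)) {
    panel <- snp_panel(synth_panel_sites(n_sites))
  }
  if (nrow(panel$sites) != n_sites) {
    stop("simulate_graph_frequencies: panel has ", nrow(panel$sites),
         " sites, expected ", n_sites)
  }
  panel$freq <- freq
  rownames(panel$freq) <- panel$sites$id
  panel
}

#' Exact first and second moments of node frequencies under the graph model
#'
#' Propagates `E[p]` and the full covariance matrix of node frequencies down
#' the graph.  Drift adds variance `f * E[p(1-p)]` (the exact Balding-Nichols
#' conditional variance in expectation) and leaves covariances with all other
#' nodes unchanged; admixture is linear in the source frequencies.  These
#' moments make expected f2/f3/f4 available in closed form as the independent
#' oracle for the estimators.
#'
#' @param graph an [admixture_graph()].
#' @return list with `mean` (named vector) and `cov` (node covariance matrix).
#' @export
graph_moments <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  mu <- stats::setNames(numeric(n), nodes)
  V <- matrix(0, n, n, dimnames = list(nodes, nodes))
  a <- graph$root_freq[1]; b <- graph$root_freq[2]
  mu[graph$root] <- (a + b) / 2
  V[graph$root, graph$root] <- (b - a)^2 / 12
  e_p1p <- function(node) mu[node] - V[node, node] - mu[node]^2  # E[p(1-p)]
  add_drift <- function(node, f) {
    V[node, node] <<- V[node, node] + f * e_p1p(node)
  }
  for (node in setdiff(nodes, graph$root)) {
    i <- which(graph$edges$child == node)
    if (length(i) == 1L) {
      par <- graph$edges$parent[i]
      mu[node] <- mu[par]
      V[node, ] <- V[par, ]; V[, node] <- V[, par]
      V[node, node] <- V[par, par]
      add_drift(node, graph$edges$f[i])
    } else {
      j <- which(graph$admixture$child == node)
      sa <- graph$admixture$source_a[j]; sb <- graph$admixture$source_b[j]
      al <- graph$admixture$alpha[j]
      mu[node] <- al * mu[sa] + (1 - al) * mu[sb]
      V[node, ] <- al * V[sa, ] + (1 - al) * V[sb, ]
      V[, node] <- V[node, ]
      V[node, node] <- al^2 * V[sa, sa] + (1 - al)^2 * V[sb, sb] +
        2 * al * (1 - al) * V[sa, sb]
      add_drift(node, graph$admixture$f[j])
    }
  }
  list(mean = mu, cov = V)
}

#' Expected f2 between two graph populations
#' @param graph an [admixture_graph()].
#' @param a,b population names.
#' @return expected value of `E[(pA - pB)^2]`.
#' @export
expected_f2 <- function(graph, a, b) {
  m <- graph_moments(graph)
  m$cov[a, a] + m$cov[b, b] - 2 * m$cov[a, b]
}

#' Expected f3(o; a, b) on the graph
#' @inheritParams expected_f2
#' @param o apex (outgroup) population.
#' @return expected value of `E[(pO - pA)(pO - pB)]`.
#' @export
expected_f3 <- function(graph, o, a, b) {
  m <- graph_moments(graph)
  m$cov[o, o] - m$cov[o, a] - m$cov[o, b] + m$cov[a, b]
}

#' Expected f4(a, b; c, d) on the graph
#' @inheritParams expected_f2
#' @param c,d second population pair.
#' @return expected value of `E[(pA - pB)(pC - pD)]`.
#' @export
expected_f4 <- function(graph, a, b, c, d) {
  m <- graph_moments(graph)
  m$cov[a, c] - m$cov[a, d] - m$cov[b, c] + m$cov[b, d]
}
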