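#' ROI-to-ROI signed Granger causal network
#'
#' Computes the signed lag-1 GC path coefficient for every ordered ROI pair
#' of a pseudo-time ROI series matrix and retains edges with
#' `|GC| > gc_threshold`.
#'
#' @param roi_series T x R matrix (columns named by ROI).
#' @param config an [analysis_config()].
#' @return a `cascn_graph`: list(nodes, adjacency (R x R signed GC, NA where
#'   no edge), edges data.frame(source, target, gc, sign), threshold).
#' @export
roi_gc_matrix <- function(roi_series, config = analysis_config()) {
  roi_series <- as.matrix(roi_series)
  R <- ncol(roi_series)
  if (R < 2) stop("need at least 2 ROIs")
  if (nrow(roi_series) < 10) stop("need at least 10 pseudo-time points")
  if (is.null(colnames(roi_series))) colnames(roi_series) <- paste0("ROI", seq_len(R))
  nodes <- colnames(roi_series)
  adj <- matrix(NA_real_, R, R, dimnames = list(nodes, nodes))
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    gc <- signed_gc_pair(roi_series[, i], roi_series[, j], config$gc_order)
    if (abs(gc) > config$gc_threshold) adj[i, j] <- gc
  }
  causal_graph(adj, config$gc_threshold)
}

#' Build a causal graph from a signed adjacency matrix
#'
#' @param adj square matrix of signed GC values; NA (or 0) = no edge. Any
#'   remaining entries with `|GC| <= threshold` are dropped.
#' @param threshold retention threshold used.
#' @return a `cascn_graph`.
#' @export
causal_graph <- function(adj, threshold = 0.20) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (is.null(rownames(adj))) {
    rownames(adj) <- colnames(adj) <- paste0("ROI", seq_len(nrow(adj)))
  }
  diag(adj) <- NA_real_
  adj[!is.na(adj) & abs(adj) <= threshold] <- NA_real_
  idx <- which(!is.na(adj), arr.ind = TRUE)
  edges <- data.frame(source = rownames(adj)[idx[, 1]],
                      target = colnames(adj)[idx[, 2]],
                      gc = adj[idx],
                      sign = sign(adj[idx]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(adj), adjacency = adj,
                 edges = edges[order(edges$source, edges$target), , drop = FALSE],
                 threshold = threshold),
            class = "cascn_graph")
}

#' Binary and weighted degree metrics of a causal graph
#'
#' In/out degree counts, weighted in/out strengths (sums of |GC|), and the
#' out-minus-in differences quantifying each node's net causal influence.
#'
#' @param graph a `cascn_graph`.
#' @return data.frame with one row per node.
#' @export
degree_metrics <- function(graph) {
  A <- graph$adjacency
  W <- abs(A); W[is.na(W)] <- 0
  B <- (W > 0) * 1
  data.frame(node = graph$nodes,
             in_degree = colSums(B), out_degree = rowSums(B),
             in_strength = colSums(W), out_strength = rowSums(W),
             outin_degree = rowSums(B) - colSums(B),
             outin_strength = rowSums(W) - colSums(W),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify nodes as causal sources, targets, or balanced
#'
#' Sources have positive binary out-in degree (net senders of causal
#' influence), targets negative, balanced zero.
#'
#' @param degrees output of [degree_metrics()].
#' @return the table with a `role` column added.
#' @export
classify_hubs <- function(degrees) {
  degrees$role <- ifelse(degrees$outin_degree > 0, "source",
                         ifelse(degrees$outin_degree < 0, "target", "balanced"))
  degrees
}

#' Directed weighted modularity of a partition
#'
#' Q = (1/m) * sum_ij [A_ij - s_i^out * s_j^in / m] delta(c_i, c_j) with
#' A = |GC| on retained edges, m the total weight, and s the weighted
#' out/in strengths (Leicht-Newman directed form).
#'
#' @param graph a `cascn_graph`.
#' @param membership integer module label per node.
#' @return Q.
#' @export
modularity_q <- function(graph, membership) {
  A <- abs(graph$adjacency); A[is.na(A)] <- 0
  m <- sum(A)
  if (m == 0) stop("graph has no edges")
  B <- A - outer(rowSums(A), colSums(A)) / m
  same <- outer(membership, membership, "==")
  sum(B[same]) / m
}

## all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(s, mx) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return(invisible()) }
    for (v in 1:(mx + 1)) rec(c(s, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

#' Directed weighted modularity optimization
#'
#' Maximizes the Leicht-Newman directed weighted modularity over node
#' partitions: exhaustive search for graphs with <= `exhaustive_max` nodes,
#' otherwise greedy agglomeration from singletons followed by single-node
#' move refinement. Deterministic given the seed.
#'
#' @param graph a `cascn_graph` with >= 2 nodes and >= 1 edge.
#' @param seed recorded (tie-breaks are deterministic by node order).
#' @param exhaustive_max largest node count solved exhaustively.
#' @return list(membership (named), Q, method, seed).
#' @export
newman_modularity <- function(graph, seed = 1, exhaustive_max = 10) {
  n <- length(graph$nodes)
  if (n < 2) stop("need at least 2 nodes")
  A <- abs(graph$adjacency); A[is.na(A)] <- 0
  if (sum(A) == 0) stop("graph has no edges")
  if (n <= exhaustive_max) {
    parts <- all_partitions(n)
    qs <- vapply(parts, function(p) modularity_q(graph, p), 0)
    best <- which.max(qs)
    memb <- parts[[best]]; method <- "exhaustive"
  } else {
    memb <- seq_len(n)
    repeat {  # greedy agglomeration
      labs <- unique(memb)
      bestdq <- 0; bestpair <- NULL
      q0 <- modularity_q(graph, memb)
      for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
        mm <- memb; mm[mm == labs[i]] <- labs[j]
        dq <- modularity_q(graph, mm) - q0
        if (dq > bestdq + 1e-12) { bestdq <- dq; bestpair <- c(labs[i], labs[j]) }
      }
      if (is.null(bestpair)) break
      memb[memb == bestpair[1]] <- bestpair[2]
    }
    repeat {  # single-node move refinement
      improved <- FALSE
      for (v in seq_len(n)) {
        q0 <- modularity_q(graph, memb)
        for (lab in unique(memb)) {
          if (lab == memb[v]) next
          mm <- memb; mm[v] <- lab
          if (modularity_q(graph, mm) > q0 + 1e-12) {
            memb <- mm; q0 <- modularity_q(graph, memb); improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    method <- "greedy"
  }
  memb <- match(memb, unique(memb))
  names(memb) <- graph$nodes
  list(membership = memb, Q = modularity_q(graph, memb),
       method = method, seed = seed)
}

#' Binomial forward-inference functional decoding
#'
#' For each behavioural domain, tests whether the activation count inside a
#' module exceeds the database base rate: one-sided binomial tail
#' P(X >= k | n, p), Benjamini-Hochberg corrected across domains.
#'
#' @param domain_table data.frame with columns `domain`, `k` (in-module
#'   activation count), `n` (module total), `p` (database base rate).
#' @param alpha FDR level defining `enriched`.
#' @return the table with `p_value`, `q` and `enriched` columns.
#' @export
forward_inference_decoding <- function(domain_table, alpha = 0.05) {
  req <- c("domain", "k", "n", "p")
  miss <- setdiff(req, names(domain_table))
  if (length(miss)) stop("domain table missing column(s): ", paste(miss, collapse = ", "))
  with(domain_table, {
    if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
    if (any(p <= 0 | p >= 1)) stop("base rates must be in (0,1)")
  })
  domain_table$p_value <- stats::pbinom(domain_table$k - 1, domain_table$n,
                                        domain_table$p, lower.tail = FALSE)
  domain_table$q <- stats::p.adjust(domain_table$p_value, "BH")
  domain_table$enriched <- domain_table$q < alpha
  domain_table
}
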