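# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force, enumeration, textbook formulas) and
# share no code with the package internals.

# Brute-force within-set edge count: double loop over all unordered pairs.
oracle_edge_count <- function(net, genes) {
  genes <- unique(genes)
  n <- 0L
  pairs <- paste0(net$edges$from, "|", net$edges$to)
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1L)) {
      a <- min(genes[i], genes[j]); b <- max(genes[i], genes[j])
      if (paste0(a, "|", b) %in% pairs) n <- n + 1L
    }
  }
  n
}

# Union-find connected components over an edge list restricted to `genes`.
oracle_components <- function(edges_from, edges_to, genes) {
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(edges_from)) {
    a <- edges_from[k]; b <- edges_to[k]
    if (a %in% genes && b %in% genes) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(genes, find, "")
  unname(split(genes, roots))
}

# Exact upper-tail hypergeometric by factorial arithmetic (small inputs).
oracle_hyper_upper <- function(k, K, n, N) {
  ch <- function(a, b) {
    if (b < 0 || b > a) return(0)
    factorial(a) / (factorial(b) * factorial(a - b))
  }
  xs <- k:min(K, n)
  sum(vapply(xs, function(x) ch(K, x) * ch(N - K, n - x), 0)) / ch(N, n)
}

# Textbook Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Pearson chi-squared statistic from observed/expected expansion.
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  expd <- outer(rs, cs) / n
  sum((obs - expd)^2 / expd)
}

# Reachable ancestor set via boolean matrix powers of the parent relation.
oracle_ancestors <- function(ont, term) {
  n <- length(ont$terms)
  A <- matrix(FALSE, n, n, dimnames = list(ont$terms, ont$terms))
  for (t in ont$terms) A[t, ont$parents[[t]]] <- TRUE
  reach <- A
  repeat {
    nxt <- reach | (reach %*% A > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  c(term, ont$terms[reach[term, ]])
}

# Tiny 4-level ontology used across similarity tests:
# root -> P -> {D1, D2}, root -> Q
toy_ontology <- function() {
  ontology(list(root = character(0), P = "root", D1 = "P", D2 = "P",
                Q = "root"))
}

toy_annotations <- function() {
  annotation_map(list(g1 = c("D1", "D2"), g2 = "D1", g3 = "D2", g4 = "Q"))
}
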