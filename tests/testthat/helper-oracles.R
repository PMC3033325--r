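# Independent brute-force oracles, deliberately written without reusing any
# package internals: explicit contingency-table loops and path-enumeration LCA.

oracle_entropy <- function(x) {
  states <- unique(x)
  h <- 0
  for (s in states) {
    p <- sum(x == s) / length(x)
    h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(x, y) {
  sx <- unique(x)
  sy <- unique(y)
  n <- length(x)
  mi <- 0
  for (a in sx) {
    for (b in sy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  mi
}

# LCA layer by explicit root-path enumeration over a parent edge list
oracle_mrca_level <- function(leaf_a, leaf_b, parents, layers) {
  path <- function(id) {
    out <- id
    while (id %in% names(parents)) {
      id <- parents[[id]]
      out <- c(out, id)
    }
    out
  }
  common <- intersect(path(leaf_a), path(leaf_b))
  if (length(common) == 0L) return(NA_integer_)
  min(layers[common])
}

# independence log-likelihood of a categorical matrix (closed form)
oracle_independence_loglik <- function(data) {
  ll <- 0
  for (j in seq_len(ncol(data))) {
    tab <- table(data[, j])
    p <- tab / nrow(data)
    ll <- ll + sum(tab * log(p))
  }
  ll
}
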