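#' Plug-in entropy of a categorical vector, in bits
#'
#' Maximum-likelihood (plug-in) estimate \eqn{-\sum_k \hat p_k \log_2 \hat p_k}
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param x a non-empty vector treated as categorical.
#' @return Entropy in bits, between 0 and `log2` of the number of observed
#'   states.
#' @examples
#' entropy_bits(rep(0:3, 25)) # 2 bits
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0L) abort("entropy of an empty vector is undefined")
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

#' Plug-in mutual information between two categorical vectors, in bits
#'
#' Computed from the joint contingency table:
#' \eqn{I(X,Y) = \sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}}.
#' Symmetric and bounded by `min(entropy_bits(x), entropy_bits(y))`.
#'
#' @param x,y equal-length vectors.
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) == 0L) abort("mutual information of empty vectors is undefined")
  xi <- match(x, unique(x))
  yi <- match(y, unique(y))
  mi_from_codes(xi, yi, max(xi), max(yi))
}

# xi, yi are 1-based integer codes with given state counts
mi_from_codes <- function(xi, yi, kx, ky) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ky + yi, nbins = kx * ky) / n
  px <- tabulate(xi, nbins = kx) / n
  py <- tabulate(yi, nbins = ky) / n
  ep <- as.vector(t(outer(px, py))) # x-major, matching the joint layout
  pos <- joint > 0
  sum(joint[pos] * log2(joint[pos] / ep[pos]))
}

#' Scaled mutual information
#'
#' Mutual information normalized by the smaller marginal entropy,
#' \eqn{I(X,Y)/\min(H(X), H(Y))}, so that a child fully determined by its
#' latent parent scores 1. If either variable is constant (zero entropy) the
#' result is defined as 0: a variable carrying no information cannot be said
#' to be captured.
#'
#' @inheritParams mutual_information
#' @return A value in \[0, 1\].
#' @export
scaled_mutual_information <- function(x, y) {
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  m <- min(hx, hy)
  if (m <= 0) return(0)
  min(1, mutual_information(x, y) / m)
}

#' Pairwise mutual-information matrix
#'
#' Entry (i, j) is the plug-in mutual information (bits) between columns i and
#' j. The diagonal is set to zero by convention; partitioning only ever uses
#' off-diagonal dependence.
#'
#' @param data a matrix (or `snp_matrix`) with at least two columns.
#' @return A symmetric numeric matrix with zero diagonal and the column names
#'   of `data` as dimnames.
#' @export
pairwise_mi_matrix <- function(data) {
  data <- as.matrix(data)
  p <- ncol(data)
  n <- nrow(data)
  if (p < 2L) abort("need at least two variables for a pairwise MI matrix")
  # one sparse indicator matrix over all (column, state) pairs: a single
  # crossprod yields every pairwise joint contingency table at once
  ks <- integer(p)
  code_cols <- vector("list", p)
  for (j in seq_len(p)) {
    u <- sort(unique(data[, j]))
    code_cols[[j]] <- match(data[, j], u)
    ks[j] <- length(u)
  }
  offset <- c(0L, cumsum(ks))
  ind <- Matrix::sparseMatrix(
    i = rep(seq_len(n), p),
    j = unlist(code_cols) + rep(offset[seq_len(p)], each = n),
    x = 1, dims = c(n, offset[p + 1L])
  )
  counts <- as.matrix(Matrix::crossprod(ind))
  out <- matrix(0, p, p, dimnames = list(colnames(data), colnames(data)))
  marg <- lapply(seq_len(p), function(j) {
    diag(counts)[(offset[j] + 1L):offset[j + 1L]] / n
  })
  for (i in seq_len(p - 1L)) {
    ri <- (offset[i] + 1L):offset[i + 1L]
    for (j in (i + 1L):p) {
      joint <- counts[ri, (offset[j] + 1L):offset[j + 1L], drop = FALSE] / n
      ep <- outer(marg[[i]], marg[[j]])
      pos <- joint > 0
      m <- sum(joint[pos] * log2(joint[pos] / ep[pos]))
      out[i, j] <- m
      out[j, i] <- m
    }
  }
  out
}

#' Quantile threshold over a mutual-information matrix
#'
#' Nearest-rank quantile of the strictly-upper-triangle entries (the diagonal
#' is excluded: self-information would inflate the threshold). Used to derive
#' the binarization threshold `t_MI` from the current MI matrix.
#'
#' @param mi a symmetric MI matrix as from [pairwise_mi_matrix()].
#' @param q quantile in \[0, 1\].
#' @return The q-th nearest-rank order statistic of the off-diagonal entries.
#' @export
mi_quantile_threshold <- function(mi, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    abort("q must be a single value in [0, 1]")
  }
  v <- sort(mi[upper.tri(mi)])
  if (length(v) == 0L) abort("MI matrix has no off-diagonal entries")
  v[max(1L, ceiling(q * length(v)))]
}

#' Squared correlation (r-squared) between two markers
#'
#' Squared Pearson correlation of the numeric codes: the allelic r-squared on
#' 0/1 haplotypes and the composite r-squared on 0/1/2 genotype dosages.
#'
#' @param x,y equal-length numeric marker codes; neither may be constant.
#' @return A value in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("r_squared is undefined for a constant marker")
  }
  stats::cor(x, y)^2
}
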