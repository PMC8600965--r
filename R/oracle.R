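#' Closed-form directed information of the bivariate Gaussian pair
#'
#' For `(X_{i-1}, Y_i)` jointly Gaussian with correlation `rho`, the
#' directed information is `-0.5 * log(1 - rho^2)` nats.
#'
#' @param rho correlation, `|rho| < 1`.
#' @return Directed information in nats.
#' @export
analytic_pair_di <- function(rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  -0.5 * log(1 - rho^2)
}

#' Exact directed information of the binary symmetric channel pair
#'
#' Enumerates the 2 x 2 joint distribution of `(X_{i-1}, Y_i)` where
#' `X ~ Bernoulli(bern_p)` and `Y` flips `X` with probability `p_flip`, and
#' returns the exact discrete mutual information (equal to the DI of the
#' model since `Y`'s own past is independent of the pair).
#'
#' @param p_flip bit-flip probability.
#' @param bern_p source rate.
#' @return Directed information in nats.
#' @export
analytic_bsc_di <- function(p_flip, bern_p = 0.3) {
  px <- c(1 - bern_p, bern_p)
  # joint[x+1, y+1]
  joint <- rbind(
    c(px[1] * (1 - p_flip), px[1] * p_flip),
    c(px[2] * p_flip, px[2] * (1 - p_flip))
  )
  py <- colSums(joint)
  s <- 0
  for (a in 1:2) for (b in 1:2) {
    if (joint[a, b] > 0) {
      s <- s + joint[a, b] * log(joint[a, b] / (px[a] * py[b]))
    }
  }
  s
}

network_edge_beta <- function(spec, j, k) {
  e <- spec$edges[spec$edges$from == j & spec$edges$to == k, ]
  if (nrow(e) != 1) stop(sprintf("no edge %d -> %d in spec", j, k))
  e$beta
}

#' Analytic pairwise directed information of a linear-Gaussian network edge
#'
#' For an edge `j -> k` of a linear-Gaussian [network_spec], returns
#' `0.5 * log(1 + beta^2 / (alpha_k^2 + sum_l beta_{l,k}^2))` where `l`
#' runs over the other parents of `k` (reducing to
#' `0.5 * log(1 + beta^2 / alpha_k^2)` for a single-parent node). The
#' formula treats parent processes as independent unit-variance inputs; it
#' is exact when all parents of `k` are white unit-variance source nodes
#' (e.g. the sink of the shipped topology) and an approximation when
#' parents are driven nodes or share a common driver.
#'
#' @param spec a linear [network_spec].
#' @param j,k source and target node indices.
#' @return Pairwise DI in nats.
#' @export
analytic_network_di <- function(spec, j, k) {
  stopifnot(inherits(spec, "network_spec"))
  beta <- network_edge_beta(spec, j, k)
  others <- spec$edges[spec$edges$to == k & spec$edges$from != j, ]
  0.5 * log(1 + beta^2 / (spec$alpha[k]^2 + sum(others$beta^2)))
}

#' Analytic graphical directed information of a linear-Gaussian network edge
#'
#' Exact GDI (conditioning on the pasts of all other nodes, memory
#' covering at least the grandparent lag) for an edge `j -> k` of a
#' lag-1 linear-Gaussian DAG:
#' `0.5 * log(1 + beta^2 / alpha_k^2)` when `j` is a source node (its past
#' is fully exogenous), and `0.5 * log(1 + beta^2 alpha_j^2 / alpha_k^2)`
#' when `j` itself has parents, since conditioning explains all of `j`'s
#' past except its own innovation `alpha_j z`.
#'
#' @param spec a linear [network_spec].
#' @param j,k source and target node indices.
#' @return GDI in nats.
#' @export
analytic_network_gdi <- function(spec, j, k) {
  stopifnot(inherits(spec, "network_spec"))
  beta <- network_edge_beta(spec, j, k)
  j_has_parents <- j %in% spec$edges$to
  snr <- if (j_has_parents) {
    beta^2 * spec$alpha[j]^2 / spec$alpha[k]^2
  } else {
    beta^2 / spec$alpha[k]^2
  }
  0.5 * log(1 + snr)
}

encode_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 0) return(rep(0L, nrow(m)))
  apply(m, 1, paste, collapse = "\r")
}

#' Plug-in mutual information of discrete sample blocks
#'
#' Exact empirical (plug-in) MI between two blocks of discrete samples,
#' computed from the joint frequency table. Serves as the independent
#' oracle against which the classifier-based estimator is validated on
#' binary data.
#'
#' @param A,B row-aligned matrices (or vectors) of discrete values.
#' @return Plug-in MI in nats.
#' @export
discrete_mi <- function(A, B) {
  a <- encode_rows(A)
  b <- encode_rows(B)
  n <- length(a)
  pj <- table(a, b) / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  idx <- which(pj > 0, arr.ind = TRUE)
  sum(vapply(seq_len(nrow(idx)), function(i) {
    p <- pj[idx[i, 1], idx[i, 2]]
    p * log(p / (pa[idx[i, 1]] * pb[idx[i, 2]]))
  }, numeric(1)))
}

#' Plug-in conditional mutual information of discrete sample blocks
#'
#' Exact empirical CMI `I(A; B | Z)` computed as
#' `I(A; (B, Z)) - I(A; Z)` from joint frequency tables.
#'
#' @param A,B,Z row-aligned matrices of discrete values; `Z` may be NULL.
#' @return Plug-in CMI in nats.
#' @export
discrete_cmi <- function(A, B, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0) return(discrete_mi(A, B))
  discrete_mi(A, cbind(as.matrix(B), as.matrix(Z))) - discrete_mi(A, Z)
}
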