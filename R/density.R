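#' Maximum edge count of a compact honeycomb island
#'
#' The normalizer of the network-density metric: the largest number of
#' bonds any `n`-particle subgraph of the infinite honeycomb lattice can
#' carry. Exact by exhaustive search over connected lattice subgraphs for
#' `n <= 12`; for larger `n` a greedy spiral construction around a seed
#' hexagon is used (validated against the exhaustive values on its shared
#' range). Results are memoized.
#'
#' @param n Particle count(s), `n >= 1`.
#' @return Integer vector of maximum edge counts.
#' @examples
#' compact_reference_edges(c(1, 6, 10)) # 0, 6 (hexagon), 11 (fused pair)
#' @export
compact_reference_edges <- function(n) {
  stopifnot(all(n >= 1), all(n == round(n)))
  n <- as.integer(n)
  nmax <- max(n)
  tab <- .patchnet_env$cre_table
  if (is.null(tab) || length(tab) < nmax) {
    exh <- .patchnet_env$cre_exhaustive
    if (is.null(exh)) {
      exh <- honeycomb_max_edges_exhaustive_cpp(12L)
      .patchnet_env$cre_exhaustive <- exh
    }
    spir <- honeycomb_max_edges_spiral_cpp(max(nmax, 64L))
    tab <- spir
    tab[seq_along(exh)] <- pmax(exh, spir[seq_along(exh)])
    .patchnet_env$cre_table <- tab
  }
  tab[n]
}

#' Network density of an island
#'
#' ND = E / E_max(V): the island's bond count over the bond count of the
#' maximally compact honeycomb island with the same number of particles.
#' ND is 1 exactly for ideal radially grown honeycomb crystals and falls
#' toward `(V-1)/E_max(V)` for chains and trees; it is invariant under
#' rigid motion and node relabelling since it depends only on counts.
#'
#' @param island An `island` (or any list with `size` and `edges`).
#' @return ND in `[0, 1]`.
#' @export
network_density <- function(island) {
  V <- island$size
  if (is.null(V) || V == 0) stop("network density of an empty island")
  if (V == 1) return(0)
  E <- nrow(island$edges)
  E / compact_reference_edges(V)
}

#' Island-size-weighted mean ND of a frame
#'
#' The frame-level summary matching the weighted-mean ND read off AFM
#' fields: only statistics-eligible islands (at least `threshold`
#' particles) contribute, each weighted by its size. `NA` when the frame
#' has no eligible island.
#'
#' @param isl List of islands (from [islands()]).
#' @param threshold Eligibility threshold (default 24).
#' @return Weighted mean ND, or `NA`.
#' @export
weighted_nd <- function(isl, threshold = 24) {
  el <- Filter(function(i) i$size >= threshold, isl)
  if (length(el) == 0) return(NA_real_)
  nds <- vapply(el, network_density, numeric(1))
  sizes <- vapply(el, function(i) i$size, numeric(1))
  weighted.mean(nds, sizes)
}
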