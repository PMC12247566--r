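#' Parcellation metadata
#'
#' Carries parcel names, hemispheres, lobe groups, and named hub definitions
#' (index sets), e.g. a 4-parcel motor/parietal hub plus auditory and visual
#' sensory targets. Geometry is not represented; the object is bookkeeping
#' for consolidation and for the hub-level statistics.
#'
#' @param names character vector of unique parcel names.
#' @param hemisphere "L"/"R" per parcel (recycled if length 1).
#' @param lobe lobe group per parcel, one of occipital, parietal, temporal,
#'   central, frontal (recycled if length 1).
#' @param hubs named list of integer parcel-index vectors.
#' @return An object of class `parcellation`.
#' @examples
#' parcellation(paste0("p", 1:6), hubs = list(hub = 1:2, auditory = 5L))
#' @export
parcellation <- function(names, hemisphere = "L", lobe = "parietal", hubs = list()) {
  n <- length(names)
  if (n < 1L || anyDuplicated(names)) stopf("parcel names must be non-empty and unique")
  hemisphere <- rep_len(hemisphere, n)
  lobe <- rep_len(lobe, n)
  stopifnot(all(hemisphere %in% c("L", "R")),
            all(lobe %in% c("occipital", "parietal", "temporal", "central", "frontal")))
  for (h in names(hubs)) {
    idx <- hubs[[h]]
    if (!all(idx %in% seq_len(n))) stopf("hub '%s' has out-of-range parcel indices", h)
  }
  structure(list(names = names, hemisphere = hemisphere, lobe = lobe,
                 hubs = lapply(hubs, as.integer)),
            class = "parcellation")
}

#' Number of unordered parcel pairs
#'
#' @param n_parcels parcel count (e.g. 70 for the Region Growing 70 atlas,
#'   giving 2415 connections).
#' @return integer P*(P-1)/2.
#' @export
n_connections <- function(n_parcels) {
  stopifnot(n_parcels >= 2)
  as.integer(n_parcels * (n_parcels - 1) / 2)
}

#' Vertices of a recursively subdivided icosahedral surface
#'
#' Each subdivision splits every triangular face in four; starting from the
#' icosahedron (12 vertices, 30 edges, 20 faces), order n has
#' `10 * 4^n + 2` vertices. Order 5 ("ico5"), the standard cortical source
#' space spacing, gives 10242 vertices per hemisphere.
#'
#' @param order subdivision order (>= 0).
#' @return integer vertex count.
#' @examples
#' ico_vertices(5) # 10242
#' @export
ico_vertices <- function(order) {
  stopifnot(order >= 0, order == round(order))
  # V_{k+1} = V_k + E_k (one new vertex per edge); E_{k+1} = 2 E_k + 3 F_k;
  # F_{k+1} = 4 F_k. Iterated from (12, 30, 20); closed form 10*4^n + 2.
  v <- 12; e <- 30; f <- 20
  for (k in seq_len(order)) {
    v <- v + e
    e <- 2 * e + 3 * f
    f <- 4 * f
  }
  as.integer(v)
}

#' Consolidate a multi-source region into one time course (PCA flip)
#'
#' Takes the dominant left-singular direction of the sources-by-samples
#' matrix, projects the data onto it, rescales the projection so that its
#' mean squared amplitude matches the average mean squared amplitude of the
#' region's sources, and aligns its polarity with the dominant source
#' orientation: the sign is flipped when the inner product between the
#' dominant singular vector and the per-source orientation signs is
#' negative. This preserves phase across sources that the forward model
#' represents with opposite polarity.
#'
#' @param block sources x samples numeric matrix (>= 1 source, >= 2 samples).
#' @param orientation per-source orientation signs (+1/-1); defaults to +1.
#' @return numeric vector of length `ncol(block)`.
#' @export
pca_flip <- function(block, orientation = rep(1, nrow(block))) {
  block <- as.matrix(block)
  if (nrow(block) < 1L || ncol(block) < 2L) stopf("need >= 1 source and >= 2 samples")
  if (!all(is.finite(block))) stopf("block contains non-finite values")
  if (length(orientation) != nrow(block) || !all(orientation %in% c(-1, 1)))
    stopf("orientation must be +1/-1 per source")
  if (all(block == 0)) stopf("rank-0 (all-zero) source block")

  sv <- svd(block, nu = 1, nv = 0)
  u1 <- sv$u[, 1]
  tc <- drop(crossprod(u1, block))

  target_pow <- mean(rowMeans(block^2))
  cur_pow <- mean(tc^2)
  tc <- tc * sqrt(target_pow / cur_pow)

  agree <- sum(u1 * orientation)
  if (agree < 0) {
    tc <- -tc
  } else if (agree == 0) {
    # tie: positive leading-coefficient convention on the singular vector
    lead <- u1[which(u1 != 0)[1]]
    if (lead < 0) tc <- -tc
  }
  tc
}

#' Consolidate per-source values by simple averaging
#'
#' Used for oscillatory power, where the arithmetic mean over a region's
#' sources is the appropriate summary (no polarity issue).
#'
#' @param values numeric vector or sources x samples matrix.
#' @return scalar mean (vector input) or per-sample mean (matrix input).
#' @export
mean_consolidate <- function(values) {
  if (length(values) == 0L) stopf("empty source set")
  if (is.matrix(values)) colMeans(values) else mean(values)
}
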