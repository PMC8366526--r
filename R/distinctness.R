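#' Pairwise taxonomic path weights from a classification table
#'
#' Species are joined at the first shared rank, counting rank columns from
#' finest to coarsest; species sharing no rank are joined at an implicit
#' root one step above the coarsest rank. Step lengths between levels are
#' equal and the weights are scaled so that the root-level (maximal)
#' separation equals 100.
#'
#' @param taxonomy A data frame whose first column is `species` and whose
#'   remaining columns are taxonomic ranks ordered finest to coarsest
#'   (e.g. genus, family, order, class). No missing entries.
#' @return A symmetric matrix of weights on the 0-100 scale with zero
#'   diagonal.
#' @export
taxonomic_weights <- function(taxonomy) {
  if (!is.data.frame(taxonomy) || ncol(taxonomy) < 2) {
    abort("`taxonomy` needs a species column plus at least one rank column.")
  }
  if (anyNA(taxonomy)) {
    abort("Taxonomy table has missing entries; all species need the same classification depth.")
  }
  sp <- as.character(taxonomy[[1]])
  if (anyDuplicated(sp)) abort("Duplicated species in taxonomy table.")
  ranks <- as.matrix(taxonomy[, -1, drop = FALSE])
  L <- ncol(ranks)
  n <- length(sp)
  w <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(ranks[i, ] == ranks[j, ])
      lev <- if (length(shared)) shared[1] else L + 1
      w[i, j] <- w[j, i] <- 100 * lev / (L + 1)
    }
  }
  w
}

#' Taxonomic distinctness of a community
#'
#' The abundance-weighted taxonomic distinctness (often written Delta*) is
#' the expected taxonomic path weight between two randomly chosen
#' individuals belonging to different species:
#' sum over species pairs i<j of w_ij x_i x_j, divided by the sum of
#' x_i x_j, with weights w_ij on the 0-100 equal-step-length scale of
#' [taxonomic_weights()]. With `weighted = FALSE` the presence/absence
#' variant (Delta+, the mean weight over distinct present species pairs)
#' is returned instead.
#'
#' A community with fewer than two species with positive abundance has no
#' defined distinctness; `NA` is returned with a warning so the value can
#' propagate as missing.
#'
#' @param community A data frame with columns `species` and `count`
#'   (abundances >= 0).
#' @param taxonomy Classification table for at least the observed species
#'   (see [taxonomic_weights()]).
#' @param weighted Abundance-weighted Delta* (default) or
#'   presence/absence Delta+.
#' @return A single value in \[0, 100\], or `NA` if undefined.
#' @examples
#' tax <- data.frame(
#'   species = c("a", "b", "c"),
#'   genus = c("G1", "G1", "G2"),
#'   family = c("F1", "F1", "F2"))
#' com <- data.frame(species = c("a", "b", "c"), count = c(4, 1, 2))
#' taxonomic_distinctness(com, tax)
#' @export
taxonomic_distinctness <- function(community, taxonomy, weighted = TRUE) {
  if (!all(c("species", "count") %in% names(community))) {
    abort("`community` needs `species` and `count` columns.")
  }
  if (any(community$count < 0)) abort("Abundances must be >= 0.")
  community <- dplyr::filter(community, .data$count > 0)
  missing_sp <- setdiff(community$species, taxonomy[[1]])
  if (length(missing_sp)) {
    abort(sprintf("Species missing from taxonomy: %s.",
                  paste(missing_sp, collapse = ", ")))
  }
  if (nrow(community) < 2) {
    warn("Fewer than two species present; taxonomic distinctness undefined.")
    return(NA_real_)
  }
  w <- taxonomic_weights(taxonomy)[community$species, community$species]
  x <- community$count
  num <- den <- 0
  for (i in seq_len(length(x) - 1)) {
    for (j in (i + 1):length(x)) {
      xx <- if (weighted) x[i] * x[j] else 1
      num <- num + w[i, j] * xx
      den <- den + xx
    }
  }
  num / den
}
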