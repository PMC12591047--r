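## Per-specimen cluster-frequency profiles and their grouping: the basis of
## the clustered frequency heatmap comparing 3D models with live animals.

#' Per-specimen cluster frequency profiles
#'
#' Joins anonymised pixel labels back to their specimen provenance and
#' computes, for each specimen, the proportion of its pixels assigned to each
#' colour cluster.
#'
#' @param assignment A `cluster_assignment` from [assign_pixels()].
#' @param provenance Character vector of specimen ids, one per pixel row (for
#'   a [pixel_spectra()] input use `x$provenance$specimen`).
#' @return A `frequency_profile`: `specimen_ids` and a specimens x K
#'   `frequencies` matrix with unit row sums.
#' @export
frequency_profiles <- function(assignment, provenance) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  provenance <- as.character(provenance)
  if (length(provenance) != length(assignment$labels)) {
    stopf("provenance has %d entries for %d pixel labels",
          length(provenance), length(assignment$labels))
  }
  K <- ncol(assignment$responsibilities)
  tab <- table(factor(provenance),
               factor(assignment$labels, levels = seq_len(K)))
  freq <- sweep(unclass(tab), 1L, rowSums(tab), "/")
  dimnames(freq) <- list(rownames(tab), paste0("colour_", seq_len(K)))
  structure(list(specimen_ids = rownames(tab), frequencies = freq),
            class = "frequency_profile")
}

#' Group specimens by the similarity of their colour composition
#'
#' Pairwise Bray-Curtis dissimilarities between specimen frequency rows,
#' agglomerated by UPGMA (average linkage). Deterministic given input order.
#'
#' @param profile A `frequency_profile`.
#' @return An [stats::hclust] tree over the specimens.
#' @export
specimen_grouping <- function(profile) {
  stopifnot(inherits(profile, "frequency_profile"))
  if (nrow(profile$frequencies) < 2L) {
    stopf("grouping needs at least 2 specimens")
  }
  d <- vegan::vegdist(profile$frequencies, method = "bray")
  stats::hclust(d, method = "average")
}
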