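#' Standard 19-channel 10-20 montage with a 4-neighborhood graph
#'
#' The neighbor graph is the customary nearest-neighbor adjacency on the
#' 10-20 grid (shipped as \code{extdata/montage_1020.tsv}); the surface
#' Laplacian uses unit distance weights, and only the nine interior channels
#' F3, Fz, F4, C3, Cz, C4, P3, Pz, P4 act as working (surrogate) channels
#' since only these are fully surrounded.
#'
#' @param file optional path to a two-column TSV (channel, comma-separated
#'   neighbors) overriding the shipped table
#' @return a list of class \code{Montage} with fields \code{channelNames},
#'   \code{neighbors} (named list), \code{workingChannels}
#' @export
standardMontage <- function(file = system.file("extdata", "montage_1020.tsv",
                                               package = "mrcpbench")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           comment.char = "#")
  neighbors <- lapply(strsplit(tab$neighbors, ","), trimws)
  names(neighbors) <- tab$channel
  # symmetry check: the relation must be undirected
  for (ch in names(neighbors)) {
    for (nb in neighbors[[ch]]) {
      if (!ch %in% neighbors[[nb]])
        stop("montage neighbor relation not symmetric: ", ch, " -> ", nb)
    }
  }
  working <- c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")
  working <- intersect(working, names(neighbors))
  if (any(vapply(neighbors[working], length, 0L) < 3L))
    stop("every working SL channel needs at least 3 neighbors")
  structure(list(channelNames = tab$channel, neighbors = neighbors,
                 workingChannels = working), class = "Montage")
}
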