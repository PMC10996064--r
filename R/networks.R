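#' Canonical functional brain network labels
#'
#' The 14 ICA-derived functional brain networks (FBNs) used throughout the
#' pipeline: posterior/anterior default mode, left/right frontoparietal,
#' dorsal attention, auditory, medial temporal, basal ganglia, salience,
#' sensorimotor, primary visual, two lateral visual, and cerebellum networks.
#'
#' @return Character vector of 14 network abbreviations.
#' @export
fbn_labels <- function() {
  c("pDMN", "aDMN", "lFPN", "rFPN", "DAN", "AN", "MTN",
    "BGN", "SN", "SMN", "pVN", "lVN1", "lVN2", "CN")
}

#' Enumerate network pairs
#'
#' Builds the unordered (i < j) and ordered (i != j) pair grids over a set of
#' network labels. With N networks there are N(N-1)/2 unordered and N(N-1)
#' ordered pairs; for the default 14 networks that is 91 and 182. Pair names
#' join the two labels with `"__"` (first label leads for ordered pairs).
#'
#' @param networks Character vector of network labels (default [fbn_labels()]).
#' @return List with data frames `unordered` and `ordered`, each with integer
#'   columns `i`, `j` and a character `name` column.
#' @export
pair_grid <- function(networks = fbn_labels()) {
  n <- length(networks)
  stopifnot(n >= 2, !anyDuplicated(networks))
  un <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  un <- un[order(un[, 1], un[, 2]), , drop = FALSE]
  unordered <- data.frame(
    i = un[, 1], j = un[, 2],
    name = paste(networks[un[, 1]], networks[un[, 2]], sep = "__"),
    stringsAsFactors = FALSE
  )
  od <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
  od <- od[od$i != od$j, , drop = FALSE]
  od <- od[order(od$i, od$j), , drop = FALSE]
  ordered <- data.frame(
    i = od$i, j = od$j,
    name = paste(networks[od$i], networks[od$j], sep = "__"),
    stringsAsFactors = FALSE
  )
  rownames(unordered) <- rownames(ordered) <- NULL
  list(networks = networks, unordered = unordered, ordered = ordered)
}
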