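# Canonical spatial structures used by the simulator and for template
# sorting: a mirror-symmetric 2-D head layout, the four classical microstate
# topographies (A-D), and the 14-entry CAP network-pair library.

#' Mirror-symmetric 2-D channel layout on the unit disk
#'
#' Places channels on a disk so that every off-midline channel has an exact
#' left-right mirror partner (needed both for plausible topographies and for
#' symmetry checks). x runs left (-) to right (+), y posterior (-) to
#' anterior (+).
#'
#' @param n_channels number of channels (>= 8).
#' @return n x 2 matrix of coordinates with attribute `mirror_index`, the
#'   index of each channel's left-right mirror (itself on the midline).
#' @export
disk_layout <- function(n_channels) {
  if (n_channels < 8)
    ns_stop("neurostate_error_too_few_channels",
            "need >= 8 channels to express topographic gradients")
  n_pair <- n_channels %/% 2L
  odd <- n_channels %% 2L == 1L
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_pair)
  r <- sqrt((i - 0.5) / n_pair)
  # angles confined to the right half-plane, spread by the golden angle
  theta <- ((i * golden) %% pi) - pi / 2
  right <- cbind(r * cos(theta) * 0.95 + 0.02, r * sin(theta))
  left <- cbind(-right[, 1], right[, 2])
  pos <- rbind(right, left)
  mirror <- c(n_pair + i, i)
  if (odd) {
    pos <- rbind(pos, c(0, 0.9))
    mirror <- c(mirror, n_channels)
  }
  attr(pos, "mirror_index") <- mirror
  pos
}

avg_ref <- function(maps) {
  # rows = maps; subtract the channel mean of each row
  sweep(maps, 1, rowMeans(maps))
}

map_gfp <- function(maps) sqrt(rowMeans(avg_ref(maps)^2))

unit_gfp <- function(maps) {
  m <- avg_ref(maps)
  g <- sqrt(rowMeans(m^2))
  if (any(g == 0))
    ns_stop("neurostate_error_degenerate_map", "all-zero map cannot be normalized")
  m / g
}

#' Canonical microstate template topographies A-D
#'
#' Four average-referenced, unit-GFP maps with the classical motifs:
#' A a left-posterior to right-frontal diagonal, B its left-right mirror,
#' C an anterior-posterior gradient, D a fronto-central peak.
#'
#' @param n_channels number of channels (>= 8); ignored when `positions`
#'   is supplied.
#' @param positions optional n x 2 layout; defaults to [disk_layout()].
#' @return 4 x n_channels matrix with rownames `A`..`D` and the layout in
#'   attribute `positions`.
#' @export
make_canonical_templates <- function(n_channels = 32, positions = NULL) {
  if (is.null(positions)) positions <- disk_layout(n_channels)
  if (nrow(positions) < 8)
    ns_stop("neurostate_error_too_few_channels",
            "need >= 8 channels to express topographic gradients")
  x <- positions[, 1]; y <- positions[, 2]
  maps <- rbind(
    A = x + y,
    B = y - x,
    C = y,
    D = exp(-((x^2 + (y - 0.4)^2) / (2 * 0.35^2))))
  maps <- unit_gfp(maps)
  attr(maps, "positions") <- positions
  maps
}

#' The 14-entry CAP network-pair library
#'
#' Each CAP is one activated and one deactivated network from the seven
#' canonical resting-state networks. The four pairs reported by name in the
#' source analyses (DAN+ VAN-, VAN+ DAN-, FPN+ VN-, SMN+ FPN-) come first,
#' followed by ten fillers so that every network appears.
#'
#' @return data.frame with columns `name`, `pos`, `neg`.
#' @export
cap_pattern_library <- function() {
  pairs <- matrix(c(
    "DAN", "VAN",
    "VAN", "DAN",
    "FPN", "VN",
    "SMN", "FPN",
    "VN",  "DMN",
    "DMN", "VN",
    "LN",  "SMN",
    "DMN", "DAN",
    "VN",  "LN",
    "FPN", "SMN",
    "SMN", "VN",
    "VAN", "LN",
    "DAN", "DMN",
    "LN",  "FPN"), ncol = 2, byrow = TRUE)
  data.frame(name = paste0(pairs[, 1], "+ ", pairs[, 2], "-"),
             pos = pairs[, 1], neg = pairs[, 2])
}

#' Synthetic ROI-to-network atlas
#'
#' Assigns `n_rois` ROIs round-robin to the seven networks so every network
#' is non-empty.
#'
#' @param n_rois number of ROIs (>= 7).
#' @return named character vector (class `atlas_map`), roi_id -> network.
#' @export
make_atlas <- function(n_rois = 100) {
  if (n_rois < 7)
    ns_stop("neurostate_error_too_few_rois", "need >= 7 ROIs (one per network)")
  ids <- sprintf("roi%03d", seq_len(n_rois))
  structure(stats::setNames(rep(YEO7, length.out = n_rois), ids),
            class = "atlas_map")
}

#' Build the 14 x ROIs CAP pattern matrix
#'
#' Each row is +1 on the ROIs of the pattern's activated network, -1 on the
#' deactivated network's ROIs, 0 elsewhere, normalised to unit Euclidean
#' norm.
#'
#' @param atlas atlas map from [make_atlas()] or [read_atlas()].
#' @param library pattern library (default [cap_pattern_library()]).
#' @return k x n_rois matrix with pattern names as rownames.
#' @export
make_cap_patterns <- function(atlas, library = cap_pattern_library()) {
  nets <- as.character(atlas)
  pat <- matrix(0, nrow(library), length(atlas),
                dimnames = list(library$name, names(atlas)))
  for (i in seq_len(nrow(library))) {
    pat[i, nets == library$pos[i]] <- 1
    pat[i, nets == library$neg[i]] <- -1
  }
  pat / sqrt(rowSums(pat^2))
}
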