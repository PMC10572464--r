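#' Network atlas objects
#'
#' A `network_atlas` maps ROI labels to large-scale resting-state networks.
#' ROI labels follow the grammar `"Network.ROIName (L|R)"` with the
#' hemisphere suffix optional, e.g. `"DorsalAttention.FEF (R)"` or
#' `"DefaultMode.PCC"`.
#'
#' The packaged default (see [default_atlas()]) defines 8 networks over
#' 32 ROIs: default mode (4), sensorimotor (3), visual (4),
#' salience/cingulo-opercular (7), dorsal attention (4),
#' frontoparietal/central executive (4), language (4), cerebellar (2).
#' A companion inventory of 164 labels (the 32 network ROIs plus 132
#' anatomical parcels) is packaged for bookkeeping (see [full_atlas()]).
#'
#' @param networks named list: network name -> character vector of ROI
#'   short names (without the network prefix).
#' @return an object of class `network_atlas` with elements
#'   `roi_labels` (full `Network.ROI` labels, in atlas order),
#'   `network_of` (named character vector, label -> network) and
#'   `networks` (ordered network names).
#' @examples
#' atl <- default_atlas()
#' length(atl$roi_labels)   # 32
#' table(atl$network_of)[atl$networks]
#' @export
network_atlas <- function(networks) {
  if (!is.list(networks) || is.null(names(networks)) || any(names(networks) == ""))
    stopf("'networks' must be a named list of ROI name vectors")
  if (any(lengths(networks) < 1))
    stopf("every network must contain at least one ROI")
  labels <- unlist(mapply(function(net, rois) paste0(net, ".", rois),
                          names(networks), networks, SIMPLIFY = FALSE),
                   use.names = FALSE)
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stopf("duplicate ROI label in atlas: '%s'", dup[1])
  structure(
    list(roi_labels = labels,
         network_of = stats::setNames(rep(names(networks), lengths(networks)), labels),
         networks = names(networks)),
    class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat(sprintf("<network_atlas> %d ROIs in %d networks\n",
              length(x$roi_labels), length(x$networks)))
  counts <- table(factor(x$network_of, levels = x$networks))
  for (n in x$networks) cat(sprintf("  %-18s %d ROIs\n", n, counts[[n]]))
  invisible(x)
}

#' Read a network atlas from a JSON file
#'
#' The file format is a single JSON object mapping network names to arrays
#' of ROI short names, as in the packaged `atlas_networks32.json`.
#'
#' @param path path to a JSON atlas definition.
#' @return a [network_atlas()] object.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stopf("atlas file not found: %s", path)
  networks <- jsonlite::read_json(path, simplifyVector = TRUE)
  network_atlas(as.list(networks))
}

#' Write a network atlas to JSON
#'
#' Inverse of [read_atlas()]: `read_atlas(write_atlas(atlas, f))` recovers
#' the atlas.
#'
#' @param atlas a `network_atlas`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "network_atlas"))
  nets <- lapply(stats::setNames(atlas$networks, atlas$networks), function(n) {
    labs <- atlas$roi_labels[atlas$network_of == n]
    sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", n), "\\."), "", labs)
  })
  jsonlite::write_json(nets, path, pretty = TRUE)
  invisible(path)
}

#' The packaged 8-network, 32-ROI atlas
#'
#' Eight large-scale resting-state networks with per-network ROI counts
#' (4, 3, 4, 7, 4, 4, 4, 2): default mode, sensorimotor, visual, salience,
#' dorsal attention, frontoparietal, language, cerebellar.
#'
#' @return a [network_atlas()] with 32 ROIs.
#' @export
default_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_networks32.json",
                         package = "conntfce", mustWork = TRUE))
}

#' The packaged 164-label ROI inventory
#'
#' The 32 network ROIs of [default_atlas()] plus 132 anatomical parcel
#' labels (cortical/subcortical/cerebellar naming), packaged for
#' bookkeeping when interfacing with whole-brain parcellations. Only the
#' 32 network ROIs enter the statistical analysis.
#'
#' @return a [network_atlas()] with 164 labels.
#' @export
full_atlas <- function() {
  read_atlas(system.file("extdata", "atlas_full164.json",
                         package = "conntfce", mustWork = TRUE))
}

#' Parse an ROI label into its components
#'
#' @param label character vector of labels like `"Salience.AInsula (R)"`.
#' @return data.frame with columns `network`, `roi`, `hemisphere`
#'   (`"L"`, `"R"` or `NA`).
#' @examples
#' parse_roi_label("DorsalAttention.FEF (R)")
#' @export
parse_roi_label <- function(label) {
  m <- regmatches(label, regexec("^([^.]+)\\.(.+?)(?: \\((L|R)\\))?$", label))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) stopf("malformed ROI label: '%s'", label[bad][1])
  data.frame(
    network = vapply(m, `[`, "", 2L),
    roi = vapply(m, `[`, "", 3L),
    hemisphere = ifelse(vapply(m, `[`, "", 4L) == "", NA, vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}
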