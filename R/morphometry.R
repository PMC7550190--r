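#' Tectal layer atlas
#'
#' Ordered laminae of the tectal neuropil, superficial to deep, with
#' strictly increasing boundary depths (micrometers along the depth axis).
#' Layer i occupies [boundaries[i], boundaries[i+1]); the deepest layer is
#' closed at its lower face. Boundaries are flat planes perpendicular to
#' the depth axis.
#'
#' @param boundaries Numeric vector of length `length(layers) + 1`,
#'   strictly increasing.
#' @param layers Layer names, superficial to deep.
#' @return A `layer_atlas`.
#' @export
layer_atlas <- function(boundaries = c(0, 8, 16, 28, 40, 52, 62, 72, 84),
                        layers = c("SM", "SO", "SFGS1/2", "SFGS3/4",
                                   "SFGS5/6", "SGC", "SAC", "SAC/SPV")) {
  stopifnot(length(boundaries) == length(layers) + 1,
            all(diff(boundaries) > 0))
  structure(list(layers = layers, boundaries = boundaries),
            class = "layer_atlas")
}

#' Read a neuron tracing from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; `#` comments).
#' The tracing must be a single connected tree in which every parent
#' appears before its children.
#'
#' @param path SWC file path.
#' @return A `neuron_tracing` data frame.
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  as_neuron_tracing(df)
}

#' Validate and class an SWC node table
#'
#' @param df Data frame with columns id, type, x, y, z, radius, parent.
#' @return A `neuron_tracing`.
#' @export
as_neuron_tracing <- function(df) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(need %in% names(df)))
  roots <- sum(df$parent == -1)
  if (roots != 1) stop("tracing must have exactly one root, found ", roots)
  known <- df$parent == -1 | df$parent %in% df$id
  if (!all(known)) stop("disconnected tracing: unknown parent ids")
  pos <- match(df$parent, df$id)
  if (any(pos >= seq_len(nrow(df)), na.rm = TRUE))
    stop("parent nodes must precede children")
  structure(df[, need], class = c("neuron_tracing", "data.frame"))
}

#' Write a tracing to an SWC file
#'
#' @param tracing A `neuron_tracing`.
#' @param path Output path.
#' @export
write_swc <- function(tracing, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC tracing (id type x y z radius parent)", con)
  utils::write.table(tracing, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# split the depth span [z1, z2] of one edge across atlas layers;
# returns a named vector of length fractions (layers + "outside")
edge_layer_fractions <- function(z1, z2, atlas) {
  b <- atlas$boundaries
  bins <- c(-Inf, b, Inf)
  names_all <- c("outside_above", atlas$layers, "outside_below")
  lo <- min(z1, z2); hi <- max(z1, z2)
  fr <- stats::setNames(numeric(length(names_all)), names_all)
  if (hi == lo) {
    i <- findInterval(lo, b, rightmost.closed = TRUE) + 1L
    fr[i] <- 1
  } else {
    for (i in seq_along(names_all)) {
      ov <- max(0, min(hi, bins[i + 1]) - max(lo, bins[i]))
      fr[i] <- ov / (hi - lo)
    }
  }
  out <- fr[atlas$layers]
  c(out, outside = unname(fr["outside_above"] + fr["outside_below"]))
}

#' Proportional branch length per tectal layer
#'
#' Splits each edge's 3-D cable length across the atlas layers by clipping
#' the edge at the boundary planes, and reports the fraction of total
#' neurite length per layer. Cable outside the atlas depth range goes into
#' an explicit `outside` bin; fractions sum to 1.
#'
#' @param tracing A `neuron_tracing`.
#' @param atlas A `layer_atlas`.
#' @param depth_axis Coordinate used as depth (default `"z"`).
#' @return Named numeric vector: one fraction per layer plus `outside`.
#' @export
proportional_branch_length <- function(tracing, atlas, depth_axis = "z") {
  stopifnot(inherits(tracing, "neuron_tracing"),
            inherits(atlas, "layer_atlas"))
  acc <- stats::setNames(numeric(length(atlas$layers) + 1),
                         c(atlas$layers, "outside"))
  idx <- match(tracing$parent, tracing$id)
  total <- 0
  for (i in which(tracing$parent != -1)) {
    p <- idx[i]
    len <- sqrt((tracing$x[i] - tracing$x[p])^2 +
                (tracing$y[i] - tracing$y[p])^2 +
                (tracing$z[i] - tracing$z[p])^2)
    if (len == 0) next
    fr <- edge_layer_fractions(tracing[[depth_axis]][p],
                               tracing[[depth_axis]][i], atlas)
    acc <- acc + len * fr
    total <- total + len
  }
  if (total == 0) stop("tracing has zero cable length")
  acc / total
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Planar arbor area per layer and deep/superficial ratio
#'
#' For each layer, the area of the 2-D convex hull of the tracing's nodes
#' within that layer, projected onto the layer plane (x, y). Layers with
#' fewer than 3 nodes, or with collinear nodes, get area 0. The
#' deep/superficial ratio is the summed area of SFGS5/6 through SAC/SPV
#' over the summed area of SM through SFGS3/4 (`Inf` when the superficial
#' area is 0 and the deep area positive, `NaN` when both are 0).
#'
#' @param tracing A `neuron_tracing`.
#' @param atlas A `layer_atlas`.
#' @param depth_axis Coordinate used as depth (default `"z"`).
#' @return List with `areas` (named, square micrometers) and
#'   `deep_superficial_ratio`.
#' @export
arbor_area_per_layer <- function(tracing, atlas, depth_axis = "z") {
  z <- tracing[[depth_axis]]
  b <- atlas$boundaries
  areas <- stats::setNames(numeric(length(atlas$layers)), atlas$layers)
  for (i in seq_along(atlas$layers)) {
    inl <- z >= b[i] & (if (i == length(atlas$layers)) z <= b[i + 1]
                        else z < b[i + 1])
    if (sum(inl) < 3) next
    xy <- cbind(tracing$x[inl], tracing$y[inl])
    hull <- grDevices::chull(xy)
    areas[i] <- shoelace_area(xy[hull, , drop = FALSE])
  }
  deep <- c("SFGS5/6", "SGC", "SAC", "SAC/SPV")
  sup <- c("SM", "SO", "SFGS1/2", "SFGS3/4")
  list(areas = areas,
       deep_superficial_ratio = sum(areas[deep]) / sum(areas[sup]))
}

#' Anterior-posterior distribution of a functional cluster
#'
#' Kernel density estimates (Gaussian, Scott's-rule bandwidth) of a
#' cluster's anterior-posterior soma positions and of all units, plus a
#' two-tailed two-sample t-test of the cluster's positions against the
#' remaining units.
#'
#' @param positions Per-unit A-P coordinates in [0, 1].
#' @param labels Per-unit cluster labels.
#' @param cluster The cluster to profile.
#' @return List with `cluster_density`, `all_density` (both `density`
#'   objects), `mean_diff` (cluster mean minus all-units mean), `p_value`,
#'   `statistic`.
#' @export
ap_cluster_distribution <- function(positions, labels, cluster) {
  stopifnot(all(positions >= 0 & positions <= 1),
            length(positions) == length(labels))
  inc <- labels == cluster
  if (sum(inc) < 3) stop("cluster has fewer than 3 members")
  if (sum(!inc) < 3) stop("complement has fewer than 3 members")
  tt <- stats::t.test(positions[inc], positions[!inc],
                      alternative = "two.sided")
  list(cluster_density = stats::density(positions[inc], bw = "nrd"),
       all_density = stats::density(positions, bw = "nrd"),
       mean_diff = mean(positions[inc]) - mean(positions),
       p_value = tt$p.value, statistic = unname(tt$statistic))
}
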