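# Layer stratification by the in/out degree ratio: sources of signal
# (hormones, paracrine factors) sit near DR_io = 0, terminal follicular
# events near DR_io = 100, signal-processing molecules in between.

#' In/out degree ratio
#'
#' The in-fraction of a node's links mapped to \[0, 100\]:
#' `100 * gamma_in / (gamma_in + gamma_out)`. A pure source scores 0, a
#' pure sink 100. Undefined for isolated nodes (both degrees zero).
#'
#' @param gamma_in,gamma_out in- and out-degree (vectors allowed).
#' @return numeric vector in \[0, 100\]; `NA` where both degrees are 0.
#' @export
dr_io <- function(gamma_in, gamma_out) {
  tot <- gamma_in + gamma_out
  ifelse(tot > 0, 100 * gamma_in / tot, NA_real_)
}

#' Assign a layer from a DR_io value
#'
#' The published integer bands 0-35 / 36-67 / 68-100 are generalized to
#' the half-open real intervals \[0, 36) input, \[36, 68) processing,
#' \[68, 100\] output, since DR_io is in general non-integer.
#'
#' @param dr numeric vector of DR_io values in \[0, 100\].
#' @return factor with levels `input`, `processing`, `output`.
#' @export
assign_layer <- function(dr) {
  ok <- is.na(dr) | (dr >= 0 & dr <= 100)
  if (!all(ok)) stop("DR_io values must lie in [0, 100]")
  out <- ifelse(is.na(dr), NA_character_,
                ifelse(dr < 36, "input",
                       ifelse(dr < 68, "processing", "output")))
  factor(out, levels = c("input", "processing", "output"))
}

#' Stratify a network into input / processing / output layers
#'
#' Computes DR_io for every node and assigns each non-isolated node to
#' exactly one layer; isolated nodes (no links) are excluded from the
#' stratification and counted. When a [find_controllers()] result is
#' supplied, each node is also classed as `hub`, `BN`, `hub.BN` or
#' `other` and the summary cross-tabulates layer by controller class.
#'
#' @param net a `signaling_network` or igraph.
#' @param controllers optional `controller_set`.
#' @return list with `assignments` (data.frame: node, gamma_in,
#'   gamma_out, dr_io, layer, controller_class), `composition` (layer x
#'   controller-class contingency table), and `n_isolated`.
#' @export
stratify_network <- function(net, controllers = NULL) {
  deg <- degree_profile(net)
  deg$dr_io <- dr_io(deg$gamma_in, deg$gamma_out)
  n_isolated <- sum(is.na(deg$dr_io))
  if (n_isolated > 0) {
    message(n_isolated, " isolated node(s) excluded from stratification")
  }
  deg$layer <- assign_layer(deg$dr_io)
  cls <- rep("other", nrow(deg))
  if (!is.null(controllers)) {
    stopifnot(inherits(controllers, "controller_set"))
    cls[deg$node %in% controllers$hubs] <- "hub"
    cls[deg$node %in% controllers$bottlenecks] <- "BN"
    cls[deg$node %in% controllers$hub_bn] <- "hub.BN"
  }
  deg$controller_class <- factor(cls, levels = c("hub", "BN", "hub.BN", "other"))
  keep <- !is.na(deg$layer)
  composition <- table(layer = deg$layer[keep],
                       controller_class = deg$controller_class[keep])
  list(assignments = deg, composition = composition, n_isolated = n_isolated)
}
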