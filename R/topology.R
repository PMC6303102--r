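#' TTF regulatory circuit topology
#'
#' A topology is the regulatory graph between the four TTFs: a set of signed
#' interactions classified as forward activator-relay (blue in the field's
#' circuit diagrams), forward repressor-decay (red), or backward repression
#' (black).
#'
#' @name ttf_topology
NULL

TTFS <- c("Hb", "Kr", "Pdm", "Cas")

#' Identifier of a regulatory interaction
#'
#' Activations are written `"Src->Tgt"`, repressions `"Src-|Tgt"`.
#'
#' @param source,target TTF names.
#' @param sign `"activation"` or `"repression"`.
#' @return Character id.
#' @export
interaction_id <- function(source, target, sign) {
  paste0(source, ifelse(sign == "activation", "->", "-|"), target)
}

new_topology <- function(interactions, ttfs = TTFS) {
  stopifnot(is.data.frame(interactions))
  req <- c("source", "target", "sign", "klass", "has_threshold")
  if (!all(req %in% names(interactions)))
    stop("interactions must have columns: ", paste(req, collapse = ", "))
  bad <- setdiff(unique(c(interactions$source, interactions$target)), ttfs)
  if (length(bad))
    stop("unknown TTF name(s) in topology: ", paste(bad, collapse = ", "))
  if (any(interactions$source == interactions$target))
    stop("self-edges are not allowed")
  if (!all(interactions$sign %in% c("activation", "repression")))
    stop("sign must be 'activation' or 'repression'")
  interactions$id <- interaction_id(interactions$source, interactions$target,
                                    interactions$sign)
  if (anyDuplicated(interactions$id))
    stop("duplicate interactions: ",
         paste(interactions$id[duplicated(interactions$id)], collapse = ", "))
  structure(list(ttfs = ttfs, interactions = interactions),
            class = "ttf_topology")
}

#' Default TTF circuit topology
#'
#' The experimentally described circuit: three forward activator-relay edges
#' (Hb->Kr, Kr->Pdm, Pdm->Cas), three forward repressor-decay edges (Hb-|Pdm,
#' Kr-|Cas, Hb-|Cas) and one backward repression (Cas-|Pdm). All seven edges
#' carry a free regulation threshold, which together with 4 production, 2
#' basal and 4 degradation rates gives the 17 free parameters of a circuit.
#'
#' @return A `ttf_topology`.
#' @export
build_default_topology <- function() {
  new_topology(data.frame(
    source = c("Hb", "Kr", "Hb",  "Pdm", "Kr",  "Hb",  "Cas"),
    target = c("Kr", "Pdm", "Pdm", "Cas", "Cas", "Cas", "Pdm"),
    sign   = c("activation", "activation", "repression", "activation",
               "repression", "repression", "repression"),
    klass  = c("forward-relay", "forward-relay", "forward-decay",
               "forward-relay", "forward-decay", "forward-decay",
               "backward"),
    has_threshold = TRUE,
    stringsAsFactors = FALSE
  ))
}

#' Read / write a topology config file (YAML)
#'
#' @param path File path.
#' @return `read_topology` returns a `ttf_topology`; `write_topology` returns
#'   `path` invisibly.
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$interactions)) stop("topology config lacks 'interactions'")
  ints <- do.call(rbind, lapply(cfg$interactions, function(x) {
    data.frame(source = x$source, target = x$target, sign = x$sign,
               klass = x$klass,
               has_threshold = isTRUE(x$has_threshold),
               stringsAsFactors = FALSE)
  }))
  ttfs <- if (!is.null(cfg$ttfs)) unlist(cfg$ttfs) else TTFS
  new_topology(ints, ttfs = ttfs)
}

#' @rdname read_topology
#' @param topology A `ttf_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "ttf_topology"))
  ints <- topology$interactions
  yaml::write_yaml(list(
    ttfs = as.list(topology$ttfs),
    interactions = lapply(seq_len(nrow(ints)), function(i) list(
      source = ints$source[i], target = ints$target[i], sign = ints$sign[i],
      klass = ints$klass[i], has_threshold = ints$has_threshold[i]))
  ), path)
  invisible(path)
}

#' @export
print.ttf_topology <- function(x, ...) {
  cat("TTF circuit topology:", paste(x$ttfs, collapse = " -> "), "\n")
  cat(paste0("  ", x$interactions$id, "  [", x$interactions$klass, "]"),
      sep = "\n")
  invisible(x)
}

threshold_ids <- function(topology) {
  ints <- topology$interactions
  ints$id[ints$has_threshold]
}

# Threshold parameter names are "T_<Src><Tgt>", e.g. T_HbPdm.
threshold_param_names <- function(topology) {
  ints <- topology$interactions
  paste0("T_", ints$source[ints$has_threshold], ints$target[ints$has_threshold])
}
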