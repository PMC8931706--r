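# Ancestral placement of shared lesions by Dollo parsimony: a lesion is
# gained once and never reverts, so a shared event signature is placed on the
# branch above the MRCA of its carriers when every descendant of that MRCA
# carries it; otherwise the minimal set of independent gains is reported.

#' Branch labels of a rooted tree
#'
#' Each branch is named after its child node: the tip label for terminal
#' branches, the node label (or `node_<k>`) for internal ones.
#'
#' @param tree An `ape::phylo`.
#' @return Character vector, one label per row of `tree$edge`.
#' @export
branch_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- character(length(child))
  is_tip <- child <= n_tip
  lab[is_tip] <- tree$tip.label[child[is_tip]]
  internal <- child[!is_tip]
  if (!is.null(tree$node.label) && all(nzchar(tree$node.label[internal - n_tip]))) {
    lab[!is_tip] <- tree$node.label[internal - n_tip]
  } else {
    lab[!is_tip] <- paste0("node_", internal)
  }
  lab
}

# tips (integer indices) descending from each node, as a list indexed by node
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; c <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

# minimal Dollo gain set: smallest set of branches whose subtrees exactly
# cover the carrier tips (each gained subtree all-carrier)
dollo_gains <- function(tree, carrier_tips) {
  n_tip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  carriers <- match(carrier_tips, tree$tip.label)
  root <- n_tip + 1L
  gains <- integer()
  recurse <- function(node) {
    tips <- desc[[node]]
    if (all(tips %in% carriers)) {
      gains <<- c(gains, node)
      return(invisible())
    }
    if (!any(tips %in% carriers)) return(invisible())
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (k in kids) recurse(k)
  }
  recurse(root)
  gains
}

#' Map shared lesions onto ancestral branches
#'
#' Groups events into signatures (identical type + aligned position +
#' observed state) and places each signature on the tree: if the carriers
#' form exactly one clade the origin is the branch above their MRCA (a single
#' gain, no reversals); otherwise the signature is homoplasic and the minimal
#' set of independent gains is reported.
#'
#' @param events Event tibble (typically [all_events()] filtered to
#'   inactivating calls).
#' @param tree Rooted `ape::phylo` whose tips include every carrier.
#' @return Tibble with one row per event signature: `event_type`, `position`,
#'   `obs_state`, `n_carriers`, `carriers` (list), `homoplasic`, `n_gains`,
#'   `origin_branch` (label of the single-gain branch, `NA` when homoplasic)
#'   and `gain_branches` (list of branch labels).
#' @export
map_events_to_tree <- function(events, tree) {
  if (nrow(events) == 0) {
    return(tibble::tibble(
      event_type = character(), position = integer(), obs_state = character(),
      n_carriers = integer(), carriers = list(), homoplasic = logical(),
      n_gains = integer(), origin_branch = character(), gain_branches = list()
    ))
  }
  bad <- setdiff(unique(events$species_id), tree$tip.label)
  if (length(bad) > 0) {
    stop("event carriers not in tree: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  events$position <- ifelse(is.na(events$codon_index),
                            events$junction_index, events$codon_index)
  key <- paste(events$event_type, events$position, events$obs_state, sep = "|")
  elab <- branch_labels(tree)
  child <- tree$edge[, 2]

  groups <- split(events, key)
  out <- lapply(groups, function(g) {
    carriers <- sort(unique(g$species_id))
    gains <- dollo_gains(tree, carriers)
    single <- length(gains) == 1L
    gain_lab <- elab[match(gains, child)]
    # the root itself has no parent edge; label it explicitly
    gain_lab[is.na(gain_lab)] <- "root"
    tibble::tibble(
      event_type = g$event_type[1], position = as.integer(g$position[1]),
      obs_state = g$obs_state[1], n_carriers = length(carriers),
      carriers = list(carriers), homoplasic = !single,
      n_gains = length(gains),
      origin_branch = if (single) gain_lab else NA_character_,
      gain_branches = list(gain_lab)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$event_type, .data$position)
}
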