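#' Expression levels of Notch pathway components in one cell type
#'
#' @param notch_production Notch production rate (model units/time).
#' @param ligand_production named vector of ligand production rates, e.g.
#'   `c(Dll1 = 1, Jag1 = 10)` (mammalian) or `c(Delta = , Serrate = )`
#'   (fly).
#' @param fringe a [fringe_config()] whose factor maps cover the ligand
#'   repertoire.
#' @return A list of class `component_levels`.
#' @export
component_levels <- function(notch_production, ligand_production,
                             fringe = fringe_config()) {
  ligand_production <- unlist(ligand_production)
  stopifnot(notch_production >= 0, all(ligand_production >= 0),
            !is.null(names(ligand_production)),
            inherits(fringe, "fringe_config"))
  structure(list(notch_production = notch_production,
                 ligand_production = ligand_production,
                 fringe = fringe),
            class = "component_levels")
}

#' Classify the signaling state of a cell type
#'
#' Determines which ligands a cell can send with and which it can
#' receive from, given its component expression levels, the kinetic
#' parameters and its Fringe state.  The per-ligand Fringe-modified cis
#' strengths are computed, the multi-ligand cis steady state is solved,
#' and capabilities follow from the surviving free levels:
#' * `receive_from` contains ligand `l` when free Notch is at least
#'   `receive_frac` of its unopposed level `beta_N/gamma_N` **and**
#'   trans-activation by `l` is not blocked by Fringe (receiver
#'   `trans_factor[l] >= block_cutoff`);
#' * `send_with` contains ligand `l` when the cell's free ligand `l` is
#'   at least `send_frac` of the cell's dominant unopposed expression
#'   level, `max(beta_N/gamma_N, max_l beta_D_l/gamma_D)`.
#'
#' Sending is thresholded against the cell's dominant expression scale
#' (not the ligand's own unopposed level) because a minority ligand that
#' escapes cis-inhibition only through weak expression still presents
#' too little ligand to activate neighbours; this reproduces the
#' excess-based endpoint states of the pathway (see the methods
#' vignette).
#'
#' @param levels a [component_levels()] object.
#' @param params base [kinetic_params()]; `beta_N` and `beta_D` are
#'   overridden by `levels`.
#' @param thresholds list with `send_frac`, `receive_frac` in (0,1) and
#'   `block_cutoff` (trans factor below which receiving is blocked).
#' @return A list of class `signaling_state`: `free_notch`,
#'   `free_ligand` (named), `receive_from`, `send_with` (character
#'   vectors), plus the inputs.
#' @export
classify_state <- function(levels, params = kinetic_params(),
                           thresholds = list(send_frac = 0.2,
                                             receive_frac = 0.2,
                                             block_cutoff = 0.5)) {
  stopifnot(inherits(levels, "component_levels"),
            thresholds$send_frac > 0, thresholds$send_frac < 1,
            thresholds$receive_frac > 0, thresholds$receive_frac < 1)
  fr <- levels$fringe
  ligs <- names(levels$ligand_production)
  plist <- lapply(ligs, function(l) {
    p <- apply_fringe(params, fr, l)
    p$beta_N <- levels$notch_production
    p$beta_D <- levels$ligand_production[[l]]
    do.call(kinetic_params, unclass(p))
  })
  names(plist) <- ligs
  ss <- solve_cis_steady_state(plist)
  n0 <- levels$notch_production / params$gamma_N
  d0 <- levels$ligand_production / params$gamma_D
  dominant <- max(n0, d0)
  receive_from <- if (levels$notch_production > 0 &&
                      ss$N >= thresholds$receive_frac * n0)
    names(fr$trans_factor)[fr$trans_factor >= thresholds$block_cutoff]
  else character(0)
  send_with <- ligs[levels$ligand_production > 0 &
                      ss$D >= thresholds$send_frac * dominant]
  structure(list(free_notch = ss$N, free_ligand = ss$D,
                 receive_from = receive_from, send_with = send_with,
                 levels = levels, thresholds = thresholds),
            class = "signaling_state")
}

#' @export
print.signaling_state <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat(sprintf("Signaling state [fringe %s]:\n", x$levels$fringe$identity))
  cat(sprintf("  free Notch %.3g; free ligand %s\n", x$free_notch,
              paste(sprintf("%s=%.3g", names(x$free_ligand), x$free_ligand),
                    collapse = ", ")))
  cat("  receives from:", fmt(x$receive_from), "\n")
  cat("  sends with:   ", fmt(x$send_with), "\n")
  invisible(x)
}

#' Directed inter-state signaling graph
#'
#' Classifies each named cell type and draws a directed edge
#' `(sender, receiver, ligand)` exactly when the sender's `send_with`
#' and the receiver's `receive_from` both contain the ligand.  Self-edges
#' (a state that could signal to a cell in the same state) and directed
#' cycles are detected and reported, not suppressed: with strong mutual
#' cis-inhibition the canonical endpoint states form a self-edge-free
#' acyclic graph, but weak-cis configurations can and do violate this.
#'
#' @param named_levels named list of [component_levels()].
#' @param params base [kinetic_params()].
#' @param thresholds see [classify_state()].
#' @return A list of class `state_graph`: `states` (named list of
#'   [classify_state()] results), `edges` (data.frame `sender`,
#'   `receiver`, `ligand`), `self_edges` (subset of edges), `has_cycle`
#'   (logical; cycle search on the digraph ignoring ligand identity, self
#'   loops included).
#' @export
build_state_graph <- function(named_levels, params = kinetic_params(),
                              thresholds = list(send_frac = 0.2,
                                                receive_frac = 0.2,
                                                block_cutoff = 0.5)) {
  stopifnot(length(named_levels) >= 1, !is.null(names(named_levels)))
  states <- lapply(named_levels, classify_state, params = params,
                   thresholds = thresholds)
  nodes <- names(states)
  edges <- do.call(rbind, lapply(nodes, function(s) {
    do.call(rbind, lapply(nodes, function(r) {
      lig <- intersect(states[[s]]$send_with, states[[r]]$receive_from)
      if (length(lig) == 0) return(NULL)
      data.frame(sender = s, receiver = r, ligand = lig,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(edges))
    edges <- data.frame(sender = character(0), receiver = character(0),
                        ligand = character(0))
  self_edges <- edges[edges$sender == edges$receiver, , drop = FALSE]
  structure(list(states = states, edges = edges, self_edges = self_edges,
                 has_cycle = digraph_has_cycle(nodes, edges)),
            class = "state_graph")
}

# DFS cycle detection on the (sender -> receiver) digraph
digraph_has_cycle <- function(nodes, edges) {
  if (nrow(edges) == 0) return(FALSE)
  adj <- split(edges$receiver, factor(edges$sender, levels = nodes))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  visit <- function(v) {
    color[v] <<- 1L
    for (w in unique(adj[[v]])) {
      if (color[w] == 1L) return(TRUE)
      if (color[w] == 0L && visit(w)) return(TRUE)
    }
    color[v] <<- 2L
    FALSE
  }
  for (v in nodes) if (color[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("Signaling-state graph: %d states, %d edges\n",
              length(x$states), nrow(x$edges)))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s --[%s]--> %s\n", x$edges$sender[i],
                  x$edges$ligand[i], x$edges$receiver[i]))
  cat(sprintf("  self-edges: %d; directed cycle: %s\n",
              nrow(x$self_edges), x$has_cycle))
  invisible(x)
}

#' Canonical endpoint states of the Notch1/Dll1/Jag1/Fringe system
#'
#' The enumerated limiting configurations — receptor or ligand in large
#' excess (`high`:`low` production ratio), with no Fringe, Lfng/Mfng or
#' Rfng — whose classified states form the canonical signaling-state
#' repertoire: exclusive receivers and senders, the Lfng receiver
#' restricted to Dll1, and the Lfng/Jag1 cell that sends with Jag1 while
#' receiving from Dll1.
#'
#' @param high,low production rates used for "much higher" and "much
#'   lower" expression.
#' @return A named list of [component_levels()] suitable for
#'   [build_state_graph()].
#' @export
canonical_states <- function(high = 10, low = 1) {
  none <- fringe_preset("none"); lfng <- fringe_preset("lfng")
  rfng <- fringe_preset("rfng")
  list(
    "N>Dll1"       = component_levels(high, c(Dll1 = low, Jag1 = 0), none),
    "Dll1>N"       = component_levels(low, c(Dll1 = high, Jag1 = 0), none),
    "N>Dll1+Lfng"  = component_levels(high, c(Dll1 = low, Jag1 = 0), lfng),
    "Dll1>N+Lfng"  = component_levels(low, c(Dll1 = high, Jag1 = 0), lfng),
    "N>Dll1+Rfng"  = component_levels(high, c(Dll1 = low, Jag1 = 0), rfng),
    "N>Jag1"       = component_levels(high, c(Dll1 = 0, Jag1 = low), none),
    "Jag1>N"       = component_levels(low, c(Dll1 = 0, Jag1 = high), none),
    "N>Jag1+Rfng"  = component_levels(high, c(Dll1 = 0, Jag1 = low), rfng),
    "Jag1>N+Rfng"  = component_levels(low, c(Dll1 = 0, Jag1 = high), rfng),
    "N>Jag1+Lfng"  = component_levels(high, c(Dll1 = 0, Jag1 = low), lfng),
    "Jag1>N+Lfng"  = component_levels(low, c(Dll1 = 0, Jag1 = high), lfng))
}
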