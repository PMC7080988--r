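# Marker-based classification of states and attractors into endothelial /
# mesenchymal / phalanx / stalk / tip cell classes, the nine-way disjoint
# partition, and Monte Carlo trap-space estimation.

BASE_LABELS <- c("EC", "MC", "Phalanx", "Stalk", "Tip")
NINE_CLASSES <- c("nECsnMCs", "EConly", "Phalanx", "nMCStalk", "MCStalk",
                  "nMCTip", "MCTip", "MCEConly", "MCsnECs")

#' Classifier configuration
#'
#' Marker predicates over node activities:
#' \itemize{
#'   \item EC: FLI1 and GATA2 active.
#'   \item MC: ZEB1, ZEB2, TWIST1 and (SNAI1 or SNAI2) active.
#'   \item Phalanx: EC with NRP1, CTNNB, SNAI1, SNAI2 all inactive.
#'   \item Tip: EC with NRP1 and ETS1 active.
#'   \item Stalk: EC with NRP1 inactive and a positive stalk marker.
#' }
#' The stalk-positive marker proxies JAG1 (which is not a network node).
#' The default, \code{"CTNNB_SNAI2"} (canonical-Wnt signaling on and the
#' activation factor SNAI2 expressed), was calibrated against the
#' published stalk signatures, trap fraction and mutation-response table;
#' the alternatives label the same wild-type attractors (except
#' \code{"LEF1"}) but respond differently to clamps. See the methods
#' vignette for the calibration.
#'
#' @param stalk_marker one of \code{"CTNNB_SNAI2"}, \code{"CTNNB_LEF1"},
#'   \code{"LEF1"}, \code{"CTNNB"}.
#' @return a list of class \code{endmt_classifier} holding one predicate
#'   (over a named 0/1 state vector) per base label.
#' @export
endmt_classifier <- function(stalk_marker = c("CTNNB_SNAI2", "CTNNB_LEF1",
                                              "LEF1", "CTNNB")) {
  stalk_marker <- match.arg(stalk_marker)
  stalk_pos <- switch(stalk_marker,
                      CTNNB_SNAI2 = function(v) v[["CTNNB"]] & v[["SNAI2"]],
                      CTNNB_LEF1 = function(v) v[["CTNNB"]] & v[["LEF1"]],
                      LEF1 = function(v) v[["LEF1"]],
                      CTNNB = function(v) v[["CTNNB"]])
  cfg <- structure(list(
    stalk_marker = stalk_marker,
    predicates = list(
      EC = function(v) v[["FLI1"]] & v[["GATA2"]],
      MC = function(v) v[["ZEB1"]] & v[["ZEB2"]] & v[["TWIST1"]] &
        (v[["SNAI1"]] | v[["SNAI2"]]),
      Phalanx = function(v) v[["FLI1"]] & v[["GATA2"]] & !v[["NRP1"]] &
        !v[["CTNNB"]] & !v[["SNAI1"]] & !v[["SNAI2"]],
      Stalk = function(v) v[["FLI1"]] & v[["GATA2"]] & !v[["NRP1"]] &
        stalk_pos(v),
      Tip = function(v) v[["FLI1"]] & v[["GATA2"]] & v[["NRP1"]] &
        v[["ETS1"]])),
    class = "endmt_classifier")
  # Phalanx forbids SNAI1/SNAI2 while MC requires one: jointly unsatisfiable
  probe <- expand_label_grid()
  both <- cfg$predicates$Phalanx(probe) & cfg$predicates$MC(probe)
  stopifnot(!any(both))
  cfg
}

# All 2^9 assignments of the marker nodes, as a list of logical columns.
#' @keywords internal
expand_label_grid <- function() {
  vars <- c("FLI1", "GATA2", "ZEB1", "ZEB2", "TWIST1", "SNAI1", "SNAI2",
            "NRP1", "CTNNB", "LEF1", "ETS1")
  rows <- seq_len(2^length(vars)) - 1L
  out <- lapply(seq_along(vars), function(k)
    bitwAnd(bitwShiftR(rows, k - 1L), 1L) == 1L)
  names(out) <- vars
  out
}

#' Label a single state
#'
#' @param network a \code{boolean_network} whose nodes include the marker
#'   nodes.
#' @param state a state in any representation.
#' @param config an \code{endmt_classifier}.
#' @return character vector: the subset of
#'   \code{c("EC","MC","Phalanx","Stalk","Tip")} whose predicates hold.
#' @export
label_state <- function(network, state, config = endmt_classifier()) {
  v <- as.logical(state_to_named(network, state))
  names(v) <- network$nodes
  hits <- vapply(config$predicates, function(p) isTRUE(p(v)), logical(1))
  BASE_LABELS[hits[BASE_LABELS]]
}

#' Label an attractor
#'
#' A label applies to a cyclic attractor only when it applies to every
#' state of the cycle (for both presence and absence markers). The base
#' label set is then collapsed onto the nine-way disjoint partition.
#'
#' @param network a \code{boolean_network}.
#' @param attractor a \code{bn_attractor}, or a vector/list of cycle
#'   states.
#' @param config an \code{endmt_classifier}.
#' @return list with \code{base} (character subset of the five labels) and
#'   \code{nine_class} (one of the nine class names).
#' @export
label_attractor <- function(network, attractor, config = endmt_classifier()) {
  states <- if (inherits(attractor, "bn_attractor")) attractor$states
            else attractor
  labs <- lapply(states, function(s) label_state(network, s, config))
  base <- Reduce(intersect, labs)
  list(base = base, nine_class = nine_class_of(base))
}

# The nine disjoint classes as a function of the base label set.
#' @keywords internal
nine_class_of <- function(base) {
  ec <- "EC" %in% base; mc <- "MC" %in% base
  if (!ec && !mc) return("nECsnMCs")
  if (mc && !ec) return("MCsnECs")
  if ("Phalanx" %in% base) return("Phalanx")
  if ("Stalk" %in% base) return(if (mc) "MCStalk" else "nMCStalk")
  if ("Tip" %in% base) return(if (mc) "MCTip" else "nMCTip")
  if (ec && mc) return("MCEConly")
  "EConly"
}

#' Classify a whole atlas
#'
#' Counts attractors per base label and per nine-way class, and reports for
#' each labeled group the nodes active in all member states and inactive in
#' all member states (the expression signature of the class).
#'
#' @param network a \code{boolean_network}.
#' @param atlas a \code{bn_atlas} of that network.
#' @param config an \code{endmt_classifier}.
#' @return a list of class \code{endmt_classification}:
#'   \code{per_attractor} (data.frame: attractor id, period, env_id,
#'   nine_class, one logical column per base label), \code{base_counts},
#'   \code{nine_counts} (named integer vectors), and \code{signatures}
#'   (per label/class: list with \code{common_active},
#'   \code{common_inactive})).
#' @export
classify_atlas <- function(network, atlas, config = endmt_classifier()) {
  n <- length(network$nodes)
  labs <- lapply(atlas$attractors, label_attractor, network = network,
                 config = config)
  base_mat <- vapply(labs, function(l) BASE_LABELS %in% l$base,
                     logical(length(BASE_LABELS)))
  rownames(base_mat) <- BASE_LABELS
  nine <- vapply(labs, `[[`, character(1), "nine_class")
  per_attractor <- data.frame(
    attractor = seq_along(atlas$attractors),
    period = vapply(atlas$attractors, `[[`, numeric(1), "period"),
    env_id = vapply(atlas$attractors, `[[`, numeric(1), "env_id"),
    nine_class = nine)
  for (lb in BASE_LABELS) per_attractor[[lb]] <- base_mat[lb, ]
  base_counts <- rowSums(base_mat)
  nine_counts <- vapply(NINE_CLASSES, function(cl) sum(nine == cl), numeric(1))
  groups <- c(as.list(as.data.frame(t(base_mat))),
              lapply(NINE_CLASSES, function(cl) nine == cl))
  names(groups) <- c(BASE_LABELS, NINE_CLASSES)
  signatures <- lapply(groups, function(member) {
    if (!any(member)) return(list(common_active = character(0),
                                  common_inactive = character(0)))
    states <- unlist(lapply(atlas$attractors[member], `[[`, "states"))
    bits <- vapply(states, int_to_bits, integer(n), n = n)
    act <- rowSums(bits) == ncol(bits)
    ina <- rowSums(bits) == 0L
    list(common_active = network$nodes[act],
         common_inactive = network$nodes[ina])
  })
  structure(list(per_attractor = per_attractor,
                 base_counts = base_counts,
                 nine_counts = nine_counts,
                 signatures = signatures,
                 stalk_marker = config$stalk_marker),
            class = "endmt_classification")
}

#' @export
print.endmt_classification <- function(x, ...) {
  cat("Attractor classification (stalk marker:", x$stalk_marker, ")\n")
  cat("  base labels: ",
      paste(sprintf("%s=%d", names(x$base_counts), x$base_counts),
            collapse = ", "), "\n")
  cat("  nine classes:",
      paste(sprintf("%s=%d", names(x$nine_counts), x$nine_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' Signature table in the style of a cell-type characteristics table
#'
#' @param classification an \code{endmt_classification}.
#' @param trap an optional trap-space estimate whose fractions are joined
#'   by group name.
#' @return data.frame with columns group, common_active, common_inactive
#'   (comma-separated) and, when \code{trap} is given, trap_fraction_pct.
#' @export
classification_table <- function(classification, trap = NULL) {
  grp <- names(classification$signatures)
  df <- data.frame(
    group = grp,
    common_active = vapply(classification$signatures, function(s)
      paste(s$common_active, collapse = ", "), character(1)),
    common_inactive = vapply(classification$signatures, function(s)
      paste(s$common_inactive, collapse = ", "), character(1)),
    row.names = NULL)
  if (!is.null(trap))
    df$trap_fraction_pct <- trap$fractions[grp] * 100
  df
}

#' Monte Carlo trap-space estimation
#'
#' Draws uniform random states from the full state space (source bits
#' included), iterates each to its attractor, labels the attractor, and
#' reports the fraction of the state space draining into each label and
#' nine-way class, with binomial standard errors.
#'
#' @param network a \code{boolean_network}.
#' @param config an \code{endmt_classifier}.
#' @param n_samples number of random states (the reference protocol uses
#'   1e7).
#' @param seed integer seed (recorded in the output).
#' @param atlas optional precomputed complete \code{bn_atlas}; computed
#'   when missing.
#' @return a list of class \code{endmt_trapspace}: \code{fractions} (named,
#'   in [0,1], over base labels and nine classes), \code{se} (binomial
#'   standard errors), \code{n_samples}, \code{seed}.
#' @export
estimate_trap_spaces <- function(network, config = endmt_classifier(),
                                 n_samples = 1e6, seed = 42L,
                                 atlas = NULL) {
  stopifnot(n_samples >= 1)
  if (is.null(atlas)) atlas <- enumerate_attractors(network)
  if (!atlas$complete)
    stop("trap-space estimation needs a complete atlas", call. = FALSE)
  eng <- engine_compile(network)
  n <- eng$n
  cls <- classify_atlas(network, atlas, config)
  # membership matrix per attractor over all groups
  groups <- c(BASE_LABELS, NINE_CLASSES)
  member <- matrix(FALSE, length(atlas$attractors), length(groups),
                   dimnames = list(NULL, groups))
  for (lb in BASE_LABELS) member[, lb] <- cls$per_attractor[[lb]]
  member[cbind(seq_len(nrow(member)),
               match(cls$per_attractor$nine_class, groups))] <- TRUE
  # known attractor states for the absorbing walk
  states <- unlist(lapply(atlas$attractors, `[[`, "states"))
  owner <- rep(seq_along(atlas$attractors),
               vapply(atlas$attractors, `[[`, numeric(1), "period"))
  ord <- order(states)
  set.seed(seed)
  hits <- numeric(length(groups))
  names(hits) <- groups
  done <- 0
  chunk <- 1e6
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    draws <- sample.int(2^n, m, replace = TRUE) - 1L
    res <- cpp_walk_to_known(eng$regs, eng$tables, n, as.integer(draws),
                             as.integer(states[ord]), as.integer(owner[ord]),
                             10000L)
    counts <- tabulate(res$attractor, nbins = length(atlas$attractors))
    hits <- hits + as.numeric(counts %*% member)
    done <- done + m
  }
  fr <- hits / n_samples
  structure(list(fractions = fr,
                 se = sqrt(pmax(fr * (1 - fr), 0) / n_samples),
                 n_samples = n_samples,
                 seed = seed),
            class = "endmt_trapspace")
}

#' @export
print.endmt_trapspace <- function(x, ...) {
  cat(sprintf("Trap-space estimate (%s samples, seed %d)\n",
              format(x$n_samples, big.mark = ","), x$seed))
  for (nm in names(x$fractions))
    cat(sprintf("  %-10s %9.5f%%  (se %.5f pp)\n", nm,
                100 * x$fractions[[nm]], 100 * x$se[[nm]]))
  invisible(x)
}
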