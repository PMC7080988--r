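# Robustness protocols: node-clamping mutants, update-rule bit-flip
# robustness, state-noise sensitivity, and perturbation-driven cell-fate
# transitions.

#' Clamp nodes (gain/loss-of-function mutations)
#'
#' Loss of function clamps a node's rule to the constant 0, gain of
#' function to the constant 1; all other rules are untouched. Rebuilding
#' from the original network undoes any clamp.
#'
#' @param network a \code{boolean_network}.
#' @param specs named integer/logical vector: \code{specs[node]} is 0
#'   (loss) or 1 (gain).
#' @return the clamped \code{boolean_network} (name suffixed with the
#'   specs).
#' @examples
#' mut <- apply_mutations(build_endmt_network(), c(ETS1 = 0, FLI1 = 0))
#' @export
apply_mutations <- function(network, specs) {
  if (length(specs) == 0L) return(network)
  if (is.null(names(specs)) || anyDuplicated(names(specs)))
    stop("mutation specs must be uniquely named by node", call. = FALSE)
  bad <- setdiff(names(specs), network$nodes)
  if (length(bad) > 0L)
    stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  vals <- as.integer(specs)
  if (any(is.na(vals)) || any(vals < 0L | vals > 1L))
    stop("mutation values must be 0 (loss) or 1 (gain)", call. = FALSE)
  exprs <- vapply(network$nodes, function(nd)
    network$rules[[nd]]$expression, character(1))
  exprs[names(specs)] <- as.character(vals)
  tag <- paste(sprintf("%s%s", names(specs), ifelse(vals == 1L, "+", "-")),
               collapse = "/")
  boolean_network(exprs, name = paste0(network$name, " [", tag, "]"),
                  nodes = network$nodes, provenance = network$provenance)
}

#' Full enumeration and classification of a mutant
#'
#' Clamps the given nodes, re-enumerates all attractors of the mutant
#' network exactly, classifies them, and compares the qualitative profile
#' (the set of nine classes with at least one attractor) against the wild
#' type.
#'
#' @param network the unperturbed \code{boolean_network}.
#' @param specs mutation specs as in \code{\link{apply_mutations}}.
#' @param config an \code{endmt_classifier}.
#' @param wt_classification optional precomputed wild-type
#'   \code{endmt_classification} for the profile comparison.
#' @return a list of class \code{endmt_mutant_report}: \code{specs},
#'   \code{n_attractors}, \code{nine_counts}, \code{base_counts},
#'   \code{fractions} (per nine class and base label, of the mutant's
#'   attractors), \code{profile} (nine classes present),
#'   \code{wild_type_effect} (profile equals wild type's),
#'   \code{lost_classes}, \code{gained_classes}.
#' @export
mutant_report <- function(network, specs, config = endmt_classifier(),
                          wt_classification = NULL) {
  mut <- apply_mutations(network, specs)
  atlas <- enumerate_attractors(mut)
  cls <- classify_atlas(mut, atlas, config)
  profile <- names(which(cls$nine_counts > 0))
  out <- list(specs = specs,
              n_attractors = length(atlas$attractors),
              nine_counts = cls$nine_counts,
              base_counts = cls$base_counts,
              fractions = c(cls$nine_counts, cls$base_counts) /
                length(atlas$attractors),
              profile = profile)
  if (!is.null(wt_classification)) {
    wt_profile <- names(which(wt_classification$nine_counts > 0))
    out$wild_type_effect <- setequal(profile, wt_profile)
    out$lost_classes <- setdiff(wt_profile, profile)
    out$gained_classes <- setdiff(profile, wt_profile)
  }
  structure(out, class = "endmt_mutant_report")
}

#' @export
print.endmt_mutant_report <- function(x, ...) {
  tag <- paste(sprintf("%s%s", names(x$specs),
                       ifelse(x$specs == 1, "+", "-")), collapse = "/")
  cat(sprintf("Mutant %s: %d attractors\n", tag, x$n_attractors))
  cat("  ", paste(sprintf("%s=%d", names(x$nine_counts), x$nine_counts),
                  collapse = ", "), "\n")
  if (!is.null(x$wild_type_effect))
    cat(if (x$wild_type_effect) "  qualitative profile unchanged\n"
        else paste0("  lost: ", paste(x$lost_classes, collapse = ", "), "\n"))
  invisible(x)
}

#' Double-mutant analysis
#'
#' @param network a \code{boolean_network}.
#' @param specs named vector of exactly two clamps, e.g.
#'   \code{c(ETS1 = 0, FLI1 = 0)}.
#' @param config an \code{endmt_classifier}.
#' @param wt_classification optional wild-type classification.
#' @return an \code{endmt_mutant_report}.
#' @export
double_mutant_analysis <- function(network, specs,
                                   config = endmt_classifier(),
                                   wt_classification = NULL) {
  if (length(specs) != 2L || anyDuplicated(names(specs)))
    stop("specs must clamp exactly two distinct nodes", call. = FALSE)
  mutant_report(network, specs, config, wt_classification)
}

#' Scan all single gain/loss-of-function mutations
#'
#' Enumerates and classifies the attractors of every single-node clamp (2
#' per node), flags which leave the nine-class qualitative profile
#' unchanged, and reports per-class robustness: the fraction of mutations
#' under which the class retains at least one attractor.
#'
#' @param network a \code{boolean_network}.
#' @param config an \code{endmt_classifier}.
#' @param nodes nodes to scan (default all); the full 29-node scan is
#'   exact but takes tens of minutes.
#' @param wt_classification optional precomputed wild-type classification.
#' @param progress print one line per mutant to stderr.
#' @return a list of class \code{endmt_mutation_scan}: \code{reports}
#'   (named list of \code{endmt_mutant_report}), \code{summary}
#'   (data.frame: mutation, n_attractors, wild_type_effect, lost classes),
#'   \code{n_wild_type_effect}, \code{robustness} (per nine class, the
#'   fraction of scanned mutations preserving it; the \code{wild_type}
#'   entry is the fraction with an unchanged profile).
#' @export
scan_single_mutations <- function(network, config = endmt_classifier(),
                                  nodes = network$nodes,
                                  wt_classification = NULL,
                                  progress = FALSE) {
  if (is.null(wt_classification)) {
    atlas <- enumerate_attractors(network)
    wt_classification <- classify_atlas(network, atlas, config)
  }
  specs <- list()
  for (nd in nodes) {
    specs[[paste0(nd, "-")]] <- stats::setNames(0L, nd)
    specs[[paste0(nd, "+")]] <- stats::setNames(1L, nd)
  }
  reports <- vector("list", length(specs))
  names(reports) <- names(specs)
  for (i in seq_along(specs)) {
    if (progress) message("mutant ", names(specs)[i])
    reports[[i]] <- mutant_report(network, specs[[i]], config,
                                  wt_classification)
  }
  wt_eff <- vapply(reports, `[[`, logical(1), "wild_type_effect")
  summary <- data.frame(
    mutation = names(specs),
    n_attractors = vapply(reports, `[[`, numeric(1), "n_attractors"),
    wild_type_effect = wt_eff,
    lost_classes = vapply(reports, function(r)
      paste(r$lost_classes, collapse = ", "), character(1)),
    row.names = NULL)
  keeps <- vapply(NINE_CLASSES, function(cl)
    mean(vapply(reports, function(r) r$nine_counts[[cl]] > 0, logical(1))),
    numeric(1))
  robustness <- c(wild_type = mean(wt_eff), keeps)
  structure(list(reports = reports, summary = summary,
                 n_wild_type_effect = sum(wt_eff),
                 robustness = robustness),
            class = "endmt_mutation_scan")
}

#' @export
print.endmt_mutation_scan <- function(x, ...) {
  cat(sprintf("Mutation scan: %d mutants, %d with unchanged profile (%.2f%%)\n",
              nrow(x$summary), x$n_wild_type_effect,
              100 * x$robustness[["wild_type"]]))
  invisible(x)
}

# ---- update-rule bit-flip robustness --------------------------------------

#' Robustness to single bit-flips in the update rules
#'
#' Draws network instances whose update rule differs from the original by
#' one flipped truth-table output bit (node chosen uniformly, then the
#' output row uniformly within that node's table — or a row uniform over
#' all rows pooled across nodes), enumerates and classifies each
#' instance's attractors, and aggregates per-class count statistics.
#'
#' @param network a \code{boolean_network}.
#' @param config an \code{endmt_classifier}.
#' @param n_instances number of perturbed instances.
#' @param seed integer seed (recorded in the output).
#' @param sampling \code{"node"} (uniform over nodes, then rows; default)
#'   or \code{"row"} (uniform over all rows pooled).
#' @return a list of class \code{endmt_flip_robustness}: \code{per_class}
#'   (data.frame: class, mean, sd, min, max of attractor counts over the
#'   instances), \code{counts} (instances x classes matrix),
#'   \code{flips} (data.frame: node, row flipped per instance),
#'   \code{seed}.
#' @export
rule_flip_robustness <- function(network, config = endmt_classifier(),
                                 n_instances = 100L, seed = 42L,
                                 sampling = c("node", "row")) {
  stopifnot(n_instances >= 1L)
  sampling <- match.arg(sampling)
  set.seed(seed)
  nodes <- network$nodes
  tab_len <- vapply(nodes, function(nd)
    length(network$rules[[nd]]$table), numeric(1))
  counts <- matrix(0L, n_instances, length(NINE_CLASSES),
                   dimnames = list(NULL, NINE_CLASSES))
  flips <- data.frame(node = character(n_instances), row = integer(n_instances))
  for (i in seq_len(n_instances)) {
    if (sampling == "node") {
      nd <- sample(nodes, 1L)
      row <- sample.int(tab_len[[nd]], 1L)
    } else {
      pooled <- sample.int(sum(tab_len), 1L)
      nd <- nodes[findInterval(pooled, cumsum(tab_len), left.open = TRUE) + 1L]
      row <- pooled - c(0, cumsum(tab_len))[match(nd, nodes)]
    }
    flips$node[i] <- nd
    flips$row[i] <- row
    pert <- flip_rule_bit(network, nd, row)
    atlas <- enumerate_attractors(pert)
    cls <- classify_atlas(pert, atlas, config)
    counts[i, ] <- cls$nine_counts
  }
  per_class <- data.frame(
    class = NINE_CLASSES,
    mean = colMeans(counts),
    sd = apply(counts, 2, stats::sd),
    min = apply(counts, 2, min),
    max = apply(counts, 2, max),
    row.names = NULL)
  structure(list(per_class = per_class, counts = counts, flips = flips,
                 seed = seed),
            class = "endmt_flip_robustness")
}

# Flip output bit `row` (1-based) of `node`'s truth table. The flipped rule
# is expressed as a sum-of-products over the table so it can be recompiled.
#' @keywords internal
flip_rule_bit <- function(network, node, row) {
  rule <- network$rules[[node]]
  tab <- rule$table
  tab[row] <- 1L - tab[row]
  exprs <- vapply(network$nodes, function(nd)
    network$rules[[nd]]$expression, character(1))
  exprs[[node]] <- table_to_expression(rule$regulators, tab)
  boolean_network(exprs, name = paste0(network$name, " [flip ", node, ":",
                                       row, "]"),
                  nodes = network$nodes, provenance = network$provenance)
}

# Sum-of-products rendering of a truth table (first regulator = MSB).
#' @keywords internal
table_to_expression <- function(regs, tab) {
  k <- length(regs)
  if (k == 0L) return(as.character(tab[1L]))
  ones <- which(tab == 1L) - 1L
  if (length(ones) == 0L) return("0")
  if (length(ones) == 2^k) return("1")
  terms <- vapply(ones, function(row) {
    lits <- vapply(seq_len(k), function(r) {
      bit <- bitwAnd(bitwShiftR(row, k - r), 1L)
      if (bit == 1L) regs[r] else paste0("!", regs[r])
    }, character(1))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

# ---- state-noise sensitivity ----------------------------------------------

#' Sensitivity of each update-rule component to state noise
#'
#' For each component f_i and each flip count k, estimates the fraction of
#' random states s for which flipping k uniformly chosen distinct bits of s
#' changes f_i's output.
#'
#' @param network a \code{boolean_network}.
#' @param n_samples_1bit samples at k = 1 (reference protocol: 500000).
#' @param n_samples_kbit samples per k for k >= 2 (reference: 20000).
#' @param k_range flip counts (default 1:15).
#' @param seed integer seed.
#' @return a list of class \code{endmt_sensitivity}: \code{sensitivity}
#'   (nodes x k matrix of fractions), \code{n_samples} (per k),
#'   \code{seed}.
#' @export
rule_sensitivity <- function(network, n_samples_1bit = 500000L,
                             n_samples_kbit = 20000L, k_range = 1:15,
                             seed = 42L) {
  eng <- engine_compile(network)
  n <- eng$n
  set.seed(seed)
  sens <- matrix(NA_real_, n, length(k_range),
                 dimnames = list(network$nodes, paste0("k", k_range)))
  n_used <- integer(length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    m <- if (k == 1L) n_samples_1bit else n_samples_kbit
    n_used[j] <- m
    s <- sample.int(2^n, m, replace = TRUE) - 1L
    # flip k distinct uniformly chosen bits per sample
    flips <- if (k == 1L) {
      2^(sample.int(n, m, replace = TRUE) - 1L)
    } else {
      vapply(seq_len(m), function(i) sum(2^(sample.int(n, k) - 1L)),
             numeric(1))
    }
    s2 <- bitwXor(as.integer(s), as.integer(flips))
    f1 <- cpp_step_batch(eng$regs, eng$tables, n, as.integer(s))
    f2 <- cpp_step_batch(eng$regs, eng$tables, n, s2)
    diff <- bitwXor(f1, f2)
    for (i in seq_len(n))
      sens[i, j] <- mean(bitwAnd(bitwShiftR(diff, i - 1L), 1L))
  }
  structure(list(sensitivity = sens, n_samples = n_used, k_range = k_range,
                 seed = seed),
            class = "endmt_sensitivity")
}

#' @export
print.endmt_sensitivity <- function(x, ...) {
  cat("Update-rule sensitivity to state noise (fractions):\n")
  print(round(x$sensitivity[, seq_len(min(4L, ncol(x$sensitivity))),
                            drop = FALSE], 4))
  invisible(x)
}

# ---- perturbation-driven cell-fate transitions ----------------------------

#' Map cell-fate transitions under transient perturbations
#'
#' For every attractor of the atlas and every 0/1 pattern over the
#' perturbation nodes, overwrites the pattern bits in a start state of the
#' attractor, lets the unperturbed dynamics converge, and classifies the
#' destination attractor. Counts are aggregated per (source class,
#' destination class) pair together with the nodes set active in all
#' contributing patterns ("+(...)") and inactive in all ("-(...)").
#'
#' @param network a \code{boolean_network}.
#' @param atlas a complete \code{bn_atlas} of it.
#' @param config an \code{endmt_classifier}.
#' @param perturb_nodes nodes whose activation state is overwritten
#'   (default: the seven microenvironmental inputs plus FLI1, GATA2 and
#'   VEGFA).
#' @param mode \code{"all"} (default): perturb every cycle state of each
#'   attractor (a pattern counts when it causes the transition from at
#'   least one of them); \code{"first"}: perturb only the canonical first
#'   state. The all-states protocol reproduces the reference transition
#'   table exactly; see the methods vignette.
#' @return a list of class \code{endmt_transitions}: \code{matrix} (9 x 9
#'   count matrix: patterns causing each source -> destination transition
#'   from at least one source-class attractor), \code{records} (data.frame
#'   source, destination, n_patterns, always_active, always_inactive),
#'   \code{mode}, \code{perturb_nodes}.
#' @export
perturbation_transitions <- function(network, atlas,
                                     config = endmt_classifier(),
                                     perturb_nodes = c(
                                       "DLL4", "FGF2", "FLI1", "GATA2",
                                       "HIF1a", "PDGF_AB", "TGFB", "VEGFA",
                                       "WNT5b", "WNT7a"),
                                     mode = c("all", "first")) {
  mode <- match.arg(mode)
  bad <- setdiff(perturb_nodes, network$nodes)
  if (length(bad) > 0L)
    stop("perturbation node(s) not in network: ",
         paste(bad, collapse = ", "), call. = FALSE)
  eng <- engine_compile(network)
  n <- eng$n
  cls <- classify_atlas(network, atlas, config)
  src_class <- cls$per_attractor$nine_class
  # known attractor states for the absorbing walk
  states <- unlist(lapply(atlas$attractors, `[[`, "states"))
  owner <- rep(seq_along(atlas$attractors),
               vapply(atlas$attractors, `[[`, numeric(1), "period"))
  ord <- order(states)
  pos <- match(perturb_nodes, network$nodes)
  np <- length(perturb_nodes)
  patterns <- seq_len(2^np) - 1L
  pat_bits <- vapply(seq_len(np), function(j)
    bitwAnd(bitwShiftR(patterns, j - 1L), 1L), integer(length(patterns)))
  clear_mask <- sum(2^(pos - 1L))
  # patterns as a full-state additive overlay
  overlay <- as.numeric(pat_bits %*% 2^(pos - 1L))
  # reached[pattern+1, class] per source attractor, pooled per class below
  hit <- array(FALSE, c(length(patterns), length(NINE_CLASSES),
                        length(NINE_CLASSES)),
               dimnames = list(NULL, NINE_CLASSES, NINE_CLASSES))
  for (a in seq_along(atlas$attractors)) {
    att <- atlas$attractors[[a]]
    starts0 <- if (mode == "first") att$states[1L] else att$states
    for (s0 in starts0) {
      base <- s0 - sum(int_to_bits(s0, n)[pos] * 2^(pos - 1L))
      perturbed <- base + overlay
      res <- cpp_walk_to_known(eng$regs, eng$tables, n,
                               as.integer(perturbed),
                               as.integer(states[ord]),
                               as.integer(owner[ord]), 10000L)
      dest <- cls$per_attractor$nine_class[res$attractor]
      sc <- match(src_class[a], NINE_CLASSES)
      dc <- match(dest, NINE_CLASSES)
      hit[cbind(seq_along(patterns), sc, dc)] <- TRUE
    }
  }
  counts <- apply(hit, c(2, 3), sum)
  records <- do.call(rbind, lapply(NINE_CLASSES, function(from)
    do.call(rbind, lapply(NINE_CLASSES, function(to) {
      pats <- which(hit[, from, to])
      if (length(pats) == 0L)
        return(data.frame(source = from, destination = to, n_patterns = 0L,
                          always_active = "", always_inactive = ""))
      pb <- pat_bits[pats, , drop = FALSE]
      data.frame(source = from, destination = to, n_patterns = length(pats),
                 always_active = paste(perturb_nodes[colSums(pb) == nrow(pb)],
                                       collapse = ", "),
                 always_inactive = paste(perturb_nodes[colSums(pb) == 0L],
                                         collapse = ", "))
    }))))
  structure(list(matrix = counts, records = records, mode = mode,
                 perturb_nodes = perturb_nodes),
            class = "endmt_transitions")
}

#' @export
print.endmt_transitions <- function(x, ...) {
  cat(sprintf("Cell-fate transition map (%s-state mode, %d perturbation nodes)\n",
              x$mode, length(x$perturb_nodes)))
  print(x$matrix)
  invisible(x)
}
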