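# One-call analysis driver: runs the full suite and writes a report bundle.

#' Run the full analysis suite
#'
#' Enumerates the attractor atlas, classifies it, estimates trap spaces,
#' derives the interaction graph and its feedback circuits, computes rule
#' sensitivities, and maps perturbation-driven cell-fate transitions,
#' writing each result as CSV/JSON into \code{out_dir}. The resolved
#' configuration (seed, sample sizes, classifier options, and a checksum
#' of the model rules) is written alongside the outputs so runs are fully
#' reproducible; identical configuration and seed give identical outputs.
#'
#' The single-mutation scan and rule-flip robustness are expensive and run
#' only when requested.
#'
#' @param network a \code{boolean_network} (default: the bundled EndMT
#'   model).
#' @param out_dir output directory (created if needed); NULL returns the
#'   results without writing.
#' @param seed integer seed for all stochastic stages.
#' @param trap_samples Monte Carlo sample count for trap-space estimation.
#' @param sens_samples_1bit,sens_samples_kbit sensitivity sample counts.
#' @param stalk_marker classifier option, see \code{\link{endmt_classifier}}.
#' @param mutation_scan run the 2n-clamp scan (slow).
#' @param flip_instances if > 0, run rule-flip robustness with this many
#'   instances.
#' @return (invisibly) a list with all result objects.
#' @export
run_full_report <- function(network = build_endmt_network(),
                            out_dir = NULL, seed = 42L,
                            trap_samples = 1e6,
                            sens_samples_1bit = 100000L,
                            sens_samples_kbit = 20000L,
                            stalk_marker = "CTNNB_LEF1",
                            mutation_scan = FALSE,
                            flip_instances = 0L) {
  config <- endmt_classifier(stalk_marker)
  rule_checksum <- model_checksum(network)
  message("[report] enumerating attractors")
  atlas <- enumerate_attractors(network)
  cls <- classify_atlas(network, atlas, config)
  message("[report] estimating trap spaces (", format(trap_samples), " samples)")
  trap <- estimate_trap_spaces(network, config, trap_samples, seed, atlas)
  message("[report] interaction graph and circuits")
  graph <- extract_interactions(network)
  circ <- functional_circuits(network, enumerate_circuits(graph))
  message("[report] rule sensitivity")
  sens <- rule_sensitivity(network, sens_samples_1bit, sens_samples_kbit,
                           seed = seed)
  message("[report] perturbation transitions")
  trans <- perturbation_transitions(network, atlas, config)
  scan <- NULL
  if (mutation_scan) {
    message("[report] single-mutation scan")
    scan <- scan_single_mutations(network, config,
                                  wt_classification = cls)
  }
  flip <- NULL
  if (flip_instances > 0L) {
    message("[report] rule-flip robustness")
    flip <- rule_flip_robustness(network, config, flip_instances, seed)
  }
  results <- list(atlas = atlas, classification = cls, trap = trap,
                  graph = graph, circuits = circ, sensitivity = sens,
                  transitions = trans, mutation_scan = scan,
                  flip_robustness = flip,
                  config = list(seed = seed, trap_samples = trap_samples,
                                stalk_marker = stalk_marker,
                                model = network$name,
                                rule_checksum = rule_checksum))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
    wr(cbind(model_checksum = rule_checksum,
             atlas_to_df(network, atlas)), "attractors.csv")
    wr(classification_table(cls, trap), "classification.csv")
    wr(graph$edges, "interactions.csv")
    wr(circ$table, "circuits.csv")
    sens_df <- cbind(data.frame(node = rownames(sens$sensitivity)),
                     as.data.frame(sens$sensitivity))
    wr(sens_df, "sensitivity.csv")
    wr(trans$records, "transitions.csv")
    if (!is.null(scan)) wr(scan$summary, "mutation_scan.csv")
    if (!is.null(flip)) wr(flip$per_class, "flip_robustness.csv")
    jsonlite::write_json(results$config,
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(interactions_to_dot(graph), file.path(out_dir, "interactions.dot"))
  }
  invisible(results)
}

# Checksum of the compiled truth tables so outputs cannot silently mix
# model variants.
#' @keywords internal
model_checksum <- function(network) {
  blob <- paste(vapply(network$nodes, function(nd) {
    r <- network$rules[[nd]]
    paste(nd, paste(r$regulators, collapse = ","),
          paste(r$table, collapse = ""))
  }, character(1)), collapse = ";")
  # small rolling hash; stable across platforms
  h <- 0
  for (ch in utf8ToInt(blob)) h <- (h * 131 + ch) %% 2^31
  sprintf("%08x", h)
}
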