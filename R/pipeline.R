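#' Simulate a dataset and write it to disk
#'
#' Generates a sample tree and copy-number profiles under the configured
#' mode and writes the haplotype-specific and total copy-number tables,
#' sampling times, true tree (Newick), event log (waiting-time mode) and a
#' JSON run manifest.
#'
#' @param config A \code{sim_config}.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed; recorded in the manifest.
#' @return Invisibly, the simulated objects.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tree <- sample_tree(config)
  space <- enumerate_states(config$c_max)
  if (config$mode == "direct") {
    model <- build_rate_matrix(config$u, config$e, space)
    sim <- simulate_direct(tree, model, m = config$m, config = config)
    events <- NULL
  } else {
    sim <- simulate_waiting_time(tree, config)
    events <- sim$events
    utils::write.table(events, file.path(out_dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_cn_table(sim$cn, file.path(out_dir, "cn_haplotype.tsv"))
  write_cn_table(as_total(sim$cn), file.path(out_dir, "cn_total.tsv"))
  timing <- sample_timing(tree$tip_times, config$patient_age)
  write_timing(timing, file.path(out_dir, "timing.tsv"))
  write_newick(tree, file.path(out_dir, "true_tree.nwk"))
  manifest <- list(tool = "cnphylo", action = "simulate", seed = seed,
                   config = config[setdiff(names(config), "bins")],
                   bins = as.list(config$bins),
                   version = as.character(utils::packageVersion("cnphylo")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

#' Infer a sample phylogeny from copy-number tables
#'
#' End-to-end inference: read the copy-number table (shifting relative
#' values by the normal ploidy when flagged), optionally merge bins into
#' segments, run the configured tree search (exhaustive for up to seven
#' samples in auto mode), and optionally bootstrap branch support and
#' reconstruct ancestral states. Results and a JSON manifest are written
#' to \code{out_dir}.
#'
#' @param cn_path Path to the copy-number TSV.
#' @param kind \code{"total"} or \code{"haplotype"}.
#' @param timing_path Optional path to the timing TSV.
#' @param out_dir Output directory.
#' @param relative Input values are relative (in -2..2); shift by +2.
#' @param merge Merge consecutive identical bins into segments first.
#' @param c_max Maximum total copy number for the model.
#' @param u0,e0 Fixed rates for same-time data.
#' @param u_init,e_init Initial rates for joint estimation.
#' @param config A \code{search_config}.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param ancestral Reconstruct ancestral states at unique variant sites.
#' @param seed RNG seed.
#' @return Invisibly, a list with the fit and any bootstrap/ancestral
#'   results.
#' @export
run_infer <- function(cn_path, kind = "total", timing_path = NULL, out_dir,
                      relative = FALSE, merge = TRUE, c_max = 6,
                      u0 = 0.001, e0 = 0.001, u_init = 5e-4, e_init = 5e-4,
                      config = search_config(), bootstrap = 0,
                      ancestral = TRUE, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cn <- read_cn_table(cn_path, kind)
  if (relative) cn <- absolutize_relative(cn)
  if (merge) cn <- merge_segments(cn)
  timing <- if (!is.null(timing_path)) read_timing(timing_path,
                                                   cn$sample_ids)
  space <- enumerate_states(c_max)
  fit <- search_ml(cn, space, timing, u0, e0, u_init, e_init, config)
  write_newick(fit$tree, file.path(out_dir, "ml_tree.nwk"))
  report <- data.frame(quantity = c("loglik", "u", "e", "mode"),
                       value = c(format(fit$loglik, digits = 10),
                                 format(fit$u, digits = 6),
                                 format(fit$e, digits = 6), fit$mode))
  utils::write.table(report, file.path(out_dir, "fit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  boot <- NULL
  if (bootstrap > 0) {
    boot <- bootstrap_trees(cn, space, timing, B = bootstrap,
                            config = config, u0 = u0, e0 = e0,
                            u_init = u_init, e_init = e_init)
    supp <- branch_support(fit, boot)
    utils::write.table(
      data.frame(node = names(supp) %||% seq_along(supp), support = supp),
      file.path(out_dir, "branch_support.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    annotated <- fit$tree$tree
    annotated$node.label <- sprintf("%g", supp)
    sub <- sub(";$", "", ape::write.tree(annotated))
    writeLines(sprintf("(%s:%.10g,normal:0);", sub, fit$tree$luca_len),
               file.path(out_dir, "ml_tree_support.nwk"))
  }
  anc <- NULL
  if (ancestral) {
    model <- build_rate_matrix(fit$u, fit$e, space)
    patterns <- compress_patterns(cn, space)
    anc <- joint_reconstruct(fit$tree, model, patterns)
    if (ncol(anc$states) > 0) {
      site_ix <- vapply(anc$pattern_index,
                        function(jp) which(patterns$site_of == jp)[1L],
                        integer(1))
      tab <- do.call(rbind, lapply(seq_len(nrow(anc$states)), function(r) {
        cns <- states_to_cn(anc$states[r, ], space)
        data.frame(node_id = rownames(anc$states)[r],
                   chrom = cn$sites$chrom[site_ix],
                   start = cn$sites$start[site_ix],
                   end = cn$sites$end[site_ix],
                   state = anc$states[r, ] - 1L,  # conventional 0-based id
                   c_A = cns$cA, c_B = cns$cB, total = cns$total)
      }))
      utils::write.table(tab, file.path(out_dir, "ancestral_states.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(tool = "cnphylo", action = "infer", seed = seed,
                   cn_path = cn_path, kind = kind,
                   timing_path = timing_path, relative = relative,
                   merge = merge, c_max = c_max, u0 = u0, e0 = e0,
                   u_init = u_init, e_init = e_init,
                   search = unclass(config), bootstrap = bootstrap,
                   version = as.character(utils::packageVersion("cnphylo")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, bootstrap = boot, ancestral = anc))
}

#' Compare an inferred tree with the truth
#'
#' Computes the evaluation metric set for simulation studies: normalized
#' RF distance, branch score distance, and (when rates/ages are available)
#' rate errors and LUCA-age error.
#'
#' @param true_tree A \code{cnp_tree} (or path to its Newick file).
#' @param inferred A \code{cn_fit} or \code{cnp_tree} (or Newick path).
#' @param true_u,true_e Optional true rates.
#' @param out_path Optional TSV output path.
#' @return Data frame of metrics.
#' @export
run_evaluate <- function(true_tree, inferred, true_u = NA, true_e = NA,
                         out_path = NULL) {
  tt <- if (is.character(true_tree)) read_newick(file = true_tree)
        else true_tree
  inf_fit <- if (is.character(inferred)) read_newick(file = inferred)
             else inferred
  p1 <- .as_phylo(tt); p2 <- .as_phylo(inf_fit)
  if (!setequal(p1$tip.label, p2$tip.label)) {
    stop("true and inferred trees have different tip sets", call. = FALSE)
  }
  metrics <- data.frame(
    metric = c("rf_normalized", "branch_score"),
    value = c(rf_normalized(tt, inf_fit), branch_score(tt, inf_fit))
  )
  if (inherits(inf_fit, "cn_fit") && !is.na(true_u)) {
    metrics <- rbind(metrics,
                     data.frame(metric = c("u_error", "e_error"),
                                value = c(inf_fit$u - true_u,
                                          inf_fit$e - true_e)))
  }
  if (inherits(inf_fit, "cn_fit") && !is.na(tt$A0) &&
      inf_fit$mode == "time_calibrated") {
    la_true <- attr(node_ages(tt), "luca_age")
    la_inf <- attr(node_ages(inf_fit$tree), "luca_age")
    metrics <- rbind(metrics,
                     data.frame(metric = "luca_age_error",
                                value = la_inf - la_true))
  }
  if (!is.null(out_path)) {
    utils::write.table(metrics, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  metrics
}
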