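#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates every stage on generated data: simulate proteins,
#' mutations and annotations; predict wild-type disorder profiles;
#' classify transitions; analyse MoRF impact; optionally curate
#' (redundancy clustering); compute the enrichment layer; and aggregate
#' everything into a machine-readable report whose percentages and folds
#' are recomputable from the counts it also contains.
#'
#' @param config a [sim_config()]; all randomness flows from its seed.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @param stages character subset of
#'   `c("simulate", "predict", "classify", "morf", "curate", "enrich")`;
#'   the report stage always runs. Later stages require earlier ones.
#' @param case,controls dataset labels for the enrichment comparisons.
#' @return report list (invisibly written to `out_dir/report.json` when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("simulate", "predict", "classify",
                                    "morf", "curate", "enrich"),
                         case = "DM", controls = c("Poly", "NES")) {
  stages <- match.arg(stages, several.ok = TRUE)
  log_line <- function(...) message("[idrmut] ", ...)
  log_line("seed = ", config$seed,
           "; threshold rule: ps >= 0.5 => disordered")

  sim <- gen_proteins(config)
  mut <- gen_mutations(sim$proteins, sim$labels, config)
  ann <- gen_annotations(sim$proteins, sim$labels, config)
  report <- list(
    parameters = list(
      seed = config$seed, window = config$window,
      steepness = config$steepness, n_proteins = config$n_proteins,
      threshold_rule = "ps >= 0.5 => disordered",
      datasets = lapply(config$datasets, function(d)
        list(n = d$n, p_do = d$p_do, p_od = d$p_od))))

  profiles <- NULL
  calls <- NULL
  if ("predict" %in% stages || "classify" %in% stages) {
    profiles <- profile_set(sim$proteins, window = config$window,
                            steepness = config$steepness)
    report$disorder <- list(
      mean_disorder_content = mean(vapply(profiles, disorder_content,
                                          numeric(1))))
  }
  if ("classify" %in% stages) {
    calls <- classify_dataset(mut$mutations, sim$proteins,
                              window = config$window,
                              steepness = config$steepness)
    counts <- transition_counts(calls)
    report$transitions <- lapply(split(counts, counts$dataset), function(r) {
      idr_n <- r[["D->O"]] + r[["D->D"]]
      or_n <- r[["O->D"]] + r[["O->O"]]
      list(n = r$n, d_to_o = r[["D->O"]], d_to_d = r[["D->D"]],
           o_to_d = r[["O->D"]], o_to_o = r[["O->O"]],
           idr_n = idr_n, or_n = or_n,
           idr_pct = 100 * idr_n / r$n,
           do_pct_of_idr = if (idr_n > 0) 100 * r[["D->O"]] / idr_n else NA,
           od_pct_of_or = if (or_n > 0) 100 * r[["O->D"]] / or_n else NA)
    })
    report$enrichment <- list()
    for (ctrl in controls) {
      tabs <- transition_tables(counts, case, ctrl)
      report$enrichment[[paste0(case, "_vs_", ctrl)]] <- list(
        idr = enrichment_row(tabs$idr), or = enrichment_row(tabs$or))
    }
    report$delta_ps <- lapply(
      split(delta_ps_summary(calls),
            delta_ps_summary(calls)$dataset),
      function(r) list(n = r$n, min = r$min, max = r$max,
                       excess_kurtosis = r$excess_kurtosis))
  }
  if ("morf" %in% stages) {
    train <- gen_morf_training(seed = config$seed + 3L)
    model <- fit_qd(train$x, train$labels)
    impact <- morf_impact_dataset(mut$mutations, sim$proteins,
                                  model = model,
                                  window = config$window,
                                  steepness = config$steepness)
    report$morf <- lapply(split(impact, impact$dataset), function(d) {
      as.list(table(factor(d$morf_impact,
                           c("lost", "gained", "present_no_change",
                             "absent"))))
    })
  }
  if ("curate" %in% stages) {
    cl <- cluster_redundant(sim$proteins, identity_threshold = 40,
                            seed = config$seed)
    out <- flag_outliers(mut$mutations, "top_k", 1L)
    report$curation <- list(
      n_clusters = length(cl$representatives),
      n_proteins = length(cl$cluster),
      outlier_protein = out$flagged[[1]],
      outlier_removed_fraction = out$removed_fraction)
  }
  if ("enrich" %in% stages && !is.null(calls)) {
    ann$dataset <- case
    norm <- normalize_ft(ann, min_count = 5L, count_dataset = case)
    strat <- calls
    strat$stratum <- ifelse(strat$wt_ps >= 0.5, "IDR", "OR")
    fte <- ft_enrichment(norm, strat, "IDR", "OR", level = "level1")
    report$ft_enrichment <- lapply(seq_len(nrow(fte)), function(i) {
      r <- fte[i, ]
      list(feature = r$label, a = r$a, b = r$b, c = r$c, d = r$d,
           fold = r$fold, fold_se = r$fold_se, p_raw = r$p_raw,
           p_adj = r$p_adj)
    })
    # pooled overlap enrichment: IDR vs OR mutations hitting any feature
    hit <- overlaps_any(strat, norm)
    tab <- c(sum(hit & strat$stratum == "IDR"),
             sum(!hit & strat$stratum == "IDR"),
             sum(hit & strat$stratum == "OR"),
             sum(!hit & strat$stratum == "OR"))
    report$annotation_overlap <- enrichment_row(tab)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$proteins, file.path(out_dir, "proteins.fasta"))
    write_mutations(mut$mutations, file.path(out_dir, "mutations.tsv"))
    write_mutations(mut$truth, file.path(out_dir, "mutations_truth.tsv"))
    write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(calls)) {
      write.table(calls, file.path(out_dir, "transition_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_report(report, file.path(out_dir, "report.json"))
    log_line("artifacts written to ", out_dir)
  }
  invisible(report)
}

enrichment_row <- function(tab) {
  r <- enrichment_result(tab)
  list(a = r$a, b = r$b, c = r$c, d = r$d, fold = r$fold,
       fold_se = r$fold_se, p_raw = r$p_raw)
}

#' Write a report (or any list) as JSON
#'
#' @param report list, e.g. from [run_pipeline()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a YAML run configuration into a `sim_config`
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an
#' error so typos do not silently fall back to defaults.
#'
#' @param path YAML file.
#' @return a `sim_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(sim_config, raw)
}
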